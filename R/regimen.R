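#' Dose events and regimens
#'
#' A `dose_event` is a single administration: an IV zero-order infusion
#' (requires a positive `duration`) or an oral dose (no duration; absorption
#' is first-order from a depot after the absorption lag). A `regimen` is a
#' non-empty, time-ordered list of dose events; concentrations from multiple
#' events superpose because the model is linear.
#'
#' @param route `"iv_infusion"` or `"oral"`.
#' @param amount Dose amount in mg, > 0.
#' @param time Administration start time in h, >= 0.
#' @param duration Infusion length in h (IV only), > 0.
#' @return `dose_event()` returns a `dose_event`; `regimen()` a `regimen`.
#' @examples
#' iv <- regimen(dose_event("iv_infusion", 130, time = 0, duration = 1))
#' po <- regimen_repeat(dose_event("oral", 600, time = 0), n_doses = 3,
#'                      interval = 24)
#' @export
dose_event <- function(route = c("iv_infusion", "oral"), amount, time = 0,
                       duration = NULL) {
  route <- match.arg(route)
  if (!is.finite(amount) || amount <= 0) stop("dose amount must be > 0")
  if (!is.finite(time) || time < 0) stop("dose time must be >= 0")
  if (route == "iv_infusion") {
    if (is.null(duration) || !is.finite(duration) || duration <= 0)
      stop("iv_infusion requires a positive infusion duration")
  } else if (!is.null(duration)) {
    stop("oral doses take no infusion duration")
  }
  structure(list(route = route, amount = as.numeric(amount),
                 time = as.numeric(time),
                 duration = if (is.null(duration)) NA_real_ else as.numeric(duration)),
            class = "dose_event")
}

#' @rdname dose_event
#' @param ... `dose_event` objects (or a single list of them).
#' @export
regimen <- function(...) {
  events <- list(...)
  if (length(events) == 1 && !inherits(events[[1]], "dose_event"))
    events <- events[[1]]
  if (!length(events)) stop("a regimen must contain at least one dose event")
  if (!all(vapply(events, inherits, logical(1), "dose_event")))
    stop("all regimen elements must be dose_event objects")
  events <- events[order(vapply(events, `[[`, numeric(1), "time"))]
  structure(list(events = events), class = "regimen")
}

#' @rdname dose_event
#' @param event A template `dose_event` given at its own `time`.
#' @param n_doses Number of administrations, >= 1.
#' @param interval Spacing between administrations in h (default 24, i.e.
#'   once daily with complete washout assumed in the exposure layer).
#' @export
regimen_repeat <- function(event, n_doses, interval = 24) {
  stopifnot(inherits(event, "dose_event"))
  if (!is.finite(n_doses) || n_doses < 1 || n_doses != round(n_doses))
    stop("n_doses must be a positive integer")
  if (interval <= 0) stop("interval must be > 0")
  evs <- lapply(seq_len(n_doses) - 1, function(k) {
    e <- event
    e$time <- event$time + k * interval
    e
  })
  regimen(evs)
}

#' @export
print.regimen <- function(x, ...) {
  cat("Dosing regimen (", length(x$events), " event",
      if (length(x$events) > 1) "s", "):\n", sep = "")
  for (e in x$events)
    cat(sprintf("  t = %g h: %s %g mg%s\n", e$time, e$route, e$amount,
                if (e$route == "iv_infusion")
                  sprintf(" over %g h", e$duration) else ""))
  invisible(x)
}

# route context of a regimen: "iv", "oral", or "mixed"
.regimen_route <- function(reg) {
  routes <- unique(vapply(reg$events, `[[`, character(1), "route"))
  if (identical(routes, "iv_infusion")) "iv"
  else if (identical(routes, "oral")) "oral"
  else "mixed"
}
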