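#' Predict unbound docetaxel concentrations for a regimen
#'
#' Solves the linear compartmental system exactly for an arbitrary sequence
#' of IV infusions and oral doses and returns the unbound plasma
#' concentration at the requested times. Disposition is mammillary with up to
#' two peripheral compartments (peripheral compartments with zero
#' inter-compartmental clearance are removed from the state, so one- and
#' two-compartment models are exact special cases). IV doses enter the
#' central compartment at the constant rate `amount / duration`; an oral dose
#' places `amount * f_oral` mg in a depot at `time + tlag`, from which it
#' transfers to the central compartment at rate `ka`.
#'
#' The solution uses the eigendecomposition of the (route-appropriate) rate
#' matrix, so it is exact for the linear system at any output grid — the
#' output grid is a reporting grid, not an integration step. A dense
#' matrix-exponential propagation ([Matrix::expm()]) is used as a fallback in
#' the rare case of a numerically defective eigenbasis.
#'
#' Unit contract: concentrations are `amount-in-central [mg] * 1000 / v1_u [L]`,
#' i.e. ng/mL for mg doses and litre volumes.
#'
#' @param params A [structural_params()] object.
#' @param regimen A [regimen()].
#' @param times Numeric vector of output times (h), non-negative and
#'   non-decreasing.
#' @return Numeric vector of unbound concentrations (ng/mL), one per time.
#' @examples
#' p <- default_population_model()$theta
#' reg <- regimen(dose_event("iv_infusion", 130, time = 0, duration = 1))
#' cu <- predict_unbound(p, reg, times = seq(0, 24, by = 0.05))
#' @export
predict_unbound <- function(params, regimen, times) {
  validate_structural_params(params)
  if (!inherits(regimen, "regimen")) stop("regimen must be a regimen object")
  times <- as.numeric(times)
  if (!length(times) || any(!is.finite(times))) stop("times must be finite")
  if (any(times < 0)) stop("times must be >= 0")
  if (is.unsorted(times)) stop("times must be non-decreasing")

  .predict_unbound_fast(params, regimen, times)
}

# prediction core without argument validation (hot path for estimation)
.predict_unbound_fast <- function(params, regimen, times) {
  has_oral <- any(vapply(regimen$events, `[[`, character(1), "route") == "oral")
  sys <- .pk_system(params, with_depot = has_oral)
  dec <- tryCatch(.pk_eigen(sys$A), error = function(e) NULL)
  if (is.null(dec)) {
    amt_central <- .predict_expm(sys, params, regimen, times)
  } else {
    amt_central <- .predict_eigen(sys, dec, params, regimen, times)
  }
  pmax(amt_central * 1000 / params$v1_u, 0)
}

# state layout and rate matrix; state = (depot?, central, p2?, p3?)
.pk_system <- function(p, with_depot) {
  use2 <- p$q2_u > 0
  use3 <- p$q3_u > 0
  n <- 1L + with_depot + use2 + use3
  i_dep <- if (with_depot) 1L else NA_integer_
  i_c <- 1L + as.integer(with_depot)
  i_p2 <- if (use2) i_c + 1L else NA_integer_
  i_p3 <- if (use3) i_c + 1L + as.integer(use2) else NA_integer_
  A <- matrix(0, n, n)
  k10 <- p$cl_u / p$v1_u
  A[i_c, i_c] <- -k10
  if (use2) {
    k12 <- p$q2_u / p$v1_u; k21 <- p$q2_u / p$v2_u
    A[i_c, i_c] <- A[i_c, i_c] - k12
    A[i_p2, i_c] <- k12
    A[i_c, i_p2] <- k21
    A[i_p2, i_p2] <- -k21
  }
  if (use3) {
    k13 <- p$q3_u / p$v1_u; k31 <- p$q3_u / p$v3_u
    A[i_c, i_c] <- A[i_c, i_c] - k13
    A[i_p3, i_c] <- k13
    A[i_c, i_p3] <- k31
    A[i_p3, i_p3] <- -k31
  }
  if (with_depot) {
    A[i_dep, i_dep] <- -p$ka
    A[i_c, i_dep] <- p$ka
  }
  list(A = A, n = n, i_dep = i_dep, i_c = i_c)
}

.pk_eigen <- function(A) {
  e <- eigen(A)
  lam <- e$values
  V <- e$vectors
  # defective or near-defective basis -> signal for the expm fallback
  scale <- max(abs(lam), 1e-12)
  if (length(lam) > 1) {
    gaps <- abs(outer(lam, lam, "-"))
    diag(gaps) <- Inf
    if (min(gaps) < 1e-9 * scale) stop("near-repeated eigenvalues")
  }
  Vinv <- solve(V)
  list(lam = lam, V = V, Vinv = Vinv)
}

# phi1(lambda, tau) = (exp(lambda * tau) - 1) / lambda, with the tau limit
.phi1 <- function(lam, tau) {
  if (abs(lam) < 1e-12) tau * (1 + lam * tau / 2) else (exp(lam * tau) - 1) / lam
}

.predict_eigen <- function(sys, dec, params, regimen, times) {
  out <- numeric(length(times))
  row_c <- dec$V[sys$i_c, ]
  for (ev in regimen$events) {
    if (ev$amount == 0) next
    if (ev$route == "oral") {
      t0 <- ev$time + params$tlag
      x0 <- numeric(sys$n)
      x0[sys$i_dep] <- ev$amount * params$f_oral
      w <- row_c * (dec$Vinv %*% x0)[, 1]
      sel <- times >= t0
      if (any(sel)) {
        tt <- times[sel] - t0
        out[sel] <- out[sel] + Re(colSums(w * exp(outer(dec$lam, tt))))
      }
    } else {
      t0 <- ev$time
      t1 <- ev$time + ev$duration
      b <- numeric(sys$n)
      b[sys$i_c] <- ev$amount / ev$duration
      w <- row_c * (dec$Vinv %*% b)[, 1]
      phi_end <- vapply(dec$lam, .phi1, complex(1), tau = ev$duration)
      during <- times >= t0 & times < t1
      after <- times >= t1
      if (any(during)) {
        tt <- times[during] - t0
        vals <- vapply(seq_along(tt), function(i)
          sum(w * vapply(dec$lam, .phi1, complex(1), tau = tt[i])), complex(1))
        out[during] <- out[during] + Re(vals)
      }
      if (any(after)) {
        tt <- times[after] - t1
        out[after] <- out[after] + Re(colSums((w * phi_end) * exp(outer(dec$lam, tt))))
      }
    }
  }
  out
}

# fallback: piecewise-constant-input propagation with an augmented matrix
# exponential, exact up to expm() accuracy even for a defective rate matrix
.predict_expm <- function(sys, params, regimen, times) {
  bolus <- list()   # time -> state increment
  rates <- list()   # (start, end, rate) infusion windows
  for (ev in regimen$events) {
    if (ev$amount == 0) next
    if (ev$route == "oral") {
      bolus[[length(bolus) + 1L]] <- list(time = ev$time + params$tlag,
                                          amt = ev$amount * params$f_oral)
    } else {
      rates[[length(rates) + 1L]] <- list(start = ev$time,
                                          end = ev$time + ev$duration,
                                          rate = ev$amount / ev$duration)
    }
  }
  brk <- sort(unique(c(0, times,
                       vapply(bolus, `[[`, numeric(1), "time"),
                       unlist(lapply(rates, function(r) c(r$start, r$end))))))
  x <- numeric(sys$n)
  out <- numeric(length(times))
  t_cur <- brk[1]
  for (b in bolus) if (b$time <= t_cur) x[sys$i_dep] <- x[sys$i_dep] + b$amt
  out[times == t_cur] <- x[sys$i_c]
  for (tn in brk[-1]) {
    h <- tn - t_cur
    rate <- 0
    mid <- (t_cur + tn) / 2
    for (r in rates) if (mid >= r$start && mid < r$end) rate <- rate + r$rate
    aug <- rbind(cbind(sys$A, c(rep(0, sys$i_c - 1), rate,
                                rep(0, sys$n - sys$i_c))),
                 rep(0, sys$n + 1))
    ph <- as.matrix(Matrix::expm(aug * h))
    x <- (ph %*% c(x, 1))[seq_len(sys$n), 1]
    for (b in bolus) if (b$time == tn) x[sys$i_dep] <- x[sys$i_dep] + b$amt
    out[times == tn] <- x[sys$i_c]
    t_cur <- tn
  }
  out
}

#' Concentration-time profile for both observables
#'
#' Convenience wrapper around [predict_unbound()] that also returns the total
#' concentration obtained through the route-specific fraction unbound.
#'
#' @inheritParams predict_unbound
#' @param route_context `"iv"` or `"oral"`, selecting which fraction unbound
#'   converts unbound to total concentration. Defaults to the route of the
#'   regimen; must be given explicitly for mixed-route regimens.
#' @return A list of class `conc_profile` with elements `times`, `c_unbound`,
#'   `c_total` (both ng/mL) and `route_context`.
#' @export
predict_profile <- function(params, regimen, times, route_context = NULL) {
  if (is.null(route_context)) {
    route_context <- .regimen_route(regimen)
    if (route_context == "mixed")
      stop("route_context must be given for mixed-route regimens")
  }
  route_context <- match.arg(route_context, c("iv", "oral"))
  if (is.unsorted(times, strictly = TRUE))
    stop("profile times must be strictly increasing")
  cu <- predict_unbound(params, regimen, times)
  fu <- if (route_context == "iv") params$fu_iv else params$fu_po
  structure(list(times = as.numeric(times), c_unbound = cu,
                 c_total = total_from_unbound(cu, fu),
                 route_context = route_context),
            class = "conc_profile")
}

#' @export
print.conc_profile <- function(x, ...) {
  cat("Concentration profile (", x$route_context, " fu context): ",
      length(x$times), " times from ", min(x$times), " to ", max(x$times),
      " h; Cmax unbound ", signif(max(x$c_unbound), 4), " ng/mL\n", sep = "")
  invisible(x)
}

#' Convert between unbound and total quantities
#'
#' With constant binding, the unbound concentration equals the total
#' concentration multiplied by the fraction unbound. These helpers apply that
#' relation to concentrations, clearance and steady-state volume:
#' `c_total = c_unbound / fu`, `cl_total = cl_u * fu`, and
#' `vss_total = (v1_u + v2_u + v3_u) * fu`.
#'
#' @param c_unbound Numeric vector of unbound concentrations (ng/mL), >= 0.
#' @param fu Fraction unbound, in (0, 1].
#' @return Numeric vector/scalar in total-concentration units.
#' @examples
#' total_cl_from_unbound(8570, 0.0067)  # about 57.4 L/h
#' @export
total_from_unbound <- function(c_unbound, fu) {
  .check_fu(fu)
  if (any(c_unbound < 0, na.rm = TRUE)) stop("concentrations must be >= 0")
  c_unbound / fu
}

#' @rdname total_from_unbound
#' @param cl_u Unbound clearance (L/h), > 0.
#' @export
total_cl_from_unbound <- function(cl_u, fu) {
  .check_fu(fu)
  if (!is.finite(cl_u) || cl_u <= 0) stop("cl_u must be > 0")
  cl_u * fu
}

#' @rdname total_from_unbound
#' @param params A [structural_params()] object.
#' @param route `"iv"` or `"oral"`, selecting the fraction unbound.
#' @export
total_vss <- function(params, route = c("iv", "oral")) {
  validate_structural_params(params)
  route <- match.arg(route)
  fu <- if (route == "iv") params$fu_iv else params$fu_po
  (params$v1_u + params$v2_u + params$v3_u) * fu
}

.check_fu <- function(fu) {
  if (!is.numeric(fu) || length(fu) != 1 || !is.finite(fu) ||
      fu <= 0 || fu > 1)
    stop("fu must be a single fraction in (0, 1]")
  invisible(fu)
}
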