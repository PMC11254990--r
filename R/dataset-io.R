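#' Read and write NONMEM-convention PK datasets
#'
#' Datasets are plain CSV with a header and the columns
#' `ID, OCC, ROUTE, TIME, EVID, AMT, RATE, DV, DVID, BLQ, LLOQ, L2, MDV`
#' (`EVID` 1 = dose row, 0 = observation; `ROUTE`/`OCC` 1 = IV, 2 = oral;
#' `DVID` 1 = total, 2 = unbound, 0 = dose row; `L2` > 0 links the two
#' observations from one blood sample; `MDV` 1 marks a row excluded from the
#' likelihood). The round trip is lossless; `NA` is written as an empty
#' field.
#'
#' `read_dataset()` validates the file: missing columns are named, rows with
#' non-numeric values are reported by row number, and every observation row
#' must be preceded (in time) by a dose row of the same subject and occasion.
#'
#' @param path CSV file path.
#' @return `read_dataset()` returns a `pk_dataset`; `write_dataset()` its
#'   `path`, invisibly.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.pk_dataset_cols(), names(raw))
  if (length(miss))
    stop("dataset is missing required column(s): ", paste(miss, collapse = ", "))
  raw <- raw[, .pk_dataset_cols()]
  for (cn in .pk_dataset_cols()) {
    v <- raw[[cn]]
    if (is.character(v)) {
      v[v %in% c("", ".", "NA")] <- NA
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(!is.na(v) & is.na(vn))
      if (length(bad))
        stop("non-numeric value in column ", cn, " at data row(s) ",
             paste(utils::head(bad, 5), collapse = ", "))
      raw[[cn]] <- vn
    }
  }
  validate_pk_dataset(raw)
}

#' @rdname read_dataset
#' @param data A `pk_dataset`.
#' @export
write_dataset <- function(data, path) {
  data <- .as_pk_dataset(data)
  utils::write.csv(as.data.frame(data)[, .pk_dataset_cols()], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname read_dataset
#' @export
validate_pk_dataset <- function(data) {
  data <- .as_pk_dataset(data)
  obs <- which(data$EVID == 0)
  if (length(obs)) {
    bad <- vapply(obs, function(r) {
      !any(data$EVID == 1 & data$ID == data$ID[r] & data$OCC == data$OCC[r] &
             data$TIME <= data$TIME[r])
    }, logical(1))
    if (any(bad))
      stop("observation row(s) without a preceding dose on the same ",
           "occasion: data row(s) ",
           paste(utils::head(obs[bad], 5), collapse = ", "))
  }
  na_dv <- which(data$EVID == 0 & is.na(data$DV) & data$MDV == 0)
  if (length(na_dv))
    stop("observation row(s) with missing DV but MDV = 0: data row(s) ",
         paste(utils::head(na_dv, 5), collapse = ", "))
  data
}

#' Read and write PTA grids and decision reports
#'
#' The PTA grid is tidy CSV (`arm, dose_mg, n_doses, ec_ng_ml, pta_pct,
#' n_sim`) with the simulation settings embedded as commented header lines;
#' the decision report is JSON.
#'
#' @param grid A `pta_grid`. @param path File path.
#' @return Readers return the object; writers the `path`, invisibly.
#' @export
write_pta_grid <- function(grid, path) {
  stopifnot(inherits(grid, "pta_grid"))
  cfg <- attr(grid, "config")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(cfg)) {
    writeLines(paste0("# sim_config: ", jsonlite::toJSON(unclass(cfg),
                                                         auto_unbox = TRUE,
                                                         digits = NA)), con)
  }
  utils::write.csv(as.data.frame(grid), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pta_grid
#' @export
read_pta_grid <- function(path) {
  if (!file.exists(path)) stop("grid file not found: ", path)
  first <- readLines(path, n = 1)
  cfg <- NULL
  if (startsWith(first, "# sim_config: ")) {
    cfg <- jsonlite::fromJSON(sub("^# sim_config: ", "", first))
    cfg$n_doses_list <- as.integer(cfg$n_doses_list)
    cfg <- structure(cfg, class = "sim_config")
  }
  grid <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("arm", "dose_mg", "n_doses", "ec_ng_ml", "pta_pct", "n_sim")
  miss <- setdiff(need, names(grid))
  if (length(miss))
    stop("grid file is missing column(s): ", paste(miss, collapse = ", "))
  attr(grid, "config") <- cfg
  class(grid) <- c("pta_grid", "data.frame")
  grid
}

#' @rdname write_pta_grid
#' @param report A `decision_report`.
#' @export
write_decision_report <- function(report, path) {
  stopifnot(inherits(report, "decision_report"))
  out <- list(classification = report$classification,
              pta_threshold_pct = report$threshold_pct,
              seed = report$seed,
              boundaries = report$boundaries)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' Render a human-readable feasibility summary
#'
#' Formats the PTA grid as one dose-by-EC table per number of doses,
#' followed by the per-regimen EC boundaries and the classification.
#'
#' @param grid A `pta_grid`.
#' @param report A `decision_report` (computed from the grid if omitted).
#' @return A character vector of report lines, invisibly; also printed.
#' @export
render_report <- function(grid, report = NULL) {
  stopifnot(inherits(grid, "pta_grid"))
  if (is.null(report)) report <- classify_decision(grid)
  lines <- character(0)
  push <- function(...) lines <<- c(lines, paste0(...))
  push("Oral docetaxel + encequidar feasibility versus IV docetaxel")
  push("PTA (%) by dose and effective concentration (ng/mL)")
  g <- grid[grid$arm == "odox_e", ]
  for (nd in sort(unique(g$n_doses))) {
    push("")
    push(sprintf("-- %d dose(s) --", nd))
    sub <- g[g$n_doses == nd, ]
    tab <- stats::xtabs(pta_pct ~ dose_mg + ec_ng_ml, data = sub)
    push(utils::capture.output(print(round(tab, 1))))
  }
  comp <- grid[grid$arm == "comparator", ]
  if (nrow(comp)) {
    push("")
    push(sprintf("Comparator (no P-gp inhibitor, F = %s at %g mg): max PTA %.1f%%",
                 format(attr(grid, "config")$comparator_f %||% NA),
                 comp$dose_mg[1], max(comp$pta_pct)))
  }
  push("")
  push(utils::capture.output(print(report)))
  writeLines(lines)
  invisible(lines)
}
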