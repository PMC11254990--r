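#' Simulation configuration for the feasibility framework
#'
#' Bundles the simulation conditions of the dose-feasibility assessment:
#' a 130 mg / 1 h IV reference infusion, candidate oral doses of 400-600 mg
#' in 50 mg increments given once, twice or three times (24 h apart, complete
#' washout), candidate effective concentrations of 0.1-1.0 ng/mL in 0.1
#' steps, 1000 virtual patients acting as their own control, a 20%
#' non-inferiority margin on the IV exposure target, an 80% PTA threshold,
#' and an 8% bioavailability comparator (oral docetaxel without encequidar)
#' at 600 mg. Profiles are simulated over a 24-h horizon on a 3-minute
#' reporting grid.
#'
#' @param iv_dose IV reference dose (mg). @param iv_infusion_duration h.
#' @param oral_doses Candidate oral doses (mg).
#' @param ec_grid Effective concentrations (ng/mL), ascending and positive.
#' @param n_doses_list Numbers of repeated oral doses evaluated.
#' @param n_patients Virtual cohort size.
#' @param margin Non-inferiority margin as a fraction in [0, 1).
#' @param pta_threshold PTA pass threshold in percent, (0, 100].
#' @param comparator_f Bioavailability of the no-inhibitor comparator.
#' @param comparator_dose Comparator dose (mg).
#' @param horizon,step Simulation length and reporting step (h).
#' @param seed Integer seed for the virtual cohort.
#' @param aucoec_mode Passed to [compute_aucoec()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(iv_dose = 130, iv_infusion_duration = 1,
                       oral_doses = seq(400, 600, by = 50),
                       ec_grid = seq(0.1, 1.0, by = 0.1),
                       n_doses_list = 1:3,
                       n_patients = 1000,
                       margin = 0.20,
                       pta_threshold = 80,
                       comparator_f = 0.08,
                       comparator_dose = 600,
                       horizon = 24, step = 3 / 60,
                       seed = 1,
                       aucoec_mode = "strict_points") {
  if (margin < 0 || margin >= 1) stop("margin must be in [0, 1)")
  if (pta_threshold <= 0 || pta_threshold > 100)
    stop("pta_threshold must be in (0, 100]")
  if (any(ec_grid <= 0) || is.unsorted(ec_grid, strictly = TRUE))
    stop("ec_grid must be positive and ascending")
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (any(n_doses_list < 1)) stop("n_doses_list entries must be >= 1")
  structure(list(iv_dose = iv_dose,
                 iv_infusion_duration = iv_infusion_duration,
                 oral_doses = oral_doses, ec_grid = ec_grid,
                 n_doses_list = sort(unique(as.integer(n_doses_list))),
                 n_patients = as.integer(n_patients), margin = margin,
                 pta_threshold = pta_threshold, comparator_f = comparator_f,
                 comparator_dose = comparator_dose, horizon = horizon,
                 step = step, seed = as.integer(seed),
                 aucoec_mode = aucoec_mode),
            class = "sim_config")
}

#' Exposure target from the IV reference regimen
#'
#' The target an oral regimen must reach in a given patient: that patient's
#' IV AUCOEC reduced by the non-inferiority margin (default 20%, the accepted
#' bioequivalence margin).
#'
#' @param iv_aucoec IV-reference AUCOEC (ng·h/mL), >= 0.
#' @param margin Fraction in [0, 1).
#' @return Target AUCOEC (ng·h/mL).
#' @examples
#' aucoec_target(100, 0.20)  # 80
#' @export
aucoec_target <- function(iv_aucoec, margin = 0.20) {
  if (any(iv_aucoec < 0)) stop("iv_aucoec must be >= 0")
  if (!is.finite(margin) || margin < 0 || margin >= 1)
    stop("margin must be in [0, 1)")
  iv_aucoec * (1 - margin)
}

#' Single-patient success indicator
#'
#' The within-patient comparison: success (1) when the oral-regimen AUCOEC is
#' greater than or equal to the patient's margin-adjusted IV target, failure
#' (0) otherwise. Ties count as successes.
#'
#' @param psi_oral Oral-regimen AUCOEC (ng·h/mL), >= 0.
#' @param target Margin-adjusted IV AUCOEC (ng·h/mL), >= 0.
#' @return Integer 0/1 (vectorized).
#' @examples
#' success_indicator(13.2, 10.6)  # 1
#' @export
success_indicator <- function(psi_oral, target) {
  if (any(!is.finite(psi_oral)) || any(!is.finite(target)))
    stop("inputs must be finite")
  if (any(psi_oral < 0) || any(target < 0)) stop("inputs must be >= 0")
  as.integer(psi_oral >= target)
}

#' Probability of target attainment
#'
#' @param successes Non-empty vector of 0/1 success indicators.
#' @return PTA in percent: `100 * mean(successes)`.
#' @examples
#' pta(c(rep(1, 740), rep(0, 260)))  # 74
#' @export
pta <- function(successes) {
  if (!length(successes)) stop("successes must be non-empty")
  if (!all(successes %in% c(0, 1))) stop("successes must be 0/1")
  100 * mean(successes)
}

#' Run the full PTA simulation grid
#'
#' Samples the virtual cohort once (common random numbers), simulates for
#' every patient the IV reference profile and a single-dose unbound profile
#' for each oral dose level with the same individual parameters (each patient
#' acts as their own control), and fills the PTA grid: for every
#' (dose, number of doses, EC) cell, the oral AUCOEC (times the number of
#' doses, complete washout assumed) is compared with that patient's
#' margin-adjusted IV target at the same EC, and the percentage of successes
#' is recorded. The no-inhibitor comparator (bioavailability
#' `config$comparator_f` at `config$comparator_dose`) is evaluated on the
#' same cohort and keyed as a separate arm. Because a single oral dose is a
#' linear system, profiles for different dose levels of the same patient are
#' exact scalar multiples of one unit profile, which the implementation
#' exploits.
#'
#' @param pop A [population_model()].
#' @param config A [sim_config()].
#' @return A `pta_grid`: data frame with columns `arm` (`"odox_e"` or
#'   `"comparator"`), `dose_mg`, `n_doses`, `ec_ng_ml`, `pta_pct`, `n_sim`,
#'   with the configuration attached as attribute `config`.
#' @export
run_pta_grid <- function(pop, config) {
  stopifnot(inherits(pop, "population_model"), inherits(config, "sim_config"))
  times <- seq(0, config$horizon, by = config$step)
  inds <- sample_individuals(pop, config$n_patients, config$seed)
  iv_reg <- regimen(dose_event("iv_infusion", config$iv_dose, time = 0,
                               duration = config$iv_infusion_duration))
  unit_oral <- regimen(dose_event("oral", 1, time = 0))
  necs <- length(config$ec_grid)
  np <- config$n_patients
  target <- matrix(0, np, necs)
  oral_auc <- array(0, dim = c(np, length(config$oral_doses), necs))
  comp_auc <- matrix(0, np, necs)
  for (i in seq_len(np)) {
    p_i <- inds[[i]]
    cu_iv <- predict_unbound(p_i, iv_reg, times)
    # unit oral profile per mg of dose at full individual bioavailability;
    # scale afterwards (single-dose profiles are linear in amount x F)
    cu_unit <- predict_unbound(p_i, unit_oral, times) / p_i$f_oral
    for (e in seq_len(necs)) {
      ec <- config$ec_grid[e]
      target[i, e] <- aucoec_target(
        compute_aucoec(times, cu_iv, ec, config$aucoec_mode)$value,
        config$margin)
      for (d in seq_along(config$oral_doses))
        oral_auc[i, d, e] <- compute_aucoec(
          times, cu_unit * config$oral_doses[d] * p_i$f_oral, ec,
          config$aucoec_mode)$value
      comp_auc[i, e] <- compute_aucoec(
        times, cu_unit * config$comparator_dose * config$comparator_f, ec,
        config$aucoec_mode)$value
    }
  }
  cells <- list()
  for (nd in config$n_doses_list) {
    for (d in seq_along(config$oral_doses)) {
      for (e in seq_len(necs)) {
        s <- success_indicator(multidose_aucoec(oral_auc[, d, e], nd),
                               target[, e])
        cells[[length(cells) + 1L]] <- data.frame(
          arm = "odox_e", dose_mg = config$oral_doses[d], n_doses = nd,
          ec_ng_ml = config$ec_grid[e], pta_pct = pta(s), n_sim = np)
      }
    }
    for (e in seq_len(necs)) {
      s <- success_indicator(multidose_aucoec(comp_auc[, e], nd), target[, e])
      cells[[length(cells) + 1L]] <- data.frame(
        arm = "comparator", dose_mg = config$comparator_dose, n_doses = nd,
        ec_ng_ml = config$ec_grid[e], pta_pct = pta(s), n_sim = np)
    }
  }
  grid <- do.call(rbind, cells)
  attr(grid, "config") <- config
  class(grid) <- c("pta_grid", "data.frame")
  grid
}

#' Classify the PTA grid into a GO / NO-GO recommendation
#'
#' Applies the two-part decision framework to the oral-with-enhancer cells of
#' a PTA grid: if no (dose, n-doses, EC) cell exceeds the threshold
#' (strictly), no practical regimen exists and the decision is `NO_GO`; if
#' some regimen exceeds the threshold at every EC on the grid the decision is
#' a clear `GO`; otherwise the decision is `CONDITIONAL_GO` and the report
#' carries, per regimen, the highest EC still exceeding the threshold — the
#' quantity further pharmacology would need to pin down.
#'
#' @param grid A `pta_grid` from [run_pta_grid()].
#' @param config The [sim_config()] used (defaults to the grid's attribute).
#' @return A list of class `decision_report` with elements `classification`,
#'   `threshold_pct`, `boundaries` (data frame: dose_mg, n_doses,
#'   max_ec_above_threshold) and `best` (the most permissive regimen).
#' @export
classify_decision <- function(grid, config = attr(grid, "config")) {
  stopifnot(inherits(grid, "pta_grid"))
  if (is.null(config)) stop("a sim_config is required")
  g <- grid[grid$arm == "odox_e", ]
  expected <- length(config$oral_doses) * length(config$n_doses_list) *
    length(config$ec_grid)
  if (nrow(g) != expected ||
      !all(config$ec_grid %in% unique(g$ec_ng_ml)))
    stop("PTA grid is incomplete for the supplied configuration")
  thr <- config$pta_threshold
  regs <- unique(g[, c("dose_mg", "n_doses")])
  boundaries <- do.call(rbind, lapply(seq_len(nrow(regs)), function(k) {
    sub <- g[g$dose_mg == regs$dose_mg[k] & g$n_doses == regs$n_doses[k], ]
    ok <- sub$ec_ng_ml[sub$pta_pct > thr]
    data.frame(dose_mg = regs$dose_mg[k], n_doses = regs$n_doses[k],
               max_ec_above_threshold = if (length(ok)) max(ok) else NA_real_,
               all_ec = length(ok) == length(config$ec_grid))
  }))
  classification <- if (!any(g$pta_pct > thr)) {
    "NO_GO"
  } else if (any(boundaries$all_ec)) {
    "GO"
  } else {
    "CONDITIONAL_GO"
  }
  best <- boundaries[order(-ifelse(is.na(boundaries$max_ec_above_threshold), -1,
                                   boundaries$max_ec_above_threshold),
                           boundaries$dose_mg, boundaries$n_doses), ][1, ]
  structure(list(classification = classification, threshold_pct = thr,
                 boundaries = boundaries[, 1:3], best = best,
                 seed = config$seed),
            class = "decision_report")
}

#' @export
print.decision_report <- function(x, ...) {
  cat("Decision:", x$classification,
      sprintf("(PTA threshold > %g%%)\n", x$threshold_pct))
  if (x$classification != "NO_GO") {
    cat("Highest EC with PTA above threshold, per regimen:\n")
    print(x$boundaries, row.names = FALSE)
  }
  invisible(x)
}
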