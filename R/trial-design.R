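#' Phase-I trial design for the docetaxel study
#'
#' Returns the sampling design of the two-period phase-I trial the synthetic
#' datasets emulate: 24 post-IV sampling times (0 min to 73 h, the early ones
#' specified in minutes and stored in hours) and 23 post-oral times (0 to
#' 96 h); an IV dose of 130 mg infused over 1 h; oral dose levels of 75, 150
#' and 300 mg/m2 scaled by body surface area (default 1.7 m2); lower limits
#' of quantification of 2 ng/mL (total) and 0.084 ng/mL (unbound); and the
#' subsets of 7 (IV) and 8 (oral) times at which the unbound assay is run.
#'
#' The unbound-assay subsets are a fixed, documented choice spanning the
#' absorption/infusion, peak and elimination phases; the original
#' optimal-design selection is not re-derived here and the subsets can be
#' overridden.
#'
#' @param unbound_subset_iv,unbound_subset_oral Optional replacement subsets
#'   (must be subsets of the corresponding schedule, sizes are free).
#' @return A list of class `trial_design`.
#' @examples
#' d <- default_trial_design()
#' length(d$iv_sample_times)    # 24
#' length(d$oral_sample_times)  # 23
#' @export
default_trial_design <- function(unbound_subset_iv = NULL,
                                 unbound_subset_oral = NULL) {
  iv_times <- c(c(0, 2, 5, 8, 12, 20, 40, 60) / 60,
                1.25, 1.5, 1.75, 2, 3, 4, 5, 7, 9, 13, 19, 25, 33, 49, 57, 73)
  oral_times <- c(0, 0.25, 0.5, 0.75, 1, 1.25, 1.5, 2, 2.5, 3, 3.5, 4, 5, 6,
                  8, 12, 18, 24, 32, 48, 56, 72, 96)
  design <- structure(list(
    iv_sample_times = iv_times,
    oral_sample_times = oral_times,
    unbound_subset_iv = unbound_subset_iv %||%
      c(20 / 60, 1, 1.5, 3, 7, 19, 49),
    unbound_subset_oral = unbound_subset_oral %||%
      c(0.5, 1.5, 2.5, 3.5, 5, 8, 12, 24),
    lloq_total = 2,
    lloq_unbound = 0.084,
    iv_dose = 130,
    iv_infusion_duration = 1,
    oral_dose_levels = c(75, 150, 300),
    bsa = 1.7), class = "trial_design")
  validate_trial_design(design)
  design
}

#' @rdname default_trial_design
#' @param design An object to validate.
#' @export
validate_trial_design <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  for (s in c("iv_sample_times", "oral_sample_times")) {
    tt <- design[[s]]
    if (any(tt < 0) || is.unsorted(tt, strictly = TRUE))
      stop(s, " must be non-negative, sorted and unique")
  }
  if (!all(design$unbound_subset_iv %in% design$iv_sample_times))
    stop("unbound_subset_iv must be a subset of iv_sample_times")
  if (!all(design$unbound_subset_oral %in% design$oral_sample_times))
    stop("unbound_subset_oral must be a subset of oral_sample_times")
  if (design$lloq_total <= 0 || design$lloq_unbound <= 0)
    stop("LLOQs must be > 0")
  if (design$iv_dose <= 0 || any(design$oral_dose_levels <= 0) ||
      design$bsa <= 0 || design$iv_infusion_duration <= 0)
    stop("doses, infusion duration and BSA must be > 0")
  invisible(design)
}

# NONMEM-convention dataset columns; DVID 1 = total, 2 = unbound, 0 = dose;
# ROUTE/OCC 1 = IV occasion, 2 = oral occasion
.pk_dataset_cols <- function() {
  c("ID", "OCC", "ROUTE", "TIME", "EVID", "AMT", "RATE",
    "DV", "DVID", "BLQ", "LLOQ", "L2", "MDV")
}

#' Generate a synthetic phase-I dataset
#'
#' Simulates the two-occasion trial for `n_subjects` virtual patients: each
#' subject receives the IV infusion on occasion 1 and a single oral dose on
#' occasion 2 (dose levels cycle 75/150/300 mg/m2 across subjects, three per
#' level at nine subjects). Individual parameters are drawn once per subject;
#' noiseless total and unbound predictions at the scheduled times are then
#' corrupted with the residual-error model, with the total/unbound
#' observations from the same draw sharing an L2 pair id at the
#' unbound-subset times. Occasions are simulated independently (no
#' between-occasion variability, carryover, period or sequence effects).
#'
#' @param pop A [population_model()].
#' @param design A `trial_design`, e.g. [default_trial_design()].
#' @param n_subjects Number of subjects, >= 1.
#' @param seed Integer seed; generation is fully deterministic given the seed.
#' @return A `pk_dataset`: a data frame in long NONMEM convention with
#'   columns `ID, OCC, ROUTE, TIME, EVID, AMT, RATE, DV, DVID, BLQ, LLOQ,
#'   L2, MDV`. `BLQ` and `LLOQ` are left unset (`NA`) until [censor_blq()].
#' @examples
#' pop <- default_population_model()
#' dat <- generate_trial_dataset(pop, default_trial_design(), 9, seed = 1)
#' sum(dat$EVID == 0 & dat$DVID == 2)  # 135 unbound observations
#' @export
generate_trial_dataset <- function(pop, design, n_subjects, seed) {
  stopifnot(inherits(pop, "population_model"))
  validate_trial_design(design)
  if (!is.finite(n_subjects) || n_subjects < 1 || n_subjects != round(n_subjects))
    stop("n_subjects must be a positive integer")
  seed <- as.integer(seed)
  sub_seeds <- withr::with_seed(seed,
    matrix(sample.int(.Machine$integer.max, 2 * n_subjects), ncol = 2))
  individuals <- sample_individuals(pop, n_subjects, seed)
  rows <- vector("list", n_subjects * 2)
  l2_counter <- 0L
  for (i in seq_len(n_subjects)) {
    p_i <- individuals[[i]]
    for (occ in 1:2) {
      if (occ == 1) {
        reg <- regimen(dose_event("iv_infusion", design$iv_dose, time = 0,
                                  duration = design$iv_infusion_duration))
        sched <- design$iv_sample_times
        subset_u <- design$unbound_subset_iv
        fu <- p_i$fu_iv
        amt <- design$iv_dose
        rate <- design$iv_dose / design$iv_infusion_duration
      } else {
        level <- design$oral_dose_levels[((i - 1) %% length(design$oral_dose_levels)) + 1]
        amt <- level * design$bsa
        reg <- regimen(dose_event("oral", amt, time = 0))
        sched <- design$oral_sample_times
        subset_u <- design$unbound_subset_oral
        fu <- p_i$fu_po
        rate <- 0
      }
      cu <- predict_unbound(p_i, reg, sched)
      pred <- cbind(total = cu / fu,
                    unbound = ifelse(sched %in% subset_u, cu, NA_real_))
      obs <- apply_residual_error(pred, pop, seed = sub_seeds[i, occ])
      is_pair <- sched %in% subset_u
      l2 <- ifelse(is_pair, l2_counter + cumsum(is_pair), 0L)
      l2_counter <- l2_counter + sum(is_pair)
      dose_row <- data.frame(ID = i, OCC = occ, ROUTE = occ, TIME = 0,
                             EVID = 1, AMT = amt, RATE = rate,
                             DV = NA_real_, DVID = 0, BLQ = NA_integer_,
                             LLOQ = NA_real_, L2 = 0, MDV = 1)
      obs_rows <- function(dvid, values) {
        keep <- !is.na(values) | dvid == 1
        data.frame(ID = i, OCC = occ, ROUTE = occ, TIME = sched,
                   EVID = 0, AMT = 0, RATE = 0, DV = values, DVID = dvid,
                   BLQ = NA_integer_, LLOQ = NA_real_, L2 = l2, MDV = 0)[keep, ]
      }
      tot <- obs_rows(1, obs[, "total"])
      unb <- obs_rows(2, obs[, "unbound"])
      blk <- rbind(dose_row, tot, unb)
      blk <- blk[order(blk$TIME, blk$EVID == 0, blk$DVID), ]
      rows[[(i - 1) * 2 + occ]] <- blk
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pk_dataset", "data.frame")
  out
}

#' Flag observations below the limit of quantification
#'
#' Sets the `LLOQ` column from the design (by observable) and flags an
#' observation as BLQ when its value is strictly below the LLOQ; negative
#' simulated values (possible through the additive residual term) are always
#' flagged. Observed values themselves are not modified — imputation is the
#' job of [apply_m6()]. A value exactly at the LLOQ is quantifiable and is
#' not flagged.
#'
#' @param data A `pk_dataset`.
#' @param design A `trial_design` supplying `lloq_total` and `lloq_unbound`;
#'   if omitted, the dataset's own `LLOQ` column must already be filled.
#' @return The dataset with `BLQ` and `LLOQ` set on observation rows.
#' @export
censor_blq <- function(data, design = NULL) {
  data <- .as_pk_dataset(data)
  is_obs <- data$EVID == 0
  if (!is.null(design)) {
    validate_trial_design(design)
    data$LLOQ[is_obs] <- ifelse(data$DVID[is_obs] == 2,
                                design$lloq_unbound, design$lloq_total)
  }
  if (any(is.na(data$LLOQ[is_obs])))
    stop("LLOQ is missing for some observation rows; supply a design")
  data$BLQ[is_obs] <- as.integer(data$DV[is_obs] < data$LLOQ[is_obs] |
                                   data$DV[is_obs] < 0)
  data
}

#' Apply the M6 method to BLQ runs
#'
#' Within each subject x occasion x observable concentration series, every
#' maximal run of consecutive BLQ observations is reduced to its first
#' observation, imputed at LLOQ/2 and retained for estimation; the remaining
#' observations of the run are marked missing (`MDV = 1`) and contribute
#' nothing to the likelihood. Leading and trailing runs are treated alike,
#' and observations above the LLOQ are untouched. The operation is
#' idempotent.
#'
#' @param data A `pk_dataset` whose `BLQ` flags have been set by
#'   [censor_blq()].
#' @return The preprocessed dataset.
#' @examples
#' # series 5, 3, BLQ, BLQ, BLQ (LLOQ 2) becomes 5, 3, 1, missing, missing
#' @export
apply_m6 <- function(data) {
  data <- .as_pk_dataset(data)
  is_obs <- data$EVID == 0
  if (any(is.na(data$BLQ[is_obs])))
    stop("BLQ flags are not set; call censor_blq() first")
  key <- interaction(data$ID, data$OCC, data$DVID, drop = TRUE)
  for (g in split(which(is_obs), key[is_obs])) {
    g <- g[order(data$TIME[g])]
    blq <- data$BLQ[g] == 1
    if (!any(blq)) next
    r <- rle(blq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      run <- g[starts[j]:ends[j]]
      first <- run[1]
      data$DV[first] <- data$LLOQ[first] / 2
      data$MDV[first] <- 0
      if (length(run) > 1) data$MDV[run[-1]] <- 1
    }
  }
  data
}

.as_pk_dataset <- function(data) {
  if (!is.data.frame(data)) stop("data must be a pk_dataset data frame")
  miss <- setdiff(.pk_dataset_cols(), names(data))
  if (length(miss))
    stop("dataset is missing required column(s): ", paste(miss, collapse = ", "))
  if (!inherits(data, "pk_dataset")) class(data) <- c("pk_dataset", class(data))
  data
}
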