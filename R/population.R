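#' Sample virtual individuals from the population model
#'
#' Draws `n` individual parameter sets using the exponential between-subject
#' variability model: for every parameter carrying a nonzero log-scale SD,
#' `p_i = theta_p * exp(eta_i)` with `eta ~ N(0, omega^2)`. Etas for
#' different parameters are independent unless the model supplies a
#' correlation matrix. Parameters with zero (or absent) omega — including
#' bioavailability and the fractions unbound unless explicitly given
#' variability — are copied from the typical values. Log-normal variability
#' can never produce a non-positive parameter.
#'
#' @param pop A [population_model()].
#' @param n Number of individuals, >= 1.
#' @param seed Integer seed; sampling is deterministic given the seed and
#'   leaves the global RNG state untouched.
#' @return A list of `n` [structural_params()] objects.
#' @examples
#' inds <- sample_individuals(default_population_model(), n = 3, seed = 1)
#' sapply(inds, `[[`, "cl_u")
#' @export
sample_individuals <- function(pop, n, seed) {
  stopifnot(inherits(pop, "population_model"))
  if (!is.finite(n) || n < 1 || n != round(n))
    stop("n must be a positive integer")
  om <- pop$omega_sd
  theta <- pop$theta
  if (!length(om)) {
    return(replicate(n, theta, simplify = FALSE))
  }
  k <- length(om)
  eta <- withr::with_seed(as.integer(seed), {
    z <- matrix(stats::rnorm(n * k), nrow = n, ncol = k)
    if (!is.null(pop$omega_corr)) {
      L <- chol(pop$omega_corr)
      z <- z %*% L
    }
    sweep(z, 2, om, `*`)
  })
  colnames(eta) <- names(om)
  lapply(seq_len(n), function(i) {
    p <- theta
    for (nm in names(om)) p[[nm]] <- theta[[nm]] * exp(eta[i, nm])
    # exponential variability keeps fractions positive but can push them
    # above 1; cap at 1 so the individual remains physically valid
    for (nm in c("f_oral", "fu_iv", "fu_po")) p[[nm]] <- min(p[[nm]], 1)
    validate_structural_params(p)
    p
  })
}

#' Corrupt paired predictions with the residual-error model
#'
#' Applies the combined additive + proportional residual model to model
#' predictions. Each blood sample yields (up to) two observations — a total
#' and an unbound concentration — whose standardized residuals are drawn
#' from a bivariate normal with correlation `rho_l2` (the L2 structure);
#' an observation without a partner (`NA` in the other column) uses the
#' univariate model. For prediction `f` the observation is
#' `y = f + sqrt(sigma_add^2 + (sigma_prop * f)^2) * z`. Negative simulated
#' values are possible through the additive term and are deliberately
#' retained; downstream BLQ censoring flags them.
#'
#' @param pred_pairs A matrix or data frame with numeric columns `total` and
#'   `unbound` (ng/mL); use `NA` for an absent member of a pair.
#' @param pop A [population_model()] supplying `sigma_add`, `sigma_prop`,
#'   `rho_l2`.
#' @param seed Integer seed (deterministic, RNG-state preserving).
#' @return A matrix with columns `total` and `unbound` of observed values.
#' @export
apply_residual_error <- function(pred_pairs, pop, seed) {
  stopifnot(inherits(pop, "population_model"))
  pred_pairs <- as.matrix(as.data.frame(pred_pairs)[, c("total", "unbound")])
  if (any(pred_pairs < 0, na.rm = TRUE)) stop("predictions must be >= 0")
  if (abs(pop$rho_l2) >= 1) stop("rho_l2 must lie strictly within (-1, 1)")
  n <- nrow(pred_pairs)
  rho <- pop$rho_l2
  z <- withr::with_seed(as.integer(seed), {
    z1 <- stats::rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
    cbind(total = z1, unbound = z2)
  })
  out <- pred_pairs
  for (obs in c("total", "unbound")) {
    f <- pred_pairs[, obs]
    sd_i <- sqrt(pop$sigma_add[[obs]]^2 + (pop$sigma_prop[[obs]] * f)^2)
    out[, obs] <- f + sd_i * z[, obs]
  }
  out
}
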