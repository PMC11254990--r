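#' Log-likelihood of one total/unbound observation pair
#'
#' Residual likelihood of the two observations drawn from one blood sample
#' under the combined error model: each observable has variance
#' `sigma_add^2 + (sigma_prop * f)^2` around its prediction `f`, and the
#' standardized residuals of the pair are bivariate normal with correlation
#' `rho_l2`. With `rho_l2 = 0` this reduces to the sum of two univariate
#' normal log-densities; a pair member given as `NA` in both vectors is
#' skipped, and a lone observation uses the univariate model.
#'
#' @param obs_pair,pred_pair Numeric vectors `c(total = , unbound = )` of
#'   observed and predicted concentrations (ng/mL); `NA` marks an absent
#'   member.
#' @param pop A [population_model()] supplying the error terms.
#' @return The log-likelihood contribution (a scalar).
#' @export
residual_pair_loglik <- function(obs_pair, pred_pair, pop) {
  stopifnot(inherits(pop, "population_model"))
  obs_pair <- .sigma_vec(obs_pair, "obs_pair")
  pred_pair <- .sigma_vec(pred_pair, "pred_pair")
  if (any(pred_pair < 0, na.rm = TRUE)) stop("predictions must be >= 0")
  rho <- pop$rho_l2
  if (abs(rho) >= 1) stop("rho_l2 must lie strictly within (-1, 1)")
  present <- !is.na(obs_pair) & !is.na(pred_pair)
  if (!any(present)) return(0)
  sds <- sqrt(pop$sigma_add[names(obs_pair)]^2 +
                (pop$sigma_prop[names(obs_pair)] * pred_pair)^2)
  if (any(sds[present] <= 0))
    stop("degenerate residual variance: sigma_add and sigma_prop are both 0")
  if (sum(present) == 1) {
    o <- names(obs_pair)[present]
    return(stats::dnorm(obs_pair[[o]], pred_pair[[o]], sds[[o]], log = TRUE))
  }
  z1 <- (obs_pair[["total"]] - pred_pair[["total"]]) / sds[["total"]]
  z2 <- (obs_pair[["unbound"]] - pred_pair[["unbound"]]) / sds[["unbound"]]
  -log(2 * pi) - log(sds[["total"]]) - log(sds[["unbound"]]) -
    0.5 * log1p(-rho^2) -
    (z1^2 - 2 * rho * z1 * z2 + z2^2) / (2 * (1 - rho^2))
}

# compile one subject's rows into plain vectors so the likelihood can be
# evaluated cheaply inside the inner/outer optimization loops
.compile_subject <- function(subj) {
  occs <- lapply(unique(subj$OCC), function(occ) {
    rows <- subj[subj$OCC == occ, ]
    doses <- rows[rows$EVID == 1, ]
    obs <- rows[rows$EVID == 0 & rows$MDV == 0, ]
    if (!nrow(obs)) return(NULL)
    if (!nrow(doses)) stop("observation rows without a dose on occasion ", occ)
    evs <- lapply(seq_len(nrow(doses)), function(k) {
      if (doses$ROUTE[k] == 1)
        dose_event("iv_infusion", doses$AMT[k], time = doses$TIME[k],
                   duration = doses$AMT[k] / doses$RATE[k])
      else
        dose_event("oral", doses$AMT[k], time = doses$TIME[k])
    })
    ut <- sort(unique(obs$TIME))
    l2 <- obs$L2
    pair_tot <- pair_unb <- integer(0)
    for (id2 in unique(l2[l2 > 0])) {
      sel <- which(l2 == id2)
      it <- sel[obs$DVID[sel] == 1]
      iu <- sel[obs$DVID[sel] == 2]
      if (length(it) == 1 && length(iu) == 1) {
        pair_tot <- c(pair_tot, it)
        pair_unb <- c(pair_unb, iu)
      }
    }
    single <- setdiff(seq_len(nrow(obs)), c(pair_tot, pair_unb))
    list(reg = regimen(evs), route = if (doses$ROUTE[1] == 1) "iv" else "oral",
         ut = ut, idx = match(obs$TIME, ut), dvid = obs$DVID, dv = obs$DV,
         pair_tot = pair_tot, pair_unb = pair_unb, single = single)
  })
  occs[!vapply(occs, is.null, logical(1))]
}

# residual negative log-likelihood of one compiled subject given eta
# (eta: named log-scale deviations applied multiplicatively to theta)
.compiled_nll <- function(eta, comp, pop, enames) {
  p_i <- pop$theta
  if (length(enames))
    for (j in seq_along(enames))
      p_i[[enames[j]]] <- pop$theta[[enames[j]]] * exp(eta[j])
  rho <- pop$rho_l2
  add <- pop$sigma_add
  prop <- pop$sigma_prop
  ll <- 0
  for (oc in comp) {
    cu <- .predict_unbound_fast(p_i, oc$reg, oc$ut)[oc$idx]
    fu <- if (oc$route == "iv") p_i$fu_iv else p_i$fu_po
    is_tot <- oc$dvid == 1
    pred <- ifelse(is_tot, cu / fu, cu)
    add_i <- ifelse(is_tot, add[["total"]], add[["unbound"]])
    prop_i <- ifelse(is_tot, prop[["total"]], prop[["unbound"]])
    sd_i <- sqrt(add_i^2 + (prop_i * pred)^2)
    if (any(sd_i <= 0))
      stop("degenerate residual variance: sigma_add and sigma_prop are both 0")
    z <- (oc$dv - pred) / sd_i
    if (length(oc$single))
      ll <- ll + sum(-0.5 * log(2 * pi) - log(sd_i[oc$single]) -
                       0.5 * z[oc$single]^2)
    if (length(oc$pair_tot)) {
      z1 <- z[oc$pair_tot]
      z2 <- z[oc$pair_unb]
      ll <- ll + sum(-log(2 * pi) - log(sd_i[oc$pair_tot]) -
                       log(sd_i[oc$pair_unb]) - 0.5 * log1p(-rho^2) -
                       (z1^2 - 2 * rho * z1 * z2 + z2^2) / (2 * (1 - rho^2)))
    }
  }
  -ll
}

# kept as the readable single-subject path for tests and ad-hoc use
.subject_nll <- function(eta, subj, pop, enames) {
  .compiled_nll(eta, .compile_subject(subj), pop, enames)
}

#' Population objective function value (-2 log marginal likelihood)
#'
#' Computes `OFV = -2 * sum_i log integral p(y_i | eta) p(eta) d eta` over
#' subjects, with the integral approximated by the Laplace method at each
#' subject's empirical-Bayes mode (a well-defined stand-in for conditional
#' estimation). With no between-subject variability in the model the
#' integral is exact and the OFV is minus twice the summed residual
#' log-likelihood. Rows flagged missing (`MDV = 1`) contribute nothing;
#' M6-imputed rows enter as ordinary observations, so the dataset should be
#' preprocessed with [censor_blq()] and [apply_m6()] when it contains
#' below-LLOQ data.
#'
#' @param pop A [population_model()].
#' @param data A `pk_dataset`.
#' @param eta_start Optional named list (by subject id) of warm-start modes.
#' @param inner_control `nlminb` control list for the inner mode search.
#' @return The OFV, with attribute `eta_modes` (per-subject empirical-Bayes
#'   modes).
#' @export
population_ofv <- function(pop, data, eta_start = NULL,
                           inner_control = list(rel.tol = 1e-8)) {
  stopifnot(inherits(pop, "population_model"))
  data <- .as_pk_dataset(data)
  if (!nrow(data) || !any(data$EVID == 0 & data$MDV == 0))
    stop("dataset contains no usable observations")
  compiled <- lapply(split(as.data.frame(data), data$ID), .compile_subject)
  .population_ofv_compiled(pop, compiled, eta_start, inner_control)
}

.population_ofv_compiled <- function(pop, compiled, eta_start = NULL,
                                     inner_control = list(rel.tol = 1e-8)) {
  enames <- names(pop$omega_sd)
  k <- length(enames)
  if (k) {
    Omega <- diag(pop$omega_sd^2, k)
    if (!is.null(pop$omega_corr))
      Omega <- diag(pop$omega_sd, k) %*% pop$omega_corr %*% diag(pop$omega_sd, k)
    Oinv <- tryCatch(solve(Omega), error = function(e)
      stop("omega matrix is not positive definite"))
    ldet_O <- determinant(Omega, logarithm = TRUE)$modulus
  }
  total <- 0
  modes <- list()
  for (id in names(compiled)) {
    comp <- compiled[[id]]
    if (k == 0) {
      total <- total + 2 * .compiled_nll(numeric(0), comp, pop, enames)
      next
    }
    g <- function(eta) .compiled_nll(eta, comp, pop, enames) +
      0.5 * drop(eta %*% Oinv %*% eta)
    start <- eta_start[[id]] %||% numeric(k)
    fit <- stats::nlminb(start, g, control = inner_control)
    if (!is.finite(fit$objective) ||
        fit$convergence != 0 && grepl("limit", fit$message, ignore.case = TRUE))
      warning("inner mode search did not converge for subject ", id,
              ": ", fit$message)
    H <- stats::optimHess(fit$par, g)
    ldet_H <- determinant(H, logarithm = TRUE)
    if (ldet_H$sign <= 0)
      warning("non-positive-definite curvature at the mode for subject ", id)
    log_marg <- -fit$objective - 0.5 * as.numeric(ldet_O) -
      0.5 * as.numeric(ldet_H$modulus)
    total <- total - 2 * log_marg
    modes[[id]] <- fit$par
  }
  structure(total, eta_modes = modes)
}

# outer-parameter bookkeeping: which scalars can be estimated and how they
# are transformed to an unconstrained scale
.fit_par_table <- function(pop) {
  th <- .theta_names()
  tab <- data.frame(
    name = c(th,
             if (length(pop$omega_sd)) paste0("omega_", names(pop$omega_sd)),
             "sigma_add_total", "sigma_add_unbound",
             "sigma_prop_total", "sigma_prop_unbound", "rho_l2"),
    stringsAsFactors = FALSE)
  tab$trans <- ifelse(tab$name %in% c("f_oral", "fu_iv", "fu_po"), "logit",
                      ifelse(tab$name == "rho_l2", "atanh", "log"))
  tab
}

.get_par <- function(pop, name) {
  if (name %in% .theta_names()) return(pop$theta[[name]])
  if (startsWith(name, "omega_")) return(pop$omega_sd[[sub("^omega_", "", name)]])
  switch(name,
         sigma_add_total = pop$sigma_add[["total"]],
         sigma_add_unbound = pop$sigma_add[["unbound"]],
         sigma_prop_total = pop$sigma_prop[["total"]],
         sigma_prop_unbound = pop$sigma_prop[["unbound"]],
         rho_l2 = pop$rho_l2,
         stop("unknown parameter: ", name))
}

.set_par <- function(pop, name, value) {
  if (name %in% .theta_names()) pop$theta[[name]] <- value
  else if (startsWith(name, "omega_")) pop$omega_sd[[sub("^omega_", "", name)]] <- value
  else if (name == "sigma_add_total") pop$sigma_add[["total"]] <- value
  else if (name == "sigma_add_unbound") pop$sigma_add[["unbound"]] <- value
  else if (name == "sigma_prop_total") pop$sigma_prop[["total"]] <- value
  else if (name == "sigma_prop_unbound") pop$sigma_prop[["unbound"]] <- value
  else if (name == "rho_l2") pop$rho_l2 <- value
  else stop("unknown parameter: ", name)
  pop
}

.transform <- function(x, trans) switch(trans, log = log(x),
                                        logit = stats::qlogis(x),
                                        atanh = atanh(x))
.untransform <- function(t, trans) switch(trans, log = exp(t),
                                          logit = stats::plogis(t),
                                          atanh = tanh(t))
.dinv <- function(est, trans) switch(trans, log = abs(est),
                                     logit = est * (1 - est),
                                     atanh = 1 - est^2)

#' Fit the population model by maximum likelihood
#'
#' Minimizes [population_ofv()] over the free parameters on unconstrained
#' scales (log for positive parameters and variability/error magnitudes,
#' logit for fractions, atanh for the residual correlation). Standard errors
#' come from the inverse observed information at the optimum (finite
#' difference Hessian) and are propagated to the natural scale by the delta
#' method; `RSE% = 100 * SE / estimate`. Empirical-Bayes modes are
#' warm-started across objective evaluations. The fit is deterministic given
#' the data and the initial model.
#'
#' @param data A `pk_dataset` (M6-preprocessed when it contains BLQ data).
#' @param init A [population_model()] of initial values; every free parameter
#'   must be initialized at a valid interior value (e.g. a free omega must
#'   start positive).
#' @param free Character vector of parameter names to estimate, from:
#'   structural names, `omega_<name>`, `sigma_add_total`, `sigma_add_unbound`,
#'   `sigma_prop_total`, `sigma_prop_unbound`, `rho_l2`. Everything else is
#'   fixed at its initial value. (Equivalently: the fixed set is the
#'   complement of `free`.)
#' @param control `nlminb` control list for the outer optimization.
#' @return A list of class `fit_result`: `estimates` (a `population_model`),
#'   `ofv`, `se`, `rse_percent`, `convergence`, `message`, `free`, `fixed`.
#' @export
fit_population <- function(data, init,
                           free = c("cl_u", "v1_u"),
                           control = list(rel.tol = 1e-6, iter.max = 300,
                                          eval.max = 600)) {
  stopifnot(inherits(init, "population_model"))
  data <- .as_pk_dataset(data)
  tab <- .fit_par_table(init)
  if (!length(free)) stop("at least one parameter must be free")
  bad <- setdiff(free, tab$name)
  if (length(bad)) stop("unknown free parameter(s): ", paste(bad, collapse = ", "))
  tab <- tab[match(free, tab$name), ]
  start_nat <- vapply(tab$name, .get_par, numeric(1), pop = init)
  if (any(!is.finite(start_nat)) ||
      any(start_nat <= 0 & tab$trans %in% c("log", "logit")))
    stop("free parameters must be initialized at interior values")
  start <- mapply(.transform, start_nat, tab$trans)
  warm <- new.env(parent = emptyenv())
  warm$modes <- NULL
  build <- function(t_par) {
    pop <- init
    for (j in seq_along(t_par))
      pop <- .set_par(pop, tab$name[j], .untransform(t_par[j], tab$trans[j]))
    pop
  }
  compiled <- lapply(split(as.data.frame(data), data$ID), .compile_subject)
  fn <- function(t_par) {
    val <- tryCatch({
      o <- .population_ofv_compiled(build(t_par), compiled,
                                    eta_start = warm$modes)
      warm$modes <- attr(o, "eta_modes")
      as.numeric(o)
    }, error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }
  f0 <- fn(start)
  if (f0 >= 1e10) stop("objective is not finite at the initial values")
  opt <- stats::nlminb(start, fn, control = control)
  est_nat <- mapply(.untransform, opt$par, tab$trans)
  names(est_nat) <- tab$name
  se <- rse <- rep(NA_real_, length(est_nat))
  names(se) <- names(rse) <- tab$name
  H <- tryCatch(stats::optimHess(opt$par, fn), error = function(e) NULL)
  if (!is.null(H)) {
    cov_t <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(cov_t) && all(diag(cov_t) > 0)) {
      se_t <- sqrt(diag(cov_t))
      se <- se_t * mapply(.dinv, est_nat, tab$trans)
      rse <- 100 * se / abs(est_nat)
    } else {
      warning("Hessian is singular or not positive definite; ",
              "standard errors are unavailable")
    }
  }
  structure(list(estimates = build(opt$par), ofv = opt$objective,
                 par = est_nat, se = se, rse_percent = rse,
                 convergence = opt$convergence == 0, message = opt$message,
                 free = tab$name,
                 fixed = setdiff(.fit_par_table(init)$name, tab$name)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Population fit: OFV =", format(x$ofv, digits = 8),
      if (x$convergence) "(converged)" else paste0("(NOT converged: ",
                                                   x$message, ")"), "\n")
  print(data.frame(estimate = x$par, se = x$se, rse_pct = x$rse_percent))
  invisible(x)
}

#' Likelihood-ratio improvement test between nested models
#'
#' A richer model is accepted when it lowers the objective function by more
#' than the 95th chi-squared percentile for the number of added parameters —
#' 3.84 units for one degree of freedom.
#'
#' @param ofv_reference,ofv_extended OFVs of the nested and extended model.
#' @param extra_df Number of added parameters, >= 1.
#' @return `TRUE` when the drop exceeds the criterion.
#' @examples
#' lrt_improved(100, 96, 1)  # TRUE, drop of 4.0 > 3.84
#' @export
lrt_improved <- function(ofv_reference, ofv_extended, extra_df = 1) {
  if (!is.finite(extra_df) || extra_df < 1 || extra_df != round(extra_df))
    stop("extra_df must be a positive integer")
  (ofv_reference - ofv_extended) > stats::qchisq(0.95, df = extra_df)
}

#' Serialize a fit result to JSON
#'
#' @param fit A `fit_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  out <- list(ofv = fit$ofv, convergence = fit$convergence,
              message = fit$message,
              estimates = as.list(fit$par), se = as.list(fit$se),
              rse_percent = as.list(fit$rse_percent),
              free = fit$free, fixed = fit$fixed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
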