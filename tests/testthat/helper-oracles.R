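# Shared fixtures and independent oracles used across the suite.

# typical docetaxel-like parameter set (the package default typical values)
theta_default <- function() default_population_model()$theta

# independent numerical oracle: stiff ODE integration of the depot +
# three-compartment system with deSolve, handling infusions as a
# time-dependent input rate and oral doses as depot events at time + tlag
ode_oracle <- function(params, regimen, times, rtol = 1e-10, atol = 1e-12) {
  p <- params
  infusions <- Filter(function(e) e$route == "iv_infusion", regimen$events)
  orals <- Filter(function(e) e$route == "oral", regimen$events)
  rate_at <- function(t) {
    r <- 0
    for (e in infusions)
      if (t >= e$time && t < e$time + e$duration)
        r <- r + e$amount / e$duration
    r
  }
  deriv <- function(t, y, parms) {
    k10 <- p$cl_u / p$v1_u
    k12 <- if (p$v2_u > 0) p$q2_u / p$v1_u else 0
    k21 <- if (p$v2_u > 0) p$q2_u / p$v2_u else 0
    k13 <- if (p$v3_u > 0) p$q3_u / p$v1_u else 0
    k31 <- if (p$v3_u > 0) p$q3_u / p$v3_u else 0
    d1 <- -p$ka * y[1]
    d2 <- p$ka * y[1] + rate_at(t) - (k10 + k12 + k13) * y[2] +
      k21 * y[3] + k31 * y[4]
    d3 <- k12 * y[2] - k21 * y[3]
    d4 <- k13 * y[2] - k31 * y[4]
    list(c(d1, d2, d3, d4))
  }
  ev_times <- vapply(orals, function(e) e$time + p$tlag, numeric(1))
  brk <- unlist(lapply(infusions, function(e) c(e$time, e$time + e$duration)))
  full_t <- sort(unique(c(0, times, ev_times, brk)))
  events <- NULL
  if (length(orals))
    events <- list(data = data.frame(
      var = "depot", time = ev_times,
      value = vapply(orals, function(e) e$amount * p$f_oral, numeric(1)),
      method = "add"))
  y0 <- c(depot = 0, central = 0, p2 = 0, p3 = 0)
  out <- deSolve::ode(y0, full_t, deriv, NULL, method = "lsoda",
                      rtol = rtol, atol = atol, events = events, maxsteps = 1e5)
  out[match(times, full_t), 3] * 1000 / p$v1_u
}

# generic multivariate-normal log-density from the quadratic form; serves as
# the independent oracle for the closed-form bivariate residual density
mvn_logdens <- function(x, mu, Sigma) {
  k <- length(x)
  -0.5 * k * log(2 * pi) -
    0.5 * as.numeric(determinant(Sigma, logarithm = TRUE)$modulus) -
    0.5 * mahalanobis(matrix(x, nrow = 1), mu, Sigma)
}

# closed-form one-compartment solutions (q2 = q3 = 0)
onecpt_iv_closed <- function(p, dose, dur, t) {
  k <- p$cl_u / p$v1_u
  r <- dose / dur
  conc_during <- r / p$cl_u * (1 - exp(-k * pmin(t, dur)))
  ifelse(t <= dur, conc_during,
         r / p$cl_u * (1 - exp(-k * dur)) * exp(-k * (t - dur))) * 1000
}

onecpt_oral_closed <- function(p, dose, t) {
  k <- p$cl_u / p$v1_u
  tt <- pmax(t - p$tlag, 0)
  dose * p$f_oral * p$ka / (p$v1_u * (p$ka - k)) *
    (exp(-k * tt) - exp(-p$ka * tt)) * 1000
}

# small two-occasion sampling design used by the estimation tests: fewer
# times than the phase-I schedules but still informative for all phases
reduced_design <- function() {
  d <- default_trial_design()
  d$iv_sample_times <- c(20 / 60, 1, 1.5, 2, 3, 5, 9, 19, 33, 57)
  d$oral_sample_times <- c(0.5, 1, 1.5, 2, 3, 4, 6, 12, 24, 48)
  d$unbound_subset_iv <- c(1, 2, 5, 19, 57)
  d$unbound_subset_oral <- c(1, 2, 4, 12, 24)
  validate_trial_design(d)
  d
}

# population model used for estimation scenarios: variability on clearance
# only, moderate noise
estimation_truth <- function() {
  population_model(
    theta_default(),
    omega_sd = c(cl_u = 0.3),
    sigma_add = c(total = 0.2, unbound = 0.01),
    sigma_prop = c(total = 0.1, unbound = 0.12),
    rho_l2 = 0.5)
}

# random valid parameter set for property sweeps (log-uniform around the
# defaults so all magnitudes are exercised)
random_params <- function() {
  td <- theta_default()
  jit <- function(x, f = 3) x * exp(stats::runif(1, -log(f), log(f)))
  structural_params(
    cl_u = jit(td$cl_u), v1_u = jit(td$v1_u),
    v2_u = jit(td$v2_u), v3_u = jit(td$v3_u),
    q2_u = jit(td$q2_u), q3_u = jit(td$q3_u),
    ka = jit(td$ka, 2), tlag = stats::runif(1, 0, 1),
    f_oral = stats::runif(1, 0.1, 0.9),
    fu_iv = stats::runif(1, 0.004, 0.02),
    fu_po = stats::runif(1, 0.004, 0.02))
}

# bare-hands dataset builder for small likelihood/M6 cases
mini_dataset <- function(times, dv, dvid = 1, blq = NA, lloq = NA,
                         mdv = 0, l2 = 0, occ = 1, route = 1, id = 1,
                         amt = 100, rate = 100) {
  dose <- data.frame(ID = id, OCC = occ, ROUTE = route, TIME = 0, EVID = 1,
                     AMT = amt, RATE = rate, DV = NA_real_, DVID = 0,
                     BLQ = NA_integer_, LLOQ = NA_real_, L2 = 0, MDV = 1)
  obs <- data.frame(ID = id, OCC = occ, ROUTE = route, TIME = times, EVID = 0,
                    AMT = 0, RATE = 0, DV = dv, DVID = dvid, BLQ = blq,
                    LLOQ = lloq, L2 = l2, MDV = mdv)
  out <- rbind(dose, obs)
  class(out) <- c("pk_dataset", "data.frame")
  out
}
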