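pop_err <- function(rho = 0.5) {
  population_model(theta_default(),
                   sigma_add = c(total = 0.3, unbound = 0.02),
                   sigma_prop = c(total = 0.15, unbound = 0.2),
                   rho_l2 = rho)
}

test_that("uncorrelated pair likelihood is the sum of univariate densities", {
  pop <- pop_err(rho = 0)
  obs <- c(total = 95, unbound = 1.1)
  pred <- c(total = 100, unbound = 1.0)
  sd_t <- sqrt(0.3^2 + (0.15 * 100)^2)
  sd_u <- sqrt(0.02^2 + (0.2 * 1.0)^2)
  expect_equal(residual_pair_loglik(obs, pred, pop),
               stats::dnorm(95, 100, sd_t, log = TRUE) +
                 stats::dnorm(1.1, 1.0, sd_u, log = TRUE))
})

test_that("pair likelihood matches a generic multivariate-normal oracle", {
  withr::with_seed(5, {
    for (rho in c(-0.6, 0, 0.5, 0.9)) {
      pop <- pop_err(rho)
      for (rep in 1:5) {
        pred <- c(total = stats::runif(1, 1, 200),
                  unbound = stats::runif(1, 0.05, 3))
        obs <- pred * exp(stats::rnorm(2, 0, 0.3))
        names(obs) <- names(pred)
        sd_t <- sqrt(0.3^2 + (0.15 * pred[["total"]])^2)
        sd_u <- sqrt(0.02^2 + (0.2 * pred[["unbound"]])^2)
        Sigma <- matrix(c(sd_t^2, rho * sd_t * sd_u,
                          rho * sd_t * sd_u, sd_u^2), 2)
        expect_equal(residual_pair_loglik(obs, pred, pop),
                     mvn_logdens(unname(obs), unname(pred), Sigma),
                     tolerance = 1e-10)
      }
    }
  })
})

test_that("lone observations fall back to the univariate model", {
  pop <- pop_err(0.8)
  obs <- c(total = 95, unbound = NA)
  pred <- c(total = 100, unbound = NA)
  sd_t <- sqrt(0.3^2 + (0.15 * 100)^2)
  expect_equal(residual_pair_loglik(obs, pred, pop),
               stats::dnorm(95, 100, sd_t, log = TRUE))
})

test_that("degenerate residual variance is rejected", {
  pop <- population_model(theta_default())  # all sigma zero
  expect_error(residual_pair_loglik(c(total = 1, unbound = 1),
                                    c(total = 1, unbound = 1), pop),
               "degenerate")
})

test_that("with no random effects the OFV is the exact residual value", {
  pop <- pop_err(0.5)
  d <- reduced_design()
  dat <- generate_trial_dataset(pop, d, 2, seed = 31)
  ofv <- as.numeric(population_ofv(pop, dat))
  # analytic: -2 * sum of pair/single log-likelihoods via the exported API
  ll <- 0
  for (id in unique(dat$ID)) for (occ in 1:2) {
    obs <- dat[dat$ID == id & dat$OCC == occ & dat$EVID == 0, ]
    reg <- if (occ == 1)
      regimen(dose_event("iv_infusion", 130, time = 0, duration = 1))
    else
      regimen(dose_event("oral",
                         dat$AMT[dat$ID == id & dat$OCC == 2 & dat$EVID == 1],
                         time = 0))
    cu <- predict_unbound(pop$theta, reg, sort(unique(obs$TIME)))
    cu <- cu[match(obs$TIME, sort(unique(obs$TIME)))]
    fu <- if (occ == 1) pop$theta$fu_iv else pop$theta$fu_po
    pred <- ifelse(obs$DVID == 1, cu / fu, cu)
    done <- rep(FALSE, nrow(obs))
    for (k in seq_len(nrow(obs))) {
      if (done[k]) next
      if (obs$L2[k] > 0) {
        j <- which(obs$L2 == obs$L2[k] & seq_len(nrow(obs)) != k)
        op <- c(total = NA_real_, unbound = NA_real_)
        pp <- op
        for (m in c(k, j)) {
          nm <- if (obs$DVID[m] == 1) "total" else "unbound"
          op[nm] <- obs$DV[m]; pp[nm] <- pred[m]
        }
        ll <- ll + residual_pair_loglik(op, pp, pop)
        done[c(k, j)] <- TRUE
      } else {
        nm <- if (obs$DVID[k] == 1) "total" else "unbound"
        op <- c(total = NA_real_, unbound = NA_real_); pp <- op
        op[nm] <- obs$DV[k]; pp[nm] <- pred[k]
        ll <- ll + residual_pair_loglik(op, pp, pop)
        done[k] <- TRUE
      }
    }
  }
  expect_equal(ofv, -2 * ll, tolerance = 1e-10)
})

laplace_toy <- function(omega = 0.3) {
  theta <- structural_params(cl_u = 10, v1_u = 50, ka = 1)
  pop <- population_model(theta, omega_sd = c(cl_u = omega),
                          sigma_add = c(total = 0.05, unbound = 0.05),
                          sigma_prop = c(total = 0.1, unbound = 0.1))
  dat <- mini_dataset(times = c(1, 4), dv = c(1500, 900), dvid = 1)
  list(pop = pop, dat = dat)
}

test_that("Laplace OFV agrees with brute-force quadrature on a toy problem", {
  toy <- laplace_toy()
  ofv <- as.numeric(population_ofv(toy$pop, toy$dat))
  nll <- function(e) odoxpk:::.subject_nll(e, toy$dat, toy$pop, "cl_u")
  marg <- stats::integrate(Vectorize(function(e)
    exp(-nll(e)) * stats::dnorm(e, 0, 0.3)), -3, 3, rel.tol = 1e-10)$value
  expect_lt(abs(ofv - (-2 * log(marg))), 0.1)
})

test_that("Laplace OFV converges to the fixed-effects OFV as omega vanishes", {
  toy0 <- laplace_toy(omega = 0)     # omega dropped -> exact path
  toye <- laplace_toy(omega = 1e-8)
  expect_equal(as.numeric(population_ofv(toye$pop, toye$dat)),
               as.numeric(population_ofv(toy0$pop, toy0$dat)),
               tolerance = 1e-6)
})

test_that("OFV is invariant to dataset row order", {
  pop <- population_model(theta_default(), omega_sd = c(cl_u = 0.25),
                          sigma_add = c(total = 0.3, unbound = 0.02),
                          sigma_prop = c(total = 0.15, unbound = 0.2),
                          rho_l2 = 0.4)
  dat <- generate_trial_dataset(pop, reduced_design(), 3, seed = 77)
  shuffled <- withr::with_seed(2, dat[sample(nrow(dat)), ])
  class(shuffled) <- c("pk_dataset", "data.frame")
  expect_equal(as.numeric(population_ofv(pop, dat)),
               as.numeric(population_ofv(pop, shuffled)), tolerance = 1e-8)
})

test_that("empty or observation-free datasets are rejected", {
  pop <- pop_err()
  empty <- mini_dataset(times = 1, dv = 1)[1, ]  # dose row only
  class(empty) <- c("pk_dataset", "data.frame")
  expect_error(population_ofv(pop, empty), "no usable observations")
})

test_that("the fitted optimum beats perturbed parameter vectors", {
  pop <- population_model(theta_default(),
                          sigma_add = c(total = 0.1, unbound = 0.005),
                          sigma_prop = c(total = 0.02, unbound = 0.02))
  dat <- generate_trial_dataset(pop, reduced_design(), 5, seed = 13)
  fit <- fit_population(dat, pop, free = c("cl_u", "v1_u"))
  expect_true(fit$convergence)
  expect_lt(abs(fit$par[["cl_u"]] - 8570) / 8570, 0.01)
  expect_lt(abs(fit$par[["v1_u"]] - 1200) / 1200, 0.01)
  for (fac in c(0.9, 1.1)) {
    pert <- pop
    pert$theta$cl_u <- fit$par[["cl_u"]] * fac
    pert$theta$v1_u <- fit$par[["v1_u"]] * fac
    expect_lt(fit$ofv, as.numeric(population_ofv(pert, dat)))
  }
  expect_error(fit_population(dat, pop, free = character(0)), "free")
})

test_that("freeing an extra parameter never raises the minimized OFV", {
  pop <- population_model(theta_default(),
                          sigma_add = c(total = 0.5, unbound = 0.02),
                          sigma_prop = c(total = 0.08, unbound = 0.08))
  dat <- generate_trial_dataset(pop, reduced_design(), 3, seed = 29)
  init <- pop
  init$theta$cl_u <- 8570 * 1.2
  f1 <- fit_population(dat, init, free = "cl_u")
  f2 <- fit_population(dat, init, free = c("cl_u", "ka"))
  expect_lte(f2$ofv, f1$ofv + 1e-4)
})

test_that("the 3.84-unit drop criterion decides nested-model improvement", {
  expect_true(lrt_improved(100, 96, 1))    # drop 4.0 > 3.84
  expect_false(lrt_improved(100, 97, 1))   # drop 3.0
  expect_false(lrt_improved(100, 96, 2))   # 4.0 < 5.99 for 2 df
  expect_error(lrt_improved(100, 96, 0), "positive integer")
})
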