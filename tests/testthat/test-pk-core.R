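test_that("a regimen delivering nothing predicts zero everywhere", {
  p <- theta_default()
  ev <- dose_event("iv_infusion", 1, time = 0, duration = 1)
  ev$amount <- 0  # validation deliberately bypassed: degenerate linear input
  reg <- regimen(ev)
  expect_equal(predict_unbound(p, reg, seq(0, 24, by = 1)), rep(0, 25))
})

test_that("simulated unbound AUC obeys dose / clearance mass balance", {
  p <- theta_default()
  reg <- regimen(dose_event("iv_infusion", 130, time = 0, duration = 1))
  f <- function(t) {
    o <- order(t)
    r <- numeric(length(t))
    r[o] <- predict_unbound(p, reg, t[o])
    r
  }
  auc <- stats::integrate(f, 0, 3000, rel.tol = 1e-9,
                          subdivisions = 2000L)$value
  expect_equal(auc, 130 * 1000 / p$cl_u, tolerance = 1e-3)

  po <- regimen(dose_event("oral", 510, time = 0))
  f2 <- function(t) {
    o <- order(t)
    r <- numeric(length(t))
    r[o] <- predict_unbound(p, po, t[o])
    r
  }
  auc2 <- stats::integrate(f2, 0, 3000, rel.tol = 1e-9,
                           subdivisions = 2000L)$value
  expect_equal(auc2, 510 * p$f_oral * 1000 / p$cl_u, tolerance = 1e-3)
})

test_that("doubling all dose amounts doubles every concentration", {
  withr::with_seed(21, {
    for (rep in 1:3) {
      p <- random_params()
      reg1 <- regimen(dose_event("iv_infusion", 130, time = 0, duration = 1),
                      dose_event("oral", 300, time = 2))
      reg2 <- regimen(dose_event("iv_infusion", 260, time = 0, duration = 1),
                      dose_event("oral", 600, time = 2))
      tt <- seq(0, 48, by = 0.5)
      c1 <- predict_unbound(p, reg1, tt)
      c2 <- predict_unbound(p, reg2, tt)
      expect_lt(max(abs(c2 - 2 * c1) / pmax(2 * c1, 1e-12)), 1e-9)
    }
  })
})

test_that("closed-form solution matches a stiff ODE oracle across random parameters", {
  withr::with_seed(37, {
    for (rep in 1:4) {
      p <- random_params()
      regs <- list(
        regimen(dose_event("iv_infusion", 130, time = 0, duration = 1)),
        regimen(dose_event("oral", 510, time = 0)),
        regimen(dose_event("iv_infusion", 100, time = 0, duration = 2),
                dose_event("oral", 400, time = 6)))
      tt <- sort(c(seq(0.25, 48, by = 0.25), 1 + 1e-6))
      for (reg in regs) {
        mine <- predict_unbound(p, reg, tt)
        orc <- ode_oracle(p, reg, tt)
        scale <- pmax(orc, max(orc) * 1e-9)
        expect_lt(max(abs(mine - orc) / scale), 1e-6)
      }
    }
  })
})

test_that("removing both peripheral compartments reproduces the 1-compartment closed form", {
  p <- structural_params(cl_u = 50, v1_u = 30, ka = 0.8, tlag = 0.5,
                         f_oral = 0.4, fu_iv = 0.01, fu_po = 0.02)
  tt <- seq(0, 24, by = 0.1)
  iv <- regimen(dose_event("iv_infusion", 100, time = 0, duration = 1.5))
  expect_equal(predict_unbound(p, iv, tt), onecpt_iv_closed(p, 100, 1.5, tt),
               tolerance = 1e-10)
  po <- regimen(dose_event("oral", 200, time = 0))
  expect_equal(predict_unbound(p, po, tt), onecpt_oral_closed(p, 200, tt),
               tolerance = 1e-10)
})

test_that("prediction rejects invalid inputs", {
  p <- theta_default()
  reg <- regimen(dose_event("oral", 100, time = 0))
  expect_error(predict_unbound(p, reg, c(2, 1)), "non-decreasing")
  expect_error(predict_unbound(p, reg, c(-1, 1)), ">= 0")
  expect_error(regimen(), "at least one")
  bad <- p
  bad$cl_u <- NaN
  expect_error(predict_unbound(bad, reg, 0:2), "finite")
})

test_that("unbound/total conversions follow the constant-binding relation", {
  expect_equal(total_from_unbound(c(1, 2), fu = 1), c(1, 2))
  expect_equal(total_from_unbound(0.67, fu = 0.0067), 100)
  expect_equal(total_from_unbound(0, fu = 0.5), 0)
  expect_error(total_from_unbound(1, fu = 0), "fu")
  expect_error(total_from_unbound(1, fu = 1.5), "fu")

  expect_equal(total_cl_from_unbound(8570, 0.0067), 57.419)
  expect_equal(total_cl_from_unbound(3, 1), 3)
  expect_error(total_cl_from_unbound(0, 0.5), "cl_u")

  p1 <- structural_params(cl_u = 1, v1_u = 10, v2_u = 20, v3_u = 30,
                          q2_u = 1, q3_u = 1)
  expect_equal(total_vss(p1, "iv"), 60)
  p2 <- structural_params(cl_u = 1, v1_u = 10, fu_iv = 0.5)
  expect_equal(total_vss(p2, "iv"), 5)
  expect_error(total_vss(p1, "intramuscular"))
})

test_that("default typical values reproduce the reported total-scale clearance and Vss", {
  p <- theta_default()
  expect_equal(total_cl_from_unbound(p$cl_u, p$fu_iv), 57.3, tolerance = 0.005)
  expect_equal(total_vss(p, "iv"), 425, tolerance = 0.05)
})

test_that("profile wrapper pairs unbound and total through the route fu", {
  p <- theta_default()
  reg <- regimen(dose_event("oral", 510, time = 0))
  pr <- predict_profile(p, reg, seq(0, 24, by = 0.5))
  expect_s3_class(pr, "conc_profile")
  expect_identical(pr$route_context, "oral")
  expect_equal(pr$c_total, pr$c_unbound / p$fu_po)
  expect_length(pr$c_total, length(pr$times))
  mixed <- regimen(dose_event("iv_infusion", 130, time = 0, duration = 1),
                   dose_event("oral", 510, time = 24))
  expect_error(predict_profile(p, mixed, 0:48), "route_context")
})
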