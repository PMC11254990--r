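make_grid <- function(pta_fun, cfg = sim_config(n_patients = 10)) {
  cells <- expand.grid(dose_mg = cfg$oral_doses, n_doses = cfg$n_doses_list,
                       ec_ng_ml = cfg$ec_grid)
  grid <- data.frame(arm = "odox_e", cells,
                     pta_pct = mapply(pta_fun, cells$dose_mg, cells$n_doses,
                                      cells$ec_ng_ml),
                     n_sim = cfg$n_patients)
  attr(grid, "config") <- cfg
  class(grid) <- c("pta_grid", "data.frame")
  grid
}

test_that("the margin-adjusted target and Eq-style success rule behave", {
  expect_equal(aucoec_target(100, 0.20), 80)
  expect_equal(aucoec_target(7, 0), 7)
  expect_equal(aucoec_target(0, 0.2), 0)
  expect_error(aucoec_target(10, 1), "margin")
  expect_error(aucoec_target(-1, 0.2), ">= 0")

  expect_identical(success_indicator(13.2, 10.6), 1L)
  expect_identical(success_indicator(10.6, 10.6), 1L)  # ties succeed
  expect_identical(success_indicator(5.0, 10.6), 0L)
  expect_error(success_indicator(-1, 1), ">= 0")
})

test_that("PTA is the success percentage", {
  expect_equal(pta(c(rep(1, 740), rep(0, 260))), 74)
  expect_equal(pta(rep(1, 10)), 100)
  expect_error(pta(integer(0)), "non-empty")
  expect_error(pta(c(1, 2)), "0/1")
})

test_that("a degenerate population gives all-or-nothing PTA", {
  pop <- population_model(theta_default())  # no BSV, no noise
  cfg <- sim_config(n_patients = 3, seed = 2)
  grid <- run_pta_grid(pop, cfg)
  expect_true(all(grid$pta_pct %in% c(0, 100)))
})

test_that("the single-dose panel spans 50 dose-by-EC cells", {
  pop <- default_population_model()
  cfg <- sim_config(n_patients = 20, seed = 3)
  grid <- run_pta_grid(pop, cfg)
  one <- grid[grid$arm == "odox_e" & grid$n_doses == 1, ]
  expect_equal(nrow(one), 50)
  expect_equal(sort(unique(one$dose_mg)), seq(400, 600, by = 50))
  expect_equal(sort(unique(one$ec_ng_ml)), seq(0.1, 1, by = 0.1))
  expect_equal(nrow(grid[grid$arm == "odox_e", ]), 150)
})

test_that("the grid is reproducible by seed", {
  pop <- default_population_model()
  cfg <- sim_config(n_patients = 15, seed = 9)
  expect_identical(run_pta_grid(pop, cfg), run_pta_grid(pop, cfg))
})

test_that("PTA is monotone in EC, dose and dose count under a shared cohort", {
  pop <- default_population_model()
  cfg <- sim_config(n_patients = 150, seed = 5)
  grid <- run_pta_grid(pop, cfg)
  g <- grid[grid$arm == "odox_e", ]
  for (d in cfg$oral_doses) for (nd in cfg$n_doses_list) {
    sub <- g[g$dose_mg == d & g$n_doses == nd, ]
    sub <- sub[order(sub$ec_ng_ml), ]
    expect_true(all(diff(sub$pta_pct) <= 0))
  }
  for (ec in cfg$ec_grid) for (nd in cfg$n_doses_list) {
    sub <- g[g$ec_ng_ml == ec & g$n_doses == nd, ]
    sub <- sub[order(sub$dose_mg), ]
    expect_true(all(diff(sub$pta_pct) >= 0))
  }
  for (ec in cfg$ec_grid) for (d in cfg$oral_doses) {
    sub <- g[g$ec_ng_ml == ec & g$dose_mg == d, ]
    sub <- sub[order(sub$n_doses), ]
    expect_true(all(diff(sub$pta_pct) >= 0))
  }
  # the 8%-bioavailability comparator can never beat the enhanced arm at
  # the same dose (bioavailability enters multiplicatively)
  comp <- grid[grid$arm == "comparator", ]
  for (k in seq_len(nrow(comp))) {
    match_cell <- g[g$dose_mg == comp$dose_mg[k] &
                      g$n_doses == comp$n_doses[k] &
                      g$ec_ng_ml == comp$ec_ng_ml[k], ]
    expect_lte(comp$pta_pct[k], match_cell$pta_pct)
  }
})

test_that("self-comparison with no margin attains the target", {
  # a patient compared to their own reference exposure with margin 0 always
  # succeeds, so the paired design yields PTA well above half
  pop <- population_model(theta_default())
  tt <- seq(0, 24, by = 3 / 60)
  cu <- predict_unbound(pop$theta,
                        regimen(dose_event("iv_infusion", 130, 0, duration = 1)),
                        tt)
  psi <- compute_aucoec(tt, cu, 0.5)$value
  expect_equal(pta(success_indicator(psi, aucoec_target(psi, 0))), 100)
})

test_that("classification follows the two-part framework", {
  cfg <- sim_config(n_patients = 10)
  expect_identical(classify_decision(make_grid(function(d, n, e) 50, cfg))$classification,
                   "NO_GO")
  grid_go <- make_grid(function(d, n, e) if (d == 600 & n == 3) 90 else 50, cfg)
  expect_identical(classify_decision(grid_go)$classification, "GO")
  # 600 mg x 3 exceeds 80% only for EC <= 0.7: conditional with boundary 0.7
  grid_cond <- make_grid(function(d, n, e)
    if (d == 600 && n == 3 && e < 0.75) 85 else 50, cfg)
  rep <- classify_decision(grid_cond)
  expect_identical(rep$classification, "CONDITIONAL_GO")
  b <- rep$boundaries
  expect_equal(b$max_ec_above_threshold[b$dose_mg == 600 & b$n_doses == 3], 0.7,
               tolerance = 1e-9)
  expect_equal(rep$best$max_ec_above_threshold, 0.7, tolerance = 1e-9)
  # exactly 80.0 is not a pass (strict threshold)
  grid_tie <- make_grid(function(d, n, e) 80, cfg)
  expect_identical(classify_decision(grid_tie)$classification, "NO_GO")
  # incomplete grids are refused
  expect_error(classify_decision(grid_cond[-1, ]), "incomplete")
})
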