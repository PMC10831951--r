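test_that("background correction is element-wise subtraction", {
  tr <- make_trace(roi = c(100, 55), bg = c(10, 10))
  expect_equal(background_correct(tr)$corrected, c(90, 45))
  tr0 <- make_trace(roi = c(100, 55), bg = c(0, 0))
  expect_equal(background_correct(tr0)$corrected, tr0$roi_mean)
})

test_that("pre-bleach normalization sets the pre-bleach mean to exactly 1", {
  proto <- frap_protocol(5, 2, 0.4, 1, c(0, 0.4))
  tr <- make_trace(roi = c(100, 102, 98, 101, 99, 50, 40, 55),
                   bg = rep(10, 8))
  curve <- normalize_prebleach(tr, proto)
  # corrected pre-bleach [90, 92, 88, 91, 89] -> mean 90; post-bleach 45/90
  expect_equal(mean(curve$value[curve$time_rel_bleach < 0]), 1, tolerance = 1e-12)
  expect_equal(curve$value[curve$time_rel_bleach == 0], 0.5)
  # bleach frames are dropped; time re-zeroed at first post-bleach frame
  expect_equal(nrow(curve), 6)
  expect_equal(curve$time_rel_bleach, c(-2.8, -2.4, -2.0, -1.6, -1.2, 0))
})

test_that("constant traces normalize to the unit curve", {
  proto <- frap_protocol(5, 2, 0.4, 3, c(0, 0.8))
  tr <- make_trace(roi = rep(110, 10), bg = rep(10, 10))
  expect_equal(normalize_prebleach(tr, proto)$value, rep(1, 8))
})

test_that("normalization is idempotent and scale invariant", {
  proto <- frap_protocol(5, 2, 0.4, 10, c(2, 3.6))
  cfg <- frap_sim_config(f_imm = 0.4, seed = 9, n_experiments = 1,
                         n_cells_per_experiment = 2)
  tr <- simulate_frap_ensemble(cfg, proto)$traces
  curve <- normalize_prebleach(tr, proto)
  # feed a normalized curve back as a trace with zero background
  renorm_proto <- frap_protocol(proto$n_prebleach, 0, proto$frame_interval,
                                proto$n_recovery, proto$steady_window)
  cell <- curve[curve$cell_id == curve$cell_id[1], ]
  as_tr <- make_trace(roi = cell$value, bg = rep(0, nrow(cell)))
  again <- normalize_prebleach(as_tr, renorm_proto)
  expect_equal(again$value, cell$value, tolerance = 1e-12)
  # common scaling of roi and background leaves the curve unchanged
  tr_scaled <- tr
  tr_scaled$roi_mean <- tr$roi_mean * 17.3
  tr_scaled$background_mean <- tr$background_mean * 17.3
  expect_equal(normalize_prebleach(tr_scaled, proto)$value, curve$value,
               tolerance = 1e-12)
})

test_that("normalization rejects short traces and non-positive pre-bleach", {
  proto <- frap_protocol(5, 2, 0.4, 3, c(0, 0.8))
  expect_error(normalize_prebleach(make_trace(rep(100, 7)), proto),
               class = "frapkit_validation_error")
  bad <- make_trace(roi = rep(5, 10), bg = rep(10, 10))
  expect_error(normalize_prebleach(bad, proto), "pre-bleach",
               class = "frapkit_validation_error")
})

test_that("ensemble averaging is hierarchical with experiment-level dispersion", {
  grid <- c(-0.4, 0, 0.4)
  one_cell <- function(exp, cell, v) {
    data.frame(experiment_id = exp, cell_id = cell, condition = "NT",
               time_rel_bleach = grid, value = v)
  }
  # single curve: itself, zero experiment SD
  e1 <- average_ensemble(one_cell("E1", "c1", c(1, 0.5, 0.6)))
  expect_equal(e1$mean, c(1, 0.5, 0.6))
  expect_equal(attr(e1, "n_cells"), 1)
  # two experiments with constant curves 0.4 and 0.6 -> mean 0.5
  two <- rbind(one_cell("E1", "c1", rep(0.4, 3)), one_cell("E2", "c2", rep(0.6, 3)))
  e2 <- average_ensemble(two)
  expect_equal(e2$mean, rep(0.5, 3))
  expect_equal(e2$sd_experiments, rep(stats::sd(c(0.4, 0.6)), 3))
  expect_equal(attr(e2, "n_experiments"), 2)
})

test_that("hierarchical mean equals the flat per-cell mean for balanced designs", {
  set.seed(31)
  grid <- seq(-0.8, 2, 0.4)
  curves <- do.call(rbind, lapply(1:3, function(e) {
    do.call(rbind, lapply(1:4, function(c) {
      data.frame(experiment_id = sprintf("E%d", e),
                 cell_id = sprintf("E%d_c%d", e, c), condition = "NT",
                 time_rel_bleach = grid, value = runif(length(grid)))
    }))
  }))
  ens <- average_ensemble(curves)
  flat <- tapply(curves$value, curves$time_rel_bleach, mean)
  expect_equal(ens$mean, as.numeric(flat[as.character(ens$time)]), tolerance = 1e-12)
})

test_that("mixed time grids are refused", {
  a <- data.frame(experiment_id = "E1", cell_id = "c1", condition = "NT",
                  time_rel_bleach = c(0, 0.4), value = c(1, 1))
  b <- data.frame(experiment_id = "E1", cell_id = "c2", condition = "NT",
                  time_rel_bleach = c(0, 0.5), value = c(1, 1))
  expect_error(average_ensemble(rbind(a, b)), "time grid",
               class = "frapkit_validation_error")
})

test_that("immobile-fraction formula is literal and unclamped", {
  expect_equal(fimm_formula(0.4, 0.7, 1.0), 0.5)
  expect_equal(fimm_formula(0.4, 0.4, 1.0), 1)    # no recovery
  expect_equal(fimm_formula(0.4, 1.0, 1.0), 0)    # identical plateaus
  expect_equal(fimm_formula(0.2, 0.95, 0.9), -0.07142857, tolerance = 1e-7)
  expect_error(fimm_formula(0.5, 0.7, 0.4), class = "frapkit_numeric_error")
})

test_that("immobile_fraction uses the treated I0 in the denominator", {
  grid <- c(-0.4, 0, 8, 9, 10, 11, 12)
  treated <- make_ensemble(grid, c(1, 0.30, rep(0.70, 5)), "UV")
  reference <- make_ensemble(grid, c(1, 0.55, rep(0.95, 5)), "NT")
  r <- immobile_fraction(treated, reference, window = c(8, 12))
  expect_equal(r$f_imm_hat, 1 - (0.70 - 0.30) / (0.95 - 0.30))
  # the deliberately wrong variant (reference's own post-bleach floor) differs
  wrong <- 1 - (0.70 - 0.30) / (0.95 - 0.55)
  expect_false(isTRUE(all.equal(r$f_imm_hat, wrong)))
  # recomputing from the reported ingredients reproduces the statistic exactly
  expect_identical(r$f_imm_hat,
                   1 - (r$i_final_uv - r$i0_uv) / (r$i_final_unc - r$i0_uv))
})

test_that("immobile_fraction validates windows and degenerate normalizers", {
  grid <- c(-0.4, 0, 8, 9, 10, 11, 12)
  treated <- make_ensemble(grid, c(1, 0.4, rep(0.7, 5)), "UV")
  reference <- make_ensemble(grid, c(1, 0.5, rep(1, 5)), "NT")
  expect_error(immobile_fraction(treated, reference, window = c(4, 6)),
               class = "frapkit_validation_error")  # no frames in window
  low_ref <- make_ensemble(grid, c(1, 0.5, rep(0.3, 5)), "NT")
  expect_error(immobile_fraction(treated, low_ref, window = c(8, 12)),
               class = "frapkit_numeric_error")
})

test_that("pipeline recovers the simulated immobile fraction", {
  # spec-highlighted regime: slower diffusion, fast exchange
  hat <- fimm_recovery(0.5, seed_treated = 7, seed_reference = 8,
                       D = 5, kon_star = 5, koff = 0.5)
  expect_lt(abs(hat - 0.5), 0.05)
})

test_that("per-cell immobile fractions distribute around the ensemble value", {
  proto <- csb_protocol
  treated <- simulate_frap_ensemble(frap_sim_config(f_imm = 0.25, seed = 7), proto, "UV")
  reference <- simulate_frap_ensemble(frap_sim_config(f_imm = 0, seed = 8), proto, "NT")
  tc <- normalize_prebleach(treated$traces, proto)
  rc <- average_ensemble(normalize_prebleach(reference$traces, proto))
  per_cell <- immobile_fraction_cells(tc, rc, protocol = proto)
  expect_equal(nrow(per_cell), 30)
  expect_lt(abs(mean(per_cell$f_imm_hat) - 0.25), 0.05)
})

test_that("two-state fit inverts its own model to high precision", {
  tt <- seq(0, 20, 0.05)
  curve <- make_ensemble(tt, closed_form_recovery(0.5, 0.3, 0.2, 0.5, 0.1, 0, tt))
  fit <- fit_two_state(curve)
  expect_true(fit$converged)
  expect_equal(fit$f_free, 0.5, tolerance = 1e-3)
  expect_equal(fit$f_exch, 0.3, tolerance = 1e-3)
  expect_equal(fit$f_imm, 0.2, tolerance = 1e-3)
  expect_equal(fit$koff, 0.5, tolerance = 1e-3)
  expect_equal(fit$tau_diff, 0.1, tolerance = 1e-3)
  expect_lt(fit$residual_rms, 1e-6)
})

test_that("two-state fit flags flat curves and recovers simulated kinetics", {
  flat <- make_ensemble(seq(0, 12, 0.4), rep(1, 31))
  ff <- fit_two_state(flat)
  expect_true(ff$degenerate)
  expect_equal(ff$f_imm, 0)
  # fit in the regime the closed form describes: bleached pool negligible
  cfg <- oracle_regime_config()
  cfg$f_imm <- 0.5
  sim <- simulate_frap_ensemble(cfg, csb_protocol)
  curve <- average_ensemble(normalize_prebleach(sim$traces, csb_protocol))
  fit <- fit_two_state(curve)
  expect_true(fit$converged)
  expect_lt(abs(fit$f_imm - 0.5), 0.05)
})
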