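test_that("accumulation normalization sets the pre-damage level to 1", {
  tr <- make_trace(roi = c(90, 91, 89, 90, 90, 100, 122, 122), bg = rep(10, 8), dt = 2)
  curve <- normalize_accumulation(tr, 5)
  expect_equal(mean(curve$value[1:5]), 1, tolerance = 1e-12)
  # pre-damage corrected mean 80; later frame 112 -> 1.4
  expect_equal(curve$value[7], 1.4)
  # time zero at damage induction (first post-pre-damage frame)
  expect_equal(curve$time_rel_damage[6], 0)
  # constant trace -> unit curve
  const <- normalize_accumulation(make_trace(rep(100, 8), rep(10, 8)), 5)
  expect_equal(const$value, rep(1, 8))
})

test_that("accumulation curves are scale invariant and validated", {
  sim <- simulate_accumulation(accumulation_sim_config(n_cells = 3, seed = 4))
  curve <- normalize_accumulation(sim$traces, 5)
  scaled <- sim$traces
  scaled$roi_mean <- scaled$roi_mean * 3.7
  scaled$background_mean <- scaled$background_mean * 3.7
  expect_equal(normalize_accumulation(scaled, 5)$value, curve$value,
               tolerance = 1e-12)
  expect_error(normalize_accumulation(make_trace(rep(100, 4)), 5),
               class = "frapkit_validation_error")
})

test_that("simulator plateau matches the configured fold", {
  # no-accumulation null: post-damage mean equals pre-damage mean
  null_sim <- simulate_accumulation(
    accumulation_sim_config(fold_accumulation = 1, n_cells = 20, seed = 2))
  null_curve <- average_ensemble(normalize_accumulation(null_sim$traces, 5))
  expect_lt(abs(accumulation_plateau(null_curve, c(100, 228)) - 1), 0.02)
  # noise-free asymptote is the fold by construction
  clean <- simulate_accumulation(
    accumulation_sim_config(fold_accumulation = 1.6, noise_model = noise_none(),
                            n_cells = 1, n_frames = 300, seed = 1))
  cc <- normalize_accumulation(clean$traces, 5)
  expect_equal(tail(cc$value, 1), 1.6, tolerance = 1e-3)
})

test_that("AUC follows the trapezoid rule with interpolated endpoints", {
  expect_equal(curve_auc(data.frame(time = 0:10, value = rep(1, 11)), c(0, 10)), 10)
  expect_equal(curve_auc(data.frame(time = 0:10, value = rep(0, 11)), c(0, 10)), 0)
  poly <- data.frame(time = c(0, 5, 10), value = c(1, 2, 2))
  # hand integration of the polyline: 5*(1+2)/2 + 5*2 = 17.5
  expect_equal(curve_auc(poly, c(0, 10)), 17.5)
  # additivity over adjacent ranges, with an off-grid cut point
  expect_equal(curve_auc(poly, c(0, 3.3)) + curve_auc(poly, c(3.3, 10)),
               curve_auc(poly, c(0, 10)), tolerance = 1e-12)
  expect_error(curve_auc(poly, c(0, 12)), class = "frapkit_validation_error")
  expect_error(curve_auc(poly, c(5, 5)), class = "frapkit_validation_error")
})

test_that("AUC comparison handles identical and degenerate groups", {
  same <- compare_auc(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_false(same$degenerate)
  deg <- suppressMessages(compare_auc(c(2, 2, 2), c(2, 2, 2)))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
  expect_error(compare_auc(1, c(1, 2)), class = "frapkit_validation_error")
  # equal-variance default matches stats::t.test
  set.seed(5)
  a <- rnorm(8); b <- rnorm(8, 0.5)
  expect_equal(compare_auc(a, b)$p, t.test(a, b, var.equal = TRUE)$p.value)
  expect_equal(compare_auc(a, b, welch = TRUE)$p, t.test(a, b)$p.value)
})

test_that("group separation is detected on simulated fold difference", {
  a <- simulate_accumulation(accumulation_sim_config(n_cells = 10, seed = 21), "none")
  b <- simulate_accumulation(
    accumulation_sim_config(fold_accumulation = 1.15, n_cells = 10, seed = 22), "THZ1")
  auc_a <- cell_aucs(normalize_accumulation(a$traces, 5), c(0, 200))
  auc_b <- cell_aucs(normalize_accumulation(b$traces, 5), c(0, 200))
  res <- compare_auc(auc_a, auc_b)
  expect_lt(res$p, 0.001)
  expect_gt(res$mean_a, res$mean_b)
})
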