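test_that("no-bleach, no-noise simulation conserves signal and stays constant", {
  cfg <- frap_sim_config(bleach_depth = 1, noise_model = noise_none(),
                         cell_to_cell_cv = 0, n_experiments = 1,
                         n_cells_per_experiment = 1, seed = 1)
  prof <- frapkit:::frap_profile(cfg, csb_protocol)
  total <- attr(prof, "total_signal")
  expect_lt(max(abs(total - total[1])) / total[1], 1e-9)
  # uniform initial state with no perturbation: trace constant over time
  sim <- simulate_frap_ensemble(cfg, csb_protocol)
  expect_equal(diff(range(sim$traces$roi_mean)), 0, tolerance = 1e-12)
})

test_that("well-mixed limit: pure fast diffusion recovers within one frame", {
  cfg <- frap_sim_config(domain_length = 200, n_bins = 200, strip_center = 100,
                         strip_width = 1, D = 1000, kon_star = 0, koff = 0,
                         f_imm = 0, bleach_depth = 0, noise_model = noise_none(),
                         cell_to_cell_cv = 0, n_experiments = 1,
                         n_cells_per_experiment = 1, seed = 1)
  proto <- frap_protocol(n_prebleach = 2, n_bleach = 1, frame_interval = 0.4,
                         n_recovery = 4, steady_window = c(0.4, 1.2))
  sim <- simulate_frap_ensemble(cfg, proto)
  curve <- average_ensemble(normalize_prebleach(sim$traces, proto))
  one_frame <- curve$mean[abs(curve$time - 0.4) < 1e-9]
  expect_gt(one_frame, 0.95)
})

test_that("identical (config, protocol, seed) gives bit-identical output", {
  cfg <- frap_sim_config(f_imm = 0.3, seed = 42)
  a <- simulate_frap_ensemble(cfg, csb_protocol, "UV")
  b <- simulate_frap_ensemble(cfg, csb_protocol, "UV")
  expect_identical(a$traces, b$traces)
})

test_that("trace dimensions follow the protocol and replication structure", {
  cfg <- frap_sim_config(n_experiments = 2, n_cells_per_experiment = 3, seed = 5)
  sim <- simulate_frap_ensemble(cfg, csb_protocol)
  expect_equal(nrow(sim$traces), 2 * 3 * 37)  # 5 pre + 2 bleach + 30 recovery
  expect_equal(length(unique(sim$traces$cell_id)), 6)
  expect_named(sim$traces, c("experiment_id", "cell_id", "condition", "frame",
                             "time_s", "roi_mean", "background_mean"))
})

test_that("ground-truth fractions partition to one and set the asymptote", {
  cfg <- frap_sim_config(f_imm = 0.25, kon_star = 2, koff = 0.5, seed = 1)
  truth <- sim_truth(cfg, csb_protocol)
  expect_equal(truth$f_free + truth$f_exch + truth$f_imm, 1, tolerance = 1e-12)
  expect_equal(truth$f_exch / truth$f_free, 2 / 0.5, tolerance = 1e-12)
  expect_equal(truth$expected_asymptote, 1 - 0.25)  # full bleach
})

test_that("noise-free asymptotic recovery is strictly decreasing in f_imm", {
  asymptote <- vapply(c(0, 0.2, 0.4, 0.6, 0.8), function(f) {
    cfg <- frap_sim_config(f_imm = f, noise_model = noise_none(),
                           cell_to_cell_cv = 0, n_experiments = 1,
                           n_cells_per_experiment = 1, seed = 1)
    sim <- simulate_frap_ensemble(cfg, csb_protocol)
    curve <- average_ensemble(normalize_prebleach(sim$traces, csb_protocol))
    mean(curve$mean[curve$time >= 10])
  }, numeric(1))
  expect_true(all(diff(asymptote) < 0))
})

test_that("invalid geometry and unmeetable stability are explicit errors", {
  expect_error(frap_sim_config(strip_center = 24.5, strip_width = 2),
               class = "frapkit_validation_error")
  expect_error(frap_sim_config(f_imm = 1.2), class = "frapkit_validation_error")
  cfg <- frap_sim_config(D = 1e9, n_bins = 2000, seed = 1)
  expect_error(frapkit:::frap_profile(cfg, csb_protocol),
               class = "frapkit_numeric_error")
})

test_that("protocol presets carry the documented acquisition parameters", {
  csb <- frap_protocol_preset("csb")
  expect_equal(c(csb$n_prebleach, csb$n_bleach, csb$n_recovery), c(5, 2, 30))
  expect_equal(csb$frame_interval, 0.4)
  expect_equal(csb$steady_window, c(8, 12))
  uvssa <- frap_protocol_preset("uvssa")
  expect_equal(uvssa$n_recovery, 20)
  expect_equal(uvssa$steady_window, c(5, 8))
  expect_error(frap_protocol(5, 2, 0.4, 5, c(8, 12)),
               class = "frapkit_validation_error")  # window beyond recovery
})
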