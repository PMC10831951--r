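# Shared fixtures, built in code.

csb_protocol <- frap_protocol_preset("csb")

# Regime in which the simulator and the closed-form reaction-dominant
# oracle should coincide: tiny strip relative to the domain (negligible
# bleached pool), fast free diffusion, exchange dominated by the bound
# state with slow turnover.
oracle_regime_config <- function() {
  frap_sim_config(domain_length = 200, n_bins = 800, strip_center = 100,
                  strip_width = 0.5, D = 120, kon_star = 0.225, koff = 0.15,
                  f_imm = 0, bleach_depth = 0, noise_model = noise_none(),
                  cell_to_cell_cv = 0, n_experiments = 1,
                  n_cells_per_experiment = 1, seed = 1)
}

# Full pipeline on the simulator's own output: simulate a treated ensemble
# with immobile fraction f_imm and an unchallenged reference, normalize,
# ensemble-average, and return the recovered immobile fraction.
fimm_recovery <- function(f_imm, seed_treated, seed_reference,
                          protocol = csb_protocol, ...) {
  treated <- simulate_frap_ensemble(
    frap_sim_config(f_imm = f_imm, seed = seed_treated, ...), protocol, "UV")
  reference <- simulate_frap_ensemble(
    frap_sim_config(f_imm = 0, seed = seed_reference, ...), protocol, "NT")
  tc <- average_ensemble(normalize_prebleach(treated$traces, protocol))
  rc <- average_ensemble(normalize_prebleach(reference$traces, protocol))
  immobile_fraction(tc, rc, protocol = protocol)$f_imm_hat
}

# Hand-built ensemble curve on an explicit grid.
make_ensemble <- function(time, mean, condition = "x",
                          n_cells = 1L, n_experiments = 1L) {
  res <- data.frame(time = time, mean = mean)
  attr(res, "n_cells") <- n_cells
  attr(res, "n_experiments") <- n_experiments
  attr(res, "condition") <- condition
  class(res) <- c("ensemble_curve", "data.frame")
  res
}

# Minimal hand-built trace for one cell.
make_trace <- function(roi, bg = rep(10, length(roi)), dt = 0.4,
                       cell = "E1_C01", experiment = "E1", condition = "NT") {
  data.frame(experiment_id = experiment, cell_id = cell, condition = condition,
             frame = seq_along(roi) - 1L, time_s = (seq_along(roi) - 1L) * dt,
             roi_mean = roi, background_mean = bg)
}
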