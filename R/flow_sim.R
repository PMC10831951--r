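#' Configuration of the flow-cytometry event simulator
#'
#' Emulates a cytometer run on cells expressing a red fluorescent reporter:
#' intact single cells form a log-normal RFP intensity distribution and a
#' compact FSC-A/SSC-A scatter cluster; a treated sample has its mean RFP
#' scaled by `1 - degradation_fraction` (reporter degradation). Contaminating
#' populations are a low-scatter debris cluster with dim autofluorescence and
#' a doublet cluster at roughly twice the single-cell scatter and RFP.
#'
#' @param n_events Events per sample (>= 1; a real run collects >= 5000).
#' @param lognormal_mu,lognormal_sigma Log-scale location/spread of the
#'   intact single-cell RFP distribution.
#' @param degradation_fraction Relative reduction of mean RFP in the treated
#'   sample (in [0,1]).
#' @param debris_fraction,doublet_fraction Contamination fractions (sum < 1).
#' @param seed RNG seed.
#' @return An object of class `flow_sim_config`.
#' @export
flow_sim_config <- function(n_events = 5000,
                            lognormal_mu = log(500),
                            lognormal_sigma = 0.35,
                            degradation_fraction = 0,
                            debris_fraction = 0.05,
                            doublet_fraction = 0.03,
                            seed = 1) {
  check_number(n_events, "n_events", min = 1, integer = TRUE)
  check_number(lognormal_mu, "lognormal_mu")
  check_number(lognormal_sigma, "lognormal_sigma", min = 0)
  check_number(degradation_fraction, "degradation_fraction", min = 0, max = 1)
  check_number(debris_fraction, "debris_fraction", min = 0, max = 1)
  check_number(doublet_fraction, "doublet_fraction", min = 0, max = 1)
  if (debris_fraction + doublet_fraction >= 1) {
    stop_validation("debris_fraction + doublet_fraction must be < 1")
  }
  check_number(seed, "seed", integer = TRUE)
  structure(list(
    n_events = as.integer(n_events), lognormal_mu = lognormal_mu,
    lognormal_sigma = lognormal_sigma,
    degradation_fraction = degradation_fraction,
    debris_fraction = debris_fraction, doublet_fraction = doublet_fraction,
    seed = as.integer(seed)
  ), class = "flow_sim_config")
}

# Scatter geometry of the simulated populations (arbitrary cytometer units).
# The default rectangular gate from default_flow_gate() separates the intact
# singles cluster from both contaminants by > 4 standard deviations.
FLOW_SINGLES_FSC <- c(mean = 1e5, sd = 1.2e4)
FLOW_SINGLES_SSC <- c(mean = 6e4, sd = 1.0e4)
FLOW_DEBRIS_FSC <- c(mean = 1.5e4, sd = 5e3)
FLOW_DEBRIS_SSC <- c(mean = 8e3, sd = 3e3)

#' Simulate flow-cytometry event tables for an untreated and a treated sample
#'
#' @param config A [flow_sim_config()].
#' @param samples Labels for the untreated and treated samples.
#' @return A list with `events` (data.frame `event_id`, `sample`, `fsc_a`,
#'   `ssc_a`, `rfp`; both samples stacked) and `truth` (the config plus the
#'   per-population event counts and `expected_relative`, the treated/mock
#'   gated-mean ratio in percent: `100 * (1 - degradation_fraction)`).
#' @export
simulate_flow <- function(config, samples = c("NT", "UV")) {
  stopifnot(inherits(config, "flow_sim_config"))
  if (length(samples) != 2L) stop_validation("samples must be two labels")
  set.seed(config$seed)

  n <- config$n_events
  n_debris <- round(n * config$debris_fraction)
  n_doublet <- round(n * config$doublet_fraction)
  n_single <- n - n_debris - n_doublet

  draw_sample <- function(label, rfp_scale) {
    rfp_single <- rfp_scale * stats::rlnorm(n_single, config$lognormal_mu,
                                            config$lognormal_sigma)
    single <- data.frame(
      sample = label,
      fsc_a = stats::rnorm(n_single, FLOW_SINGLES_FSC["mean"], FLOW_SINGLES_FSC["sd"]),
      ssc_a = stats::rnorm(n_single, FLOW_SINGLES_SSC["mean"], FLOW_SINGLES_SSC["sd"]),
      rfp = rfp_single
    )
    debris <- if (n_debris > 0) data.frame(
      sample = label,
      fsc_a = pmax(stats::rnorm(n_debris, FLOW_DEBRIS_FSC["mean"], FLOW_DEBRIS_FSC["sd"]), 0),
      ssc_a = pmax(stats::rnorm(n_debris, FLOW_DEBRIS_SSC["mean"], FLOW_DEBRIS_SSC["sd"]), 0),
      rfp = 0.05 * rfp_scale * stats::rlnorm(n_debris, config$lognormal_mu,
                                             config$lognormal_sigma)
    )
    doublet <- if (n_doublet > 0) data.frame(
      sample = label,
      fsc_a = stats::rnorm(n_doublet, 2 * FLOW_SINGLES_FSC["mean"],
                           sqrt(2) * FLOW_SINGLES_FSC["sd"]),
      ssc_a = stats::rnorm(n_doublet, 2 * FLOW_SINGLES_SSC["mean"],
                           sqrt(2) * FLOW_SINGLES_SSC["sd"]),
      rfp = rfp_scale * (stats::rlnorm(n_doublet, config$lognormal_mu, config$lognormal_sigma) +
                           stats::rlnorm(n_doublet, config$lognormal_mu, config$lognormal_sigma))
    )
    do.call(rbind, Filter(Negate(is.null), list(single, debris, doublet)))
  }

  events <- rbind(draw_sample(samples[1], 1),
                  draw_sample(samples[2], 1 - config$degradation_fraction))
  events <- data.frame(event_id = seq_len(nrow(events)), events)
  rownames(events) <- NULL

  truth <- structure(list(
    config = config,
    n_single = n_single, n_debris = n_debris, n_doublet = n_doublet,
    expected_relative = 100 * (1 - config$degradation_fraction)
  ), class = "sim_truth")
  list(events = events, truth = truth)
}
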