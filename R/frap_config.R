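#' Configuration of the strip-FRAP binding simulator
#'
#' Describes a nucleus as a one-dimensional domain along the axis normal to
#' the bleached strip, populated by a fluorescent protein that exists in
#' three states: freely diffusing, transiently chromatin-bound (exchanging
#' with the free pool at rates `kon_star`/`koff`), and damage-immobilized
#' (no exchange within the acquisition window). The defaults describe the
#' fast-diffusion, reaction-dominant regime in which the immobile-fraction
#' statistic is a calibrated estimator: free molecules equilibrate across the
#' strip within a frame interval while bound-state turnover sets the shape of
#' the recovery.
#'
#' @param domain_length Nucleus extent along the measured axis (micrometres).
#' @param n_bins Number of spatial discretization bins (>= 3).
#' @param strip_center,strip_width Position and width of the bleach/readout
#'   strip (micrometres); the strip must lie fully inside the domain.
#' @param D Diffusion coefficient of the free state (um^2/s).
#' @param kon_star Pseudo-first-order association rate free -> bound (1/s).
#' @param koff Dissociation rate of the exchanging bound state (1/s).
#' @param f_imm Fraction of molecules in the damage-induced immobile state
#'   (dimensionless in [0,1]; treated as koff = 0 within the acquisition).
#' @param bleach_depth Fraction of fluorescence surviving in the strip
#'   immediately after each bleach pulse (0 = complete bleach).
#' @param monitor_bleach_rate Whole-field photobleaching rate caused by the
#'   imaging laser itself (1/s); 0 by default.
#' @param background_level Additive background outside the cell (a.u.).
#' @param mean_intensity Mean unbleached strip fluorescence of a cell (a.u.).
#' @param noise_model A noise descriptor from [noise_gaussian()],
#'   [noise_poisson()] or [noise_none()].
#' @param n_cells_per_experiment,n_experiments Replication structure.
#' @param cell_to_cell_cv Relative spread of per-cell brightness
#'   (log-normal with mean 1).
#' @param seed RNG seed governing the whole simulated ensemble.
#' @return An object of class `frap_sim_config`.
#' @seealso [simulate_frap_ensemble()], [frap_protocol()]
#' @export
frap_sim_config <- function(domain_length = 25,
                            n_bins = 125,
                            strip_center = domain_length / 2,
                            strip_width = 2,
                            D = 30,
                            kon_star = 5,
                            koff = 0.15,
                            f_imm = 0,
                            bleach_depth = 0,
                            monitor_bleach_rate = 0,
                            background_level = 10,
                            mean_intensity = 100,
                            noise_model = noise_gaussian(0.05),
                            n_cells_per_experiment = 10,
                            n_experiments = 3,
                            cell_to_cell_cv = 0.1,
                            seed = 1) {
  check_number(domain_length, "domain_length", min = 1e-6)
  check_number(n_bins, "n_bins", min = 3, integer = TRUE)
  check_number(strip_center, "strip_center")
  check_number(strip_width, "strip_width", min = 1e-9)
  check_number(D, "D", min = 0)
  check_number(kon_star, "kon_star", min = 0)
  check_number(koff, "koff", min = 0)
  check_number(f_imm, "f_imm", min = 0, max = 1)
  check_number(bleach_depth, "bleach_depth", min = 0, max = 1)
  check_number(monitor_bleach_rate, "monitor_bleach_rate", min = 0)
  check_number(background_level, "background_level", min = 0)
  check_number(mean_intensity, "mean_intensity", min = 1e-9)
  check_number(n_cells_per_experiment, "n_cells_per_experiment", min = 1, integer = TRUE)
  check_number(n_experiments, "n_experiments", min = 1, integer = TRUE)
  check_number(cell_to_cell_cv, "cell_to_cell_cv", min = 0)
  check_number(seed, "seed", integer = TRUE)
  if (strip_center - strip_width / 2 < -1e-9 ||
      strip_center + strip_width / 2 > domain_length + 1e-9) {
    stop_validation("strip [", strip_center - strip_width / 2, ", ",
                    strip_center + strip_width / 2,
                    "] um extends outside the domain [0, ", domain_length, "] um")
  }
  cfg <- structure(list(
    domain_length = domain_length, n_bins = as.integer(n_bins),
    strip_center = strip_center, strip_width = strip_width,
    D = D, kon_star = kon_star, koff = koff, f_imm = f_imm,
    bleach_depth = bleach_depth, monitor_bleach_rate = monitor_bleach_rate,
    background_level = background_level, mean_intensity = mean_intensity,
    noise_model = as_noise_model(noise_model),
    n_cells_per_experiment = as.integer(n_cells_per_experiment),
    n_experiments = as.integer(n_experiments),
    cell_to_cell_cv = cell_to_cell_cv, seed = as.integer(seed)
  ), class = "frap_sim_config")
  # consistency of the three-state partition (f_imm caps the bound pool)
  fr <- equilibrium_fractions(cfg)
  if (fr$f_free + fr$f_exch + fr$f_imm > 1 + 1e-9) {
    stop_validation("state fractions exceed 1")
  }
  cfg
}

#' Equilibrium state fractions implied by a simulator configuration
#'
#' The immobile fraction is `f_imm`; the remaining mobile pool partitions
#' between free and exchanging-bound states as `koff : kon_star`.
#'
#' @param config A [frap_sim_config()].
#' @return List with `f_free`, `f_exch`, `f_imm` (summing to 1).
#' @export
equilibrium_fractions <- function(config) {
  mobile <- 1 - config$f_imm
  rate_sum <- config$kon_star + config$koff
  p_bound <- if (rate_sum > 0) config$kon_star / rate_sum else 0
  list(f_free = mobile * (1 - p_bound),
       f_exch = mobile * p_bound,
       f_imm = config$f_imm)
}

#' Acquisition protocol for a strip-FRAP experiment
#'
#' Mirrors the standard confocal FRAP wizard: a handful of pre-bleach frames
#' to establish steady state, a short high-power bleach, then recovery
#' imaging at a fixed frame interval. The steady-state window (seconds after
#' the first post-bleach frame) defines where the late plateau `Ifinal` is
#' averaged for the immobile-fraction statistic.
#'
#' Two presets are provided: `frap_protocol_preset("csb")` (0.4 s frames,
#' 30 recovery frames, window 8-12 s) and `frap_protocol_preset("uvssa")`
#' (0.4 s frames, 20 recovery frames, window 5-8 s).
#'
#' @param n_prebleach Frames acquired before bleaching (>= 1).
#' @param n_bleach High-power bleach frames (>= 1).
#' @param frame_interval Seconds per frame (> 0).
#' @param n_recovery Post-bleach frames (>= 1).
#' @param steady_window Two seconds `[t_start, t_end]` relative to the first
#'   post-bleach frame, inside the recovery span.
#' @return An object of class `frap_protocol`.
#' @export
frap_protocol <- function(n_prebleach = 5, n_bleach = 2, frame_interval = 0.4,
                          n_recovery = 30, steady_window = c(8, 12)) {
  check_number(n_prebleach, "n_prebleach", min = 1, integer = TRUE)
  check_number(n_bleach, "n_bleach", min = 0, integer = TRUE)
  check_number(frame_interval, "frame_interval", min = 1e-9)
  check_number(n_recovery, "n_recovery", min = 1, integer = TRUE)
  if (length(steady_window) != 2L || !all(is.finite(steady_window))) {
    stop_validation("steady_window must be two finite numbers")
  }
  if (steady_window[1] >= steady_window[2]) {
    stop_validation("steady_window start must be before its end")
  }
  span <- (n_recovery - 1) * frame_interval
  if (steady_window[1] > span + 1e-9) {
    stop_validation("steady_window [", steady_window[1], ", ", steady_window[2],
                    "] s lies beyond the recovery span (", span, " s)")
  }
  structure(list(
    n_prebleach = as.integer(n_prebleach), n_bleach = as.integer(n_bleach),
    frame_interval = frame_interval, n_recovery = as.integer(n_recovery),
    steady_window = as.numeric(steady_window)
  ), class = "frap_protocol")
}

#' @rdname frap_protocol
#' @param preset `"csb"` or `"uvssa"`.
#' @export
frap_protocol_preset <- function(preset = c("csb", "uvssa")) {
  preset <- match.arg(preset)
  switch(preset,
    csb = frap_protocol(5, 2, 0.4, 30, c(8, 12)),
    uvssa = frap_protocol(5, 2, 0.4, 20, c(5, 8))
  )
}

n_frames_total <- function(protocol) {
  protocol$n_prebleach + protocol$n_bleach + protocol$n_recovery
}

#' @export
print.frap_sim_config <- function(x, ...) {
  fr <- equilibrium_fractions(x)
  cat("strip-FRAP simulator configuration\n")
  cat(sprintf("  domain %g um in %d bins; strip %g um at %g um\n",
              x$domain_length, x$n_bins, x$strip_width, x$strip_center))
  cat(sprintf("  D = %g um^2/s, kon* = %g /s, koff = %g /s\n", x$D, x$kon_star, x$koff))
  cat(sprintf("  fractions: free %.3f, exchanging %.3f, immobile %.3f\n",
              fr$f_free, fr$f_exch, fr$f_imm))
  cat(sprintf("  bleach depth %g, %d experiments x %d cells, noise: %s, seed %d\n",
              x$bleach_depth, x$n_experiments, x$n_cells_per_experiment,
              x$noise_model$type, x$seed))
  invisible(x)
}

#' @export
print.frap_protocol <- function(x, ...) {
  cat(sprintf(
    "FRAP protocol: %d pre-bleach + %d bleach + %d recovery frames @ %g s; steady window [%g, %g] s\n",
    x$n_prebleach, x$n_bleach, x$n_recovery, x$frame_interval,
    x$steady_window[1], x$steady_window[2]))
  invisible(x)
}
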