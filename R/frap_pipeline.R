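#' Extract an intensity trace from an image stack and its label masks
#'
#' For every frame, `roi_mean` is the mean of pixels under the strip label
#' (3) and `background_mean` the mean under the background label (1) — the
#' readout "inside the nucleus" and "outside the cell" of a strip-FRAP or
#' accumulation movie.
#'
#' @param stack Numeric/integer array `height x width x n_frames` (a matrix
#'   is accepted as a single frame).
#' @param masks Integer label matrix (0 outside, 1 background, 2 nucleus,
#'   3 strip) with the same spatial dimensions.
#' @param metadata List with optional `experiment_id`, `cell_id`,
#'   `condition`, `frame_interval` (defaults `"E1"`, `"E1_C01"`, `"sim"`,
#'   `0.4`).
#' @return A trace data.frame in the standard dialect.
#' @export
extract_trace <- function(stack, masks, metadata = list()) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1L))
  if (length(dim(stack)) != 3L) stop_validation("stack must be a h x w x t array")
  if (!all(dim(stack)[1:2] == dim(masks))) {
    stop_validation("stack and mask dimensions disagree: ",
                    paste(dim(stack)[1:2], collapse = "x"), " vs ",
                    paste(dim(masks), collapse = "x"))
  }
  for (lab in c(background = MASK_BACKGROUND, nucleus = MASK_NUCLEUS,
                strip = MASK_STRIP)) {
    if (!any(masks == lab)) {
      stop_validation("mask label missing: ",
                      names(which(c(background = MASK_BACKGROUND,
                                    nucleus = MASK_NUCLEUS,
                                    strip = MASK_STRIP) == lab)),
                      " (", lab, ")")
    }
  }
  n <- dim(stack)[3]
  strip_px <- masks == MASK_STRIP
  bg_px <- masks == MASK_BACKGROUND
  roi <- numeric(n); bg <- numeric(n)
  for (t in seq_len(n)) {
    frame <- stack[, , t]
    roi[t] <- mean(frame[strip_px])
    bg[t] <- mean(frame[bg_px])
  }
  dt <- metadata$frame_interval %||% 0.4
  data.frame(
    experiment_id = metadata$experiment_id %||% "E1",
    cell_id = metadata$cell_id %||% "E1_C01",
    condition = metadata$condition %||% "sim",
    frame = seq_len(n) - 1L,
    time_s = (seq_len(n) - 1L) * dt,
    roi_mean = roi,
    background_mean = bg
  )
}

#' Background-correct a trace
#'
#' Subtracts the extracellular background from the ROI signal frame by
#' frame. Negative corrected values are permitted (they occur in deeply
#' bleached, noisy frames) and are reported via a message.
#'
#' @param trace Trace data.frame (one or several cells).
#' @return The input with an additional `corrected` column.
#' @export
background_correct <- function(trace) {
  validate_traces(trace)
  trace$corrected <- trace$roi_mean - trace$background_mean
  n_neg <- sum(trace$corrected < 0)
  if (n_neg > 0) {
    message("background_correct: ", n_neg,
            " frame(s) with negative background-corrected intensity")
  }
  trace
}

# A cell is identified by (experiment, cell, condition): different
# conditions are different cells even when id labels coincide across files.
split_cells <- function(traces) {
  key <- interaction(traces$experiment_id, traces$cell_id,
                     traces$condition %||% "", drop = TRUE)
  split(traces, key)
}

#' Normalize traces to the mean pre-bleach intensity
#'
#' Per cell: background-correct, divide by the mean of the background-
#' corrected pre-bleach frames (setting the pre-bleach level to exactly 1),
#' drop the bleach frames (their readout during high-power illumination is
#' unreliable), and re-zero time at the first post-bleach frame. The output
#' keeps the pre-bleach frames at negative `time_rel_bleach`.
#'
#' @param traces Trace data.frame (any number of cells).
#' @param protocol The [frap_protocol()] used at acquisition.
#' @return A `frap_curves` data.frame: `experiment_id`, `cell_id`,
#'   `condition`, `time_rel_bleach`, `value`.
#' @export
normalize_prebleach <- function(traces, protocol) {
  stopifnot(inherits(protocol, "frap_protocol"))
  validate_traces(traces)
  npre <- protocol$n_prebleach
  nbl <- protocol$n_bleach
  out <- lapply(split_cells(traces), function(tr) {
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) < npre + nbl + 1L) {
      stop_validation("cell ", tr$cell_id[1], " has ", nrow(tr),
                      " frames; protocol needs at least ", npre + nbl + 1L)
    }
    corrected <- tr$roi_mean - tr$background_mean
    pre_mean <- mean(corrected[seq_len(npre)])
    if (!is.finite(pre_mean) || pre_mean <= 0) {
      stop_validation("cell ", tr$cell_id[1],
                      " has non-positive pre-bleach mean (", signif(pre_mean, 4),
                      "); uninterpretable")
    }
    keep <- setdiff(seq_len(nrow(tr)), npre + seq_len(nbl))
    t0 <- tr$time_s[npre + nbl + 1L]
    data.frame(
      experiment_id = tr$experiment_id[keep],
      cell_id = tr$cell_id[keep],
      condition = tr$condition[keep],
      time_rel_bleach = tr$time_s[keep] - t0,
      value = corrected[keep] / pre_mean
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("frap_curves", "data.frame")
  res
}

#' Hierarchical ensemble average of normalized curves
#'
#' Averages cells within each independent experiment, then averages the
#' per-experiment means without weighting — the convention used when
#' plotting "the average of N independent experiments of 10 cells each".
#' All curves must share one time grid exactly; no interpolation is done.
#'
#' @param curves A `frap_curves` data.frame from [normalize_prebleach()] (or
#'   [normalize_accumulation()], whose time column is accepted too).
#' @return An `ensemble_curve` data.frame with columns `time`, `mean`
#'   (mean of experiment means), `sd_experiments`, `sem_experiments`,
#'   `sd_cells` (dispersion across all cells), and attributes `n_cells`,
#'   `n_experiments`, `condition`.
#' @export
average_ensemble <- function(curves) {
  tcol <- if ("time_rel_bleach" %in% names(curves)) "time_rel_bleach" else
    if ("time_rel_damage" %in% names(curves)) "time_rel_damage" else
      stop_validation("curves must have a time_rel_bleach or time_rel_damage column")
  if (nrow(curves) == 0L) stop_validation("empty curve collection")
  cells <- split(curves, interaction(curves$experiment_id, curves$cell_id, drop = TRUE))
  grid <- cells[[1]][[tcol]]
  for (cc in cells) {
    if (nrow(cc) != length(grid) || any(abs(cc[[tcol]] - grid) > 1e-9)) {
      stop_validation("curves do not share a common time grid (cell ",
                      cc$cell_id[1], "); resample upstream, not here")
    }
  }
  values <- vapply(cells, function(cc) cc$value, numeric(length(grid)))
  exp_of_cell <- vapply(cells, function(cc) cc$experiment_id[1], character(1))
  exps <- unique(exp_of_cell)
  exp_means <- vapply(exps, function(e) {
    rowMeans(values[, exp_of_cell == e, drop = FALSE])
  }, numeric(length(grid)))
  exp_means <- matrix(exp_means, nrow = length(grid))
  res <- data.frame(
    time = grid,
    mean = rowMeans(exp_means),
    sd_experiments = apply(exp_means, 1, stats::sd),
    sem_experiments = apply(exp_means, 1, stats::sd) / sqrt(length(exps)),
    sd_cells = apply(values, 1, stats::sd)
  )
  attr(res, "n_cells") <- length(cells)
  attr(res, "n_experiments") <- length(exps)
  attr(res, "condition") <- curves$condition[1]
  class(res) <- c("ensemble_curve", "data.frame")
  res
}

#' The renormalized immobile-fraction formula
#'
#' `Fimm = 1 - (Ifinal_uv - I0_uv) / (Ifinal_unc - I0_uv)`. Note that both
#' numerator and denominator use the post-bleach intensity of the *treated*
#' curve: the unchallenged condition only supplies the fully recovered
#' plateau. The result is deliberately not clamped to [0, 1].
#'
#' @param i0_uv Treated normalized intensity immediately after bleaching.
#' @param i_final_uv Treated plateau (steady-window mean).
#' @param i_final_unc Unchallenged plateau (steady-window mean).
#' @return The immobile fraction (dimensionless).
#' @examples
#' fimm_formula(0.4, 0.7, 1.0)  # 0.5
#' @export
fimm_formula <- function(i0_uv, i_final_uv, i_final_unc) {
  denom <- i_final_unc - i0_uv
  if (!is.finite(denom) || denom <= 0) {
    stop_numeric("degenerate normalizer: Ifinal_unc - I0_uv = ", signif(denom, 4),
                 " must be positive")
  }
  1 - (i_final_uv - i0_uv) / denom
}

window_mean <- function(curve, window, what) {
  sel <- curve$time >= window[1] - 1e-9 & curve$time <= window[2] + 1e-9
  if (!any(sel)) {
    stop_validation("steady window [", window[1], ", ", window[2],
                    "] s contains no frames of the ", what, " curve")
  }
  mean(curve$mean[sel])
}

#' Immobile fraction of a treated ensemble relative to an unchallenged one
#'
#' `I0` is the treated curve's value at the first post-bleach frame (time
#' 0); `Ifinal` values are means over frames whose time falls inside the
#' steady window (endpoints inclusive, membership decided with 1e-9
#' tolerance). The statistic is computed on ensemble-mean curves by default;
#' see [immobile_fraction_cells()] for the per-cell variant.
#'
#' @param treated `ensemble_curve` of the challenged condition.
#' @param reference `ensemble_curve` of the unchallenged condition.
#' @param window Two seconds (relative to the first post-bleach frame); by
#'   default taken from `protocol$steady_window` if supplied.
#' @param protocol Optional [frap_protocol()] supplying the default window.
#' @return An `immobile_fraction_result`: `f_imm_hat`, the three formula
#'   ingredients, the window and the condition labels.
#' @export
immobile_fraction <- function(treated, reference, window = NULL, protocol = NULL) {
  if (is.null(window)) {
    if (is.null(protocol)) stop_validation("supply a window or a protocol")
    window <- protocol$steady_window
  }
  if (length(window) != 2L || window[1] >= window[2]) {
    stop_validation("window must be two increasing numbers")
  }
  i0_row <- which(abs(treated$time) <= 1e-9)
  if (length(i0_row) != 1L) {
    stop_validation("treated curve has no frame at time 0 (first post-bleach frame)")
  }
  i0_uv <- treated$mean[i0_row]
  i_final_uv <- window_mean(treated, window, "treated")
  i_final_unc <- window_mean(reference, window, "reference")
  structure(list(
    f_imm_hat = fimm_formula(i0_uv, i_final_uv, i_final_unc),
    i0_uv = i0_uv, i_final_uv = i_final_uv, i_final_unc = i_final_unc,
    window = as.numeric(window),
    treated_condition = attr(treated, "condition"),
    reference_condition = attr(reference, "condition"),
    n_cells_treated = attr(treated, "n_cells"),
    n_cells_reference = attr(reference, "n_cells")
  ), class = "immobile_fraction_result")
}

#' @export
print.immobile_fraction_result <- function(x, ...) {
  cat(sprintf("immobile fraction: %.4f\n", x$f_imm_hat))
  cat(sprintf("  I0 = %.4f, Ifinal(treated) = %.4f, Ifinal(reference) = %.4f\n",
              x$i0_uv, x$i_final_uv, x$i_final_unc))
  cat(sprintf("  steady window [%g, %g] s; %s vs %s\n", x$window[1], x$window[2],
              x$treated_condition %||% "?", x$reference_condition %||% "?"))
  invisible(x)
}

#' Per-cell immobile fractions
#'
#' Applies the immobile-fraction formula to each treated cell's own curve
#' (its I0 and window mean) against the shared unchallenged ensemble
#' plateau, returning the distribution instead of a single ensemble value.
#'
#' @param treated_curves `frap_curves` of the challenged condition.
#' @param reference `ensemble_curve` of the unchallenged condition.
#' @inheritParams immobile_fraction
#' @return Data.frame with one row per treated cell (`experiment_id`,
#'   `cell_id`, `f_imm_hat`, `i0_uv`, `i_final_uv`).
#' @export
immobile_fraction_cells <- function(treated_curves, reference, window = NULL,
                                    protocol = NULL) {
  if (is.null(window)) {
    if (is.null(protocol)) stop_validation("supply a window or a protocol")
    window <- protocol$steady_window
  }
  i_final_unc <- window_mean(reference, window, "reference")
  rows <- lapply(split_cells(treated_curves), function(cc) {
    curve <- data.frame(time = cc$time_rel_bleach, mean = cc$value)
    i0_row <- which(abs(curve$time) <= 1e-9)
    if (length(i0_row) != 1L) {
      stop_validation("cell ", cc$cell_id[1], " has no frame at time 0")
    }
    i0 <- curve$mean[i0_row]
    ifin <- window_mean(curve, window, cc$cell_id[1])
    data.frame(experiment_id = cc$experiment_id[1], cell_id = cc$cell_id[1],
               f_imm_hat = fimm_formula(i0, ifin, i_final_unc),
               i0_uv = i0, i_final_uv = ifin)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Fit the closed-form two-binding-state model to an ensemble curve
#'
#' Nonlinear least squares (Levenberg-Marquardt with box bounds) of
#' [closed_form_recovery()] against the post-bleach part of an ensemble
#' curve. Free parameters: `f_free`, `f_exch` (with `f_imm = 1 - f_free -
#' f_exch`), `koff`, `tau_diff` and `bleach_depth`. Starting values are
#' derived from the curve itself: the first post-bleach value seeds the
#' bleach depth, the late plateau seeds the immobile fraction, and the time
#' to half recovery seeds the rates. Non-convergence and degenerate (flat)
#' curves are flagged, never silent.
#'
#' @param curve An `ensemble_curve` with at least 8 post-bleach points.
#' @param lower,upper Named bounds on `(f_free, f_exch, koff, tau_diff,
#'   bleach_depth)`.
#' @return A `kinetic_fit` list: estimates, `residual_rms`, `converged`,
#'   `degenerate`.
#' @export
fit_two_state <- function(curve,
                          lower = c(f_free = 0, f_exch = 0, koff = 1e-4,
                                    tau_diff = 1e-4, bleach_depth = 0),
                          upper = c(f_free = 1, f_exch = 1, koff = 50,
                                    tau_diff = 50, bleach_depth = 1)) {
  post <- curve[curve$time >= -1e-9, , drop = FALSE]
  if (nrow(post) < 8L) stop_validation("need at least 8 post-bleach points")
  tt <- post$time
  yy <- post$mean

  result <- function(f_free, f_exch, koff, tau_diff, bleach_depth, rms,
                     converged, degenerate = FALSE) {
    f_imm <- 1 - f_free - f_exch
    structure(list(f_free = f_free, f_exch = f_exch, f_imm = f_imm,
                   koff = koff, tau_diff = tau_diff,
                   bleach_depth = bleach_depth, residual_rms = rms,
                   converged = converged, degenerate = degenerate),
              class = "kinetic_fit")
  }

  if (max(yy) - min(yy) < 1e-8) {
    # flat curve: no bleach signature, kinetics unidentifiable; the plateau
    # still pins the immobile fraction through the asymptote relation
    out <- result(f_free = NA_real_, f_exch = NA_real_, koff = NA_real_,
                  tau_diff = NA_real_, bleach_depth = mean(yy), rms = 0,
                  converged = TRUE, degenerate = TRUE)
    out$f_imm <- max(0, 1 - mean(yy))
    return(out)
  }

  bd0 <- min(max(yy[1], 0), 1)
  tail_mean <- mean(yy[tt >= stats::quantile(tt, 0.75)])
  f_imm0 <- min(max((1 - tail_mean) / max(1 - bd0, 1e-6), 0), 0.95)
  mobile0 <- 1 - f_imm0
  half_level <- (bd0 + tail_mean) / 2
  t_half <- suppressWarnings(min(tt[yy >= half_level & tt > 0]))
  if (!is.finite(t_half)) t_half <- stats::median(tt[tt > 0])
  start <- c(f_free = 0.3 * mobile0, f_exch = 0.7 * mobile0,
             koff = min(max(log(2) / t_half, lower["koff"]), upper["koff"]),
             tau_diff = min(max(t_half / 10, lower["tau_diff"]), upper["tau_diff"]),
             bleach_depth = bd0)
  start <- pmin(pmax(start, lower + 1e-6), upper - 1e-6)

  model <- function(p) {
    diff_part <- 1 - exp(-tt / p["tau_diff"])
    bind_part <- 1 - exp(-p["koff"] * tt)
    p["bleach_depth"] + (1 - p["bleach_depth"]) *
      (p["f_free"] * diff_part + p["f_exch"] * bind_part)
  }

  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = function(p) yy - model(p),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL
  )
  if (is.null(fit) || fit$info %in% c(0, 5, 9)) {
    return(result(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_,
                  rms = NA_real_, converged = FALSE))
  }
  p <- fit$par
  rms <- sqrt(mean((yy - model(p))^2))
  out <- result(unname(p["f_free"]), unname(p["f_exch"]), unname(p["koff"]),
                unname(p["tau_diff"]), unname(p["bleach_depth"]),
                rms = rms, converged = TRUE)
  if (out$f_free + out$f_exch > 1 + 1e-9) out$degenerate <- TRUE
  out
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("two-state kinetic fit\n")
  cat(sprintf("  f_free %.4f, f_exch %.4f, f_imm %.4f\n", x$f_free, x$f_exch, x$f_imm))
  cat(sprintf("  koff %.4g /s, tau_diff %.4g s, bleach depth %.4f\n",
              x$koff, x$tau_diff, x$bleach_depth))
  cat(sprintf("  residual RMS %.4g; converged: %s%s\n", x$residual_rms,
              x$converged, if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}
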