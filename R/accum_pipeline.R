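#' Normalize accumulation traces to the pre-damage level
#'
#' Per cell: background-correct, divide by the mean of the first
#' `n_predamage` background-corrected frames (the pre-damage level is set to
#' exactly 1.0), and re-zero time at damage induction, i.e. at the frame
#' following the pre-damage block.
#'
#' @param traces Trace data.frame (any number of cells).
#' @param n_predamage Number of pre-damage frames (>= 1).
#' @return An `accumulation_curves` data.frame: `experiment_id`, `cell_id`,
#'   `condition`, `time_rel_damage`, `value`.
#' @export
normalize_accumulation <- function(traces, n_predamage) {
  check_number(n_predamage, "n_predamage", min = 1, integer = TRUE)
  validate_traces(traces)
  out <- lapply(split_cells(traces), function(tr) {
    tr <- tr[order(tr$frame), ]
    if (nrow(tr) <= n_predamage) {
      stop_validation("cell ", tr$cell_id[1], " has ", nrow(tr),
                      " frames; need more than n_predamage = ", n_predamage)
    }
    corrected <- tr$roi_mean - tr$background_mean
    pre_mean <- mean(corrected[seq_len(n_predamage)])
    if (!is.finite(pre_mean) || pre_mean <= 0) {
      stop_validation("cell ", tr$cell_id[1],
                      " has non-positive pre-damage mean (", signif(pre_mean, 4), ")")
    }
    data.frame(
      experiment_id = tr$experiment_id,
      cell_id = tr$cell_id,
      condition = tr$condition,
      time_rel_damage = tr$time_s - tr$time_s[n_predamage + 1L],
      value = corrected / pre_mean
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("accumulation_curves", "data.frame")
  res
}

#' Plateau accumulation fold of an ensemble curve
#'
#' Mean of the ensemble-mean relative intensity over a late window,
#' mirroring the steady-window mechanism of the immobile-fraction statistic.
#'
#' @param ensemble An `ensemble_curve` (from [average_ensemble()] applied to
#'   accumulation curves).
#' @param window Two seconds relative to damage induction.
#' @return The plateau fold (dimensionless).
#' @export
accumulation_plateau <- function(ensemble, window) {
  if (length(window) != 2L || window[1] >= window[2]) {
    stop_validation("window must be two increasing numbers")
  }
  window_mean(ensemble, window, "accumulation")
}

#' Area under an accumulation (or any time-value) curve
#'
#' Trapezoidal integral of the curve over `range` (units: relative
#' fluorescence x seconds). Endpoints falling between frames are included by
#' linear interpolation; the range must be covered by the curve.
#'
#' @param curve Data.frame with a time column (`time`, `time_rel_damage` or
#'   `time_rel_bleach`) and a `value` (or `mean`) column.
#' @param range Two seconds `c(from, to)`.
#' @return The integral (scalar).
#' @examples
#' curve_auc(data.frame(time = 0:10, value = 1), c(0, 10))  # 10
#' @export
curve_auc <- function(curve, range) {
  tcol <- intersect(c("time", "time_rel_damage", "time_rel_bleach"), names(curve))[1]
  vcol <- intersect(c("value", "mean"), names(curve))[1]
  if (is.na(tcol) || is.na(vcol)) {
    stop_validation("curve must have a time and a value column")
  }
  if (length(range) != 2L || range[1] >= range[2]) {
    stop_validation("empty or inverted integration range")
  }
  x <- curve[[tcol]]; y <- curve[[vcol]]
  o <- order(x); x <- x[o]; y <- y[o]
  if (range[1] < x[1] - 1e-9 || range[2] > x[length(x)] + 1e-9) {
    stop_validation("integration range [", range[1], ", ", range[2],
                    "] not covered by the curve [", x[1], ", ", x[length(x)], "]")
  }
  inside <- x > range[1] & x < range[2]
  xs <- c(range[1], x[inside], range[2])
  ys <- stats::approx(x, y, xout = xs)$y
  n <- length(xs)
  sum(diff(xs) * (ys[-1] + ys[-n]) / 2)
}

#' Compare per-cell AUC values between two groups by unpaired t test
#'
#' Equal-variance two-sample t test by default (the convention of the usual
#' graphing software); set `welch = TRUE` for the unequal-variance form.
#' When both groups are constant and equal, the statistic is undefined and
#' the result is returned as t = 0, p = 1 with `degenerate = TRUE`.
#'
#' @param group_a,group_b Numeric vectors of per-cell AUCs (each >= 2).
#' @param welch Use the Welch correction.
#' @return An `auc_test_result`: per-group values and means, `t`, `df`,
#'   two-sided `p`.
#' @export
compare_auc <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop_validation("each group needs at least 2 AUC values")
  }
  res <- tryCatch(
    stats::t.test(group_a, group_b, var.equal = !welch),
    error = function(e) NULL
  )
  degenerate <- is.null(res)
  if (degenerate) {
    if (!isTRUE(all.equal(mean(group_a), mean(group_b)))) {
      stop_numeric("t test failed on non-degenerate input")
    }
    message("compare_auc: zero variance in both groups with equal means; p = 1 by convention")
  }
  structure(list(
    auc_a = group_a, auc_b = group_b,
    mean_a = mean(group_a), mean_b = mean(group_b),
    t = if (degenerate) 0 else unname(res$statistic),
    df = if (degenerate) length(group_a) + length(group_b) - 2 else unname(res$parameter),
    p = if (degenerate) 1 else res$p.value,
    welch = welch, degenerate = degenerate
  ), class = "auc_test_result")
}

#' @export
print.auc_test_result <- function(x, ...) {
  cat(sprintf("AUC comparison (%s t test): t = %.4g, df = %.4g, p = %.4g\n",
              if (x$welch) "Welch" else "equal-variance", x$t, x$df, x$p))
  cat(sprintf("  group means %.4g (n = %d) vs %.4g (n = %d)%s\n",
              x$mean_a, length(x$auc_a), x$mean_b, length(x$auc_b),
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Per-cell AUCs of a curve collection
#'
#' Convenience wrapper applying [curve_auc()] to every cell.
#'
#' @param curves `accumulation_curves` (or `frap_curves`).
#' @param range Integration range in seconds.
#' @return Named numeric vector of AUCs, one per cell.
#' @export
cell_aucs <- function(curves, range) {
  vapply(split_cells(curves), curve_auc, numeric(1), range = range)
}
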