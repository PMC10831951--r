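#' Rectangular forward/side-scatter gate
#'
#' Selects single viable cells on the FSC-A / SSC-A plane. The default
#' bounds match the simulator's population geometry: they retain the intact
#' singles cluster while excluding low-scatter debris and the doublet
#' cluster at twice the single-cell scatter.
#'
#' @param fsc Two increasing FSC-A bounds.
#' @param ssc Two increasing SSC-A bounds.
#' @param warn_below Emit a warning when the retained fraction falls below
#'   this value (in (0,1)).
#' @return An object of class `gate_config`.
#' @export
gate_config <- function(fsc = c(5e4, 1.55e5), ssc = c(2e4, 1.15e5),
                        warn_below = 0.5) {
  if (length(fsc) != 2L || fsc[1] >= fsc[2]) stop_validation("fsc bounds out of order")
  if (length(ssc) != 2L || ssc[1] >= ssc[2]) stop_validation("ssc bounds out of order")
  check_number(warn_below, "warn_below", min = 0, max = 1)
  structure(list(fsc = as.numeric(fsc), ssc = as.numeric(ssc),
                 warn_below = warn_below), class = "gate_config")
}

#' @rdname gate_config
#' @export
default_flow_gate <- function() gate_config()

#' Gate a flow-cytometry event table
#'
#' Retains events inside the rectangular FSC-A/SSC-A gate, reports the
#' retained fraction (attribute `retained_fraction` and a message), and
#' warns when it drops below the configured threshold. Gating is idempotent.
#'
#' @param events Data.frame with columns `fsc_a`, `ssc_a`, `rfp` (an
#'   `event_id`/`sample` column is carried through).
#' @param gate A [gate_config()].
#' @return The gated subset of `events`.
#' @export
gate_events <- function(events, gate = default_flow_gate()) {
  stopifnot(inherits(gate, "gate_config"))
  missing <- setdiff(c("fsc_a", "ssc_a", "rfp"), names(events))
  if (length(missing) > 0) {
    stop_validation("event table lacks column(s): ", paste(missing, collapse = ", "))
  }
  keep <- events$fsc_a >= gate$fsc[1] & events$fsc_a <= gate$fsc[2] &
    events$ssc_a >= gate$ssc[1] & events$ssc_a <= gate$ssc[2]
  retained <- sum(keep) / nrow(events)
  if (sum(keep) == 0L) stop_validation("gate retains no events")
  if (retained < gate$warn_below) {
    warning("gate retains only ", signif(100 * retained, 3), "% of events",
            call. = FALSE)
  }
  message("gate_events: retained ", sum(keep), "/", nrow(events), " events (",
          signif(100 * retained, 4), "%)")
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "retained_fraction") <- retained
  out
}

#' Relative protein levels from gated mean fluorescence
#'
#' Mean RFP intensity per sample (arithmetic mean of the linear
#' fluorescence, the "average FI" statistic; use `geometric = TRUE` for the
#' log-mean alternative), expressed relative to a reference sample set to
#' 100.
#'
#' @param events Gated event table with a `sample` column.
#' @param reference Label of the reference (e.g. untreated) sample.
#' @param geometric Use the geometric instead of the arithmetic mean.
#' @return A `relative_levels` data.frame: `sample`, `n_events`,
#'   `mean_rfp`, `sd_rfp`, `relative_level` (reference = 100 exactly).
#' @export
relative_levels <- function(events, reference, geometric = FALSE) {
  if (!"sample" %in% names(events)) stop_validation("event table lacks a sample column")
  if (!reference %in% events$sample) {
    stop_validation("reference sample '", reference, "' not present")
  }
  stat <- if (geometric) function(x) exp(mean(log(pmax(x, .Machine$double.eps))))
  else mean
  groups <- split(events$rfp, events$sample)
  means <- vapply(groups, stat, numeric(1))
  if (!is.finite(means[[reference]]) || means[[reference]] <= 0) {
    stop_numeric("reference mean fluorescence must be positive")
  }
  res <- data.frame(
    sample = names(groups),
    n_events = vapply(groups, length, integer(1)),
    mean_rfp = unname(means),
    sd_rfp = vapply(groups, stats::sd, numeric(1)),
    relative_level = unname(100 * means / means[[reference]])
  )
  rownames(res) <- NULL
  class(res) <- c("relative_levels", "data.frame")
  res
}

#' Relative transcription score (recovery of RNA synthesis)
#'
#' Relative integrated density of nucleotide-analog incorporation: the mean
#' per-cell integrated intensity of a treated group divided by the mock
#' group's mean, scaled so mock = 100. Per-cell relative values are returned
#' for plotting and downstream ANOVA.
#'
#' @param treated,mock Numeric vectors of per-cell integrated intensities.
#' @return An `rrs_score` list: `score` (percent), `per_cell_relative`,
#'   group sizes.
#' @export
rrs_score <- function(treated, mock) {
  if (length(treated) < 1L || length(mock) < 1L) {
    stop_validation("both groups must be non-empty")
  }
  mock_mean <- mean(mock)
  if (!is.finite(mock_mean) || mock_mean <= 0) {
    stop_numeric("mock mean integrated intensity must be positive")
  }
  structure(list(
    score = 100 * mean(treated) / mock_mean,
    per_cell_relative = 100 * treated / mock_mean,
    n_treated = length(treated), n_mock = length(mock)
  ), class = "rrs_score")
}

#' @export
print.rrs_score <- function(x, ...) {
  cat(sprintf("relative RNA synthesis: %.1f%% of mock (n = %d treated, %d mock cells)\n",
              x$score, x$n_treated, x$n_mock))
  invisible(x)
}
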