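# CSV/TIFF/JSON dialects. CSV is used for traces and events so fixtures stay
# human-diffable; TIFF only for the optional image mode.

TRACE_COLUMNS <- c("experiment_id", "cell_id", "condition", "frame", "time_s",
                   "roi_mean", "background_mean")
EVENT_COLUMNS <- c("event_id", "sample", "fsc_a", "ssc_a", "rfp")

# Structural validation shared by read_traces() and the pipeline entry
# points. `lines`: original file line numbers (header = line 1) for error
# reporting; defaults to in-memory row numbers.
validate_traces <- function(traces, lines = seq_len(nrow(traces)) + 1L) {
  missing <- setdiff(TRACE_COLUMNS, names(traces))
  if (length(missing) > 0) {
    stop_validation("trace table lacks column(s): ", paste(missing, collapse = ", "))
  }
  num <- c("frame", "time_s", "roi_mean", "background_mean")
  for (col in num) {
    bad <- which(!is.finite(traces[[col]]))
    if (length(bad) > 0) {
      stop_validation("non-finite ", col, " at line ", lines[bad[1]])
    }
  }
  key <- interaction(traces$experiment_id, traces$cell_id, traces$condition,
                     drop = TRUE)
  for (idx in split(seq_len(nrow(traces)), key)) {
    idx <- idx[order(traces$frame[idx])]
    fr <- traces$frame[idx]
    dup <- which(duplicated(fr))
    if (length(dup) > 0) {
      stop_validation("duplicate (cell, frame) at line ", lines[idx[dup[1]]],
                      " (cell ", traces$cell_id[idx[1]], ", frame ", fr[dup[1]], ")")
    }
    gap <- which(diff(fr) != 1L)
    if (length(gap) > 0) {
      stop_validation("non-contiguous frames for cell ", traces$cell_id[idx[1]],
                      " at line ", lines[idx[gap[1] + 1L]])
    }
    tm <- traces$time_s[idx]
    bad <- which(diff(tm) <= 0)
    if (length(bad) > 0) {
      stop_validation("time not strictly increasing for cell ",
                      traces$cell_id[idx[1]], " at line ", lines[idx[bad[1] + 1L]])
    }
  }
  invisible(traces)
}

#' Read and write intensity traces (CSV dialect)
#'
#' The trace dialect is a UTF-8 CSV with a header row and exactly the
#' columns `experiment_id, cell_id, condition, frame, time_s, roi_mean,
#' background_mean`. `read_traces()` validates strictly (header, finiteness,
#' contiguous frames, strictly increasing time, no duplicate (cell, frame))
#' and reports the offending file line in errors; rows are returned grouped
#' by (experiment, cell) in frame order.
#'
#' @param path File path.
#' @param traces Trace data.frame to write.
#' @return `read_traces()`: a validated trace data.frame;
#'   `write_traces()`: the path, invisibly.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop_validation("trace file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  if (!identical(header, TRACE_COLUMNS)) {
    off <- which(header != TRACE_COLUMNS[seq_along(header)])
    detail <- if (length(header) != length(TRACE_COLUMNS)) {
      paste0("expected ", length(TRACE_COLUMNS), " columns, found ", length(header))
    } else {
      paste0("column ", off[1], " is '", header[off[1]], "', expected '",
             TRACE_COLUMNS[off[1]], "'")
    }
    stop_validation("trace header mismatch in ", path, ": ", detail)
  }
  traces <- utils::read.csv(path, colClasses = c(
    experiment_id = "character", cell_id = "character", condition = "character",
    frame = "integer", time_s = "numeric", roi_mean = "numeric",
    background_mean = "numeric"))
  validate_traces(traces)
  o <- order(traces$experiment_id, traces$cell_id, traces$condition, traces$frame)
  traces <- traces[o, , drop = FALSE]
  rownames(traces) <- NULL
  traces
}

#' @rdname read_traces
#' @export
write_traces <- function(traces, path) {
  validate_traces(traces)
  utils::write.csv(traces[, TRACE_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write flow-cytometry event tables (CSV dialect)
#'
#' Columns: `event_id, sample, fsc_a, ssc_a, rfp`.
#'
#' @param path File path.
#' @param events Event data.frame to write.
#' @return `read_events()`: the event data.frame; `write_events()`: the
#'   path, invisibly.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop_validation("event file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), ",")[[1]]
  if (!identical(header, EVENT_COLUMNS)) {
    stop_validation("event header mismatch in ", path, ": expected '",
                    paste(EVENT_COLUMNS, collapse = ","), "'")
  }
  ev <- utils::read.csv(path, colClasses = c(
    event_id = "integer", sample = "character", fsc_a = "numeric",
    ssc_a = "numeric", rfp = "numeric"))
  for (col in c("fsc_a", "ssc_a", "rfp")) {
    bad <- which(!is.finite(ev[[col]]))
    if (length(bad) > 0) stop_validation("non-finite ", col, " at line ", bad[1] + 1L)
  }
  ev
}

#' @rdname read_events
#' @export
write_events <- function(events, path) {
  missing <- setdiff(EVENT_COLUMNS, names(events))
  if (length(missing) > 0) {
    stop_validation("event table lacks column(s): ", paste(missing, collapse = ", "))
  }
  utils::write.csv(events[, EVENT_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and read a ground-truth JSON sidecar
#'
#' Serializes a `sim_truth` record (generating parameters, derived
#' fractions) next to a simulated dataset so recovery tests can load both.
#'
#' @param truth A `sim_truth` object (or any list of scalars/lists).
#' @param path File path (conventionally `<data>.truth.json`).
#' @return `write_truth()`: the path, invisibly; `read_truth()`: a list.
#' @export
write_truth <- function(truth, path) {
  ser <- unclass(truth)
  ser$config <- if (!is.null(ser$config)) {
    cfg <- unclass(ser$config)
    cfg$noise_model <- if (!is.null(cfg$noise_model)) unclass(cfg$noise_model)
    cfg
  }
  ser$protocol <- if (!is.null(ser$protocol)) unclass(ser$protocol)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop_validation("truth file not found: ", path)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write and read a 16-bit multi-page TIFF image stack with its label masks
#'
#' The stack is stored as one grayscale 16-bit page per frame; masks as a
#' single 8-bit page (0 = outside, 1 = background region, 2 = nucleus,
#' 3 = strip).
#'
#' @param stack Integer array `height x width x n_frames` (values 0..65535).
#' @param masks Integer label matrix.
#' @param path Stack path; `mask_path` defaults to `<path>.masks.tif`.
#' @param mask_path Path of the mask TIFF.
#' @return Writers return paths invisibly; readers the array/matrix.
#' @export
write_image_stack <- function(stack, masks, path,
                              mask_path = paste0(path, ".masks.tif")) {
  if (length(dim(stack)) != 3L) stop_validation("stack must be a h x w x t array")
  pages <- lapply(seq_len(dim(stack)[3]), function(t) stack[, , t] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  tiff::writeTIFF(masks / 255, mask_path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path, mask_path = paste0(path, ".masks.tif")) {
  if (!file.exists(path)) stop_validation("image stack not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  stack <- array(0L, dim = c(dim(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) {
    stack[, , t] <- as.integer(round(pages[[t]] * 65535))
  }
  masks <- NULL
  if (file.exists(mask_path)) {
    masks <- matrix(as.integer(round(tiff::readTIFF(mask_path) * 255)),
                    nrow = dim(stack)[1])
  }
  list(stack = stack, masks = masks)
}
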