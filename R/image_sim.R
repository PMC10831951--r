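#' Geometry of a synthetic strip-FRAP image frame
#'
#' Defines, in pixel coordinates, the nucleus ellipse, the bleach/readout
#' strip rectangle and an extracellular background rectangle used by
#' [render_image_stack()]. Rectangles are given as `c(x0, y0, x1, y1)`
#' (inclusive pixel ranges, 1-based); the ellipse as
#' `c(cx, cy, rx, ry)`. All regions must lie strictly inside the frame and
#' the background region must not touch the nucleus.
#'
#' @param width,height Frame size in pixels.
#' @param nucleus Ellipse `c(cx, cy, rx, ry)`.
#' @param strip Rectangle `c(x0, y0, x1, y1)`, the measured strip.
#' @param background Rectangle `c(x0, y0, x1, y1)` outside the cell.
#' @param nucleus_level Fluorescence of nuclear pixels outside the strip (a.u.).
#' @param background_level Extracellular light level (a.u.).
#' @return An object of class `image_geometry`.
#' @export
image_geometry <- function(width = 96, height = 96,
                           nucleus = c(48, 48, 34, 26),
                           strip = c(40, 26, 56, 70),
                           background = c(2, 2, 14, 14),
                           nucleus_level = 100,
                           background_level = 10) {
  check_number(width, "width", min = 4, integer = TRUE)
  check_number(height, "height", min = 4, integer = TRUE)
  check_rect <- function(r, name) {
    if (length(r) != 4L || any(!is.finite(r))) {
      stop_validation(name, " must be c(x0, y0, x1, y1)")
    }
    if (r[1] > r[3] || r[2] > r[4]) stop_validation(name, " corners out of order")
    if (r[1] < 1 || r[2] < 1 || r[3] > width || r[4] > height) {
      stop_validation(name, " overlaps the frame boundary")
    }
  }
  check_rect(strip, "strip")
  check_rect(background, "background")
  if (length(nucleus) != 4L || any(!is.finite(nucleus)) || any(nucleus[3:4] <= 0)) {
    stop_validation("nucleus must be c(cx, cy, rx, ry) with positive radii")
  }
  if (nucleus[1] - nucleus[3] < 1 || nucleus[1] + nucleus[3] > width ||
      nucleus[2] - nucleus[4] < 1 || nucleus[2] + nucleus[4] > height) {
    stop_validation("nucleus overlaps the frame boundary")
  }
  check_number(nucleus_level, "nucleus_level", min = 0)
  check_number(background_level, "background_level", min = 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 nucleus = as.numeric(nucleus), strip = as.numeric(strip),
                 background = as.numeric(background),
                 nucleus_level = nucleus_level,
                 background_level = background_level),
            class = "image_geometry")
}

# label codes of the mask image
MASK_OUTSIDE <- 0L
MASK_BACKGROUND <- 1L
MASK_NUCLEUS <- 2L
MASK_STRIP <- 3L

build_masks <- function(geometry) {
  w <- geometry$width; h <- geometry$height
  x <- matrix(rep(seq_len(w), each = h), nrow = h)
  y <- matrix(rep(seq_len(h), times = w), nrow = h)
  masks <- matrix(MASK_OUTSIDE, nrow = h, ncol = w)
  nuc <- geometry$nucleus
  in_nucleus <- ((x - nuc[1]) / nuc[3])^2 + ((y - nuc[2]) / nuc[4])^2 <= 1
  masks[in_nucleus] <- MASK_NUCLEUS
  s <- geometry$strip
  in_strip <- x >= s[1] & x <= s[3] & y >= s[2] & y <= s[4] & in_nucleus
  masks[in_strip] <- MASK_STRIP
  b <- geometry$background
  in_bg <- x >= b[1] & x <= b[3] & y >= b[2] & y <= b[4]
  if (any(in_bg & in_nucleus)) {
    stop_validation("background region overlaps the nucleus")
  }
  masks[in_bg] <- MASK_BACKGROUND
  if (!any(masks == MASK_STRIP)) stop_validation("strip does not intersect the nucleus")
  masks
}

#' Render a synthetic 16-bit time-lapse stack from a strip-intensity profile
#'
#' Produces an image stack whose strip-mask mean per frame reproduces the
#' input profile (within noise), together with the label masks needed to
#' extract it back: 0 = outside, 1 = background region, 2 = nucleus,
#' 3 = strip. Values are rounded to 16-bit integers. The round-trip property
#' `extract_trace(render_image_stack(profile)) ~ profile` is what the image
#' mode of the pipeline is tested against.
#'
#' @param profile Numeric vector: noise-free strip fluorescence per frame
#'   (a.u., before background addition).
#' @param geometry An [image_geometry()].
#' @param noise_model See [noise_gaussian()].
#' @param seed Optional RNG seed (integer) for the pixel noise.
#' @return A list with `stack` (integer array `height x width x n_frames`)
#'   and `masks` (integer label matrix `height x width`).
#' @export
render_image_stack <- function(profile, geometry = image_geometry(),
                               noise_model = noise_none(), seed = NULL) {
  if (!is.numeric(profile) || length(profile) < 1L || any(!is.finite(profile))) {
    stop_validation("profile must be a finite numeric vector")
  }
  noise_model <- as_noise_model(noise_model)
  if (!is.null(seed)) set.seed(seed)
  masks <- build_masks(geometry)
  h <- geometry$height; w <- geometry$width
  n <- length(profile)
  stack <- array(0L, dim = c(h, w, n))
  base <- matrix(geometry$background_level, nrow = h, ncol = w)
  base[masks == MASK_NUCLEUS] <- geometry$nucleus_level + geometry$background_level
  strip_px <- masks == MASK_STRIP
  for (t in seq_len(n)) {
    frame <- base
    frame[strip_px] <- profile[t] + geometry$background_level
    frame <- apply_noise(as.vector(frame), noise_model)
    frame <- matrix(pmin(pmax(round(frame), 0), 65535), nrow = h)
    stack[, , t] <- as.integer(frame)
  }
  list(stack = stack, masks = masks)
}
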