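#' Measurement-noise models for the simulators
#'
#' The generators accept a noise descriptor built by one of these
#' constructors. `noise_gaussian()` adds zero-mean Gaussian noise whose
#' standard deviation is `cv` times the noise-free signal (the default model:
#' single-cell FRAP curves acquired on a confocal are visually smooth, with a
#' relative spread of around 5%). `noise_poisson()` draws photon counts
#' `Poisson(signal * scale) / scale`, i.e. `scale` counts per arbitrary
#' fluorescence unit. `noise_none()` disables noise, which the conservation
#' and oracle-equivalence checks rely on.
#'
#' @param cv Coefficient of variation of the Gaussian model (dimensionless).
#' @param scale Photon counts per fluorescence unit for the Poisson model.
#' @return A list describing the noise model.
#' @export
noise_gaussian <- function(cv = 0.05) {
  check_number(cv, "cv", min = 0)
  structure(list(type = "gaussian", cv = cv), class = "frap_noise_model")
}

#' @rdname noise_gaussian
#' @export
noise_poisson <- function(scale = 1) {
  check_number(scale, "scale", min = 1e-12)
  structure(list(type = "poisson", scale = scale), class = "frap_noise_model")
}

#' @rdname noise_gaussian
#' @export
noise_none <- function() {
  structure(list(type = "none"), class = "frap_noise_model")
}

# Apply a noise model to a vector of non-negative noise-free intensities.
apply_noise <- function(values, model) {
  switch(model$type,
    none = values,
    gaussian = values + stats::rnorm(length(values), mean = 0, sd = model$cv * abs(values)),
    poisson = stats::rpois(length(values), lambda = pmax(values, 0) * model$scale) / model$scale,
    stop_validation("unknown noise model type: ", model$type)
  )
}

as_noise_model <- function(x) {
  if (inherits(x, "frap_noise_model")) return(x)
  if (is.list(x) && !is.null(x$type)) {
    return(switch(x$type,
      none = noise_none(),
      gaussian = noise_gaussian(x$cv %||% 0.05),
      poisson = noise_poisson(x$scale %||% 1),
      stop_validation("unknown noise model type: ", x$type)
    ))
  }
  stop_validation("noise_model must be built by noise_gaussian()/noise_poisson()/noise_none()")
}
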