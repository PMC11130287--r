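#' Generate a synthetic EPR power-saturation curve
#'
#' Evaluates the saturation model [saturation_model()] on a power grid and
#' adds additive Gaussian amplitude noise. The default grid is the 2-30 dB
#' (2 dB steps) attenuation series of a 200 mW source, i.e. 0.2-126.2 mW.
#'
#' @param I amplitude scaling factor.
#' @param P_half half-saturation power in mW (> 0).
#' @param epsilon homogeneity exponent in `[0.5, 1.5]` (1.5 = homogeneous).
#' @param powers power grid in mW, all > 0.
#' @param noise_sd additive Gaussian noise sd in amplitude units.
#' @param seed integer seed.
#' @param site,condition optional labels attached as columns.
#' @return tibble with columns `site`, `condition`, `power_mW`, `amplitude`;
#'   true parameters attached as attribute `ground_truth`.
#' @export
gen_saturation_curve <- function(I, P_half, epsilon,
                                 powers = default_power_grid(),
                                 noise_sd = 0, seed = 1L,
                                 site = NA_character_,
                                 condition = NA_character_) {
  if (P_half <= 0) abort("P_half must be > 0")
  if (any(powers <= 0)) abort("all powers must be > 0")
  if (epsilon < 0.5 || epsilon > 1.5) abort("epsilon must lie in [0.5, 1.5]")
  A <- saturation_model(powers, I, P_half, epsilon)
  if (noise_sd > 0) {
    A <- with_seed(
      substream_seed(seed, 101L),
      A + rnorm(length(A), 0, noise_sd)
    )
  }
  out <- tibble(
    site = site, condition = condition,
    power_mW = powers, amplitude = A
  )
  attr(out, "ground_truth") <- list(
    I = I, P_half = P_half, epsilon = epsilon,
    noise_sd = noise_sd, seed = seed
  )
  out
}
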