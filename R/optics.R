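#' Optical properties of a tissue
#'
#' @param mu_a absorption coefficient (mm^-1), > 0.
#' @param mu_s_prime reduced scattering coefficient (1-g)*mu_s (mm^-1),
#'   > 0.
#' @param g scattering anisotropy factor, in [0, 1).
#' @return an object of class `optical_properties`.
#' @export
optical_properties <- function(mu_a, mu_s_prime, g = 0.9) {
  if (!is.finite(mu_a) || mu_a <= 0) stop("mu_a must be > 0")
  if (!is.finite(mu_s_prime) || mu_s_prime <= 0) stop("mu_s_prime must be > 0")
  if (!is.finite(g) || g < 0 || g >= 1) stop("g must lie in [0, 1)")
  structure(list(mu_a = mu_a, mu_s_prime = mu_s_prime, g = g),
            class = "optical_properties")
}

#' Reference tissue optics at 630 nm
#'
#' Absorption, reduced scattering and anisotropy for the organs of the
#' standard numerical-mouse phantom at the 630 nm Cerenkov band. The
#' scattering column is interpreted as the reduced coefficient
#' mu_s' = (1-g)*mu_s; its magnitudes (0.5-2.5 mm^-1) match published
#' reduced coefficients in this band.
#'
#' @return data frame with rownames = tissue names and columns `mu_a`,
#'   `mu_s_prime`, `g`.
#' @export
tissue_optics <- function() {
  data.frame(
    mu_a       = c(0.016, 0.011, 0.002, 0.065, 0.012, 0.036),
    mu_s_prime = c(0.510, 1.053, 1.525, 0.723, 2.472, 2.246),
    g          = c(0.9,   0.86,  0.9,   0.9,   0.9,   0.9),
    row.names  = c("Muscle", "Heart", "Stomach", "Liver", "Kidney", "Lung"))
}

#' Diffusion coefficient
#'
#' D = 1 / (3 * (mu_a + mu_s')) in mm, the diffusion-approximation
#' coefficient. With `mus_interpretation = "raw"` the scattering value
#' is first reduced by (1-g), for tables whose column holds the raw
#' mu_s.
#'
#' @param optics an [optical_properties()] or anything with `mu_a`,
#'   `mu_s_prime`, `g` fields.
#' @param mus_interpretation `"reduced"` (default: the value is already
#'   mu_s') or `"raw"`.
#' @return diffusion coefficient D (mm).
#' @export
diffusion_coefficient <- function(optics, mus_interpretation = c("reduced", "raw")) {
  mus_interpretation <- match.arg(mus_interpretation)
  musp <- if (mus_interpretation == "raw")
    (1 - optics$g) * optics$mu_s_prime else optics$mu_s_prime
  mu_a <- optics$mu_a
  if (!is.finite(mu_a) || mu_a < 0 || !is.finite(musp) || musp <= 0)
    stop("optical coefficients must be positive")
  1 / (3 * (mu_a + musp))
}

#' Robin boundary mismatch factor
#'
#' F = (1 + Rf) / (1 - Rf), where Rf is the internal reflection
#' coefficient produced by the refractive-index mismatch at the tissue
#' surface. Rf = 0.431 (tissue n ~ 1.37 against air) gives F ~ 2.515.
#'
#' @param rf internal reflection coefficient in [0, 1).
#' @return boundary factor F >= 1.
#' @export
boundary_factor <- function(rf = 0.431) {
  if (!is.finite(rf) || rf < 0 || rf >= 1) stop("rf must lie in [0, 1)")
  (1 + rf) / (1 - rf)
}
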