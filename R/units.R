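#' Laboratory-scale reference quantities
#'
#' The model works in normalized biovolume densities: bacterial abundances
#' are divided by the half-saturation abundance \code{N_H = 1e7} particles/mL
#' and phage abundances are additionally scaled by the phage-to-bacteria
#' biovolume ratio \code{c = 3.14e-4} (a phage particle carries far less
#' biovolume than a cell). This object collects the constants needed to move
#' between the two unit systems.
#'
#' @param half_saturation_abundance Half-saturation abundance, particles/mL.
#' @param phage_to_bacteria_volume_ratio Biovolume of a phage relative to a
#'   bacterium, dimensionless.
#' @return An object of class \code{raw_quantities}.
#' @examples
#' raw_quantities()
#' @export
raw_quantities <- function(half_saturation_abundance = 1e7,
                           phage_to_bacteria_volume_ratio = 3.14e-4) {
  if (half_saturation_abundance <= 0 || phage_to_bacteria_volume_ratio <= 0)
    stop("reference quantities must be strictly positive", call. = FALSE)
  structure(list(half_saturation_abundance = half_saturation_abundance,
                 phage_to_bacteria_volume_ratio =
                   phage_to_bacteria_volume_ratio),
            class = "raw_quantities")
}

#' Normalize a bacterial abundance
#'
#' Divides an abundance in particles/mL by the half-saturation abundance,
#' giving the dimensionless density used by the model.
#'
#' @param abundance Abundance, particles/mL (non-negative); vectorised.
#' @param raw A \code{\link{raw_quantities}} object.
#' @return Normalized density.
#' @examples
#' normalize_bacteria(8.3e6, raw_quantities())  # 0.83
#' @export
normalize_bacteria <- function(abundance, raw = raw_quantities()) {
  if (any(abundance < 0))
    stop("abundance must be non-negative", call. = FALSE)
  abundance / raw$half_saturation_abundance
}

#' Normalize a phage abundance
#'
#' Phage particles are converted to bacterial-equivalent biovolume via the
#' volume ratio before dividing by the half-saturation abundance:
#' \code{abundance * c / N_H}.
#'
#' @inheritParams normalize_bacteria
#' @return Normalized density.
#' @examples
#' normalize_phage(1e7, raw_quantities())  # 3.14e-4
#' @export
normalize_phage <- function(abundance, raw = raw_quantities()) {
  if (any(abundance < 0))
    stop("abundance must be non-negative", call. = FALSE)
  abundance * raw$phage_to_bacteria_volume_ratio /
    raw$half_saturation_abundance
}

#' Normalize the phage adsorption rate
#'
#' A laboratory adsorption rate in mL/h multiplies an abundance; in the
#' normalized system it multiplies a phage biovolume density, so the rate is
#' rescaled by \code{N_H / c}: \code{rate * N_H / c}. The reference value
#' 1.64e-10 mL/h maps to about 5.22 per hour (reported rounded as 5.23).
#'
#' @param rate Adsorption rate, mL/h (non-negative); vectorised.
#' @param raw A \code{\link{raw_quantities}} object.
#' @return Normalized adsorption rate, 1/h.
#' @examples
#' normalize_adsorption(1.64e-10, raw_quantities())
#' @export
normalize_adsorption <- function(rate, raw = raw_quantities()) {
  if (any(rate < 0))
    stop("adsorption rate must be non-negative", call. = FALSE)
  rate * raw$half_saturation_abundance /
    raw$phage_to_bacteria_volume_ratio
}

#' Convert a normalized density back to an abundance
#'
#' Inverse of \code{\link{normalize_bacteria}} /
#' \code{\link{normalize_phage}}; the round trip is an identity to machine
#' precision.
#'
#' @param density Normalized density (non-negative); vectorised.
#' @param compartment \code{"bacteria"} or \code{"phage"}.
#' @param raw A \code{\link{raw_quantities}} object.
#' @return Abundance, particles/mL.
#' @examples
#' denormalize_abundance(0.83, "bacteria")  # 8.3e6
#' @export
denormalize_abundance <- function(density,
                                  compartment = c("bacteria", "phage"),
                                  raw = raw_quantities()) {
  compartment <- match.arg(compartment)
  if (any(density < 0))
    stop("density must be non-negative", call. = FALSE)
  out <- density * raw$half_saturation_abundance
  if (compartment == "phage")
    out <- out / raw$phage_to_bacteria_volume_ratio
  out
}
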