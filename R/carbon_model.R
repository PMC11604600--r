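## Cellular carbon allometries. POC follows the prymnesiophyte biovolume to
## organic-carbon power law; PIC follows the calcite shape-factor approach:
## coccolith calcite volume scales with the cube of a characteristic lith
## dimension times a morphogroup-specific shape factor Ks, converted to mass
## with the density of calcite (2.7 pg um^-3) and to elemental carbon with
## the fixed 0.12 carbon fraction of CaCO3.

#' Sphere volume from diameter
#' @param theta Diameter, um (> 0).
#' @return Volume, um^3.
#' @export
sphere_volume <- function(theta) {
  if (any(theta <= 0)) stop("diameter must be > 0", call. = FALSE)
  (pi / 6) * theta^3
}

#' Cellular POC from cell volume
#'
#' `POC (pg C) = 0.228 * volume^0.899`, the prymnesiophyte biovolume to
#' organic-carbon relationship. Sub-linear exponent: carbon density falls
#' with cell size.
#'
#' @param volume Cell volume, um^3 (>= 0).
#' @return POC, pg C per cell.
#' @export
poc_from_volume <- function(volume) {
  if (any(volume < 0)) stop("volume must be >= 0", call. = FALSE)
  0.228 * volume^0.899
}

#' Calcite carbon of a single coccolith
#'
#' `coccolith PIC (pg C) = dimension^3 * ks * 2.7 * 0.12`, where `dimension`
#' is the characteristic lith dimension the shape factor was calibrated on
#' (distal shield length for placoliths, base length for *Sphenolithus*, ray
#' length for *Discoaster*, lith height for *Z. bijugatus*).
#'
#' @param dimension Characteristic coccolith dimension, um (> 0).
#' @param ks Shape factor (> 0), or a parameter entry carrying `ks`.
#' @return PIC, pg C per coccolith.
#' @export
coccolith_pic <- function(dimension, ks) {
  if (is.list(ks)) ks <- ks$ks
  if (any(dimension <= 0)) stop("dimension must be > 0", call. = FALSE)
  if (any(ks <= 0)) stop("ks must be > 0", call. = FALSE)
  dimension^3 * ks * 2.7 * 0.12
}

#' Cellular PIC from coccolith PIC
#'
#' @param lith_pic PIC of one coccolith, pg C (>= 0).
#' @param cn Coccoliths per cell (>= 1).
#' @return PIC, pg C per cell.
#' @export
cellular_pic <- function(lith_pic, cn) {
  if (any(lith_pic < 0)) stop("lith_pic must be >= 0", call. = FALSE)
  if (any(cn < 1)) stop("cn must be >= 1", call. = FALSE)
  lith_pic * cn
}

#' PIC:POC ratio
#'
#' Both quantities are pg of elemental carbon, so the mass ratio equals the
#' molar ratio.
#'
#' @param pic PIC, pg C (>= 0).
#' @param poc POC, pg C (> 0).
#' @return PIC:POC, mol:mol.
#' @export
pic_poc_ratio <- function(pic, poc) {
  if (any(poc <= 0)) stop("POC must be > 0", call. = FALSE)
  if (any(pic < 0)) stop("PIC must be >= 0", call. = FALSE)
  pic / poc
}
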