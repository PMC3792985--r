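#' Astronomical day length
#'
#' Hours between sunrise and sunset (geometric, centre of the solar disk,
#' no atmospheric refraction) from the standard solar-declination
#' approximation.  Used as the photoperiod input of the day-length-extended
#' forcing models.
#'
#' @param latitude latitude in degrees north; must satisfy `|latitude| < 66.6`
#'   (no polar day/night handling)
#' @param doy day of year, 1-366 (vectorised)
#' @return day length in hours, same length as `doy`
#' @examples
#' compute_daylength(52.5, c(80, 172, 355))
#' @export
compute_daylength <- function(latitude, doy) {
  stopifnot(length(latitude) == 1L, is.finite(latitude))
  if (abs(latitude) >= 66.6)
    stop("polar latitudes (|lat| >= 66.6 deg) are not supported")
  stopifnot(all(doy >= 1 & doy <= 366))
  ## solar declination with the first-order eccentricity correction
  decl <- -asin(0.39779 * cos(0.017202 * (doy + 10) +
                                0.0334 * sin(0.017202 * (doy - 2))))
  phi <- latitude * pi / 180
  x <- pmin(1, pmax(-1, -tan(phi) * tan(decl)))
  24 * acos(x) / pi
}

## (D / 12 h)^c, the photoperiod multiplier of the extended models
daylength_factor <- function(D, c) (D / 12)^c
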