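#' Apparent-temperature heat index
#'
#' NWS heat index combining air temperature and relative humidity, computed in
#' Fahrenheit internally and returned in Celsius. Branch logic follows NWS
#' practice: at or below 40 F the index is the temperature itself; otherwise
#' the Steadman-style simple formula
#' \code{0.5 (T + 61 + 1.2 (T - 68) + 0.094 RH)} is evaluated first, and only
#' when it reaches 80 F is the full Rothfusz regression applied, together with
#' the low-RH adjustment (RH < 13%, T in 80-112 F, subtractive) and the
#' high-RH adjustment (RH > 85%, T in 80-87 F, additive).
#'
#' @param tmean_c air temperature, degrees C (vectorised).
#' @param rh_pct relative humidity, percent, in [0, 100].
#' @return heat index, degrees C.
#' @export
compute_heat_index <- function(tmean_c, rh_pct) {
  if (any(!is.finite(tmean_c))) stop("non-finite temperature")
  if (any(!is.finite(rh_pct)) || any(rh_pct < 0 | rh_pct > 100))
    stop("relative humidity must be in [0, 100]")
  tf <- tmean_c * 9 / 5 + 32
  r <- rh_pct
  hi <- tf                                   # <= 40 F: index is temperature
  warm <- tf > 40
  simple <- 0.5 * (tf + 61 + 1.2 * (tf - 68) + 0.094 * r)
  hi[warm] <- simple[warm]
  hot <- warm & simple >= 80
  if (any(hot)) {
    t2 <- tf[hot]; r2 <- r[hot]
    full <- -42.379 + 2.04901523 * t2 + 10.14333127 * r2 -
      0.22475541 * t2 * r2 - 6.83783e-3 * t2^2 - 5.481717e-2 * r2^2 +
      1.22874e-3 * t2^2 * r2 + 8.5282e-4 * t2 * r2^2 - 1.99e-6 * t2^2 * r2^2
    lo <- r2 < 13 & t2 >= 80 & t2 <= 112
    full[lo] <- full[lo] -
      ((13 - r2[lo]) / 4) * sqrt((17 - abs(t2[lo] - 95)) / 17)
    hirh <- r2 > 85 & t2 >= 80 & t2 <= 87
    full[hirh] <- full[hirh] + ((r2[hirh] - 85) / 10) * ((87 - t2[hirh]) / 2)
    hi[hot] <- full
  }
  (hi - 32) * 5 / 9
}
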