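# Reference evapotranspiration (FAO-56 Penman-Monteith), crop water stress
# and the stage-wise yield-response calculation.

.solar_geometry <- function(doy, lat_deg) {
  phi <- lat_deg * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  x <- pmin(1, pmax(-1, -tan(phi) * tan(delta)))
  ws <- acos(x)
  list(dr = dr, delta = delta, phi = phi, ws = ws)
}

#' Astronomical day length
#'
#' @param doy day of year (1-365), vectorized.
#' @param lat_deg latitude in decimal degrees.
#' @return Maximum possible sunshine duration (h).
#' @export
daylight_hours <- function(doy, lat_deg) {
  g <- .solar_geometry(doy, lat_deg)
  24 / pi * g$ws
}

# Extraterrestrial radiation (MJ m-2 day-1), FAO-56.
.radiation_extraterrestrial <- function(doy, lat_deg) {
  g <- .solar_geometry(doy, lat_deg)
  24 * 60 / pi * 0.0820 * g$dr *
    (g$ws * sin(g$phi) * sin(g$delta) + cos(g$phi) * cos(g$delta) * sin(g$ws))
}

.svp <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))

#' Daily reference evapotranspiration (FAO-56 Penman-Monteith)
#'
#' Standard daily grass-reference ET0: shortwave radiation is estimated
#' from sunshine duration via the Angstrom formula (a = 0.25, b = 0.50),
#' net longwave from temperature, humidity and relative sunshine, the
#' psychrometric constant from station pressure at `elev`, and actual
#' vapour pressure from the daily mean relative humidity. Soil heat flux is
#' taken as zero at the daily step. All arguments are vectorized.
#'
#' @param tmin,tmax daily minimum/maximum air temperature (degC).
#' @param rh daily mean relative humidity (%).
#' @param wind wind speed at 2 m (m/s).
#' @param sunshine sunshine duration (h).
#' @param doy day of year (1-365).
#' @param lat_deg latitude (decimal degrees).
#' @param elev elevation (m).
#' @return ET0 in mm/day (floored at 0).
#' @export
et0_fao56 <- function(tmin, tmax, rh, wind, sunshine, doy, lat_deg, elev) {
  if (any(rh < 0 | rh > 100)) {
    stop("relative humidity must lie in [0, 100]", call. = FALSE)
  }
  tmean <- (tmax + tmin) / 2
  pres <- 101.3 * ((293 - 0.0065 * elev) / 293)^5.26
  gam <- 0.000665 * pres
  es <- (.svp(tmax) + .svp(tmin)) / 2
  ea <- pmin(es, rh / 100 * es)
  delta <- 4098 * .svp(tmean) / (tmean + 237.3)^2
  ra <- .radiation_extraterrestrial(doy, lat_deg)
  nn <- daylight_hours(doy, lat_deg)
  rs <- (0.25 + 0.50 * pmin(1, sunshine / nn)) * ra
  rso <- (0.75 + 2e-5 * elev) * ra
  rel <- pmin(1, ifelse(rso > 0, rs / rso, 0))
  rns <- (1 - 0.23) * rs
  rnl <- 4.903e-9 * ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(ea)) * (1.35 * rel - 0.35)
  rn <- rns - rnl
  et0 <- (0.408 * delta * rn + gam * 900 / (tmean + 273) * wind * (es - ea)) /
    (delta + gam * (1 + 0.34 * wind))
  pmax(0, et0)
}

#' Daily ET0 series for a weather series
#'
#' @param weather a `weather_series`.
#' @param lat,elev site latitude (deg) and elevation (m); default to the
#'   attributes carried by `weather`.
#' @return Numeric vector of ET0 (mm/day), one value per row of `weather`.
#' @export
et0_series <- function(weather, lat = attr(weather, "lat"),
                       elev = attr(weather, "elev")) {
  if (is.null(lat) || is.null(elev)) {
    stop("latitude/elevation missing: pass `lat` and `elev`", call. = FALSE)
  }
  et0_fao56(weather$tmin_c, weather$tmax_c, weather$rh_pct, weather$wind_ms,
            weather$sunshine_h, weather$doy, lat, elev)
}

#' Crop parameters for paddy rice
#'
#' Stage-wise crop coefficients Kc, yield-response factors Ky, stage
#' lengths, and the post-ponding soil water store used for the water-stress
#' coefficient. Stages are (initial, development, mid-season, late-season).
#' Defaults: Kc 1.05/1.10/1.20/0.90 (FAO-56 paddy rice values), Ky
#' 1.0/1.09/1.32/0.5, stage lengths 30/30/40/30 days, total available soil
#' water TAW = 60 mm with depletion fraction p = 0.2.
#'
#' @param kc,ky numeric(4) stage coefficients.
#' @param stage_len integer(4) stage lengths in days.
#' @param taw total available soil water after ponding disappears (mm).
#' @param p readily-available fraction of TAW before stress sets in.
#' @return A list of class `crop_params`.
#' @export
crop_params <- function(kc = c(1.05, 1.10, 1.20, 0.90),
                        ky = c(1.0, 1.09, 1.32, 0.5),
                        stage_len = c(30L, 30L, 40L, 30L),
                        taw = 60, p = 0.2) {
  stopifnot(length(kc) == 4, length(ky) == 4, length(stage_len) == 4,
            all(kc > 0), all(ky > 0), taw > 0, p >= 0, p < 1)
  structure(list(kc = kc, ky = ky, stage_len = as.integer(stage_len),
                 taw = taw, p = p),
            class = "crop_params")
}

#' Water-stress coefficient (FAO CROPWAT convention)
#'
#' Ks = 1 while the field is ponded or the root-zone depletion is within
#' the readily available water (`Dr <= p * TAW`); below that it declines
#' linearly, `(TAW - Dr) / ((1 - p) * TAW)`, reaching 0 at full depletion.
#'
#' @param field_depth ponded water depth (mm); any positive depth gives Ks = 1.
#' @param dr root-zone depletion (mm).
#' @param taw total available soil water (mm).
#' @param p depletion fraction at which stress starts.
#' @return Ks in \[0, 1\].
#' @export
water_stress_coefficient <- function(field_depth, dr, taw, p = 0.2) {
  stopifnot(taw > 0)
  ks <- ifelse(field_depth > 0 | dr <= p * taw, 1,
               (taw - dr) / ((1 - p) * taw))
  pmin(1, pmax(0, ks))
}

#' Stage-wise yield loss from evapotranspiration deficit
#'
#' For each growth stage, the relative yield loss is
#' `YL_i = Ky_i * (1 - ETa_i / ETc_i)`; the seasonal relative yield
#' `Ya/Yx = prod(1 - YL_i)` combines the stages multiplicatively (the
#' CROPWAT convention), and the returned loss is `(1 - Ya/Yx) * 100`.
#' Stage losses are clamped to \[0, 1\].
#'
#' @param eta numeric(4): actual crop evapotranspiration per stage (mm).
#' @param etc numeric(4): maximum crop evapotranspiration per stage (mm);
#'   all must be > 0.
#' @param ky numeric(4) stage yield-response factors.
#' @return Seasonal yield loss in percent (0 when unstressed).
#' @examples
#' yield_loss(c(100, 100, 90, 100), c(100, 100, 100, 100))  # 13.2
#' @export
yield_loss <- function(eta, etc, ky = crop_params()$ky) {
  if (length(eta) != length(etc) || length(eta) != length(ky)) {
    stop("`eta`, `etc`, `ky` must have equal length", call. = FALSE)
  }
  if (any(etc <= 0)) stop("stage ETc must be > 0", call. = FALSE)
  ratio <- pmin(1, pmax(0, eta / etc))
  yl_stage <- pmin(1, pmax(0, ky * (1 - ratio)))
  (1 - prod(1 - yl_stage)) * 100
}
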