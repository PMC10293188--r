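#' Monthly climate parameters for the synthetic weather generator
#'
#' Bundles the monthly climatology that drives [generate_daily_weather()]:
#' mean rainfall totals, wet-day occurrence and persistence, temperature,
#' humidity, wind and sunshine normals, plus the site coordinates and the
#' rice growing-season window. Rainfall occurrence follows a first-order
#' two-state Markov chain (wet/dry) with month-specific probabilities;
#' wet-day amounts are gamma distributed.
#'
#' @param monthly_rain numeric(12), mean monthly rainfall totals (mm).
#' @param wet_prob numeric(12), unconditional wet-day probability per month.
#' @param persistence scalar in \[0,1): lag-1 correlation of wet-day
#'   occurrence; the chain transition probabilities are
#'   `p11 = p + (1-p)*r` and `p01 = p*(1-r)`.
#' @param tmin,tmax numeric(12), mean daily minimum/maximum temperature (degC).
#' @param rh numeric(12), mean relative humidity (%).
#' @param wind numeric(12), mean wind speed at 2 m (m/s).
#' @param sunshine numeric(12), mean daily sunshine duration (h).
#' @param lat latitude (decimal degrees, north positive).
#' @param elev station elevation (m above sea level).
#' @param season integer(2), growing-season window as day-of-year
#'   (start, end), inclusive.
#' @param gamma_shape shape of the gamma distribution of wet-day amounts.
#'
#' @return An object of class `climate_params`.
#' @seealso [climate_preset()] for shipped regional archetypes.
#' @export
climate_params <- function(monthly_rain, wet_prob, persistence = 0.25,
                           tmin, tmax, rh, wind, sunshine,
                           lat, elev, season, gamma_shape = 0.75) {
  for (v in list(monthly_rain, wet_prob, tmin, tmax, rh, wind, sunshine)) {
    if (length(v) != 12L || !is.numeric(v)) {
      stop("monthly inputs must be numeric vectors of length 12", call. = FALSE)
    }
  }
  if (any(monthly_rain < 0)) stop("monthly rainfall must be >= 0", call. = FALSE)
  if (any(wet_prob < 0 | wet_prob > 1)) {
    stop("wet-day probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (persistence < 0 || persistence >= 1) {
    stop("`persistence` must lie in [0, 1)", call. = FALSE)
  }
  if (any(tmax < tmin)) stop("tmax must be >= tmin in every month", call. = FALSE)
  if (length(season) != 2L || season[1] < 1 || season[2] > 365 ||
      season[2] <= season[1]) {
    stop("`season` must be c(start, end) day-of-year with start < end <= 365",
         call. = FALSE)
  }
  structure(
    list(monthly_rain = as.numeric(monthly_rain),
         wet_prob = as.numeric(wet_prob),
         persistence = persistence,
         tmin = as.numeric(tmin), tmax = as.numeric(tmax),
         rh = as.numeric(rh), wind = as.numeric(wind),
         sunshine = as.numeric(sunshine),
         lat = lat, elev = elev,
         season = as.integer(season),
         gamma_shape = gamma_shape),
    class = "climate_params")
}

#' Shipped monsoonal climate archetypes
#'
#' Monthly climatologies for three rice-region archetypes: `"NE"`
#' (northeast, single early season, strongly peaked summer monsoon),
#' `"CJ"` (middle Changjiang basin, humid subtropical) and `"SE"`
#' (southeast coastal, long wet season). They are synthetic normals chosen
#' to emulate the monsoonal structure of the respective regions, including
#' a growing-season aridity-index distribution with roughly a quarter of
#' seasons drier than balance (index > 1) and a few percent beyond 1.6.
#'
#' @param region one of `"NE"`, `"CJ"`, `"SE"`.
#' @return A [climate_params()] object.
#' @export
climate_preset <- function(region = c("NE", "CJ", "SE")) {
  region <- match.arg(region)
  switch(region,
    NE = climate_params(
      monthly_rain = c(5, 7, 15, 35, 70, 122, 200, 190, 82, 35, 15, 8),
      wet_prob     = c(.08, .08, .12, .20, .25, .33, .43, .40, .26, .20, .12, .08),
      persistence = 0.40, gamma_shape = 0.5,
      tmin = c(-18, -14, -5, 4, 11, 17, 21, 20, 13, 5, -5, -14),
      tmax = c(-7, -3, 5, 15, 22, 26, 29, 28, 23, 15, 4, -4),
      rh   = c(60, 58, 55, 52, 58, 68, 78, 78, 68, 62, 60, 62),
      wind = c(3, 3.5, 3.5, 3.5, 3.2, 2.8, 2.5, 2.5, 2.8, 3, 3, 3),
      sunshine = c(6, 7, 8, 8, 9, 8, 7, 7, 8, 7, 6, 5),
      lat = 41.1, elev = 5, season = c(135L, 264L)),
    CJ = climate_params(
      monthly_rain = c(45, 60, 95, 135, 170, 212, 200, 128, 85, 72, 50, 30),
      wet_prob     = c(.28, .32, .38, .42, .42, .45, .40, .32, .28, .25, .22, .20),
      persistence = 0.40, gamma_shape = 0.5,
      tmin = c(0, 2, 6, 12, 17, 22, 25, 24, 19, 13, 7, 2),
      tmax = c(8, 10, 15, 21, 26, 30, 33, 33, 28, 22, 16, 10),
      rh   = c(77, 76, 76, 75, 75, 77, 78, 77, 75, 74, 73, 73),
      wind = rep(2.0, 12),
      sunshine = c(4, 4, 4, 5, 6, 6, 8, 8, 6, 5, 5, 4),
      lat = 30.6, elev = 30, season = c(152L, 281L)),
    SE = climate_params(
      monthly_rain = c(40, 70, 85, 180, 270, 280, 210, 200, 148, 58, 36, 30),
      wet_prob     = c(.22, .30, .35, .45, .52, .55, .48, .48, .40, .25, .18, .15),
      persistence = 0.40, gamma_shape = 0.5,
      tmin = c(10, 11, 15, 19, 23, 25, 26, 26, 24, 20, 15, 11),
      tmax = c(18, 18, 22, 26, 30, 32, 33, 33, 31, 28, 24, 20),
      rh   = c(72, 77, 80, 82, 82, 82, 80, 80, 76, 70, 66, 66),
      wind = rep(1.8, 12),
      sunshine = c(4, 3, 3, 3, 4, 5, 7, 6, 6, 6, 5, 5),
      lat = 23.1, elev = 20, season = c(190L, 319L)))
}

.month_len <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
.month_of_doy <- rep.int(1:12, .month_len)

# Linear interpolation of 12 monthly values to 365 daily values, periodic,
# anchored at mid-month so monthly means are approximately preserved.
.monthly_to_daily <- function(x) {
  mids <- cumsum(.month_len) - .month_len / 2
  xx <- c(x[12], x, x[1])
  dd <- c(mids[12] - 365, mids, mids[1] + 365)
  stats::approx(dd, xx, xout = 1:365)$y
}

#' Generate synthetic daily weather
#'
#' Simulates `n_years` of daily weather (365-day years, no leap days) from a
#' monthly climatology. Rainfall occurrence follows a first-order two-state
#' Markov chain with month-specific transition probabilities; wet-day
#' amounts are drawn from a month-specific gamma distribution whose mean is
#' set so that the expected monthly total matches the configured normal.
#' Temperatures carry a shared AR(1) anomaly; sunshine is reduced on wet
#' days and capped at the astronomical day length.
#'
#' @param params a [climate_params()] object.
#' @param n_years number of years to simulate (>= 1).
#' @param seed integer seed; identical seeds give bit-identical series.
#' @return A `weather_series` data frame with one row per day and columns
#'   `date`, `year`, `month`, `day`, `doy`, `precip_mm`, `tmin_c`, `tmax_c`,
#'   `rh_pct`, `wind_ms`, `sunshine_h`. Latitude, elevation and the
#'   growing-season window are attached as attributes.
#' @examples
#' wx <- generate_daily_weather(climate_preset("CJ"), n_years = 2, seed = 1)
#' summary(wx$precip_mm)
#' @export
generate_daily_weather <- function(params, n_years, seed = 1L) {
  stopifnot(inherits(params, "climate_params"))
  stopifnot_scalar(n_years, "n_years", positive = TRUE)
  n_years <- as.integer(n_years)
  ndays <- 365L * n_years
  doy <- rep.int(1:365, n_years)
  mon <- .month_of_doy[doy]
  year <- rep(seq_len(n_years), each = 365L)

  tmin_d <- .monthly_to_daily(params$tmin)[doy]
  tmax_d <- .monthly_to_daily(params$tmax)[doy]
  rh_d <- .monthly_to_daily(params$rh)[doy]
  wind_d <- .monthly_to_daily(params$wind)[doy]
  sun_d <- .monthly_to_daily(params$sunshine)[doy]
  daylen <- daylight_hours(1:365, params$lat)[doy]

  p <- params$wet_prob
  r <- params$persistence
  p11 <- p + (1 - p) * r       # P(wet | wet)
  p01 <- p * (1 - r)           # P(wet | dry)
  mean_amt <- ifelse(p > 0, params$monthly_rain / (p * .month_len), 0)

  with_seed(seed, {
    u <- stats::runif(ndays)
    wet <- logical(ndays)
    prev <- stats::runif(1) < p[mon[1]]
    for (i in seq_len(ndays)) {
      m <- mon[i]
      pr <- if (prev) p11[m] else p01[m]
      wet[i] <- u[i] < pr && p[m] > 0
      prev <- wet[i]
    }
    amount <- numeric(ndays)
    nw <- sum(wet)
    if (nw > 0) {
      sh <- params$gamma_shape
      mu <- mean_amt[mon[wet]]
      amount[wet] <- stats::rgamma(nw, shape = sh, scale = mu / sh)
    }
    # shared AR(1) temperature anomaly
    rho <- 0.7
    eps <- stats::rnorm(ndays, sd = 1.5 * sqrt(1 - rho^2))
    anom <- numeric(ndays)
    a <- 0
    for (i in seq_len(ndays)) {
      a <- rho * a + eps[i]
      anom[i] <- a
    }
    rh_day <- rh_d + ifelse(wet, 8, 0) + stats::rnorm(ndays, sd = 4)
    wind_day <- wind_d * exp(stats::rnorm(ndays, sd = 0.25))
    sun_day <- sun_d * ifelse(wet, 0.35, 1.1) + stats::rnorm(ndays, sd = 0.8)
    dom <- doy - c(0L, cumsum(.month_len))[mon]
    out <- data.frame(
      date = as.Date(sprintf("%04d-%02d-%02d", 2000L + year, mon, dom)),
      year = year, month = mon, day = dom,
      doy = doy,
      precip_mm = amount,
      tmin_c = tmin_d + anom,
      tmax_c = tmax_d + anom,
      rh_pct = pmin(100, pmax(20, rh_day)),
      wind_ms = pmin(15, pmax(0.1, wind_day)),
      sunshine_h = pmin(daylen, pmax(0, sun_day)))
    out
  }) -> out
  structure(out,
            class = c("weather_series", "data.frame"),
            lat = params$lat, elev = params$elev, season = params$season)
}

#' Read / write daily weather CSV
#'
#' One row per day with columns `date` (ISO-8601), `precip_mm`, `tmin_c`,
#' `tmax_c`, `rh_pct`, `wind_ms`, `sunshine_h`.
#'
#' @param file path to a CSV file.
#' @param lat,elev site latitude (deg) and elevation (m) to attach.
#' @param season optional growing-season window `c(start, end)` (day-of-year).
#' @return `read_weather_csv()` returns a `weather_series`;
#'   `write_weather_csv()` returns `file` invisibly.
#' @export
read_weather_csv <- function(file, lat, elev, season = NULL) {
  x <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("date", "precip_mm", "tmin_c", "tmax_c", "rh_pct", "wind_ms",
            "sunshine_h")
  if (!all(need %in% names(x))) {
    stop("weather CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  x$date <- as.Date(x$date)
  lt <- as.POSIXlt(x$date)
  x$year <- lt$year + 1900L
  x$month <- lt$mon + 1L
  x$day <- lt$mday
  x$doy <- lt$yday + 1L
  # drop leap day so that all years are 365 days long
  leap <- x$month == 2L & x$day == 29L
  if (any(leap)) x <- x[!leap, , drop = FALSE]
  x$doy <- ifelse(x$month > 2L & x$doy > 59L &
                    (x$year %% 4 == 0 & (x$year %% 100 != 0 | x$year %% 400 == 0)),
                  x$doy - 1L, x$doy)
  x$year <- x$year - min(x$year) + 1L
  structure(x[, c("date", "year", "month", "day", "doy", need[-1])],
            class = c("weather_series", "data.frame"),
            lat = lat, elev = elev, season = season)
}

#' @rdname read_weather_csv
#' @param weather a `weather_series`.
#' @export
write_weather_csv <- function(weather, file) {
  cols <- c("date", "precip_mm", "tmin_c", "tmax_c", "rh_pct", "wind_ms",
            "sunshine_h")
  utils::write.csv(as.data.frame(weather)[, cols], file, row.names = FALSE)
  invisible(file)
}

#' Growing-season aridity index
#'
#' The aridity index of a growing season is the ratio of cumulative
#' reference evapotranspiration to cumulative precipitation over the season
#' window: values above 1 mark dry seasons, above 1.6 extreme-dry seasons
#' (see [classify_years()]).
#'
#' @param weather a `weather_series` (one or more whole years).
#' @param season integer(2) day-of-year window; defaults to the window
#'   attached to `weather`.
#' @param et0 optional numeric vector of daily reference evapotranspiration
#'   (mm/day) aligned with the rows of `weather`; computed with
#'   [et0_series()] when missing.
#' @param lat,elev site latitude/elevation, defaulting to the attributes of
#'   `weather`; only needed when `et0` is missing.
#' @return Named numeric vector, one index per year. Seasons with zero
#'   precipitation yield `Inf` with a warning.
#' @export
aridity_index <- function(weather, season = attr(weather, "season"),
                          et0 = NULL, lat = attr(weather, "lat"),
                          elev = attr(weather, "elev")) {
  if (is.null(season)) stop("no season window available", call. = FALSE)
  if (is.null(et0)) et0 <- et0_series(weather, lat = lat, elev = elev)
  if (length(et0) != nrow(weather)) {
    stop("`et0` must align with the rows of `weather`", call. = FALSE)
  }
  inwin <- weather$doy >= season[1] & weather$doy <= season[2]
  if (!any(inwin)) stop("season window is empty", call. = FALSE)
  psum <- tapply(weather$precip_mm[inwin], weather$year[inwin], sum)
  esum <- tapply(et0[inwin], weather$year[inwin], sum)
  idx <- as.numeric(esum) / as.numeric(psum)
  if (any(!is.finite(idx))) {
    warning("growing season(s) with zero precipitation: aridity index infinite")
  }
  stats::setNames(idx, names(psum))
}

#' Classify growing seasons by dryness
#'
#' Applies the dry-season thresholds to aridity indices: index > 1 is a
#' dry season (`dry25`), index > 1.6 an extreme-dry season (`extreme5`),
#' everything else `normal`. The inequalities are strict, so an index of
#' exactly 1.0 (or 1.6) falls in the less dry class.
#'
#' @param indices numeric vector of aridity indices ([aridity_index()]).
#' @return Factor with levels `normal`, `dry25`, `extreme5`.
#' @examples
#' classify_years(c(0.5, 1.2, 1.7))
#' @export
classify_years <- function(indices) {
  lab <- ifelse(indices > 1.6, "extreme5",
                ifelse(indices > 1, "dry25", "normal"))
  factor(lab, levels = c("normal", "dry25", "extreme5"))
}

#' Length of the no-rain spell preceding a day
#'
#' Counts the maximal run of consecutive no-rain days ending the day before
#' `day`. A day counts as no-rain when its precipitation is below
#' `threshold` (default 1 mm, a conventional trace cutoff).
#'
#' @param weather a `weather_series`.
#' @param day a `Date` present in `weather`, or a row index.
#' @param threshold precipitation (mm) below which a day counts as no-rain.
#' @return Integer count of days (0 when it rained the day before).
#' @export
no_rain_run <- function(weather, day, threshold = 1) {
  if (inherits(day, "Date")) {
    i <- match(day, weather$date)
    if (is.na(i)) stop("`day` not found in the weather series", call. = FALSE)
  } else {
    i <- as.integer(day)
    if (i < 1L || i > nrow(weather)) stop("`day` outside the series", call. = FALSE)
  }
  dry <- weather$precip_mm < threshold
  n <- 0L
  j <- i - 1L
  while (j >= 1L && dry[j]) {
    n <- n + 1L
    j <- j - 1L
  }
  n
}
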