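# Shared fixtures: small geometries, canned weather and randomized IDU
# configurations, all built in code.

fix_geom <- function(a_field = 1e5, a_ditch = 4500, a_pond = 1500, ...) {
  idu_geometry(a_field, a_ditch, a_pond, ...)
}

fix_weather <- function(n_years = 1, seed = 1, region = "CJ") {
  generate_daily_weather(climate_preset(region), n_years = n_years,
                         seed = seed)
}

# A constant-forcing weather series (no stochasticity) for targeted
# hydrology tests: `precip` mm/day every day.
flat_weather <- function(precip = 0, tmin = 18, tmax = 28, rh = 75,
                         wind = 2, sunshine = 6, season = c(152L, 281L)) {
  structure(data.frame(
    date = as.Date("2001-01-01") + 0:364,
    year = 1L, month = rep.int(1:12, c(31, 28, 31, 30, 31, 30, 31, 31,
                                       30, 31, 30, 31)),
    day = 1L, doy = 1:365,
    precip_mm = precip, tmin_c = tmin, tmax_c = tmax, rh_pct = rh,
    wind_ms = wind, sunshine_h = sunshine),
    class = c("weather_series", "data.frame"),
    lat = 30.6, elev = 30, season = season)
}

# One randomized synthetic IDU configuration for conservation suites.
random_config <- function(seed) {
  set.seed(seed)
  a_field <- runif(1, 2e4, 2e5)
  geom <- idu_geometry(
    a_field,
    a_ditch = runif(1, 0.01, 0.06) * a_field,
    a_pond = sample(c(0, 1), 1) * runif(1, 0.005, 0.03) * a_field,
    ditch_depth = runif(1, 0.4, 1.2),
    pond_depth = runif(1, 0.8, 2),
    perc_mm = runif(1, 0, 4))
  style <- management_style(sample(c("TC", "PD1", "PD2", "QD"), 1))
  region <- sample(c("NE", "CJ", "SE"), 1)
  fert <- default_fert_events(
    offsets = sort(sample(1:80, 3)),
    n = runif(3, 5, 40), p = runif(3, 0.2, 3))
  params <- nutrient_params(runif(1, 4.2, 44), runif(1, 1.5, 9),
                            runif(1, 0.4, 5), runif(1, 0.03, 1.1))
  cap <- sample(c(Inf, runif(1, 100, 400)), 1)
  list(geom = geom, style = style, region = region, fert = fert,
       params = params, cap = cap, seed = seed)
}

run_random_config <- function(cfg) {
  wx <- fix_weather(1, seed = cfg$seed, region = cfg$region)
  simulate_idu(wx, cfg$geom, cfg$style, params = cfg$params,
               fert_events = cfg$fert, freshwater_cap = cfg$cap,
               init_storage = runif(1),
               decay = runif(1, 0.05, 0.3))
}
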