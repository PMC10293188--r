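test_that("weather generation is deterministic under a fixed seed", {
  a <- fix_weather(3, seed = 99)
  b <- fix_weather(3, seed = 99)
  expect_identical(a, b)
  c <- fix_weather(3, seed = 100)
  expect_false(identical(a$precip_mm, c$precip_mm))
})

test_that("zero wet-day probability gives an entirely dry series", {
  cp <- climate_preset("CJ")
  dry <- climate_params(cp$monthly_rain * 0, rep(0, 12), 0.3,
                        cp$tmin, cp$tmax, cp$rh, cp$wind, cp$sunshine,
                        cp$lat, cp$elev, cp$season)
  wx <- generate_daily_weather(dry, 2, seed = 1)
  expect_true(all(wx$precip_mm == 0))
  expect_equal(nrow(wx), 730L)
})

test_that("long-run monthly rainfall means match the configured normals", {
  wx <- generate_daily_weather(climate_preset("CJ"), 400, seed = 7)
  jul <- tapply(wx$precip_mm[wx$month == 7], wx$year[wx$month == 7], sum)
  # 400-year sampling error of the July mean is ~2.6%; allow 3 sigma
  expect_lt(abs(mean(jul) / 200 - 1), 0.075)
  ann <- tapply(wx$precip_mm, wx$year, sum)
  expect_lt(abs(mean(ann) / sum(climate_preset("CJ")$monthly_rain) - 1), 0.05)
})

test_that("generator rejects invalid inputs", {
  cp <- climate_preset("CJ")
  expect_error(generate_daily_weather(cp, 0), "n_years")
  expect_error(climate_params(cp$monthly_rain, rep(1.5, 12), 0.3,
                              cp$tmin, cp$tmax, cp$rh, cp$wind, cp$sunshine,
                              cp$lat, cp$elev, cp$season),
               "probabilities")
  expect_error(climate_params(cp$monthly_rain, cp$wet_prob, 0.3,
                              cp$tmax, cp$tmin, cp$rh, cp$wind, cp$sunshine,
                              cp$lat, cp$elev, cp$season),
               "tmax")
})

test_that("aridity index is the seasonal ET0/P ratio with boundary semantics", {
  wx <- flat_weather(precip = 5)
  et0 <- rep(5, 365)   # sums equal over any window
  expect_equal(unname(aridity_index(wx, c(152, 281), et0 = et0)), 1.0)
  et0 <- rep(8, 365)
  wx2 <- flat_weather(precip = 5)
  # sum ET0 = 800-equivalent vs P = 500-equivalent scaled ratio: 8/5 = 1.6
  expect_equal(unname(aridity_index(wx2, c(152, 281), et0 = et0)), 1.6)
  wx3 <- flat_weather(precip = 0)
  expect_warning(ai <- aridity_index(wx3, c(152, 281), et0 = rep(4, 365)),
                 "zero precipitation")
  expect_true(is.infinite(ai))
})

test_that("dryness classification uses strict thresholds at 1 and 1.6", {
  expect_equal(as.character(classify_years(c(0.5, 1.2, 1.7))),
               c("normal", "dry25", "extreme5"))
  expect_equal(length(classify_years(numeric(0))), 0L)
  expect_equal(as.character(classify_years(c(1.0, 1.6))),
               c("normal", "dry25"))
})

test_that("dry-year frequencies of the CJ preset match its calibration", {
  wx <- generate_daily_weather(climate_preset("CJ"), 200, seed = 11)
  ai <- aridity_index(wx)
  cls <- classify_years(ai)
  p_dry <- mean(cls != "normal")
  expect_gt(p_dry, 0.10)
  expect_lt(p_dry, 0.45)
  # 75th percentile of the index sits near the dry-year threshold
  expect_lt(abs(stats::quantile(ai, 0.75, names = FALSE) - 1), 0.2)
})

test_that("no_rain_run counts the antecedent dry spell and matches a scan", {
  wx <- flat_weather(precip = 5)
  expect_equal(no_rain_run(wx, 100L), 0L)
  wx$precip_mm[86:99] <- 0
  expect_equal(no_rain_run(wx, 100L), 14L)
  expect_equal(no_rain_run(wx, wx$date[100]), 14L)
  expect_error(no_rain_run(wx, 9999L), "outside")
  # brute-force oracle on a generated series: forward run-length counter
  gen <- fix_weather(1, seed = 5)
  dry <- gen$precip_mm < 1
  oracle <- integer(nrow(gen))
  run <- 0L
  for (i in seq_len(nrow(gen))) {
    oracle[i] <- run
    run <- if (dry[i]) run + 1L else 0L
  }
  got <- vapply(seq_len(nrow(gen)), function(i) no_rain_run(gen, i),
                integer(1))
  expect_identical(got, oracle)
})

test_that("weather CSV round-trips", {
  wx <- fix_weather(1, seed = 3)
  f <- tempfile(fileext = ".csv")
  write_weather_csv(wx, f)
  back <- read_weather_csv(f, lat = attr(wx, "lat"), elev = attr(wx, "elev"),
                           season = attr(wx, "season"))
  expect_equal(back$precip_mm, wx$precip_mm, tolerance = 1e-12)
  expect_equal(back$doy, wx$doy)
  unlink(f)
})
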