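# One-season IDU simulation: daily hydrology + nutrient mass balance,
# season totals and water-footprint accounting.

#' Default fertilization schedule
#'
#' Basal, tillering and panicle applications expressed as initial field
#' concentrations on the fertilization day (mg/L), at offsets (days) from
#' the season start.
#'
#' @param offsets days after season start.
#' @param n,p initial field concentrations (mg/L) per event.
#' @return Data frame with columns `offset`, `n`, `p`.
#' @export
default_fert_events <- function(offsets = c(1L, 25L, 55L),
                                n = c(25, 15, 10),
                                p = c(1.5, 0.5, 0.3)) {
  stopifnot(length(offsets) == length(n), length(n) == length(p),
            all(n >= 0), all(p >= 0))
  data.frame(offset = as.integer(offsets), n = n, p = p)
}

# Hydrology-only season run. `rows` indexes weather/et0 for the season
# days in order. Returns per-day flux list plus hydro season sums.
.sim_hydro <- function(weather, et0, rows, geom, style, scheme, crop,
                       cap_remote = Inf, init_storage = 0.5,
                       openwater_kc = 1.05) {
  st <- hydro_state(geom, depth = 0, storage_frac = init_storage)
  st0 <- st
  nf <- length(rows)
  fluxes <- vector("list", nf)
  for (k in seq_len(nf)) {
    i <- rows[k]
    stp <- step_water_balance(st, weather$precip_mm[i], et0[i],
                              weather$doy[i], geom, style, scheme, crop,
                              cap_remote, openwater_kc)
    st <- stp$state
    cap_remote <- stp$cap_remote
    fluxes[[k]] <- stp$fluxes
  }
  g <- function(nm) vapply(fluxes, `[[`, numeric(1), nm)
  eta_src <- t(vapply(fluxes, `[[`, numeric(3), "eta_src"))
  stage <- vapply(fluxes, function(f) {
    if (is.na(f$stage)) NA_integer_ else as.integer(f$stage)
  }, integer(1))
  eta_stage <- vapply(1:4, function(s) sum(g("eta")[which(stage == s)]), 0)
  etc_stage <- vapply(1:4, function(s) sum(g("etc")[which(stage == s)]), 0)
  list(fluxes = fluxes, state0 = st0, state = st,
       i_dp = sum(g("irr_ditch")) + sum(g("irr_pond")),
       i_remote = sum(g("irr_remote")),
       unmet = sum(g("unmet")),
       eta = sum(g("eta")), etc = sum(g("etc")),
       eta_green = sum(eta_src[, 1]), eta_blue = sum(eta_src[, 2]),
       eta_recycled = sum(eta_src[, 3]),
       eta_stage = eta_stage, etc_stage = etc_stage,
       precip = sum(g("precip")), perc = sum(g("perc")),
       outflow = sum(g("outflow")),
       daily = data.frame(
         doy = g("doy"), precip = g("precip"), et0 = g("et0"),
         etc = g("etc"), eta = g("eta"),
         eta_green = eta_src[, 1], eta_blue = eta_src[, 2],
         eta_recycled = eta_src[, 3],
         perc = g("perc"), irr_ditch = g("irr_ditch"),
         irr_pond = g("irr_pond"), irr_remote = g("irr_remote"),
         unmet = g("unmet"), drain_f2d = g("drain_f2d"),
         outflow = g("outflow"), depth = g("depth1"),
         vd = g("vd1"), vp = g("vp1")))
}

# Relative water-balance closure of a hydro run (should be ~0).
.water_balance_residual <- function(h, geom, crop) {
  mmA <- geom$a_field / 1000
  g <- function(nm) sum(vapply(h$fluxes, `[[`, numeric(1), nm))
  storage <- function(s) s$depth + (crop$taw - s$dr) + (s$vd + s$vp) / mmA
  inputs <- g("precip") + (g("rain_ditch") + g("rain_pond")) / mmA +
    g("irr_remote")
  outputs <- g("eta") + g("perc") +
    (g("ev_ditch") + g("ev_pond") + g("outflow")) / mmA
  (inputs - outputs - (storage(h$state) - storage(h$state0))) /
    max(1, inputs)
}

# Nutrient replay over a stored flux list. `fert_by_doy` maps doy -> event.
.sim_nutrients <- function(h, geom, params, fert_by_doy, init_mass,
                           decay = 0.15) {
  mass <- init_mass
  zero <- c(n = 0, p = 0)
  leach <- runoff <- ret <- sink <- fert_in <- zero
  daily_runoff_n <- numeric(length(h$fluxes))
  for (k in seq_along(h$fluxes)) {
    fx <- h$fluxes[[k]]
    ev <- fert_by_doy[[as.character(fx$doy)]]
    s <- step_nutrient(mass, fx, params, geom, fert = ev, decay = decay)
    mass <- s$mass
    leach <- leach + s$loads$leach
    runoff <- runoff + s$loads$runoff
    ret <- ret + s$retention
    sink <- sink + s$field_sink
    fert_in <- fert_in + s$fert_in
    daily_runoff_n[k] <- s$loads$runoff[["n"]]
  }
  mass0 <- init_mass
  tot0 <- mass0$field + mass0$ditch + mass0$pond
  tot1 <- mass$field + mass$ditch + mass$pond
  residual <- (fert_in - (leach + runoff + ret + sink) - (tot1 - tot0)) /
    pmax(1, abs(fert_in) + tot0)
  # g over the field area -> kg/ha
  to_kgha <- 10 / geom$a_field
  list(mass = mass,
       l_runoff = runoff * to_kgha, l_leach = leach * to_kgha,
       retention = ret * to_kgha, field_sink = sink * to_kgha,
       fert_in = fert_in * to_kgha,
       daily_runoff_n = daily_runoff_n * to_kgha,
       residual = residual)
}

#' Simulate one growing season of an irrigation-drainage unit
#'
#' Runs the daily water balance of a paddy field + ditch (+ pond) unit
#' over the growing-season window, then the nitrogen/phosphorus mass
#' balance on the simulated fluxes, and assembles the season ledger:
#' irrigation by source, ETa by source, nutrient loads via runoff and
#' leaching, the stage-wise yield loss under water stress, and the
#' green/blue/gray water footprints.
#'
#' @param weather a `weather_series` covering at least the requested year.
#' @param geom an [idu_geometry()].
#' @param style a [management_style()] or style string.
#' @param scheme a [default_water_scheme()]; defaults to normal farmer
#'   management starting at the season window attached to `weather`.
#' @param crop a [crop_params()].
#' @param params a [nutrient_params()] (one Monte-Carlo draw or defaults).
#' @param fert_events fertilization schedule ([default_fert_events()]).
#' @param year which simulated year to run (default: first).
#' @param et0 optional precomputed ET0 vector aligned with `weather`.
#' @param yield_max unstressed rice yield (ton/ha).
#' @param freshwater_cap seasonal remote freshwater allowance (mm);
#'   `Inf` in unrestricted (normal) years.
#' @param init_storage initial fill fraction of ditch/pond storage.
#' @param init_conc initial ditch/pond concentrations `c(n, p)` (mg/L);
#'   defaults to the equilibrium concentrations of `params`.
#' @param decay first-order field concentration decline rate (1/day).
#' @param openwater_kc open-water evaporation coefficient.
#' @param consts a [gray_wf_constants()] object.
#' @return An object of class `idu_sim`: list with `daily` (data frame of
#'   daily fluxes and states), `totals` (season ledger incl. `iss`, `lsv`,
#'   `yl`, `yield`, `wf` components), `balance` (water and nutrient
#'   closure residuals) and the configuration used.
#' @examples
#' wx <- generate_daily_weather(climate_preset("CJ"), n_years = 1, seed = 1)
#' geom <- idu_geometry(1e5, a_ditch = 4500, a_pond = 1500)
#' sim <- simulate_idu(wx, geom, "QD")
#' sim$totals$wf
#' @export
simulate_idu <- function(weather, geom, style, scheme = NULL,
                         crop = crop_params(), params = nutrient_params(),
                         fert_events = default_fert_events(), year = NULL,
                         et0 = NULL, yield_max = 8.5, freshwater_cap = Inf,
                         init_storage = 0.5, init_conc = NULL, decay = 0.15,
                         openwater_kc = 1.05,
                         consts = gray_wf_constants()) {
  if (is.character(style)) style <- management_style(style)
  if (is.null(scheme)) {
    season <- attr(weather, "season")
    if (is.null(season)) stop("no season window: supply `scheme`", call. = FALSE)
    scheme <- default_water_scheme(season_start = season[1])
  }
  if (is.null(year)) year <- weather$year[1]
  if (is.null(et0)) et0 <- et0_series(weather)
  rows <- which(weather$year == year & weather$doy >= scheme$season[1] &
                  weather$doy <= scheme$season[2])
  if (!length(rows)) stop("no weather rows in the season window", call. = FALSE)

  h <- .sim_hydro(weather, et0, rows, geom, style, scheme, crop,
                  cap_remote = freshwater_cap, init_storage = init_storage,
                  openwater_kc = openwater_kc)
  if (is.null(init_conc)) init_conc <- c(n = params$enc0, p = params$epc0)
  init_mass <- nutrient_state(geom, h$state0, init_conc = init_conc)
  fert_by_doy <- split(fert_events, scheme$season[1] - 1L + fert_events$offset)
  nr <- .sim_nutrients(h, geom, params, fert_by_doy, init_mass, decay = decay)

  yl <- yield_loss(h$eta_stage, h$etc_stage, crop$ky)
  yield <- yield_max * (1 - yl / 100)
  i_all <- h$i_dp + h$i_remote
  gbw <- green_blue_wf(h$eta_green, h$eta_blue, h$eta_recycled, yield)
  gw <- gray_wf(nr$l_runoff[["n"]], nr$l_runoff[["p"]],
                nr$l_leach[["n"]], nr$l_leach[["p"]], yield, consts)
  totals <- list(
    precip = h$precip, eta = h$eta, etc = h$etc, perc = h$perc,
    outflow_m3 = h$outflow,
    eta_green = h$eta_green, eta_blue = h$eta_blue,
    eta_recycled = h$eta_recycled,
    i_dp = h$i_dp, i_remote = h$i_remote, i_all = i_all,
    unmet = h$unmet,
    iss = irrigation_self_sufficiency(h$i_dp, i_all),
    lsv = local_storage_volume(geom),
    yl = yl, yield = yield,
    l_runoff_n = nr$l_runoff[["n"]], l_runoff_p = nr$l_runoff[["p"]],
    l_leach_n = nr$l_leach[["n"]], l_leach_p = nr$l_leach[["p"]],
    retention_n = nr$retention[["n"]], retention_p = nr$retention[["p"]],
    fert_in_n = nr$fert_in[["n"]], fert_in_p = nr$fert_in[["p"]],
    wf = c(green = unname(gbw["green"]), blue = unname(gbw["blue"]),
           recycled = unname(gbw["recycled"]), gray = as.numeric(gw),
           total = unname(gbw["green"] + gbw["blue"]) + as.numeric(gw)))
  daily <- h$daily
  daily$runoff_load_n <- nr$daily_runoff_n
  structure(list(daily = daily, totals = totals,
                 balance = list(water = .water_balance_residual(h, geom, crop),
                                nutrient = nr$residual),
                 geom = geom, style = style, scheme = scheme, crop = crop,
                 params = params, year = year,
                 fluxes = h$fluxes, state0 = h$state0, state = h$state),
            class = "idu_sim")
}

#' @export
print.idu_sim <- function(x, ...) {
  t <- x$totals
  cat(sprintf("IDU season simulation (%s style, year %s)\n",
              x$style$style, x$year))
  cat(sprintf("  rain %.0f mm | ETa %.0f mm (green %.0f / blue %.0f / recycled %.0f)\n",
              t$precip, t$eta, t$eta_green, t$eta_blue, t$eta_recycled))
  cat(sprintf("  irrigation %.0f mm (local %.0f, remote %.0f) -> ISS %.1f%% | LSV %.1f mm\n",
              t$i_all, t$i_dp, t$i_remote, t$iss, t$lsv))
  cat(sprintf("  loads out: TN %.2f, TP %.3f kg/ha | yield loss %.1f%% | yield %.2f t/ha\n",
              t$l_runoff_n, t$l_runoff_p, t$yl, t$yield))
  cat(sprintf("  WF (m3/ton): green %.0f, blue %.0f, gray %.0f, total %.0f\n",
              t$wf["green"], t$wf["blue"], t$wf["gray"], t$wf["total"]))
  invisible(x)
}

#' @export
summary.idu_sim <- function(object, ...) {
  print(object)
  cat(sprintf("  balance closure: water %.2e, nutrient N %.2e / P %.2e (relative)\n",
              object$balance$water, object$balance$nutrient[["n"]],
              object$balance$nutrient[["p"]]))
  invisible(object$totals)
}

#' @export
plot.idu_sim <- function(x, ...) {
  d <- x$daily
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(d$doy, d$depth, type = "l", xlab = "day of year",
                 ylab = "field depth (mm)",
                 main = sprintf("%s-style IDU water balance", x$style$style))
  graphics::lines(d$doy, d$precip, col = "steelblue", lty = 3)
  graphics::legend("topright", c("field depth", "rain"), lty = c(1, 3),
                   col = c("black", "steelblue"), bty = "n", cex = 0.8)
  vdp <- (d$vd + d$vp) * 1000 / x$geom$a_field
  graphics::plot(d$doy, vdp, type = "l", col = "darkgreen",
                 xlab = "day of year",
                 ylab = "ditch+pond storage (mm field eq.)")
  invisible(x)
}

#' As-data-frame method for daily simulation output
#'
#' @param x an `idu_sim` object.
#' @param ... unused.
#' @return The daily flux data frame.
#' @export
as.data.frame.idu_sim <- function(x, ...) x$daily

#' Write the daily fluxes of a simulation to CSV
#'
#' @param sim an `idu_sim` object.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_daily_csv <- function(sim, file) {
  utils::write.csv(sim$daily, file, row.names = FALSE)
  invisible(file)
}
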