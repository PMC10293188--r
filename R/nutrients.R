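# Nitrogen / phosphorus dynamics: fully mixed compartments with
# fertilization-day concentration resets and nutrient-spiraling retention
# in ditches and ponds; lognormal Monte-Carlo sampling of the retention
# parameters.

# Literature ranges of the retention parameters (read as the 5th-95th
# percentiles of their lognormal distributions).
.retention_ranges <- list(
  vf_n = c(4.2, 44),     # N uptake velocity, cm/day
  vf_p = c(1.5, 9.0),    # P uptake velocity, cm/day
  enc0 = c(0.4, 5.0),    # equilibrium N concentration, mg/L
  epc0 = c(0.03, 1.1))   # equilibrium P concentration, mg/L

#' Nutrient retention parameters
#'
#' One parameter set for the nutrient-spiraling retention model: uptake
#' velocities `vf_n`, `vf_p` (cm/day) and equilibrium concentrations
#' `enc0`, `epc0` (mg/L) toward which ditch/pond concentrations relax.
#' Defaults are the geometric midpoints of the literature ranges.
#'
#' @param vf_n,vf_p uptake velocities (cm/day), > 0.
#' @param enc0,epc0 equilibrium concentrations (mg/L), >= 0.
#' @return An object of class `nutrient_params`.
#' @export
nutrient_params <- function(vf_n = sqrt(prod(.retention_ranges$vf_n)),
                            vf_p = sqrt(prod(.retention_ranges$vf_p)),
                            enc0 = sqrt(prod(.retention_ranges$enc0)),
                            epc0 = sqrt(prod(.retention_ranges$epc0))) {
  if (vf_n <= 0 || vf_p <= 0) stop("uptake velocities must be > 0", call. = FALSE)
  if (enc0 < 0 || epc0 < 0) {
    stop("equilibrium concentrations must be >= 0", call. = FALSE)
  }
  structure(list(vf_n = vf_n, vf_p = vf_p, enc0 = enc0, epc0 = epc0),
            class = "nutrient_params")
}

#' Fit a lognormal distribution to a literature range
#'
#' Interprets `(low, high)` as the symmetric quantiles enclosing
#' `coverage` probability mass of a lognormal distribution, so
#' `meanlog = (log(low) + log(high)) / 2` and
#' `sdlog = (log(high) - log(low)) / (2 * qnorm((1 + coverage) / 2))`.
#'
#' @param low,high range bounds, 0 < low <= high.
#' @param coverage central probability mass enclosed by the range
#'   (default 0.90, i.e. the range is read as the 5th-95th percentiles).
#' @return Named numeric vector `c(meanlog, sdlog)`.
#' @examples
#' fit_lognormal_from_range(4.2, 44)     # N uptake velocity range
#' @export
fit_lognormal_from_range <- function(low, high, coverage = 0.90) {
  if (!(low > 0) || high < low) stop("need 0 < low <= high", call. = FALSE)
  if (coverage <= 0 || coverage >= 1) {
    stop("`coverage` must lie in (0, 1)", call. = FALSE)
  }
  z <- stats::qnorm((1 + coverage) / 2)
  c(meanlog = (log(low) + log(high)) / 2,
    sdlog = (log(high) - log(low)) / (2 * z))
}

#' Monte-Carlo sample of retention parameter sets
#'
#' Draws `n_sets` independent parameter sets from the four lognormal
#' distributions fitted to the literature ranges of `vf_n`, `vf_p`,
#' `enc0` and `epc0`.
#'
#' @param n_sets number of parameter sets (the reference ensemble uses 100).
#' @param seed integer seed; identical seeds give identical sets.
#' @param coverage central mass assigned to each literature range.
#' @param ranges named list of `c(low, high)` ranges (defaults to the
#'   built-in literature ranges).
#' @return A data frame with columns `vf_n`, `vf_p`, `enc0`, `epc0`, one
#'   row per draw.
#' @export
sample_retention_params <- function(n_sets, seed = 1L, coverage = 0.90,
                                    ranges = .retention_ranges) {
  stopifnot_scalar(n_sets, "n_sets", positive = TRUE)
  fits <- lapply(ranges, function(r) {
    fit_lognormal_from_range(r[1], r[2], coverage)
  })
  with_seed(seed, {
    out <- lapply(fits, function(f) {
      stats::rlnorm(n_sets, meanlog = f["meanlog"], sdlog = f["sdlog"])
    })
    as.data.frame(out)
  })
}

#' Areal nutrient-spiraling retention flux
#'
#' First-order retention toward the equilibrium concentration: the mass
#' removed over `dt` is `vf * (C - EC0) * A`, with `vf` converted from
#' cm/day to m/day and concentrations in g/m^3 (= mg/L). The flux is
#' floored at zero when `C <= EC0` (no net release), and, when the water
#' volume is supplied, capped so the concentration cannot be driven below
#' `EC0` within the step.
#'
#' @param conc compartment concentration (mg/L).
#' @param ec0 equilibrium concentration (mg/L).
#' @param vf uptake velocity (cm/day).
#' @param a_water wetted surface area (m^2).
#' @param dt time step (days).
#' @param volume optional water volume (m^3) used to cap the removal.
#' @return Mass removed (g).
#' @examples
#' retention_flux(3, 1, 10, 1000)  # 200 g
#' @export
retention_flux <- function(conc, ec0, vf, a_water, dt = 1, volume = NULL) {
  if (any(c(conc, ec0, vf, a_water, dt) < 0)) {
    stop("all arguments must be >= 0", call. = FALSE)
  }
  flux <- max(0, vf / 100 * (conc - ec0) * a_water * dt)
  if (!is.null(volume)) flux <- min(flux, max(0, (conc - ec0) * volume))
  flux
}

#' Set field concentrations on a fertilization day
#'
#' Fertilization resets the field N and P concentrations to the initial
#' concentrations of the event (which encode fertilizer rate and soil
#' properties); ditch and pond concentrations are unchanged.
#'
#' @param conc list with per-compartment concentration vectors `c(n, p)`
#'   (mg/L): elements `field`, `ditch`, `pond`.
#' @param event list or one-row data frame with elements `n`, `p` (mg/L).
#' @return The updated concentration list.
#' @export
apply_fertilization <- function(conc, event) {
  if (event$n < 0 || event$p < 0) {
    stop("event concentrations must be >= 0", call. = FALSE)
  }
  conc$field <- c(n = as.numeric(event$n), p = as.numeric(event$p))
  conc
}

.conc_of <- function(mass, vol) {
  if (vol > 1e-12) mass / vol else c(n = 0, p = 0)
}

#' Initial nutrient mass state
#'
#' @param geom an [idu_geometry()].
#' @param state a `hydro_state` giving the initial volumes.
#' @param init_conc named vector `c(n, p)` of initial ditch/pond
#'   concentrations (mg/L); the field starts nutrient-free until the first
#'   fertilization.
#' @return A `nutrient_state` list of per-compartment masses (g).
#' @export
nutrient_state <- function(geom, state, init_conc = c(n = 1, p = 0.1)) {
  structure(list(field = c(n = 0, p = 0),
                 ditch = init_conc * state$vd,
                 pond = init_conc * state$vp),
            class = "nutrient_state")
}

#' One day of nutrient mass balance
#'
#' Replays the day's water fluxes (from [step_water_balance()]) as a
#' sequential mass balance over the fully mixed field, ditch and pond
#' compartments: rain dilutes, the fertilization event (if any) resets the
#' field concentration, evapotranspiration removes water but no mass,
#' percolation exports mass as leaching load, a first-order field decline
#' stands in for soil adsorption and plant uptake, recycled irrigation
#' transfers mass from ditch/pond back to the field, drainage advects mass
#' downstream, and spiraling retention acts on ditch and pond at the end of
#' the day. Infiltrated and dried-out field mass is routed to a field soil
#' sink so the season-scale budget closes exactly.
#'
#' @param mass a `nutrient_state` ([nutrient_state()]), masses in g.
#' @param fluxes the `fluxes` list returned by [step_water_balance()].
#' @param params a [nutrient_params()].
#' @param geom the [idu_geometry()] used for the hydrology step.
#' @param fert optional fertilization event (`list(n =, p =)`, mg/L).
#' @param decay first-order field concentration decline rate (1/day).
#' @return List with the updated `mass`, exported `loads` (g:
#'   `leach`, `runoff`, each `c(n, p)`), `retention` (ditch + pond, g),
#'   `field_sink` (infiltration + decay + dry-out, g) and `fert_in`
#'   (mass added by the fertilization reset, g).
#' @export
step_nutrient <- function(mass, fluxes, params, geom, fert = NULL,
                          decay = 0.15) {
  fx <- fluxes
  mmA <- geom$a_field / 1000
  vf_ <- fx$depth0 * mmA
  vd <- fx$vd0
  vp <- fx$vp0
  mf <- mass$field; md <- mass$ditch; mp <- mass$pond
  ec0 <- c(n = params$enc0, p = params$epc0)
  vf_vel <- c(n = params$vf_n, p = params$vf_p)

  # rain (nutrient-free) on all compartments
  vf_ <- vf_ + fx$precip * mmA
  vd <- vd + fx$rain_ditch
  vp <- vp + fx$rain_pond
  # infiltration into the soil deficit carries field mass to the soil sink
  cf <- .conc_of(mf, vf_)
  sink <- cf * fx$inf * mmA
  mf <- mf - sink
  vf_ <- vf_ - fx$inf * mmA
  # fertilization-day reset
  fert_in <- c(n = 0, p = 0)
  if (!is.null(fert)) {
    new_m <- c(n = as.numeric(fert$n), p = as.numeric(fert$p)) * vf_
    fert_in <- new_m - mf
    mf <- new_m
  }
  # evaporation: water leaves, mass stays
  vf_ <- vf_ - fx$eta_ponded * mmA
  vd <- vd - fx$ev_ditch
  vp <- vp - fx$ev_pond
  # percolation -> leaching load
  cf <- .conc_of(mf, vf_)
  leach <- cf * fx$perc * mmA
  mf <- mf - leach
  vf_ <- vf_ - fx$perc * mmA
  # first-order field decline (soil adsorption / plant uptake stand-in)
  dec <- mf * (1 - exp(-decay))
  mf <- mf - dec
  sink <- sink + dec
  # irrigation: local transfers mass, remote is nutrient-free
  cd <- .conc_of(md, vd)
  tr_d <- cd * fx$irr_ditch * mmA
  md <- md - tr_d
  vd <- vd - fx$irr_ditch * mmA
  cp <- .conc_of(mp, vp)
  tr_p <- cp * fx$irr_pond * mmA
  mp <- mp - tr_p
  vp <- vp - fx$irr_pond * mmA
  mf <- mf + tr_d + tr_p
  vf_ <- vf_ + (fx$irr_ditch + fx$irr_pond + fx$irr_remote) * mmA
  # drainage: field -> ditch
  cf <- .conc_of(mf, vf_)
  dm <- cf * fx$drain_f2d
  mf <- mf - dm
  vf_ <- vf_ - fx$drain_f2d
  md <- md + dm
  vd <- vd + fx$drain_f2d
  # ditch overflow -> pond and/or out of the IDU
  cd <- .conc_of(md, vd)
  ov <- fx$ditch_to_pond + fx$outflow_ditch
  md <- md - cd * ov
  vd <- vd - ov
  runoff <- cd * fx$outflow_ditch
  mp <- mp + cd * fx$ditch_to_pond
  vp <- vp + fx$ditch_to_pond
  cp <- .conc_of(mp, vp)
  runoff <- runoff + cp * fx$outflow_pond
  mp <- mp - cp * fx$outflow_pond
  vp <- vp - fx$outflow_pond
  # spiraling retention on ditch and pond (end-of-day volumes)
  ret <- c(n = 0, p = 0)
  for (nut in c("n", "p")) {
    if (vd > 1e-9) {
      r <- retention_flux(max(0, md[[nut]] / vd), ec0[[nut]], vf_vel[[nut]],
                          geom$a_ditch, volume = vd)
      md[[nut]] <- md[[nut]] - r
      ret[[nut]] <- ret[[nut]] + r
    }
    if (vp > 1e-9) {
      r <- retention_flux(max(0, mp[[nut]] / vp), ec0[[nut]], vf_vel[[nut]],
                          geom$a_pond, volume = vp)
      mp[[nut]] <- mp[[nut]] - r
      ret[[nut]] <- ret[[nut]] + r
    }
  }
  # field dried out: residual dissolved mass joins the soil sink
  if (fx$depth1 <= 0) {
    sink <- sink + mf
    mf <- c(n = 0, p = 0)
  }
  mass$field <- mf; mass$ditch <- md; mass$pond <- mp
  list(mass = mass,
       loads = list(leach = leach, runoff = runoff),
       retention = ret, field_sink = sink, fert_in = fert_in)
}
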