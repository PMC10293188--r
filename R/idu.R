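# Geometry, management style and daily water balance of one
# irrigation-drainage unit (IDU): paddy field + ditch (+ optional pond).

#' IDU geometry
#'
#' Areas and depths of the field, ditch and (optional) pond compartments.
#' The combined ditch+pond storage capacity `v_dp` is derived from areas
#' and maximum depths. Ditch and pond percolation is assumed zero (lined /
#' puddled); field percolation is a constant daily rate while ponded.
#'
#' @param a_field paddy field area (m^2), > 0.
#' @param a_ditch ditch surface area (m^2).
#' @param a_pond pond surface area (m^2); 0 for styles without a pond.
#' @param ditch_depth,pond_depth maximum storage depths (m).
#' @param perc_mm field percolation rate while ponded (mm/day).
#' @return An object of class `idu_geometry` with derived capacities
#'   `v_ditch`, `v_pond`, `v_dp` (m^3).
#' @export
idu_geometry <- function(a_field, a_ditch, a_pond = 0,
                         ditch_depth = 0.8, pond_depth = 1.5,
                         perc_mm = 2) {
  stopifnot_scalar(a_field, "a_field", positive = TRUE)
  if (a_ditch < 0 || a_pond < 0) stop("areas must be >= 0", call. = FALSE)
  if (perc_mm < 0) stop("`perc_mm` must be >= 0", call. = FALSE)
  structure(list(a_field = a_field, a_ditch = a_ditch, a_pond = a_pond,
                 ditch_depth = ditch_depth, pond_depth = pond_depth,
                 perc_mm = perc_mm,
                 v_ditch = a_ditch * ditch_depth,
                 v_pond = a_pond * pond_depth,
                 v_dp = a_ditch * ditch_depth + a_pond * pond_depth),
            class = "idu_geometry")
}

#' IDU management style
#'
#' The four ways ditches and ponds are used for irrigation and drainage:
#' \describe{
#'   \item{TC}{totally centralized: no pond in the drainage path, remote
#'     freshwater irrigation only.}
#'   \item{PD1}{partly decentralized 1: no pond in the drainage path, but
#'     ditch water is used for irrigation with priority.}
#'   \item{PD2}{partly decentralized 2: pond in the drainage path, remote
#'     freshwater irrigation only.}
#'   \item{QD}{quasi-decentralized: pond in the drainage path and ditch +
#'     pond water prioritized for irrigation.}
#' }
#'
#' @param style one of `"TC"`, `"PD1"`, `"PD2"`, `"QD"`.
#' @return An object of class `management_style` with logical flags
#'   `pond_in_drainage` and `local_priority`.
#' @export
management_style <- function(style = c("TC", "PD1", "PD2", "QD")) {
  style <- match.arg(style)
  structure(list(style = style,
                 pond_in_drainage = style %in% c("PD2", "QD"),
                 local_priority = style %in% c("PD1", "QD")),
            class = "management_style")
}

#' Field water-level management scheme
#'
#' Encodes "normal management by farmers": shallow continuous ponding with
#' per-stage lower irrigation-trigger depth, upper refill target and
#' maximum allowable depth before drainage, a mid-season drying window and
#' a final pre-harvest drainage window. During drainage windows irrigation
#' is suppressed and the field is drained.
#'
#' @param season_start first day-of-year of the growing season.
#' @param stage_len integer(4): lengths of the initial, development,
#'   mid-season and late-season stages (days).
#' @param trigger,target,max_depth per-stage depths (mm), recycled to
#'   length 4; must satisfy trigger <= target <= max_depth.
#' @param midseason_dry length (days) of the drying window placed at the
#'   end of the development stage.
#' @param final_drain length (days) of the terminal drainage window.
#' @return An object of class `water_scheme` with elements `stages` (data
#'   frame), `drain` (drainage windows) and `season` (start/end doy).
#' @export
default_water_scheme <- function(season_start = 152L,
                                 stage_len = c(30L, 30L, 40L, 30L),
                                 trigger = 10, target = 40, max_depth = 60,
                                 midseason_dry = 7L, final_drain = 10L) {
  stopifnot(length(stage_len) == 4)
  trigger <- rep_len(trigger, 4)
  target <- rep_len(target, 4)
  max_depth <- rep_len(max_depth, 4)
  if (any(trigger > target) || any(target > max_depth)) {
    stop("need trigger <= target <= max_depth in every stage", call. = FALSE)
  }
  ends <- season_start - 1L + cumsum(as.integer(stage_len))
  starts <- c(season_start, ends[-4] + 1L)
  stages <- data.frame(
    stage = c("initial", "development", "mid-season", "late-season"),
    start = starts, end = ends,
    trigger = trigger, target = target, max = max_depth)
  drain <- data.frame(
    window = c("midseason-drying", "final-drainage"),
    start = c(ends[2] - as.integer(midseason_dry) + 1L,
              ends[4] - as.integer(final_drain) + 1L),
    end = c(ends[2], ends[4]))
  structure(list(stages = stages, drain = drain,
                 season = c(starts[1], ends[4])),
            class = "water_scheme")
}

.stage_at <- function(scheme, doy) {
  i <- which(doy >= scheme$stages$start & doy <= scheme$stages$end)
  if (length(i)) i[1] else NA_integer_
}

.in_drain_window <- function(scheme, doy) {
  any(doy >= scheme$drain$start & doy <= scheme$drain$end)
}

#' Local storage volume of an IDU
#'
#' The ditch + pond storage capacity expressed as an equivalent depth of
#' field water: `LSV = V_DP * 1000 / A_F` (mm). IDUs with LSV below 35 mm,
#' 35-55 mm and above 55 mm behave very differently in irrigation
#' self-sufficiency.
#'
#' @param geom an [idu_geometry()].
#' @return LSV in mm of field-water equivalent.
#' @examples
#' local_storage_volume(idu_geometry(1e5, a_ditch = 2500, a_pond = 1000,
#'                                   ditch_depth = 0.8, pond_depth = 1.5))
#' @export
local_storage_volume <- function(geom) {
  stopifnot(inherits(geom, "idu_geometry"))
  geom$v_dp * 1000 / geom$a_field
}

#' Daily irrigation demand from the water-level scheme
#'
#' Demand is `target - depth` when the ponded depth has fallen below the
#' stage's trigger depth; zero otherwise, zero outside the growing season,
#' and zero during scheduled drainage windows.
#'
#' @param depth current ponded depth (mm).
#' @param scheme a [default_water_scheme()] object.
#' @param doy day of year.
#' @return Demand in mm.
#' @export
irrigation_demand <- function(depth, scheme, doy) {
  i <- .stage_at(scheme, doy)
  if (is.na(i) || .in_drain_window(scheme, doy)) return(0)
  if (depth < scheme$stages$trigger[i]) scheme$stages$target[i] - depth else 0
}

#' Allocate irrigation between local storage and remote freshwater
#'
#' Styles with local priority (PD1, QD) draw from the ditch first (QD also
#' from the pond), then from remote freshwater up to `cap_remote`; TC and
#' PD2 draw remote water only. Unmet demand is returned when the remote
#' cap binds.
#'
#' @param demand irrigation demand (mm over the field area), >= 0.
#' @param style a [management_style()].
#' @param avail_ditch,avail_pond available local storage (mm of field-water
#'   equivalent).
#' @param cap_remote remaining remote freshwater allowance (mm); `Inf` in
#'   unrestricted years.
#' @return List with `from_ditch`, `from_pond`, `from_remote`, `unmet`
#'   (all mm).
#' @export
allocate_irrigation <- function(demand, style, avail_ditch, avail_pond = 0,
                                cap_remote = Inf) {
  if (demand < 0) stop("`demand` must be >= 0", call. = FALSE)
  if (cap_remote < 0) cap_remote <- 0
  from_ditch <- from_pond <- 0
  rest <- demand
  if (style$local_priority) {
    from_ditch <- min(rest, avail_ditch)
    rest <- rest - from_ditch
    if (style$style == "QD") {
      from_pond <- min(rest, avail_pond)
      rest <- rest - from_pond
    }
  }
  from_remote <- min(rest, cap_remote)
  list(from_ditch = from_ditch, from_pond = from_pond,
       from_remote = from_remote, unmet = rest - from_remote)
}

#' Initial hydrological state of an IDU
#'
#' @param geom an [idu_geometry()].
#' @param depth initial ponded depth (mm).
#' @param storage_frac initial fill fraction of ditch and pond storage
#'   (carry-over from the pre-season period).
#' @return A `hydro_state` list: ponded `depth` (mm), root-zone depletion
#'   `dr` (mm), field-water source fractions `frac` (rain/remote/local),
#'   and ditch/pond volumes `vd`, `vp` (m^3).
#' @export
hydro_state <- function(geom, depth = 0, storage_frac = 0.5) {
  structure(list(depth = depth, dr = 0,
                 frac = c(rain = 1, remote = 0, local = 0),
                 vd = storage_frac * geom$v_ditch,
                 vp = storage_frac * geom$v_pond),
            class = "hydro_state")
}

#' One day of the IDU water balance
#'
#' Applies the daily operation sequence: rain (on field, ditch and pond
#' surfaces) and infiltration into the soil deficit; crop
#' evapotranspiration (from ponded water first, then the soil store under
#' the stress coefficient) and open-water evaporation from ditch and pond;
#' field percolation; irrigation per the water-level scheme and management
#' style; surplus drainage with field excess routed to the ditch, ditch
#' overflow to the pond when the pond is in the drainage path, and final
#' overflow leaving the IDU. Water mass is conserved exactly; field-water
#' source fractions are updated by volume-weighted mixing.
#'
#' @param state a `hydro_state` ([hydro_state()]).
#' @param precip precipitation (mm).
#' @param et0 reference evapotranspiration (mm).
#' @param doy day of year.
#' @param geom an [idu_geometry()].
#' @param style a [management_style()].
#' @param scheme a [default_water_scheme()].
#' @param crop a [crop_params()].
#' @param cap_remote remaining remote freshwater allowance (mm).
#' @param openwater_kc open-water evaporation coefficient applied to ET0
#'   on ditch/pond surfaces.
#' @return List with the updated `state`, a `fluxes` list (all water fluxes
#'   of the day: mm on the field area, m^3 for channel transfers, plus
#'   begin/end storage snapshots), and the updated `cap_remote`.
#' @export
step_water_balance <- function(state, precip, et0, doy, geom, style, scheme,
                               crop = crop_params(), cap_remote = Inf,
                               openwater_kc = 1.05) {
  if (!is.finite(precip) || !is.finite(et0) || precip < 0 || et0 < 0) {
    stop("`precip` and `et0` must be finite and >= 0", call. = FALSE)
  }
  mmA <- geom$a_field / 1000   # mm on the field -> m^3
  d <- state$depth; dr <- state$dr; f <- state$frac
  vd <- state$vd; vp <- state$vp
  depth0 <- d; dr0 <- dr; vd0 <- vd; vp0 <- vp

  # --- rain ---
  f <- mix_frac(f, d, c(1, 0, 0), precip)
  d <- d + precip
  rain_ditch <- precip / 1000 * geom$a_ditch
  rain_pond <- precip / 1000 * geom$a_pond
  vd <- vd + rain_ditch
  vp <- vp + rain_pond
  inf <- min(d, dr)            # ponded water refills the soil deficit
  d <- d - inf
  dr <- dr - inf

  # --- evapotranspiration ---
  i_stage <- .stage_at(scheme, doy)
  kc <- if (is.na(i_stage)) 0 else crop$kc[i_stage]
  etc <- kc * et0
  if (d > 0) {
    ks <- 1
    eta_ponded <- min(d, etc)
    d <- d - eta_ponded
    eta_soil <- if (etc > eta_ponded) min(etc - eta_ponded, crop$taw - dr) else 0
  } else {
    ks <- water_stress_coefficient(0, dr, crop$taw, crop$p)
    eta_ponded <- 0
    eta_soil <- min(ks * etc, crop$taw - dr)
  }
  dr <- dr + eta_soil
  eta <- eta_ponded + eta_soil
  eta_src <- eta * f
  ev_ditch <- min(vd, openwater_kc * et0 / 1000 * geom$a_ditch)
  ev_pond <- min(vp, openwater_kc * et0 / 1000 * geom$a_pond)
  vd <- vd - ev_ditch
  vp <- vp - ev_pond

  # --- percolation (ponded fields only) ---
  perc <- min(d, geom$perc_mm)
  d <- d - perc

  # --- irrigation ---
  demand <- irrigation_demand(d, scheme, doy)
  al <- allocate_irrigation(demand, style,
                            avail_ditch = vd * 1000 / geom$a_field,
                            avail_pond = vp * 1000 / geom$a_field,
                            cap_remote = cap_remote)
  irr_local <- al$from_ditch + al$from_pond
  vd <- vd - al$from_ditch * mmA
  vp <- vp - al$from_pond * mmA
  cap_remote <- cap_remote - al$from_remote
  supplied <- irr_local + al$from_remote
  f <- mix_frac(f, d, c(0, 0, 1), irr_local)
  f <- mix_frac(f, d + irr_local, c(0, 1, 0), al$from_remote)
  d <- d + supplied

  # --- drainage & routing ---
  maxd <- if (is.na(i_stage)) 0 else scheme$stages$max[i_stage]
  if (.in_drain_window(scheme, doy)) maxd <- 0
  exc <- max(0, d - maxd)
  d <- d - exc
  drain_f2d <- exc * mmA
  vd <- vd + drain_f2d
  ov_ditch <- max(0, vd - geom$v_ditch)
  vd <- vd - ov_ditch
  if (style$pond_in_drainage && geom$a_pond > 0) {
    ditch_to_pond <- ov_ditch
    vp <- vp + ditch_to_pond
    outflow_pond <- max(0, vp - geom$v_pond)
    vp <- vp - outflow_pond
    outflow_ditch <- 0
  } else {
    ditch_to_pond <- 0
    outflow_ditch <- ov_ditch
    outflow_pond <- 0
  }

  state$depth <- d; state$dr <- dr; state$frac <- f
  state$vd <- vd; state$vp <- vp
  fluxes <- list(
    doy = doy, precip = precip, et0 = et0, etc = etc, ks = ks,
    rain_ditch = rain_ditch, rain_pond = rain_pond, inf = inf,
    eta = eta, eta_ponded = eta_ponded, eta_soil = eta_soil,
    eta_src = eta_src,
    ev_ditch = ev_ditch, ev_pond = ev_pond,
    perc = perc, demand = demand,
    irr_ditch = al$from_ditch, irr_pond = al$from_pond,
    irr_remote = al$from_remote, unmet = al$unmet,
    drain_f2d = drain_f2d, ditch_to_pond = ditch_to_pond,
    outflow_ditch = outflow_ditch, outflow_pond = outflow_pond,
    outflow = outflow_ditch + outflow_pond,
    stage = i_stage,
    depth0 = depth0, dr0 = dr0, vd0 = vd0, vp0 = vp0,
    depth1 = d, dr1 = dr, vd1 = vd, vp1 = vp)
  list(state = state, fluxes = fluxes, cap_remote = cap_remote)
}
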