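# Ensemble execution over climate years x retention-parameter sets,
# dry-year freshwater restriction, style-share upscaling and the
# recycling-irrigation / pond-reconnection / pond-construction scenario
# ladder.

#' Province profile
#'
#' Describes how a province's rice systems are configured: area
#' percentages of ditches and ponds, the shares of the four management
#' styles, the probability-of-irrigation guarantee (PI), and the
#' statistical rice yield. `pond_bearing` is the fraction of
#' non-pond-connected IDUs that possess an (isolated) pond and can
#' therefore be reconnected.
#'
#' @param region one of `"NE"`, `"CJ"`, `"SE"`.
#' @param ditch_pct,pond_pct area percentages of ditches and ponds in the
#'   rice system.
#' @param shares named numeric vector of style shares
#'   (`TC`, `PD1`, `PD2`, `QD`) summing to 1.
#' @param pi probability of irrigation guarantee (%); defaults to the
#'   regional rule (79 NE, 87 CJ, 83 SE).
#' @param yield statistical rice yield (ton/ha).
#' @param pond_bearing fraction of PD1 IDUs possessing reconnectable ponds.
#' @return An object of class `province_profile`.
#' @export
province_profile <- function(region = c("NE", "CJ", "SE"),
                             ditch_pct, pond_pct, shares,
                             pi = NULL, yield,
                             pond_bearing = 0.5) {
  region <- match.arg(region)
  if (is.null(pi)) pi <- switch(region, NE = 79, CJ = 87, SE = 83)
  shares <- shares[c("TC", "PD1", "PD2", "QD")]
  if (anyNA(shares) || abs(sum(shares) - 1) > 1e-9 || any(shares < 0)) {
    stop("`shares` must be named TC/PD1/PD2/QD, non-negative, summing to 1",
         call. = FALSE)
  }
  if (ditch_pct < 0 || pond_pct < 0 || ditch_pct + pond_pct >= 100) {
    stop("invalid ditch/pond area percentages", call. = FALSE)
  }
  structure(list(region = region, ditch_pct = ditch_pct,
                 pond_pct = pond_pct, shares = shares, pi = pi,
                 yield = yield, pond_bearing = pond_bearing,
                 converted_field_pct = 0),
            class = "province_profile")
}

#' Shipped province profiles
#'
#' Current-status archetypes for the three rice regions, with totally
#' centralized management dominant (> 60% of IDUs), ponds out of the
#' drainage path in ~80% of IDUs and a quasi-decentralized share below 5%.
#'
#' @param region one of `"NE"`, `"CJ"`, `"SE"`.
#' @return A [province_profile()].
#' @export
province_preset <- function(region = c("NE", "CJ", "SE")) {
  region <- match.arg(region)
  switch(region,
    NE = province_profile("NE", ditch_pct = 3.5, pond_pct = 0.3,
      shares = c(TC = 0.70, PD1 = 0.15, PD2 = 0.10, QD = 0.05),
      yield = 8.5, pond_bearing = 0.3),
    CJ = province_profile("CJ", ditch_pct = 4.5, pond_pct = 1.5,
      shares = c(TC = 0.62, PD1 = 0.18, PD2 = 0.15, QD = 0.05),
      yield = 8.0, pond_bearing = 0.5),
    SE = province_profile("SE", ditch_pct = 4.9, pond_pct = 1.2,
      shares = c(TC = 0.65, PD1 = 0.15, PD2 = 0.15, QD = 0.05),
      yield = 7.0, pond_bearing = 0.5))
}

#' Scenario specification
#'
#' One point on the easy-to-difficult redesign ladder: the recycling
#' irrigation (RI) target share, the pond reconnection (PR) target share
#' of reconnectable ponds, and the pond construction (PC) target combined
#' ditch+pond area percentage (capped at 8%, the maximum allowed by
#' well-facilitated farmland construction standards).
#'
#' @param ri target recycling-irrigation share of IDUs (%), or `NA`.
#' @param pr target share of reconnectable ponds reconnected (%), or `NA`.
#' @param pc_area target ditch+pond area percentage (<= 8), or `NA`.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(ri = NA_real_, pr = NA_real_, pc_area = NA_real_) {
  for (v in c(ri, pr)) {
    if (!is.na(v) && (v < 0 || v > 100)) {
      stop("`ri` and `pr` targets must lie in [0, 100]", call. = FALSE)
    }
  }
  if (!is.na(pc_area) && (pc_area < 0 || pc_area > 8)) {
    stop("`pc_area` must lie in [0, 8] (% of system area)", call. = FALSE)
  }
  structure(list(ri = ri, pr = pr, pc_area = pc_area),
            class = "scenario_spec")
}

#' Apply a redesign scenario to a province profile
#'
#' Recycling irrigation (RI) moves share mass TC -> PD1 and PD2 -> QD,
#' proportionally, until the recycling share (PD1 + QD) reaches the
#' target. Pond reconnection (PR) moves the pond-bearing part of PD1 into
#' QD. Pond construction (PC) raises the pond area percentage until
#' ditch + pond reaches the target, records the converted field area, and
#' connects ponds into the drainage path for every style (TC -> PD2,
#' PD1 -> QD); irrigation priority remains governed by the RI lever.
#'
#' @param profile a [province_profile()].
#' @param spec a [scenario_spec()].
#' @return The modified `province_profile`.
#' @export
apply_scenario <- function(profile, spec) {
  stopifnot(inherits(profile, "province_profile"),
            inherits(spec, "scenario_spec"))
  s <- profile$shares
  if (!is.na(spec$ri)) {
    r0 <- s[["PD1"]] + s[["QD"]]
    tgt <- spec$ri / 100
    pool <- s[["TC"]] + s[["PD2"]]
    if (tgt > r0 && pool > 0) {
      phi <- min(1, (tgt - r0) / pool)
      s[["PD1"]] <- s[["PD1"]] + phi * s[["TC"]]
      s[["QD"]] <- s[["QD"]] + phi * s[["PD2"]]
      s[["TC"]] <- (1 - phi) * s[["TC"]]
      s[["PD2"]] <- (1 - phi) * s[["PD2"]]
    }
  }
  if (!is.na(spec$pr)) {
    mv <- s[["PD1"]] * profile$pond_bearing * spec$pr / 100
    s[["PD1"]] <- s[["PD1"]] - mv
    s[["QD"]] <- s[["QD"]] + mv
  }
  if (!is.na(spec$pc_area)) {
    add <- max(0, min(spec$pc_area, 8) -
                 (profile$ditch_pct + profile$pond_pct))
    if (add > 0) {
      profile$pond_pct <- profile$pond_pct + add
      profile$converted_field_pct <- profile$converted_field_pct + add
      profile$pond_bearing <- 1
      s[["QD"]] <- s[["QD"]] + s[["PD1"]]
      s[["PD1"]] <- 0
      s[["PD2"]] <- s[["PD2"]] + s[["TC"]]
      s[["TC"]] <- 0
    }
  }
  profile$shares <- s / sum(s)
  profile
}

#' Dry-year remote freshwater cap
#'
#' Remote reservoir supply is guaranteed up to the PI percentile of
#' growing-season dryness; in drier years the seasonal remote supply is
#' capped at the demand level of the PI-percentile year of the demand
#' series.
#'
#' @param year_rank dryness percentile rank of the year (0-100, 100 =
#'   driest).
#' @param profile a [province_profile()], or the PI value (%) directly.
#' @param demand_series seasonal remote irrigation demands (mm) across
#'   years, used to locate the PI-percentile demand.
#' @return The seasonal freshwater cap (mm); `Inf` when unrestricted.
#' @export
restrict_freshwater <- function(year_rank, profile, demand_series) {
  pi_pct <- if (inherits(profile, "province_profile")) profile$pi else profile
  if (year_rank < 0 || year_rank > 100) {
    stop("`year_rank` must lie in [0, 100]", call. = FALSE)
  }
  if (year_rank <= pi_pct) return(Inf)
  stats::quantile(demand_series, pi_pct / 100, names = FALSE)
}

#' Land occupation trade-off of pond construction
#'
#' Assuming all newly constructed ponds are converted from paddy fields,
#' returns the percentage of current fields occupied and the resulting
#' production change in normal years (yield per unit area unchanged, so
#' production falls in proportion to the occupied field share).
#'
#' @param added_pond_pct newly constructed pond area, as a percentage of
#'   the system area.
#' @param profile a [province_profile()] (pre-construction status).
#' @return Named vector `c(field_pct_occupied, yield_change_pct)`.
#' @export
land_tradeoff <- function(added_pond_pct, profile) {
  if (added_pond_pct < 0) stop("`added_pond_pct` must be >= 0", call. = FALSE)
  field_pct <- 100 - profile$ditch_pct - profile$pond_pct
  if (added_pond_pct > field_pct) {
    stop("added pond area exceeds the field area", call. = FALSE)
  }
  occ <- added_pond_pct / field_pct * 100
  c(field_pct_occupied = occ, yield_change_pct = -occ)
}

.ens_metrics <- c("wf_green", "wf_blue", "wf_recycled", "wf_gray",
                  "wf_total", "iss", "yl")

#' Run a climate x parameter ensemble for a province
#'
#' Simulates every management style over the Cartesian product of
#' synthetic climate years ("year-sites") and Monte-Carlo retention
#' parameter sets, applies the dry-year freshwater restriction, and
#' aggregates the styles into the provincial mixture. Hydrology is
#' independent of the retention parameters, so each style-year is
#' simulated once and the nutrient balance replayed per parameter set.
#'
#' By default styles are combined by deterministic share weighting (the
#' expectation of proportional random sampling); `aggregate = "sample"`
#' draws one style per record proportionally instead.
#'
#' @param profile a [province_profile()].
#' @param scenario optional [scenario_spec()] applied before simulation.
#' @param climate a [climate_params()]; defaults to the regional preset.
#' @param n_years number of synthetic climate years (year-sites).
#' @param n_param_sets number of retention parameter draws.
#' @param seed root seed; climate, parameters and style sampling use
#'   derived substreams.
#' @param a_sys system area (m^2) of the simulated unit.
#' @param restrict apply the PI-based dry-year freshwater cap.
#' @param aggregate `"weights"` (share-weighted) or `"sample"`.
#' @param crop,fert_events,decay,init_storage passed to the simulator.
#' @return An object of class `wf_ensemble`: `runs` (per style x year x
#'   parameter-set records), `mix` (provincial mixture records), `summary`
#'   (mean/median/IQR/90% range per metric), plus the aridity indices,
#'   dryness classes and freshwater caps of the simulated years.
#' @export
run_ensemble <- function(profile, scenario = NULL, climate = NULL,
                         n_years = 10, n_param_sets = 10, seed = 1L,
                         a_sys = 1e6, restrict = TRUE,
                         aggregate = c("weights", "sample"),
                         crop = crop_params(),
                         fert_events = default_fert_events(),
                         decay = 0.15, init_storage = 0.5) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(profile, "province_profile"))
  if (!is.null(scenario)) profile <- apply_scenario(profile, scenario)
  if (is.null(climate)) climate <- climate_preset(profile$region)

  wx <- generate_daily_weather(climate, n_years, seed = seed)
  et0v <- et0_series(wx)
  scheme <- default_water_scheme(season_start = climate$season[1])
  ai <- aridity_index(wx, season = scheme$season, et0 = et0v)
  cls <- classify_years(ai)
  rank_pct <- 100 * rank(ai, ties.method = "average") / n_years

  a_ditch <- profile$ditch_pct / 100 * a_sys
  a_pond <- profile$pond_pct / 100 * a_sys
  a_field <- a_sys - a_ditch - a_pond
  geom_pond <- idu_geometry(a_field, a_ditch, a_pond)
  geom_nopond <- idu_geometry(a_field, a_ditch, 0)

  row_sets <- lapply(seq_len(n_years), function(y) {
    which(wx$year == y & wx$doy >= scheme$season[1] &
            wx$doy <= scheme$season[2])
  })

  # demand series from unrestricted TC runs -> PI-based caps
  caps <- rep(Inf, n_years)
  if (restrict) {
    tc <- management_style("TC")
    demand <- vapply(seq_len(n_years), function(y) {
      h <- .sim_hydro(wx, et0v, row_sets[[y]], geom_nopond, tc, scheme,
                      crop, cap_remote = Inf, init_storage = init_storage)
      h$i_dp + h$i_remote
    }, numeric(1))
    caps <- vapply(seq_len(n_years), function(y) {
      restrict_freshwater(rank_pct[y], profile, demand)
    }, numeric(1))
  }

  pdf_ <- sample_retention_params(n_param_sets, seed = seed + 7919L)
  fert_by_doy <- split(fert_events, scheme$season[1] - 1L + fert_events$offset)

  styles <- c("TC", "PD1", "PD2", "QD")
  runs <- vector("list", length(styles) * n_years * n_param_sets)
  k <- 0L
  for (sty in styles) {
    style <- management_style(sty)
    geom <- if (style$pond_in_drainage && a_pond > 0) geom_pond else geom_nopond
    for (y in seq_len(n_years)) {
      h <- .sim_hydro(wx, et0v, row_sets[[y]], geom, style, scheme, crop,
                      cap_remote = caps[y], init_storage = init_storage)
      yl <- yield_loss(h$eta_stage, h$etc_stage, crop$ky)
      yield <- profile$yield * (1 - yl / 100)
      i_all <- h$i_dp + h$i_remote
      gbw <- green_blue_wf(h$eta_green, h$eta_blue, h$eta_recycled, yield)
      for (j in seq_len(n_param_sets)) {
        np <- nutrient_params(pdf_$vf_n[j], pdf_$vf_p[j],
                              pdf_$enc0[j], pdf_$epc0[j])
        init_mass <- nutrient_state(geom, h$state0,
                                    init_conc = c(n = np$enc0, p = np$epc0))
        nr <- .sim_nutrients(h, geom, np, fert_by_doy, init_mass,
                             decay = decay)
        gw <- as.numeric(gray_wf(nr$l_runoff[["n"]], nr$l_runoff[["p"]],
                                 nr$l_leach[["n"]], nr$l_leach[["p"]], yield))
        k <- k + 1L
        runs[[k]] <- data.frame(
          style = sty, year = y, param = j,
          class = as.character(cls[y]), restricted = is.finite(caps[y]),
          wf_green = unname(gbw["green"]), wf_blue = unname(gbw["blue"]),
          wf_recycled = unname(gbw["recycled"]), wf_gray = gw,
          wf_total = unname(gbw["green"] + gbw["blue"]) + gw,
          iss = irrigation_self_sufficiency(h$i_dp, i_all),
          i_dp = h$i_dp, i_all = i_all, yl = yl, yield = yield,
          l_runoff_n = nr$l_runoff[["n"]], l_runoff_p = nr$l_runoff[["p"]],
          l_leach_n = nr$l_leach[["n"]], l_leach_p = nr$l_leach[["p"]],
          lsv = local_storage_volume(geom))
      }
    }
  }
  runs <- do.call(rbind, runs)

  w <- profile$shares
  mix <- do.call(rbind, lapply(split(runs, runs[, c("year", "param")]),
                               function(d) {
    d <- d[match(styles, d$style), ]
    if (aggregate == "sample") {
      sty <- with_seed(seed + 104729L + d$year[1] * 1000L + d$param[1],
                       sample(styles, 1, prob = w))
      d1 <- d[d$style == sty, ]
      out <- d1[, c(.ens_metrics, "yield")]
    } else {
      out <- as.data.frame(as.list(colSums(
        d[, c(.ens_metrics, "yield")] * as.numeric(w))))
      out$iss <- irrigation_self_sufficiency(sum(w * d$i_dp),
                                             sum(w * d$i_all))
    }
    out$year <- d$year[1]
    out$param <- d$param[1]
    out$class <- d$class[1]
    out$restricted <- d$restricted[1]
    out
  }))
  rownames(mix) <- NULL
  # production per unit of original field area: pond construction converts
  # fields, scaling production down by the occupied share
  if (profile$converted_field_pct > 0) {
    occ <- land_tradeoff(profile$converted_field_pct, {
      p0 <- profile
      p0$pond_pct <- p0$pond_pct - p0$converted_field_pct
      p0
    })
    mix$production_factor <- 1 + occ[["yield_change_pct"]] / 100
  } else {
    mix$production_factor <- 1
  }

  qs <- function(x) {
    q <- stats::quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
    c(mean = mean(x), q05 = q[1], q25 = q[2], median = q[3], q75 = q[4],
      q95 = q[5])
  }
  summ <- t(vapply(.ens_metrics, function(m) qs(mix[[m]]), numeric(6)))
  structure(list(runs = runs, mix = mix, summary = summ,
                 profile = profile, aridity = ai, class = cls, caps = caps,
                 seed = seed, n_years = n_years,
                 n_param_sets = n_param_sets),
            class = "wf_ensemble")
}

#' @export
print.wf_ensemble <- function(x, ...) {
  cat(sprintf("Water-footprint ensemble: %d year-sites x %d parameter sets = %d runs per style\n",
              x$n_years, x$n_param_sets, x$n_years * x$n_param_sets))
  cat(sprintf("Region %s | styles weighted %s | dry years: %d of %d (%d extreme)\n",
              x$profile$region,
              paste(sprintf("%s %.0f%%", names(x$profile$shares),
                            100 * x$profile$shares), collapse = ", "),
              sum(x$class != "normal"), x$n_years,
              sum(x$class == "extreme5")))
  cat("Provincial mixture (m^3/ton; iss, yl in %):\n")
  print(round(x$summary, 1))
  invisible(x)
}

#' Run the redesign scenario ladder
#'
#' Simulates the easy-to-difficult redesign sequence on matched forcing
#' (same seed, hence identical weather and parameter draws): current
#' status, recycling irrigation to 100% (RI), plus pond reconnection to
#' 100% (RI+PR), plus pond construction to the 8% area cap (RI+PR+PC).
#'
#' @param profile a [province_profile()].
#' @param steps optional named list of [scenario_spec()]s overriding the
#'   default four-point ladder.
#' @param ... passed to [run_ensemble()].
#' @return An object of class `scenario_ladder`: a data frame of
#'   ensemble-mean metrics per ladder point (with the per-point ensembles
#'   attached as attribute `"ensembles"`).
#' @export
scenario_ladder <- function(profile, steps = NULL, ...) {
  if (is.null(steps)) {
    steps <- list(current = NULL,
                  RI = scenario_spec(ri = 100),
                  `RI+PR` = scenario_spec(ri = 100, pr = 100),
                  `RI+PR+PC` = scenario_spec(ri = 100, pr = 100, pc_area = 8))
  }
  ens <- lapply(steps, function(sp) run_ensemble(profile, scenario = sp, ...))
  out <- do.call(rbind, lapply(names(ens), function(nm) {
    e <- ens[[nm]]
    dry <- e$mix$restricted
    data.frame(scenario = nm,
               wf_green = mean(e$mix$wf_green),
               wf_blue = mean(e$mix$wf_blue),
               wf_gray = mean(e$mix$wf_gray),
               wf_total = mean(e$mix$wf_total),
               iss = mean(e$mix$iss),
               yl_dry = if (any(dry)) mean(e$mix$yl[dry]) else 0,
               land_occupied_pct = e$profile$converted_field_pct /
                 (100 - e$profile$ditch_pct - e$profile$pond_pct +
                    e$profile$converted_field_pct) * 100)
  }))
  rownames(out) <- NULL
  structure(out, ensembles = ens, class = c("scenario_ladder", "data.frame"))
}

#' Monotonicity check along the scenario ladder
#'
#' The redesign ladder should never increase the total water footprint nor
#' decrease irrigation self-sufficiency.
#'
#' @param ladder a [scenario_ladder()] result.
#' @param tol numerical slack.
#' @return List with logicals `wf_nonincreasing`, `iss_nondecreasing`.
#' @export
ladder_monotone <- function(ladder, tol = 1e-9) {
  list(wf_nonincreasing = all(diff(ladder$wf_total) <= tol),
       iss_nondecreasing = all(diff(ladder$iss) >= -tol))
}

#' @export
print.scenario_ladder <- function(x, ...) {
  cat("Redesign scenario ladder (ensemble means):\n")
  print(data.frame(lapply(as.data.frame(x), function(c) {
    if (is.numeric(c)) round(c, 1) else c
  })), row.names = FALSE)
  m <- ladder_monotone(x)
  cat(sprintf("total WF non-increasing: %s | ISS non-decreasing: %s\n",
              m$wf_nonincreasing, m$iss_nondecreasing))
  invisible(x)
}
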