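test_that("local storage volume converts ditch+pond capacity to field mm", {
  g <- idu_geometry(1e5, a_ditch = 3500, a_pond = 0, ditch_depth = 1)
  expect_equal(local_storage_volume(g), 35)       # lower class boundary
  g2 <- idu_geometry(1e5, a_ditch = 2500, a_pond = 2000,
                     ditch_depth = 1, pond_depth = 1.5)
  expect_equal(local_storage_volume(g2), 55)      # upper class boundary
  g3 <- idu_geometry(1e5, a_ditch = 0, a_pond = 0)
  expect_equal(local_storage_volume(g3), 0)
  expect_error(idu_geometry(0, 100), "a_field")
})

test_that("irrigation demand follows the trigger/target rule", {
  sch <- default_water_scheme(season_start = 152, trigger = 10, target = 40)
  expect_equal(irrigation_demand(5, sch, 160), 35)
  expect_equal(irrigation_demand(15, sch, 160), 0)
  # mid-season drying window suppresses irrigation regardless of depth
  drying_doy <- sch$drain$start[1]
  expect_equal(irrigation_demand(0, sch, drying_doy), 0)
  # outside the season no demand
  expect_equal(irrigation_demand(0, sch, 10), 0)
})

test_that("irrigation allocation respects style priority and caps", {
  qd <- management_style("QD")
  tc <- management_style("TC")
  pd1 <- management_style("PD1")
  a <- allocate_irrigation(30, qd, avail_ditch = 50, avail_pond = 20)
  expect_equal(c(a$from_ditch + a$from_pond, a$from_remote), c(30, 0))
  a <- allocate_irrigation(30, tc, avail_ditch = 50, avail_pond = 20)
  expect_equal(c(a$from_ditch + a$from_pond, a$from_remote), c(0, 30))
  a <- allocate_irrigation(30, pd1, avail_ditch = 12, avail_pond = 100,
                           cap_remote = 10)
  expect_equal(a$from_ditch, 12)   # PD1 never draws the pond
  expect_equal(a$from_remote, 10)
  expect_equal(a$unmet, 8)
  expect_error(allocate_irrigation(-1, qd, 0), "demand")
})

test_that("a null day leaves the state unchanged", {
  g <- fix_geom(perc_mm = 0)
  sch <- default_water_scheme(152)
  st <- hydro_state(g, depth = 20, storage_frac = 0.4)
  out <- step_water_balance(st, precip = 0, et0 = 0, doy = 160, geom = g,
                            style = management_style("QD"), scheme = sch,
                            crop = crop_params())
  expect_equal(out$state$depth, 20)
  expect_equal(out$state$vd, st$vd)
  expect_equal(out$state$vp, st$vp)
  expect_equal(out$fluxes$outflow, 0)
})

test_that("field excess routes to the ditch before leaving the IDU", {
  # 80 mm rain onto a dry field with stage max 60 mm: 20 mm drains to a
  # ditch large enough to hold it, nothing leaves the IDU
  g <- idu_geometry(1e5, a_ditch = 2000, a_pond = 0, ditch_depth = 2,
                    perc_mm = 0)
  sch <- default_water_scheme(152, trigger = 10, target = 40, max_depth = 60)
  st <- hydro_state(g, depth = 0, storage_frac = 0)
  out <- step_water_balance(st, precip = 80, et0 = 0, doy = 160, geom = g,
                            style = management_style("TC"), scheme = sch)
  expect_equal(out$state$depth, 60)
  expect_equal(out$fluxes$drain_f2d, 20 / 1000 * g$a_field)
  expect_equal(out$fluxes$outflow, 0)
  # same event with a tiny ditch: overflow leaves the IDU (TC: no pond)
  g2 <- idu_geometry(1e5, a_ditch = 100, a_pond = 0, ditch_depth = 0.5,
                     perc_mm = 0)
  st2 <- hydro_state(g2, depth = 0, storage_frac = 0)
  out2 <- step_water_balance(st2, precip = 80, et0 = 0, doy = 160, geom = g2,
                             style = management_style("TC"), scheme = sch)
  expect_gt(out2$fluxes$outflow, 0)
})

test_that("pond-in-path styles route ditch overflow through the pond", {
  g <- idu_geometry(1e4, a_ditch = 50, a_pond = 500, ditch_depth = 0.5,
                    pond_depth = 2, perc_mm = 0)
  sch <- default_water_scheme(152)
  st <- hydro_state(g, depth = 55, storage_frac = 1)  # ditch already full
  out <- step_water_balance(st, precip = 40, et0 = 0, doy = 160, geom = g,
                            style = management_style("QD"), scheme = sch)
  expect_gt(out$fluxes$ditch_to_pond, 0)
  expect_equal(out$fluxes$outflow_ditch, 0)
  out2 <- step_water_balance(st, precip = 40, et0 = 0, doy = 160, geom = g,
                             style = management_style("PD1"), scheme = sch)
  expect_equal(out2$fluxes$ditch_to_pond, 0)
  expect_gt(out2$fluxes$outflow_ditch, 0)
})

test_that("season water balance closes to 1e-6 relative", {
  for (style in c("TC", "QD")) {
    sim <- simulate_idu(fix_weather(1, seed = 2), fix_geom(), style)
    expect_lt(abs(sim$balance$water), 1e-6)
  }
})

test_that("TC never irrigates locally; QD covers demand locally first", {
  wx <- fix_weather(1, seed = 4)
  tc <- simulate_idu(wx, fix_geom(), "TC")
  expect_equal(tc$totals$i_dp, 0)
  expect_equal(sum(tc$daily$irr_ditch) + sum(tc$daily$irr_pond), 0)
  # huge local storage: QD needs no remote water at all
  g_big <- idu_geometry(1e4, a_ditch = 500, a_pond = 3000, pond_depth = 3)
  qd <- simulate_idu(wx, g_big, "QD")
  expect_equal(qd$totals$i_remote, 0)
  expect_equal(qd$totals$iss, 100)
})

test_that("IDU outflow is non-increasing in local storage capacity", {
  wx <- fix_weather(1, seed = 6)
  depths <- c(0.5, 1, 1.5, 2.5)
  outs <- vapply(depths, function(pd) {
    g <- idu_geometry(1e5, 4500, 1500, pond_depth = pd)
    simulate_idu(wx, g, "QD")$totals$outflow_m3
  }, numeric(1))
  expect_true(all(diff(outs) <= 1e-9))
})

test_that("source fractions stay a valid partition through a season", {
  wx <- fix_weather(1, seed = 8)
  g <- fix_geom()
  sch <- default_water_scheme(attr(wx, "season")[1])
  st <- hydro_state(g)
  et0 <- et0_series(wx)
  rows <- which(wx$doy >= sch$season[1] & wx$doy <= sch$season[2])
  for (i in rows) {
    out <- step_water_balance(st, wx$precip_mm[i], et0[i], wx$doy[i], g,
                              management_style("QD"), sch)
    st <- out$state
    expect_true(all(st$frac >= -1e-12 & st$frac <= 1 + 1e-12))
    expect_equal(sum(st$frac), 1, tolerance = 1e-9)
    expect_gte(st$depth, 0)
    expect_lte(st$vd, g$v_ditch + 1e-9)
    expect_lte(st$vp, g$v_pond + 1e-9)
  }
})
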