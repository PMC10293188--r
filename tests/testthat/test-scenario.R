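test_that("scenario application moves style shares as specified", {
  p <- province_preset("CJ")
  # full recycling irrigation: no TC or PD2 IDUs remain
  p_ri <- apply_scenario(p, scenario_spec(ri = 100))
  expect_equal(unname(p_ri$shares[["TC"]]), 0)
  expect_equal(unname(p_ri$shares[["PD2"]]), 0)
  expect_equal(sum(p_ri$shares), 1)
  # plus full pond reconnection: the pond-bearing PD1 mass joins QD
  p_pr <- apply_scenario(p, scenario_spec(ri = 100, pr = 100))
  expect_equal(unname(p_pr$shares[["QD"]]),
               unname(p_ri$shares[["QD"]] +
                        p_ri$shares[["PD1"]] * p$pond_bearing))
  # identity: a spec equal to the current status changes nothing
  ri_now <- (p$shares[["PD1"]] + p$shares[["QD"]]) * 100
  p_id <- apply_scenario(p, scenario_spec(
    ri = ri_now, pr = 0, pc_area = p$ditch_pct + p$pond_pct))
  expect_equal(p_id$shares, p$shares)
  expect_equal(p_id$pond_pct, p$pond_pct)
  expect_equal(p_id$converted_field_pct, 0)
})

test_that("pond construction is capped at 8% combined area", {
  p <- province_preset("CJ")   # ditch 4.5 + pond 1.5
  p_pc <- apply_scenario(p, scenario_spec(pc_area = 8))
  expect_equal(p_pc$pond_pct + p_pc$ditch_pct, 8)
  expect_equal(p_pc$converted_field_pct, 2)
  expect_error(scenario_spec(pc_area = 12), "pc_area")
})

test_that("land trade-off arithmetic matches the field-share conversion", {
  p <- province_preset("CJ")   # fields are 94% of the system
  lt <- land_tradeoff(2, p)
  expect_equal(unname(lt["field_pct_occupied"]), 2 / 94 * 100)
  expect_equal(unname(lt["yield_change_pct"]), -2 / 94 * 100)
  expect_equal(unname(land_tradeoff(0, p)), c(0, 0))
  expect_error(land_tradeoff(99, p), "exceeds")
})

test_that("freshwater restriction caps only years beyond the PI", {
  demand <- seq(100, 500, length.out = 30)
  expect_true(is.infinite(restrict_freshwater(50, 87, demand)))
  expect_true(is.infinite(restrict_freshwater(79, 79, demand)))
  cap <- restrict_freshwater(95, 79, demand)
  expect_true(is.finite(cap))
  expect_equal(cap, stats::quantile(demand, 0.79, names = FALSE))
})

test_that("small ensembles have the expected record counts and summaries", {
  ens <- run_ensemble(province_preset("CJ"), n_years = 2, n_param_sets = 2,
                      seed = 17, restrict = FALSE)
  expect_equal(nrow(ens$runs), 4 * 2 * 2)   # styles x years x params
  expect_equal(sum(ens$runs$style == "QD"), 4)
  expect_equal(nrow(ens$mix), 4)
  # quantile summary agrees with a brute-force computation on the table
  expect_equal(unname(ens$summary["iss", "q05"]),
               stats::quantile(ens$mix$iss, 0.05, names = FALSE))
  expect_equal(unname(ens$summary["wf_gray", "median"]),
               stats::median(ens$mix$wf_gray))
  # a 1x1 ensemble's summary collapses onto the single run
  e1 <- run_ensemble(province_preset("CJ"), n_years = 1, n_param_sets = 1,
                     seed = 17, restrict = FALSE)
  expect_equal(unname(e1$summary["wf_total", "mean"]),
               unname(e1$summary["wf_total", "median"]))
  expect_equal(nrow(e1$mix), 1)
})

test_that("ensembles are reproducible and style sampling is seeded", {
  a <- run_ensemble(province_preset("NE"), n_years = 2, n_param_sets = 2,
                    seed = 5)
  b <- run_ensemble(province_preset("NE"), n_years = 2, n_param_sets = 2,
                    seed = 5)
  expect_identical(a$summary, b$summary)
  s1 <- run_ensemble(province_preset("NE"), n_years = 2, n_param_sets = 2,
                     seed = 5, aggregate = "sample")
  s2 <- run_ensemble(province_preset("NE"), n_years = 2, n_param_sets = 2,
                     seed = 5, aggregate = "sample")
  expect_identical(s1$mix, s2$mix)
})

test_that("matched-forcing runs order the styles as expected", {
  ens <- run_ensemble(province_preset("CJ"), n_years = 4, n_param_sets = 3,
                      seed = 19)
  r <- ens$runs
  key <- paste(r$year, r$param)
  qd <- r[r$style == "QD", ][order(key[r$style == "QD"]), ]
  tc <- r[r$style == "TC", ][order(key[r$style == "TC"]), ]
  expect_true(all(qd$wf_gray < tc$wf_gray))
  expect_true(all(qd$wf_blue <= tc$wf_blue + 1e-9))
  expect_true(all(tc$yl >= qd$yl - 1e-9))
  expect_true(all(tc$iss == 0))
})

test_that("the redesign ladder improves WF and self-sufficiency", {
  lad <- scenario_ladder(province_preset("CJ"), n_years = 3,
                         n_param_sets = 2, seed = 23)
  expect_equal(nrow(lad), 4)
  mono <- ladder_monotone(lad)
  expect_true(mono$wf_nonincreasing)
  expect_true(mono$iss_nondecreasing)
  # pond construction occupies land; earlier rungs do not
  expect_equal(lad$land_occupied_pct[1:3], rep(0, 3))
  expect_gt(lad$land_occupied_pct[4], 0)
  expect_output(print(lad), "non-increasing: TRUE")
})
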