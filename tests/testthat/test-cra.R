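test_that("mortality dose-response interpolates and caps correctly", {
  rk <- coventry$risks
  expect_equal(mortality_rr(0, rk), 1.0)
  expect_equal(mortality_rr(rk$reference_volume_km_per_year, rk),
               rk$rr_reference)
  # cap: rr 0.9, max ratio 2, volume 3x reference -> 1 - 0.1 * 2 = 0.8
  rk2 <- rk
  rk2$rr_reference <- 0.9
  rk2$max_volume_ratio <- 2
  expect_equal(mortality_rr(3 * rk2$reference_volume_km_per_year, rk2), 0.8)
  expect_error(mortality_rr(-1, rk), "nonnegative")
})

test_that("physical-activity deaths are zero at no change, negative toward level 1, linear in population", {
  cfg <- coventry
  pop <- cfg$population
  expect_equal(
    pa_deaths(pop$baseline, pop$baseline, pop, cfg$behaviour, cfg$risks), 0
  )
  post <- shifted_post(cfg, source_level = 3, share = 0.02)
  d <- pa_deaths(pop$baseline, post, pop, cfg$behaviour, cfg$risks)
  expect_lt(d, 0)
  pop2 <- pop
  pop2$size <- 2 * pop$size
  expect_equal(
    pa_deaths(pop$baseline, post, pop2, cfg$behaviour, cfg$risks), 2 * d
  )
})

test_that("air-pollution deaths are a nonnegative disbenefit proportional to exposure", {
  cfg <- coventry
  expect_equal(ap_deaths(0, cfg$risks, cfg$population), 0)
  rk0 <- cfg$risks
  rk0$in_traffic_fraction <- 0
  expect_equal(ap_deaths(1e6, rk0, cfg$population), 0)
  expect_gt(ap_deaths(1e6, cfg$risks, cfg$population), 0)
  expect_error(ap_deaths(-1, cfg$risks, cfg$population), "nonnegative")
})

test_that("crash deaths follow the fatality rate per 100M km", {
  rk <- coventry$risks
  rk$crash_fatalities_per_100M_km <- 0.67
  expect_equal(crash_deaths(1e8, rk), 0.67)
  expect_equal(crash_deaths(0, rk), 0)
  expect_error(crash_deaths(-5, rk), "nonnegative")
})

test_that("carbon savings follow the modal-shift-weighted emission factors", {
  rk <- coventry$risks
  expect_equal(carbon_tonnes(0, rk), 0)
  rk_walk <- rk
  rk_walk$modal_shift[] <- c(0, 0, 1)
  expect_equal(carbon_tonnes(1e6, rk_walk), 0)
  expect_lt(carbon_tonnes(1e6, rk), 0)
  # 1e6 km at 0.5*90 + 0.3*171 + 0.2*0 = 96.3 g/km -> -96.3 t
  expect_equal(carbon_tonnes(1e6, rk), -96.3)
})

test_that("discounting matches hand-computed values and the take-up ramp", {
  eco <- economic_params(vsl = 1, discount_rate = 0, horizon_years = 10,
                         takeup_years = 1, ppp_coefficient = 1,
                         carbon_damage_cost = 1)
  expect_equal(discounted_stream(100, eco), 1000)
  eco$discount_rate <- 0.05
  expect_equal(discounted_stream(100, eco), 772.1735, tolerance = 1e-6)
  # longer horizon accumulates more value
  eco5 <- eco
  eco5$horizon_years <- 5
  expect_lt(discounted_stream(100, eco5), discounted_stream(100, eco))
  # slower take-up forfeits early-year value
  eco_slow <- eco
  eco_slow$takeup_years <- 5
  expect_lt(discounted_stream(100, eco_slow), discounted_stream(100, eco))
})

test_that("appraisal of an unchanged distribution is all zeros", {
  r <- appraise(coventry, coventry$population$baseline)
  expect_equal(r$impacts$discounted_value, rep(0, 4))
  expect_equal(r$total_benefit, 0)
  expect_equal(r$bcr, 0)
})

test_that("appraisal is additive and identical under equivalent volume changes", {
  for (cfg in random_configs(5)) {
    post <- apply_shift(cfg$population$baseline,
                        scenario_shift(5, unclass(cfg$population$baseline)[5] / 2))
    r <- appraise(cfg, post)
    expect_equal(r$total_benefit, sum(r$impacts$discounted_value),
                 tolerance = 1e-6)
    cfg_trips <- cfg
    cfg_trips$behaviour$trips_per_day <- cfg$behaviour$trips_per_day * 1.2
    cfg_len <- cfg
    cfg_len$behaviour$trip_length_km <- cfg$behaviour$trip_length_km * 1.2
    expect_equal(appraise(cfg_trips, post)$impacts,
                 appraise(cfg_len, post)$impacts)
  }
})

test_that("VSL scales the three mortality domains and leaves carbon unchanged", {
  cfg <- coventry
  post <- shifted_post(cfg, 2, 0.01)
  r1 <- appraise(cfg, post)
  cfg$economics$vsl <- cfg$economics$vsl * 1.2
  r2 <- appraise(cfg, post)
  mort <- c("physical_activity", "air_pollution", "crash_risk")
  i <- r1$impacts$domain %in% mort
  expect_equal(r2$impacts$discounted_value[i],
               1.2 * r1$impacts$discounted_value[i])
  expect_equal(r2$impacts$discounted_value[!i],
               r1$impacts$discounted_value[!i])
})

test_that("appraise rejects invalid inputs", {
  expect_error(appraise(inject_violation(coventry, "vsl"),
                        coventry$population$baseline), "invalid config")
  expect_error(appraise(coventry,
                        cycling_distribution(c(0.5, 0.5, 0.5, 0, 0))),
               "invalid post distribution")
})
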