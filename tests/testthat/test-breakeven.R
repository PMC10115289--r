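test_that("shifting a share moves mass from the source level to level 1 only", {
  base <- cycling_distribution(c(0.01, 0.09, 0.15, 0.25, 0.50))
  post <- apply_shift(base, scenario_shift(2, 0.01242))
  expect_equal(unclass(post), c(0.02242, 0.07758, 0.15, 0.25, 0.50),
               ignore_attr = TRUE)
  post4 <- apply_shift(base, scenario_shift(5, 0.00793))
  expect_equal(unclass(post4), c(0.01793, 0.09, 0.15, 0.25, 0.49207),
               ignore_attr = TRUE)
  expect_equal(unclass(apply_shift(base, scenario_shift(3, 0))),
               unclass(base))
  expect_error(apply_shift(base, scenario_shift(2, 0.5)), "infeasible shift")
})

test_that("share mass is conserved exactly and only two levels change", {
  set.seed(7)
  for (cfg in random_configs(10, seed = 7)) {
    base <- cfg$population$baseline
    src <- sample(2:5, 1)
    s <- runif(1, 0, unclass(base)[src])
    post <- apply_shift(base, scenario_shift(src, s))
    expect_equal(sum(unclass(post)), sum(unclass(base)), tolerance = 1e-14)
    untouched <- setdiff(2:5, src)
    expect_identical(unclass(post)[untouched], unclass(base)[untouched])
  }
})

test_that("bisection recovers a closed-form break-even on a stubbed engine", {
  # linear benefit k * share against cost C: BCR = share / s_star
  s_star <- 0.01234
  bcr_fn <- function(s) s / s_star
  sol <- cyclebreakeven:::bisect_breakeven(bcr_fn, upper = 0.09,
                                           tolerance = 1e-9)
  expect_equal(sol$share, s_star, tolerance = 1e-6)
  expect_error(cyclebreakeven:::bisect_breakeven(function(s) 2, 0.1),
               "already cost-saving")
  expect_error(cyclebreakeven:::bisect_breakeven(function(s) s, 0.5),
               "source level exhausted")
  # dips below its value at the lower bracket before recovering
  expect_error(
    cyclebreakeven:::bisect_breakeven(function(s) 3 * (s - 0.5)^2, 1.2),
    "not monotone"
  )
})

test_that("the solver is deterministic and lands on BCR = 1 within tolerance", {
  r1 <- solve_breakeven(coventry, 2, tolerance = 1e-6)
  r2 <- solve_breakeven(coventry, 2, tolerance = 1e-6)
  expect_identical(r1$scenario$shifted_share, r2$scenario$shifted_share)
  expect_lt(abs(r1$bcr_achieved - 1), 1e-6)
  expect_equal(r1$new_regular_cyclists,
               count_from_share(r1$scenario$shifted_share,
                                coventry$population$size))
})

test_that("less frequent baseline cyclists need a smaller shift to break even", {
  shares <- vapply(2:5, function(l) {
    solve_breakeven(coventry, l)$scenario$shifted_share
  }, numeric(1))
  # each shifted person gains more cycling volume the lower their baseline
  expect_true(all(diff(shares) < 0))
  expect_gt(shares[1], shares[4]) # level 2 needs more people than level 5
})

test_that("the solver reports infeasibility when the source level is exhausted", {
  cfg <- coventry
  cfg$intervention$cost_intl_dollars <- 1e12
  expect_error(solve_breakeven(cfg, 2), "source level exhausted")
})

test_that("scenario summaries reproduce the reported headline statistics", {
  ref <- coventry_breakeven_scenarios()
  results <- Map(function(lvl, share) breakeven_result(coventry, lvl, share),
                 ref$source_level, ref$required_share)
  expect_equal(vapply(results, `[[`, integer(1), "new_regular_cyclists"),
               ref$new_regular_cyclists)
  summ <- summarize_breakeven(results, coventry$intervention,
                              coventry$economics)
  expect_identical(summ$mean_new_regular_cyclists, 1604L)
  expect_equal(round(summ$cyclists_per_km), 267)
  expect_equal(round(summ$per_cyclist_annual_value), 798)
})

test_that("per-cyclist value halves when the horizon doubles at fixed counts", {
  ref <- coventry_breakeven_scenarios()
  results <- Map(function(lvl, share) breakeven_result(coventry, lvl, share),
                 ref$source_level, ref$required_share)
  eco20 <- coventry$economics
  eco20$horizon_years <- 20L
  s10 <- summarize_breakeven(results, coventry$intervention,
                             coventry$economics)
  s20 <- summarize_breakeven(results, coventry$intervention, eco20)
  expect_equal(s20$per_cyclist_annual_value,
               s10$per_cyclist_annual_value / 2)
})

test_that("PPP conversion is a simple positive scaling", {
  eco <- coventry$economics
  expect_equal(round(ppp_convert(798, eco)), 533)
  expect_equal(ppp_convert(0, eco), 0)
  eco$ppp_coefficient <- 1
  expect_equal(ppp_convert(1234.5, eco), 1234.5)
})
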