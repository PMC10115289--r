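test_that("the Coventry fixture pins the case-study base values", {
  cfg <- coventry_fixture()
  expect_identical(validate_config(cfg), character(0))
  expect_equal(sum(unclass(cfg$population$baseline)), 1)
  expect_equal(unclass(cfg$population$baseline),
               c(0.01, 0.09, 0.15, 0.25, 0.50), ignore_attr = TRUE)
  expect_identical(cfg$population$size, 173169)
  expect_equal(cfg$intervention$cost_intl_dollars, 12800491)
  expect_equal(cfg$intervention$cycleway_length_km, 6)
  # the pinned dollar cost and the PPP coefficient are ~0.5% inconsistent
  # in the source material; the dollar figure is authoritative
  expect_equal(ppp_convert(cfg$intervention$cost_intl_dollars,
                           cfg$economics),
               8548999.9, tolerance = 1e-6)
  # +/-20% behaviour probes reproduce the standard sensitivity grid values
  expect_equal(0.8 * cfg$behaviour$trip_length_km, 3.28)
  expect_equal(1.2 * cfg$behaviour$trip_length_km, 4.92)
  expect_equal(0.8 * cfg$behaviour$trips_per_day, 1.6)
  expect_equal(1.2 * cfg$behaviour$trips_per_day, 2.4)
})

test_that("the generator is deterministic under a seed and leaves the RNG alone", {
  spec <- generator_spec(seed = 11, n_configs = 5)
  set.seed(999)
  before <- .Random.seed
  a <- sample_configs(spec)
  expect_identical(.Random.seed, before)
  b <- sample_configs(spec)
  expect_identical(lapply(a, cyclebreakeven:::config_to_list),
                   lapply(b, cyclebreakeven:::config_to_list))
  c2 <- sample_configs(generator_spec(seed = 12, n_configs = 5))
  expect_false(identical(cyclebreakeven:::config_to_list(a[[1]]),
                         cyclebreakeven:::config_to_list(c2[[1]])))
})

test_that("every sampled configuration is valid", {
  cfgs <- sample_configs(generator_spec(seed = 5, n_configs = 500))
  violations <- lapply(cfgs, validate_config)
  expect_true(all(lengths(violations) == 0))
})

test_that("sampled shares follow the stated Dirichlet expectation", {
  alpha <- c(1, 2, 3, 5, 9)
  cfgs <- sample_configs(generator_spec(seed = 21, n_configs = 1000))
  share1 <- vapply(cfgs, function(cfg) unclass(cfg$population$baseline)[1],
                   numeric(1))
  expected <- alpha[1] / sum(alpha)
  # sd of a Dirichlet component is sqrt(a1 (a0 - a1) / (a0^2 (a0 + 1)));
  # allow 4 standard errors around the analytic mean
  se <- sqrt(alpha[1] * (sum(alpha) - alpha[1]) /
               (sum(alpha)^2 * (sum(alpha) + 1))) / sqrt(length(cfgs))
  expect_lt(abs(mean(share1) - expected), 4 * se)
})

test_that("degenerate generator ranges are rejected", {
  expect_error(generator_spec(1, 10, ranges = list(vsl = c(2e6, 1e6))),
               "degenerate")
  expect_error(generator_spec(1, 10, ranges = list(bogus = c(0, 1))),
               "unknown range")
})

test_that("violation injection breaks exactly the named invariant", {
  cfg <- coventry_fixture()
  bad <- inject_violation(cfg, "shares_sum")
  expect_match(validate_config(bad), "shares sum != 1")
  bad2 <- inject_violation(cfg, "modal_shift")
  expect_match(validate_config(bad2), "modal shares sum != 1")
  bad3 <- inject_violation(cfg, "vsl")
  expect_match(validate_config(bad3), "vsl")
})
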