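# the solved base-case level-2 break-even, reused across blocks
base_be <- solve_breakeven(coventry, 2, tolerance = 1e-8)
base_shift <- base_be$scenario

test_that("a null variation reproduces the base case exactly", {
  v <- variation("vsl", coventry$economics$vsl, "unchanged VSL")
  row <- run_variation(coventry, base_shift, v)
  expect_equal(row$bcr_at_base_shift, 1, tolerance = 1e-6)
  expect_equal(row$additional_vs_base, 0L)
  expect_true(row$feasible)
})

test_that("sensitivity rows satisfy the count identities", {
  v <- variation("discount_rate", 0.065, "Discount rate 6.50%")
  row <- run_variation(coventry, base_shift, v)
  post1 <- unclass(coventry$population$baseline)[1] + row$breakeven_share
  expect_identical(row$absolute_regular_cyclists,
                   count_from_share(post1, coventry$population$size))
  base_abs <- count_from_share(
    unclass(base_be$post)[1], coventry$population$size
  )
  expect_identical(row$additional_vs_base,
                   row$absolute_regular_cyclists - base_abs)
})

test_that("each variation moves the BCR and requirement in opposite directions", {
  # benefit-increasing variations: BCR > 1 at the base shift, smaller
  # break-even share; benefit-decreasing: the reverse
  up <- list(
    variation("vsl", 1.2 * coventry$economics$vsl),
    variation("discount_rate", 0.035),
    variation("horizon_years", 15L),
    variation("trip_length_km", 1.2 * coventry$behaviour$trip_length_km)
  )
  down <- list(
    variation("vsl", 0.8 * coventry$economics$vsl),
    variation("discount_rate", 0.065),
    variation("horizon_years", 5L),
    variation("takeup_years", 5),
    variation("post_trip_length_km", 0.8 * coventry$behaviour$trip_length_km)
  )
  for (v in up) {
    row <- run_variation(coventry, base_shift, v)
    expect_gt(row$bcr_at_base_shift, 1)
    expect_lt(row$breakeven_share, base_shift$shifted_share)
    expect_lte(row$additional_vs_base, 0L)
  }
  for (v in down) {
    row <- run_variation(coventry, base_shift, v)
    expect_lt(row$bcr_at_base_shift, 1)
    expect_gt(row$breakeven_share, base_shift$shifted_share)
    expect_gte(row$additional_vs_base, 0L)
  }
})

test_that("a post-state volume increase is cost-saving with no shift at all", {
  # raising every cyclist's post-intervention volume by 20% already clears
  # the cost before anyone changes frequency level, so no nonnegative
  # break-even shift exists; the row is flagged rather than solved
  v <- variation("post_trips_per_day", 1.2 * coventry$behaviour$trips_per_day)
  row <- run_variation(coventry, base_shift, v)
  expect_gt(row$bcr_at_base_shift, 1)
  expect_false(row$feasible)
  expect_true(is.na(row$breakeven_share))
})

test_that("slower take-up degrades the BCR monotonically", {
  bcrs <- vapply(c(2, 3, 5), function(y) {
    run_variation(coventry, base_shift,
                  variation("takeup_years", y))$bcr_at_base_shift
  }, numeric(1))
  expect_true(all(diff(bcrs) < 0))
  expect_true(all(bcrs < 1))
})

test_that("the VSL+20% BCR equals the engine-linearity prediction exactly", {
  r <- appraise(coventry, base_be$post)
  mort <- r$impacts$domain != "carbon"
  predicted <- (1.2 * sum(r$impacts$discounted_value[mort]) +
                  sum(r$impacts$discounted_value[!mort])) / r$cost
  v <- variation("vsl", 1.2 * coventry$economics$vsl)
  row <- run_variation(coventry, base_shift, v)
  expect_equal(row$bcr_at_base_shift, predicted, tolerance = 1e-12)
})

test_that("the default grid has the full variation set in stable order", {
  vars <- default_variations(coventry)
  expect_length(vars, 20)
  tab <- sensitivity_table(coventry, base_shift, vars, tolerance = 1e-6)
  expect_equal(nrow(tab), 20)
  expect_equal(tab$label, vapply(vars, `[[`, character(1), "label"))
  # VSL probes are symmetric +/-20% around the base value
  vsl_rows <- which(tab$parameter == "vsl")
  expect_equal(vapply(vars[vsl_rows], `[[`, numeric(1), "value"),
               c(0.8, 1.2) * coventry$economics$vsl)
  # rerunning yields the identical table
  expect_identical(tab, sensitivity_table(coventry, base_shift, vars,
                                          tolerance = 1e-6))
})

test_that("an infeasible variation is flagged without aborting the table", {
  starve <- variation("annual_mortality_rate", 0.000001, "implausibly low mortality")
  tab <- sensitivity_table(
    coventry, base_shift,
    list(starve, variation("vsl", coventry$economics$vsl))
  )
  expect_false(tab$feasible[1])
  expect_true(is.na(tab$breakeven_share[1]))
  expect_true(is.finite(tab$bcr_at_base_shift[1]))
  expect_true(tab$feasible[2])
})

test_that("unknown variation parameters are rejected", {
  expect_error(variation("cycleway_colour", 3), "unknown variation parameter")
})
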