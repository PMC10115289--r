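#' A one-way parameter variation
#'
#' @param parameter One of `"annual_mortality_rate"`, `"vsl"`,
#'   `"discount_rate"`, `"horizon_years"`, `"takeup_years"`,
#'   `"in_traffic_fraction"`, `"modal_shift"`, `"trip_length_km"`,
#'   `"trips_per_day"` (the last two rescale travel in both the pre and
#'   post states), `"post_trip_length_km"`, `"post_trips_per_day"` (post
#'   state only).
#' @param value Replacement value (numeric; a 3-vector for
#'   `modal_shift`).
#' @param label Human-readable description used in reports.
#' @return A `variation` list.
#' @export
variation <- function(parameter, value, label = NULL) {
  allowed <- c(
    "annual_mortality_rate", "vsl", "discount_rate", "horizon_years",
    "takeup_years", "in_traffic_fraction", "modal_shift",
    "trip_length_km", "trips_per_day",
    "post_trip_length_km", "post_trips_per_day"
  )
  if (!parameter %in% allowed) {
    stop("unknown variation parameter: ", parameter)
  }
  if (is.null(label)) {
    label <- paste(parameter, paste(signif(value, 6), collapse = "/"))
  }
  structure(list(parameter = parameter, value = value, label = label),
            class = "variation")
}

# Returns list(config = modified config, post_behaviour = behaviour for the
# post state or NULL when it equals the configured one).
apply_variation <- function(config, v) {
  stopifnot(inherits(config, "appraisal_config"), inherits(v, "variation"))
  post_behaviour <- NULL
  p <- v$parameter
  val <- v$value
  if (p == "annual_mortality_rate") {
    config$population$annual_mortality_rate <- val
  } else if (p == "vsl") {
    config$economics$vsl <- val
  } else if (p == "discount_rate") {
    config$economics$discount_rate <- val
  } else if (p == "horizon_years") {
    config$economics$horizon_years <- val
    if (config$economics$takeup_years > val) {
      config$economics$takeup_years <- val
    }
  } else if (p == "takeup_years") {
    config$economics$takeup_years <- val
  } else if (p == "in_traffic_fraction") {
    config$risks$in_traffic_fraction <- val
  } else if (p == "modal_shift") {
    ms <- config$risks$modal_shift
    ms[] <- val
    config$risks$modal_shift <- ms
  } else if (p == "trip_length_km") {
    config$behaviour$trip_length_km <- val
  } else if (p == "trips_per_day") {
    config$behaviour$trips_per_day <- val
  } else if (p == "post_trip_length_km") {
    post_behaviour <- config$behaviour
    post_behaviour$trip_length_km <- val
  } else if (p == "post_trips_per_day") {
    post_behaviour <- config$behaviour
    post_behaviour$trips_per_day <- val
  }
  list(config = config, post_behaviour = post_behaviour)
}

#' Evaluate one sensitivity variation
#'
#' Recomputes the appraisal under a single changed parameter, in two steps:
#' the BCR attained by the *base-case* break-even shift under the varied
#' parameter, and the new break-even requirement (shift from level 2)
#' under the varied parameter. Head counts are reported as the absolute
#' number of regular cyclists at break-even (including those already at
#' level 1) and as the difference from the base case.
#'
#' @param config [appraisal_config()], the base case.
#' @param base_shift [scenario_shift()], the base-case level-2 break-even
#'   shift.
#' @param v [variation()].
#' @param tolerance Solver tolerance on `|BCR - 1|`.
#' @return One-row data frame (`sensitivity_row`): `parameter`, `label`,
#'   `bcr_at_base_shift`, `breakeven_share`, `absolute_regular_cyclists`,
#'   `additional_vs_base`, `feasible`.
#' @export
run_variation <- function(config, base_shift, v, tolerance = 1e-6) {
  stopifnot(inherits(base_shift, "scenario_shift"))
  applied <- apply_variation(config, v)
  vc <- applied$config
  pb <- applied$post_behaviour

  baseline <- vc$population$baseline
  size <- vc$population$size
  post_base <- apply_shift(baseline, base_shift)
  bcr_fixed <- appraise(vc, post_base, post_behaviour = pb)$bcr

  base_absolute <- count_from_share(
    unclass(baseline)[1] + base_shift$shifted_share, size
  )

  be <- tryCatch(
    solve_breakeven(vc, source_level = 2L, tolerance = tolerance,
                    post_behaviour = pb),
    error = function(e) e
  )
  if (inherits(be, "error")) {
    row <- data.frame(
      parameter = v$parameter, label = v$label,
      bcr_at_base_shift = bcr_fixed,
      breakeven_share = NA_real_,
      absolute_regular_cyclists = NA_integer_,
      additional_vs_base = NA_integer_,
      feasible = FALSE,
      stringsAsFactors = FALSE
    )
  } else {
    absolute <- count_from_share(
      unclass(be$post)[1], size
    )
    row <- data.frame(
      parameter = v$parameter, label = v$label,
      bcr_at_base_shift = bcr_fixed,
      breakeven_share = be$scenario$shifted_share,
      absolute_regular_cyclists = absolute,
      additional_vs_base = as.integer(absolute - base_absolute),
      feasible = TRUE,
      stringsAsFactors = FALSE
    )
  }
  class(row) <- c("sensitivity_row", "data.frame")
  row
}

#' One-way deterministic sensitivity table
#'
#' Runs [run_variation()] for each variation in order, collecting rows into
#' one table. Per-row failures (for example an infeasible break-even under
#' the varied parameter) are recorded in the row rather than aborting the
#' table.
#'
#' @param config [appraisal_config()].
#' @param base_shift [scenario_shift()], the base-case level-2 break-even.
#' @param variations List of [variation()]s; see [default_variations()].
#' @param tolerance Solver tolerance.
#' @return A `sensitivity_table` data frame, one row per variation, input
#'   order preserved.
#' @export
sensitivity_table <- function(config, base_shift, variations,
                              tolerance = 1e-6) {
  stopifnot(length(variations) >= 1)
  rows <- lapply(variations, function(v) {
    run_variation(config, base_shift, v, tolerance = tolerance)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sensitivity_table", "data.frame")
  out
}

#' The standard one-way sensitivity grid
#'
#' The 20-variation grid used for the Coventry case study: target-age
#' cohorts (implemented as swapping the cohort's all-cause mortality
#' rate), VSL +/-20%, discount rate +/-1.5 percentage points, 5- and
#' 15-year horizons, +/-20% trip length and trips per day (both states,
#' then post state only), take-up times of 2/3/5 years, and cycling fully
#' in traffic.
#'
#' @param config [appraisal_config()] supplying the base values the
#'   relative probes are built from.
#' @param mortality_20_44,mortality_45_64 Annual all-cause mortality rates
#'   for the 20-44 and 45-64 cohorts (defaults are England-scale
#'   order-of-magnitude rates).
#' @return List of [variation()]s.
#' @export
default_variations <- function(config, mortality_20_44 = 0.0009,
                               mortality_45_64 = 0.0052) {
  vsl <- config$economics$vsl
  dr <- config$economics$discount_rate
  len <- config$behaviour$trip_length_km
  trips <- config$behaviour$trips_per_day
  list(
    variation("annual_mortality_rate", mortality_20_44, "Age group: 20-44 years"),
    variation("annual_mortality_rate", mortality_45_64, "Age group: 45-64 years"),
    variation("vsl", 0.8 * vsl, sprintf("VSL $%s", format(0.8 * vsl, big.mark = ","))),
    variation("vsl", 1.2 * vsl, sprintf("VSL $%s", format(1.2 * vsl, big.mark = ","))),
    variation("discount_rate", dr + 0.015, sprintf("Discount rate %.2f%%", 100 * (dr + 0.015))),
    variation("discount_rate", dr - 0.015, sprintf("Discount rate %.2f%%", 100 * (dr - 0.015))),
    variation("horizon_years", 5L, "Time horizon 5 years"),
    variation("horizon_years", 15L, "Time horizon 15 years"),
    variation("trip_length_km", 0.8 * len, sprintf("Baseline trip length %.2f km", 0.8 * len)),
    variation("trip_length_km", 1.2 * len, sprintf("Baseline trip length %.2f km", 1.2 * len)),
    variation("trips_per_day", 0.8 * trips, sprintf("Baseline trips per day %.1f", 0.8 * trips)),
    variation("trips_per_day", 1.2 * trips, sprintf("Baseline trips per day %.1f", 1.2 * trips)),
    variation("post_trip_length_km", 0.8 * len, sprintf("Post trip length %.2f km", 0.8 * len)),
    variation("post_trip_length_km", 1.2 * len, sprintf("Post trip length %.2f km", 1.2 * len)),
    variation("post_trips_per_day", 0.8 * trips, sprintf("Post trips per day %.1f", 0.8 * trips)),
    variation("post_trips_per_day", 1.2 * trips, sprintf("Post trips per day %.1f", 1.2 * trips)),
    variation("takeup_years", 2, "Take-up time 2 years"),
    variation("takeup_years", 3, "Take-up time 3 years"),
    variation("takeup_years", 5, "Take-up time 5 years"),
    variation("in_traffic_fraction", 1.0, "Proportion in traffic 100%")
  )
}
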