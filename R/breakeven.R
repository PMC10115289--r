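#' A shift of population share into regular cycling
#'
#' @param source_level Level the shifted people come from (2-5).
#' @param shifted_share Fraction of the *total* population moved from
#'   `source_level` to level 1 (regular cycling).
#' @return A `scenario_shift` list.
#' @export
scenario_shift <- function(source_level, shifted_share) {
  stopifnot(
    length(source_level) == 1, source_level %in% 2:5,
    is.numeric(shifted_share), length(shifted_share) == 1, shifted_share >= 0
  )
  structure(
    list(source_level = as.integer(source_level),
         shifted_share = shifted_share),
    class = "scenario_shift"
  )
}

#' Apply a share shift to a cycling distribution
#'
#' Moves `shifted_share` of the population from the source level to level 1,
#' leaving all other levels untouched. Total share mass is conserved
#' exactly.
#'
#' @param baseline [cycling_distribution()].
#' @param shift [scenario_shift()]; `shifted_share` must not exceed the
#'   baseline share of the source level.
#' @return The post-shift [cycling_distribution()].
#' @examples
#' base <- cycling_distribution(c(0.01, 0.09, 0.15, 0.25, 0.50))
#' apply_shift(base, scenario_shift(2, 0.01242)) # level 1 -> 2.242%
#' @export
apply_shift <- function(baseline, shift) {
  stopifnot(inherits(baseline, "cycling_distribution"),
            inherits(shift, "scenario_shift"))
  src <- shift$source_level
  if (shift$shifted_share > unclass(baseline)[src] + 1e-12) {
    stop(sprintf(
      "infeasible shift: share %.6g exceeds baseline share %.6g of level %d",
      shift$shifted_share, unclass(baseline)[src], src
    ))
  }
  out <- unclass(baseline)
  out[1] <- out[1] + shift$shifted_share
  out[src] <- out[src] - shift$shifted_share
  cycling_distribution(out)
}

# Bisection for benefit(share) = cost on [0, upper]; benefit_fn returns a
# BCR. Separated from the appraisal engine so it can be exercised against
# closed-form stubs.
bisect_breakeven <- function(bcr_fn, upper, tolerance = 1e-6,
                             max_iter = 200L) {
  stopifnot(upper > 0, tolerance > 0)
  f0 <- bcr_fn(0)
  if (f0 >= 1) stop("already cost-saving: BCR >= 1 at zero shift")
  f_up <- bcr_fn(upper)
  if (f_up < 1) stop("infeasible: source level exhausted (BCR < 1 at full shift)")
  lo <- 0; hi <- upper
  flo <- f0
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    fm <- bcr_fn(mid)
    if (fm < flo - 1e-12) {
      stop("benefit is not monotone increasing in the shifted share")
    }
    if (abs(fm - 1) <= tolerance) {
      return(list(share = mid, bcr = fm, iterations = i))
    }
    if (fm < 1) {
      lo <- mid; flo <- fm
    } else {
      hi <- mid
    }
  }
  stop("bisection failed to reach tolerance within max_iter iterations")
}

#' Solve for the break-even shift into regular cycling
#'
#' Finds the fraction of the population that must move from a given
#' frequency level to level 1 (regular cycling) for the discounted
#' four-domain benefit to exactly offset the intervention cost
#' (benefit-cost ratio 1:1). The benefit is monotone increasing in the
#' shifted share (asserted during the search), so bisection on
#' `[0, baseline source share]` is guaranteed to converge; an initial
#' probe at the share that lifts regular cycling to 5% of the population
#' (a 400% increase on the Coventry baseline) narrows the bracket when it
#' already over-shoots break-even.
#'
#' @param config [appraisal_config()] with BCR below 1 at zero shift.
#' @param source_level Level 2-5 the new regular cyclists come from.
#' @param tolerance Convergence tolerance on `|BCR - 1|`.
#' @param post_behaviour Optional post-state [travel_behaviour()] (see
#'   [appraise()]).
#' @return A `breakeven_result`: `scenario` ([scenario_shift()]),
#'   `new_regular_cyclists` (rounded head count), `post` distribution,
#'   `bcr_achieved`, `per_km_cyclists` and `per_cyclist_annual_value`
#'   ($/person/year = cost / (count x horizon)).
#' @examples
#' solve_breakeven(coventry_fixture(), source_level = 2)
#' @export
solve_breakeven <- function(config, source_level, tolerance = 1e-6,
                            post_behaviour = NULL) {
  violations <- validate_config(config)
  if (length(violations) > 0) {
    stop("invalid config:\n  ", paste(violations, collapse = "\n  "))
  }
  stopifnot(source_level %in% 2:5, tolerance > 0)
  baseline <- config$population$baseline
  upper <- unclass(baseline)[source_level]
  if (upper <= 0) stop("infeasible: source level holds no population")

  bcr_at <- function(s) {
    appraise(config, apply_shift(baseline, scenario_shift(source_level, s)),
             post_behaviour = post_behaviour)$bcr
  }

  # probe: shift that takes level 1 to 5% of the population, if feasible
  probe <- 0.05 - unclass(baseline)[1]
  use_upper <- upper
  if (probe > 0 && probe < upper && bcr_at(probe) >= 1) {
    if (bcr_at(upper) < 1) {
      stop("benefit is not monotone increasing in the shifted share")
    }
    use_upper <- probe
  }
  sol <- bisect_breakeven(bcr_at, use_upper, tolerance = tolerance)

  shift <- scenario_shift(source_level, sol$share)
  count <- count_from_share(sol$share, config$population$size)
  structure(
    list(
      scenario = shift,
      new_regular_cyclists = count,
      post = apply_shift(baseline, shift),
      bcr_achieved = sol$bcr,
      per_km_cyclists = count / config$intervention$cycleway_length_km,
      per_cyclist_annual_value =
        config$intervention$cost_intl_dollars /
          (count * config$economics$horizon_years),
      iterations = sol$iterations
    ),
    class = "breakeven_result"
  )
}

#' Construct a break-even scenario record directly
#'
#' Builds a `breakeven_result` from a known shifted share (for example one
#' taken from a published scenario table) without running the solver, so
#' that summary statistics can be computed from reported shares.
#'
#' @param config [appraisal_config()].
#' @param source_level Source level 2-5.
#' @param shifted_share Fraction of the population shifted to level 1.
#' @param bcr_achieved BCR attained at that shift (default 1, the
#'   break-even definition).
#' @return A `breakeven_result` (see [solve_breakeven()]).
#' @export
breakeven_result <- function(config, source_level, shifted_share,
                             bcr_achieved = 1) {
  shift <- scenario_shift(source_level, shifted_share)
  count <- count_from_share(shifted_share, config$population$size)
  structure(
    list(
      scenario = shift,
      new_regular_cyclists = count,
      post = apply_shift(config$population$baseline, shift),
      bcr_achieved = bcr_achieved,
      per_km_cyclists = count / config$intervention$cycleway_length_km,
      per_cyclist_annual_value =
        config$intervention$cost_intl_dollars /
          (count * config$economics$horizon_years),
      iterations = 0L
    ),
    class = "breakeven_result"
  )
}

#' Summarise break-even scenarios across source levels
#'
#' Averages the per-scenario break-even requirements and derives the
#' headline statistics: mean new regular cyclists (rounded half-up), mean
#' shifted share, cyclists required per km of cycleway, and the annual
#' value each additional regular cyclist must generate
#' (`cost / (mean count x horizon)`), also converted to local currency via
#' purchasing power parity.
#'
#' @param results List of `breakeven_result`s (typically one per source
#'   level 2-5).
#' @param intervention [intervention_spec()].
#' @param econ [economic_params()].
#' @return A `breakeven_summary` list.
#' @export
summarize_breakeven <- function(results, intervention, econ) {
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, logical(1), "breakeven_result")))
  counts <- vapply(results, function(r) as.numeric(r$new_regular_cyclists),
                   numeric(1))
  shares <- vapply(results, function(r) r$scenario$shifted_share, numeric(1))
  mean_count <- round_half_up(mean(counts))
  per_cyclist <- intervention$cost_intl_dollars /
    (mean_count * econ$horizon_years)
  structure(
    list(
      n_scenarios = length(results),
      mean_new_regular_cyclists = as.integer(mean_count),
      mean_shifted_share = mean(shares),
      cyclists_per_km = mean_count / intervention$cycleway_length_km,
      per_cyclist_annual_value = per_cyclist,
      per_cyclist_annual_value_local = ppp_convert(per_cyclist, econ),
      horizon_years = econ$horizon_years,
      cost_intl_dollars = intervention$cost_intl_dollars
    ),
    class = "breakeven_summary"
  )
}

#' Convert international dollars to local currency
#'
#' Purchasing-power-parity conversion: `amount * ppp_coefficient`.
#'
#' @param amount Amount in international $.
#' @param econ [economic_params()] carrying the PPP coefficient.
#' @return Amount in local currency (GBP for the Coventry fixture).
#' @examples
#' ppp_convert(798, coventry_fixture()$economics) # ~533
#' @export
ppp_convert <- function(amount, econ) {
  stopifnot(econ$ppp_coefficient > 0)
  amount * econ$ppp_coefficient
}

#' @export
print.breakeven_result <- function(x, ...) {
  cat(sprintf(
    "Break-even shift from level %d: %.4f%% of the population (%s new regular cyclists)\n",
    x$scenario$source_level, 100 * x$scenario$shifted_share,
    format(x$new_regular_cyclists, big.mark = ",")
  ))
  cat(sprintf("  BCR achieved %.6f; %.1f cyclists/km; $%.0f per cyclist per year\n",
              x$bcr_achieved, x$per_km_cyclists, x$per_cyclist_annual_value))
  invisible(x)
}

#' @export
print.breakeven_summary <- function(x, ...) {
  cat(sprintf("Across %d scenarios: mean %s new regular cyclists (%.3f%% of population)\n",
              x$n_scenarios, format(x$mean_new_regular_cyclists, big.mark = ","),
              100 * x$mean_shifted_share))
  cat(sprintf("  %.0f cyclists per km; $%.0f (local %.0f) generated per cyclist per year over %d years\n",
              x$cyclists_per_km, x$per_cyclist_annual_value,
              x$per_cyclist_annual_value_local, x$horizon_years))
  invisible(x)
}
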