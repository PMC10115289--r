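#' Mortality relative risk as a function of cycling volume
#'
#' Linear dose-response in cycling volume, capped at `max_volume_ratio`
#' times the reference volume: `1 - (1 - rr_reference) *
#' min(volume / reference, max_volume_ratio)`. At zero volume the relative
#' risk is 1; at the reference volume it equals `rr_reference`; beyond the
#' cap no further risk reduction accrues.
#'
#' @param volume_km_per_year Cycling volume (km/year), vectorised,
#'   nonnegative.
#' @param risks [risk_params()].
#' @return Relative risk in `(0, 1]`.
#' @examples
#' rk <- coventry_fixture()$risks
#' mortality_rr(0, rk)                                  # 1
#' mortality_rr(rk$reference_volume_km_per_year, rk)    # rr_reference
#' @export
mortality_rr <- function(volume_km_per_year, risks) {
  if (any(volume_km_per_year < 0)) {
    stop("volume_km_per_year must be nonnegative")
  }
  ratio <- pmin(volume_km_per_year / risks$reference_volume_km_per_year,
                risks$max_volume_ratio)
  1 - (1 - risks$rr_reference) * ratio
}

#' Physical-activity mortality impact of a distribution change
#'
#' Expected all-cause deaths per year in the post-intervention steady state
#' minus the baseline steady state, attributing to each frequency level the
#' relative risk implied by its annual cycling volume. Negative values are
#' deaths averted.
#'
#' @param baseline,post [cycling_distribution()]s before and after.
#' @param pop [population_spec()].
#' @param behaviour [travel_behaviour()].
#' @param risks [risk_params()].
#' @param levels [frequency_levels()].
#' @param post_behaviour Optional [travel_behaviour()] for the post state
#'   (defaults to `behaviour`); used by sensitivity analyses that vary only
#'   post-intervention travel.
#' @return Deaths per year (negative = averted).
#' @export
pa_deaths <- function(baseline, post, pop, behaviour, risks,
                      levels = frequency_levels(), post_behaviour = NULL) {
  if (is.null(post_behaviour)) post_behaviour <- behaviour
  rr_base <- mortality_rr(annual_km(1:5, behaviour, levels), risks)
  rr_post <- mortality_rr(annual_km(1:5, post_behaviour, levels), risks)
  pop$size * pop$annual_mortality_rate *
    sum(unclass(post) * rr_post - unclass(baseline) * rr_base)
}

#' Air-pollution mortality impact of additional cycling
#'
#' Additional cycling means extra hours breathing elevated particulate
#' concentrations. The excess inhaled dose is expressed as an
#' annual-equivalent PM2.5 increment: ambient concentration times
#' `(ventilation_ratio - 1)` times the fraction of cycling done in
#' traffic, applied over the cycling hours implied by the shifted
#' kilometres. Extra deaths are then person-years of exposure times the
#' exposure-response slope times baseline mortality. The result is always
#' a disbenefit (nonnegative deaths) for a nonnegative shift.
#'
#' @param shift_km_per_year Additional population cycling volume
#'   (person-km/year), nonnegative.
#' @param risks [risk_params()].
#' @param pop [population_spec()].
#' @return Extra deaths per year (>= 0).
#' @export
ap_deaths <- function(shift_km_per_year, risks, pop) {
  if (any(shift_km_per_year < 0)) {
    stop("shift_km_per_year must be nonnegative")
  }
  hours <- shift_km_per_year / risks$cycling_speed_kmh
  person_years <- hours / 8760
  excess_conc <- risks$pm25_ugm3 * (risks$ventilation_ratio - 1) *
    risks$in_traffic_fraction
  person_years * excess_conc * risks$er_slope_per_ugm3 *
    pop$annual_mortality_rate
}

#' Crash mortality impact of additional cycling
#'
#' @param extra_km_per_year Additional population cycling volume
#'   (person-km/year), nonnegative.
#' @param risks [risk_params()].
#' @return Extra cyclist deaths per year (>= 0).
#' @examples
#' rk <- coventry_fixture()$risks
#' crash_deaths(1e8, rk) # == rk$crash_fatalities_per_100M_km
#' @export
crash_deaths <- function(extra_km_per_year, risks) {
  if (any(extra_km_per_year < 0)) {
    stop("extra_km_per_year must be nonnegative")
  }
  extra_km_per_year * risks$crash_fatalities_per_100M_km / 1e8
}

#' Carbon impact of additional cycling
#'
#' New cycling kilometres replace other modes according to the modal-shift
#' shares; each replaced mode saves its CO2 emission factor. Walking
#' contributes nothing.
#'
#' @param extra_cycling_km_per_year Additional population cycling volume
#'   (person-km/year), nonnegative.
#' @param risks [risk_params()].
#' @return Tonnes of CO2 per year; negative = emissions saved.
#' @export
carbon_tonnes <- function(extra_cycling_km_per_year, risks) {
  if (any(extra_cycling_km_per_year < 0)) {
    stop("extra_cycling_km_per_year must be nonnegative")
  }
  g_per_km <- sum(risks$modal_shift * risks$emission_factor_g_per_km)
  -extra_cycling_km_per_year * g_per_km / 1e6
}

#' Present value of a benefit stream with demand take-up
#'
#' Benefits start after construction, ramp up linearly until cycling demand
#' reaches its steady state at `takeup_years`, and are discounted annually:
#' `sum over t = 1..horizon of min(t / takeup, 1) * value * (1 + r)^-t`
#' (end-of-year convention; `discount_convention = "mid"` uses
#' `(1 + r)^-(t - 1/2)`).
#'
#' @param annual_value Steady-state value per year ($/year).
#' @param econ [economic_params()].
#' @return Present value over the horizon ($).
#' @examples
#' eco <- economic_params(4260000, 0.05, 10, 1, 0.667865, 130)
#' discounted_stream(100, eco) # 772.17
#' @export
discounted_stream <- function(annual_value, econ) {
  t <- seq_len(econ$horizon_years)
  uptake <- pmin(t / econ$takeup_years, 1)
  lag <- if (identical(econ$discount_convention, "mid")) 0.5 else 0
  disc <- (1 + econ$discount_rate)^(-(t - lag))
  annual_value * sum(uptake * disc)
}

#' Four-domain appraisal of a change in cycling levels
#'
#' The core comparative risk assessment: compares the baseline steady
#' state against a post-intervention cycling distribution across four
#' domains — physical-activity mortality, air-pollution exposure, crash
#' risk and carbon emissions. Mortality impacts are monetised with the
#' value of a statistical life, carbon with the damage cost per tonne;
#' each domain's annual value is discounted over the horizon with the
#' take-up ramp, and the benefit-cost ratio is taken against the
#' intervention cost.
#'
#' @param config [appraisal_config()]; must pass [validate_config()].
#' @param post [cycling_distribution()] after the intervention.
#' @param post_behaviour Optional [travel_behaviour()] for the post state
#'   (defaults to the configured behaviour).
#' @return An `appraisal_result`: list with `impacts` (data frame with one
#'   row per domain: `annual_deaths_delta`, `annual_tonnes_co2_delta`,
#'   `discounted_value`), `total_benefit`, `bcr`, `cost`.
#' @examples
#' cfg <- coventry_fixture()
#' post <- apply_shift(cfg$population$baseline, scenario_shift(2, 0.04))
#' appraise(cfg, post)
#' @export
appraise <- function(config, post, post_behaviour = NULL) {
  violations <- validate_config(config)
  if (length(violations) > 0) {
    stop("invalid config:\n  ", paste(violations, collapse = "\n  "))
  }
  stopifnot(inherits(post, "cycling_distribution"))
  sh <- unclass(post)
  if (any(sh < 0) || abs(sum(sh) - 1) > 1e-9) {
    stop("invalid post distribution: shares must be nonnegative and sum to 1")
  }
  if (is.null(post_behaviour)) post_behaviour <- config$behaviour

  pop <- config$population
  rk <- config$risks
  eco <- config$economics
  lv <- config$levels

  pa <- pa_deaths(pop$baseline, post, pop, config$behaviour, rk,
                  levels = lv, post_behaviour = post_behaviour)

  km_base <- sum(unclass(pop$baseline) * annual_km(1:5, config$behaviour, lv))
  km_post <- sum(sh * annual_km(1:5, post_behaviour, lv))
  delta_km <- pop$size * (km_post - km_base)
  sgn <- sign(delta_km)

  ap <- sgn * ap_deaths(abs(delta_km), rk, pop)
  crash <- sgn * crash_deaths(abs(delta_km), rk)
  co2 <- sgn * carbon_tonnes(abs(delta_km), rk)

  # deaths averted (negative delta) -> positive value; CO2 saved likewise
  values <- c(
    physical_activity = discounted_stream(-pa * eco$vsl, eco),
    air_pollution = discounted_stream(-ap * eco$vsl, eco),
    crash_risk = discounted_stream(-crash * eco$vsl, eco),
    carbon = discounted_stream(-co2 * eco$carbon_damage_cost, eco)
  )
  impacts <- data.frame(
    domain = c("physical_activity", "air_pollution", "crash_risk", "carbon"),
    annual_deaths_delta = c(pa, ap, crash, 0),
    annual_tonnes_co2_delta = c(0, 0, 0, co2),
    discounted_value = as.numeric(values),
    row.names = NULL
  )
  total <- sum(impacts$discounted_value)
  structure(
    list(
      impacts = impacts,
      total_benefit = total,
      bcr = total / config$intervention$cost_intl_dollars,
      cost = config$intervention$cost_intl_dollars
    ),
    class = "appraisal_result"
  )
}

#' @export
print.appraisal_result <- function(x, ...) {
  cat("Four-domain appraisal (international $)\n")
  imp <- x$impacts
  for (i in seq_len(nrow(imp))) {
    qty <- if (imp$domain[i] == "carbon") {
      sprintf("%+.2f tCO2/yr", imp$annual_tonnes_co2_delta[i])
    } else {
      sprintf("%+.4f deaths/yr", imp$annual_deaths_delta[i])
    }
    cat(sprintf("  %-18s %18s   value $%s\n", imp$domain[i], qty,
                format(round(imp$discounted_value[i]), big.mark = ",")))
  }
  cat(sprintf("  total benefit $%s over the horizon; BCR %.3f against cost $%s\n",
              format(round(x$total_benefit), big.mark = ","), x$bcr,
              format(round(x$cost), big.mark = ",")))
  invisible(x)
}
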