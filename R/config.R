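#' Cycling-frequency levels
#'
#' The appraisal classifies the population into five cycling-frequency
#' levels, from level 1 ("daily or almost daily", the *regular cyclist*)
#' down to level 5 ("never"). Survey categories are ranges of days, so each
#' level must be mapped to a representative number of cycling days per
#' year; the defaults are category midpoints (6/week, 2/week, 2/month,
#' 6/year, 0) and can be overridden.
#'
#' @param days_per_year Numeric vector of length 5: representative cycling
#'   days per year for levels 1-5. Must be strictly decreasing and level 5
#'   must be exactly 0.
#' @return A `frequency_levels` data frame with columns `index`, `label`
#'   and `cycling_days_per_year`.
#' @examples
#' frequency_levels()
#' @export
frequency_levels <- function(days_per_year = c(312, 104, 24, 6, 0)) {
  stopifnot(is.numeric(days_per_year), length(days_per_year) == 5)
  if (any(days_per_year < 0)) {
    stop("cycling_days_per_year must be nonnegative")
  }
  if (any(diff(days_per_year) >= 0)) {
    stop("cycling_days_per_year must strictly decrease from level 1 to level 5")
  }
  if (days_per_year[5] != 0) {
    stop("level 5 ('never') must have exactly 0 cycling days per year")
  }
  structure(
    data.frame(
      index = 1:5,
      label = c(
        "daily or almost daily", "one to three days a week",
        "one to three days a month", "less than once a month", "never"
      ),
      cycling_days_per_year = as.numeric(days_per_year)
    ),
    class = c("frequency_levels", "data.frame")
  )
}

#' Distribution of a population over the five cycling levels
#'
#' @param shares Numeric vector of length 5: the proportion of the
#'   population at each frequency level (level 1 first). A valid
#'   distribution has shares in `[0, 1]` summing to 1; the constructor only
#'   enforces shape so that deliberately broken objects can be fed to
#'   [validate_config()].
#' @return A `cycling_distribution` (named numeric vector).
#' @examples
#' cycling_distribution(c(0.01, 0.09, 0.15, 0.25, 0.50))
#' @export
cycling_distribution <- function(shares) {
  stopifnot(is.numeric(shares), length(shares) == 5)
  structure(
    as.numeric(shares),
    names = paste0("level", 1:5),
    class = "cycling_distribution"
  )
}

#' Population under appraisal
#'
#' @param size Adult population of the intervention catchment area (persons).
#' @param age_band Integer pair, the age range the mortality rate refers to.
#' @param annual_mortality_rate All-cause deaths per person-year in the
#'   population, in `(0, 1)`.
#' @param baseline [cycling_distribution()] before the intervention.
#' @return A `population_spec` list.
#' @export
population_spec <- function(size, age_band, annual_mortality_rate, baseline) {
  stopifnot(
    is.numeric(size), length(size) == 1,
    is.numeric(age_band), length(age_band) == 2,
    is.numeric(annual_mortality_rate), length(annual_mortality_rate) == 1,
    inherits(baseline, "cycling_distribution")
  )
  structure(
    list(
      size = size, age_band = as.integer(age_band),
      annual_mortality_rate = annual_mortality_rate, baseline = baseline
    ),
    class = "population_spec"
  )
}

#' Travel behaviour on a cycling day
#'
#' @param trips_per_day Trips made on a day with any cycling.
#' @param trip_length_km Length of one trip (km).
#' @return A `travel_behaviour` list.
#' @export
travel_behaviour <- function(trips_per_day, trip_length_km) {
  stopifnot(
    is.numeric(trips_per_day), length(trips_per_day) == 1,
    is.numeric(trip_length_km), length(trip_length_km) == 1
  )
  structure(
    list(trips_per_day = trips_per_day, trip_length_km = trip_length_km),
    class = "travel_behaviour"
  )
}

#' Economic valuation parameters
#'
#' @param vsl Value of a statistical life (international $ per death averted).
#' @param discount_rate Annual discount rate (e.g. 0.05).
#' @param horizon_years Appraisal horizon (whole years, >= 1).
#' @param takeup_years Years after construction until cycling demand reaches
#'   its steady state; benefits ramp up linearly over this period. Must not
#'   exceed the horizon.
#' @param ppp_coefficient Purchasing-power-parity multiplier converting
#'   international $ to local currency (here GBP).
#' @param carbon_damage_cost Monetised global damage of one tonne of CO2
#'   (international $/tonne).
#' @param discount_convention `"end"` (default) discounts each year's
#'   benefit at the end of the year; `"mid"` at mid-year.
#' @return An `economic_params` list.
#' @export
economic_params <- function(vsl, discount_rate, horizon_years, takeup_years,
                            ppp_coefficient, carbon_damage_cost,
                            discount_convention = c("end", "mid")) {
  discount_convention <- match.arg(discount_convention)
  stopifnot(
    is.numeric(vsl), is.numeric(discount_rate), is.numeric(horizon_years),
    is.numeric(takeup_years), is.numeric(ppp_coefficient),
    is.numeric(carbon_damage_cost)
  )
  structure(
    list(
      vsl = vsl, discount_rate = discount_rate,
      horizon_years = horizon_years, takeup_years = takeup_years,
      ppp_coefficient = ppp_coefficient,
      carbon_damage_cost = carbon_damage_cost,
      discount_convention = discount_convention
    ),
    class = "economic_params"
  )
}

#' Risk and exposure parameters
#'
#' Parameters of the four-domain comparative risk assessment: the
#' mortality dose-response for cycling volume, the air-pollution exposure
#' model, the crash fatality rate, and the modal-shift/emission assumptions
#' behind the carbon domain.
#'
#' @param rr_reference Mortality relative risk for a person cycling
#'   `reference_volume_km_per_year`, in `(0, 1]` (e.g. 0.90 = 10% lower
#'   all-cause mortality).
#' @param reference_volume_km_per_year Cycling volume at which
#'   `rr_reference` applies (km/year).
#' @param max_volume_ratio Cap on `volume / reference` in the linear
#'   dose-response (e.g. 4.5 caps the risk reduction at 45% when
#'   `rr_reference = 0.90`).
#' @param pm25_ugm3 Ambient fine-particulate concentration (ug/m3).
#' @param ventilation_ratio Ratio of inhaled dose while cycling to dose at
#'   rest (>= 1).
#' @param er_slope_per_ugm3 Proportional increase in all-cause mortality per
#'   ug/m3 of annual-equivalent PM2.5 dose.
#' @param in_traffic_fraction Fraction of cycling done in traffic, i.e.
#'   exposed to elevated pollution, in `[0, 1]`.
#' @param crash_fatalities_per_100M_km Cyclist deaths per 100 million km
#'   cycled.
#' @param cycling_speed_kmh Average cycling speed (km/h), used to convert
#'   cycled kilometres into exposure hours.
#' @param modal_shift Named shares (`public_transport`, `car`, `walking`)
#'   apportioning new cycling km to the modes they replace; must sum to 1.
#' @param emission_factor_g_per_km Named CO2 emission factors (g/km) for the
#'   same three modes; walking must be 0.
#' @return A `risk_params` list.
#' @export
risk_params <- function(rr_reference, reference_volume_km_per_year,
                        max_volume_ratio, pm25_ugm3, ventilation_ratio,
                        er_slope_per_ugm3, in_traffic_fraction,
                        crash_fatalities_per_100M_km, cycling_speed_kmh,
                        modal_shift, emission_factor_g_per_km) {
  stopifnot(
    is.numeric(modal_shift), length(modal_shift) == 3,
    is.numeric(emission_factor_g_per_km), length(emission_factor_g_per_km) == 3
  )
  modes <- c("public_transport", "car", "walking")
  if (is.null(names(modal_shift))) names(modal_shift) <- modes
  if (is.null(names(emission_factor_g_per_km))) {
    names(emission_factor_g_per_km) <- modes
  }
  structure(
    list(
      rr_reference = rr_reference,
      reference_volume_km_per_year = reference_volume_km_per_year,
      max_volume_ratio = max_volume_ratio,
      pm25_ugm3 = pm25_ugm3,
      ventilation_ratio = ventilation_ratio,
      er_slope_per_ugm3 = er_slope_per_ugm3,
      in_traffic_fraction = in_traffic_fraction,
      crash_fatalities_per_100M_km = crash_fatalities_per_100M_km,
      cycling_speed_kmh = cycling_speed_kmh,
      modal_shift = modal_shift[modes],
      emission_factor_g_per_km = emission_factor_g_per_km[modes]
    ),
    class = "risk_params"
  )
}

#' Intervention being appraised
#'
#' @param cost_intl_dollars Construction cost (international $).
#' @param cycleway_length_km Length of the new cycleway (km).
#' @return An `intervention_spec` list.
#' @export
intervention_spec <- function(cost_intl_dollars, cycleway_length_km) {
  stopifnot(is.numeric(cost_intl_dollars), is.numeric(cycleway_length_km))
  structure(
    list(
      cost_intl_dollars = cost_intl_dollars,
      cycleway_length_km = cycleway_length_km
    ),
    class = "intervention_spec"
  )
}

#' Full appraisal configuration
#'
#' Bundles everything one appraisal run needs: the population and its
#' baseline cycling distribution, travel behaviour, economic parameters,
#' risk parameters and the intervention. Use [validate_config()] to check
#' all invariants and [coventry_fixture()] for a ready-made base case.
#'
#' @param population [population_spec()].
#' @param behaviour [travel_behaviour()].
#' @param economics [economic_params()].
#' @param risks [risk_params()].
#' @param intervention [intervention_spec()].
#' @param levels [frequency_levels()] mapping the five frequency categories
#'   to cycling days per year.
#' @return An `appraisal_config` list.
#' @export
appraisal_config <- function(population, behaviour, economics, risks,
                             intervention, levels = frequency_levels()) {
  stopifnot(
    inherits(population, "population_spec"),
    inherits(behaviour, "travel_behaviour"),
    inherits(economics, "economic_params"),
    inherits(risks, "risk_params"),
    inherits(intervention, "intervention_spec"),
    inherits(levels, "frequency_levels")
  )
  structure(
    list(
      population = population, behaviour = behaviour, economics = economics,
      risks = risks, intervention = intervention, levels = levels
    ),
    class = "appraisal_config"
  )
}

#' Validate an appraisal configuration
#'
#' Checks every domain invariant and reports all violations at once rather
#' than stopping at the first. Each message names the offending field and
#' the rule broken.
#'
#' @param config An [appraisal_config()].
#' @return Character vector of violation messages; `character(0)` if the
#'   configuration is valid.
#' @examples
#' validate_config(coventry_fixture()) # character(0)
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "appraisal_config"))
  v <- character()
  chk <- function(ok, msg) {
    if (!isTRUE(ok)) v <<- c(v, msg)
    invisible(NULL)
  }

  pop <- config$population
  chk(pop$size > 0 && pop$size == floor(pop$size),
      "population.size: must be a positive integer")
  chk(pop$annual_mortality_rate > 0 && pop$annual_mortality_rate < 1,
      "population.annual_mortality_rate: must lie in (0, 1)")
  chk(pop$age_band[1] < pop$age_band[2],
      "population.age_band: lower bound must be below upper bound")
  sh <- unclass(pop$baseline)
  chk(all(sh >= 0) && all(sh <= 1),
      "population.baseline: each share must lie in [0, 1]")
  chk(abs(sum(sh) - 1) <= 1e-9,
      sprintf("population.baseline: shares sum != 1 (got %.6g)", sum(sh)))

  beh <- config$behaviour
  chk(beh$trips_per_day > 0, "behaviour.trips_per_day: must be > 0")
  chk(beh$trip_length_km > 0, "behaviour.trip_length_km: must be > 0")

  eco <- config$economics
  chk(eco$vsl > 0, "economics.vsl: must be > 0")
  chk(eco$discount_rate >= 0, "economics.discount_rate: must be >= 0")
  chk(eco$horizon_years >= 1 && eco$horizon_years == floor(eco$horizon_years),
      "economics.horizon_years: must be an integer >= 1")
  chk(eco$takeup_years > 0, "economics.takeup_years: must be > 0")
  chk(eco$takeup_years <= eco$horizon_years,
      "economics.takeup_years: must not exceed horizon_years")
  chk(eco$ppp_coefficient > 0, "economics.ppp_coefficient: must be > 0")
  chk(eco$carbon_damage_cost > 0, "economics.carbon_damage_cost: must be > 0")

  rk <- config$risks
  chk(rk$rr_reference > 0 && rk$rr_reference <= 1,
      "risks.rr_reference: must lie in (0, 1]")
  chk(rk$reference_volume_km_per_year > 0,
      "risks.reference_volume_km_per_year: must be > 0")
  chk(rk$max_volume_ratio > 0, "risks.max_volume_ratio: must be > 0")
  chk(rk$pm25_ugm3 >= 0, "risks.pm25_ugm3: must be >= 0")
  chk(rk$ventilation_ratio >= 1, "risks.ventilation_ratio: must be >= 1")
  chk(rk$er_slope_per_ugm3 >= 0, "risks.er_slope_per_ugm3: must be >= 0")
  chk(rk$in_traffic_fraction >= 0 && rk$in_traffic_fraction <= 1,
      "risks.in_traffic_fraction: must lie in [0, 1]")
  chk(rk$crash_fatalities_per_100M_km >= 0,
      "risks.crash_fatalities_per_100M_km: must be >= 0")
  chk(rk$cycling_speed_kmh > 0, "risks.cycling_speed_kmh: must be > 0")
  chk(all(rk$modal_shift >= 0),
      "risks.modal_shift: shares must be nonnegative")
  chk(abs(sum(rk$modal_shift) - 1) <= 1e-9,
      sprintf("risks.modal_shift: modal shares sum != 1 (got %.6g)",
              sum(rk$modal_shift)))
  chk(all(rk$emission_factor_g_per_km >= 0),
      "risks.emission_factor_g_per_km: factors must be nonnegative")
  chk(rk$emission_factor_g_per_km[["walking"]] == 0,
      "risks.emission_factor_g_per_km: walking must be 0")

  int <- config$intervention
  chk(int$cost_intl_dollars > 0, "intervention.cost_intl_dollars: must be > 0")
  chk(int$cycleway_length_km > 0,
      "intervention.cycleway_length_km: must be > 0")

  lv <- config$levels
  chk(all(diff(lv$cycling_days_per_year) < 0),
      "levels.cycling_days_per_year: must strictly decrease with level index")
  chk(lv$cycling_days_per_year[5] == 0,
      "levels.cycling_days_per_year: level 5 must be 0")

  v
}

#' Annual cycling volume of one person at a frequency level
#'
#' Kilometres cycled per year by a person at a given frequency level:
#' `cycling_days_per_year * trips_per_day * trip_length_km`. The result
#' depends on trips and trip length only through their product, so a 20%
#' change in either is equivalent.
#'
#' @param level Integer level index 1-5 (vectorised).
#' @param behaviour [travel_behaviour()].
#' @param levels [frequency_levels()] mapping levels to days per year.
#' @return Kilometres per person per year.
#' @examples
#' annual_km(1, travel_behaviour(2, 4.1)) # 312 * 2 * 4.1 = 2558.4
#' annual_km(5, travel_behaviour(2, 4.1)) # 0
#' @export
annual_km <- function(level, behaviour, levels = frequency_levels()) {
  stopifnot(all(level %in% 1:5), inherits(behaviour, "travel_behaviour"))
  levels$cycling_days_per_year[level] * behaviour$trips_per_day *
    behaviour$trip_length_km
}

#' @export
print.cycling_distribution <- function(x, ...) {
  cat("Cycling distribution (share of population):\n")
  print(round(unclass(x), 6))
  invisible(x)
}

#' @export
print.appraisal_config <- function(x, ...) {
  cat("Appraisal configuration\n")
  cat(sprintf("  population: %s persons, ages %d-%d, mortality %.4g/yr\n",
              format(x$population$size, big.mark = ","),
              x$population$age_band[1], x$population$age_band[2],
              x$population$annual_mortality_rate))
  cat(sprintf("  baseline shares: %s\n",
              paste(sprintf("%.3g%%", 100 * unclass(x$population$baseline)),
                    collapse = " / ")))
  cat(sprintf("  behaviour: %.3g trips/day x %.3g km\n",
              x$behaviour$trips_per_day, x$behaviour$trip_length_km))
  cat(sprintf("  economics: VSL $%s, %.3g%% discount, %d y horizon, %.3g y take-up\n",
              format(x$economics$vsl, big.mark = ","),
              100 * x$economics$discount_rate, x$economics$horizon_years,
              x$economics$takeup_years))
  cat(sprintf("  intervention: $%s for %.3g km\n",
              format(x$intervention$cost_intl_dollars, big.mark = ","),
              x$intervention$cycleway_length_km))
  n <- length(validate_config(x))
  if (n > 0) cat(sprintf("  ** %d invariant violation(s); see validate_config() **\n", n))
  invisible(x)
}
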