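#' The Coventry cycleway base-case configuration
#'
#' The built-in case study: a 6-km separated cycleway serving an adult
#' catchment population of 173,169, costed at $12,800,491 (international
#' dollars; £8,594,000 converted at a 0.667865 PPP coefficient — the
#' printed dollar figure is pinned as authoritative since the two printed
#' numbers are ~0.5% inconsistent), appraised over 10 years at a 5%
#' discount rate with a 1-year take-up, a VSL of $4,260,000 and baseline
#' cycling shares of 1/9/15/25/50% across the five frequency levels.
#' Travel behaviour is 2 trips of 4.1 km on a cycling day (the values the
#' sensitivity probes 3.28/4.92 km and 1.6/2.4 trips are +/-20% around).
#'
#' Risk parameters the case study report does not print (they come from
#' the appraisal tool's background data) are filled with documented
#' order-of-magnitude defaults from the public HEAT methodology: mortality
#' relative risk 0.90 at 1,200 km/year with the risk reduction capped at
#' 45%; all-cause mortality 0.004/year (ages 20-74); crash rate 2.0
#' fatalities per 100 million km; PM2.5 10 ug/m3, ventilation ratio 2,
#' exposure-response 0.008 per ug/m3, half of cycling in traffic, 14 km/h;
#' modal shift 50/30/20% from public transport/car/walking with emission
#' factors 90/171/0 g CO2 per km; carbon damage cost $130/tonne. Results
#' computed with these defaults are order-of-magnitude estimates and are
#' not claimed to reproduce the case study's printed domain values (see
#' [coventry_breakeven_scenarios()] for those).
#'
#' @return A valid [appraisal_config()].
#' @examples
#' cfg <- coventry_fixture()
#' validate_config(cfg)
#' @export
coventry_fixture <- function() {
  appraisal_config(
    population = population_spec(
      size = 173169,
      age_band = c(20L, 74L),
      annual_mortality_rate = 0.004,
      baseline = cycling_distribution(c(0.01, 0.09, 0.15, 0.25, 0.50))
    ),
    behaviour = travel_behaviour(trips_per_day = 2, trip_length_km = 4.1),
    economics = economic_params(
      vsl = 4260000,
      discount_rate = 0.05,
      horizon_years = 10L,
      takeup_years = 1,
      ppp_coefficient = 0.667865,
      carbon_damage_cost = 130
    ),
    risks = risk_params(
      rr_reference = 0.90,
      reference_volume_km_per_year = 1200,
      max_volume_ratio = 4.5,
      pm25_ugm3 = 10,
      ventilation_ratio = 2,
      er_slope_per_ugm3 = 0.008,
      in_traffic_fraction = 0.5,
      crash_fatalities_per_100M_km = 2.0,
      cycling_speed_kmh = 14,
      modal_shift = c(public_transport = 0.5, car = 0.3, walking = 0.2),
      emission_factor_g_per_km = c(public_transport = 90, car = 171,
                                   walking = 0)
    ),
    intervention = intervention_spec(
      cost_intl_dollars = 12800491,
      cycleway_length_km = 6
    )
  )
}

#' Sampling specification for random configurations
#'
#' @param seed Integer RNG seed.
#' @param n_configs Number of configurations to draw.
#' @param ranges Named list of sampling intervals overriding the defaults
#'   (see [sample_configs()] for the sampled distributions).
#' @return A `generator_spec` list.
#' @export
generator_spec <- function(seed, n_configs, ranges = list()) {
  stopifnot(is.numeric(seed), length(seed) == 1,
            is.numeric(n_configs), n_configs >= 1, is.list(ranges))
  defaults <- list(
    shares_alpha = c(1, 2, 3, 5, 9),
    vsl = c(1e6, 1e7),              # log-uniform
    discount_rate = c(0, 0.1),
    horizon_years = c(5L, 20L),     # uniform over integers
    takeup_years = c(1, 5),
    size = c(2e4, 5e5),
    annual_mortality_rate = c(0.001, 0.02),
    trips_per_day = c(1, 3),
    trip_length_km = c(1, 8),
    cost_intl_dollars = c(1e6, 5e7),
    cycleway_length_km = c(1, 20),
    rr_reference = c(0.85, 0.95),
    reference_volume_km_per_year = c(800, 2000),
    max_volume_ratio = c(2, 5),
    pm25_ugm3 = c(5, 25),
    ventilation_ratio = c(1, 3),
    er_slope_per_ugm3 = c(0.004, 0.012),
    in_traffic_fraction = c(0, 1),
    crash_fatalities_per_100M_km = c(0.5, 5),
    cycling_speed_kmh = c(12, 18),
    carbon_damage_cost = c(50, 300),
    emission_car = c(120, 220),
    emission_public_transport = c(60, 120)
  )
  unknown <- setdiff(names(ranges), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown range name(s): ", paste(unknown, collapse = ", "))
  }
  r <- modifyList(defaults, ranges)
  degenerate <- vapply(
    setdiff(names(r), "shares_alpha"),
    function(nm) r[[nm]][2] < r[[nm]][1], logical(1)
  )
  if (any(degenerate)) {
    stop("degenerate range(s): ",
         paste(setdiff(names(r), "shares_alpha")[degenerate], collapse = ", "))
  }
  structure(list(seed = as.integer(seed), n_configs = as.integer(n_configs),
                 ranges = r),
            class = "generator_spec")
}

# run expr with a local RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Draw randomised valid appraisal configurations
#'
#' Samples configurations with the statistical structure the appraisal
#' assumes, for property testing: cycling shares from a Dirichlet
#' distribution (gamma draws normalised; default concentration
#' `(1, 2, 3, 5, 9)`, skewed towards "never"), VSL log-uniform on
#' `[1e6, 1e7]`, discount rate uniform on `[0, 0.1]`, horizon uniform on
#' `{5..20}` years, take-up uniform on `[1, 5]` (capped at the horizon),
#' and all remaining parameters uniform on their specified ranges. Every
#' draw passes [validate_config()]; the sequence is deterministic given
#' the seed.
#'
#' @param spec [generator_spec()].
#' @return List of `spec$n_configs` valid [appraisal_config()]s.
#' @examples
#' cfgs <- sample_configs(generator_spec(seed = 1, n_configs = 3))
#' @export
sample_configs <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  r <- spec$ranges
  u <- function(nm) runif(1, r[[nm]][1], r[[nm]][2])
  with_local_seed(spec$seed, {
    lapply(seq_len(spec$n_configs), function(i) {
      g <- rgamma(5, shape = r$shares_alpha, rate = 1)
      shares <- g / sum(g)
      horizon <- sample(seq(r$horizon_years[1], r$horizon_years[2]), 1)
      takeup <- min(u("takeup_years"), horizon)
      ms <- rgamma(3, shape = c(2, 2, 1), rate = 1)
      ms <- ms / sum(ms)
      appraisal_config(
        population = population_spec(
          size = round(u("size")),
          age_band = c(20L, 74L),
          annual_mortality_rate = u("annual_mortality_rate"),
          baseline = cycling_distribution(shares)
        ),
        behaviour = travel_behaviour(
          trips_per_day = u("trips_per_day"),
          trip_length_km = u("trip_length_km")
        ),
        economics = economic_params(
          vsl = exp(runif(1, log(r$vsl[1]), log(r$vsl[2]))),
          discount_rate = u("discount_rate"),
          horizon_years = horizon,
          takeup_years = takeup,
          ppp_coefficient = 0.667865,
          carbon_damage_cost = u("carbon_damage_cost")
        ),
        risks = risk_params(
          rr_reference = u("rr_reference"),
          reference_volume_km_per_year = u("reference_volume_km_per_year"),
          max_volume_ratio = u("max_volume_ratio"),
          pm25_ugm3 = u("pm25_ugm3"),
          ventilation_ratio = u("ventilation_ratio"),
          er_slope_per_ugm3 = u("er_slope_per_ugm3"),
          in_traffic_fraction = u("in_traffic_fraction"),
          crash_fatalities_per_100M_km = u("crash_fatalities_per_100M_km"),
          cycling_speed_kmh = u("cycling_speed_kmh"),
          modal_shift = c(public_transport = ms[1], car = ms[2],
                          walking = ms[3]),
          emission_factor_g_per_km = c(
            public_transport = u("emission_public_transport"),
            car = u("emission_car"),
            walking = 0
          )
        ),
        intervention = intervention_spec(
          cost_intl_dollars = u("cost_intl_dollars"),
          cycleway_length_km = u("cycleway_length_km")
        )
      )
    })
  })
}

#' Break exactly one configuration invariant
#'
#' Negative-testing support: returns a copy of `config` violating exactly
#' one named invariant, so validators can be checked field by field.
#'
#' @param config A valid [appraisal_config()].
#' @param field One of `"shares_sum"`, `"share_negative"`,
#'   `"modal_shift"`, `"vsl"`, `"discount_rate"`, `"horizon_years"`,
#'   `"takeup_years"`, `"trip_length_km"`, `"trips_per_day"`, `"size"`,
#'   `"annual_mortality_rate"`, `"cost"`, `"cycleway_length_km"`,
#'   `"crash_rate"`, `"in_traffic_fraction"`, `"rr_reference"`,
#'   `"ventilation_ratio"`, `"walking_emission"`.
#' @return An `appraisal_config` failing exactly one validation check.
#' @examples
#' bad <- inject_violation(coventry_fixture(), "shares_sum")
#' validate_config(bad)
#' @export
inject_violation <- function(config, field) {
  stopifnot(inherits(config, "appraisal_config"))
  switch(field,
    shares_sum = {
      config$population$baseline <-
        cycling_distribution(unclass(config$population$baseline) * 1.05)
    },
    share_negative = {
      sh <- unclass(config$population$baseline)
      sh[1] <- sh[1] - 2 * sh[5]
      sh[5] <- 3 * sh[5] # keep the sum intact; level 1 goes negative
      config$population$baseline <- cycling_distribution(sh)
    },
    modal_shift = {
      config$risks$modal_shift[] <- c(0.6, 0.3, 0.2)
    },
    vsl = config$economics$vsl <- -1,
    discount_rate = config$economics$discount_rate <- -0.01,
    horizon_years = config$economics$horizon_years <- 7.5,
    takeup_years = {
      config$economics$takeup_years <- config$economics$horizon_years + 1
    },
    trip_length_km = config$behaviour$trip_length_km <- -2,
    trips_per_day = config$behaviour$trips_per_day <- 0,
    size = config$population$size <- 0,
    annual_mortality_rate = config$population$annual_mortality_rate <- 1.5,
    cost = config$intervention$cost_intl_dollars <- -5,
    cycleway_length_km = config$intervention$cycleway_length_km <- 0,
    crash_rate = config$risks$crash_fatalities_per_100M_km <- -1,
    in_traffic_fraction = config$risks$in_traffic_fraction <- 1.5,
    rr_reference = config$risks$rr_reference <- 1.2,
    ventilation_ratio = config$risks$ventilation_ratio <- 0.5,
    walking_emission = {
      config$risks$emission_factor_g_per_km[["walking"]] <- 10
    },
    stop("unknown field: ", field)
  )
  config
}

#' Fields understood by [inject_violation()]
#' @return Character vector of field names.
#' @export
violation_fields <- function() {
  c("shares_sum", "share_negative", "modal_shift", "vsl", "discount_rate",
    "horizon_years", "takeup_years", "trip_length_km", "trips_per_day",
    "size", "annual_mortality_rate", "cost", "cycleway_length_km",
    "crash_rate", "in_traffic_fraction", "rr_reference",
    "ventilation_ratio", "walking_emission")
}
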