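# serialisable plain-list view of a config (field names match the
# constructors; fixed field order so digests are stable)
config_to_list <- function(config) {
  stopifnot(inherits(config, "appraisal_config"))
  list(
    population = list(
      size = config$population$size,
      age_band = as.integer(config$population$age_band),
      annual_mortality_rate = config$population$annual_mortality_rate,
      baseline = list(shares = as.numeric(config$population$baseline))
    ),
    behaviour = list(
      trips_per_day = config$behaviour$trips_per_day,
      trip_length_km = config$behaviour$trip_length_km
    ),
    economics = list(
      vsl = config$economics$vsl,
      discount_rate = config$economics$discount_rate,
      horizon_years = config$economics$horizon_years,
      takeup_years = config$economics$takeup_years,
      ppp_coefficient = config$economics$ppp_coefficient,
      carbon_damage_cost = config$economics$carbon_damage_cost,
      discount_convention = config$economics$discount_convention
    ),
    risks = list(
      rr_reference = config$risks$rr_reference,
      reference_volume_km_per_year = config$risks$reference_volume_km_per_year,
      max_volume_ratio = config$risks$max_volume_ratio,
      pm25_ugm3 = config$risks$pm25_ugm3,
      ventilation_ratio = config$risks$ventilation_ratio,
      er_slope_per_ugm3 = config$risks$er_slope_per_ugm3,
      in_traffic_fraction = config$risks$in_traffic_fraction,
      crash_fatalities_per_100M_km = config$risks$crash_fatalities_per_100M_km,
      cycling_speed_kmh = config$risks$cycling_speed_kmh,
      modal_shift = as.list(config$risks$modal_shift),
      emission_factor_g_per_km = as.list(config$risks$emission_factor_g_per_km)
    ),
    intervention = list(
      cost_intl_dollars = config$intervention$cost_intl_dollars,
      cycleway_length_km = config$intervention$cycleway_length_km
    ),
    levels = list(
      cycling_days_per_year = config$levels$cycling_days_per_year
    )
  )
}

reject_unknown <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0) {
    stop(sprintf("unknown key(s) in %s: %s", where,
                 paste(unknown, collapse = ", ")))
  }
}

need <- function(x, key, where) {
  if (is.null(x[[key]])) stop(sprintf("missing key in %s: %s", where, key))
  x[[key]]
}

list_to_config <- function(x) {
  reject_unknown(x, c("population", "behaviour", "economics", "risks",
                      "intervention", "levels"), "config")
  pop <- need(x, "population", "config")
  reject_unknown(pop, c("size", "age_band", "annual_mortality_rate",
                        "baseline"), "population")
  bl <- need(pop, "baseline", "population")
  reject_unknown(bl, "shares", "population.baseline")
  beh <- need(x, "behaviour", "config")
  reject_unknown(beh, c("trips_per_day", "trip_length_km"), "behaviour")
  eco <- need(x, "economics", "config")
  reject_unknown(eco, c("vsl", "discount_rate", "horizon_years",
                        "takeup_years", "ppp_coefficient",
                        "carbon_damage_cost", "discount_convention"),
                 "economics")
  rk <- need(x, "risks", "config")
  reject_unknown(rk, c("rr_reference", "reference_volume_km_per_year",
                       "max_volume_ratio", "pm25_ugm3", "ventilation_ratio",
                       "er_slope_per_ugm3", "in_traffic_fraction",
                       "crash_fatalities_per_100M_km", "cycling_speed_kmh",
                       "modal_shift", "emission_factor_g_per_km"), "risks")
  modes <- c("public_transport", "car", "walking")
  reject_unknown(rk$modal_shift, modes, "risks.modal_shift")
  reject_unknown(rk$emission_factor_g_per_km, modes,
                 "risks.emission_factor_g_per_km")
  int <- need(x, "intervention", "config")
  reject_unknown(int, c("cost_intl_dollars", "cycleway_length_km"),
                 "intervention")
  levels <- frequency_levels()
  if (!is.null(x$levels)) {
    reject_unknown(x$levels, "cycling_days_per_year", "levels")
    levels <- frequency_levels(unlist(x$levels$cycling_days_per_year))
  }
  appraisal_config(
    population = population_spec(
      size = need(pop, "size", "population"),
      age_band = unlist(need(pop, "age_band", "population")),
      annual_mortality_rate = need(pop, "annual_mortality_rate", "population"),
      baseline = cycling_distribution(unlist(need(bl, "shares",
                                                  "population.baseline")))
    ),
    behaviour = travel_behaviour(
      trips_per_day = need(beh, "trips_per_day", "behaviour"),
      trip_length_km = need(beh, "trip_length_km", "behaviour")
    ),
    economics = economic_params(
      vsl = need(eco, "vsl", "economics"),
      discount_rate = need(eco, "discount_rate", "economics"),
      horizon_years = need(eco, "horizon_years", "economics"),
      takeup_years = need(eco, "takeup_years", "economics"),
      ppp_coefficient = need(eco, "ppp_coefficient", "economics"),
      carbon_damage_cost = need(eco, "carbon_damage_cost", "economics"),
      discount_convention = if (is.null(eco$discount_convention)) "end"
                            else eco$discount_convention
    ),
    risks = risk_params(
      rr_reference = need(rk, "rr_reference", "risks"),
      reference_volume_km_per_year =
        need(rk, "reference_volume_km_per_year", "risks"),
      max_volume_ratio = need(rk, "max_volume_ratio", "risks"),
      pm25_ugm3 = need(rk, "pm25_ugm3", "risks"),
      ventilation_ratio = need(rk, "ventilation_ratio", "risks"),
      er_slope_per_ugm3 = need(rk, "er_slope_per_ugm3", "risks"),
      in_traffic_fraction = need(rk, "in_traffic_fraction", "risks"),
      crash_fatalities_per_100M_km =
        need(rk, "crash_fatalities_per_100M_km", "risks"),
      cycling_speed_kmh = need(rk, "cycling_speed_kmh", "risks"),
      modal_shift = unlist(need(rk, "modal_shift", "risks"))[modes],
      emission_factor_g_per_km =
        unlist(need(rk, "emission_factor_g_per_km", "risks"))[modes]
    ),
    intervention = intervention_spec(
      cost_intl_dollars = need(int, "cost_intl_dollars", "intervention"),
      cycleway_length_km = need(int, "cycleway_length_km", "intervention")
    ),
    levels = levels
  )
}

#' Load an appraisal configuration from YAML or JSON
#'
#' Reads one configuration document (format chosen by file extension),
#' rejects unknown keys at every nesting level, and validates all
#' invariants before returning.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A valid [appraisal_config()].
#' @seealso [write_config()] for the inverse; the two round-trip.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext, " (use .yaml/.yml/.json)")
  )
  config <- list_to_config(x)
  violations <- validate_config(config)
  if (length(violations) > 0) {
    stop("invalid config in ", path, ":\n  ",
         paste(violations, collapse = "\n  "))
  }
  config
}

#' Write an appraisal configuration to YAML or JSON
#'
#' @param config [appraisal_config()].
#' @param path Destination `.yaml`/`.yml` or `.json` path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  x <- config_to_list(config)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = ,
    yml = yaml::write_yaml(x, path, precision = 15),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    stop("unsupported config format: .", ext, " (use .yaml/.yml/.json)")
  )
  invisible(path)
}

#' Stable digest of a configuration
#'
#' MD5 digest of the canonical JSON serialisation; identical
#' configurations always digest identically, so run manifests can tie
#' outputs to their inputs.
#'
#' @param config [appraisal_config()].
#' @return 32-character hex string.
#' @export
config_digest <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(
    jsonlite::toJSON(config_to_list(config), auto_unbox = TRUE, digits = 15),
    tmp
  )
  unname(tools::md5sum(tmp))
}

fmt_dollar <- function(x) sprintf("%.0f", x)           # whole dollars
fmt_share <- function(x) sprintf("%.3f", 100 * x)      # percent, 3 dp

breakeven_csv <- function(results, config) {
  header <- data.frame(
    scenario = integer(), source_level = integer(),
    required_share_percent = character(), new_regular_cyclists = integer(),
    domain = character(), annual_deaths = character(),
    annual_tonnes_co2 = character(), discounted_value = character(),
    currency = character(), stringsAsFactors = FALSE
  )
  if (length(results) == 0) return(header)
  blocks <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    imp <- appraise(config, r$post)$impacts
    data.frame(
      scenario = i,
      source_level = r$scenario$source_level,
      required_share_percent = fmt_share(r$scenario$shifted_share),
      new_regular_cyclists = r$new_regular_cyclists,
      domain = imp$domain,
      annual_deaths = sprintf("%.4f", imp$annual_deaths_delta),
      annual_tonnes_co2 = sprintf("%.4f", imp$annual_tonnes_co2_delta),
      discounted_value = fmt_dollar(imp$discounted_value),
      currency = "intl_dollar",
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, blocks)
}

sensitivity_csv <- function(tab) {
  data.frame(
    parameter = tab$parameter,
    label = tab$label,
    bcr_at_base_shift = sprintf("%.3f", tab$bcr_at_base_shift),
    breakeven_share_percent = ifelse(is.na(tab$breakeven_share), "",
                                     fmt_share(tab$breakeven_share)),
    absolute_regular_cyclists = tab$absolute_regular_cyclists,
    additional_vs_base = tab$additional_vs_base,
    feasible = tab$feasible,
    stringsAsFactors = FALSE
  )
}

#' Write deterministic result reports
#'
#' Serialises results to CSV and JSON in a scenario-table layout (one row
#' per scenario and domain for break-even runs; one row per variation for
#' sensitivity runs), together with a run manifest tying outputs to the
#' configuration digest. With the default `timestamp = NULL` the outputs
#' are byte-identical across reruns on identical input. All currency
#' columns carry an explicit unit tag (`intl_dollar`; PPP-converted
#' figures are tagged `gbp`) so the two currencies can never be silently
#' mixed.
#'
#' @param results A list of `breakeven_result`s, a `sensitivity_table`, or
#'   an `appraisal_result`.
#' @param out_dir Output directory (created if missing).
#' @param config The [appraisal_config()] the results were computed from.
#' @param timestamp Optional timestamp string recorded in the manifest;
#'   omit for reproducible output.
#' @param arguments Optional character description of the invocation,
#'   recorded in the manifest.
#' @return Character vector of file paths written.
#' @export
write_reports <- function(results, out_dir, config, timestamp = NULL,
                          arguments = character()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- character()

  is_be_list <- is.list(results) && !is.data.frame(results) &&
    !inherits(results, "appraisal_result") &&
    (length(results) == 0 ||
       all(vapply(results, inherits, logical(1), "breakeven_result")))

  if (is_be_list) {
    csv <- file.path(out_dir, "breakeven_scenarios.csv")
    write.csv(breakeven_csv(results, config), csv, row.names = FALSE,
              quote = TRUE)
    paths <- c(paths, csv)
    if (length(results) > 0) {
      summ <- summarize_breakeven(results, config$intervention,
                                  config$economics)
      js <- file.path(out_dir, "breakeven_summary.json")
      jsonlite::write_json(
        list(
          n_scenarios = summ$n_scenarios,
          mean_new_regular_cyclists = summ$mean_new_regular_cyclists,
          mean_shifted_share = summ$mean_shifted_share,
          cyclists_per_km = summ$cyclists_per_km,
          per_cyclist_annual_value = list(
            value = summ$per_cyclist_annual_value, currency = "intl_dollar"),
          per_cyclist_annual_value_local = list(
            value = summ$per_cyclist_annual_value_local, currency = "gbp"),
          horizon_years = summ$horizon_years,
          cost = list(value = summ$cost_intl_dollars,
                      currency = "intl_dollar")
        ),
        js, auto_unbox = TRUE, digits = 8, pretty = TRUE
      )
      paths <- c(paths, js)
    }
  } else if (inherits(results, "sensitivity_table")) {
    csv <- file.path(out_dir, "sensitivity.csv")
    write.csv(sensitivity_csv(results), csv, row.names = FALSE, quote = TRUE)
    paths <- c(paths, csv)
  } else if (inherits(results, "appraisal_result")) {
    csv <- file.path(out_dir, "appraisal.csv")
    imp <- results$impacts
    write.csv(
      data.frame(
        domain = imp$domain,
        annual_deaths = sprintf("%.4f", imp$annual_deaths_delta),
        annual_tonnes_co2 = sprintf("%.4f", imp$annual_tonnes_co2_delta),
        discounted_value = fmt_dollar(imp$discounted_value),
        currency = "intl_dollar",
        stringsAsFactors = FALSE
      ),
      csv, row.names = FALSE, quote = TRUE
    )
    paths <- c(paths, csv)
  } else {
    stop("unsupported results object of class: ",
         paste(class(results), collapse = "/"))
  }

  manifest <- list(
    config_digest = config_digest(config),
    tool_version = as.character(utils::packageVersion("cyclebreakeven")),
    arguments = as.character(arguments)
  )
  if (!is.null(timestamp)) manifest$timestamp <- as.character(timestamp)
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, mf)
  invisible(paths)
}
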