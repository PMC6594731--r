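# internal: schema-checked CSV read. `schema` is a named list, one entry per
# required column: list(type = "numeric"|"character", min =, max =).
# Errors name the offending column and row.
read_checked_csv <- function(path, schema) {
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(names(schema), names(df))
  if (length(miss)) {
    stop(sprintf("%s: missing required column(s): %s", basename(path),
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  for (col in names(schema)) {
    sc <- schema[[col]]
    v <- df[[col]]
    if (identical(sc$type, "numeric")) {
      if (!is.numeric(v) || anyNA(v)) {
        stop(sprintf("%s: column `%s` must be numeric with no missing values",
                     basename(path), col), call. = FALSE)
      }
      if (!is.null(sc$min) && any(v < sc$min)) {
        stop(sprintf("%s: column `%s` below %s at row %d", basename(path),
                     col, format(sc$min), which(v < sc$min)[1L]),
             call. = FALSE)
      }
      if (!is.null(sc$max) && any(v > sc$max)) {
        stop(sprintf("%s: column `%s` above %s at row %d", basename(path),
                     col, format(sc$max), which(v > sc$max)[1L]),
             call. = FALSE)
      }
    }
  }
  df
}

#' Read a population table
#'
#' @param path CSV with columns `year`, `age_band`, `persons`.
#' @return validated data.frame.
#' @export
read_population_csv <- function(path) {
  df <- read_checked_csv(path, list(
    year = list(type = "numeric"),
    age_band = list(type = "character"),
    persons = list(type = "numeric", min = 0)))
  parse_age_band(unique(df$age_band))  # label validity
  df
}

#' Read a mortality schedule
#'
#' @param path CSV with columns `year`, `age_band`, `deaths_per_1000`.
#' @return validated data.frame.
#' @export
read_mortality_csv <- function(path) {
  df <- read_checked_csv(path, list(
    year = list(type = "numeric"),
    age_band = list(type = "character"),
    deaths_per_1000 = list(type = "numeric", min = 0)))
  parse_age_band(unique(df$age_band))
  df
}

#' Read an assistance profile
#'
#' @param path CSV with columns `age_band`, `p_need_assist`, `p_household`
#'   and optionally `p_household_and_need`, `p_cared_accommodation`.
#' @return an [assistance_profile()].
#' @export
read_assistance_csv <- function(path) {
  df <- read_checked_csv(path, list(
    age_band = list(type = "character"),
    p_need_assist = list(type = "numeric", min = 0, max = 1),
    p_household = list(type = "numeric", min = 0, max = 1)))
  assistance_profile(df)
}

#' Read a disease-count distribution
#'
#' @param path CSV with columns `n_diseases` (`0`, `1`, `2`, `3plus` and
#'   optionally `total`) and `persons_thousands`.
#' @return a [disease_count_distribution()].
#' @export
read_disease_counts_csv <- function(path) {
  df <- read_checked_csv(path, list(
    n_diseases = list(type = "character"),
    persons_thousands = list(type = "numeric", min = 0)))
  pools <- stats::setNames(df$persons_thousands, df$n_diseases)
  total <- if ("total" %in% names(pools)) pools[["total"]] else
    sum(pools[c("0", "1", "2", "3plus")])
  disease_count_distribution(pools[c("0", "1", "2", "3plus")], total = total)
}

#' Read a comorbidity pair table
#'
#' @param path CSV with columns `disease_a`, `disease_b`,
#'   `persons_thousands` (one row per unordered pair).
#' @param marginals optional named per-disease totals.
#' @param diseases disease ids; defaults to [chronic_diseases()].
#' @return a [comorbidity_matrix()].
#' @export
read_comorbidity_csv <- function(path, marginals = NULL,
                                 diseases = chronic_diseases()) {
  df <- read_checked_csv(path, list(
    disease_a = list(type = "character"),
    disease_b = list(type = "character"),
    persons_thousands = list(type = "numeric", min = 0)))
  comorbidity_matrix(df, marginals = marginals, diseases = diseases)
}

#' Read a technology catalog
#'
#' @param path catalog CSV (see [technology_catalog()] for columns).
#' @return a [technology_catalog()].
#' @export
read_catalog_csv <- function(path) {
  df <- read_checked_csv(path, list(
    item_id = list(type = "character"),
    function_category = list(type = "character"),
    price_low_aud = list(type = "numeric", min = 0),
    price_avg_aud = list(type = "numeric", min = 0),
    lifespan_years = list(type = "numeric"),
    maintenance_fraction = list(type = "numeric", min = 0, max = 1),
    installation_fraction = list(type = "numeric", min = 0, max = 1)))
  technology_catalog(df)
}

#' Read a bundle map
#'
#' @param path CSV with columns `disease` (a disease id or `basic`) and
#'   `item_id`, one row per (bundle, item).
#' @param catalog optional catalog for id validation.
#' @return a [bundle_map()].
#' @export
read_bundles_csv <- function(path, catalog = NULL) {
  df <- read_checked_csv(path, list(
    disease = list(type = "character"),
    item_id = list(type = "character")))
  basic <- df$item_id[df$disease == "basic"]
  rest <- df[df$disease != "basic", , drop = FALSE]
  diseases <- split(rest$item_id, rest$disease)
  bundle_map(basic, diseases, catalog = catalog)
}

#' Write a table to CSV
#'
#' @param df data.frame.
#' @param path output path; parent directories are created.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @describeIn write_table write a [bundle_map()] in the two-column CSV
#'   layout read by [read_bundles_csv()].
#' @param bundles a [bundle_map()].
#' @export
write_bundles_csv <- function(bundles, path) {
  stopifnot(inherits(bundles, "bundle_map"))
  df <- rbind(
    data.frame(disease = "basic", item_id = bundles$basic,
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(names(bundles$diseases), function(d)
      data.frame(disease = d, item_id = bundles$diseases[[d]],
                 stringsAsFactors = FALSE))))
  write_table(df, path)
}

#' Load the shipped regional case-study inputs
#'
#' The published demographic and comorbidity tables for the Fitzroy and
#' Central West case study region, shipped as plain CSV: population by age
#' band (2006/2011/2016 plus the published 2021/2026 projections),
#' Queensland death rates, regional totals, the assistance profile, the
#' disease-count distribution, per-disease counts and the pairwise
#' comorbidity matrix.
#'
#' @return named list: `population`, `printed_forecast`, `regional`,
#'   `mortality`, `assistance`, `dist`, `disease_table`, `single_counts`,
#'   `single_total`, `marginals`, `comorbidity`, `config`.
#' @export
fcw_published_inputs <- function() {
  ext <- function(f) system.file("extdata", f, package = "ageplacecost",
                                 mustWork = TRUE)
  disease_table <- read_checked_csv(ext("chronic_disease_counts.csv"), list(
    disease = list(type = "character"),
    one = list(type = "numeric", min = 0),
    two = list(type = "numeric", min = 0),
    three_plus = list(type = "numeric", min = 0),
    total = list(type = "numeric", min = 0)))
  marginals <- stats::setNames(disease_table$total, disease_table$disease)
  dist <- read_disease_counts_csv(ext("disease_counts.csv"))
  list(
    population = read_population_csv(ext("fcw_population.csv")),
    printed_forecast =
      read_population_csv(ext("fcw_population_printed_forecast.csv")),
    regional = read_checked_csv(ext("regional_population.csv"), list(
      region = list(type = "character"),
      year = list(type = "numeric"),
      persons = list(type = "numeric", min = 0))),
    mortality = read_mortality_csv(ext("qld_mortality.csv")),
    assistance = read_assistance_csv(ext("assistance_profile.csv")),
    dist = dist,
    disease_table = disease_table,
    single_counts = stats::setNames(disease_table$one,
                                    disease_table$disease),
    single_total = dist$pools[["1"]],
    marginals = marginals,
    comorbidity = read_comorbidity_csv(ext("comorbidity_pairs.csv"),
                                       marginals = marginals),
    config = read_run_config(ext("fcw_config.yaml"))
  )
}

#' Read a run configuration
#'
#' @param path YAML file; recognised keys are `base_year`,
#'   `horizon_years`, `nom_rate`, `nim_rate`, `rate_convention`, `mode`,
#'   `assist_rate_overall`, `inflation_rate`, `price_source_year`,
#'   `scenarios`, `top_k`, `seed`. Missing keys take the defaults of the
#'   shipped case-study configuration.
#' @return named list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(base_year = 2016, horizon_years = 10,
                   nom_rate = -0.00006, nim_rate = 0.00058,
                   rate_convention = "destination", mode = "published",
                   assist_rate_overall = 0.3661, inflation_rate = 0.019,
                   price_source_year = 2018,
                   scenarios = c("low", "average"), top_k = 4,
                   seed = 20160630)
  cfg <- defaults
  if (!is.null(path)) {
    if (!file.exists(path)) {
      stop("config file does not exist: ", path, call. = FALSE)
    }
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  if (!cfg$mode %in% c("published", "strict")) {
    stop("config `mode` must be 'published' or 'strict'", call. = FALSE)
  }
  check_number(cfg$horizon_years, "horizon_years", min = 5)
  cfg$scenarios <- match.arg(unlist(cfg$scenarios), c("low", "average"),
                             several.ok = TRUE)
  class(cfg) <- "run_config"
  cfg
}
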