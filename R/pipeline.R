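#' Deflate a catalog's prices to the base year
#'
#' @param catalog a [technology_catalog()] priced at `source_year`.
#' @param annual_inflation annual inflation fraction.
#' @param base_year target year; defaults to 2 years before the catalog's
#'   `source_year` when that column exists.
#' @param source_year year the prices were observed.
#' @return catalog with both price columns expressed in base-year AUD.
#' @export
deflate_catalog <- function(catalog, annual_inflation, base_year,
                            source_year = NULL) {
  stopifnot(inherits(catalog, "technology_catalog"))
  if (is.null(source_year)) {
    source_year <- if ("source_year" %in% names(catalog)) {
      max(catalog$source_year)
    } else base_year
  }
  years <- max(source_year - base_year, 0)
  catalog$price_low_aud <- deflate_price(catalog$price_low_aud,
                                         annual_inflation, years)
  catalog$price_avg_aud <- deflate_price(catalog$price_avg_aud,
                                         annual_inflation, years)
  catalog
}

# internal: stage log
stage_msg <- function(quiet, ...) if (!quiet) message(...)

#' Run the five-stage cost-estimation pipeline end to end
#'
#' Executes, in order: (1) progressive forecasting of the 65+ population
#' over the horizon; (2) assistance-need estimation; (3) categorisation by
#' number of chronic diseases and combinatorial allocation to specific
#' disease-combination strata; (4) device bundling and life-cycle costing;
#' (5) report assembly. Every stage logs row counts and conservation
#' checks (suppress with `quiet = TRUE`).
#'
#' @param config a `run_config` (see [read_run_config()]); defaults to the
#'   shipped case-study configuration.
#' @param inputs input list as returned by [fcw_published_inputs()] (the
#'   default) or assembled from the `read_*_csv` readers.
#' @param catalog,bundles a [technology_catalog()] and [bundle_map()];
#'   when `NULL` a synthetic catalog is generated from `config$seed` and
#'   deflated from `config$price_source_year` to the base year.
#' @param out_dir optional directory; when given, all intermediate tables
#'   and the final report are written there as CSV plus a JSON summary.
#' @param quiet suppress stage logging.
#' @return list: `forecast` (population table), `totals_65plus`,
#'   `assisted` (per report year, unrounded), `allocations`,
#'   `category_table` (published-table-shaped category counts, displayed
#'   rounding), `single_table` (one-disease breakdown by year), `report`
#'   (a `cost_report`), `catalog`, `bundles`, `config`.
#' @export
run_pipeline <- function(config = read_run_config(), inputs = fcw_published_inputs(),
                         catalog = NULL, bundles = NULL, out_dir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))

  # stage 1: progressive forecast
  base <- inputs$population[inputs$population$year == config$base_year, ,
                            drop = FALSE]
  if (!nrow(base)) {
    stop("forecast stage: no base-year rows (", config$base_year,
         ") in the population input", call. = FALSE)
  }
  schedule <- collapse_top_band(inputs$mortality, top_label = "85+")
  regional <- inputs$regional[inputs$regional$region == "fcw",
                              c("year", "persons"), drop = FALSE]
  forecast <- forecast_population(
    base, schedule, base_year = config$base_year,
    horizon_years = config$horizon_years, nom_rate = config$nom_rate,
    nim_rate = config$nim_rate, regional_population = regional,
    rate_convention = config$rate_convention)
  totals <- total_65plus(forecast)
  years <- names(totals)
  stage_msg(quiet, sprintf(
    "[forecast] %d band-years; 65+ total %s -> %s (%+.1f%%)",
    nrow(forecast), round_half_up(totals[[1L]]),
    round_half_up(totals[[length(totals)]]),
    growth_percent(totals[[1L]], totals[[length(totals)]])))

  # stage 2: assistance need
  assisted <- vapply(totals, aggregate_assisted, numeric(1),
                     overall_rate = config$assist_rate_overall)
  stage_msg(quiet, sprintf(
    "[assist] overall rate %.2f%%; assisted: %s",
    100 * config$assist_rate_overall,
    paste(sprintf("%s=%d", years, round_half_up(assisted)),
          collapse = ", ")))

  # stage 3: categorisation + combinatorial allocation
  allocations <- lapply(stats::setNames(years, years), function(y) {
    allocate(assisted[[y]], inputs$dist, inputs$single_counts,
             single_total = inputs$single_total, cm = inputs$comorbidity,
             top_k = config$top_k, mode = config$mode)
  })
  for (y in years) {
    al <- allocations[[y]]
    gap <- sum(al$strata$persons) - assisted[[y]]
    stage_msg(quiet, sprintf(
      "[allocate] %s: %d strata, conservation gap %+.2f persons (%s mode)",
      y, nrow(al$strata), gap, config$mode))
  }
  category_table <- do.call(rbind, lapply(years, function(y) {
    cats <- allocations[[y]]$categories
    data.frame(year = as.numeric(y),
               total_65plus = round_half_up(totals[[y]]),
               assisted = round_half_up(assisted[[y]]),
               no_disease = round_half_up(cats[["0"]]),
               one_disease = round_half_up(cats[["1"]]),
               two_diseases = round_half_up(cats[["2"]]),
               three_plus = round_half_up(cats[["3plus"]]))
  }))
  single_table <- do.call(rbind, lapply(years, function(y) {
    st <- allocations[[y]]$strata
    one <- st[st$n_diseases == "1", , drop = FALSE]
    data.frame(year = as.numeric(y), disease = one$combination,
               persons = round_half_up(one$persons),
               stringsAsFactors = FALSE)
  }))

  # stage 4: catalog and bundles
  if (is.null(catalog)) {
    synth <- synth_catalog(seed = config$seed,
                           source_year = config$price_source_year)
    catalog <- synth$catalog
    if (is.null(bundles)) bundles <- synth$bundles
    stage_msg(quiet, sprintf(
      "[catalog] synthetic catalog: %d items (seed %d)", nrow(catalog),
      config$seed))
  }
  if (is.null(bundles)) {
    stop("costing stage: `bundles` must be supplied with a custom catalog",
         call. = FALSE)
  }
  catalog <- deflate_catalog(catalog, config$inflation_rate,
                             base_year = config$base_year,
                             source_year = config$price_source_year)

  # stage 5: costing and report
  report <- aggregate_costs(allocations, catalog, bundles,
                            scenarios = config$scenarios)
  grand <- report[report$category == "all", , drop = FALSE]
  stage_msg(quiet, sprintf(
    "[cost] %d report rows; totals: %s", nrow(report),
    paste(sprintf("%s/%s=%.0f", grand$year, grand$scenario,
                  grand$total_aud), collapse = ", ")))

  out <- list(forecast = forecast, totals_65plus = totals,
              assisted = assisted, allocations = allocations,
              category_table = category_table, single_table = single_table,
              report = report, catalog = catalog, bundles = bundles,
              config = config)
  if (!is.null(out_dir)) {
    write_table(forecast, file.path(out_dir, "forecast_population.csv"))
    write_table(category_table, file.path(out_dir, "category_counts.csv"))
    write_table(single_table, file.path(out_dir, "single_disease.csv"))
    strata_all <- do.call(rbind, lapply(years, function(y) {
      cbind(year = as.numeric(y), allocations[[y]]$strata)
    }))
    write_table(strata_all, file.path(out_dir, "combination_strata.csv"))
    write_table(as.data.frame(report), file.path(out_dir, "cost_report.csv"))
    meta <- list(mode = config$mode, seed = config$seed,
                 base_year = config$base_year,
                 horizon_years = config$horizon_years,
                 scenarios = config$scenarios,
                 n_items = nrow(catalog))
    jsonlite::write_json(
      list(meta = meta, report = as.data.frame(report)),
      file.path(out_dir, "cost_report.json"),
      auto_unbox = TRUE, digits = NA)
    stage_msg(quiet, "[write] outputs in ", out_dir)
  }
  invisible(out)
}

#' Emit a full synthetic input bundle to a directory
#'
#' Writes every CSV the pipeline consumes — population, mortality,
#' assistance, disease counts, comorbidity pairs, catalog and bundles —
#' generated synthetically from one seed, so the whole pipeline can be
#' exercised with no access to the published tables.
#'
#' @param dir output directory (created).
#' @param seed integer seed driving every generator.
#' @param n_individuals synthetic survey size for the comorbidity inputs.
#' @param prevalences named disease prevalences for the log-linear model.
#' @param base_year,horizon_years demographic frame for the synthetic
#'   population (base-year bands decline ~8% per 5-year band step).
#' @return named character vector of the files written, invisibly.
#' @export
synth_input_bundle <- function(dir, seed = 1L, n_individuals = 20000,
                               prevalences = NULL, base_year = 2016,
                               horizon_years = 10) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(prevalences)) {
    prevalences <- stats::setNames(
      c(0.45, 0.10, 0.25, 0.06, 0.08, 0.17, 0.50, 0.17), chronic_diseases())
  }
  files <- c()
  with_local_seed(seed, {
    bands <- c("55-59", "60-64", "65-69", "70-74", "75-79", "80-84", "85+")
    base_counts <- round(15000 * 0.92^(seq_along(bands) - 1) *
                           stats::runif(length(bands), 0.9, 1.1))
    years <- seq(base_year - 10, base_year, by = 5)
    pop <- do.call(rbind, lapply(seq_along(years), function(i)
      data.frame(year = years[i], age_band = bands,
                 persons = round(base_counts * (0.94 + 0.03 * i)))))
    files["population"] <- write_table(pop, file.path(dir, "population.csv"))
    rates <- c(4, 6, 10, 16, 27, 50, 100)
    mort <- do.call(rbind, lapply(seq_along(years), function(i)
      data.frame(year = years[i], age_band = bands,
                 deaths_per_1000 = rates * (1.06 - 0.03 * i))))
    files["mortality"] <- write_table(mort, file.path(dir, "mortality.csv"))
    assist <- data.frame(
      age_band = c("65-69", "70-74", "75-79", "80-84", "85-89", "90+"),
      p_need_assist = round(stats::runif(6, 0.2, 0.9), 3),
      p_household = round(stats::runif(6, 0.6, 1.0), 3))
    assist$p_household_and_need <-
      round(assist$p_need_assist * assist$p_household, 4)
    files["assistance"] <- write_table(assist,
                                       file.path(dir, "assistance.csv"))
  })
  ind <- synth_individuals(n_individuals, prevalences, seed = seed + 1L)
  tab <- tabulate_individuals(ind)
  dist_df <- data.frame(
    n_diseases = c(names(tab$dist$pools), "total"),
    persons_thousands = c(unname(tab$dist$pools), tab$dist$total) / 1000)
  files["disease_counts"] <- write_table(dist_df,
                                         file.path(dir, "disease_counts.csv"))
  cm <- tab$matrix
  pr <- utils::combn(rownames(cm$counts), 2L)
  pairs_df <- data.frame(disease_a = pr[1L, ], disease_b = pr[2L, ],
                         persons_thousands =
                           cm$counts[cbind(pr[1L, ], pr[2L, ])] / 1000)
  files["comorbidity"] <- write_table(pairs_df,
                                      file.path(dir, "comorbidity.csv"))
  marg_df <- data.frame(disease = names(cm$marginals),
                        persons_thousands = unname(cm$marginals) / 1000)
  files["marginals"] <- write_table(marg_df, file.path(dir, "marginals.csv"))
  synth <- synth_catalog(seed = seed + 2L)
  files["catalog"] <- write_table(as.data.frame(synth$catalog),
                                  file.path(dir, "catalog.csv"))
  files["bundles"] <- write_bundles_csv(synth$bundles,
                                        file.path(dir, "bundles.csv"))
  invisible(files)
}
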