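#' Annual life-cycle cost of one device
#'
#' In the default amortized mode the purchase price plus one-off
#' installation is spread uniformly over the device lifespan, and annual
#' maintenance is added on top:
#' `price * (1 + installation) / lifespan + maintenance * price`.
#' In cash-flow mode the purchase and installation are instead booked in
#' full in replacement years (year offsets 0, lifespan, 2*lifespan, ...),
#' with maintenance every year — useful for budget planners who care about
#' lumpy outlays rather than smoothed annual figures.
#'
#' @param item one catalog row (list or one-row data.frame with the
#'   [technology_catalog()] columns).
#' @param scenario `"low"` or `"average"` price scenario.
#' @param mode `"amortized"` (default) or `"cashflow"`.
#' @param year_offset years since the start of provision; only used in
#'   cash-flow mode.
#' @return AUD per year for this device.
#' @export
#' @examples
#' it <- list(price_low_aud = 1000, price_avg_aud = 1500, lifespan_years = 5,
#'            maintenance_fraction = 0.15, installation_fraction = 0.05)
#' annual_item_cost(it, "low")  # 1000 * 1.05 / 5 + 150 = 360
annual_item_cost <- function(item, scenario = c("low", "average"),
                             mode = c("amortized", "cashflow"),
                             year_offset = 0) {
  scenario <- match.arg(scenario)
  mode <- match.arg(mode)
  price <- if (scenario == "low") item$price_low_aud else item$price_avg_aud
  check_number(price, "price", min = 0, len = length(price))
  if (mode == "amortized") {
    price * (1 + item$installation_fraction) / item$lifespan_years +
      item$maintenance_fraction * price
  } else {
    replace_year <- (year_offset %% item$lifespan_years) == 0
    price * (1 + item$installation_fraction) * as.numeric(replace_year) +
      item$maintenance_fraction * price
  }
}

# internal: annual cost of every catalog item under one scenario, named by
# item id (vectorised over the catalog)
catalog_item_costs <- function(catalog, scenario, mode = "amortized",
                               year_offset = 0) {
  stats::setNames(
    annual_item_cost(catalog, scenario, mode = mode,
                     year_offset = year_offset),
    catalog$item_id)
}

#' Annual technology cost for one person with a given disease combination
#'
#' Sums [annual_item_cost()] over the person's device bundle
#' ([bundle_for()]).
#'
#' @param combination disease ids (or canonical key) for this person.
#' @param catalog a [technology_catalog()].
#' @param bundles a [bundle_map()].
#' @param scenario,mode,year_offset passed to [annual_item_cost()].
#' @return AUD per person per year.
#' @export
person_annual_cost <- function(combination, catalog, bundles,
                               scenario = c("low", "average"),
                               mode = "amortized", year_offset = 0) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(catalog, "technology_catalog"))
  ids <- bundle_for(combination, bundles)
  if (!length(ids)) return(0)
  unknown <- setdiff(ids, catalog$item_id)
  if (length(unknown)) {
    stop("bundle item(s) absent from catalog: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  costs <- catalog_item_costs(catalog, scenario, mode, year_offset)
  sum(costs[ids])
}

#' Population cost report across years, categories and price scenarios
#'
#' For every stratum (specific disease combination) the per-person annual
#' cost is multiplied by the stratum's unrounded person count; strata are
#' then summed within the four care-needs categories (0, 1, 2, 3+ chronic
#' diseases), and a grand total row per year and scenario is appended.
#' Per-capita figures divide by the unrounded category population.
#'
#' @param allocations named list, one [allocate()] result per report year
#'   (names are the years).
#' @param catalog a [technology_catalog()].
#' @param bundles a [bundle_map()].
#' @param scenarios character subset of `c("low", "average")`.
#' @param mode cost timing mode, `"amortized"` or `"cashflow"`; in
#'   cash-flow mode `year_offset` for a report year is its distance from
#'   the first report year.
#' @return data.frame of class `cost_report`: `year`, `category` (`"0"`,
#'   `"1"`, `"2"`, `"3plus"`, `"all"`), `scenario`, `population`,
#'   `total_aud`, `per_capita_aud` (both unrounded; round for display with
#'   [round_half_up()]).
#' @export
aggregate_costs <- function(allocations, catalog, bundles,
                            scenarios = c("low", "average"),
                            mode = "amortized") {
  stopifnot(is.list(allocations), length(allocations) > 0,
            !is.null(names(allocations)))
  scenarios <- match.arg(scenarios, several.ok = TRUE)
  years <- names(allocations)
  first_year <- suppressWarnings(min(as.numeric(years)))
  rows <- list()
  for (y in years) {
    alloc <- allocations[[y]]
    stopifnot(inherits(alloc, "combination_allocation"))
    offset <- if (is.finite(first_year)) as.numeric(y) - first_year else 0
    combos <- unique(alloc$strata$combination)
    for (sc in scenarios) {
      item_costs <- catalog_item_costs(catalog, sc, mode, offset)
      combo_cost <- vapply(combos, function(k) {
        ids <- bundle_for(k, bundles)
        if (!length(ids)) return(0)
        unknown <- setdiff(ids, catalog$item_id)
        if (length(unknown)) {
          stop("stratum ", k, " references unknown item(s): ",
               paste(unknown, collapse = ", "), call. = FALSE)
        }
        sum(item_costs[ids])
      }, numeric(1))
      st <- alloc$strata
      st$cost <- st$persons * combo_cost[st$combination]
      for (cat in c("0", "1", "2", "3plus")) {
        sel <- st$n_diseases == cat
        pop <- alloc$categories[[cat]]
        tot <- sum(st$cost[sel])
        rows[[length(rows) + 1L]] <- data.frame(
          year = y, category = cat, scenario = sc, population = pop,
          total_aud = tot,
          per_capita_aud = if (pop > 0) tot / pop else NA_real_,
          stringsAsFactors = FALSE)
      }
      pop_all <- sum(alloc$categories)
      rows[[length(rows) + 1L]] <- data.frame(
        year = y, category = "all", scenario = sc, population = pop_all,
        total_aud = sum(st$cost),
        per_capita_aud = if (pop_all > 0) sum(st$cost) / pop_all else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cost_report", "data.frame")
  out
}

#' Per-capita annual cost
#'
#' Divides a total by an unrounded population. The divisor must be kept at
#' full precision (e.g. 11097.955 persons, not the displayed 11098):
#' published per-capita figures are only recoverable from unrounded
#' denominators.
#'
#' @param total AUD per year (>= 0).
#' @param population persons (> 0), unrounded.
#' @param rounding `"display"` (default) rounds half-up to whole AUD, as
#'   figures are published; `"none"` returns the exact quotient.
#' @return AUD per person per year.
#' @export
#' @examples
#' per_capita(46263591, 11097.955)  # 4169
per_capita <- function(total, population, rounding = c("display", "none")) {
  rounding <- match.arg(rounding)
  check_number(total, "total", min = 0)
  check_number(population, "population")
  if (population <= 0) {
    stop("`population` must be > 0 for a per-capita cost", call. = FALSE)
  }
  q <- total / population
  if (rounding == "display") round_half_up(q) else q
}

#' @export
print.cost_report <- function(x, ...) {
  disp <- x
  disp$population <- round_half_up(disp$population)
  disp$total_aud <- round_half_up(disp$total_aud)
  disp$per_capita_aud <- round_half_up(disp$per_capita_aud)
  cat("Cost report (", length(unique(x$year)), "year(s),",
      length(unique(x$scenario)), "scenario(s) )\n")
  print(as.data.frame(disp), ...)
  invisible(x)
}
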