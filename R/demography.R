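#' @section Age bands:
#' Populations and death rates are tabulated on five-year age bands written
#' `"65-69"`, with a single open-ended top band written `"85+"`. Bands are
#' disjoint and ordered by their lower bound.
#' @name demography
#' @keywords internal
NULL

#' Parse age-band labels
#'
#' @param label character vector of band labels such as `"65-69"` or `"85+"`.
#' @return data.frame with columns `label`, `lower`, `upper` (`Inf` for an
#'   open-ended band).
#' @export
parse_age_band <- function(label) {
  label <- trimws(as.character(label))
  open <- grepl("^[0-9]+\\+$", label)
  closed <- grepl("^[0-9]+-[0-9]+$", label)
  bad <- !(open | closed)
  if (any(bad)) {
    stop("unparseable age band label(s): ",
         paste(unique(label[bad]), collapse = ", "), call. = FALSE)
  }
  lower <- as.integer(sub("[-+].*$", "", label))
  upper <- rep(Inf, length(label))
  upper[closed] <- as.integer(sub("^[0-9]+-", "", label[closed]))
  if (any(!open & upper - lower != 4L)) {
    stop("closed age bands must span exactly 5 years: ",
         paste(label[!open & upper - lower != 4L], collapse = ", "),
         call. = FALSE)
  }
  if (any(!open & lower >= upper)) {
    stop("age band lower bound must be below upper bound", call. = FALSE)
  }
  data.frame(label = label, lower = lower, upper = upper,
             stringsAsFactors = FALSE)
}

# internal: order band labels by lower bound, open band last
order_bands <- function(labels) {
  b <- parse_age_band(unique(labels))
  b$label[order(b$lower)]
}

#' Fit a linear time trend by ordinary least squares
#'
#' Used to project age-specific death rates (and any other slowly moving
#' demographic rate) forward from a handful of census observations.
#'
#' @param years numeric vector of observation years.
#' @param values numeric vector of observed values, same length.
#' @return object of class `trend_model` with fields `intercept` (fitted
#'   value at `reference_year`), `slope` (change per year) and
#'   `reference_year` (the mean observation year).
#' @export
#' @examples
#' m <- fit_linear_trend(c(2006, 2011, 2016), c(4.40, 4.20, 4.10))
#' predict(m, year = 2021)
fit_linear_trend <- function(years, values) {
  if (length(years) != length(values)) {
    stop("`years` and `values` must have the same length", call. = FALSE)
  }
  check_number(years, "years", len = length(years))
  check_number(values, "values", len = length(values))
  if (length(unique(years)) < 2L) {
    stop("degenerate input: need observations at >= 2 distinct years",
         call. = FALSE)
  }
  ref <- mean(years)
  fit <- stats::lm(values ~ I(years - ref))
  co <- stats::coef(fit)
  structure(
    list(intercept = unname(co[1L]), slope = unname(co[2L]),
         reference_year = ref),
    class = "trend_model"
  )
}

#' @describeIn fit_linear_trend predict the trend at new years.
#' @param object a `trend_model`.
#' @param year numeric vector of years to predict at.
#' @param ... unused.
#' @export
predict.trend_model <- function(object, year, ...) {
  check_number(year, "year", len = length(year))
  object$intercept + object$slope * (year - object$reference_year)
}

#' @export
print.trend_model <- function(x, ...) {
  cat(sprintf("Linear trend: %.6g %+.6g * (year - %s)\n",
              x$intercept, x$slope, format(x$reference_year)))
  invisible(x)
}

#' Advance one cohort through annual survival and net migration
#'
#' Applies, once per year, the survival factor `1 - death_rate/1000`
#' followed by the addition of `annual_net_migration` persons. The count is
#' clamped at zero (out-migration cannot empty a cohort below nothing).
#'
#' @param count persons in the cohort at the start (>= 0).
#' @param death_rate deaths per 1,000 persons per year (>= 0); either a
#'   scalar applied every year or a vector of length `years`.
#' @param years integer number of annual steps (>= 0).
#' @param annual_net_migration persons added per year (may be negative).
#' @return surviving persons after `years` annual steps, full precision.
#' @export
#' @examples
#' advance_cohort(1000, 10, 5)       # ~ 1000 * 0.99^5
#' advance_cohort(1000, 10, 5, 10)   # fixed point: loss 10/yr offset
advance_cohort <- function(count, death_rate, years, annual_net_migration = 0) {
  check_number(count, "count", min = 0)
  check_number(years, "years", min = 0)
  if (years != floor(years)) stop("`years` must be an integer", call. = FALSE)
  years <- as.integer(years)
  if (!length(death_rate) %in% c(1L, max(years, 1L))) {
    stop("`death_rate` must be scalar or one value per year", call. = FALSE)
  }
  check_number(death_rate, "death_rate", min = 0, len = length(death_rate))
  check_number(annual_net_migration, "annual_net_migration")
  rates <- rep_len(death_rate, length.out = max(years, 0L))
  for (i in seq_len(years)) {
    count <- max(count * (1 - rates[i] / 1000) + annual_net_migration, 0)
  }
  count
}

#' Percentage growth between two population counts
#'
#' @param initial starting persons (> 0).
#' @param final ending persons.
#' @return growth as a percentage, `100 * (final - initial) / initial`.
#' @export
#' @examples
#' growth_percent(30314, 43824)  # 44.57
growth_percent <- function(initial, final) {
  check_number(initial, "initial")
  check_number(final, "final")
  if (initial <= 0) {
    stop("`initial` population must be > 0 to compute growth", call. = FALSE)
  }
  100 * (final - initial) / initial
}

# internal: death rate for (band, year), using the printed schedule cell when
# present and a per-band linear trend otherwise; never negative
mortality_at <- function(schedule, band, year) {
  hit <- schedule$age_band == band & schedule$year == year
  if (any(hit)) return(schedule$deaths_per_1000[hit][1L])
  rows <- schedule[schedule$age_band == band, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop(sprintf("mortality schedule has no rates for band %s", band),
         call. = FALSE)
  }
  if (length(unique(rows$year)) < 2L) return(rows$deaths_per_1000[1L])
  max(predict(fit_linear_trend(rows$year, rows$deaths_per_1000), year), 0)
}

#' Collapse a mortality schedule's top bands into one open-ended band
#'
#' Published death-rate tables often split the oldest ages (85-89, 90-94)
#' while population tables stop at an open 85+ band. This helper rewrites
#' the schedule onto the population table's top band.
#'
#' @param schedule data.frame with columns `year`, `age_band`,
#'   `deaths_per_1000`.
#' @param top_label label of the open band, default `"85+"`.
#' @param method `"first"` keeps the youngest collapsed band's rate (the
#'   bulk of an 85+ cohort sits in 85-89); `"mean"` averages the collapsed
#'   bands.
#' @return schedule with the bands at or above the open band's lower bound
#'   replaced by a single `top_label` row per year.
#' @export
collapse_top_band <- function(schedule, top_label = "85+",
                              method = c("first", "mean")) {
  method <- match.arg(method)
  lower <- parse_age_band(top_label)$lower
  bands <- parse_age_band(unique(schedule$age_band))
  over <- bands$label[bands$lower >= lower]
  keep <- schedule[!schedule$age_band %in% over, , drop = FALSE]
  top <- schedule[schedule$age_band %in% over, , drop = FALSE]
  if (nrow(top) == 0L) return(schedule)
  agg <- if (method == "first") {
    first_band <- bands$label[bands$lower == min(bands$lower[bands$lower >= lower])]
    top <- top[top$age_band == first_band, , drop = FALSE]
    stats::aggregate(deaths_per_1000 ~ year, top, FUN = identity)
  } else {
    stats::aggregate(deaths_per_1000 ~ year, top, FUN = mean)
  }
  agg$age_band <- top_label
  out <- rbind(keep, agg[, c("year", "age_band", "deaths_per_1000")])
  out[order(out$year, out$age_band), ]
}

#' Progressive (cohort-survival) population forecast
#'
#' Advances five-year age cohorts through five-year steps: each closed band
#' at year t+5 derives from the next-younger band at year t via
#' [advance_cohort()]; the open-ended top band additionally retains its own
#' survivors. Regional net migration (overseas + interstate rates applied to
#' the whole regional population) is apportioned across the 65+ bands in
#' proportion to the size of each destination band's feeder cohort.
#'
#' No births are modelled: over a 10-year horizon the 65+ bands are fed
#' entirely by cohorts already aged 55+ at the base year, which is why the
#' base table must include every band from 55-59 upward.
#'
#' @param base data.frame with columns `age_band`, `persons`: the base-year
#'   population from 55-59 up to the open top band.
#' @param schedule mortality data.frame (`year`, `age_band`,
#'   `deaths_per_1000`) on the same bands as `base` (see
#'   [collapse_top_band()]); years missing from the schedule are projected
#'   by per-band linear trends.
#' @param base_year integer base year.
#' @param horizon_years forecast horizon, a positive multiple of 5.
#' @param nom_rate,nim_rate net overseas / interstate migration, as annual
#'   fractions of the regional population (e.g. `-0.00006` for -0.006%).
#' @param regional_population optional data.frame (`year`, `persons`) giving
#'   the whole region's population at each forecast year, used to convert
#'   migration rates into person counts. When `NULL` the rates are applied
#'   to the 65+ subtotal itself.
#' @param rate_convention which band's death rate governs a 5-year
#'   advancement: the destination band's rate at the destination year
#'   (default), the origin band's rate at the origin year, or their mean.
#' @return data.frame (`year`, `age_band`, `persons`) covering the base year
#'   and every 5-year forecast year; bands that can no longer be fed from
#'   below drop out of later years.
#' @export
forecast_population <- function(base, schedule, base_year, horizon_years,
                                nom_rate = 0, nim_rate = 0,
                                regional_population = NULL,
                                rate_convention = c("destination", "origin",
                                                    "mean")) {
  rate_convention <- match.arg(rate_convention)
  check_number(base_year, "base_year")
  check_number(horizon_years, "horizon_years", min = 0)
  if (horizon_years %% 5 != 0) {
    stop("`horizon_years` must be a multiple of 5", call. = FALSE)
  }
  check_number(nom_rate, "nom_rate", min = -1, max = 1)
  check_number(nim_rate, "nim_rate", min = -1, max = 1)
  stopifnot(is.data.frame(base), all(c("age_band", "persons") %in% names(base)))
  if (any(base$persons < 0)) stop("base counts must be >= 0", call. = FALSE)

  labels <- order_bands(base$age_band)
  info <- parse_age_band(labels)
  if (sum(!is.finite(info$upper)) != 1L || !is.infinite(info$upper[nrow(info)])) {
    stop("`base` must contain exactly one open-ended top band", call. = FALSE)
  }
  if (nrow(info) > 1L) {
    gap <- which(diff(info$lower) != 5L)
    if (length(gap)) {
      stop(sprintf("missing feeder band between %s and %s",
                   info$label[gap[1L]], info$label[gap[1L] + 1L]),
           call. = FALSE)
    }
  }
  pop <- stats::setNames(base$persons[match(labels, base$age_band)], labels)
  top <- labels[length(labels)]
  mig_rate <- nom_rate + nim_rate

  out <- data.frame(year = base_year, age_band = labels,
                    persons = unname(pop), stringsAsFactors = FALSE)
  cur_labels <- labels
  for (step in seq_len(horizon_years / 5)) {
    t0 <- base_year + 5 * (step - 1L)
    t1 <- t0 + 5L
    # destination bands this step: everything with a feeder below it, plus
    # the open band, which always retains its own survivors
    if (length(cur_labels) > 1L) {
      dest <- cur_labels[-1L]
      feeders <- stats::setNames(as.list(cur_labels[-length(cur_labels)]),
                                 dest)
      feeders[[top]] <- c(feeders[[top]], top)
    } else {
      dest <- top
      feeders <- stats::setNames(list(top), top)
    }
    lower65 <- parse_age_band(dest)$lower >= 65
    dest65 <- dest[lower65]
    feeder_size <- vapply(feeders[dest65], function(f) sum(pop[f]), numeric(1))
    annual_mig_total <- if (mig_rate == 0) 0 else {
      regpop <- if (is.null(regional_population)) sum(feeder_size) else {
        hit <- regional_population$persons[regional_population$year == t1]
        if (!length(hit)) {
          stop("`regional_population` has no entry for year ", t1,
               call. = FALSE)
        }
        hit[1L]
      }
      mig_rate * regpop
    }
    mig_share <- if (sum(feeder_size) > 0) {
      annual_mig_total * feeder_size / sum(feeder_size)
    } else stats::setNames(rep(0, length(dest65)), dest65)

    new_pop <- stats::setNames(numeric(length(dest)), dest)
    for (b in dest) {
      mig <- if (b %in% dest65) mig_share[[b]] else 0
      total <- 0
      for (f in feeders[[b]]) {
        rate_band <- switch(rate_convention, destination = b, origin = f,
                            mean = NA)
        rate_year <- switch(rate_convention, destination = t1, origin = t0,
                            mean = NA)
        r <- if (rate_convention == "mean") {
          (mortality_at(schedule, b, t1) + mortality_at(schedule, f, t0)) / 2
        } else if (f == top) {
          # survivors of the open band age within it
          mortality_at(schedule, top, rate_year)
        } else {
          mortality_at(schedule, rate_band, rate_year)
        }
        # migration enters once per destination band, via its first feeder
        m <- if (f == feeders[[b]][1L]) mig else 0
        total <- total + advance_cohort(pop[[f]], r, 5L, m)
      }
      new_pop[[b]] <- total
    }
    pop <- new_pop
    cur_labels <- dest
    out <- rbind(out, data.frame(year = t1, age_band = dest,
                                 persons = unname(new_pop),
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Total population aged 65 and over in a forecast table
#'
#' @param pop data.frame (`year`, `age_band`, `persons`) as returned by
#'   [forecast_population()].
#' @param min_age lower age cut, default 65.
#' @return named numeric vector of 65+ totals by year.
#' @export
total_65plus <- function(pop, min_age = 65) {
  lower <- parse_age_band(pop$age_band)$lower
  keep <- pop[lower >= min_age, , drop = FALSE]
  tot <- tapply(keep$persons, keep$year, sum)
  stats::setNames(as.numeric(tot), names(tot))
}
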