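#' Functional categories of assistive technologies
#'
#' @return the eight recognised function categories.
#' @export
function_categories <- function() {
  c("mobility", "vision", "hearing", "home_safety", "fitness",
    "health_monitoring", "cognition", "communication")
}

#' Validate a technology catalog
#'
#' A catalog row is one device: its function category, its lowest and
#' average observed retail price (AUD), and the life-cycle parameters used
#' by the cost engine — lifespan in years, annual maintenance as a fraction
#' of price, and one-off installation as a fraction of price.
#'
#' @param df data.frame with columns `item_id`, `name`,
#'   `function_category`, `price_low_aud`, `price_avg_aud`,
#'   `lifespan_years`, `maintenance_fraction`, `installation_fraction` and
#'   optionally `source_year`.
#' @return the validated data.frame with class `technology_catalog`.
#' @export
technology_catalog <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("item_id", "name", "function_category", "price_low_aud",
            "price_avg_aud", "lifespan_years", "maintenance_fraction",
            "installation_fraction")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("catalog is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$item_id)) {
    stop("duplicate item_id in catalog: ",
         paste(unique(df$item_id[duplicated(df$item_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_cat <- setdiff(unique(df$function_category), function_categories())
  if (length(bad_cat)) {
    stop("unknown function_category: ", paste(bad_cat, collapse = ", "),
         call. = FALSE)
  }
  check_number(df$price_low_aud, "price_low_aud", min = 0, len = nrow(df))
  check_number(df$price_avg_aud, "price_avg_aud", min = 0, len = nrow(df))
  if (any(df$price_low_aud > df$price_avg_aud)) {
    stop("price_low_aud must not exceed price_avg_aud (item ",
         df$item_id[which(df$price_low_aud > df$price_avg_aud)[1L]], ")",
         call. = FALSE)
  }
  if (any(df$price_low_aud <= 0)) {
    stop("prices must be > 0 (item ",
         df$item_id[which(df$price_low_aud <= 0)[1L]], ")", call. = FALSE)
  }
  if (any(df$lifespan_years <= 0)) {
    stop("lifespan_years must be > 0", call. = FALSE)
  }
  check_fraction(df$maintenance_fraction, "maintenance_fraction",
                 len = nrow(df))
  check_fraction(df$installation_fraction, "installation_fraction",
                 len = nrow(df))
  class(df) <- c("technology_catalog", "data.frame")
  df
}

#' Map diseases to device bundles
#'
#' The basic bundle lists devices every older person is assumed to use
#' regardless of chronic disease (safety, mobility, fitness); each
#' disease's bundle lists the condition-specific devices (typically
#' monitoring). A person's full bundle is the union, so shared devices are
#' never double-counted.
#'
#' @param basic character vector of item ids in the basic bundle.
#' @param diseases named list (one entry per disease id) of character
#'   vectors of item ids.
#' @param catalog optional [technology_catalog()] against which every
#'   referenced id is checked.
#' @return list of class `bundle_map` with elements `basic` and `diseases`.
#' @export
bundle_map <- function(basic, diseases, catalog = NULL) {
  stopifnot(is.character(basic), is.list(diseases))
  if (is.null(names(diseases)) || any(!nzchar(names(diseases)))) {
    stop("`diseases` must be a fully named list", call. = FALSE)
  }
  empty <- names(diseases)[!vapply(diseases, length, integer(1))]
  if (length(basic) == 0L || length(empty)) {
    stop("bundles must be non-empty (offenders: ",
         paste(c(if (!length(basic)) "basic", empty), collapse = ", "), ")",
         call. = FALSE)
  }
  if (!is.null(catalog)) {
    all_ids <- unique(c(basic, unlist(diseases, use.names = FALSE)))
    unknown <- setdiff(all_ids, catalog$item_id)
    if (length(unknown)) {
      stop("bundle references item id(s) absent from catalog: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(basic = unique(basic),
                 diseases = lapply(diseases, unique)),
            class = "bundle_map")
}

#' Deflate a price to an earlier base year
#'
#' Converts a price observed at a later year back to base-year dollars by
#' dividing out compound annual inflation; exact inverse of compounding the
#' base-year price forward.
#'
#' @param price price at the source year (>= 0).
#' @param annual_inflation annual inflation as a fraction (> -1).
#' @param years whole years between base year and source year (>= 0).
#' @return price expressed in base-year dollars.
#' @export
#' @examples
#' deflate_price(100, 0.02, 2)  # 96.12
deflate_price <- function(price, annual_inflation, years) {
  check_number(price, "price", min = 0, len = length(price))
  check_number(annual_inflation, "annual_inflation")
  if (annual_inflation <= -1) {
    stop("`annual_inflation` must be > -1", call. = FALSE)
  }
  check_number(years, "years", min = 0)
  price / (1 + annual_inflation)^years
}

#' Device bundle for a disease combination
#'
#' @param combination character vector of disease ids (empty for the
#'   no-chronic-disease group) or a canonical `"a+b"` key.
#' @param bundles a [bundle_map()].
#' @return sorted character vector of item ids: the basic bundle plus the
#'   union of each member disease's bundle.
#' @export
#' @examples
#' bm <- bundle_map(basic = "falls", diseases = list(cvd = c("ecg", "bp")))
#' bundle_for("cvd", bm)
bundle_for <- function(combination, bundles) {
  stopifnot(inherits(bundles, "bundle_map"))
  if (length(combination) == 1L && grepl("+", combination, fixed = TRUE)) {
    combination <- combo_split(combination)
  }
  if (length(combination) == 1L && combination %in% c("none", "")) {
    combination <- character(0)
  }
  unknown <- setdiff(combination, names(bundles$diseases))
  if (length(unknown)) {
    stop("no bundle defined for disease id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  sort(unique(c(bundles$basic,
                unlist(bundles$diseases[combination], use.names = FALSE))))
}
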