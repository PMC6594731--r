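#' Proportion living in households who need assistance
#'
#' Combines the two survey marginals for an age band — the proportion
#' needing assistance with at least one daily activity, and the proportion
#' living in households (as opposed to cared accommodation) — into the
#' proportion both living at home and needing assistance, assuming the two
#' attributes combine multiplicatively within a band.
#'
#' @param p_need fraction needing assistance with at least one activity.
#' @param p_household fraction living in households.
#' @return fraction living in households and needing assistance
#'   (`p_need * p_household`), full precision.
#' @export
#' @examples
#' household_assist_rate(0.568, 0.923)  # 0.5243 (52.43%)
household_assist_rate <- function(p_need, p_household) {
  check_fraction(p_need, "p_need", len = length(p_need))
  check_fraction(p_household, "p_household", len = length(p_household))
  p_need * p_household
}

#' Assisted population from a total and an overall assistance rate
#'
#' The cost model's denominator: persons 65+ living in households who need
#' help with at least one daily activity. Full precision is retained; round
#' only for display (see [round_half_up()]).
#'
#' @param total_65plus persons aged 65 and over (>= 0).
#' @param overall_rate overall household-and-assistance fraction. The
#'   shipped Australian survey value is 0.3661; it is kept as a scalar input
#'   rather than recomputed from rounded marginals, whose product (38.6% x
#'   94.8% = 36.59%) differs by a rounding artifact.
#' @return assisted persons, unrounded.
#' @export
#' @examples
#' aggregate_assisted(30314, 0.3661)  # 11097.955 -> displays as 11098
aggregate_assisted <- function(total_65plus, overall_rate = 0.3661) {
  check_number(total_65plus, "total_65plus", min = 0,
               len = length(total_65plus))
  check_fraction(overall_rate, "overall_rate")
  total_65plus * overall_rate
}

#' Assistance profile by age band
#'
#' Validates a table of per-band assistance and residence fractions.
#'
#' @param df data.frame with columns `age_band`, `p_need_assist`,
#'   `p_household` and optionally `p_household_and_need` (the published
#'   combined row, kept for cross-checks) and `p_cared_accommodation`.
#' @return the validated data.frame, class `assistance_profile`.
#' @export
assistance_profile <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("age_band", "p_need_assist", "p_household")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("assistance profile is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in intersect(c("p_need_assist", "p_household",
                          "p_household_and_need", "p_cared_accommodation"),
                        names(df))) {
    check_fraction(df[[col]], col, len = nrow(df))
  }
  if (all(c("p_household", "p_cared_accommodation") %in% names(df))) {
    gap <- abs(df$p_household + df$p_cared_accommodation - 1)
    if (any(gap > 0.01)) {
      warning("p_household + p_cared_accommodation deviates from 1 by > 0.01 ",
              "in band(s): ",
              paste(df$age_band[gap > 0.01], collapse = ", "), call. = FALSE)
    }
  }
  class(df) <- c("assistance_profile", "data.frame")
  df
}
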