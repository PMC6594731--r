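# Shipped case-study tables, loaded once per test run.
fcw <- fcw_published_inputs()

# A tiny fully hand-checkable catalog: every derived cost can be summed by
# hand in the tests.
tiny_catalog <- function() {
  technology_catalog(data.frame(
    item_id = c("falls", "ecg", "bp", "glucose", "puzzle"),
    name = paste("synthetic", c("fall detector", "ecg monitor",
                                "bp monitor", "glucose meter",
                                "cognition trainer")),
    function_category = c("home_safety", "health_monitoring",
                          "health_monitoring", "health_monitoring",
                          "cognition"),
    price_low_aud = c(100, 1000, 200, 150, 50),
    price_avg_aud = c(200, 1500, 400, 300, 80),
    lifespan_years = 5,
    maintenance_fraction = 0.15,
    installation_fraction = 0.05,
    source_year = 2018,
    stringsAsFactors = FALSE))
}

tiny_bundles <- function() {
  bundle_map(
    basic = "falls",
    diseases = list(arthritis = "puzzle", asthma = "bp", back = "puzzle",
                    cancer = "bp", copd = "bp", diabetes = "glucose",
                    cvd = c("ecg", "bp"), mental = "puzzle"),
    catalog = tiny_catalog())
}

# Amortized annual cost written out longhand, as the independent check on
# annual_item_cost(): price*(1+install)/life + maint*price.
hand_item_cost <- function(price, life = 5, maint = 0.15, install = 0.05) {
  price * (1 + install) / life + maint * price
}

# Grid-search least-squares minimiser over the slope (with the intercept at
# the centred-mean optimum), independent of the closed-form OLS path: the
# slope grid is repeatedly refined around the best cell.
grid_ols <- function(years, values, iters = 30, width = NULL) {
  xc <- years - mean(years)
  yc <- values - mean(values)
  if (is.null(width)) width <- max(abs(yc)) / max(abs(xc)) * 4 + 1
  centre <- 0
  for (i in seq_len(iters)) {
    grid <- seq(centre - width, centre + width, length.out = 41)
    sse <- vapply(grid, function(b) sum((yc - b * xc)^2), numeric(1))
    centre <- grid[which.min(sse)]
    width <- width / 10
  }
  list(slope = centre, intercept = mean(values), reference_year = mean(years))
}
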