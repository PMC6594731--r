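#' Exact disease-set distribution of the log-linear pairwise model
#'
#' The synthetic multimorbidity model: each person's set of chronic
#' diseases follows a log-linear model with independent per-disease
#' prevalences tilted by pairwise odds multipliers,
#' `P(x) ~ prod_i p_i^x_i (1-p_i)^(1-x_i) * prod_{i<j} theta_ij^(x_i x_j)`.
#' With 8 diseases the 256-point outcome space is enumerated exactly, so
#' sampled frequencies can be checked against closed-form probabilities.
#'
#' @param prevalences named vector of marginal-style prevalences in `[0, 1]`
#'   (the `p_i`; exact marginals only when all multipliers are 1).
#' @param pair_odds optional symmetric matrix of positive odds multipliers
#'   (`theta_ij`), dimnames matching `prevalences`; default all 1
#'   (independence).
#' @return list of class `disease_set_distribution`: `outcomes` (logical
#'   matrix, one row per outcome), `prob` (normalised probabilities),
#'   `keys` (canonical combination keys), `diseases`.
#' @export
disease_set_distribution <- function(prevalences, pair_odds = NULL) {
  diseases <- names(prevalences)
  if (is.null(diseases)) {
    stop("`prevalences` must be named by disease id", call. = FALSE)
  }
  check_fraction(unname(prevalences), "prevalences",
                 len = length(prevalences))
  d <- length(diseases)
  if (d > 16) stop("exact enumeration limited to 16 diseases", call. = FALSE)
  if (is.null(pair_odds)) {
    pair_odds <- matrix(1, d, d, dimnames = list(diseases, diseases))
  }
  pair_odds <- pair_odds[diseases, diseases]
  if (any(pair_odds <= 0)) {
    stop("pairwise odds multipliers must be > 0", call. = FALSE)
  }
  if (!isTRUE(all.equal(pair_odds, t(pair_odds)))) {
    stop("`pair_odds` must be symmetric", call. = FALSE)
  }
  outcomes <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), d)))
  colnames(outcomes) <- diseases
  w <- apply(outcomes, 1L, function(x) {
    base <- prod(ifelse(x, prevalences, 1 - prevalences))
    if (base == 0) return(0)
    on_idx <- which(x)
    tilt <- 1
    if (length(on_idx) >= 2L) {
      pr <- utils::combn(on_idx, 2L)
      tilt <- prod(pair_odds[cbind(pr[1L, ], pr[2L, ])])
    }
    base * tilt
  })
  if (sum(w) <= 0) stop("degenerate model: all outcomes have weight 0",
                        call. = FALSE)
  keys <- apply(outcomes, 1L, function(x) combo_key(diseases[x]))
  structure(list(outcomes = outcomes, prob = w / sum(w), keys = keys,
                 diseases = diseases),
            class = "disease_set_distribution")
}

#' Exact pairwise co-occurrence probabilities of a disease-set model
#'
#' @param dist a [disease_set_distribution()].
#' @return named vector over the canonical pair keys:
#'   `P(both diseases present)`.
#' @export
exact_pair_probs <- function(dist) {
  stopifnot(inherits(dist, "disease_set_distribution"))
  pairs <- utils::combn(dist$diseases, 2L, simplify = FALSE)
  out <- vapply(pairs, function(p) {
    sum(dist$prob[dist$outcomes[, p[1L]] & dist$outcomes[, p[2L]]])
  }, numeric(1))
  names(out) <- vapply(pairs, combo_key, character(1))
  out
}

#' Sample synthetic individuals' disease sets
#'
#' Draws `n` disease sets from the exact log-linear distribution
#' ([disease_set_distribution()]); bit-reproducible for a given seed.
#'
#' @param n number of individuals (> 0).
#' @param prevalences,pair_odds model parameters, see
#'   [disease_set_distribution()].
#' @param seed integer seed (required for reproducibility; `NULL` uses the
#'   session RNG stream).
#' @return list of `n` character vectors, each a (possibly empty) subset of
#'   the disease ids.
#' @export
synth_individuals <- function(n, prevalences, pair_odds = NULL, seed = NULL) {
  check_number(n, "n", min = 1)
  dist <- disease_set_distribution(prevalences, pair_odds)
  idx <- with_local_seed(seed, {
    sample.int(length(dist$prob), size = n, replace = TRUE, prob = dist$prob)
  })
  lapply(idx, function(i) dist$diseases[dist$outcomes[i, ]])
}

#' Tabulate individuals into the pipeline's input shapes
#'
#' Reconstructs, from individual-level disease sets, the three aggregate
#' inputs the allocation stage consumes: the disease-count distribution
#' (pools for 0/1/2/3+ diseases), the single-disease column (persons with
#' exactly one disease, by disease), and the pairwise co-occurrence matrix
#' (every within-person pair counted once, so a person with three diseases
#' contributes three cells — the same double-counting convention as
#' published comorbidity matrices).
#'
#' @param individuals list of character disease-set vectors.
#' @param diseases disease ids; defaults to [chronic_diseases()].
#' @return list with `dist` (a [disease_count_distribution()] in persons),
#'   `single_counts` (named vector) and `matrix` (a
#'   [comorbidity_matrix()]).
#' @export
tabulate_individuals <- function(individuals, diseases = chronic_diseases()) {
  if (!length(individuals)) stop("no individuals to tabulate", call. = FALSE)
  sizes <- lengths(individuals)
  pools <- c("0" = sum(sizes == 0), "1" = sum(sizes == 1),
             "2" = sum(sizes == 2), "3plus" = sum(sizes >= 3))
  singles <- stats::setNames(numeric(length(diseases)), diseases)
  ones <- unlist(individuals[sizes == 1L], use.names = FALSE)
  if (length(ones)) {
    tab <- table(factor(ones, levels = diseases))
    singles[] <- as.numeric(tab)
  }
  m <- matrix(0, length(diseases), length(diseases),
              dimnames = list(diseases, diseases))
  marg <- stats::setNames(numeric(length(diseases)), diseases)
  for (set in individuals) {
    marg[set] <- marg[set] + 1
    if (length(set) >= 2L) {
      pr <- utils::combn(set, 2L)
      for (j in seq_len(ncol(pr))) {
        m[pr[1L, j], pr[2L, j]] <- m[pr[1L, j], pr[2L, j]] + 1
        m[pr[2L, j], pr[1L, j]] <- m[pr[2L, j], pr[1L, j]] + 1
      }
    }
  }
  list(dist = disease_count_distribution(pools, total = length(individuals)),
       single_counts = singles,
       matrix = comorbidity_matrix(m, marginals = marg,
                                   diseases = diseases))
}

#' Generate a synthetic technology catalog and bundle map
#'
#' A clearly synthetic stand-in for a retail price survey of assistive
#' devices (the published survey's price list is not reproduced here): per
#' function category, `items_per_category` devices with the low price drawn
#' uniformly from the category's price range and the average price a
#' uniform 1.2-3x multiple of the low price. Every item carries the
#' standard life-cycle assumptions (5-year lifespan, 15%/yr maintenance,
#' 5% installation). Each disease is assigned 2-6 items from the
#' monitoring-oriented categories (health monitoring, cognition,
#' communication, hearing, vision); the basic bundle draws from home
#' safety, mobility and fitness.
#'
#' @param seed integer seed; identical seeds give identical catalogs.
#' @param price_ranges named list of `c(min, max)` AUD per function
#'   category; a sensible default spans cheap wearables to powered
#'   mobility aids.
#' @param items_per_category devices generated per category (default 3).
#' @param lifespan_years,maintenance_fraction,installation_fraction
#'   life-cycle defaults applied to every generated item.
#' @param source_year nominal price-collection year recorded on each item.
#' @return list with `catalog` (a [technology_catalog()]) and `bundles`
#'   (a [bundle_map()]).
#' @export
synth_catalog <- function(seed = NULL, price_ranges = NULL,
                          items_per_category = 3, lifespan_years = 5,
                          maintenance_fraction = 0.15,
                          installation_fraction = 0.05,
                          source_year = 2018) {
  cats <- function_categories()
  if (is.null(price_ranges)) {
    price_ranges <- list(
      mobility = c(300, 6000), vision = c(50, 1500), hearing = c(100, 4000),
      home_safety = c(80, 1200), fitness = c(150, 2500),
      health_monitoring = c(60, 2000), cognition = c(50, 1000),
      communication = c(100, 1500))
  }
  miss <- setdiff(cats, names(price_ranges))
  if (length(miss)) {
    stop("price_ranges missing categor(ies): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- names(price_ranges)[!vapply(price_ranges, function(r)
    length(r) == 2 && r[1] > 0 && r[1] <= r[2], logical(1))]
  if (length(bad)) {
    stop("invalid price range for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  check_number(items_per_category, "items_per_category", min = 1)
  with_local_seed(seed, {
    rows <- list()
    for (fc in cats) {
      r <- price_ranges[[fc]]
      for (i in seq_len(items_per_category)) {
        low <- stats::runif(1, r[1], r[2])
        rows[[length(rows) + 1L]] <- data.frame(
          item_id = sprintf("%s_%02d", fc, i),
          name = sprintf("synthetic %s device %d", gsub("_", " ", fc), i),
          function_category = fc,
          price_low_aud = round(low, 2),
          price_avg_aud = round(low * stats::runif(1, 1.2, 3), 2),
          lifespan_years = lifespan_years,
          maintenance_fraction = maintenance_fraction,
          installation_fraction = installation_fraction,
          source_year = source_year, stringsAsFactors = FALSE)
      }
    }
    catalog <- technology_catalog(do.call(rbind, rows))
    monitoring <- catalog$item_id[catalog$function_category %in%
      c("health_monitoring", "cognition", "communication", "hearing",
        "vision")]
    basic_pool <- catalog$item_id[catalog$function_category %in%
      c("home_safety", "mobility", "fitness")]
    basic <- sort(sample(basic_pool, min(3L, length(basic_pool))))
    disease_bundles <- lapply(stats::setNames(chronic_diseases(),
                                              chronic_diseases()),
      function(d) {
        k <- sample(2:6, 1L)
        sort(sample(monitoring, min(k, length(monitoring))))
      })
    list(catalog = catalog,
         bundles = bundle_map(basic, disease_bundles, catalog = catalog))
  })
}
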