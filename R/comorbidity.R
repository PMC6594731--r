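#' The eight common chronic diseases
#'
#' Canonical identifiers for the eight chronic diseases that dominate
#' multimorbidity among Australians aged 65+: arthritis, asthma, back
#' problems (dorsopathies), cancer, COPD, diabetes, cardiovascular disease,
#' and mental/behavioural problems.
#'
#' @return character vector of the 8 canonical ids.
#' @export
chronic_diseases <- function() {
  c("arthritis", "asthma", "back", "cancer", "copd", "diabetes", "cvd",
    "mental")
}

# internal: canonical name for a disease subset ("none" for the empty set)
combo_key <- function(diseases) {
  if (length(diseases) == 0L) return("none")
  paste(sort(diseases), collapse = "+")
}

# internal: split a canonical key back into a disease vector
combo_split <- function(key) {
  if (identical(key, "none") || !nzchar(key)) return(character(0))
  strsplit(key, "+", fixed = TRUE)[[1L]]
}

#' Distribution of the 65+ population by number of chronic diseases
#'
#' Pool sizes (conventionally in thousands of persons) for 0, 1, 2 and 3+
#' chronic diseases, plus the published total. Published tables can be
#' internally inconsistent at the final printed digit, so the sum check is
#' a warning with a configurable tolerance rather than an error.
#'
#' @param pools named numeric vector with names `"0"`, `"1"`, `"2"`,
#'   `"3plus"`.
#' @param total published total; defaults to `sum(pools)`.
#' @param tolerance allowed |sum(pools) - total| before warning.
#' @return list of class `disease_count_distribution` with `pools`, `total`
#'   and `shares` (pools / total, unnormalised).
#' @export
disease_count_distribution <- function(pools, total = sum(pools),
                                       tolerance = 1.0) {
  want <- c("0", "1", "2", "3plus")
  if (!all(want %in% names(pools))) {
    stop("`pools` must be named with ", paste(want, collapse = ", "),
         call. = FALSE)
  }
  pools <- pools[want]
  check_number(pools, "pools", min = 0, len = 4L)
  check_number(total, "total", min = 0)
  if (total <= 0) stop("distribution total must be > 0", call. = FALSE)
  if (abs(sum(pools) - total) > tolerance) {
    warning(sprintf(
      "category pools sum to %.1f but the stated total is %.1f", sum(pools),
      total), call. = FALSE)
  }
  structure(list(pools = pools, total = total, shares = pools / total),
            class = "disease_count_distribution")
}

#' Pairwise comorbidity matrix for the eight chronic diseases
#'
#' Symmetric co-occurrence counts (persons with both diseases, in
#' thousands), stored as an 8x8 matrix with a zero diagonal, plus the
#' per-disease marginal totals. Note the pair cells count everyone with
#' both diseases regardless of how many further diseases they have, so a
#' person with three diseases appears in three cells.
#'
#' @param counts either a symmetric numeric matrix with disease dimnames or
#'   a data.frame with columns `disease_a`, `disease_b`,
#'   `persons_thousands` (one row per unordered pair).
#' @param marginals optional named per-disease totals; defaults to the
#'   matrix row sums (which overcount relative to published marginals when
#'   higher-order comorbidity is present).
#' @param diseases disease ids; defaults to [chronic_diseases()].
#' @return object of class `comorbidity_matrix`: list with `counts` (matrix)
#'   and `marginals`.
#' @export
comorbidity_matrix <- function(counts, marginals = NULL,
                               diseases = chronic_diseases()) {
  if (is.data.frame(counts)) {
    need <- c("disease_a", "disease_b", "persons_thousands")
    miss <- setdiff(need, names(counts))
    if (length(miss)) {
      stop("pair table missing column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    m <- matrix(0, length(diseases), length(diseases),
                dimnames = list(diseases, diseases))
    for (i in seq_len(nrow(counts))) {
      a <- as.character(counts$disease_a[i])
      b <- as.character(counts$disease_b[i])
      if (!a %in% diseases || !b %in% diseases) {
        stop(sprintf("unknown disease id in pair row %d: %s/%s", i, a, b),
             call. = FALSE)
      }
      if (a == b) stop("self-pair in row ", i, call. = FALSE)
      m[a, b] <- m[a, b] + counts$persons_thousands[i]
      m[b, a] <- m[b, a] + counts$persons_thousands[i]
    }
    counts <- m
  }
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts))
  if (is.null(dimnames(counts))) dimnames(counts) <- list(diseases, diseases)
  if (!isTRUE(all.equal(counts, t(counts)))) {
    stop("comorbidity matrix must be symmetric", call. = FALSE)
  }
  if (any(counts < 0)) stop("comorbidity counts must be >= 0", call. = FALSE)
  diag(counts) <- 0
  if (is.null(marginals)) marginals <- rowSums(counts)
  marginals <- marginals[rownames(counts)]
  check_number(unname(marginals), "marginals", min = 0, len = nrow(counts))
  structure(list(counts = counts, marginals = marginals),
            class = "comorbidity_matrix")
}

#' @export
print.comorbidity_matrix <- function(x, ...) {
  cat("Comorbidity matrix over", nrow(x$counts), "diseases (",
      sum(x$counts[upper.tri(x$counts)]), "pair-count mass )\n")
  print(x$counts, ...)
  invisible(x)
}

#' Split an assisted population by number of chronic diseases
#'
#' @param assisted assisted persons (full precision, >= 0).
#' @param dist a [disease_count_distribution()].
#' @param mode `"published"` divides each pool by the published total, exactly
#'   as the source tables do (the categories may then sum slightly off the
#'   input when the source total is inconsistent); `"strict"` normalises by
#'   the pool sum so the categories conserve the assisted population.
#' @return named numeric vector of persons for `"0"`, `"1"`, `"2"`,
#'   `"3plus"`, unrounded.
#' @export
#' @examples
#' d <- disease_count_distribution(
#'   c("0" = 447.2, "1" = 872.6, "2" = 1004.3, "3plus" = 962.4),
#'   total = 3285.6)
#' round_half_up(categorize(11097.955, d))  # 1511 2947 3392 3251
categorize <- function(assisted, dist, mode = c("published", "strict")) {
  mode <- match.arg(mode)
  check_number(assisted, "assisted", min = 0)
  stopifnot(inherits(dist, "disease_count_distribution"))
  denom <- if (mode == "published") dist$total else sum(dist$pools)
  assisted * dist$pools / denom
}

#' Break the one-chronic-disease pool down by disease
#'
#' @param pool persons with exactly one chronic disease.
#' @param single_counts named per-disease counts from the
#'   one-chronic-disease column of the national survey (thousands).
#' @param single_total the column's published total; defaults to
#'   `sum(single_counts)`. Published tables may print a total that differs
#'   from the column sum; published mode preserves that inconsistency.
#' @param mode `"published"` rounds each disease's share to 0.1% before
#'   multiplying (as the published table's percent column does) and leaves
#'   shares unrenormalised; `"strict"` uses unrounded shares renormalised
#'   to sum to one.
#' @return named per-disease persons.
#' @export
breakdown_single <- function(pool, single_counts,
                             single_total = sum(single_counts),
                             mode = c("published", "strict")) {
  mode <- match.arg(mode)
  check_number(pool, "pool", min = 0)
  check_number(unname(single_counts), "single_counts", min = 0,
               len = length(single_counts))
  check_number(single_total, "single_total", min = 0)
  if (single_total <= 0) {
    stop("single-disease total must be > 0", call. = FALSE)
  }
  shares <- if (mode == "published") {
    round_half_up(single_counts / single_total, 3)
  } else {
    single_counts / sum(single_counts)
  }
  pool * shares
}

#' Normalised-ratio shares over the 28 disease pairs
#'
#' Each unordered pair's co-occurrence count divided by the sum over all 28
#' pairs: the normalised ratios used to spread the two-disease pool over
#' specific pairs.
#'
#' @param cm a [comorbidity_matrix()].
#' @return named numeric vector over the 28 canonical pair keys
#'   (`"arthritis+cvd"` style), summing to 1.
#' @export
pair_shares <- function(cm) {
  stopifnot(inherits(cm, "comorbidity_matrix"))
  ids <- rownames(cm$counts)
  pairs <- utils::combn(ids, 2L, simplify = FALSE)
  counts <- vapply(pairs, function(p) cm$counts[p[1L], p[2L]], numeric(1))
  names(counts) <- vapply(pairs, combo_key, character(1))
  tot <- sum(counts)
  if (tot <= 0) {
    stop("degenerate comorbidity matrix: all pair counts are zero",
         call. = FALSE)
  }
  counts / tot
}

#' Count disease subsets of given sizes
#'
#' @param n number of diseases.
#' @param k_min,k_max inclusive subset-size range, `0 <= k_min <= k_max <= n`.
#' @return the number of subsets, `sum(choose(n, k))` for k in the range.
#' @export
#' @examples
#' enumerate_combinations(8, 2, 2)  # 28 pairs
#' enumerate_combinations(8, 3, 8)  # 219 subsets of size >= 3
enumerate_combinations <- function(n, k_min, k_max) {
  check_number(n, "n", min = 0)
  check_number(k_min, "k_min", min = 0)
  check_number(k_max, "k_max", min = 0)
  if (!(k_min <= k_max && k_max <= n)) {
    stop("require 0 <= k_min <= k_max <= n", call. = FALSE)
  }
  sum(choose(n, k_min:k_max))
}

# internal: all subsets of `ids` with size in [k_min, k_max], as a list of
# character vectors
all_subsets <- function(ids, k_min, k_max) {
  out <- list()
  for (k in k_min:k_max) {
    out <- c(out, utils::combn(ids, k, simplify = FALSE))
  }
  out
}

# internal: score a subset of size >= 3 by its pairwise co-occurrence counts
subset_pair_score <- function(subset, counts,
                              score = c("sum", "min", "prod")) {
  score <- match.arg(score)
  pr <- utils::combn(subset, 2L, simplify = FALSE)
  v <- vapply(pr, function(p) counts[p[1L], p[2L]], numeric(1))
  switch(score, sum = sum(v), min = min(v), prod = prod(v))
}

#' Shares over the 219 subsets of three or more diseases
#'
#' The most common triples — scored by the sum (configurably the min or
#' product) of their three pairwise co-occurrence counts — receive mass
#' proportional to their scores relative to all triples; the remaining mass
#' is spread over every other subset of size three or more by a weighted
#' average, each subset weighted by the mean marginal prevalence of its
#' member diseases.
#'
#' @param cm a [comorbidity_matrix()].
#' @param top_k how many top-scoring triples get score-proportional mass
#'   (default 4, the number of common 3+ patterns usually singled out).
#' @param score scoring rule for triples: `"sum"` (default), `"min"` or
#'   `"prod"` of the three pair counts.
#' @param residual_mass optional fraction of total mass reserved for the
#'   weighted-average remainder; default is whatever score mass the top
#'   triples do not account for.
#' @return named numeric vector over all size >= 3 subsets (219 for eight
#'   diseases), summing to 1.
#' @export
multi_shares <- function(cm, top_k = 4, score = c("sum", "min", "prod"),
                         residual_mass = NULL) {
  score <- match.arg(score)
  stopifnot(inherits(cm, "comorbidity_matrix"))
  check_number(top_k, "top_k", min = 0)
  if (!is.null(residual_mass)) check_fraction(residual_mass, "residual_mass")
  ids <- rownames(cm$counts)
  if (sum(cm$counts) <= 0) {
    stop("degenerate comorbidity matrix: all pair counts are zero",
         call. = FALSE)
  }
  triples <- utils::combn(ids, 3L, simplify = FALSE)
  tscore <- vapply(triples, subset_pair_score, numeric(1),
                   counts = cm$counts, score = score)
  tkey <- vapply(triples, combo_key, character(1))
  total_score <- sum(tscore)

  subsets <- all_subsets(ids, 3L, length(ids))
  keys <- vapply(subsets, combo_key, character(1))
  shares <- stats::setNames(numeric(length(keys)), keys)

  top_k <- min(top_k, length(triples))
  ord <- order(-tscore, tkey)  # score desc, name as deterministic tie-break
  top_idx <- ord[seq_len(top_k)]
  top_mass_default <- if (total_score > 0) {
    sum(tscore[top_idx]) / total_score
  } else 0
  top_mass <- if (is.null(residual_mass)) top_mass_default else 1 - residual_mass
  if (top_k > 0 && sum(tscore[top_idx]) > 0) {
    shares[tkey[top_idx]] <-
      top_mass * tscore[top_idx] / sum(tscore[top_idx])
  } else {
    top_mass <- 0
  }

  rest <- setdiff(keys, tkey[top_idx])
  if (length(rest) && top_mass < 1) {
    w <- vapply(rest, function(k) mean(cm$marginals[combo_split(k)]),
                numeric(1))
    if (sum(w) <= 0) w[] <- 1  # fall back to uniform spreading
    shares[rest] <- (1 - top_mass) * w / sum(w)
  }
  shares
}

#' Allocate an assisted population across disease-combination strata
#'
#' Composes [categorize()], [breakdown_single()], [pair_shares()] and
#' [multi_shares()] into the full stratification: one stratum for the
#' no-chronic-disease group, eight single-disease strata, 28 pair strata
#' and 219 strata of size three or more.
#'
#' @param assisted assisted persons (full precision).
#' @param dist a [disease_count_distribution()].
#' @param single_counts,single_total see [breakdown_single()].
#' @param cm a [comorbidity_matrix()].
#' @param top_k,score passed to [multi_shares()].
#' @param mode `"published"` reproduces the published tables (percent rounding,
#'   rounded one-disease pool, published totals as denominators);
#'   `"strict"` conserves every category total exactly.
#' @return object of class `combination_allocation`: list with `strata` (a
#'   data.frame `combination`, `n_diseases`, `persons`), `categories` (the
#'   unrounded category totals) and `mode`.
#' @export
allocate <- function(assisted, dist, single_counts,
                     single_total = sum(single_counts), cm, top_k = 4,
                     score = "sum", mode = c("published", "strict")) {
  mode <- match.arg(mode)
  cats <- categorize(assisted, dist, mode = mode)
  single_pool <- if (mode == "published") round_half_up(cats[["1"]]) else cats[["1"]]
  singles <- breakdown_single(single_pool, single_counts,
                              single_total = single_total, mode = mode)
  ps <- pair_shares(cm)
  ms <- multi_shares(cm, top_k = top_k, score = score)
  strata <- rbind(
    data.frame(combination = "none", n_diseases = "0",
               persons = cats[["0"]], stringsAsFactors = FALSE),
    data.frame(combination = names(singles), n_diseases = "1",
               persons = unname(singles), stringsAsFactors = FALSE),
    data.frame(combination = names(ps), n_diseases = "2",
               persons = unname(ps) * cats[["2"]], stringsAsFactors = FALSE),
    data.frame(combination = names(ms), n_diseases = "3plus",
               persons = unname(ms) * cats[["3plus"]],
               stringsAsFactors = FALSE)
  )
  rownames(strata) <- NULL
  structure(list(strata = strata, categories = cats, mode = mode),
            class = "combination_allocation")
}

#' @export
print.combination_allocation <- function(x, ...) {
  cat(sprintf("Combination allocation (%s mode): %d strata, %s persons\n",
              x$mode, nrow(x$strata),
              format(round_half_up(sum(x$categories)))))
  print(round_half_up(x$categories))
  invisible(x)
}
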