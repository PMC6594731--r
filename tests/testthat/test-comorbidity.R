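test_that("categorisation reproduces the published category counts", {
  a16 <- aggregate_assisted(30314, 0.3661)
  cats <- categorize(a16, fcw$dist)
  expect_equal(unname(round_half_up(cats)), c(1511, 2947, 3392, 3251))
  # 2026: the printed 4699 reflects an unrounded upstream forecast; from
  # the printed 43,824 the cell lands within one person
  cats26 <- categorize(aggregate_assisted(43824, 0.3661), fcw$dist)
  expect_lte(abs(round_half_up(cats26[["3plus"]]) - 4699), 1)
  expect_equal(unname(categorize(0, fcw$dist)), rep(0, 4))
})

test_that("strict-mode categories conserve the assisted population", {
  cats <- categorize(11097.9554, fcw$dist, mode = "strict")
  expect_equal(sum(cats), 11097.9554, tolerance = 1e-9)
  # published mode inherits the source table's 0.9-thousand inconsistency
  cats_p <- categorize(11097.9554, fcw$dist, mode = "published")
  expect_gt(sum(cats_p), 11097.9554)
  expect_lt(sum(cats_p) - 11097.9554, 5)
})

test_that("single-disease breakdown reproduces all published 2016 cells", {
  got <- breakdown_single(2947, fcw$single_counts,
                          single_total = fcw$single_total)
  expect_equal(unname(round_half_up(got)),
               c(805, 97, 324, 53, 29, 195, 1314, 144))
  # documented overshoot: the single-disease column sums to 876.0, not
  # 872.6, so published-mode cells total 2961 against a pool of 2947
  expect_equal(sum(round_half_up(got)), 2961)
  strict <- breakdown_single(2947, fcw$single_counts, mode = "strict")
  expect_equal(sum(strict), 2947, tolerance = 1e-9)
  expect_equal(unname(breakdown_single(0, fcw$single_counts)), rep(0, 8))
  expect_error(breakdown_single(100, fcw$single_counts, single_total = 0),
               "> 0")
})

test_that("pair shares are normalised ratios over the 28 pairs", {
  ps <- pair_shares(fcw$comorbidity)
  expect_length(ps, 28)
  expect_equal(sum(ps), 1, tolerance = 1e-12)
  expect_true(all(ps >= 0))
  top3 <- names(sort(ps, decreasing = TRUE))[1:3]
  expect_equal(top3, c("arthritis+cvd", "arthritis+back", "back+cvd"))

  ids <- LETTERS[1:4]
  one <- matrix(0, 4, 4, dimnames = list(ids, ids))
  one["A", "B"] <- one["B", "A"] <- 7
  expect_equal(unname(pair_shares(comorbidity_matrix(one))["A+B"]), 1)
  unif <- matrix(1, 4, 4, dimnames = list(ids, ids))
  expect_equal(unname(pair_shares(comorbidity_matrix(unif))),
               rep(1 / 6, 6))
  expect_error(pair_shares(comorbidity_matrix(one * 0)), "degenerate")
})

test_that("subset counting matches brute-force power-set enumeration", {
  expect_equal(enumerate_combinations(8, 2, 2), 28)
  expect_equal(enumerate_combinations(8, 3, 8), 219)
  expect_equal(enumerate_combinations(8, 8, 8), 1)
  expect_error(enumerate_combinations(8, 5, 3), "k_min <= k_max")
  expect_error(enumerate_combinations(8, 0, 9), "<= n")
  for (n in 0:10) {
    sizes <- vapply(0:(2^n - 1), function(m)
      sum(as.integer(intToBits(m))[seq_len(n)]), numeric(1))
    for (k_min in 0:n) for (k_max in k_min:n) {
      expect_equal(enumerate_combinations(n, k_min, k_max),
                   sum(sizes >= k_min & sizes <= k_max))
    }
  }
})

test_that("multi shares cover all 219 subsets and sum to one", {
  ms <- multi_shares(fcw$comorbidity, top_k = 4)
  expect_length(ms, 219)
  expect_equal(sum(ms), 1, tolerance = 1e-9)
  expect_true(all(ms >= 0))
  # top triples by summed pair counts, with their hand-added scores
  top <- names(sort(ms, decreasing = TRUE))[1:3]
  expect_equal(top, c("arthritis+back+cvd", "arthritis+cvd+mental",
                      "arthritis+cvd+diabetes"))
  cm <- fcw$comorbidity$counts
  expect_equal(cm["arthritis", "back"] + cm["arthritis", "cvd"] +
                 cm["back", "cvd"], 2146.0)
  expect_equal(cm["arthritis", "mental"] + cm["arthritis", "cvd"] +
                 cm["cvd", "mental"], 1805.2)
  expect_equal(cm["arthritis", "diabetes"] + cm["arthritis", "cvd"] +
                 cm["cvd", "diabetes"], 1779.8)
})

test_that("multi shares handle degenerate and symmetric matrices", {
  ids <- LETTERS[1:5]
  m <- matrix(0, 5, 5, dimnames = list(ids, ids))
  for (p in combn(c("A", "B", "C"), 2, simplify = FALSE)) {
    m[p[1], p[2]] <- m[p[2], p[1]] <- 3
  }
  # under min or product scoring only the fully co-occurring triple scores,
  # so it takes all the mass; sum scoring also credits partial overlaps
  for (sc in c("min", "prod")) {
    ms <- multi_shares(comorbidity_matrix(m), top_k = 1, score = sc)
    expect_equal(unname(ms["A+B+C"]), 1)
  }
  ms_sum <- multi_shares(comorbidity_matrix(m), top_k = 1, score = "sum")
  expect_gt(unname(ms_sum["A+B+C"]), 1 / 3 - 1e-9)

  unif <- comorbidity_matrix(matrix(1, 5, 5, dimnames = list(ids, ids)))
  n3 <- choose(5, 3)
  # with every triple promoted, symmetry forces equal triple shares
  all_t <- multi_shares(unif, top_k = n3)
  expect_equal(unname(all_t[nchar(names(all_t)) == 5]), rep(1 / n3, n3))
  # with none promoted, the weighted-average spread is uniform everywhere
  none <- multi_shares(unif, top_k = 0)
  expect_equal(unname(none), rep(1 / length(none), length(none)))
  expect_error(multi_shares(comorbidity_matrix(m * 0)), "degenerate")
})

test_that("allocation composes the stages and conserves in strict mode", {
  a16 <- aggregate_assisted(30314, 0.3661)
  al <- allocate(a16, fcw$dist, fcw$single_counts,
                 single_total = fcw$single_total, cm = fcw$comorbidity)
  expect_equal(unname(round_half_up(al$categories)),
               c(1511, 2947, 3392, 3251))
  expect_equal(nrow(al$strata), 1 + 8 + 28 + 219)
  expect_true(all(al$strata$persons >= 0))

  strict <- allocate(a16, fcw$dist, fcw$single_counts,
                     single_total = fcw$single_total,
                     cm = fcw$comorbidity, mode = "strict")
  expect_lt(abs(sum(strict$strata$persons) - a16), 1)
  for (cat in c("0", "1", "2", "3plus")) {
    expect_equal(sum(strict$strata$persons[strict$strata$n_diseases == cat]),
                 unname(strict$categories[[cat]]), tolerance = 1e-9)
  }

  zero <- allocate(0, fcw$dist, fcw$single_counts,
                   single_total = fcw$single_total, cm = fcw$comorbidity)
  expect_equal(sum(zero$strata$persons), 0)
})

test_that("allocation is equivariant under disease relabelling", {
  perm <- c(arthritis = "cvd", asthma = "mental", back = "back",
            cancer = "copd", copd = "cancer", diabetes = "diabetes",
            cvd = "arthritis", mental = "asthma")
  relabel_key <- function(k) {
    if (k == "none") return("none")
    paste(sort(unname(perm[strsplit(k, "+", fixed = TRUE)[[1]]])),
          collapse = "+")
  }
  cm <- fcw$comorbidity
  m2 <- cm$counts
  rownames(m2) <- colnames(m2) <- unname(perm[rownames(cm$counts)])
  m2 <- m2[chronic_diseases(), chronic_diseases()]
  marg2 <- cm$marginals
  names(marg2) <- unname(perm[names(cm$marginals)])
  singles2 <- fcw$single_counts
  names(singles2) <- unname(perm[names(fcw$single_counts)])

  al1 <- allocate(5000, fcw$dist, fcw$single_counts,
                  single_total = fcw$single_total, cm = cm)
  al2 <- allocate(5000, fcw$dist, singles2[chronic_diseases()],
                  single_total = fcw$single_total,
                  cm = comorbidity_matrix(m2, marginals = marg2))
  got1 <- setNames(al1$strata$persons, al1$strata$combination)
  got2 <- setNames(al2$strata$persons, al2$strata$combination)
  mapped <- setNames(got1, vapply(names(got1), relabel_key, character(1)))
  expect_equal(got2[names(mapped)], mapped, tolerance = 1e-9)
})
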