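simple_truth <- function(n = 10, chrom = "ctg1") {
  tibble::tibble(chrom = chrom, pos = seq(100L, by = 100L, length.out = n),
                 ref = "A", alt = "T",
                 expected_vaf = seq(0.05, 0.5, length.out = n))
}

as_calls <- function(df, score = NULL, vaf = NULL) {
  out <- df[c("chrom", "pos", "ref", "alt")]
  out$score <- score %||% rep(NA_real_, nrow(out))
  out$vaf <- vaf %||% df$expected_vaf %||% rep(0.3, nrow(out))
  out
}

test_that("allele-exact matching splits calls into TP, FP and FN", {
  truth <- simple_truth(10)
  perfect <- match_calls(truth, as_calls(truth))
  expect_equal(nrow(perfect$tp), 10L)
  expect_equal(nrow(perfect$fp), 0L)
  expect_equal(nrow(perfect$fn), 0L)
  expect_equal(glance(perfect)$f1, 1)

  # same position, different alternate allele: one FP and one FN
  calls <- as_calls(truth)
  calls$alt[1] <- "G"
  m <- match_calls(truth, calls)
  expect_equal(nrow(m$fp), 1L)
  expect_equal(nrow(m$fn), 1L)
  expect_equal(nrow(m$tp), 9L)

  # calls on unknown contigs are an error naming the offenders
  bad <- calls; bad$chrom[1] <- "ctgZ"
  expect_error(match_calls(truth, bad), "ctgZ")

  # matching is invariant to record order
  shuffled <- calls[sample.int(nrow(calls)), ]
  m2 <- match_calls(truth[sample.int(nrow(truth)), ], shuffled)
  expect_equal(glance(m2), glance(m))
})

test_that("region restriction removes truth from the denominator", {
  truth <- simple_truth(10)  # positions 100..1000
  regions <- tibble::tibble(chrom = "ctg1", start = 0L, end = 550L)
  calls <- as_calls(truth[1:3, ])  # find 3 of the 5 in-region variants
  m <- match_calls(truth, calls, regions = regions)
  expect_equal(nrow(m$tp), 3L)
  expect_equal(nrow(m$fn), 2L)   # only in-region truth can be missed
  expect_equal(precision_recall_f1(m)$recall, 0.6)
})

test_that("precision/recall/F1 conventions handle degenerate sets", {
  truth <- simple_truth(10)
  # 8 TP + 2 FP, 2 FN -> (0.8, 0.8, 0.8)
  calls <- dplyr::bind_rows(
    as_calls(truth[1:8, ]),
    tibble::tibble(chrom = "ctg1", pos = c(5000L, 6000L), ref = "C",
                   alt = "G", score = NA_real_, vaf = 0.2)
  )
  m <- match_calls(truth, calls)
  prf <- precision_recall_f1(m)
  expect_equal(c(prf$precision, prf$recall, prf$f1), c(0.8, 0.8, 0.8))

  empty <- match_calls(truth, as_calls(truth[0, ]))
  prf0 <- precision_recall_f1(empty)
  expect_equal(c(prf0$precision, prf0$recall, prf0$f1), c(0, 0, 0))
  expect_true(prf0$degenerate)
})

test_that("PR curves enumerate thresholds exactly as hand enumeration", {
  truth <- tibble::tibble(chrom = "ctg1", pos = c(100L, 200L), ref = "A",
                          alt = "T")
  calls <- tibble::tibble(
    chrom = "ctg1", pos = c(100L, 300L, 200L), ref = c("A", "C", "A"),
    alt = c("T", "G", "T"), score = c(0.9, 0.5, 0.1), vaf = 0.3
  )
  m <- match_calls(truth, calls)
  curve <- pr_curve(m)
  expect_equal(curve$threshold, c(0.9, 0.5, 0.1))
  expect_equal(curve$recall, c(0.5, 0.5, 1.0))
  expect_equal(curve$precision, c(1.0, 0.5, 2 / 3))
  # the final point equals the un-thresholded metrics
  prf <- precision_recall_f1(m)
  expect_equal(curve$precision[nrow(curve)], prf$precision)
  expect_equal(curve$recall[nrow(curve)], prf$recall)

  # unscored call sets warn and return an empty curve
  m_unscored <- match_calls(truth, dplyr::mutate(calls, score = NA_real_))
  expect_warning(empty_curve <- pr_curve(m_unscored), "no scored")
  expect_equal(nrow(empty_curve), 0L)
})

test_that("PR metrics equal brute-force confusion counting on fuzzed sets", {
  set.seed(60)
  for (rep in 1:25) {
    n_truth <- sample(1:100, 1)
    n_calls <- sample(1:100, 1)
    pool <- tibble::tibble(
      chrom = sample(c("c1", "c2"), 150, replace = TRUE),
      pos = sample.int(500, 150, replace = TRUE),
      ref = sample(c("A", "C"), 150, replace = TRUE),
      alt = sample(c("G", "T"), 150, replace = TRUE)
    ) |> dplyr::distinct()
    truth <- pool[sample.int(nrow(pool), min(n_truth, nrow(pool))), ]
    calls <- pool[sample.int(nrow(pool), min(n_calls, nrow(pool))), ]
    calls$score <- round(runif(nrow(calls)), 2)  # induce ties
    calls$vaf <- runif(nrow(calls))
    m <- match_calls(truth, calls)
    prf <- precision_recall_f1(m)
    oracle <- brute_confusion(
      paste(truth$chrom, truth$pos, truth$ref, truth$alt),
      paste(calls$chrom, calls$pos, calls$ref, calls$alt)
    )
    expect_equal(prf$precision, oracle$precision)
    expect_equal(prf$recall, oracle$recall)
    expect_equal(prf$f1, oracle$f1)

    curve <- pr_curve(m)
    # brute force each threshold independently
    tkey <- paste(truth$chrom, truth$pos, truth$ref, truth$alt)
    for (i in seq_len(nrow(curve))) {
      kept <- calls[calls$score >= curve$threshold[i], ]
      o <- brute_confusion(tkey, paste(kept$chrom, kept$pos, kept$ref,
                                       kept$alt))
      expect_equal(curve$precision[i], o$precision)
      expect_equal(curve$tp[i] / length(tkey), curve$recall[i])
    }
    # recall never decreases as the threshold drops
    expect_true(all(diff(curve$recall) >= 0))
  }
})

test_that("VAF-stratified recall and precision respect bin membership", {
  truth <- tibble::tibble(
    chrom = "ctg1", pos = seq(100L, by = 10L, length.out = 20), ref = "A",
    alt = "T", expected_vaf = rep(c(0.1, 0.4), each = 10)
  )
  # find 5 of the low-VAF and all of the high-VAF variants
  found <- truth[c(1:5, 11:20), ]
  calls <- tibble::tibble(chrom = found$chrom, pos = found$pos,
                          ref = found$ref, alt = found$alt,
                          score = 1, vaf = found$expected_vaf)
  m <- match_calls(truth, calls)
  strat <- stratified_metrics(m, bins = c(0, 0.25, 0.5))
  rec <- strat[strat$metric == "recall", ]
  expect_equal(rec$value, c(0.5, 1.0))
  # a bin with no calls has undefined precision, not zero
  prec <- strat[strat$metric == "precision", ]
  expect_equal(prec$n[prec$lower == 0], 5L)
  strat2 <- stratified_metrics(m, bins = c(0, 0.25, 0.5, 0.75))
  prec2 <- strat2[strat2$metric == "precision", ]
  expect_true(is.na(prec2$value[prec2$lower == 0.5]))
})

test_that("ensemble union and intersect obey set laws", {
  truth <- simple_truth(20)
  a <- as_calls(truth[1:12, ], score = runif(12))
  b <- as_calls(truth[8:20, ], score = runif(13))

  expect_equal(nrow(callset_union(a, a)), nrow(a))
  expect_equal(nrow(callset_intersect(a, a)), nrow(a))

  u <- callset_union(a, b)
  i <- callset_intersect(a, b)
  expect_equal(nrow(u), 20L)
  expect_equal(nrow(i), 5L)
  expect_equal(nrow(u) + nrow(i), nrow(a) + nrow(b))

  # disjoint sets
  d1 <- as_calls(truth[1:5, ]); d2 <- as_calls(truth[6:9, ])
  expect_equal(nrow(callset_union(d1, d2)), 9L)
  expect_equal(nrow(callset_intersect(d1, d2)), 0L)

  # union keeps max score, intersect min score
  shared_key <- paste(i$chrom, i$pos)
  au <- u[paste(u$chrom, u$pos) %in% shared_key, ]
  aa <- a[paste(a$chrom, a$pos) %in% shared_key, ]
  bb <- b[paste(b$chrom, b$pos) %in% shared_key, ]
  ord <- order(au$pos); orda <- order(aa$pos); ordb <- order(bb$pos)
  expect_equal(au$score[ord], pmax(aa$score[orda], bb$score[ordb]))
  expect_equal(i$score[order(i$pos)], pmin(aa$score[orda], bb$score[ordb]))

  # recall of the union dominates both inputs
  ru <- precision_recall_f1(match_calls(truth, u))$recall
  ra <- precision_recall_f1(match_calls(truth, a))$recall
  rb <- precision_recall_f1(match_calls(truth, b))$recall
  expect_gte(ru, max(ra, rb))
})
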