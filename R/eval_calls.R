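# Scoring of somatic point-mutation call sets against simulated truth:
# allele-exact matching, precision/recall/F1, score-thresholded PR curves,
# VAF-stratified metrics, and union/intersect ensembles.

restrict_to_regions <- function(df, regions) {
  if (is.null(regions) || nrow(df) == 0L) return(df)
  keep <- logical(nrow(df))
  for (ch in unique(df$chrom)) {
    sel <- which(df$chrom == ch)
    reg <- regions[regions$chrom == ch, , drop = FALSE]
    if (nrow(reg) == 0L) next
    p0 <- df$pos[sel] - 1L
    keep[sel] <- vapply(p0, function(p) any(reg$start <= p & p < reg$end),
                        logical(1))
  }
  df[keep, , drop = FALSE]
}

#' Match a call set against truth
#'
#' Calls and truth are compared allele-exactly on
#' `(chrom, pos, ref, alt)` after left-normalisation. When `regions` is
#' given, both tables are restricted to those regions *before* matching,
#' so truth outside the regions leaves the denominator entirely (the way
#' exon-targeted evaluations are scored).
#'
#' @param truth Truth tibble (`chrom`, `pos`, `ref`, `alt`, plus any
#'   annotation columns such as `expected_vaf`, `true_ccf`, `origin`).
#' @param calls A `callset` tibble (`chrom`, `pos`, `ref`, `alt`, optional
#'   `score`, `vaf`).
#' @param regions Optional BED-style tibble (`chrom`, `start`, `end`,
#'   0-based half-open).
#' @return A `match_result` with tibbles `$tp` (call columns joined to
#'   truth columns), `$fp`, `$fn`. Errors when calls name contigs unknown
#'   to both truth and regions.
#' @export
match_calls <- function(truth, calls, regions = NULL) {
  known_contigs <- union(unique(truth$chrom),
                         if (!is.null(regions)) unique(regions$chrom))
  offenders <- setdiff(unique(calls$chrom), known_contigs)
  if (length(offenders)) {
    abort(sprintf("calls name contigs absent from truth/regions: %s",
                  paste(offenders, collapse = ", ")))
  }
  truth <- distinct(truth, .data$chrom, .data$pos, .data$ref, .data$alt,
                    .keep_all = TRUE)
  norm_t <- normalise_alleles(truth$pos, truth$ref, truth$alt)
  truth$pos <- norm_t$pos; truth$ref <- norm_t$ref; truth$alt <- norm_t$alt
  calls <- distinct(as_tibble(calls), .data$chrom, .data$pos, .data$ref,
                    .data$alt, .keep_all = TRUE)
  norm_c <- normalise_alleles(calls$pos, calls$ref, calls$alt)
  calls$pos <- norm_c$pos; calls$ref <- norm_c$ref; calls$alt <- norm_c$alt

  truth <- restrict_to_regions(truth, regions)
  calls <- restrict_to_regions(calls, regions)

  tkey <- variant_key(truth$chrom, truth$pos, truth$ref, truth$alt)
  ckey <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  is_tp <- ckey %in% tkey
  found <- tkey %in% ckey

  tp <- left_join(calls[is_tp, , drop = FALSE],
                  select(truth, any_of(c("chrom", "pos", "ref", "alt",
                                         "expected_vaf", "true_ccf",
                                         "origin", "m", "n"))),
                  by = c("chrom", "pos", "ref", "alt"))
  structure(list(tp = tp, fp = calls[!is_tp, , drop = FALSE],
                 fn = truth[!found, , drop = FALSE],
                 regions_applied = !is.null(regions)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP %d, FP %d, FN %d%s\n", nrow(x$tp),
              nrow(x$fp), nrow(x$fn),
              if (x$regions_applied) " (region-restricted)" else ""))
  invisible(x)
}

#' @describeIn match_calls All records with a `status` column
#'   (`TP`/`FP`/`FN`).
#' @param x A `match_result`.
#' @param ... Unused.
#' @export
tidy.match_result <- function(x, ...) {
  bind_rows(mutate(x$tp, status = "TP"), mutate(x$fp, status = "FP"),
            mutate(x$fn, status = "FN"))
}

#' @describeIn match_calls One-row precision/recall/F1 summary.
#' @export
glance.match_result <- function(x, ...) {
  precision_recall_f1(x)
}

#' Precision, recall and F1 of a match result
#'
#' Zero-denominator conventions: an empty call set has precision 0, empty
#' truth has recall 0, and F1 is 0 when precision and recall are both 0
#' (flagged by the `degenerate` column).
#'
#' @param match A `match_result`.
#' @return A one-row tibble `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f1`, `degenerate`.
#' @export
precision_recall_f1 <- function(match) {
  tp <- nrow(match$tp); fp <- nrow(match$fp); fn <- nrow(match$fn)
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  tibble(tp = tp, fp = fp, fn = fn, precision = precision, recall = recall,
         f1 = f1, degenerate = (tp + fp == 0L) || (precision + recall == 0))
}

#' Precision-recall curve over call scores
#'
#' One point per distinct score threshold, descending; at each threshold
#' the calls scoring at least it are kept. Ties share a point; unscored
#' calls (`NA`) rank below every scored call; the final point equals the
#' un-thresholded precision/recall.
#'
#' @param match A `match_result` whose calls carry a `score` column.
#' @return A `pr_curve` tibble `threshold`, `tp`, `fp`, `precision`,
#'   `recall` (empty, with a warning, when no call has a score).
#' @export
pr_curve <- function(match) {
  calls <- bind_rows(mutate(match$tp, is_tp = TRUE),
                     mutate(match$fp, is_tp = FALSE))
  n_truth <- nrow(match$tp) + nrow(match$fn)
  empty <- tibble(threshold = numeric(), tp = integer(), fp = integer(),
                  precision = numeric(), recall = numeric())
  if (nrow(calls) == 0L || !"score" %in% names(calls) ||
      all(is.na(calls$score))) {
    warn("no scored calls; returning an empty precision-recall curve")
    return(structure(empty, class = c("pr_curve", class(empty))))
  }
  sc <- ifelse(is.na(calls$score), -Inf, calls$score)
  ord <- order(sc, decreasing = TRUE)
  sc <- sc[ord]
  is_tp <- calls$is_tp[ord]
  cum_tp <- cumsum(is_tp)
  cum_fp <- cumsum(!is_tp)
  last_of_tie <- c(sc[-1] != sc[-length(sc)], TRUE)
  out <- tibble(
    threshold = sc[last_of_tie],
    tp = as.integer(cum_tp[last_of_tie]),
    fp = as.integer(cum_fp[last_of_tie])
  ) |>
    mutate(precision = .data$tp / (.data$tp + .data$fp),
           recall = if (n_truth == 0L) 0 else .data$tp / n_truth)
  structure(out, class = c("pr_curve", class(out)))
}

#' VAF-stratified recall and precision
#'
#' Recall is binned by the *true* expected VAF of truth variants; precision
#' is binned by the *called* VAF of calls. Bins with no members are
#' reported as `NA`, not 0.
#'
#' @param match A `match_result` whose truth rows carry `expected_vaf` and
#'   whose calls carry `vaf`.
#' @param bins Increasing numeric vector of bin edges (left-closed,
#'   right-open; the last bin is closed).
#' @return A tibble `metric` (`recall`/`precision`), `bin`, `lower`,
#'   `upper`, `n`, `value`.
#' @export
stratified_metrics <- function(match, bins = seq(0, 1, by = 0.1)) {
  stopifnot(length(bins) >= 2L, !is.unsorted(bins))
  bin_of <- function(x) {
    cut(x, breaks = bins, right = FALSE, include.lowest = TRUE)
  }
  truth <- bind_rows(mutate(match$tp, found = TRUE),
                     mutate(match$fn, found = FALSE))
  recall_tab <- truth |>
    mutate(bin = bin_of(.data$expected_vaf)) |>
    filter(!is.na(.data$bin)) |>
    group_by(.data$bin, .drop = FALSE) |>
    summarise(n = n(),
              value = ifelse(n() == 0L, NA_real_, mean(.data$found)),
              .groups = "drop") |>
    mutate(metric = "recall")
  calls <- bind_rows(mutate(match$tp, is_tp = TRUE),
                     mutate(match$fp, is_tp = FALSE))
  precision_tab <- calls |>
    mutate(bin = bin_of(.data$vaf)) |>
    filter(!is.na(.data$bin)) |>
    group_by(.data$bin, .drop = FALSE) |>
    summarise(n = n(),
              value = ifelse(n() == 0L, NA_real_, mean(.data$is_tp)),
              .groups = "drop") |>
    mutate(metric = "precision")
  bind_rows(recall_tab, precision_tab) |>
    mutate(lower = bins[as.integer(.data$bin)],
           upper = bins[as.integer(.data$bin) + 1L]) |>
    select("metric", "bin", "lower", "upper", "n", "value")
}

callset_key_join <- function(a, b, how) {
  a <- as_tibble(a); b <- as_tibble(b)
  if (!"score" %in% names(a)) a$score <- NA_real_
  if (!"score" %in% names(b)) b$score <- NA_real_
  keys <- c("chrom", "pos", "ref", "alt")
  joined <- switch(how,
    union = full_join(a[c(keys, "score")], b[c(keys, "score")],
                      by = keys, suffix = c(".a", ".b")),
    intersect = inner_join(a[c(keys, "score")], b[c(keys, "score")],
                           by = keys, suffix = c(".a", ".b"))
  )
  joined$score <- if (how == "union") {
    pmax(joined$score.a, joined$score.b, na.rm = TRUE)
  } else {
    pmin(joined$score.a, joined$score.b)
  }
  out <- select(joined, all_of(keys), "score")
  structure(out, class = c("callset", class(out)))
}

#' Ensemble union and intersection of call sets
#'
#' Set operations on the `(chrom, pos, ref, alt)` key: the union keeps the
#' maximum score of a shared call, the intersection the minimum.
#'
#' @param a,b Callset tibbles.
#' @return A `callset` tibble.
#' @export
callset_union <- function(a, b) callset_key_join(a, b, "union")

#' @rdname callset_union
#' @export
callset_intersect <- function(a, b) callset_key_join(a, b, "intersect")
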