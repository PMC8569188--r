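# Cancer-cell-fraction evaluation: the doubled-VAF and K-means baselines,
# the MADif statistic (per-sample mean absolute true-vs-estimated CCF
# difference, averaged equally over samples), and the adjusted Rand index
# for cluster assignments.

#' Doubled-VAF baseline CCF estimate
#'
#' The simplest CCF estimator: assume a purely heterozygous diploid
#' genome, so `CCF = 2 * VAF / purity`, capped at 1.
#'
#' @param vaf Observed variant allele frequencies in `[0, 1]`.
#' @param purity True sample purity in `(0, 1]`.
#' @return CCF estimates in `[0, 1]`.
#' @examples
#' doubled_vaf_baseline(0.3, 0.75) # 0.8
#' @export
doubled_vaf_baseline <- function(vaf, purity) {
  if (any(purity <= 0 | purity > 1)) abort("`purity` must lie in (0, 1]")
  if (any(vaf < 0 | vaf > 1, na.rm = TRUE)) abort("`vaf` must lie in [0, 1]")
  pmin(2 * vaf / purity, 1)
}

#' K-means baseline clustering of CCF estimates
#'
#' One-dimensional K-means (default `k = 3`) over per-variant CCFs, with
#' multiple restarts for stability. Each variant's assigned CCF is its
#' cluster mean. When fewer distinct values than `k` exist, `k` is reduced
#' with a warning.
#'
#' @param ccfs Numeric vector of per-variant CCF estimates.
#' @param k Number of clusters.
#' @param seed Integer seed (set before clustering for reproducibility).
#' @param nstart Number of random restarts.
#' @return A `cluster_assignment` tibble `ccf`, `cluster` (integer label),
#'   `cluster_ccf` (the cluster mean), with attribute `centers`.
#' @export
kmeans_baseline <- function(ccfs, k = 3, seed = 1, nstart = 10) {
  if (length(ccfs) == 0L) abort("`ccfs` is empty")
  if (k < 1) abort("`k` must be >= 1")
  n_distinct_vals <- length(unique(ccfs))
  if (n_distinct_vals < k) {
    warn(sprintf("only %d distinct CCF values; reducing k from %d",
                 n_distinct_vals, k))
    k <- n_distinct_vals
  }
  if (!is.null(seed)) set.seed(seed)
  km <- kmeans(matrix(ccfs, ncol = 1L), centers = k, nstart = nstart)
  centers <- as.numeric(km$centers)
  out <- tibble(ccf = ccfs, cluster = as.integer(km$cluster),
                cluster_ccf = centers[km$cluster])
  structure(out, centers = centers,
            class = c("cluster_assignment", class(out)))
}

#' MADif: mean absolute difference of true vs estimated CCFs
#'
#' Per sample, the mean absolute difference between true and estimated
#' CCFs over its called true variants; samples are then averaged with
#' equal weight, so samples with many variants do not dominate:
#' `MADif = (1/n) * sum_i [ sum_j |T_ij - E_ij| / m_i ]`.
#'
#' @param cmp A CCF comparison tibble with columns `sample`, `true_ccf`,
#'   `estimated_ccf` (restricted upstream to called true variants).
#' @return A single nonnegative number.
#' @examples
#' madif(tibble::tibble(
#'   sample = c("s1", "s1", "s2"),
#'   true_ccf = c(1.0, 0.5, 1.0),
#'   estimated_ccf = c(0.9, 0.7, 1.0)
#' )) # 0.075
#' @export
madif <- function(cmp) {
  need <- c("sample", "true_ccf", "estimated_ccf")
  if (!all(need %in% names(cmp))) {
    abort(sprintf("`cmp` must have columns %s", paste(need, collapse = ", ")))
  }
  if (nrow(cmp) == 0L) abort("`cmp` is empty")
  if (any(!is.finite(cmp$true_ccf)) || any(!is.finite(cmp$estimated_ccf))) {
    abort("non-finite CCF values in comparison set")
  }
  per_sample <- cmp |>
    group_by(.data$sample) |>
    summarise(mad = mean(abs(.data$true_ccf - .data$estimated_ccf)),
              .groups = "drop")
  mean(per_sample$mad)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labellings of the same items,
#' computed from the pair-counting contingency-table closed form. 1 for
#' identical partitions, around 0 for independent ones.
#'
#' @param labels_true,labels_pred Equal-length label vectors (any atomic
#'   type).
#' @return A number in `[-1, 1]`.
#' @export
adjusted_rand <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred)) {
    abort("label vectors must have equal length")
  }
  n <- length(labels_true)
  if (n == 0L) abort("empty label vectors")
  tab <- table(labels_true, labels_pred)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Build a CCF comparison set over true positive calls
#'
#' Joins per-variant CCF estimates to truth over the true positives of a
#' match, yielding the pairs MADif consumes.
#'
#' @param truth Truth tibble (with `true_ccf`).
#' @param estimates Tibble `chrom`, `pos`, `ref`, `alt`, `ccf` (and
#'   optionally `cluster`).
#' @param match A `match_result` from [match_calls()].
#' @param sample_id Sample label for the comparison rows.
#' @return A tibble `sample`, `chrom`, `pos`, `ref`, `alt`, `origin`,
#'   `true_ccf`, `estimated_ccf` (plus `cluster` when supplied).
#' @export
ccf_comparison <- function(truth, estimates, match, sample_id = "S1") {
  keys <- c("chrom", "pos", "ref", "alt")
  tp <- match$tp[keys]
  if (nrow(tp) == 0L) abort("no true positive calls to compare")
  est <- rename(estimates, estimated_ccf = "ccf")
  out <- tp |>
    inner_join(select(truth, all_of(keys), "origin", "true_ccf"),
               by = keys) |>
    inner_join(select(est, all_of(keys), "estimated_ccf",
                      any_of("cluster")),
               by = keys) |>
    mutate(sample = sample_id, .before = 1)
  if (nrow(out) == 0L) {
    abort("estimates share no variants with the true positives")
  }
  out
}

#' Evaluate a CCF-estimation pipeline
#'
#' Builds the comparison set over true positives and reports MADif for the
#' non-clustered per-variant estimates; when a cluster assignment is
#' given, additionally reports MADif over assigned cluster CCFs and the
#' adjusted Rand index of the clustering against the true partition
#' (variants sharing an origin clone share a true label).
#'
#' @inheritParams ccf_comparison
#' @param clusters Optional `cluster_assignment` rows aligned with
#'   `estimates` (columns `cluster`, `cluster_ccf`), or `NULL`.
#' @return A `ccf_eval` object with `$comparison` (the pair table),
#'   `$madif` (non-clustered), and when clustered `$madif_clustered` and
#'   `$ari`.
#' @export
evaluate_ccf_pipeline <- function(truth, estimates, match, clusters = NULL,
                                  sample_id = "S1") {
  if (!is.null(clusters)) {
    estimates <- bind_cols(estimates,
                           clusters[c("cluster", "cluster_ccf")])
  }
  cmp <- ccf_comparison(truth, estimates, match, sample_id)
  res <- list(comparison = cmp, madif = madif(cmp))
  if (!is.null(clusters)) {
    cl <- estimates |>
      select("chrom", "pos", "ref", "alt", "cluster", "cluster_ccf")
    cmp_cl <- cmp |>
      select(-any_of(c("cluster", "cluster_ccf"))) |>
      inner_join(cl, by = c("chrom", "pos", "ref", "alt"))
    res$madif_clustered <- madif(
      mutate(cmp_cl, estimated_ccf = .data$cluster_ccf)
    )
    res$ari <- adjusted_rand(cmp_cl$origin, cmp_cl$cluster)
    res$comparison <- cmp_cl
  }
  structure(res, class = "ccf_eval")
}

#' @export
print.ccf_eval <- function(x, ...) {
  cat(sprintf("<ccf_eval> %d pairs, MADif %.4f", nrow(x$comparison),
              x$madif))
  if (!is.null(x$madif_clustered)) {
    cat(sprintf(", clustered MADif %.4f, ARI %.3f", x$madif_clustered,
                x$ari))
  }
  cat("\n")
  invisible(x)
}

#' @describeIn evaluate_ccf_pipeline The per-variant comparison tibble.
#' @param x A `ccf_eval`.
#' @param ... Unused.
#' @export
tidy.ccf_eval <- function(x, ...) x$comparison

#' @describeIn evaluate_ccf_pipeline One-row summary of the metrics.
#' @export
glance.ccf_eval <- function(x, ...) {
  tibble(n_pairs = nrow(x$comparison), madif = x$madif,
         madif_clustered = x$madif_clustered %||% NA_real_,
         ari = x$ari %||% NA_real_)
}
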