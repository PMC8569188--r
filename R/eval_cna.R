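# Copy-number evaluation: purity/ploidy accuracy with whole-genome
# duplication failure classes, and binned total/allelic copy-number
# agreement between predicted segments and simulated truth.

#' Classify a ploidy estimate
#'
#' Callers that miss (or hallucinate) a whole-genome duplication report a
#' ploidy near half (or double) the truth but are otherwise accurate.
#' Classification order: `accurate` (`|pred - true| <= tol`), then
#' `halved` (`|pred - true/2| <= tol`), then `doubled`
#' (`|pred - 2 true| <= tol`), else `wrong`.
#'
#' @param pred,true Positive ploidy values (vectorised).
#' @param tol Absolute tolerance (default 0.3).
#' @return Character vector in
#'   `c("accurate", "halved", "doubled", "wrong")`.
#' @export
ploidy_class <- function(pred, true, tol = 0.3) {
  if (any(pred <= 0 | true <= 0)) abort("ploidy values must be > 0")
  out <- rep("wrong", length(pred))
  out[abs(pred - 2 * true) <= tol] <- "doubled"
  out[abs(pred - true / 2) <= tol] <- "halved"
  out[abs(pred - true) <= tol] <- "accurate"
  out
}

#' Absolute purity error
#'
#' @param pred,true Purity estimates in `(0, 1]`.
#' @return `|pred - true|`.
#' @export
purity_error <- function(pred, true) {
  if (any(pred <= 0 | pred > 1 | true <= 0 | true > 1)) {
    abort("purity values must lie in (0, 1]")
  }
  abs(pred - true)
}

bin_one_track <- function(segments, bin_width, contig_lengths, track) {
  out <- list()
  for (ch in names(contig_lengths)) {
    len <- contig_lengths[[ch]]
    starts <- seq(0L, len - 1L, by = bin_width)
    ends <- pmin(starts + bin_width, len)
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    total <- major <- minor <- rep(NA_real_, length(starts))
    if (nrow(seg)) {
      bins_rng <- IRanges::IRanges(start = starts + 1L, end = ends)
      seg_rng <- IRanges::IRanges(start = seg$start + 1L, end = seg$end)
      hits <- IRanges::findOverlaps(bins_rng, seg_rng)
      if (length(hits)) {
        qi <- S4Vectors::queryHits(hits)
        si <- S4Vectors::subjectHits(hits)
        ov <- IRanges::width(IRanges::pintersect(bins_rng[qi], seg_rng[si]))
        agg <- tibble(bin = qi, w = ov,
                      total = seg$total[si], major = seg$major[si],
                      minor = seg$minor[si]) |>
          group_by(.data$bin) |>
          summarise(total = sum(.data$w * .data$total) / sum(.data$w),
                    major = sum(.data$w * .data$major) / sum(.data$w),
                    minor = sum(.data$w * .data$minor) / sum(.data$w),
                    .groups = "drop")
        total[agg$bin] <- agg$total
        major[agg$bin] <- agg$major
        minor[agg$bin] <- agg$minor
      }
    }
    out[[ch]] <- tibble(track = track, chrom = ch, start = starts,
                        end = ends, total = total, major = major,
                        minor = minor)
  }
  bind_rows(out)
}

#' Bin copy numbers onto a fixed genome grid
#'
#' Projects allele-specific segments onto fixed-width bins; each bin's
#' value is the length-weighted mean of overlapping segment values, `NA`
#' where no segment covers the bin. Given simulated `clone_profiles`, one
#' track per clone is emitted plus a `"bulk"` track: the tumour-proportion
#' weighted mean of the clone tracks (purity-independent).
#'
#' @param x A predicted segment table (`chrom`, `start`, `end`,
#'   `total_cn`, `major_cn`, `minor_cn`) or a `clone_profiles` object.
#' @param bin_width Bin width in bp.
#' @param contig_lengths Named vector of contig lengths (taken from the
#'   profiles when `x` is a `clone_profiles`).
#' @param comp `bulk_composition` used to weight the truth `"bulk"` track.
#' @param track Track label for a predicted segment table.
#' @return A `cn_matrix` tibble: `track`, `chrom`, `start`, `end`,
#'   `total`, `major`, `minor`.
#' @export
bin_copy_numbers <- function(x, bin_width, contig_lengths = NULL,
                             comp = NULL, track = "predicted") {
  if (bin_width < 1) abort("`bin_width` must be >= 1")
  if (inherits(x, "clone_profiles")) {
    contig_lengths <- x$contig_lengths
    clones <- setdiff(names(x$states), "germline")
    tracks <- map(clones, function(cl) {
      seg <- profile_segments(x, cl)
      bin_one_track(seg, bin_width, contig_lengths, cl)
    })
    out <- bind_rows(tracks)
    if (!is.null(comp)) {
      wtab <- setNames(comp$tumour_fraction, comp$clone)
      bulk <- out |>
        filter(.data$track %in% comp$clone) |>
        mutate(w = wtab[.data$track]) |>
        group_by(.data$chrom, .data$start, .data$end) |>
        summarise(total = sum(.data$w * .data$total),
                  major = sum(.data$w * .data$major),
                  minor = sum(.data$w * .data$minor), .groups = "drop") |>
        mutate(track = "bulk")
      out <- bind_rows(out, bulk)
    }
  } else {
    if (is.null(contig_lengths)) {
      abort("`contig_lengths` is required for a segment-table input")
    }
    seg <- as_tibble(x)
    nm <- names(seg)
    if ("total_cn" %in% nm) {
      seg <- rename(seg, total = "total_cn", major = "major_cn",
                    minor = "minor_cn")
    }
    out <- bin_one_track(seg, bin_width, contig_lengths, track)
  }
  out <- relocate(out, "track")
  structure(out, bin_width = bin_width,
            class = c("cn_matrix", class(out)))
}

#' Agreement between two binned copy-number tracks
#'
#' Compares one predicted track to one truth track over the bins
#' non-missing in both: mean absolute error of total and minor copy
#' number, plus the fraction of bins whose rounded (total, minor) pair
#' matches exactly.
#'
#' @param pred,true `cn_matrix` tibbles holding a single track each, on
#'   identical bin grids.
#' @return A one-row tibble `n_bins`, `mae_total`, `mae_minor`,
#'   `exact_match`.
#' @export
copy_number_agreement <- function(pred, true) {
  keys <- c("chrom", "start", "end")
  if (nrow(pred) != nrow(true) ||
      !identical(pred[keys], true[keys])) {
    abort("bin grids differ between `pred` and `true`")
  }
  ok <- !is.na(pred$total) & !is.na(true$total)
  p <- pred[ok, ]; t <- true[ok, ]
  tibble(
    n_bins = sum(ok),
    mae_total = mean(abs(p$total - t$total)),
    mae_minor = mean(abs(p$minor - t$minor)),
    exact_match = mean(round(p$total) == round(t$total) &
                         round(p$minor) == round(t$minor))
  )
}
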