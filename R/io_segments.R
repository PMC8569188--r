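# Allele-specific segment tables: one neutral schema for copy-number
# caller output (chrom, start, end, total_cn, major_cn, minor_cn,
# cellular_fraction) with purity/ploidy carried as ## header metadata.

#' Write an allele-specific segment profile
#'
#' @param segments Tibble `chrom`, `start`, `end` (0-based half-open),
#'   `total_cn`, `major_cn`, `minor_cn`, `cellular_fraction`.
#' @param path Output path.
#' @param purity,ploidy Sample-level estimates stored as `##purity=` /
#'   `##ploidy=` header lines.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path, purity, ploidy) {
  cols <- c("chrom", "start", "end", "total_cn", "major_cn", "minor_cn",
            "cellular_fraction")
  missing <- setdiff(cols, names(segments))
  if (length(missing)) {
    abort(sprintf("segment table lacks columns: %s",
                  paste(missing, collapse = ", ")))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("##purity=%s", format(purity, digits = 6)),
               sprintf("##ploidy=%s", format(ploidy, digits = 6)),
               paste(cols, collapse = "\t")), con)
  body <- do.call(sprintf, c(
    list("%s\t%d\t%d\t%s\t%s\t%s\t%s"),
    list(segments$chrom, as.integer(segments$start),
         as.integer(segments$end)),
    lapply(segments[cols[4:7]], function(x) {
      ifelse(is.na(x), "NA", format(x, digits = 6, trim = TRUE))
    })
  ))
  writeLines(body, con)
  invisible(path)
}

#' Read an allele-specific segment profile
#'
#' Validates the schema: segments must not overlap within a chromosome,
#' `major_cn + minor_cn` must equal `total_cn` where all three are
#' present, and `major_cn < minor_cn` is repaired by swapping with a
#' warning. A missing `##purity=` header is an error.
#'
#' @param path Path to a file written by [write_segments()] (or any TSV in
#'   the same schema).
#' @return A `segment_profile` tibble with attributes `purity` and
#'   `ploidy`.
#' @export
read_segments <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- lines[startsWith(lines, "##")]
  get_meta <- function(key) {
    hit <- grep(sprintf("^##%s=", key), meta, value = TRUE)
    if (!length(hit)) return(NA_real_)
    as.numeric(sub(sprintf("^##%s=", key), "", hit[1]))
  }
  pur <- get_meta("purity")
  plo <- get_meta("ploidy")
  if (is.na(pur)) abort(sprintf("%s: missing ##purity= header", path))
  body <- lines[!startsWith(lines, "##")]
  df <- readr::read_tsv(I(paste(body, collapse = "\n")),
                        show_col_types = FALSE)
  df <- as_tibble(df)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  swap <- !is.na(df$major_cn) & !is.na(df$minor_cn) &
    df$major_cn < df$minor_cn
  if (any(swap)) {
    warn(sprintf("%d segments had major_cn < minor_cn; swapped", sum(swap)))
    tmp <- df$major_cn[swap]
    df$major_cn[swap] <- df$minor_cn[swap]
    df$minor_cn[swap] <- tmp
  }
  both <- !is.na(df$major_cn) & !is.na(df$minor_cn) & !is.na(df$total_cn)
  bad_sum <- both & (df$major_cn + df$minor_cn != df$total_cn)
  if (any(bad_sum)) {
    abort(sprintf("segment %d: major_cn + minor_cn != total_cn",
                  which(bad_sum)[1]))
  }
  for (ch in unique(df$chrom)) {
    s <- arrange(filter(df, .data$chrom == ch), .data$start)
    if (nrow(s) > 1L && any(s$start[-1] < s$end[-nrow(s)])) {
      abort(sprintf("overlapping segments on %s", ch))
    }
  }
  if (any(df$cellular_fraction < 0 | df$cellular_fraction > 1,
          na.rm = TRUE)) {
    abort("cellular_fraction outside [0, 1]")
  }
  structure(df, purity = pur, ploidy = plo,
            class = c("segment_profile", class(df)))
}

#' Prepare per-variant input for subclonal deconvolution
#'
#' Annotates each called variant with the major/minor copy number of its
#' containing segment, applying the subclonal-CNA filter: a segment is
#' only used when its cellular fraction is at least `cf_threshold`
#' (inclusive; the published rule keeps CNAs estimated in >= 50% of
#' cells). Variants in sub-threshold segments, outside all segments, or on
#' contigs the segment table does not cover default to the diploid 1/1
#' state (the latter with a warning).
#'
#' @param calls Tibble with `chrom`, `pos`, `ref`, `alt`, `ref_count`,
#'   `alt_count`.
#' @param segments A `segment_profile` (or plain tibble in its schema).
#' @param cf_threshold Minimum cellular fraction, inclusive; default 0.5.
#' @return A tibble `chrom`, `pos`, `ref`, `alt`, `ref_count`,
#'   `alt_count`, `major_cn`, `minor_cn`, `normal_cn` (always 2).
#' @export
prepare_deconv_input <- function(calls, segments, cf_threshold = 0.5) {
  need <- c("ref_count", "alt_count")
  if (!all(need %in% names(calls))) {
    abort("`calls` must carry allele depths (ref_count, alt_count)")
  }
  major <- rep(1L, nrow(calls))
  minor <- rep(1L, nrow(calls))
  seg_chroms <- unique(segments$chrom)
  off_contig <- !(calls$chrom %in% seg_chroms)
  if (any(off_contig) && length(seg_chroms)) {
    warn(sprintf("%d variants on contigs absent from the segment table; assigned 1/1",
                 sum(off_contig)))
  }
  usable <- !is.na(segments$cellular_fraction) &
    segments$cellular_fraction >= cf_threshold
  seg <- segments[usable, , drop = FALSE]
  if (nrow(seg)) {
    for (i in seq_len(nrow(calls))) {
      hit <- which(seg$chrom == calls$chrom[i] &
                     seg$start <= calls$pos[i] - 1L &
                     calls$pos[i] - 1L < seg$end)
      if (length(hit)) {
        major[i] <- as.integer(seg$major_cn[hit[1]])
        minor[i] <- as.integer(seg$minor_cn[hit[1]])
      }
    }
  }
  tibble(chrom = calls$chrom, pos = calls$pos, ref = calls$ref,
         alt = calls$alt, ref_count = calls$ref_count,
         alt_count = calls$alt_count, major_cn = major, minor_cn = minor,
         normal_cn = 2L)
}
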