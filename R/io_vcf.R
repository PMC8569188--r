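# VCF, BED and truth-table interchange.
#
# Reading goes through vcfR; writing uses a minimal VCF 4.2 emitter (the
# records carry only the fields the evaluators consume).

vcf_header <- function(info = character(), format = character(),
                       samples = character()) {
  c("##fileformat=VCFv4.2",
    "##source=clonebench",
    info, format,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (length(samples)) c("FORMAT", samples)),
          collapse = "\t"))
}

#' Write a truth table as VCF
#'
#' Somatic ground truth exported with `CCF`, `EVAF` (expected VAF),
#' `ORIGIN`, `M` and `N` in INFO.
#'
#' @param truth Truth tibble from [compose_bulk()] (`$truth`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_vcf <- function(truth, path) {
  hdr <- vcf_header(info = c(
    '##INFO=<ID=CCF,Number=1,Type=Float,Description="True cancer cell fraction">',
    '##INFO=<ID=EVAF,Number=1,Type=Float,Description="Expected bulk variant allele frequency">',
    '##INFO=<ID=ORIGIN,Number=1,Type=String,Description="Clone of origin">',
    '##INFO=<ID=M,Number=1,Type=Integer,Description="Mutated copies in origin clone">',
    '##INFO=<ID=N,Number=1,Type=Integer,Description="Locus total copies in origin clone">'
  ))
  fmt_num <- function(x) ifelse(is.na(x), ".", format(x, digits = 6,
                                                      scientific = FALSE,
                                                      trim = TRUE))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tCCF=%s;EVAF=%s;ORIGIN=%s;M=%d;N=%d",
                  truth$chrom, truth$pos, truth$ref, truth$alt,
                  fmt_num(truth$true_ccf), fmt_num(truth$expected_vaf),
                  truth$origin, truth$m, truth$n)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write sampled observations as VCF with allele depths
#'
#' One sample column with `GT:AD:DP`; `AD` holds reference and alternate
#' read counts.
#'
#' @param obs Observations tibble from [compose_bulk()] (`$observations`).
#' @param path Output path.
#' @param sample_name Sample column name.
#' @return `path`, invisibly.
#' @export
write_observations_vcf <- function(obs, path, sample_name = "TUMOUR") {
  hdr <- vcf_header(
    info = '##INFO=<ID=ORIGIN,Number=1,Type=String,Description="Clone of origin">',
    format = c(
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
      '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allele depths">',
      '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">'
    ),
    samples = sample_name
  )
  depth <- ifelse(is.na(obs$depth), 0L, obs$depth)
  alt <- ifelse(is.na(obs$alt_count), 0L, obs$alt_count)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tORIGIN=%s\tGT:AD:DP\t0/1:%d,%d:%d",
                  obs$chrom, obs$pos, obs$ref, obs$alt, obs$origin,
                  depth - alt, alt, depth)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a call set as VCF
#'
#' @param calls Callset tibble (`chrom`, `pos`, `ref`, `alt`, optional
#'   `score`, `filter`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_callset_vcf <- function(calls, path) {
  hdr <- vcf_header(
    info = '##INFO=<ID=SCORE,Number=1,Type=Float,Description="Call confidence score">'
  )
  score <- if ("score" %in% names(calls)) calls$score else
    rep(NA_real_, nrow(calls))
  filt <- if ("filter" %in% names(calls)) calls$filter else
    rep("PASS", nrow(calls))
  info <- ifelse(is.na(score), ".",
                 paste0("SCORE=", format(score, digits = 6, trim = TRUE)))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t%s",
                  calls$chrom, calls$pos, calls$ref, calls$alt, filt, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a variant caller's VCF into a call set
#'
#' Multiallelic records are split into one call per alternate allele;
#' alleles are left-normalised (shared suffix then prefix trimmed, keeping
#' an anchor base). Scores come from `QUAL` or a named INFO field; calls
#' without a score receive `NA` and rank below every scored call in
#' precision-recall thresholding.
#'
#' @param path Path to a VCF (plain text or bgzipped).
#' @param score_field `"QUAL"` (default) or the name of a numeric INFO
#'   field.
#' @param pass_only Keep only records whose FILTER is `PASS` or `.`.
#' @return A `callset` tibble: `chrom`, `pos`, `ref`, `alt`, `score`,
#'   `filter`, with attribute `provenance` (the file path) and a count of
#'   dropped records reported via message.
#' @export
read_caller_vcf <- function(path, score_field = "QUAL",
                            pass_only = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  n_in <- nrow(fix)
  if (n_in == 0L) {
    out <- tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), score = numeric(), filter = character())
    return(structure(out, provenance = path,
                     class = c("callset", class(out))))
  }
  filt <- fix$FILTER %||% rep(".", n_in)
  filt[is.na(filt)] <- "."
  keep <- rep(TRUE, n_in)
  if (pass_only) keep <- filt %in% c("PASS", ".")
  dropped <- sum(!keep)
  fix <- fix[keep, , drop = FALSE]
  filt <- filt[keep]

  score <- if (identical(score_field, "QUAL")) {
    suppressWarnings(as.numeric(fix$QUAL))
  } else {
    suppressWarnings(as.numeric(
      vcfR::extract.info(v, element = score_field)[keep]
    ))
  }

  alt_split <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alt_split)
  pos <- suppressWarnings(as.integer(rep(fix$POS, n_alt)))
  if (anyNA(pos)) {
    abort(sprintf("unreadable POS at VCF record %d of %s",
                  which(is.na(as.integer(fix$POS)))[1], path))
  }
  rec <- tibble(
    chrom = rep(fix$CHROM, n_alt),
    pos = pos,
    ref = rep(toupper(fix$REF), n_alt),
    alt = toupper(unlist(alt_split)),
    score = rep(score, n_alt),
    filter = rep(filt, n_alt)
  )
  rec <- filter(rec, .data$alt != "*")
  norm <- normalise_alleles(rec$pos, rec$ref, rec$alt)
  rec$pos <- norm$pos
  rec$ref <- norm$ref
  rec$alt <- norm$alt
  rec <- distinct(rec, .data$chrom, .data$pos, .data$ref, .data$alt,
                  .keep_all = TRUE)
  if (dropped > 0L) {
    inform(sprintf("read %d records from %s; dropped %d by FILTER",
                   n_in, basename(path), dropped))
  }
  structure(rec, provenance = path, class = c("callset", class(rec)))
}

#' Read BED regions
#'
#' @param path BED file (first three columns used; 0-based half-open).
#' @return A tibble `chrom`, `start`, `end`.
#' @export
read_regions <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                        show_col_types = FALSE)
  if (ncol(df) < 3L) abort("BED file needs at least 3 columns")
  out <- tibble(chrom = as.character(df[[1]]), start = as.integer(df[[2]]),
                end = as.integer(df[[3]]))
  if (any(out$end <= out$start)) abort("BED intervals must have end > start")
  out
}

#' Write BED regions
#' @param regions Tibble `chrom`, `start`, `end` (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  readr::write_tsv(regions[c("chrom", "start", "end")], path,
                   col_names = FALSE)
  invisible(path)
}

#' Write / read a truth table as TSV
#'
#' Plain-text companion to the truth VCF: 1-based positions, one row per
#' variant with origin clone, true CCF, expected VAF, multiplicity and
#' locus total.
#'
#' @param truth Truth tibble.
#' @param path File path.
#' @return `path` (writer) or the truth tibble (reader).
#' @export
write_truth_table <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    chrom = readr::col_character(),
                    ref = readr::col_character(),
                    alt = readr::col_character()
                  ))
}
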