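# Seeded toy-data generators: reference sequences, known germline sites,
# and a synthetic "caller" that perturbs a truth table. Everything the
# toolkit consumes can be produced here, reproducibly, with no downloads.

#' Generate a toy reference genome
#'
#' Uniform-random sequence per contig, deterministic for a fixed seed.
#'
#' @param n_contigs Number of contigs (named `ctg1`, `ctg2`, ...).
#' @param contig_length Length of each contig in bp.
#' @param seed Integer seed.
#' @param path Optional FASTA output path; when given the sequences are
#'   also written there.
#' @return A named character vector of sequences (usable everywhere a
#'   reference is accepted).
#' @export
toy_reference <- function(n_contigs = 2, contig_length = 1e5, seed = 1,
                          path = NULL) {
  if (n_contigs < 1) abort("`n_contigs` must be >= 1")
  if (contig_length < 1) abort("`contig_length` must be >= 1")
  set.seed(seed)
  seqs <- vapply(seq_len(n_contigs), function(i) {
    paste(sample(c("A", "C", "G", "T"), contig_length, replace = TRUE),
          collapse = "")
  }, character(1))
  names(seqs) <- paste0("ctg", seq_len(n_contigs))
  if (!is.null(path)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  }
  seqs
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA path.
#' @return A named character vector of uppercase sequences.
#' @export
read_reference <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Generate a toy panel of known germline sites
#'
#' Stand-in for a dbSNP-style panel: biallelic sites at uniform positions,
#' roughly `density * genome length` of them, a configurable fraction
#' being short indels.
#'
#' @param ref Reference genome.
#' @param density Expected sites per bp, in `[0, 1]`.
#' @param seed Integer seed.
#' @param indel_fraction Fraction of sites that are indels.
#' @param path Optional VCF output path.
#' @return A tibble `chrom`, `pos`, `ref`, `alt`.
#' @export
toy_known_sites <- function(ref, density = 0.001, seed = 1,
                            indel_fraction = 0.1, path = NULL) {
  if (density < 0 || density > 1) abort("`density` must lie in [0, 1]")
  set.seed(seed)
  seqs <- ref_as_chars(ref)
  genome_len <- sum(nchar(seqs))
  n <- rbinom(1L, genome_len, density)
  if (n == 0L) {
    out <- known_sites_empty()
  } else {
    where <- draw_positions(seqs, n)
    is_indel <- runif(n) < indel_fraction
    rb <- ref_base(seqs, where$chrom, where$pos)
    out <- tibble(chrom = where$chrom, pos = where$pos, ref = rb,
                  alt = random_alt_base(rb))
    if (any(is_indel)) {
      ind <- novel_indels(seqs, sum(is_indel), mean = 0.5, variance = 0.3,
                          multiplier = 1)
      out$pos[is_indel] <- ind$pos
      out$chrom[is_indel] <- ind$chrom
      out$ref[is_indel] <- ind$ref
      out$alt[is_indel] <- ind$alt
    }
    out <- distinct(out, .data$chrom, .data$pos, .keep_all = TRUE) |>
      arrange(.data$chrom, .data$pos)
  }
  if (!is.null(path)) write_callset_vcf(out, path)
  out
}

#' Perturb a truth table into a synthetic call set
#'
#' A synthetic "caller" for exercising the evaluators with known error
#' labels: each truth variant is dropped (a false negative) with
#' probability `fn_rate`; `fp_count` novel false positive calls are
#' injected at uniform positions; observed VAFs are jittered with Gaussian
#' noise truncated to `[0, 1]`. Scores are drawn from Beta(4, 2) for true
#' calls and Beta(2, 4) for false ones, so score thresholds trade
#' precision against recall the way caller confidence scores do.
#'
#' @param truth Truth tibble with `chrom`, `pos`, `ref`, `alt` and
#'   optionally `expected_vaf` (used as the pre-noise VAF).
#' @param ref Reference genome (for false positive alleles); falls back to
#'   random alleles when `NULL`.
#' @param fn_rate False negative probability per truth variant, in
#'   `[0, 1]`.
#' @param fp_count Number of injected false positives.
#' @param vaf_noise Standard deviation of the VAF jitter.
#' @param seed Optional integer seed.
#' @return A `callset` tibble `chrom`, `pos`, `ref`, `alt`, `score`,
#'   `vaf`, `truth_label` (`"TP"`/`"FP"`).
#' @export
perturbed_callset <- function(truth, ref = NULL, fn_rate = 0.1,
                              fp_count = 10, vaf_noise = 0.02,
                              seed = NULL) {
  if (fn_rate < 0 || fn_rate > 1) abort("`fn_rate` must lie in [0, 1]")
  if (vaf_noise < 0) abort("`vaf_noise` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  kept <- truth[runif(nrow(truth)) >= fn_rate, , drop = FALSE]
  base_vaf <- if ("expected_vaf" %in% names(kept)) kept$expected_vaf else
    rep(0.5, nrow(kept))
  tp <- tibble(
    chrom = kept$chrom, pos = kept$pos, ref = kept$ref, alt = kept$alt,
    vaf = pmin(1, pmax(0, base_vaf + rnorm(nrow(kept), 0, vaf_noise))),
    score = rbeta(nrow(kept), 4, 2),
    truth_label = "TP"
  )
  fp <- tibble(chrom = character(), pos = integer(), ref = character(),
               alt = character(), vaf = numeric(), score = numeric(),
               truth_label = character())
  if (fp_count > 0) {
    if (!is.null(ref)) {
      where <- draw_positions(ref, fp_count)
      rb <- ref_base(ref, where$chrom, where$pos)
    } else {
      contigs <- unique(truth$chrom)
      where <- tibble(
        chrom = sample(contigs, fp_count, replace = TRUE),
        pos = sample.int(max(truth$pos), fp_count, replace = TRUE)
      )
      rb <- sample(c("A", "C", "G", "T"), fp_count, replace = TRUE)
    }
    fp <- tibble(
      chrom = where$chrom, pos = where$pos, ref = rb,
      alt = random_alt_base(rb),
      vaf = pmin(1, pmax(0, rbeta(fp_count, 1, 6))),
      score = rbeta(fp_count, 2, 4),
      truth_label = "FP"
    )
    # an injected position colliding with a truth variant would not be FP
    tkey <- variant_key(truth$chrom, truth$pos, truth$ref, truth$alt)
    fp <- fp[!variant_key(fp$chrom, fp$pos, fp$ref, fp$alt) %in% tkey, ]
  }
  out <- bind_rows(tp, fp)
  structure(out, class = c("callset", class(out)))
}
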