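#' Draw event lengths from a discretised lognormal
#'
#' CNV, indel and added-copy sizes follow `round(exp(g) * multiplier)`
#' with `g ~ Normal(mean, variance)`, floored at 1. With `variance = 0`
#' the draw is deterministic.
#'
#' @param n Number of draws.
#' @param mean,variance Parameters of the underlying normal (`variance`,
#'   not standard deviation).
#' @param multiplier Positive scale factor applied before rounding.
#' @return Integer vector of length `n`, all values `>= 1`.
#' @examples
#' sample_lognormal_length(3, -1, 0, 1e6) # always 367879
#' @export
sample_lognormal_length <- function(n, mean, variance, multiplier = 1) {
  if (variance < 0) abort("`variance` must be >= 0")
  if (multiplier <= 0) abort("`multiplier` must be > 0")
  g <- rnorm(n, mean = mean, sd = sqrt(variance))
  pmax(1L, as.integer(round(exp(g) * multiplier)))
}

#' Simulate germline point variants
#'
#' SNV and indel counts are binomial in the genome length at the
#' configured per-base rates. A configured fraction of each class is drawn
#' from a known-sites panel (position and alleles reused); the remainder
#' are placed uniformly with random alternate alleles, indel lengths drawn
#' from the configured lognormal. Each variant lands on one of the two
#' parental allele copies (A/B, equiprobable), i.e. all germline variants
#' are heterozygous.
#'
#' @param ref Reference genome: named character vector or `DNAStringSet`.
#' @param config A [sim_config()].
#' @param known_sites Optional tibble of known germline sites with columns
#'   `chrom`, `pos`, `ref`, `alt` (e.g. from [toy_known_sites()] or
#'   [read_caller_vcf()]). Required when either `dbsnp*proportion` is
#'   positive.
#' @return A tibble of variants: `chrom`, `pos` (1-based), `ref`, `alt`
#'   (VCF anchor-base convention for indels), `class`
#'   (`snv`/`insertion`/`deletion`), `origin = "germline"`, `allele`
#'   (`A`/`B`), `known`.
#' @export
simulate_germline_variants <- function(ref, config = sim_config(),
                                       known_sites = NULL) {
  seqs <- ref_as_chars(ref)
  genome_len <- sum(nchar(seqs))
  n_snv <- rbinom(1L, genome_len, config$snvgermline)
  n_ind <- rbinom(1L, genome_len, config$indgermline)

  need_known <- (config$dbsnpsnvproportion > 0 && n_snv > 0) ||
    (config$dbsnpindelproportion > 0 && n_ind > 0)
  if (need_known &&
      (is.null(known_sites) || nrow(known_sites) == 0L)) {
    abort("nonzero dbsnp proportion requires a non-empty `known_sites` table")
  }

  take_known <- function(sites, n) {
    if (n == 0L || nrow(sites) == 0L) return(sites[0, ])
    if (n > nrow(sites)) {
      warn(sprintf("only %d known sites available for %d requested; capping",
                   nrow(sites), n))
      n <- nrow(sites)
    }
    sites[sample.int(nrow(sites), n), ]
  }

  is_snv_site <- function(s) nchar(s$ref) == 1L & nchar(s$alt) == 1L

  # SNVs
  n_snv_known <- rbinom(1L, n_snv, config$dbsnpsnvproportion)
  snv_sites <- if (is.null(known_sites)) known_sites_empty() else
    known_sites[is_snv_site(known_sites), c("chrom", "pos", "ref", "alt")]
  if (config$dbsnpsnvproportion > 0 && n_snv_known > 0 &&
      nrow(snv_sites) == 0L) {
    abort("known_sites contains no SNV sites but dbsnpsnvproportion > 0")
  }
  ks <- take_known(snv_sites, n_snv_known)
  n_novel <- n_snv - nrow(ks)
  novel_pos <- draw_positions(seqs, n_novel)
  novel_ref <- ref_base(seqs, novel_pos$chrom, novel_pos$pos)
  snvs <- bind_rows(
    tibble(chrom = ks$chrom, pos = as.integer(ks$pos), ref = ks$ref,
           alt = ks$alt, known = TRUE),
    tibble(chrom = novel_pos$chrom, pos = novel_pos$pos, ref = novel_ref,
           alt = random_alt_base(novel_ref), known = FALSE)
  )
  if (nrow(snvs)) snvs$class <- "snv"

  # indels
  n_ind_known <- rbinom(1L, n_ind, config$dbsnpindelproportion)
  ind_sites <- if (is.null(known_sites)) known_sites_empty() else
    known_sites[!is_snv_site(known_sites), c("chrom", "pos", "ref", "alt")]
  if (config$dbsnpindelproportion > 0 && n_ind_known > 0 &&
      nrow(ind_sites) == 0L) {
    abort("known_sites contains no indel sites but dbsnpindelproportion > 0")
  }
  ki <- take_known(ind_sites, n_ind_known)
  n_ind_novel <- n_ind - nrow(ki)
  indels <- bind_rows(
    if (nrow(ki)) tibble(chrom = ki$chrom, pos = as.integer(ki$pos),
                         ref = ki$ref, alt = ki$alt, known = TRUE),
    novel_indels(seqs, n_ind_novel, config$indmean, config$indvariance,
                 config$indmultiply)
  )
  if (nrow(indels)) {
    indels$class <- ifelse(nchar(indels$alt) > nchar(indels$ref),
                           "insertion", "deletion")
  }

  out <- bind_rows(snvs, indels)
  if (nrow(out) == 0L) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), class = character(),
                  origin = character(), allele = character(),
                  known = logical()))
  }
  out$origin <- "germline"
  out$allele <- sample(c("A", "B"), nrow(out), replace = TRUE)
  out[c("chrom", "pos", "ref", "alt", "class", "origin", "allele", "known")]
}

known_sites_empty <- function() {
  tibble(chrom = character(), pos = integer(), ref = character(),
         alt = character())
}

# novel indels with lognormal lengths, VCF anchor-base alleles
novel_indels <- function(seqs, n, mean, variance, multiplier) {
  if (n <= 0L) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), known = logical()))
  }
  lens <- sample_lognormal_length(n, mean, variance, multiplier)
  where <- draw_positions(seqs, n)
  is_ins <- runif(n) < 0.5
  chrom_len <- nchar(seqs)[where$chrom]
  # deletions must fit on the contig after the anchor base
  lens <- pmin(lens, pmax(1L, chrom_len - where$pos))
  anchor <- ref_base(seqs, where$chrom, where$pos)
  ref <- ifelse(is_ins, anchor,
                toupper(substring(seqs[where$chrom], where$pos,
                                  where$pos + lens)))
  alt <- ifelse(is_ins, paste0(anchor, random_bases(lens)), anchor)
  tibble(chrom = where$chrom, pos = where$pos, ref = ref, alt = alt,
         known = FALSE)
}

#' Simulate germline copy-number variants
#'
#' Exactly `cnvrepgermline` replications and `cnvdelgermline` deletions are
#' placed uniformly over the genome, with lognormal lengths
#' (`cnvgermline*` parameters) and, for replications, lognormal added-copy
#' counts (`cnvcopies*`, rounded and floored at 1). Each event targets one
#' parental allele copy.
#'
#' @inheritParams simulate_germline_variants
#' @return A tibble of CNA events: `chrom`, `start`, `end` (0-based
#'   half-open), `kind` (`replication`/`deletion`), `added_copies`,
#'   `allele`, `origin = "germline"`, `time` (uniform application order).
#' @export
simulate_germline_cnas <- function(ref, config = sim_config()) {
  n_rep <- config$cnvrepgermline
  n_del <- config$cnvdelgermline
  n <- n_rep + n_del
  if (n == 0L) {
    return(cna_events_empty())
  }
  seqs <- ref_as_chars(ref)
  lens <- sample_lognormal_length(n, config$cnvgermlinemean,
                                  config$cnvgermlinevariance,
                                  config$cnvgermlinemultiply)
  where <- draw_positions(seqs, n)
  chrom_len <- nchar(seqs)[where$chrom]
  start <- pmin(where$pos - 1L, pmax(0L, chrom_len - lens))
  end <- pmin(start + lens, chrom_len)
  kind <- c(rep("replication", n_rep), rep("deletion", n_del))
  added <- ifelse(kind == "replication",
                  sample_lognormal_length(n, config$cnvcopiesmean,
                                          config$cnvcopiesvariance, 1),
                  NA_integer_)
  tibble(chrom = where$chrom, start = as.integer(start),
         end = as.integer(end), kind = kind,
         added_copies = as.integer(added),
         allele = sample(c("A", "B"), n, replace = TRUE),
         origin = "germline", time = runif(n))
}

cna_events_empty <- function() {
  tibble(chrom = character(), start = integer(), end = integer(),
         kind = character(), added_copies = integer(), allele = character(),
         origin = character(), time = numeric())
}

#' Simulate tumour-wide somatic events on a clone tree
#'
#' Tumour-wide somatic SNV, indel and CNV counts are split across branches
#' multinomially with probabilities proportional to branch weights. Exactly
#' `aneuploid` single-chromosome events are assigned (uniform clone,
#' uniform chromosome, gain/loss equiprobable), and with probability
#' `wgdprob` exactly one whole-genome duplication is assigned to a
#' uniformly chosen clone. Every event carries a uniform `time` in `(0,1)`
#' giving its order along the branch.
#'
#' @param config A [sim_config()].
#' @param tree A `clone_tree`.
#' @param ref Reference genome (for positions and alleles).
#' @return A tibble of events with columns `origin` (clone), `class`
#'   (`snv`, `insertion`, `deletion`, `cnv_replication`, `cnv_deletion`,
#'   `aneuploidy_gain`, `aneuploidy_loss`, `wgd`), `chrom`, `pos`, `ref`,
#'   `alt`, `start`, `end`, `added_copies`, `time`.
#' @export
simulate_somatic_events <- function(config, tree, ref) {
  bw <- branch_weights(tree)
  seqs <- ref_as_chars(ref)
  chroms <- names(seqs)

  split_counts <- function(total) {
    if (total == 0L) return(setNames(integer(length(bw$clone)), bw$clone))
    setNames(as.integer(rmultinom(1L, total, bw$weight)), bw$clone)
  }
  per_clone <- list(
    snv = split_counts(config$snvsomatic_total),
    indel = split_counts(config$indsomatic_total),
    cnv_rep = split_counts(config$cnvsomatic_rep),
    cnv_del = split_counts(config$cnvsomatic_del)
  )

  pieces <- list()
  n_snv <- sum(per_clone$snv)
  if (n_snv > 0L) {
    where <- draw_positions(seqs, n_snv)
    rb <- ref_base(seqs, where$chrom, where$pos)
    pieces$snv <- tibble(
      origin = rep(names(per_clone$snv), per_clone$snv),
      class = "snv", chrom = where$chrom, pos = where$pos,
      ref = rb, alt = random_alt_base(rb)
    )
  }
  n_ind <- sum(per_clone$indel)
  if (n_ind > 0L) {
    ind <- novel_indels(seqs, n_ind, config$indmean, config$indvariance,
                        config$indmultiply)
    pieces$indel <- tibble(
      origin = rep(names(per_clone$indel), per_clone$indel),
      class = ifelse(nchar(ind$alt) > nchar(ind$ref),
                     "insertion", "deletion"),
      chrom = ind$chrom, pos = ind$pos, ref = ind$ref, alt = ind$alt
    )
  }
  n_cna <- sum(per_clone$cnv_rep) + sum(per_clone$cnv_del)
  if (n_cna > 0L) {
    lens <- sample_lognormal_length(n_cna, config$cnvsomaticmean,
                                    config$cnvsomaticvariance,
                                    config$cnvsomaticmultiply)
    where <- draw_positions(seqs, n_cna)
    chrom_len <- nchar(seqs)[where$chrom]
    start <- pmin(where$pos - 1L, pmax(0L, chrom_len - lens))
    end <- pmin(start + lens, chrom_len)
    kind <- c(rep("cnv_replication", sum(per_clone$cnv_rep)),
              rep("cnv_deletion", sum(per_clone$cnv_del)))
    pieces$cna <- tibble(
      origin = c(rep(names(per_clone$cnv_rep), per_clone$cnv_rep),
                 rep(names(per_clone$cnv_del), per_clone$cnv_del)),
      class = kind, chrom = where$chrom, start = as.integer(start),
      end = as.integer(end),
      added_copies = ifelse(kind == "cnv_replication",
                            sample_lognormal_length(n_cna,
                                                    config$cnvcopiesmean,
                                                    config$cnvcopiesvariance,
                                                    1),
                            NA_integer_)
    )
  }
  if (config$aneuploid > 0L) {
    pieces$aneuploidy <- tibble(
      origin = sample(bw$clone, config$aneuploid, replace = TRUE),
      class = sample(c("aneuploidy_gain", "aneuploidy_loss"),
                     config$aneuploid, replace = TRUE),
      chrom = sample(chroms, config$aneuploid, replace = TRUE)
    )
  }
  if (runif(1L) < config$wgdprob) {
    pieces$wgd <- tibble(origin = sample(bw$clone, 1L), class = "wgd")
  }

  template <- tibble(
    origin = character(), class = character(), chrom = character(),
    pos = integer(), ref = character(), alt = character(),
    start = integer(), end = integer(), added_copies = integer(),
    time = numeric()
  )
  out <- bind_rows(c(list(template), unname(pieces)))
  if (nrow(out)) out$time <- runif(nrow(out))
  arrange(out, .data$origin, .data$time)
}
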