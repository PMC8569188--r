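# Bulk-sample composition: mix clone genomes at a chosen purity, derive
# per-variant ground truth (CCF, expected VAF) and sample count-level
# observations at a target depth.

# locus totals n for arbitrary loci in one clone's state
state_locus_totals <- function(st, chrom, pos) {
  n <- integer(length(pos))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    ids <- copies_of_chrom(st, ch)
    cnt <- integer(length(sel))
    for (id in ids) {
      segs <- st$copies[[id]]$segs
      cnt <- cnt + vapply(pos[sel] - 1L, function(p) iv_covers(segs, p),
                          logical(1))
    }
    n[sel] <- cnt
  }
  n
}

# m (mutated copies) and n (locus total) for a set of variant keys in one
# clone; variants absent from the clone's table get m = 0
state_m_n <- function(st, variants) {
  key <- variant_key(variants$chrom, variants$pos, variants$ref,
                     variants$alt)
  vkey <- variant_key(st$variants$chrom, st$variants$pos, st$variants$ref,
                      st$variants$alt)
  m <- integer(length(key))
  hit <- match(key, vkey)
  m[!is.na(hit)] <- lengths(st$variants$copy_ids)[hit[!is.na(hit)]]
  n <- state_locus_totals(st, variants$chrom, variants$pos)
  tibble(m = m, n = n)
}

#' True cancer cell fractions of somatic variants
#'
#' The true CCF of a somatic variant is the sum of tumour proportions of
#' the clones that contain it. By default a clone whose profile has lost
#' the variant again (multiplicity 0 after a deletion) is excluded from the
#' sum; set `adjust_deletions = FALSE` to use the plain subtree sum at the
#' origin clone instead.
#'
#' @param profiles A `clone_profiles` object.
#' @param tree The `clone_tree` the profiles were built on.
#' @param comp A `bulk_composition`.
#' @param variants Tibble of somatic variants (`chrom`, `pos`, `ref`,
#'   `alt`, `origin`); defaults to every somatic variant present in any
#'   composition clone.
#' @param adjust_deletions Exclude clones that lost the variant.
#' @return The `variants` tibble with a `true_ccf` column.
#' @export
true_ccf <- function(profiles, tree, comp, variants = NULL,
                     adjust_deletions = TRUE) {
  variants <- variants %||% somatic_variant_universe(profiles, comp)
  if (any(variants$origin == "germline")) {
    abort("CCF is defined for somatic variants only; germline rows present")
  }
  if (adjust_deletions) {
    carried <- matrix(0, nrow(variants), length(comp$clone),
                      dimnames = list(NULL, comp$clone))
    for (clone in comp$clone) {
      mn <- state_m_n(profile_state(profiles, clone), variants)
      carried[, clone] <- mn$m >= 1L
    }
    ccf <- as.numeric(carried %*% comp$tumour_fraction)
  } else {
    ccf <- vapply(variants$origin, function(cl) subtree_ccf(tree, comp, cl),
                  numeric(1), USE.NAMES = FALSE)
  }
  mutate(variants, true_ccf = ccf)
}

# all somatic variants with m >= 1 in at least one composition clone;
# the rare case of two branches independently drawing the same variant
# key collapses to one record (its CCF sums over all carrying clones)
somatic_variant_universe <- function(profiles, comp) {
  tabs <- map(comp$clone, function(clone) {
    st <- profile_state(profiles, clone)
    v <- st$variants
    v[v$origin != "germline" & lengths(v$copy_ids) >= 1L,
      c("chrom", "pos", "ref", "alt", "class", "origin")]
  })
  distinct(bind_rows(tabs), .data$chrom, .data$pos, .data$ref, .data$alt,
           .keep_all = TRUE)
}

#' Expected bulk variant allele frequency
#'
#' The allele fraction that mixing reads from the composition's clones and
#' normal cells induces at a variant:
#' `sum_c f_c * m_c / (sum_c f_c * n_c + f_normal * n_germline)`,
#' where `f_c` are clone read fractions, `m_c` / `n_c` the mutated and
#' total copy numbers at the locus in clone `c`, and `n_germline` the
#' germline copy number there (2 at autosomal loci unless a germline CNV
#' altered it).
#'
#' @inheritParams true_ccf
#' @param variants Tibble of variants (`chrom`, `pos`, `ref`, `alt`).
#' @return `variants` with an `expected_vaf` column; loci deleted from
#'   every cell get `NA` and a warning.
#' @export
expected_vaf <- function(profiles, comp, variants) {
  num <- den <- numeric(nrow(variants))
  for (i in seq_along(comp$clone)) {
    clone <- comp$clone[i]
    f <- comp$read_fraction[i]
    mn <- state_m_n(profile_state(profiles, clone), variants)
    num <- num + f * mn$m
    den <- den + f * mn$n
  }
  f_normal <- attr(comp, "normal_fraction")
  germ <- profile_state(profiles, "germline")
  germ_mn <- state_m_n(germ, variants)
  den <- den + f_normal * germ_mn$n
  # germline variants contribute their germline mutated copies too
  if ("origin" %in% names(variants)) {
    num <- num + ifelse(variants$origin == "germline",
                        f_normal * germ_mn$m, 0)
  }
  vaf <- ifelse(den > 0, num / den, NA_real_)
  if (anyNA(vaf)) {
    warn(sprintf("%d variant loci are deleted in all cells; expected VAF undefined",
                 sum(is.na(vaf))))
  }
  mutate(variants, expected_vaf = vaf)
}

#' Sample a count-level sequencing observation
#'
#' Depth is Poisson around the mean target depth; the alternate-allele
#' count is binomial in the depth at the expected VAF, or beta-binomial
#' when `overdispersion > 0` (`overdispersion` is the intra-class
#' correlation rho; the beta success probability has mean `expected_vaf`).
#'
#' @param expected_vaf Numeric vector of expected allele fractions.
#' @param mean_depth Mean coverage (single value or per-variant vector).
#' @param overdispersion Beta-binomial rho in `[0, 1)`; 0 gives plain
#'   binomial sampling.
#' @return A tibble `depth`, `alt_count`, `vaf` (`NA` when depth is 0 —
#'   the locus is uncovered).
#' @export
sample_observation <- function(expected_vaf, mean_depth,
                               overdispersion = 0) {
  if (any(expected_vaf < 0 | expected_vaf > 1, na.rm = TRUE)) {
    abort("`expected_vaf` must lie in [0, 1]")
  }
  if (any(mean_depth < 0)) abort("`mean_depth` must be >= 0")
  if (overdispersion < 0 || overdispersion >= 1) {
    abort("`overdispersion` must lie in [0, 1)")
  }
  n <- length(expected_vaf)
  depth <- rpois(n, rep_len(mean_depth, n))
  p <- expected_vaf
  if (overdispersion > 0) {
    s <- (1 - overdispersion) / overdispersion
    a <- p * s
    b <- (1 - p) * s
    ok <- !is.na(p) & p > 0 & p < 1
    p[ok] <- rbeta(sum(ok), a[ok], b[ok])
  }
  alt <- ifelse(is.na(p), NA_integer_, rbinom(n, depth, ifelse(is.na(p), 0, p)))
  tibble(depth = depth, alt_count = alt,
         vaf = ifelse(depth > 0, alt / depth, NA_real_))
}

#' Compose a bulk tumour sample with ground truth
#'
#' Mixes the composition's clones and normal cells, producing one truth
#' record per somatic variant present in at least one composition clone
#' (true CCF, expected VAF, origin-clone multiplicity and locus total) and
#' one sampled observation per variant. Germline variants are included in
#' the observations and flagged in the truth table with no CCF.
#'
#' @inheritParams true_ccf
#' @param target_depth Mean coverage; `Inf` gives noise-free observations
#'   whose VAF equals the expected VAF exactly.
#' @param overdispersion Passed to [sample_observation()].
#' @param sample_id Sample identifier recorded in both tables.
#' @param include_germline Include germline variants in the observations.
#' @return A `bulk_sample` object with tibbles `$truth` (somatic ground
#'   truth) and `$observations` (all variants with sampled depths and
#'   VAFs), plus `$composition`, `$purity`, `$target_depth`, `$sample_id`.
#' @export
compose_bulk <- function(profiles, tree, comp, target_depth,
                         overdispersion = 0, sample_id = "S1",
                         include_germline = TRUE) {
  missing <- setdiff(comp$clone, names(profiles$states))
  if (length(missing)) {
    abort(sprintf("composition clones lack profiles: %s",
                  paste(missing, collapse = ", ")))
  }
  if (target_depth < 0) abort("`target_depth` must be >= 0")

  somatic <- somatic_variant_universe(profiles, comp)
  somatic <- true_ccf(profiles, tree, comp, somatic)
  somatic <- expected_vaf(profiles, comp, somatic)
  origin_mn <- map(seq_len(nrow(somatic)), function(i) {
    state_m_n(profile_state(profiles, somatic$origin[i]), somatic[i, ])
  })
  somatic$m <- map_int(origin_mn, ~ as.integer(.x$m[1]))
  somatic$n <- map_int(origin_mn, ~ as.integer(.x$n[1]))

  germ <- profile_state(profiles, "germline")
  truth <- somatic |>
    transmute(sample = sample_id, chrom = .data$chrom, pos = .data$pos,
              ref = .data$ref, alt = .data$alt, class = .data$class,
              origin = .data$origin, true_ccf = .data$true_ccf,
              expected_vaf = .data$expected_vaf, m = .data$m, n = .data$n)

  obs_vars <- somatic[c("chrom", "pos", "ref", "alt", "class", "origin",
                        "expected_vaf")]
  if (include_germline && nrow(germ$variants)) {
    gv <- germ$variants[c("chrom", "pos", "ref", "alt", "class")]
    gv$origin <- "germline"
    gv <- expected_vaf(profiles, comp, gv)
    obs_vars <- bind_rows(obs_vars, gv)
  }
  if (is.infinite(target_depth)) {
    obs <- mutate(obs_vars, depth = NA_integer_, alt_count = NA_integer_,
                  vaf = .data$expected_vaf)
  } else {
    drawn <- sample_observation(obs_vars$expected_vaf, target_depth,
                                overdispersion)
    obs <- bind_cols(obs_vars, drawn)
  }
  obs <- mutate(obs, sample = sample_id, .before = 1)

  structure(list(truth = truth, observations = obs, composition = comp,
                 purity = purity(comp), target_depth = target_depth,
                 sample_id = sample_id),
            class = "bulk_sample")
}

#' @export
print.bulk_sample <- function(x, ...) {
  cat(sprintf(
    "<bulk_sample %s> purity %.2f, target depth %sx, %d somatic truth records, %d observations\n",
    x$sample_id, x$purity, format(x$target_depth), nrow(x$truth),
    nrow(x$observations)))
  invisible(x)
}

#' @describeIn compose_bulk Truth and observations joined into one tibble.
#' @param x A `bulk_sample`.
#' @param ... Unused.
#' @export
tidy.bulk_sample <- function(x, ...) {
  left_join(x$observations,
            select(x$truth, -"sample", -"class", -"origin",
                   -"expected_vaf"),
            by = c("chrom", "pos", "ref", "alt")) |>
    relocate("sample")
}

#' @describeIn compose_bulk One-row summary (purity, depth, counts).
#' @export
glance.bulk_sample <- function(x, ...) {
  tibble(sample = x$sample_id, purity = x$purity,
         target_depth = x$target_depth, n_truth = nrow(x$truth),
         n_observations = nrow(x$observations),
         mean_depth = mean(x$observations$depth, na.rm = TRUE))
}

#' Emit toy paired-end reads over target regions
#'
#' A deliberately simple read emitter for smoke-testing downstream format
#' handling: fragments are drawn uniformly from target regions of source
#' haplotype sequences chosen in proportion to mixing weights, and the two
#' mates are the fragment's ends (mate 2 reverse-complemented), with
#' independent per-base substitution errors. There is no error profile, GC
#' bias, or insert-size model.
#'
#' @param sources Named list of haplotype sequence sets (each a named
#'   character vector of contig sequences), e.g. one per clone plus
#'   germline.
#' @param weights Named nonnegative weights over `names(sources)`.
#' @param targets Tibble `chrom`, `start`, `end` (0-based half-open)
#'   naming contigs present in every source.
#' @param depth Desired mean coverage of the target regions.
#' @param read_len Read length in bp.
#' @param error_rate Per-base substitution error probability.
#' @param fragment_len Outer fragment length (`>= read_len`).
#' @param prefix Output path prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq`.
#' @return Invisibly, the number of read pairs written.
#' @export
emit_toy_reads <- function(sources, weights, targets, depth,
                           read_len = 151, error_rate = 0,
                           fragment_len = 2 * read_len, prefix = "toy") {
  stopifnot(read_len >= 1, fragment_len >= read_len)
  f1 <- paste0(prefix, "_1.fastq")
  f2 <- paste0(prefix, "_2.fastq")
  if (nrow(targets) == 0L || depth <= 0) {
    if (nrow(targets) == 0L) warn("empty target set; writing empty FASTQ files")
    writeLines(character(), f1)
    writeLines(character(), f2)
    return(invisible(0L))
  }
  w <- weights[names(sources)] / sum(weights)
  tlen <- targets$end - targets$start
  n_pairs <- as.integer(round(depth * sum(tlen) / (2 * read_len)))
  if (n_pairs == 0L) {
    writeLines(character(), f1)
    writeLines(character(), f2)
    return(invisible(0L))
  }
  src <- sample(names(sources), n_pairs, replace = TRUE, prob = w)
  ti <- sample.int(nrow(targets), n_pairs, replace = TRUE,
                   prob = tlen / sum(tlen))
  frag_start <- targets$start[ti] +
    floor(runif(n_pairs) * pmax(1, tlen[ti] - fragment_len + 1))
  add_errors <- function(seqs) {
    if (error_rate <= 0) return(seqs)
    vapply(seqs, function(s) {
      b <- strsplit(s, "")[[1]]
      hit <- runif(length(b)) < error_rate
      if (any(hit)) b[hit] <- random_alt_base(b[hit])
      paste(b, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  revcomp <- function(s) {
    chartr("ACGT", "TGCA",
           vapply(strsplit(s, ""), function(x) paste(rev(x), collapse = ""),
                  character(1)))
  }
  r1 <- r2 <- character(n_pairs)
  for (i in seq_len(n_pairs)) {
    seq <- ref_as_chars(sources[[src[i]]])[[targets$chrom[ti[i]]]]
    lo <- frag_start[i] + 1L
    hi <- min(nchar(seq), frag_start[i] + fragment_len)
    frag <- substring(seq, lo, hi)
    r1[i] <- substring(frag, 1L, min(read_len, nchar(frag)))
    r2[i] <- revcomp(substring(frag, max(1L, nchar(frag) - read_len + 1L),
                               nchar(frag)))
  }
  r1 <- add_errors(r1)
  r2 <- add_errors(r2)
  qual <- function(s) strrep("I", nchar(s))
  ids <- sprintf("@toyread%06d", seq_len(n_pairs))
  writeLines(as.vector(rbind(paste0(ids, "/1"), r1, "+", qual(r1))), f1)
  writeLines(as.vector(rbind(paste0(ids, "/2"), r2, "+", qual(r2))), f2)
  invisible(n_pairs)
}
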