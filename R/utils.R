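# Internal helpers: interval arithmetic on 0-based half-open segment sets,
# allele normalisation, and variant keys.
#
# A segment set is a two-column numeric matrix (start, end), start < end,
# kept sorted and disjoint. An empty set is a 0-row matrix.

iv_new <- function(start = numeric(), end = numeric()) {
  keep <- end > start
  m <- cbind(start = start[keep], end = end[keep])
  if (nrow(m) > 1L) m <- m[order(m[, 1L]), , drop = FALSE]
  m
}

iv_len <- function(iv) if (nrow(iv) == 0L) 0 else sum(iv[, 2L] - iv[, 1L])

# intersect a segment set with a single window [start, end)
iv_intersect <- function(iv, start, end) {
  if (nrow(iv) == 0L) return(iv)
  s <- pmax(iv[, 1L], start)
  e <- pmin(iv[, 2L], end)
  iv_new(s, e)
}

# remove window [start, end) from a segment set
iv_subtract <- function(iv, start, end) {
  if (nrow(iv) == 0L) return(iv)
  out_s <- c(iv[, 1L], pmax(iv[, 1L], end))
  out_e <- c(pmin(iv[, 2L], start), iv[, 2L])
  iv_new(out_s, out_e)
}

# does the set cover 0-based position `pos0`?
iv_covers <- function(iv, pos0) {
  nrow(iv) > 0L && any(iv[, 1L] <= pos0 & pos0 < iv[, 2L])
}

iv_overlaps <- function(iv, start, end) {
  nrow(iv) > 0L && any(iv[, 1L] < end & start < iv[, 2L])
}

# Left-normalise indel alleles by trimming the shared suffix, then the
# shared prefix (keeping one anchor base), adjusting the 1-based position.
# Vectorised over records.
normalise_alleles <- function(pos, ref, alt) {
  pos <- as.integer(pos)
  ref <- toupper(ref)
  alt <- toupper(alt)
  for (i in seq_along(pos)) {
    r <- ref[i]; a <- alt[i]
    # trim common suffix
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    # trim common prefix, keeping at least one base each
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r))
      a <- substr(a, 2L, nchar(a))
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- r; alt[i] <- a
  }
  tibble(pos = pos, ref = ref, alt = alt)
}

variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Coerce a reference (named character vector or Biostrings::DNAStringSet)
# to a named character vector of sequences.
ref_as_chars <- function(ref) {
  if (inherits(ref, "DNAStringSet")) {
    out <- as.character(ref)
    names(out) <- names(ref)
    return(out)
  }
  if (is.character(ref) && !is.null(names(ref))) return(toupper(ref))
  abort("`ref` must be a named character vector or a DNAStringSet")
}

ref_lengths <- function(ref) {
  seqs <- ref_as_chars(ref)
  setNames(nchar(seqs), names(seqs))
}

# draw n genome positions uniformly: contig proportional to length,
# 1-based position uniform within contig
draw_positions <- function(ref, n) {
  lens <- ref_lengths(ref)
  if (n == 0L) {
    return(tibble(chrom = character(), pos = integer()))
  }
  chrom <- sample(names(lens), n, replace = TRUE, prob = lens / sum(lens))
  pos <- as.integer(floor(runif(n) * lens[chrom])) + 1L
  tibble(chrom = chrom, pos = pos)
}

ref_base <- function(ref, chrom, pos) {
  seqs <- ref_as_chars(ref)
  toupper(substring(seqs[chrom], pos, pos))
}

random_alt_base <- function(ref_base) {
  vapply(ref_base, function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  }, character(1), USE.NAMES = FALSE)
}

random_bases <- function(n_each) {
  vapply(n_each, function(k) {
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
  }, character(1))
}
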