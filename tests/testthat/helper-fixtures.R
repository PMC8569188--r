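# Shared builders for tests. Everything is generated in code at test time.

eight_clone_structure <- function() {
  paste0("clone1,2,germline,clone2,1,clone1,clone3,3,clone1,",
         "clone4,1,clone2,clone5,1,clone2,clone6,1,clone4,",
         "clone7,1,clone5,clone8,1,clone5")
}

chain_tree <- function() {
  # germline -> A -> B -> C
  parse_structure("A,1,germline,B,1,A,C,1,B")
}

small_ref <- function(len = 2e4, n = 1, seed = 11) {
  toy_reference(n_contigs = n, contig_length = len, seed = seed)
}

# a diploid tumour simulation: SNVs only, no copy-number events
diploid_sim <- function(tree, ref, n_snv = 200, seed = 1) {
  set.seed(seed)
  cfg <- sim_config(snvsomatic_total = n_snv, indsomatic_total = 0,
                    cnvsomatic_rep = 0, cnvsomatic_del = 0,
                    cnvrepgermline = 0, cnvdelgermline = 0,
                    aneuploid = 0, wgdprob = 0)
  ev <- simulate_somatic_events(cfg, tree, ref)
  build_clone_profiles(tree, ref, somatic_events = ev)
}

# hand-written somatic event rows in the schema build_clone_profiles expects
somatic_event_row <- function(origin, class, chrom = "ctg1", pos = NA,
                              ref = NA, alt = NA, start = NA, end = NA,
                              added_copies = NA, allele = NA, time = 0.5) {
  tibble::tibble(origin = origin, class = class, chrom = chrom,
                 pos = as.integer(pos), ref = ref, alt = alt,
                 start = as.integer(start), end = as.integer(end),
                 added_copies = as.integer(added_copies), allele = allele,
                 time = time)
}

# brute-force confusion counting on keyed sets (independent of match_calls)
brute_confusion <- function(truth_keys, call_keys) {
  tp <- sum(call_keys %in% truth_keys)
  fp <- sum(!call_keys %in% truth_keys)
  fn <- sum(!truth_keys %in% call_keys)
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(tp = tp, fp = fp, fn = fn, precision = p, recall = r, f1 = f)
}

# brute-force adjusted Rand index from explicit pair counting
brute_ari <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa && !sb) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  denom <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (denom == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / denom
}

# brute-force MADif straight from its definition
brute_madif <- function(cmp) {
  samples <- unique(cmp$sample)
  vals <- vapply(samples, function(s) {
    rows <- cmp[cmp$sample == s, ]
    sum(abs(rows$true_ccf - rows$estimated_ccf)) / nrow(rows)
  }, numeric(1))
  sum(vals) / length(samples)
}
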