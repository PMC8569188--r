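test_that("expected VAF matches the read-mixing arithmetic", {
  ref <- small_ref(len = 1e4, seed = 2)
  tree <- parse_structure("A,1,germline")
  base <- substring(ref[["ctg1"]], 500, 500)
  ev <- somatic_event_row("A", "snv", pos = 500, ref = base, alt = "N",
                          time = 0.5)
  prof <- build_clone_profiles(tree, ref, somatic_events = ev)
  v <- tibble::tibble(chrom = "ctg1", pos = 500L, ref = base, alt = "N",
                      origin = "A")

  # clonal het SNV, diploid, purity 1 -> 0.5
  full <- bulk_composition(c(A = 1), purity = 1)
  expect_equal(expected_vaf(prof, full, v)$expected_vaf, 0.5)
  # purity 0.75 -> 0.75 * 1 / (0.75 * 2 + 0.25 * 2) = 0.375
  part <- bulk_composition(c(A = 1), purity = 0.75)
  expect_equal(expected_vaf(prof, part, v)$expected_vaf, 0.375)
})

test_that("expected VAF agrees with independent recomputation from m and n", {
  ref <- small_ref(len = 2e4, seed = 4)
  tree <- chain_tree()
  set.seed(40)
  cfg <- sim_config(snvsomatic_total = 60, indsomatic_total = 0,
                    cnvsomatic_rep = 3, cnvsomatic_del = 3,
                    cnvrepgermline = 0, cnvdelgermline = 0,
                    aneuploid = 1, wgdprob = 1)
  ev <- simulate_somatic_events(cfg, tree, ref)
  prof <- suppressWarnings(build_clone_profiles(tree, ref,
                                                somatic_events = ev))
  comp <- bulk_composition(c(A = 0.5, B = 0.3, C = 0.2), purity = 0.8)
  vars <- true_ccf(prof, tree, comp)
  got <- expected_vaf(prof, comp, vars)
  mult <- variant_multiplicity(prof)
  for (i in sample.int(nrow(got), 15)) {
    num <- den <- 0
    for (j in seq_len(nrow(comp))) {
      cl <- comp$clone[j]
      row <- mult[mult$clone == cl & mult$chrom == got$chrom[i] &
                    mult$pos == got$pos[i] & mult$alt == got$alt[i], ]
      m <- if (nrow(row)) row$m else 0L
      n_cl <- cn_at(prof, cl, got$chrom[i], got$pos[i])$total
      num <- num + comp$read_fraction[j] * m
      den <- den + comp$read_fraction[j] * n_cl
    }
    den <- den + attr(comp, "normal_fraction") *
      cn_at(prof, "germline", got$chrom[i], got$pos[i])$total
    expect_equal(got$expected_vaf[i], num / den, tolerance = 1e-12)
  }
})

test_that("true CCF subtracts clones that lost the variant to deletions", {
  ref <- small_ref(len = 1e4, seed = 2)
  tree <- chain_tree()
  base <- substring(ref[["ctg1"]], 800, 800)
  germ_cna <- tibble::tibble(chrom = "ctg1", start = 0L, end = 10000L,
                             kind = "deletion", added_copies = NA_integer_,
                             allele = "B", origin = "germline", time = 0.5)
  ev <- dplyr::bind_rows(
    somatic_event_row("A", "snv", pos = 800, ref = base, alt = "N",
                      time = 0.2),
    somatic_event_row("C", "cnv_deletion", start = 700, end = 900,
                      allele = "A", time = 0.5)
  )
  prof <- build_clone_profiles(tree, ref, germline_cnas = germ_cna,
                               somatic_events = ev)
  comp <- bulk_composition(c(A = 0.1, B = 0.2, C = 0.7), purity = 1)
  v <- tibble::tibble(chrom = "ctg1", pos = 800L, ref = base, alt = "N",
                      origin = "A")
  # subtree of A spans the whole tumour but C (0.7) lost the variant
  expect_equal(true_ccf(prof, tree, comp, v)$true_ccf, 0.3)
  expect_equal(true_ccf(prof, tree, comp, v,
                        adjust_deletions = FALSE)$true_ccf, 1.0)
  # germline rows are rejected
  expect_error(
    true_ccf(prof, tree, comp,
             tibble::tibble(chrom = "ctg1", pos = 1L, ref = "A", alt = "C",
                            origin = "germline")),
    "somatic"
  )
})

test_that("count observations follow Poisson depth and binomial alts", {
  set.seed(41)
  obs0 <- sample_observation(rep(0, 50), 30)
  expect_true(all(obs0$alt_count == 0L))
  zero_depth <- sample_observation(0.3, 0)
  expect_equal(zero_depth$depth, 0L)
  expect_true(is.na(zero_depth$vaf))

  set.seed(42)
  many <- sample_observation(rep(0.25, 1e4), 250)
  vafs <- many$vaf[!is.na(many$vaf)]
  se <- stats::sd(vafs) / sqrt(length(vafs))
  expect_lt(abs(mean(vafs) - 0.25), 3 * se)
  expect_true(all(many$alt_count <= many$depth))

  # beta-binomial overdispersion widens the VAF spread
  set.seed(43)
  od <- sample_observation(rep(0.25, 1e4), 250, overdispersion = 0.05)
  expect_gt(stats::sd(od$vaf, na.rm = TRUE), stats::sd(vafs))

  expect_error(sample_observation(1.2, 10), "0, 1")
  expect_error(sample_observation(0.5, -1), "mean_depth")
})

test_that("bulk composition produces complete, seed-invariant truth", {
  ref <- small_ref(len = 2e4, seed = 4)
  tree <- parse_structure("A,1,germline")
  prof <- diploid_sim(tree, ref, n_snv = 80, seed = 44)
  comp <- bulk_composition(c(A = 1), purity = 1)

  set.seed(1); bs1 <- compose_bulk(prof, tree, comp, target_depth = 60)
  set.seed(2); bs2 <- compose_bulk(prof, tree, comp, target_depth = 60)
  expect_equal(bs1$truth, bs2$truth)             # truth is seed-invariant
  expect_false(isTRUE(all.equal(bs1$observations$alt_count,
                                bs2$observations$alt_count)))

  # single-clone tumour at purity 1: every somatic variant is clonal
  expect_true(all(bs1$truth$true_ccf == 1))
  expect_equal(nrow(bs1$truth), 80L)

  # zero depth: uncovered observations, complete truth
  set.seed(3)
  bs0 <- compose_bulk(prof, tree, comp, target_depth = 0)
  expect_true(all(bs0$observations$depth == 0L))
  expect_true(all(is.na(bs0$observations$vaf)))
  expect_equal(nrow(bs0$truth), 80L)

  # unknown clone in the composition errors
  bad <- bulk_composition(c(Z = 1), purity = 1)
  expect_error(compose_bulk(prof, tree, bad, 60), "lack profiles")

  # tidy() joins truth onto observations
  td <- tidy(bs1)
  expect_true(all(c("vaf", "true_ccf", "m", "n") %in% names(td)))
})

test_that("noise-free diploid bulks satisfy the doubled-VAF identity", {
  ref <- small_ref(len = 2e4, seed = 4)
  tree <- chain_tree()
  prof <- diploid_sim(tree, ref, n_snv = 120, seed = 45)
  comp <- bulk_composition(c(A = 0.5, B = 0.3, C = 0.2), purity = 1)
  bs <- compose_bulk(prof, tree, comp, target_depth = Inf)
  som <- bs$observations[bs$observations$origin != "germline", ]
  joined <- dplyr::left_join(
    som, bs$truth[c("chrom", "pos", "ref", "alt", "true_ccf")],
    by = c("chrom", "pos", "ref", "alt"))
  est <- doubled_vaf_baseline(joined$vaf, purity = 1)
  expect_equal(est, joined$true_ccf)
})

test_that("toy read pairs cover targets at the requested depth", {
  ref <- small_ref(len = 2e4, seed = 4)
  prefix <- withr::local_tempfile()
  targets <- tibble::tibble(chrom = "ctg1", start = 1000L, end = 16100L)
  set.seed(46)
  n <- emit_toy_reads(list(germline = ref), c(germline = 1), targets,
                      depth = 10, read_len = 151, prefix = prefix)
  expect_equal(n, 500L)  # 10 * 15100 / (2 * 151)
  r1 <- readLines(paste0(prefix, "_1.fastq"))
  expect_equal(length(r1), 4L * n)
  # with no errors every read is an exact substring of the haplotype
  reads <- r1[seq(2, length(r1), by = 4)][1:25]
  expect_true(all(vapply(reads, function(s) grepl(s, ref[["ctg1"]],
                                                  fixed = TRUE),
                         logical(1))))
  # zero depth emits nothing; empty targets warn
  expect_equal(emit_toy_reads(list(g = ref), c(g = 1), targets, depth = 0,
                              prefix = prefix), 0L)
  expect_warning(emit_toy_reads(list(g = ref), c(g = 1), targets[0, ],
                                depth = 5, prefix = prefix), "empty")
})
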