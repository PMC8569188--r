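test_that("with no events every clone is diploid and germline variants are het", {
  ref <- small_ref(len = 1e4, seed = 2)
  tree <- chain_tree()
  set.seed(20)
  gv <- simulate_germline_variants(
    ref, sim_config(snvgermline = 0.001, indgermline = 0,
                    dbsnpsnvproportion = 0))
  prof <- build_clone_profiles(tree, ref, germline_variants = gv)
  for (cl in c("germline", "A", "B", "C")) {
    cn <- cn_at(prof, cl, "ctg1", 5000)
    expect_equal(cn$total, 2L)
    expect_equal(cn$major, 1L)
    seg <- profile_segments(prof, cl)
    expect_equal(nrow(seg), 1L)
    expect_equal(seg$total, 2)
  }
  mult <- variant_multiplicity(prof, "C")
  expect_true(all(mult$m == 1L))
  expect_true(all(mult$n == 2L))
  expect_true(all(mult$origin == "germline"))
})

test_that("event timestamps order application within a branch", {
  ref <- small_ref(len = 1e4, seed = 2)
  tree <- chain_tree()
  base <- substring(ref[["ctg1"]], 500, 500)

  # SNV before WGD: the mutated copy is duplicated -> m = 2, n = 4
  ev1 <- dplyr::bind_rows(
    somatic_event_row("A", "snv", pos = 500, ref = base, alt = "N",
                      time = 0.2),
    somatic_event_row("A", "wgd", time = 0.7)
  )
  p1 <- build_clone_profiles(tree, ref, somatic_events = ev1)
  m1 <- variant_multiplicity(p1, "A")
  expect_equal(m1$m, 2L)
  expect_equal(m1$n, 4L)

  # WGD before SNV: the variant lands on one of four copies -> m = 1
  ev2 <- dplyr::bind_rows(
    somatic_event_row("A", "wgd", time = 0.2),
    somatic_event_row("A", "snv", pos = 500, ref = base, alt = "N",
                      time = 0.7)
  )
  set.seed(21)
  p2 <- build_clone_profiles(tree, ref, somatic_events = ev2)
  m2 <- variant_multiplicity(p2, "A")
  expect_equal(m2$m, 1L)
  expect_equal(m2$n, 4L)
})

test_that("replication of a mutated copy raises multiplicity", {
  ref <- small_ref(len = 1e4, seed = 2)
  tree <- parse_structure("A,1,germline")
  # delete the whole B copy in the germline so the somatic SNV must land
  # on the A copy, then replicate the A copy: multiplicity is determined
  germ_cna <- tibble::tibble(chrom = "ctg1", start = 0L, end = 10000L,
                             kind = "deletion", added_copies = NA_integer_,
                             allele = "B", origin = "germline", time = 0.5)
  base <- substring(ref[["ctg1"]], 800, 800)
  ev <- dplyr::bind_rows(
    somatic_event_row("A", "snv", pos = 800, ref = base, alt = "N",
                      time = 0.2),
    somatic_event_row("A", "cnv_replication", start = 700, end = 900,
                      added_copies = 2, allele = "A", time = 0.7)
  )
  prof <- build_clone_profiles(tree, ref, germline_cnas = germ_cna,
                               somatic_events = ev)
  m <- variant_multiplicity(prof, "A")
  expect_equal(m$m, 3L)  # original + 2 added copies
  expect_equal(m$n, 3L)
  # outside the replicated window the clone is haploid
  expect_equal(cn_at(prof, "A", "ctg1", 5000)$total, 1L)
  # germline locus total reflects the germline CNV
  expect_equal(cn_at(prof, "germline", "ctg1", 800)$total, 1L)
})

test_that("deletions remove variants and never drive copies negative", {
  ref <- small_ref(len = 1e4, seed = 2)
  tree <- chain_tree()
  germ_cna <- tibble::tibble(chrom = "ctg1", start = 0L, end = 10000L,
                             kind = "deletion", added_copies = NA_integer_,
                             allele = "B", origin = "germline", time = 0.5)
  base <- substring(ref[["ctg1"]], 800, 800)
  ev <- dplyr::bind_rows(
    somatic_event_row("A", "snv", pos = 800, ref = base, alt = "N",
                      time = 0.2),
    somatic_event_row("B", "cnv_deletion", start = 700, end = 900,
                      allele = "A", time = 0.5)
  )
  prof <- build_clone_profiles(tree, ref, germline_cnas = germ_cna,
                               somatic_events = ev)
  expect_equal(variant_multiplicity(prof, "A")$m, 1L)
  # the deletion removed the only copy carrying the variant in B and C
  mult_b <- variant_multiplicity(prof, "B")
  expect_equal(mult_b$m[mult_b$origin == "A"], 0L)
  expect_equal(cn_at(prof, "B", "ctg1", 800)$total, 0L)
  # deleting an already-empty region is skipped with a warning, not an error
  ev2 <- dplyr::bind_rows(
    ev,
    somatic_event_row("C", "cnv_deletion", start = 700, end = 900,
                      allele = "A", time = 0.5)
  )
  expect_warning(
    build_clone_profiles(tree, ref, germline_cnas = germ_cna,
                         somatic_events = ev2),
    "skipped"
  )
})

test_that("WGD doubles copy totals in the clone and its descendants only", {
  ref <- small_ref(len = 1e4, seed = 2)
  tree <- parse_structure("A,1,germline,B,1,A,C,1,B,D,1,A")
  ev <- somatic_event_row("B", "wgd", time = 0.5)
  prof <- build_clone_profiles(tree, ref, somatic_events = ev)
  seg_a <- profile_segments(prof, "A")
  for (cl in c("B", "C")) {
    seg <- profile_segments(prof, cl)
    expect_equal(seg$total, 2 * seg_a$total)
  }
  expect_equal(profile_segments(prof, "D")$total, seg_a$total)
})

test_that("aneuploidy adds or removes exactly one chromosome copy", {
  ref <- toy_reference(n_contigs = 2, contig_length = 5e3, seed = 3)
  tree <- parse_structure("A,1,germline")
  gain <- somatic_event_row("A", "aneuploidy_gain", chrom = "ctg2",
                            time = 0.5)
  loss <- somatic_event_row("A", "aneuploidy_loss", chrom = "ctg2",
                            time = 0.5)
  pg <- build_clone_profiles(tree, ref, somatic_events = gain)
  pl <- build_clone_profiles(tree, ref, somatic_events = loss)
  expect_equal(cn_at(pg, "A", "ctg2", 100)$total, 3L)
  expect_equal(cn_at(pl, "A", "ctg2", 100)$total, 1L)
  # untouched contig stays diploid
  expect_equal(cn_at(pg, "A", "ctg1", 100)$total, 2L)
})

test_that("clones inherit ancestor variants (monotone inheritance)", {
  ref <- small_ref(len = 2e4, seed = 4)
  tree <- chain_tree()
  prof <- diploid_sim(tree, ref, n_snv = 100, seed = 30)
  mult <- variant_multiplicity(prof)
  key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt)
  vA <- key(mult[mult$clone == "A" & mult$m > 0, ])
  vB <- key(mult[mult$clone == "B" & mult$m > 0, ])
  vC <- key(mult[mult$clone == "C" & mult$m > 0, ])
  expect_true(all(vA %in% vB))
  expect_true(all(vB %in% vC))
  # diploid simulation: every variant het on a diploid background
  expect_true(all(mult$m == 1L))
  expect_true(all(mult$n == 2L))
})

test_that("copy totals are conserved through mixed event cascades", {
  ref <- small_ref(len = 2e4, seed = 4)
  tree <- parse_structure("A,2,germline,B,1,A")
  set.seed(31)
  cfg <- sim_config(snvsomatic_total = 50, indsomatic_total = 5,
                    cnvsomatic_rep = 4, cnvsomatic_del = 4,
                    cnvrepgermline = 2, cnvdelgermline = 2,
                    aneuploid = 1, wgdprob = 0.5)
  ev <- simulate_somatic_events(cfg, tree, ref)
  gc <- simulate_germline_cnas(ref, cfg)
  prof <- suppressWarnings(
    build_clone_profiles(tree, ref, germline_cnas = gc,
                         somatic_events = ev))
  for (cl in c("germline", "A", "B")) {
    seg <- profile_segments(prof, cl)
    expect_true(all(seg$total >= 0))
    expect_true(all(seg$major >= seg$minor))
    expect_true(all(seg$major + seg$minor == seg$total))
    # segments tile each contig exactly
    for (ch in unique(seg$chrom)) {
      s <- seg[seg$chrom == ch, ]
      expect_equal(s$start[1], 0L)
      expect_equal(s$end[nrow(s)], 20000L)
      if (nrow(s) > 1) expect_equal(s$start[-1], s$end[-nrow(s)])
    }
  }
})
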