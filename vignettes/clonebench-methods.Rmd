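---
title: "Simulating clonal tumour genomes and benchmarking subclonal deconvolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating clonal tumour genomes and benchmarking subclonal deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonebench)
library(dplyr)
```

## The problem

Bulk tumour sequencing mixes reads from genetically distinct subclones and
from contaminating normal cells. Subclonal deconvolution tries to undo that
mixture: estimate each somatic mutation's cancer cell fraction (CCF — the
fraction of tumour cells carrying it) and group mutations into clones.
Benchmarking such pipelines needs datasets where the clonal architecture is
known with certainty, which only simulation provides. `clonebench`
implements both halves of that exercise: a clone-tree genome simulator that
produces bulk samples with exact per-variant ground truth, and evaluators
that score point-mutation calls, allele-specific copy-number calls and CCF
estimates against that truth.

## The simulation model

### Clone trees and compositions

A tumour is a rooted tree of clones. The textual format is a list of
`name,branch_weight,parent` triplets with the literal token `germline` as
root marker:

```{r}
tree <- parse_structure(
  paste0("clone1,2,germline,clone2,1,clone1,clone3,3,clone1,",
         "clone4,1,clone2,clone5,1,clone2,clone6,1,clone4,",
         "clone7,1,clone5,clone8,1,clone5"))
tree
```

The second field is interpreted as a *relative mutational branch length*:
normalised branch weights are the multinomial probabilities used to
distribute tumour-wide somatic mutation counts across branches. The format
itself does not pin this meaning down; treating it as a branch length is
the simplest interpretation consistent with how such strings are used to
allocate mutation numbers, and it is the one this package fixes.

A bulk sample is described by a `bulk_composition()`: relative clone
weights renormalised to tumour proportions, scaled by purity into read
fractions, the remainder being normal (germline) reads. A mutation arising
on the branch to clone *c* is inherited by every descendant, so its true
CCF is the subtree sum of tumour proportions (`subtree_ccf()`), minus any
clone whose genome later lost the variant to a deletion. Whether published
truth sets account for such subclonal losses is usually unstated; we
subtract lost clones by default and expose
`true_ccf(..., adjust_deletions = FALSE)` to disable it.

### Events

`sim_config()` holds every rate. Defaults are the parameter listing used
for the whole-exome benchmarking tumours this package is designed to
emulate: germline SNVs at 0.0014/bp and indels at 0.00014/bp, with 90% of
germline SNVs (50% of indels) drawn from a known-sites panel; exactly 160
germline replication and 1,000 germline deletion CNVs; four
single-chromosome aneuploidy events per tumour; a whole-genome duplication
(WGD) with probability 0.333; lognormal CNV lengths
(`round(exp(N(mean, var)) * multiply)`, floored at 1 bp — germline
`(-10, 3, 1e6)`, i.e. median ≈ 45 bp; somatic `(-1, 3, 1e6)`, median ≈
368 kb); lognormal indel lengths `(-2, 2, 1)`; and lognormal added-copy
counts `(1, 0.5)`. Tumour-wide somatic totals are study-specific (they
were varied between parameter sets rather than fixed), so they are plain
configuration; the package defaults (1,000 SNVs, 100 indels, 10 + 10
CNVs) give realistic density on toy references of a few hundred kb.

Choices the printed parameters do not determine, fixed once here:

* Germline and somatic CNV counts are **exact event counts**, not Poisson
  means — the simplest reading of printed integers. Tests assert them
  exactly.
* Added copies of a replication are `max(1, round(lognormal))`; the
  distribution is given, the discretisation is ours.
* Aneuploidy picks a uniform clone and chromosome, gain/loss equiprobable;
  at most one WGD per tumour and never in the germline; `aneuploid` counts
  events per tumour.
* Somatic variants are placed uniformly over the genome: exome studies
  restrict *sequencing* to exons, not mutagenesis.
* Germline point variants are heterozygous, one parental copy each;
  homozygous sites are not modelled.

### Genome bookkeeping

Each clone's genome is a set of *allele copies* — descendants of the two
parental copies of each chromosome, each holding the intervals it still
covers. Branch events carry uniform timestamps and are applied in time
order: a replication clones the target copy's overlap with the event
window (variants on it gain multiplicity), a deletion punches a hole (and
removes the variants in it from that copy), aneuploidy duplicates or drops
a whole chromosome copy, and WGD duplicates every copy. A variant's
multiplicity *m* in a clone is the number of copies carrying it; the locus
total *n* is the number of copies covering its position. Deleting a region
with no remaining copies is skipped with a warning rather than an error.
Sequence-level realisation of rearranged chromosomes is deliberately out
of scope — the bookkeeping is at segment/count level.

### Bulk mixing and observations

The expected bulk VAF of a variant is
$\mathrm{VAF} = \frac{\sum_c f_c\, m_c}{\sum_c f_c\, n_c + f_{normal}\, n_{germ}}$
over read fractions $f$; $n_{germ}$ is 2 unless a germline CNV altered the
locus. Observations are simulated at count level: depth is Poisson around
the target depth and the alt count binomial (optionally beta-binomial with
an intra-class correlation `overdispersion`). This mirrors read
down-sampling at the level the evaluators consume; full read-level
simulation with empirical error profiles is explicitly not attempted.
`emit_toy_reads()` exists only to smoke-test FASTQ plumbing — uniform
fragments, uniform substitution errors, no insert-size or GC model.
`target_depth = Inf` yields noise-free observations whose VAF equals the
expected VAF, which gives the end-to-end identity used in testing: on a
diploid, purity-1, noise-free simulation the doubled-VAF baseline recovers
true CCFs exactly and MADif is 0.

## Evaluation

**Point mutations.** Matching is allele-exact on `(chrom, pos, ref, alt)`
after trimming-based left-normalisation (shared suffix, then shared
prefix, keeping an anchor base). Reference-aware repeat shifting is not
performed; within the package's own exports the trimmed representation is
canonical. Region restriction removes *both* truth and calls outside the
regions before matching, so off-target truth does not inflate the false
negative count. Precision of an empty call set is 0 (and F1 is 0 when both
components are 0), flagged via a `degenerate` column. PR curves enumerate
distinct score thresholds descending, ties grouped, unscored calls ranked
last; the final point equals the un-thresholded metrics. Union/intersect
ensembles act on the variant key, keeping max/min scores respectively.

**Copy number.** `ploidy_class()` encodes the observation that callers
missing a WGD report half the true ploidy but are otherwise accurate:
accurate / halved / doubled / wrong with a default absolute tolerance of
0.3 (the published classification is visual; 0.3 separates the diploid
and tetraploid bands without absorbing genuinely wrong estimates).
`bin_copy_numbers()` projects segments onto a fixed grid by
length-weighted averaging; for simulated truth it emits per-clone tracks
plus a bulk track, the tumour-proportion-weighted mean across clones
(purity-independent, since copy number is a property of tumour cells).
Which truth track a published heatmap uses is unstated, so both are
available. Agreement is MAE of total and minor copy number plus the
fraction of bins exactly matching after rounding, over bins non-missing in
both tracks.

**CCFs.** The two baselines real methods should beat: doubled VAFs
(`min(2 VAF / purity, 1)` — a purely het-diploid assumption) and
one-dimensional K-means with `k = 3` on those estimates (cluster CCF =
cluster mean; `k` is reduced with a warning when fewer distinct values
exist; seed and restart count are explicit arguments). The headline
statistic is
$\mathrm{MADif} = \frac{1}{n}\sum_{i=1}^{n}\frac{\sum_{j=1}^{m_i}\lvert T_{ij}-E_{ij}\rvert}{m_i}$ —
the per-sample mean absolute difference between true and estimated CCFs
over called true variants, averaged with equal sample weight so
variant-rich samples do not dominate. Pairs are restricted to true
positives; samples with none are dropped upstream with a note rather than
failing a whole report. Clustering accuracy uses the adjusted Rand index
(contingency-table closed form, cross-checked in tests against brute-force
pair counting and an independent implementation); the true partition is
"variants sharing an origin clone share a label". We report the mean ARI
across samples; since ARI can in principle be negative, callers wanting
the mean *absolute* ARI can take `abs()` themselves — for any reasonable
clustering the two coincide.

When preparing deconvolution inputs, copy-number segments are only applied
to variants when the segment's cellular fraction is **at least 0.5**
(inclusive — the rule is "in ≥ 50% of cells"); otherwise, and outside all
segments, the diploid 1/1 state is assumed.

## What the toy generators do and do not emulate

`toy_reference()` (uniform-random sequence), `toy_known_sites()` (a
dbSNP-like panel) and `perturbed_callset()` (a synthetic caller with known
FN rate, FP count, VAF jitter and Beta-distributed confidence scores)
make the whole chain runnable with no downloads, byte-reproducibly per
seed. They emulate the *structure* of real inputs, not their statistics:
no sequence context effects, mappability, capture-probe bias, alignment
artefacts or caller-specific error modes. Passing tests therefore
demonstrate that the simulator's event arithmetic and the evaluators'
metrics are correct, and that parameter-level behaviour (rates, counts,
WGD frequency) matches configuration — not that any particular real
caller will achieve a given score on real data. Reproducing published
per-caller scores would require running those tools on the deposited
datasets, which is outside this package's scope.

## Numerical choices and problem sizes

* Variant positions are 1-based (VCF convention) throughout the R API;
  segment and BED intervals are 0-based half-open. Exports follow the
  respective format conventions.
* Compositions must sum to 1 after renormalisation (checked to 1e-9 by
  construction); CCFs and VAFs are validated into `[0, 1]`.
* A single seeded RNG stream drives each simulation; identical seed and
  configuration give identical output, and truth tables are invariant to
  the observation-sampling seed.
* Default test and acceptance scales, chosen so the full suite runs in a
  few minutes on one core: toy references of 10–200 kb for unit tests, a
  5 Mb reference for the germline-rate check, 3,000 event-level tumours
  for the WGD-frequency check, and 20-seed replicates for the stochastic
  properties (all asserted within three standard errors).

## Known limitations

Only autosome-like contigs are modelled (no sex chromosomes, matching the
chromosomes-1–22 design it emulates); no structural variants beyond
CNV/aneuploidy/WGD, no mutational signatures or kataegis, no neutral-tail
mutation accumulation within clones; indel matching is trim-normalised
rather than reference-left-aligned; and no phylogeny reconstruction or
scoring — trees are inputs, never inferred.
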