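#' Simulation configuration
#'
#' Collects every rate and distribution parameter the genome simulator
#' uses. Defaults are the published parameter listing for whole-exome
#' benchmarking tumours: per-base germline SNV/indel rates, counts of
#' germline CNVs, lognormal length distributions for CNVs and indels,
#' lognormal added-copy counts, per-tumour aneuploidy count, whole-genome
#' duplication probability, and the fractions of germline variants drawn
#' from a known-sites panel. Tumour-wide somatic totals are study-specific
#' and default to a scale suitable for toy references of a few hundred kb.
#'
#' Lognormal lengths are drawn as `round(exp(N(mean, variance)) * multiply)`
#' floored at 1 bp, so e.g. germline CNVs with `(-10, 3, 1e6)` have median
#' length `exp(-10) * 1e6 ~ 45` bp.
#'
#' @param snvgermline,indgermline Per-base germline SNV / indel rates.
#' @param snvsomatic_total,indsomatic_total Tumour-wide somatic SNV / indel
#'   counts, distributed across branches by branch weight.
#' @param cnvsomatic_rep,cnvsomatic_del Tumour-wide somatic CNV replication
#'   / deletion counts.
#' @param cnvrepgermline,cnvdelgermline Exact counts of germline
#'   replication / deletion CNVs per genome.
#' @param aneuploid Number of single-chromosome aneuploidy events per
#'   tumour.
#' @param wgdprob Probability that the tumour contains one whole-genome
#'   duplication.
#' @param cnvgermlinemean,cnvgermlinevariance,cnvgermlinemultiply Lognormal
#'   length parameters for germline CNVs.
#' @param cnvsomaticmean,cnvsomaticvariance,cnvsomaticmultiply Lognormal
#'   length parameters for somatic CNVs.
#' @param indmean,indvariance,indmultiply Lognormal indel-length
#'   parameters.
#' @param cnvcopiesmean,cnvcopiesvariance Lognormal parameters for the
#'   number of copies a replication adds (rounded, floored at 1).
#' @param dbsnpsnvproportion,dbsnpindelproportion Fractions of germline
#'   SNVs / indels drawn from the known-sites panel.
#' @param seed Optional integer seed applied by the top-level simulators.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(snvgermline = 0.0014,
                       indgermline = 0.00014,
                       snvsomatic_total = 1000L,
                       indsomatic_total = 100L,
                       cnvsomatic_rep = 10L,
                       cnvsomatic_del = 10L,
                       cnvrepgermline = 160L,
                       cnvdelgermline = 1000L,
                       aneuploid = 4L,
                       wgdprob = 0.333,
                       cnvgermlinemean = -10,
                       cnvgermlinevariance = 3,
                       cnvgermlinemultiply = 1e6,
                       cnvsomaticmean = -1,
                       cnvsomaticvariance = 3,
                       cnvsomaticmultiply = 1e6,
                       indmean = -2,
                       indvariance = 2,
                       indmultiply = 1,
                       cnvcopiesmean = 1,
                       cnvcopiesvariance = 0.5,
                       dbsnpsnvproportion = 0.9,
                       dbsnpindelproportion = 0.5,
                       seed = NULL) {
  cfg <- list(
    snvgermline = snvgermline, indgermline = indgermline,
    snvsomatic_total = as.integer(snvsomatic_total),
    indsomatic_total = as.integer(indsomatic_total),
    cnvsomatic_rep = as.integer(cnvsomatic_rep),
    cnvsomatic_del = as.integer(cnvsomatic_del),
    cnvrepgermline = as.integer(cnvrepgermline),
    cnvdelgermline = as.integer(cnvdelgermline),
    aneuploid = as.integer(aneuploid), wgdprob = wgdprob,
    cnvgermlinemean = cnvgermlinemean,
    cnvgermlinevariance = cnvgermlinevariance,
    cnvgermlinemultiply = cnvgermlinemultiply,
    cnvsomaticmean = cnvsomaticmean,
    cnvsomaticvariance = cnvsomaticvariance,
    cnvsomaticmultiply = cnvsomaticmultiply,
    indmean = indmean, indvariance = indvariance,
    indmultiply = indmultiply,
    cnvcopiesmean = cnvcopiesmean, cnvcopiesvariance = cnvcopiesvariance,
    dbsnpsnvproportion = dbsnpsnvproportion,
    dbsnpindelproportion = dbsnpindelproportion,
    seed = seed
  )
  rates <- c("snvgermline", "indgermline", "wgdprob",
             "dbsnpsnvproportion", "dbsnpindelproportion")
  for (nm in rates) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1) {
      abort(sprintf("`%s` must be a single value in [0, 1]", nm))
    }
  }
  counts <- c("snvsomatic_total", "indsomatic_total", "cnvsomatic_rep",
              "cnvsomatic_del", "cnvrepgermline", "cnvdelgermline",
              "aneuploid")
  for (nm in counts) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] < 0L) {
      abort(sprintf("`%s` must be a nonnegative integer", nm))
    }
  }
  vars <- c("cnvgermlinevariance", "cnvsomaticvariance", "indvariance",
            "cnvcopiesvariance")
  for (nm in vars) {
    if (cfg[[nm]] < 0) abort(sprintf("`%s` must be >= 0", nm))
  }
  mults <- c("cnvgermlinemultiply", "cnvsomaticmultiply", "indmultiply")
  for (nm in mults) {
    if (cfg[[nm]] <= 0) abort(sprintf("`%s` must be > 0", nm))
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  flat <- x[!vapply(x, is.null, logical(1))]
  cat(paste0("  ", names(flat), " = ", unlist(flat), collapse = "\n"), "\n")
  invisible(x)
}

#' Read a simulation configuration from a key/value file
#'
#' Accepts a plain `key:value` or `key=value` listing (one pair per line,
#' `#` comments allowed; quotes around keys or values are ignored). The key
#' `structure` holds the clone-tree structure string.
#'
#' @param path Path to the configuration file.
#' @return A list with elements `config` (a [sim_config()]) and `tree`
#'   (a `clone_tree`, or `NULL` when no `structure` key is present).
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "[:=]", perl = TRUE)
  keys <- trimws(gsub('["“”]', "", vapply(kv, `[[`, character(1), 1L)))
  vals <- trimws(gsub('["“”]', "", vapply(
    kv, function(x) paste(x[-1L], collapse = ":"), character(1)
  )))
  named <- setNames(as.list(vals), keys)
  tree <- NULL
  if (!is.null(named$structure)) {
    tree <- parse_structure(named$structure)
    named$structure <- NULL
  }
  known <- names(formals(sim_config))
  args <- named[intersect(names(named), known)]
  args <- lapply(args, function(v) as.numeric(v))
  list(config = do.call(sim_config, args), tree = tree)
}
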