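# Per-clone genome bookkeeping.
#
# A clone's genome is a set of "allele copies". Each copy descends from one
# of the two parental copies (allele A or B) of one chromosome and holds the
# set of 0-based half-open intervals it still covers (deletions punch holes;
# replications create new partial copies). Variants record the copy ids that
# carry them, so the mutated-copy multiplicity m of a variant in a clone is
# simply the number of its copy ids alive in that clone, and the locus total
# n is the number of copies covering the position.

new_copy_counter <- function() {
  env <- new.env(parent = emptyenv())
  env$i <- 0L
  function() {
    env$i <- env$i + 1L
    sprintf("cp%06d", env$i)
  }
}

empty_variant_table <- function() {
  tibble(chrom = character(), pos = integer(), ref = character(),
         alt = character(), class = character(), origin = character(),
         copy_ids = list())
}

new_diploid_state <- function(ref, next_id) {
  lens <- ref_lengths(ref)
  copies <- list()
  for (chrom in names(lens)) {
    for (allele in c("A", "B")) {
      id <- next_id()
      copies[[id]] <- list(chrom = chrom, allele = allele,
                           segs = iv_new(0, lens[[chrom]]))
    }
  }
  list(copies = copies, variants = empty_variant_table())
}

copies_of_chrom <- function(state, chrom) {
  names(state$copies)[vapply(state$copies, function(cp) cp$chrom == chrom,
                             logical(1))]
}

# add a point variant on a specific copy
state_add_variant <- function(state, chrom, pos, ref, alt, class, origin,
                              copy_id) {
  state$variants <- bind_rows(
    state$variants,
    tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
           class = class, origin = origin, copy_ids = list(copy_id))
  )
  state
}

# duplicate one copy (aneuploidy gain, or a building block of WGD);
# variants carried by it gain the new id
state_duplicate_copy <- function(state, copy_id, next_id) {
  new_id <- next_id()
  state$copies[[new_id]] <- state$copies[[copy_id]]
  carries <- map_lgl(state$variants$copy_ids, ~ copy_id %in% .x)
  if (any(carries)) {
    state$variants$copy_ids[carries] <-
      map(state$variants$copy_ids[carries], ~ c(.x, new_id))
  }
  state
}

# remove a copy entirely (aneuploidy loss / fully deleted copy)
state_drop_copy <- function(state, copy_id) {
  state$copies[[copy_id]] <- NULL
  holds <- map_lgl(state$variants$copy_ids, ~ copy_id %in% .x)
  if (any(holds)) {
    state$variants$copy_ids[holds] <-
      map(state$variants$copy_ids[holds], ~ setdiff(.x, copy_id))
  }
  state
}

state_apply_replication <- function(state, chrom, start, end, added,
                                    target, next_id) {
  tgt <- state$copies[[target]]
  piece <- iv_intersect(tgt$segs, start, end)
  if (nrow(piece) == 0L) return(state)
  in_region <- state$variants$chrom == chrom &
    (state$variants$pos - 1L) >= start & (state$variants$pos - 1L) < end &
    map_lgl(state$variants$copy_ids, ~ target %in% .x)
  for (k in seq_len(added)) {
    new_id <- next_id()
    state$copies[[new_id]] <- list(chrom = chrom, allele = tgt$allele,
                                   segs = piece)
    if (any(in_region)) {
      state$variants$copy_ids[in_region] <-
        map(state$variants$copy_ids[in_region], ~ c(.x, new_id))
    }
  }
  state
}

state_apply_deletion <- function(state, chrom, start, end, target) {
  tgt <- state$copies[[target]]
  remaining <- iv_subtract(tgt$segs, start, end)
  hit <- state$variants$chrom == chrom &
    (state$variants$pos - 1L) >= start & (state$variants$pos - 1L) < end &
    map_lgl(state$variants$copy_ids, ~ target %in% .x)
  if (any(hit)) {
    state$variants$copy_ids[hit] <-
      map(state$variants$copy_ids[hit], ~ setdiff(.x, target))
  }
  if (nrow(remaining) == 0L) {
    state <- state_drop_copy(state, target)
  } else {
    state$copies[[target]]$segs <- remaining
  }
  state
}

state_apply_wgd <- function(state, next_id) {
  for (id in names(state$copies)) {
    state <- state_duplicate_copy(state, id, next_id)
  }
  state
}

# choose a CNA target copy: among copies of the chromosome overlapping the
# region, preferring the requested parental allele when available
choose_cna_target <- function(state, chrom, start, end, allele = NULL) {
  ids <- copies_of_chrom(state, chrom)
  ids <- ids[vapply(ids, function(id) {
    iv_overlaps(state$copies[[id]]$segs, start, end)
  }, logical(1))]
  if (!length(ids)) return(NULL)
  if (!is.null(allele)) {
    same <- ids[vapply(ids, function(id) state$copies[[id]]$allele == allele,
                       logical(1))]
    if (length(same)) ids <- same
  }
  if (length(ids) == 1L) ids else sample(ids, 1L)
}

apply_event <- function(state, ev, next_id, skips) {
  cls <- ev$class
  if (cls %in% c("snv", "insertion", "deletion")) {
    ids <- copies_of_chrom(state, ev$chrom)
    ids <- ids[vapply(ids, function(id) {
      iv_covers(state$copies[[id]]$segs, ev$pos - 1L)
    }, logical(1))]
    if (!length(ids)) {
      skips$point <- skips$point + 1L
      return(state)
    }
    id <- if (length(ids) == 1L) ids else sample(ids, 1L)
    return(state_add_variant(state, ev$chrom, ev$pos, ev$ref, ev$alt,
                             cls, ev$origin, id))
  }
  if (cls %in% c("cnv_replication", "replication")) {
    tgt <- choose_cna_target(state, ev$chrom, ev$start, ev$end, ev$allele)
    if (is.null(tgt)) {
      skips$cna <- skips$cna + 1L
      return(state)
    }
    return(state_apply_replication(state, ev$chrom, ev$start, ev$end,
                                   ev$added_copies, tgt, next_id))
  }
  if (cls %in% c("cnv_deletion", "deletion_cna")) {
    tgt <- choose_cna_target(state, ev$chrom, ev$start, ev$end, ev$allele)
    if (is.null(tgt)) {
      skips$cna <- skips$cna + 1L
      return(state)
    }
    return(state_apply_deletion(state, ev$chrom, ev$start, ev$end, tgt))
  }
  if (cls == "aneuploidy_gain") {
    ids <- copies_of_chrom(state, ev$chrom)
    if (!length(ids)) {
      skips$cna <- skips$cna + 1L
      return(state)
    }
    id <- if (length(ids) == 1L) ids else sample(ids, 1L)
    return(state_duplicate_copy(state, id, next_id))
  }
  if (cls == "aneuploidy_loss") {
    ids <- copies_of_chrom(state, ev$chrom)
    if (!length(ids)) {
      skips$cna <- skips$cna + 1L
      return(state)
    }
    id <- if (length(ids) == 1L) ids else sample(ids, 1L)
    return(state_drop_copy(state, id))
  }
  if (cls == "wgd") {
    return(state_apply_wgd(state, next_id))
  }
  abort(sprintf("unknown event class: %s", cls))
}

#' Build per-clone genome profiles from simulated events
#'
#' Starting from a heterozygous diploid germline, applies germline variants
#' and germline CNAs, then walks the clone tree parents-first, each clone
#' inheriting its parent's genome and applying its own branch events in
#' timestamp order. Replications duplicate variants already on the
#' duplicated copy (raising their multiplicity), deletions remove one
#' allele copy's interval along with the variants on it, aneuploidies add
#' or remove one whole chromosome copy, and a whole-genome duplication
#' doubles every copy (and every multiplicity) in that clone and its
#' descendants.
#'
#' @param tree A `clone_tree`.
#' @param ref Reference genome (named character vector or `DNAStringSet`).
#' @param germline_variants Tibble from [simulate_germline_variants()]
#'   (or `NULL`).
#' @param germline_cnas Tibble from [simulate_germline_cnas()] (or `NULL`).
#' @param somatic_events Tibble from [simulate_somatic_events()] (or
#'   `NULL`).
#' @return A `clone_profiles` object: per-clone (plus `"germline"`) allele
#'   copies and variant tables, queryable with [cn_at()],
#'   [profile_segments()] and [variant_multiplicity()]. Point events
#'   falling in regions deleted from every copy are skipped with a summary
#'   warning.
#' @export
build_clone_profiles <- function(tree, ref, germline_variants = NULL,
                                 germline_cnas = NULL,
                                 somatic_events = NULL) {
  validate_clone_tree(tree)
  next_id <- new_copy_counter()
  skips <- new.env(parent = emptyenv())
  skips$point <- 0L
  skips$cna <- 0L

  germ <- new_diploid_state(ref, next_id)
  # germline het variants sit on the parental copy matching their allele
  if (!is.null(germline_variants) && nrow(germline_variants)) {
    copy_lookup <- list()
    for (id in names(germ$copies)) {
      cp <- germ$copies[[id]]
      copy_lookup[[paste0(cp$chrom, ".", cp$allele)]] <- id
    }
    gv <- germline_variants
    ids <- unlist(copy_lookup[paste0(gv$chrom, ".", gv$allele)])
    germ$variants <- bind_rows(
      germ$variants,
      tibble(chrom = gv$chrom, pos = as.integer(gv$pos), ref = gv$ref,
             alt = gv$alt, class = gv$class, origin = "germline",
             copy_ids = as.list(ids))
    )
  }
  if (!is.null(germline_cnas) && nrow(germline_cnas)) {
    gc <- arrange(germline_cnas, .data$time)
    gc$class <- ifelse(gc$kind == "replication",
                       "cnv_replication", "cnv_deletion")
    gc$origin <- "germline"
    for (i in seq_len(nrow(gc))) {
      germ <- apply_event(germ, as.list(gc[i, ]), next_id, skips)
    }
  }

  states <- list(germline = germ)
  ev <- somatic_events
  for (clone in clone_order(tree)) {
    parent <- as_tibble(tree)$parent[as_tibble(tree)$clone == clone]
    state <- states[[parent]]
    if (!is.null(ev) && nrow(ev)) {
      branch <- arrange(filter(ev, .data$origin == clone), .data$time)
      bad <- setdiff(unique(ev$origin), c(as_tibble(tree)$clone, "germline"))
      if (length(bad)) {
        abort(sprintf("events reference unknown clones: %s",
                      paste(bad, collapse = ", ")))
      }
      for (i in seq_len(nrow(branch))) {
        state <- apply_event(state, as.list(branch[i, ]), next_id, skips)
      }
    }
    states[[clone]] <- state
  }
  if (skips$point + skips$cna > 0L) {
    warn(sprintf(
      "skipped %d point and %d copy-number events falling in regions with no remaining copies",
      skips$point, skips$cna
    ))
  }
  structure(list(states = states, tree = tree,
                 contig_lengths = ref_lengths(ref)),
            class = "clone_profiles")
}

#' @export
print.clone_profiles <- function(x, ...) {
  cat(sprintf("<clone_profiles> %d clones + germline, %d contigs\n",
              length(x$states) - 1L, length(x$contig_lengths)))
  invisible(x)
}

profile_state <- function(profiles, clone) {
  st <- profiles$states[[clone]]
  if (is.null(st)) abort(sprintf("no profile for clone: %s", clone))
  st
}

#' Copy number at a position
#'
#' @param profiles A `clone_profiles` object.
#' @param clone Clone identifier (or `"germline"`).
#' @param chrom,pos Contig and 1-based position.
#' @return A one-row tibble with `total`, `a_count`, `b_count`, `major`,
#'   `minor` copy counts at the position.
#' @export
cn_at <- function(profiles, clone, chrom, pos) {
  st <- profile_state(profiles, clone)
  ids <- copies_of_chrom(st, chrom)
  covering <- vapply(ids, function(id) {
    iv_covers(st$copies[[id]]$segs, pos - 1L)
  }, logical(1))
  alleles <- vapply(ids, function(id) st$copies[[id]]$allele, character(1))
  a <- sum(covering & alleles == "A")
  b <- sum(covering & alleles == "B")
  tibble(total = a + b, a_count = a, b_count = b,
         major = max(a, b), minor = min(a, b))
}

#' Allele-specific copy-number segments of a clone
#'
#' Collapses a clone's allele copies into disjoint segments of constant
#' copy number along each contig.
#'
#' @param profiles A `clone_profiles` object.
#' @param clone Clone identifier (or `"germline"`).
#' @return A tibble `chrom`, `start`, `end` (0-based half-open), `total`,
#'   `major`, `minor`; adjacent equal-valued segments are merged.
#' @export
profile_segments <- function(profiles, clone) {
  st <- profile_state(profiles, clone)
  out <- list()
  for (chrom in names(profiles$contig_lengths)) {
    len <- profiles$contig_lengths[[chrom]]
    ids <- copies_of_chrom(st, chrom)
    brk <- c(0, len)
    for (id in ids) brk <- c(brk, st$copies[[id]]$segs)
    brk <- sort(unique(pmin(pmax(brk, 0), len)))
    if (length(brk) < 2L) next
    starts <- brk[-length(brk)]
    ends <- brk[-1L]
    a <- b <- integer(length(starts))
    for (id in ids) {
      cp <- st$copies[[id]]
      covered <- vapply(starts, function(s) iv_covers(cp$segs, s), logical(1))
      if (cp$allele == "A") a <- a + covered else b <- b + covered
    }
    seg <- tibble(chrom = chrom, start = starts, end = ends,
                  total = a + b, major = pmax(a, b), minor = pmin(a, b))
    # merge adjacent runs with identical values
    run <- cumsum(c(TRUE, seg$total[-1] != seg$total[-nrow(seg)] |
                      seg$major[-1] != seg$major[-nrow(seg)] |
                      seg$minor[-1] != seg$minor[-nrow(seg)]))
    seg <- seg |>
      mutate(run = run) |>
      group_by(.data$chrom, .data$run) |>
      summarise(start = min(.data$start), end = max(.data$end),
                total = first(.data$total), major = first(.data$major),
                minor = first(.data$minor), .groups = "drop") |>
      select(-"run") |>
      arrange(.data$start)
    out[[chrom]] <- seg
  }
  bind_rows(out) |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end))
}

#' Variant multiplicities within clones
#'
#' For each variant present in a clone, reports the mutated-copy
#' multiplicity `m` (number of allele copies carrying the variant) and the
#' locus total `n` (number of copies covering its position).
#'
#' @param profiles A `clone_profiles` object.
#' @param clones Clone identifiers (default: all clones plus germline).
#' @return A tibble `clone`, `chrom`, `pos`, `ref`, `alt`, `class`,
#'   `origin`, `m`, `n`. Variants whose copies were all deleted appear with
#'   `m = 0`.
#' @export
variant_multiplicity <- function(profiles, clones = NULL) {
  clones <- clones %||% names(profiles$states)
  out <- list()
  for (clone in clones) {
    st <- profile_state(profiles, clone)
    v <- st$variants
    if (nrow(v) == 0L) next
    m <- lengths(v$copy_ids)
    n <- integer(nrow(v))
    for (chrom in unique(v$chrom)) {
      sel <- which(v$chrom == chrom)
      ids <- copies_of_chrom(st, chrom)
      cnt <- integer(length(sel))
      for (id in ids) {
        segs <- st$copies[[id]]$segs
        cnt <- cnt + vapply(v$pos[sel] - 1L, function(p) iv_covers(segs, p),
                            logical(1))
      }
      n[sel] <- cnt
    }
    out[[clone]] <- tibble(clone = clone, chrom = v$chrom, pos = v$pos,
                           ref = v$ref, alt = v$alt, class = v$class,
                           origin = v$origin, m = as.integer(m),
                           n = as.integer(n))
  }
  bind_rows(out) %||% tibble()
}
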