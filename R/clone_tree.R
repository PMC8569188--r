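#' Parse a clone-tree structure string
#'
#' A tumour's clonal architecture is written as a comma-separated list of
#' triplets `name,branch_weight,parent`, e.g.
#' `"clone1,2,germline,clone2,1,clone1"`. The literal parent token
#' `"germline"` marks the root; `branch_weight` is a nonnegative relative
#' branch length used to distribute somatic mutations across branches.
#'
#' @param text A structure string (whitespace and surrounding quotes are
#'   ignored).
#' @return A `clone_tree`: a tibble with columns `clone`, `branch_weight`
#'   and `parent`, one row per clone, validated (unique names, resolvable
#'   parents, acyclic, a single root-attached component).
#' @examples
#' parse_structure("cA,1,germline,cB,2,cA")
#' @export
parse_structure <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  cleaned <- gsub('["“”\\s]', "", text, perl = TRUE)
  tokens <- strsplit(cleaned, ",", fixed = TRUE)[[1]]
  if (length(tokens) == 0L || length(tokens) %% 3L != 0L) {
    abort(sprintf(
      "structure string has %d comma-separated tokens; expected a nonzero multiple of 3 (name,weight,parent triplets)",
      length(tokens)
    ))
  }
  idx <- seq(1L, length(tokens), by = 3L)
  df <- tibble(
    clone = tokens[idx],
    weight_raw = tokens[idx + 1L],
    parent = tokens[idx + 2L]
  )
  bad_w <- suppressWarnings(is.na(as.numeric(df$weight_raw)))
  if (any(bad_w)) {
    i <- which(bad_w)[1]
    abort(sprintf(
      "non-numeric branch weight in triplet (%s,%s,%s)",
      df$clone[i], df$weight_raw[i], df$parent[i]
    ))
  }
  tree <- tibble(
    clone = df$clone,
    branch_weight = as.numeric(df$weight_raw),
    parent = df$parent
  )
  validate_clone_tree(new_clone_tree(tree))
}

new_clone_tree <- function(df) {
  structure(df, class = c("clone_tree", class(tibble())))
}

#' Construct a clone tree from a data frame
#'
#' @param nodes A data frame with columns `clone`, `branch_weight`,
#'   `parent` (use `"germline"` as the root marker).
#' @return A validated `clone_tree` tibble.
#' @export
clone_tree <- function(nodes) {
  nodes <- as_tibble(nodes)
  stopifnot(all(c("clone", "branch_weight", "parent") %in% names(nodes)))
  validate_clone_tree(new_clone_tree(nodes[c("clone", "branch_weight", "parent")]))
}

#' Validate a clone tree
#'
#' Checks uniqueness of clone names, that `"germline"` is reserved for the
#' root marker, that every parent resolves, that branch weights are
#' nonnegative, and that the tree is a single acyclic component hanging off
#' the root.
#'
#' @param tree A `clone_tree`.
#' @return The tree, invisibly unchanged, or an error describing the
#'   offending triplet.
#' @export
validate_clone_tree <- function(tree) {
  df <- as_tibble(tree)
  if (anyDuplicated(df$clone)) {
    abort(sprintf("duplicate clone name: %s",
                  df$clone[duplicated(df$clone)][1]))
  }
  if ("germline" %in% df$clone) {
    abort('"germline" is the reserved root marker and cannot name a clone')
  }
  if (any(df$branch_weight < 0)) {
    i <- which(df$branch_weight < 0)[1]
    abort(sprintf("negative branch weight in triplet (%s,%s,%s)",
                  df$clone[i], df$branch_weight[i], df$parent[i]))
  }
  unknown <- !(df$parent %in% c("germline", df$clone))
  if (any(unknown)) {
    i <- which(unknown)[1]
    abort(sprintf("unknown parent in triplet (%s,%s,%s)",
                  df$clone[i], df$branch_weight[i], df$parent[i]))
  }
  if (!any(df$parent == "germline")) {
    abort("no clone attaches to the root marker \"germline\"")
  }
  # walk up from every clone; detect cycles / unreachable nodes
  parent_of <- setNames(df$parent, df$clone)
  for (cl in df$clone) {
    seen <- character()
    cur <- cl
    while (cur != "germline") {
      if (cur %in% seen) {
        abort(sprintf("cycle involving clone %s (triplet (%s,%s,%s))",
                      cur, cl, df$branch_weight[df$clone == cl],
                      parent_of[[cl]]))
      }
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
    }
  }
  tree
}

#' Serialise a clone tree back to its structure string
#'
#' @param tree A `clone_tree`.
#' @return A single string of `name,weight,parent` triplets; parsing it
#'   reproduces the tree.
#' @export
format_structure <- function(tree) {
  df <- as_tibble(tree)
  paste(
    paste(df$clone,
          vapply(df$branch_weight, format, character(1), scientific = FALSE),
          df$parent, sep = ","),
    collapse = ","
  )
}

# clones ordered parents-before-children (root children first)
clone_order <- function(tree) {
  df <- as_tibble(tree)
  done <- "germline"
  out <- character()
  remaining <- df$clone
  while (length(remaining)) {
    ready <- remaining[df$parent[match(remaining, df$clone)] %in% done]
    out <- c(out, ready)
    done <- c(done, ready)
    remaining <- setdiff(remaining, ready)
  }
  out
}

# clone plus all its descendants
clone_subtree <- function(tree, clone) {
  df <- as_tibble(tree)
  if (!clone %in% df$clone) {
    abort(sprintf("unknown clone: %s", clone))
  }
  members <- clone
  repeat {
    kids <- df$clone[df$parent %in% members & !(df$clone %in% members)]
    if (!length(kids)) break
    members <- c(members, kids)
  }
  members
}

#' Normalised branch weights of a clone tree
#'
#' Branch weights (the second triplet field) are relative mutational branch
#' lengths; normalised they give the multinomial probabilities used to
#' distribute tumour-wide somatic mutation counts across branches.
#'
#' @param tree A `clone_tree`.
#' @return A tibble with columns `clone` and `weight`; weights sum to 1.
#' @export
branch_weights <- function(tree) {
  df <- as_tibble(tree)
  total <- sum(df$branch_weight)
  if (total <= 0) abort("all branch weights are zero; cannot normalise")
  tibble(clone = df$clone, weight = df$branch_weight / total)
}

#' Define the composition of a bulk sample
#'
#' A bulk sample mixes reads from tumour clones and from normal (germline)
#' cells. Clone weights are renormalised to tumour proportions; read
#' fractions are tumour proportions scaled by purity, with the normal
#' fraction making the total 1.
#'
#' @param weights Named nonnegative numeric vector of relative clone
#'   weights (names are clone identifiers).
#' @param purity Fraction of reads from tumour cells, in `[0, 1]`.
#' @return A `bulk_composition`: a tibble with columns `clone`,
#'   `tumour_fraction` (sums to 1) and `read_fraction` (sums to `purity`),
#'   with attributes `purity` and `normal_fraction`.
#' @examples
#' bulk_composition(c(cA = 2, cB = 1, cC = 1), purity = 0.75)
#' @export
bulk_composition <- function(weights, purity = 1) {
  stopifnot(is.numeric(weights), length(weights) > 0,
            !is.null(names(weights)), all(nzchar(names(weights))))
  if (any(weights < 0)) abort("clone weights must be nonnegative")
  if (sum(weights) <= 0) abort("clone weights must not all be zero")
  if (!is.numeric(purity) || length(purity) != 1 || purity < 0 || purity > 1) {
    abort("`purity` must be a single value in [0, 1]")
  }
  tf <- weights / sum(weights)
  out <- tibble(
    clone = names(weights),
    tumour_fraction = unname(tf),
    read_fraction = unname(tf * purity)
  )
  structure(out,
            purity = purity,
            normal_fraction = 1 - purity,
            class = c("bulk_composition", class(out)))
}

#' Sample purity of a bulk composition
#' @param comp A `bulk_composition`.
#' @return The tumour read fraction in `[0, 1]`.
#' @export
purity <- function(comp) attr(comp, "purity")

#' Cancer cell fraction of a clone's subtree
#'
#' The CCF of a mutation arising on the branch leading to `clone` is the
#' sum of tumour proportions of that clone and all its descendants: every
#' cell below the branch inherits the mutation.
#'
#' @param tree A `clone_tree`.
#' @param comp A `bulk_composition` over (a subset of) the tree's clones.
#' @param clone Clone identifier.
#' @return A fraction in `[0, 1]`.
#' @export
subtree_ccf <- function(tree, comp, clone) {
  members <- clone_subtree(tree, clone)
  bad <- setdiff(comp$clone, as_tibble(tree)$clone)
  if (length(bad)) {
    abort(sprintf("composition names clones absent from the tree: %s",
                  paste(bad, collapse = ", ")))
  }
  sum(comp$tumour_fraction[comp$clone %in% members])
}
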