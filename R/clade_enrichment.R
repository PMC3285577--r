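# Clade-enrichment analysis: per-branch hypergeometric tests on a rooted
# lineage tree, FDR control, and nested-subtree pruning. Drives the
# population-clustering and left/right-ovary analyses.

# list of tip-index sets per internal node (node numbers Ntip+1 .. Ntip+Nnode)
clade_tip_sets <- function(tree) {
  pp <- ape::prop.part(tree)
  lapply(pp, identity)
}

#' Per-branch hypergeometric enrichment tests
#'
#' For every internal branch of a rooted lineage tree, tests whether the
#' leaves of the subtree below it (the side away from the root) are enriched
#' for a given cell population. With `N` leaves in the tree, `K` of the
#' population, and a subtree of `n` leaves containing `k` of them, the
#' one-sided enrichment p-value is the hypergeometric upper tail
#' `P(X >= k)`.
#'
#' @param tree rooted `phylo`/`lineage_tree`; every leaf must be labelled.
#' @param labels named character vector, cell_id -> population.
#' @param population the population label to test.
#' @return data.frame with one row per internal branch: `branch_id` (internal
#'   node number), `population`, `k`, `n`, `K`, `N`, `p`, `q_significant`
#'   (NA until [fdr_select()]), `pruned`. Empty (with a warning) if the
#'   population is absent from the tree.
#' @export
subtree_enrichment <- function(tree, labels, population) {
  tips <- tree$tip.label
  miss <- setdiff(tips, names(labels))
  if (length(miss)) stop("unlabelled leaves: ", paste(miss, collapse = ", "))
  lab <- labels[tips]
  N <- length(tips)
  K <- sum(lab == population)
  empty <- data.frame(branch_id = integer(), population = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p = numeric(), q_significant = logical(),
                      pruned = logical(), stringsAsFactors = FALSE)
  if (K == 0L) {
    warning("population '", population, "' absent from tree")
    return(empty)
  }
  sets <- clade_tip_sets(tree)
  if (length(sets) <= 1L) return(empty)  # no internal branch besides the root
  is_pop <- lab == population
  rows <- lapply(seq_along(sets)[-1L], function(i) {  # sets[[1]] = whole tree
    idx <- sets[[i]]
    n <- length(idx)
    k <- sum(is_pop[idx])
    data.frame(branch_id = ape::Ntip(tree) + i, population = population,
               k = k, n = n, K = K, N = N,
               p = phyper(k - 1L, K, N - K, n, lower.tail = FALSE),
               q_significant = NA, pruned = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Benjamini-Hochberg selection of enriched branches
#'
#' Applies the BH step-up procedure at level `q` over all supplied branch x
#' population p-values (by default one pooled family per tree) and sets
#' `q_significant`.
#'
#' @param records data.frame from [subtree_enrichment()] (possibly several
#'   populations row-bound together).
#' @param q FDR level: the study used 0.2 for data analyses and 0.05 for
#'   simulation studies.
#' @return the records with `q_significant` filled in.
#' @export
fdr_select <- function(records, q = 0.2) {
  stopifnot(q > 0, q < 1)
  if (!nrow(records)) return(records)
  records$q_significant <- p.adjust(records$p, method = "BH") <= q
  records
}

#' Prune nested significant subtrees
#'
#' Whenever two significant subtrees are nested (ancestor/descendant), only
#' the one with the most significant p-value is retained; ties keep the
#' larger subtree. Dominated records get `pruned = TRUE` and lose
#' significance.
#'
#' @param records records from [fdr_select()] for a single tree.
#' @param tree the rooted tree the records came from.
#' @return the records with `pruned`/`q_significant` updated.
#' @export
prune_nested <- function(records, tree) {
  if (!nrow(records)) return(records)
  sig <- which(records$q_significant %in% TRUE)
  if (length(sig) < 2L) return(records)
  sets <- clade_tip_sets(tree)
  ntip <- ape::Ntip(tree)
  tipset <- lapply(records$branch_id[sig], function(b) sets[[b - ntip]])
  ord <- sig[order(records$p[sig], -records$n[sig])]
  otips <- tipset[match(ord, sig)]
  kept <- integer(0)
  kept_sets <- list()
  for (i in seq_along(ord)) {
    s <- otips[[i]]
    nested <- any(vapply(kept_sets, function(ks) {
      all(s %in% ks) || all(ks %in% s)
    }, logical(1)))
    if (nested) {
      records$pruned[ord[i]] <- TRUE
      records$q_significant[ord[i]] <- FALSE
    } else {
      kept <- c(kept, ord[i])
      kept_sets <- c(kept_sets, list(s))
    }
  }
  records
}

#' Is a population clustered on the tree?
#'
#' `TRUE` iff at least one branch survives [fdr_select()] plus
#' [prune_nested()] for the given population.
#'
#' @inheritParams subtree_enrichment
#' @param q FDR level.
#' @return logical flag; attribute `"records"` carries the full table.
#' @export
clustering_detected <- function(tree, labels, population, q = 0.05) {
  rec <- subtree_enrichment(tree, labels, population)
  rec <- prune_nested(fdr_select(rec, q), tree)
  structure(any(rec$q_significant %in% TRUE), records = rec)
}

#' Left/right ovary mixing report
#'
#' Tests whether oocytes from the two ovaries form side-specific clades. The
#' oocyte-only induced subtree is extracted and each side label is tested for
#' clade enrichment; under spatially incoherent progenitor expansion and
#' migration neither side should cluster.
#'
#' @param tree rooted lineage tree.
#' @param side_labels named vector cell_id -> `"left"`/`"right"` for the
#'   oocytes (other leaves are ignored).
#' @param q FDR level (default 0.2 as for the data analyses).
#' @return list with `detected` (logical: either side clusters), per-side
#'   flags, and the combined record table; `NA` with a warning when a side
#'   has fewer than 3 oocytes.
#' @export
ovary_mixing_report <- function(tree, side_labels, q = 0.2) {
  side_labels <- side_labels[!is.na(side_labels)]
  oocytes <- intersect(tree$tip.label, names(side_labels))
  n_side <- table(factor(side_labels[oocytes], levels = c("left", "right")))
  if (any(n_side < 3L)) {
    warning("fewer than 3 oocytes on one side; mixing report undefined")
    return(list(detected = NA, left = NA, right = NA, records = NULL))
  }
  sub <- ape::keep.tip(tree, oocytes)
  class(sub) <- c("lineage_tree", "phylo")
  rec <- rbind(subtree_enrichment(sub, side_labels, "left"),
               subtree_enrichment(sub, side_labels, "right"))
  rec <- prune_nested(fdr_select(rec, q), sub)
  left <- any(rec$q_significant %in% TRUE & rec$population == "left")
  right <- any(rec$q_significant %in% TRUE & rec$population == "right")
  list(detected = left || right, left = left, right = right, records = rec)
}
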