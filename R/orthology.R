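#' Maximum-inclusion orthology
#'
#' Extracts orthologs from cleaned homolog trees by repeatedly taking the
#' edge-induced subtree that covers the most distinct taxa without repeating
#' any taxon, until no subtree with at least `min_taxa` taxa remains.
#'
#' @name orthology
NULL

#' Maximum-inclusion parameters
#'
#' Defaults follow the long-branch cutoffs reused from tree cleaning
#' (relative 0.02 subs/site, absolute 0.03 subs/site, sister factor 10) and
#' require a minimum of ten taxa per ortholog.
#'
#' @param relative_cutoff,absolute_cutoff,sister_factor long-branch trim
#'   settings applied inside the extraction loop.
#' @param min_taxa minimum distinct taxa for an emitted ortholog (>= 2).
#' @param retrim `"each_iteration"` re-trims long tips before every
#'   extraction; `"once"` trims only before the first.
#' @return an `mi_params` list.
#' @export
mi_params <- function(relative_cutoff = 0.02, absolute_cutoff = 0.03,
                      min_taxa = 10L, sister_factor = 10,
                      retrim = c("each_iteration", "once")) {
  stopifnot(min_taxa >= 2L)
  structure(list(relative_cutoff = relative_cutoff,
                 absolute_cutoff = absolute_cutoff,
                 min_taxa = as.integer(min_taxa),
                 sister_factor = sister_factor,
                 retrim = match.arg(retrim)),
            class = "mi_params")
}

# all candidate tip sets: both sides of every edge, plus the full tip set
edge_induced_tip_sets <- function(tree) {
  tips <- tree$tip.label
  ntip <- length(tips)
  desc <- descendant_tips_by_node(tree)
  sets <- list(tips)
  for (e in seq_len(nrow(tree$edge))) {
    below <- desc[[tree$edge[e, 2]]]
    if (length(below) >= 2L && length(below) < ntip) {
      sets[[length(sets) + 1L]] <- tips[below]
    }
    above <- setdiff(seq_len(ntip), below)
    if (length(above) >= 2L && length(above) < ntip) {
      sets[[length(sets) + 1L]] <- tips[above]
    }
  }
  unique(lapply(sets, sort))
}

subtree_total_length <- function(tree, tip_set) {
  if (length(tip_set) == length(tree$tip.label)) return(sum(tree$edge.length))
  sub <- ape::keep.tip(tree, tip_set)
  sum(sub$edge.length)
}

mi_trim <- function(tree, params) {
  if (is.null(tree) || length(tree$tip.label) < 3L) return(tree)
  cp <- clean_params(relative_cutoff = params$relative_cutoff,
                     sister_factor = params$sister_factor,
                     absolute_cutoff = params$absolute_cutoff)
  res <- trim_long_tips(tree, cp)
  if (res$discarded) NULL else res$tree
}

#' Extract orthologs by maximum inclusion
#'
#' Iterates: (1) trim long tips with the reused relative/absolute cutoffs;
#' (2) among all rooted subtrees induced by cutting each edge in each
#' direction (plus the full tree), find those with no repeated taxon and
#' select the one with the most distinct taxa, breaking ties by smaller
#' total branch length and then by the lexicographically smallest sorted
#' tip-label list; (3) if it reaches `min_taxa` distinct taxa, emit it as an
#' ortholog and delete its tips from the working tree. Stops when no
#' qualifying subtree remains.
#'
#' @param tree a cleaned homolog `phylo`.
#' @param params an [mi_params()] list.
#' @return list of `phylo` orthologs (possibly empty); tip-disjoint, each
#'   containing every taxon at most once.
#' @export
max_inclusion <- function(tree, params = mi_params()) {
  stopifnot(inherits(tree, "phylo"))
  out <- list()
  working <- tree
  first <- TRUE
  repeat {
    if (is.null(working) || length(working$tip.label) < 2L) break
    if (length(unique(tip_taxon(working$tip.label))) < params$min_taxa) break
    if (params$retrim == "each_iteration" || first) {
      working <- mi_trim(working, params)
      first <- FALSE
      if (is.null(working) || length(working$tip.label) < 2L) break
    }
    sets <- edge_induced_tip_sets(working)
    sets <- Filter(function(s) !anyDuplicated(tip_taxon(s)), sets)
    if (length(sets) == 0L) break
    ntaxa <- vapply(sets, length, integer(1))
    best <- which(ntaxa == max(ntaxa))
    if (length(best) > 1L) {
      tl <- vapply(sets[best], subtree_total_length, numeric(1), tree = working)
      best <- best[tl == min(tl)]
      if (length(best) > 1L) {
        keys <- vapply(sets[best], paste, character(1), collapse = "\r")
        best <- best[order(keys)][1]
      }
    }
    pick <- sets[[best[1]]]
    if (length(pick) < params$min_taxa) break
    out[[length(out) + 1L]] <- ape::keep.tip(working, pick)
    rest <- setdiff(working$tip.label, pick)
    if (length(rest) < 2L) break
    working <- ape::keep.tip(working, rest)
  }
  out
}

#' Extract an ortholog alignment from its homolog alignment
#'
#' Subsets the homolog alignment to the ortholog's tips, re-applies column
#' occupancy cleaning at the given threshold and renames rows to the bare
#' taxon (the copy suffix is dropped).
#'
#' @param homolog_aln character alignment matrix (rows named by record id).
#' @param ortholog a `phylo` emitted by [max_inclusion()].
#' @param occupancy minimum column occupancy (default 0.10).
#' @return alignment matrix with one row per taxon.
#' @export
extract_ortholog_alignment <- function(homolog_aln, ortholog, occupancy = 0.10) {
  tips <- ortholog$tip.label
  missing <- setdiff(tips, rownames(homolog_aln))
  if (length(missing) > 0L) {
    stop("ortholog tip(s) absent from homolog alignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sub <- homolog_aln[tips, , drop = FALSE]
  sub <- clean_columns(sub, min_occupancy = occupancy)
  rownames(sub) <- tip_taxon(rownames(sub))
  sub
}
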