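#' Homolog gene-tree cleaning
#'
#' Two-round hygiene for homolog trees: removal of long terminal branches
#' (relative-to-sister and absolute cutoffs), splitting of trees on deep
#' internal branches, and per-sample removal-rate accounting.
#'
#' @name treeclean
NULL

#' Cleaning parameters
#'
#' Defaults: a tip is removed when its terminal branch is at least 0.02
#' subs/site and ten times its sister branch, and/or at least 0.03 subs/site
#' in absolute terms; trees are split on internal branches above 0.2
#' subs/site with at least four taxa on each side; the whole procedure runs
#' for two rounds.
#'
#' @param relative_cutoff relative tip-length cutoff (subs/site).
#' @param sister_factor required multiple of the sister branch length.
#' @param absolute_cutoff absolute tip-length cutoff (subs/site).
#' @param deep_cutoff internal branch length above which trees are split.
#' @param min_side_taxa minimum distinct taxa required on each side of a
#'   split.
#' @param rounds number of trim+split rounds.
#' @return a `clean_params` list.
#' @export
clean_params <- function(relative_cutoff = 0.02, sister_factor = 10,
                         absolute_cutoff = 0.03, deep_cutoff = 0.2,
                         min_side_taxa = 4L, rounds = 2L) {
  stopifnot(relative_cutoff > 0, sister_factor > 0, absolute_cutoff > 0,
            deep_cutoff > 0, min_side_taxa > 0, rounds > 0,
            relative_cutoff <= absolute_cutoff)
  structure(list(relative_cutoff = relative_cutoff,
                 sister_factor = sister_factor,
                 absolute_cutoff = absolute_cutoff,
                 deep_cutoff = deep_cutoff,
                 min_side_taxa = as.integer(min_side_taxa),
                 rounds = as.integer(rounds)),
            class = "clean_params")
}

#' Remove long terminal branches from a gene tree
#'
#' A tip is removed iff its terminal branch length is at least
#' `relative_cutoff` AND at least `sister_factor` times its sister branch
#' length, OR at least `absolute_cutoff`. The sister length is the minimum
#' terminal branch length among other tips on the same internal node, or the
#' sibling edge length when the sibling subtree is internal. All removals
#' are decided on the input tree in one sweep (no cascading), then degree-2
#' nodes are suppressed with their edge lengths summed.
#'
#' @param tree a `phylo` with >= 3 tips.
#' @param params a [clean_params()] list.
#' @return list with `tree` (pruned `phylo`, or `NULL` when fewer than 2
#'   tips would remain — flagged by `discarded = TRUE`), `removed`
#'   (character vector of removed tip labels) and `discarded`.
#' @export
trim_long_tips <- function(tree, params = clean_params()) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (ntip < 3L) stop("trim_long_tips() needs a tree with >= 3 tips", call. = FALSE)
  term <- terminal_edge_lengths(tree)
  drop <- logical(ntip)
  for (i in seq_len(ntip)) {
    len <- term[i]
    if (len >= params$absolute_cutoff) {
      drop[i] <- TRUE
    } else if (len >= params$relative_cutoff) {
      sis <- sister_branch_length(tree, i)
      drop[i] <- len >= params$sister_factor * sis
    }
  }
  removed <- tree$tip.label[drop]
  if (!any(drop)) return(list(tree = tree, removed = character(), discarded = FALSE))
  if (ntip - sum(drop) < 2L) {
    return(list(tree = NULL, removed = removed, discarded = TRUE))
  }
  list(tree = ape::drop.tip(tree, which(drop)), removed = removed,
       discarded = FALSE)
}

# distinct-taxon counts on both sides of every internal edge
internal_edge_sides <- function(tree) {
  ntip <- length(tree$tip.label)
  desc <- descendant_tips_by_node(tree)
  internal <- which(tree$edge[, 2] > ntip)
  lapply(internal, function(e) {
    below <- desc[[tree$edge[e, 2]]]
    list(edge = e, length = tree$edge.length[e],
         below = tree$tip.label[below],
         above = tree$tip.label[setdiff(seq_len(ntip), below)])
  })
}

#' Split a gene tree on deep internal branches
#'
#' Internal edges longer than `deep_cutoff` whose removal leaves at least
#' `min_side_taxa` distinct taxa on each side are cut, longest first, and
#' the resulting components are re-examined. Surviving edges keep their
#' branch lengths (degree-2 merges sum the two merged edges).
#'
#' @param tree a `phylo`, treated as unrooted.
#' @param params a [clean_params()] list.
#' @return list of `phylo` trees (length 1 when nothing is split).
#' @export
split_deep_branches <- function(tree, params = clean_params()) {
  stopifnot(inherits(tree, "phylo"))
  sides <- internal_edge_sides(tree)
  cand <- Filter(function(s) {
    s$length > params$deep_cutoff &&
      length(s$below) >= 2L && length(s$above) >= 2L &&
      length(unique(tip_taxon(s$below))) >= params$min_side_taxa &&
      length(unique(tip_taxon(s$above))) >= params$min_side_taxa
  }, sides)
  if (length(cand) == 0L) return(list(tree))
  best <- cand[[which.max(vapply(cand, `[[`, numeric(1), "length"))]]
  part1 <- ape::keep.tip(tree, best$below)
  part2 <- ape::keep.tip(tree, best$above)
  c(split_deep_branches(part1, params), split_deep_branches(part2, params))
}

#' One cleaning round over a batch of trees
#'
#' Applies [trim_long_tips()] then [split_deep_branches()] to every tree and
#' aggregates a per-sample removal report. The removal rate for a sample is
#' tips removed divided by tips present before the round, across the whole
#' batch.
#'
#' @param trees list of `phylo` trees.
#' @param params a [clean_params()] list.
#' @param round_index integer recorded in the report.
#' @return list with `trees` (cleaned, possibly more than entered via
#'   splitting), `report` (data frame `sample_id`, `tips_before`,
#'   `tips_removed`, `removal_rate`, `round`), and `n_discarded`,
#'   `trees_split`.
#' @export
clean_round <- function(trees, params = clean_params(), round_index = 1L) {
  before <- table(tip_taxon(unlist(lapply(trees, `[[`, "tip.label"))))
  removed_all <- character()
  out <- list()
  n_discarded <- 0L
  trees_split <- 0L
  for (tr in trees) {
    trimmed <- trim_long_tips(tr, params)
    removed_all <- c(removed_all, trimmed$removed)
    if (trimmed$discarded) {
      n_discarded <- n_discarded + 1L
      next
    }
    parts <- split_deep_branches(trimmed$tree, params)
    if (length(parts) > 1L) trees_split <- trees_split + 1L
    out <- c(out, parts)
  }
  removed <- table(tip_taxon(removed_all))
  samples <- names(before)
  rem <- as.integer(removed[samples])
  rem[is.na(rem)] <- 0L
  report <- data.frame(sample_id = samples,
                       tips_before = as.integer(before),
                       tips_removed = rem,
                       removal_rate = rem / as.integer(before),
                       round = round_index)
  list(trees = out, report = report, n_discarded = n_discarded,
       trees_split = trees_split)
}

#' Run the full multi-round cleaning procedure
#'
#' Calls [clean_round()] `params$rounds` times (default two rounds with the
#' same settings), returning the surviving trees and one report per round.
#'
#' @inheritParams clean_round
#' @return list with `trees` and `reports` (row-bound per-round data frame).
#' @export
clean_trees <- function(trees, params = clean_params()) {
  reports <- list()
  for (r in seq_len(params$rounds)) {
    res <- clean_round(trees, params, round_index = r)
    trees <- res$trees
    reports[[r]] <- res$report
  }
  list(trees = trees, reports = do.call(rbind, reports))
}

#' Write a cleaning report as TSV
#'
#' @param report data frame from [clean_round()] / [clean_trees()].
#' @param path output file.
#' @export
write_clean_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
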