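#' Tree and distance plumbing
#'
#' Gene trees are represented as `ape::phylo` objects with branch lengths in
#' substitutions per site. Tip labels are sample identifiers with an optional
#' copy suffix separated by `@` (e.g. `"Sample_07@2"`); the taxon of a tip is
#' the label before the `@`.
#'
#' @name treekit
NULL

#' Extract the taxon (sample id) from tip labels
#'
#' Strips the optional `@<copy>` suffix so paralog copies of one sample map to
#' the same taxon.
#'
#' @param labels character vector of tip labels.
#' @return character vector of taxon names.
#' @export
#' @examples
#' tip_taxon(c("Sample_07@2", "Sample_01"))
tip_taxon <- function(labels) {
  sub("@.*$", "", labels)
}

validate_newick_text <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    stop("newick parse error: empty input", call. = FALSE)
  }
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("newick parse error: unbalanced ')' at position %d", i),
             call. = FALSE)
      }
    }
  }
  if (depth > 0L) {
    stop(sprintf(
      "newick parse error: %d unclosed '(' at end of input (position %d)",
      depth, length(chars)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Parse a newick string into a gene tree
#'
#' Absent branch lengths default to 0. Support values after closing
#' parentheses are accepted and discarded; only topology and branch lengths
#' are retained.
#'
#' @param text a single newick string (terminating `;` optional).
#' @return an object of class `phylo`.
#' @export
#' @examples
#' tr <- parse_newick("(A:0.1,B:0.2,(C:0.05,D:0.05):0.3);")
parse_newick <- function(text) {
  validate_newick_text(text)
  text <- trimws(text)
  if (!endsWith(text, ";")) text <- paste0(text, ";")
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr)) stop("newick parse error: unreadable tree text", call. = FALSE)
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  tr$edge.length[is.na(tr$edge.length)] <- 0
  tr$node.label <- NULL  # support values are discarded
  if (any(tr$edge.length < 0)) stop("negative branch length in input", call. = FALSE)
  tr
}

#' Serialize a gene tree to newick
#'
#' Labels are written unquoted and without support values; branch lengths are
#' written with enough digits that write/parse round-trips reproduce them to
#' 1e-9.
#'
#' @param tree a `phylo` object.
#' @return a single newick string ending in `;`.
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tree$node.label <- NULL
  ape::write.tree(tree, digits = 12)
}

#' Read/write newick files, one tree per line
#'
#' @param path file path.
#' @return `read_newick_file()` returns a list of `phylo` objects.
#' @export
read_newick_file <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, parse_newick)
}

#' @param trees a list of `phylo` objects.
#' @rdname read_newick_file
#' @export
write_newick_file <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  writeLines(vapply(trees, write_newick, character(1)), path)
}

#' Jukes-Cantor distance between two aligned sequences
#'
#' Sites where either sequence carries a gap (`-`) or `N` are excluded. The
#' distance is -(3/4) log(1 - (4/3) p) with p the mismatch proportion over
#' the compared sites.
#'
#' @param a,b equal-length nucleotide strings (or character vectors of
#'   single characters).
#' @return the JC distance in substitutions per site.
#' @export
#' @examples
#' jc_distance(strrep("ACGT", 25), strrep("ACGT", 25))  # 0
jc_distance <- function(a, b) {
  a <- as_char_vector(a)
  b <- as_char_vector(b)
  if (length(a) != length(b)) stop("sequences differ in length", call. = FALSE)
  ok <- !(a %in% c("-", "N")) & !(b %in% c("-", "N"))
  n <- sum(ok)
  if (n == 0L) stop("undefined JC distance: no comparable sites", call. = FALSE)
  p <- sum(a[ok] != b[ok]) / n
  if (p >= 0.75) {
    stop(sprintf("undefined JC distance: mismatch proportion %.3f >= 0.75", p),
         call. = FALSE)
  }
  -0.75 * log(1 - 4 * p / 3)
}

as_char_vector <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1]]
  toupper(as.character(x))
}

#' Pairwise Jukes-Cantor distance matrix
#'
#' @param seqs named character vector (or named list) of aligned sequences.
#' @return symmetric numeric matrix with sequence names as dimnames.
#' @export
jc_distance_matrix <- function(seqs) {
  labs <- names(seqs)
  if (is.null(labs) || anyDuplicated(labs)) {
    stop("sequences must carry unique names", call. = FALSE)
  }
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  chars <- lapply(seqs, as_char_vector)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- jc_distance(chars[[i]], chars[[j]])
    }
  }
  d
}

validate_distance_matrix <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) {
    stop("distance matrix must be square", call. = FALSE)
  }
  if (is.null(rownames(d))) stop("distance matrix must be labelled", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero", call. = FALSE)
  if (any(d < 0)) stop("distances must be non-negative", call. = FALSE)
  invisible(TRUE)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via [ape::nj()] for >= 3 taxa); negative
#' intermediate branch lengths are clamped to zero. The output is unrooted.
#'
#' @param d labelled symmetric distance matrix with zero diagonal.
#' @return an unrooted `phylo` object.
#' @export
neighbor_joining <- function(d) {
  validate_distance_matrix(d)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 labels", call. = FALSE)
  if (n == 2L) {
    return(parse_newick(sprintf("(%s:%.12g,%s:%.12g);",
                                rownames(d)[1], d[1, 2] / 2,
                                rownames(d)[2], d[1, 2] / 2)))
  }
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

## --- internal phylo helpers shared by treeclean / orthology ---------------

# terminal edge length for each tip, named by tip label order
terminal_edge_lengths <- function(tree) {
  ntip <- length(tree$tip.label)
  idx <- match(seq_len(ntip), tree$edge[, 2])
  out <- tree$edge.length[idx]
  names(out) <- tree$tip.label
  out
}

# tip indices (1..ntip) descending from each node; list indexed by node id
descendant_tips_by_node <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  desc <- vector("list", nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  # postorder: children before parents
  ord <- ape::postorder(tree)
  for (e in ord) {
    p <- tree$edge[e, 1]
    ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

# sister branch length of a tip: min terminal length among tip siblings, or
# the sibling edge length when every sibling subtree is internal
sister_branch_length <- function(tree, tip_index) {
  parent <- tree$edge[tree$edge[, 2] == tip_index, 1]
  sib_edges <- which(tree$edge[, 1] == parent & tree$edge[, 2] != tip_index)
  sib_nodes <- tree$edge[sib_edges, 2]
  ntip <- length(tree$tip.label)
  tip_sibs <- sib_edges[sib_nodes <= ntip]
  if (length(tip_sibs) > 0L) {
    min(tree$edge.length[tip_sibs])
  } else if (length(sib_edges) > 0L) {
    min(tree$edge.length[sib_edges])
  } else {
    Inf  # tip hangs off the root alone; nothing to compare against
  }
}
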