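#' Read a rooted, branch-lengthed phylogeny from Newick
#'
#' Parses a Newick string or file into an \code{ape} \code{phylo} object and
#' validates the invariants the downstream analyses rely on: every edge has a
#' nonnegative branch length, tip labels are unique, and the tree has a single
#' root. Tip labels are canonicalized (whitespace trimmed, spaces/underscores
#' unified to underscores).
#'
#' @param text Newick string, or \code{NULL} if \code{file} is given.
#' @param file path to a Newick file.
#' @return an object of class \code{phylo}.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) && is.null(file))
    stop("provide `text` or `file`")
  if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("Newick parse failure: ",
                                            conditionMessage(e), call. = FALSE))
  if (is.null(tree))
    stop("Newick parse failure: input did not yield a tree (check for an ",
         "unbalanced parenthesis or missing terminal ';' near the end of: ",
         substr(text, 1, 60), ")")
  validate_phylogeny(tree)
}

#' @rdname read_newick
#' @param tree a \code{phylo} object.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  tree$tip.label <- canonical_name(tree$tip.label)
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (anyNA(tree$edge.length) || any(is.nan(tree$edge.length))) {
    bad <- which(is.na(tree$edge.length) | is.nan(tree$edge.length))
    stop("missing branch length on ", length(bad), " edge(s), e.g. edge to ",
         edge_child_label(tree, bad[1]))
  }
  if (any(tree$edge.length < 0))
    stop("negative branch length")
  # exactly one root: every non-root node has exactly one parent
  parents <- tabulate(tree$edge[, 2], nbins = max(tree$edge))
  if (any(parents > 1)) stop("node with multiple parents (not a tree)")
  tree
}

edge_child_label <- function(tree, edge_row) {
  child <- tree$edge[edge_row, 2]
  if (child <= length(tree$tip.label)) tree$tip.label[child]
  else paste0("internal node ", child)
}

#' Write a phylogeny to Newick
#'
#' @param tree a \code{phylo} object.
#' @param file optional path; if \code{NULL} the Newick string is returned.
#' @param digits significant digits for branch lengths.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL, digits = 15) {
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Read a clade-filter taxon list
#'
#' One taxon name per line; blank lines and \code{#} comments ignored.
#'
#' @param file path to the list file.
#' @return character vector of canonical taxon names.
#' @export
read_taxon_list <- function(file) {
  x <- readLines(file, warn = FALSE)
  x <- sub("#.*$", "", x)
  x <- trimws(x)
  canonical_name(x[nzchar(x)])
}

#' Remove a set of taxa (e.g. gymnosperms) from a tree
#'
#' Drops the named tips and suppresses the degree-2 internal nodes that
#' pruning creates, summing their branch lengths, so that patristic distances
#' among the surviving taxa are unchanged. Names absent from the tree are
#' reported as a warning, not an error.
#'
#' @param tree a \code{phylo} object.
#' @param taxa character vector of tip names to remove (may be empty).
#' @return the pruned \code{phylo}; at least 2 tips must survive.
#' @export
apply_clade_filter <- function(tree, taxa) {
  tree <- validate_phylogeny(tree)
  taxa <- canonical_name(taxa)
  unmatched <- setdiff(taxa, tree$tip.label)
  if (length(unmatched))
    warning("filter names not in tree: ", paste(unmatched, collapse = ", "))
  drop <- intersect(taxa, tree$tip.label)
  if (!length(drop)) return(tree)
  keep_n <- length(tree$tip.label) - length(drop)
  if (keep_n < 2)
    stop("fewer than 2 tips would remain after filtering (", keep_n, ")")
  ape::drop.tip(tree, drop, collapse.singles = TRUE)
}

#' Patristic (cophenetic) distance matrix
#'
#' \code{d[i, j]} is the sum of branch lengths on the tip-to-tip path.
#'
#' @param tree a \code{phylo} object.
#' @return symmetric numeric matrix with zero diagonal, rows/cols in tip order.
#' @export
cophenetic_matrix <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label]
}

#' Phylogenetic (Brownian-motion) covariance matrix
#'
#' \code{C[i, j]} is the shared root-to-MRCA path length of tips i and j; the
#' diagonal holds root-to-tip depths. Under Brownian motion the expected trait
#' covariance is \code{sigma2 * C}.
#'
#' @param tree a \code{phylo} object.
#' @return symmetric positive-semidefinite matrix in tip order.
#' @export
phylo_covariance <- function(tree) {
  C <- ape::vcv.phylo(tree)
  C[tree$tip.label, tree$tip.label]
}

#' Faith's phylogenetic diversity (root-inclusive)
#'
#' Sum of branch lengths of the minimal subtree connecting the given taxa
#' \emph{and the root}. With a single taxon this is its root-to-tip path;
#' with all taxa it is the total branch length of the tree.
#'
#' @param tree a \code{phylo} object.
#' @param taxa nonempty character vector of tip labels.
#' @return numeric branch-length sum.
#' @export
faith_pd <- function(tree, taxa) {
  taxa <- unique(canonical_name(taxa))
  if (!length(taxa)) stop("taxa must be nonempty")
  idx <- match(taxa, tree$tip.label)
  if (anyNA(idx))
    stop("unknown taxa: ", paste(taxa[is.na(idx)], collapse = ", "))
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  parent_of <- integer(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  elen <- numeric(max(tree$edge))
  elen[tree$edge[, 2]] <- tree$edge.length
  used <- logical(max(tree$edge))
  for (tip in idx) {
    node <- tip
    while (node != root && !used[node]) {
      used[node] <- TRUE
      node <- parent_of[node]
    }
  }
  sum(elen[used])
}

#' Total branch length of a tree
#' @param tree a \code{phylo} object.
#' @export
total_branch_length <- function(tree) sum(tree$edge.length)
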