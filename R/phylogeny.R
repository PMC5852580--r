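# Distance-based phylogeny: p-distances under complete deletion,
# neighbor-joining (via ape), bootstrap supports from column resampling,
# and clade-based class assignment of unlabeled leaves.

.msa_matrix <- function(msa) {
  if (is.matrix(msa)) return(msa)
  stopifnot(is.character(msa), !is.null(names(msa)))
  lens <- nchar(msa)
  if (length(unique(lens)) != 1)
    stop("alignment rows must have equal length")
  m <- do.call(rbind, strsplit(toupper(msa), ""))
  rownames(m) <- names(msa)
  m
}

.complete_deletion <- function(mat) {
  keep <- colSums(mat == "-" | mat == ".") == 0
  mat[, keep, drop = FALSE]
}

.pdist_mat <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d[i, j] <- d[j, i] <- mean(mat[i, ] != mat[j, ])
    }
  }
  d
}

#' Pairwise p-distance matrix under complete deletion
#'
#' Columns containing a gap in any sequence are removed globally, then each
#' pairwise distance is the proportion of mismatching retained columns.
#'
#' @param msa Named character vector of aligned sequences (equal lengths,
#'   `-` gaps), or a character matrix (rows = taxa).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(msa) {
  mat <- .complete_deletion(.msa_matrix(msa))
  if (nrow(mat) < 2) stop("need at least 2 sequences")
  if (ncol(mat) == 0) stop("complete deletion removed all columns")
  .pdist_mat(mat)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via `ape::nj`). Negative branch
#' lengths, which can arise on non-additive matrices, are clamped to zero
#' with the deficit transferred to a sibling branch at the same node so that
#' adjacent path lengths are preserved.
#'
#' @param d Symmetric distance matrix or `dist` object with >= 3 taxa.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor-joining needs at least 3 taxa")
  tr <- ape::nj(stats::as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sibs <- setdiff(which(tr$edge[, 1] == parent | tr$edge[, 2] == parent), e)
    if (length(sibs) > 0) {
      k <- sibs[which.max(tr$edge.length[sibs])]
      tr$edge.length[k] <- tr$edge.length[k] + tr$edge.length[e]
    }
    tr$edge.length[e] <- 0
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Neighbor-joining tree with bootstrap supports from an alignment
#'
#' Builds the full-data NJ tree from p-distances (complete deletion), then
#' resamples retained alignment columns with replacement `n_replicates`
#' times, rebuilds a tree per replicate, and reports for each internal edge
#' of the full-data tree the percentage of replicates containing that
#' bipartition (stored in `tree$node.label`). When the alignment is
#' degenerate (all pairwise distances zero) the arbitrary resolution is
#' flagged via `attr(tree, "unresolved")`.
#'
#' @inheritParams p_distance_matrix
#' @param n_replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer seed making the resampling reproducible.
#' @return A `phylo` tree with node labels = supports in \[0, 100\].
#' @export
bootstrap_supports <- function(msa, n_replicates = 1000, seed = 1) {
  mat <- .complete_deletion(.msa_matrix(msa))
  if (ncol(mat) == 0) stop("complete deletion removed all columns")
  d <- .pdist_mat(mat)
  tree <- nj_tree(d)
  if (all(d == 0)) {
    tree$node.label <- c("", rep(NA_character_, tree$Nnode - 1L))
    attr(tree, "unresolved") <- TRUE
    return(tree)
  }
  set.seed(seed)
  counts <- ape::boot.phylo(tree, mat,
                            function(x) nj_tree(.pdist_mat(x)),
                            B = n_replicates, quiet = TRUE, rooted = FALSE)
  supports <- round(counts / n_replicates * 100)
  supports[1] <- NA  # root "bipartition" is the trivial full leaf set
  tree$node.label <- ifelse(is.na(supports), "", as.character(supports))
  attr(tree, "unresolved") <- FALSE
  tree
}

#' Assign classes to unlabeled leaves from labeled reference leaves
#'
#' Each unlabeled (query) leaf receives the class of the smallest
#' surrounding clade (a side of some bipartition of the unrooted tree, or
#' the whole tree as last resort) that contains at least one labeled
#' reference and whose references are unanimous. Queries with no such clade,
#' or with conflicting smallest clades, are `"unclassified"`.
#'
#' @param tree A `phylo` tree.
#' @param ref_classes Named character vector: reference leaf id -> class.
#' @return Named character vector: query leaf id -> class.
#' @export
assign_classes <- function(tree, ref_classes) {
  tips <- tree$tip.label
  refs <- intersect(names(ref_classes), tips)
  if (length(refs) == 0) stop("tree has no labeled reference leaf")
  queries <- setdiff(tips, names(ref_classes))
  # All bipartition sides: descendant tip sets of each node and complements.
  parts <- ape::prop.part(tree)
  sides <- list()
  for (p in parts) {
    sides[[length(sides) + 1L]] <- tips[p]
    comp <- tips[-p]
    if (length(comp) > 0) sides[[length(sides) + 1L]] <- comp
  }
  # Cherries (pairs of sister leaves) are sides of trivial edges too: a leaf
  # plus each side containing it is already covered; single leaves are not
  # informative. prop.part covers clades of the rooted representation; the
  # complements cover the rest.
  out <- stats::setNames(rep("unclassified", length(queries)), queries)
  for (q in queries) {
    cand <- Filter(function(s) q %in% s && any(s %in% refs), sides)
    if (length(cand) == 0) next
    ok <- Filter(function(s) {
      cls <- unique(ref_classes[intersect(s, refs)])
      length(cls) == 1
    }, cand)
    if (length(ok) == 0) next
    sizes <- vapply(ok, length, integer(1))
    best <- ok[sizes == min(sizes)]
    cls <- unique(vapply(best, function(s) ref_classes[[intersect(s, refs)[1]]],
                         character(1)))
    if (length(cls) == 1) out[[q]] <- cls
  }
  out
}

#' Write a tree to Newick
#'
#' @param tree A `phylo` tree (node labels carry bootstrap supports).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
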