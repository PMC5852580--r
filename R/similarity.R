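# Pairwise protein alignment producing the identity/coverage evidence used
# to call duplicate gene pairs. Local alignment with affine gaps and
# BLOSUM62 stands in for a reciprocal BLASTP search: the duplicate rule
# depends only on identity and coverage, not on search statistics.

.blosum_env <- new.env(parent = emptyenv())

.blosum62 <- function() {
  if (is.null(.blosum_env$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .blosum_env$m <- e$BLOSUM62
  }
  .blosum_env$m
}

#' Locally align two proteins and report identity/coverage evidence
#'
#' Smith-Waterman alignment with affine gap penalties (open 11, extend 1)
#' and the BLOSUM62 substitution matrix. Identity is the percentage of
#' identical positions over all aligned columns of the local region (a gap
#' column counts as a mismatch); coverage of each sequence is the aligned
#' span on that sequence as a percentage of its length.
#'
#' @param protein_a,protein_b Non-empty amino-acid strings.
#' @param ids Length-2 character vector of ids for reporting.
#' @return An `alignment_result`: one-row data.frame with `id_a`, `id_b`,
#'   `identity`, `coverage_a`, `coverage_b`, `aligned_length`, `score`.
#' @export
#' @examples
#' align_pair("MKTAYIAKQR", "MKTAYIAK")
align_pair <- function(protein_a, protein_b, ids = c("seq_a", "seq_b")) {
  if (!nzchar(protein_a) || !nzchar(protein_b)) stop("empty protein sequence")
  pa <- Biostrings::pairwiseAlignment(protein_a, protein_b, type = "local",
                                      substitutionMatrix = .blosum62(),
                                      gapOpening = 11, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::subject(pa)), "")[[1]]
  ncol_aln <- length(p)
  ident <- sum(p == s & p != "-") / ncol_aln * 100
  span_a <- sum(p != "-")
  span_b <- sum(s != "-")
  data.frame(id_a = ids[1], id_b = ids[2],
             identity = ident,
             coverage_a = span_a / nchar(protein_a) * 100,
             coverage_b = span_b / nchar(protein_b) * 100,
             aligned_length = ncol_aln,
             score = Biostrings::score(pa),
             stringsAsFactors = FALSE)
}

#' Call duplicate gene pairs from all-against-all protein alignment
#'
#' Every unordered pair of family members is aligned with [align_pair()];
#' a pair is called a duplicate when its identity AND both coverages are
#' strictly greater than `threshold` percent.
#'
#' @param family A `family_table` with a `protein` column, or a named
#'   character vector of proteins.
#' @param threshold Percent identity/coverage cutoff (strict `>`), default 80.
#' @return Data frame of all pairs with alignment evidence and a logical
#'   `called` column, ordered by (id_a, id_b) in input order.
#' @export
call_duplicates <- function(family, threshold = 80) {
  prot <- if (inherits(family, "family_table")) {
    if (is.null(family$protein)) stop("family table has no protein column")
    stats::setNames(family$protein, family$gene_id)
  } else family
  if (length(prot) < 2) stop("need at least 2 family members")
  ids <- names(prot)
  rows <- list()
  for (i in seq_len(length(ids) - 1L)) {
    for (j in seq(i + 1L, length(ids))) {
      rows[[length(rows) + 1L]] <-
        align_pair(prot[[i]], prot[[j]], ids = c(ids[i], ids[j]))
    }
  }
  out <- do.call(rbind, rows)
  out$called <- out$identity > threshold &
    pmin(out$coverage_a, out$coverage_b) > threshold
  out
}
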