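# Tandem/segmental classification of duplicate pairs and gene-cluster
# detection from genomic coordinates.

#' Nearest-edge genomic distance between two gene spans
#'
#' Distance between the closest edges of the two spans on the same
#' chromosome (0 for overlapping spans); `NA` across chromosomes where a
#' linear distance is undefined.
#'
#' @param a,b Single rows of a `family_table` (or lists with `chromosome`,
#'   `start`, `end`).
#' @return Distance in bp, or `NA` for different chromosomes.
#' @export
gene_distance <- function(a, b) {
  if (a$chromosome != b$chromosome) return(NA_integer_)
  if (a$start > b$start) { tmp <- a; a <- b; b <- tmp }
  max(0L, b$start - a$end)
}

#' Classify a duplicate pair as tandem or segmental
#'
#' A pair is tandem when both genes lie on the same chromosome within
#' `tandem_window` bp (nearest-edge distance, inclusive boundary);
#' otherwise it is segmental. Cross-chromosome pairs are always segmental.
#'
#' @param a,b Distinct gene rows (see [gene_distance()]); each must carry a
#'   `gene_id`.
#' @param tandem_window Maximum tandem distance in bp (default 100 kb).
#' @return A `duplicate_pair`: one-row data.frame with `id_a`, `id_b`,
#'   `same_chromosome`, `genomic_distance`, `dup_type`.
#' @export
classify_pair <- function(a, b, tandem_window = 100000) {
  if (identical(a$gene_id, b$gene_id)) stop("a and b must be distinct genes")
  d <- gene_distance(a, b)
  same <- a$chromosome == b$chromosome
  type <- if (same && !is.na(d) && d <= tandem_window) "tandem" else "segmental"
  data.frame(id_a = a$gene_id, id_b = b$gene_id,
             same_chromosome = same,
             genomic_distance = if (is.na(d)) NA_integer_ else as.integer(d),
             dup_type = type, stringsAsFactors = FALSE)
}

#' Classify a set of duplicate pairs against a family table
#'
#' @param family A `family_table`.
#' @param pairs Data frame with `id_a`, `id_b` columns; every id must
#'   resolve in `family`.
#' @inheritParams classify_pair
#' @return Data frame of `duplicate_pair` rows, one per input pair.
#' @export
classify_pairs <- function(family, pairs, tandem_window = 100000) {
  stopifnot(inherits(family, "family_table"))
  missing <- setdiff(unique(c(pairs$id_a, pairs$id_b)), family$gene_id)
  if (length(missing) > 0)
    stop("pair id(s) not in family table: ", paste(missing, collapse = ", "))
  rownames(family) <- family$gene_id
  if (nrow(pairs) == 0)
    return(data.frame(id_a = character(), id_b = character(),
                      same_chromosome = logical(),
                      genomic_distance = integer(), dup_type = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    classify_pair(family[pairs$id_a[i], ], family[pairs$id_b[i], ],
                  tandem_window = tandem_window)
  }))
}

#' Detect gene clusters on chromosomes
#'
#' Genes are sorted by start position within each chromosome and swept left
#' to right: a run is anchored at its first (leftmost unassigned) gene and
#' extends over all consecutive genes whose start lies within
#' `cluster_window` bp of the anchor's start. Runs with at least `min_genes`
#' members are reported; no gene belongs to two clusters.
#'
#' @param family A `family_table`.
#' @param cluster_window Window in bp (default 200 kb).
#' @param min_genes Minimum cluster size (default 3, i.e. "more than two").
#' @return Data frame: `chromosome`, `members` (comma-separated ids in
#'   positional order), `n_genes`, `span` (bp from first start to last end).
#' @export
find_clusters <- function(family, cluster_window = 200000, min_genes = 3) {
  stopifnot(inherits(family, "family_table"))
  out <- list()
  for (chr in unique(family$chromosome)) {
    g <- family[family$chromosome == chr, ]
    g <- g[order(g$start, g$gene_id), ]
    i <- 1L
    while (i <= nrow(g)) {
      anchor <- g$start[i]
      j <- i
      while (j < nrow(g) && g$start[j + 1L] - anchor <= cluster_window) j <- j + 1L
      if (j - i + 1L >= min_genes) {
        out[[length(out) + 1L]] <- data.frame(
          chromosome = chr,
          members = paste(g$gene_id[i:j], collapse = ","),
          n_genes = j - i + 1L,
          span = max(g$end[i:j]) - min(g$start[i:j]),
          stringsAsFactors = FALSE)
      }
      i <- j + 1L
    }
  }
  if (length(out) == 0)
    return(data.frame(chromosome = character(), members = character(),
                      n_genes = integer(), span = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Summarize classified duplicate pairs
#'
#' @param pairs Data frame of `duplicate_pair` rows.
#' @return List with `counts` (named integer vector per `dup_type`) and
#'   `pairs` (the input table).
#' @export
duplication_report <- function(pairs) {
  counts <- c(tandem = 0L, segmental = 0L)
  if (nrow(pairs) > 0) {
    tab <- table(pairs$dup_type)
    counts[names(tab)] <- as.integer(tab)
  }
  list(counts = counts, pairs = pairs)
}
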