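# Independent brute-force oracles and small generators used across tests.

CODE <- Biostrings::GENETIC_CODE
SENSE <- names(CODE)[CODE != "*"]

# Brute-force Nei-Gojobori site counts: direct neighbor enumeration with
# stop-renormalization, written independently of the package's memoized
# lookup tables.
oracle_sites <- function(codon) {
  s <- 0
  for (pos in 1:3) {
    syn <- 0; legal <- 0
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, pos, pos)) next
      x <- codon; substr(x, pos, pos) <- b
      if (CODE[[x]] == "*") next
      legal <- legal + 1
      if (CODE[[x]] == CODE[[codon]]) syn <- syn + 1
    }
    if (legal > 0) s <- s + syn / legal
  }
  c(syn = s, nonsyn = 3 - s)
}

# Brute-force pathway enumeration for difference counts, using explicit
# recursion over remaining mismatch positions rather than permutation
# matrices.
oracle_diffs <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(pos) == 0) return(c(syn = 0, nonsyn = 0))
  paths <- list()
  walk <- function(cur, remaining, sd, nd) {
    if (length(remaining) == 0) {
      paths[[length(paths) + 1]] <<- c(sd, nd)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (CODE[[nxt]] == "*") next
      walk(nxt, setdiff(remaining, p),
           sd + (CODE[[nxt]] == CODE[[cur]]), nd + (CODE[[nxt]] != CODE[[cur]]))
    }
  }
  walk(a, pos, 0, 0)
  if (length(paths) == 0) return(c(syn = 0, nonsyn = length(pos)))
  m <- do.call(rbind, paths)
  c(syn = mean(m[, 1]), nonsyn = mean(m[, 2]))
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

random_cds <- function(n_codons) {
  paste(sample(SENSE, n_codons, replace = TRUE), collapse = "")
}

# Bootstrap support of the bipartition separating `tips` from the rest,
# read off the node labels of a bootstrapped tree.
clade_support <- function(tree, tips) {
  parts <- ape::prop.part(tree)
  all_tips <- tree$tip.label
  target <- sort(tips)
  for (i in seq_along(parts)) {
    side <- sort(all_tips[parts[[i]]])
    comp <- sort(setdiff(all_tips, side))
    if (identical(side, target) || identical(comp, target))
      return(suppressWarnings(as.numeric(tree$node.label[i])))
  }
  NA_real_
}

# One-row family_table-like gene record for classify_pair tests.
gene_row <- function(id, chr, start, end, strand = "+") {
  data.frame(gene_id = id, chromosome = chr, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}
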