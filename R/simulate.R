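# Synthetic-data generators: gene families with planted tandem/segmental
# duplicate pairs diverged to target Ka/Ks, and qPCR Cq tables with planted
# fold-changes. The generators share only the public file formats with the
# analysis modules, so planted truths are genuine test oracles.

#' Configuration for a synthetic gene family
#'
#' @param n_genes Total number of family members.
#' @param n_chromosomes Number of chromosomes to place genes on.
#' @param codon_length Codons per CDS (excluding any stop).
#' @param duplicate_plan Data frame with columns `id_a`, `id_b`, `type`
#'   (`"tandem"`/`"segmental"`), `target_ks` (in (0, 0.7)), `target_omega`
#'   (> 0), and optionally `offset` (bp between tandem copies, < 100000;
#'   default 5000). Ids must be of the form `gene01`..`geneNN`.
#' @param gene_spacing Minimum bp between neighboring non-pair genes
#'   (default 300 kb, keeping unplanned genes out of tandem windows and
#'   clusters).
#' @return A `family_sim_config` list.
#' @export
family_sim_config <- function(n_genes = 8, n_chromosomes = 4,
                              codon_length = 300,
                              duplicate_plan = NULL,
                              gene_spacing = 300000) {
  if (is.null(duplicate_plan))
    duplicate_plan <- data.frame(id_a = character(), id_b = character(),
                                 type = character(), target_ks = numeric(),
                                 target_omega = numeric(),
                                 stringsAsFactors = FALSE)
  if (nrow(duplicate_plan) > 0) {
    stopifnot(all(duplicate_plan$type %in% c("tandem", "segmental")),
              all(duplicate_plan$target_ks > 0 & duplicate_plan$target_ks < 0.7),
              all(duplicate_plan$target_omega > 0))
    if (is.null(duplicate_plan$offset)) duplicate_plan$offset <- 5000
    stopifnot(all(duplicate_plan$offset[duplicate_plan$type == "tandem"] < 100000))
  }
  seg <- sum(duplicate_plan$type == "segmental")
  if (seg > 0 && n_chromosomes < 2)
    stop("segmental pairs need at least 2 chromosomes")
  structure(list(n_genes = n_genes, n_chromosomes = n_chromosomes,
                 codon_length = codon_length, duplicate_plan = duplicate_plan,
                 gene_spacing = gene_spacing),
            class = "family_sim_config")
}

# Inverse Jukes-Cantor: observed proportion giving corrected distance d.
.jc_inverse <- function(d) 0.75 * (1 - exp(-4 * d / 3))

.random_cds <- function(n_codons) {
  paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}

# Single-base substitutions of the requested kind ("syn"/"nonsyn") available
# at a codon, excluding changes that create stops.
.codon_moves <- function(codon, kind) {
  code <- .genetic_code()
  aa <- code[[codon]]
  moves <- list()
  for (pos in 1:3) {
    for (b in setdiff(BASES, substr(codon, pos, pos))) {
      x <- codon
      substr(x, pos, pos) <- b
      if (code[[x]] == "*") next
      syn <- code[[x]] == aa
      if ((kind == "syn") == syn)
        moves[[length(moves) + 1L]] <- x
    }
  }
  moves
}

# Diverge a CDS by n_syn synonymous and n_nonsyn nonsynonymous point
# substitutions, at most one substitution per codon.
.mutate_cds <- function(cds, n_syn, n_nonsyn) {
  codons <- split_codons(cds)
  order <- sample(length(codons))
  todo <- c(rep("syn", n_syn), rep("nonsyn", n_nonsyn))
  todo <- sample(todo)
  ti <- 1L
  for (i in order) {
    if (ti > length(todo)) break
    moves <- .codon_moves(codons[i], todo[ti])
    if (length(moves) == 0) next
    codons[i] <- moves[[sample.int(length(moves), 1)]]
    ti <- ti + 1L
  }
  if (ti <= length(todo))
    stop("infeasible substitution budget: ", length(todo) - ti + 1L,
         " change(s) could not be placed")
  paste(codons, collapse = "")
}

#' Simulate a gene family with planted duplication and divergence
#'
#' Ancestral coding sequences are drawn uniformly over sense codons. For
#' each planted pair, copy B is diverged from copy A by the number of
#' synonymous and nonsynonymous substitutions implied by `target_ks`,
#' `target_omega` and the ancestor's Nei-Gojobori site counts (inverting the
#' Jukes-Cantor correction), placed at random eligible positions with at
#' most one substitution per codon. Tandem pairs are placed on one
#' chromosome at the configured nearest-edge offset; segmental pairs on two
#' different chromosomes; all other spacings exceed `gene_spacing`.
#'
#' @param cfg A `family_sim_config`.
#' @param seed Integer seed; the output is deterministic given (cfg, seed).
#' @return List with `family` (a `family_table` with `cds`/`protein`
#'   attached), `cds`, `protein` (named vectors), and `plan` (the realized
#'   duplicate plan).
#' @export
simulate_family <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "family_sim_config"))
  set.seed(seed)
  plan <- cfg$duplicate_plan
  ids <- sprintf("gene%02d", seq_len(cfg$n_genes))
  planned <- unique(c(plan$id_a, plan$id_b))
  if (!all(planned %in% ids))
    stop("duplicate plan names genes outside gene01..gene",
         sprintf("%02d", cfg$n_genes))
  cds <- stats::setNames(rep(NA_character_, cfg$n_genes), ids)
  for (k in seq_len(nrow(plan))) {
    anc <- .random_cds(cfg$codon_length)
    sites <- .site_table()
    codons <- split_codons(anc)
    S <- sum(sites[codons, "syn"])
    N <- sum(sites[codons, "nonsyn"])
    n_syn <- round(.jc_inverse(plan$target_ks[k]) * S)
    n_nonsyn <- round(.jc_inverse(plan$target_ks[k] * plan$target_omega[k]) * N)
    cds[[plan$id_a[k]]] <- anc
    cds[[plan$id_b[k]]] <- .mutate_cds(anc, n_syn, n_nonsyn)
  }
  for (id in ids[is.na(cds)]) cds[[id]] <- .random_cds(cfg$codon_length)
  protein <- vapply(cds, translate_cds, character(1))

  # Genomic placement: per-chromosome cursors advanced by > gene_spacing.
  chroms <- sprintf("Chr%02d", seq_len(cfg$n_chromosomes))
  cursor <- stats::setNames(rep(1L, cfg$n_chromosomes), chroms)
  place <- function(chr, len, at = NULL) {
    start <- if (is.null(at))
      cursor[[chr]] + cfg$gene_spacing + sample.int(100000, 1)
    else at
    end <- start + len - 1L
    cursor[chr] <<- max(cursor[[chr]], end)
    c(start = start, end = end)
  }
  tab <- data.frame(gene_id = ids, chromosome = NA_character_,
                    start = NA_integer_, end = NA_integer_,
                    strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
                    stringsAsFactors = FALSE)
  rownames(tab) <- ids
  len <- function(id) nchar(cds[[id]])
  for (k in seq_len(nrow(plan))) {
    a <- plan$id_a[k]; b <- plan$id_b[k]
    if (plan$type[k] == "tandem") {
      chr <- sample(chroms, 1)
      pa <- place(chr, len(a))
      pb <- place(chr, len(b), at = pa[["end"]] + plan$offset[k])
      tab[a, c("chromosome", "start", "end")] <- list(chr, pa[["start"]], pa[["end"]])
      tab[b, c("chromosome", "start", "end")] <- list(chr, pb[["start"]], pb[["end"]])
    } else {
      pair_chr <- sample(chroms, 2)
      pa <- place(pair_chr[1], len(a))
      pb <- place(pair_chr[2], len(b))
      tab[a, c("chromosome", "start", "end")] <- list(pair_chr[1], pa[["start"]], pa[["end"]])
      tab[b, c("chromosome", "start", "end")] <- list(pair_chr[2], pb[["start"]], pb[["end"]])
    }
  }
  for (id in ids[is.na(tab$chromosome)]) {
    chr <- sample(chroms, 1)
    p <- place(chr, len(id))
    tab[id, c("chromosome", "start", "end")] <- list(chr, p[["start"]], p[["end"]])
  }
  rownames(tab) <- NULL
  family <- attach_sequences(as_family_table(tab), cds = cds)
  list(family = family, cds = cds, protein = protein, plan = plan)
}

#' Configuration for a synthetic qPCR experiment
#'
#' @param genes Character vector of gene ids.
#' @param lines,temperatures,times Group labels; `times` must include the
#'   calibrator time 0.
#' @param planted_log2fold Data frame with columns `gene_id`, `line`,
#'   `temperature`, `time`, `log2fold` giving planted effects relative to
#'   the time-0 calibrator (cells not listed get 0).
#' @param n_replicates Replicates per cell (default 3, the usual qPCR
#'   triplicate).
#' @param noise_sd Replicate Cq noise, cycles (default 0.2).
#' @param baseline_cq Target-gene Cq at the calibrator (default 24).
#' @param reference_cq Reference-gene Cq (default 20).
#' @return A `cq_sim_config` list.
#' @export
cq_sim_config <- function(genes, lines = "L1", temperatures = 5,
                          times = c(0, 6, 24), planted_log2fold = NULL,
                          n_replicates = 3, noise_sd = 0.2,
                          baseline_cq = 24, reference_cq = 20) {
  stopifnot(n_replicates >= 1, noise_sd >= 0, 0 %in% times)
  if (is.null(planted_log2fold))
    planted_log2fold <- data.frame(gene_id = character(), line = character(),
                                   temperature = numeric(), time = numeric(),
                                   log2fold = numeric(), stringsAsFactors = FALSE)
  structure(list(genes = genes, lines = lines, temperatures = temperatures,
                 times = times, planted_log2fold = planted_log2fold,
                 n_replicates = n_replicates, noise_sd = noise_sd,
                 baseline_cq = baseline_cq, reference_cq = reference_cq),
            class = "cq_sim_config")
}

#' Simulate a qPCR Cq table with planted fold-changes
#'
#' Per replicate, Cq_target = baseline - log2fold + N(0, sd) and
#' Cq_reference = reference + N(0, sd); planted log2 folds are relative to
#' the time-0 calibrator, which is always 0.
#'
#' @param cfg A `cq_sim_config`.
#' @param seed Integer seed.
#' @return A `cq_table` ready for [relative_expression()].
#' @export
simulate_cq <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "cq_sim_config"))
  set.seed(seed)
  grid <- expand.grid(gene_id = cfg$genes, line = cfg$lines,
                      temperature = cfg$temperatures, time = cfg$times,
                      replicate = seq_len(cfg$n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[order(grid$gene_id, grid$line, grid$temperature,
                     grid$time, grid$replicate), ]
  p <- cfg$planted_log2fold
  lf <- rep(0, nrow(grid))
  if (nrow(p) > 0) {
    key <- function(d) paste(d$gene_id, d$line, d$temperature, d$time, sep = "\r")
    hit <- match(key(grid), key(p))
    lf[!is.na(hit)] <- p$log2fold[hit[!is.na(hit)]]
  }
  lf[grid$time == 0] <- 0
  grid$cq_target <- cfg$baseline_cq - lf + stats::rnorm(nrow(grid), 0, cfg$noise_sd)
  grid$cq_reference <- cfg$reference_cq + stats::rnorm(nrow(grid), 0, cfg$noise_sd)
  rownames(grid) <- NULL
  as_cq_table(grid, calibrator_time = 0)
}
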