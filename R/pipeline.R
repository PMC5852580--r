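# Pipeline entry points: each subcommand wires readers, analysis modules,
# and report writers together. The thin command-line wrapper in
# inst/scripts/famevol.R parses arguments and delegates here.

#' Default pipeline configuration
#'
#' Thresholds default to the standard gene-family conventions: duplicate
#' identity/coverage > 80%, tandem window 100 kb, cluster window 200 kb with
#' at least 3 genes, synonymous clock 1.5e-8 /site/year, 1000 bootstrap
#' replicates, ANOVA alpha 0.05.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(identity_threshold = 80, tandem_window = 100000,
              cluster_window = 200000, min_cluster_genes = 3,
              rate = 1.5e-8, n_bootstrap = 1000, alpha = 0.05, seed = 1)
  over <- list(...)
  stopifnot(all(nzchar(names(over))))
  cfg[names(over)] <- over
  num <- c("identity_threshold", "tandem_window", "cluster_window",
           "min_cluster_genes", "rate", "n_bootstrap", "alpha")
  stopifnot(all(unlist(cfg[num]) > 0))
  cfg
}

#' Run one pipeline subcommand
#'
#' Subcommands: `duplicates` (call and/or classify duplicate pairs and
#' detect clusters), `kaks` (molecular-evolution report), `tree` (NJ with
#' bootstrap and optional class assignment), `props` (protein properties),
#' `expr` (relative expression, ANOVA letters, heatmap matrix), `simulate`
#' (write synthetic family + Cq inputs). Input paths and options are given
#' in `cfg`, a named list as produced by [pipeline_config()] merged with a
#' YAML config file; reports are written under `out_dir` as TSV/Newick.
#'
#' Config keys by subcommand (paths):
#' \itemize{
#'   \item duplicates: `gene_table`, and `protein_fasta` (call pairs by
#'     alignment) and/or `pairs` (pre-specified TSV with id_a, id_b).
#'   \item kaks: `cds_fasta`, `pairs` (TSV; `dup_type` column carried through).
#'   \item tree: `alignment_fasta` (aligned proteins), optional `classes`
#'     (TSV: gene_id, class for reference leaves).
#'   \item props: `protein_fasta`.
#'   \item expr: `cq_csv`.
#'   \item simulate: `n_genes`, `n_chromosomes`, `codon_length`, optional
#'     `duplicate_plan` (inline list) and Cq settings.
#' }
#'
#' @param name Subcommand name.
#' @param cfg Named list of configuration values.
#' @param out_dir Output directory (created if absent).
#' @return Named list of written file paths, invisibly.
#' @export
run_subcommand <- function(name, cfg = pipeline_config(), out_dir = ".") {
  name <- match.arg(name, c("duplicates", "kaks", "tree", "props",
                            "expr", "simulate"))
  cfg <- utils::modifyList(pipeline_config(), cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  need <- function(key) {
    if (is.null(cfg[[key]]))
      stop("subcommand '", name, "' requires config key '", key, "'",
           call. = FALSE)
    cfg[[key]]
  }
  written <- list()
  out <- function(file) file.path(out_dir, file)

  if (name == "duplicates") {
    family <- read_gene_table(need("gene_table"))
    pairs <- NULL
    if (!is.null(cfg$protein_fasta)) {
      prot <- read_fasta(cfg$protein_fasta, kind = "protein")
      family <- attach_sequences(family, protein = prot)
      evid <- call_duplicates(family, threshold = cfg$identity_threshold)
      write_report(evid, written$evidence <- out("duplicate_evidence.tsv"))
      pairs <- evid[evid$called, c("id_a", "id_b")]
    }
    if (!is.null(cfg$pairs))
      pairs <- utils::read.table(cfg$pairs, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE)[c("id_a", "id_b")]
    if (is.null(pairs))
      stop("duplicates: need 'protein_fasta' or a 'pairs' file", call. = FALSE)
    cls <- classify_pairs(family, pairs, tandem_window = cfg$tandem_window)
    rep <- duplication_report(cls)
    write_report(rep$pairs, written$pairs <- out("duplicate_pairs.tsv"))
    clusters <- find_clusters(family, cluster_window = cfg$cluster_window,
                              min_genes = cfg$min_cluster_genes)
    write_report(clusters, written$clusters <- out("gene_clusters.tsv"))
    message("duplicate pairs: ", rep$counts[["tandem"]], " tandem, ",
            rep$counts[["segmental"]], " segmental; ",
            nrow(clusters), " cluster(s)")
  } else if (name == "kaks") {
    cds <- read_fasta(need("cds_fasta"), kind = "nucleotide")
    pairs <- utils::read.table(need("pairs"), sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
    repd <- kaks_report(pairs, cds, rate = cfg$rate)
    write_report(repd, written$kaks <- out("kaks_report.tsv"))
  } else if (name == "tree") {
    msa <- read_fasta(need("alignment_fasta"), kind = "protein")
    msa <- gsub("\\*$", "", msa)
    tree <- bootstrap_supports(msa, n_replicates = cfg$n_bootstrap,
                               seed = cfg$seed)
    write_newick(tree, written$tree <- out("nj_tree.nwk"))
    if (!is.null(cfg$classes)) {
      cls <- utils::read.table(cfg$classes, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
      ref <- stats::setNames(cls$class, cls$gene_id)
      assigned <- assign_classes(tree, ref)
      write_report(data.frame(gene_id = names(assigned), class = assigned),
                   written$classes <- out("class_assignments.tsv"))
    }
  } else if (name == "props") {
    prot <- read_fasta(need("protein_fasta"), kind = "protein")
    write_report(protein_properties(prot),
                 written$props <- out("protein_properties.tsv"))
  } else if (name == "expr") {
    cq <- read_cq_table(need("cq_csv"))
    rel <- relative_expression(cq)
    write_report(rel, written$folds <- out("relative_expression.tsv"))
    reps <- attr(rel, "replicates")
    an_rows <- lapply(split(reps, reps$gene_id), function(g) {
      grp <- paste(g$line, g$temperature, g$time, sep = "_")
      if (length(unique(grp)) < 2) return(NULL)
      a <- anova_tukey(g$fold, grp, alpha = cfg$alpha)
      data.frame(gene_id = g$gene_id[1], F = a$F, p = a$p,
                 groups = paste(names(a$letters), collapse = ","),
                 letters = paste(a$letters, collapse = ","),
                 stringsAsFactors = FALSE)
    })
    write_report(do.call(rbind, an_rows), written$anova <- out("anova_tukey.tsv"))
    m <- heatmap_matrix(rel, cluster = nrow(rel) > 2)
    write_report(data.frame(gene_id = rownames(m), m, check.names = FALSE),
                 written$matrix <- out("log2fold_matrix.tsv"))
  } else if (name == "simulate") {
    fam_cfg <- family_sim_config(
      n_genes = cfg$n_genes %||na% 8,
      n_chromosomes = cfg$n_chromosomes %||na% 4,
      codon_length = cfg$codon_length %||na% 300,
      duplicate_plan = if (!is.null(cfg$duplicate_plan))
        as.data.frame(do.call(rbind, lapply(cfg$duplicate_plan, as.data.frame)))
      else NULL)
    sim <- simulate_family(fam_cfg, seed = cfg$seed)
    write_report(sim$family[c("gene_id", "chromosome", "start", "end", "strand")],
                 written$gene_table <- out("family.tsv"))
    write_fasta(sim$cds, written$cds <- out("family_cds.fasta"))
    write_fasta(sim$protein, written$protein <- out("family_protein.fasta"))
    cqc <- cq_sim_config(genes = sim$family$gene_id)
    cq <- simulate_cq(cqc, seed = cfg$seed)
    utils::write.csv(cq, written$cq <- out("family_cq.csv"), row.names = FALSE)
  }
  invisible(written)
}

`%||na%` <- function(a, b) if (is.null(a)) b else a
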