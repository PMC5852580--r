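# Readers and writers for the pipeline's external formats: FASTA sequence
# files, delimited gene-coordinate tables, and qPCR Cq tables. Readers are
# total on valid inputs and raise structured errors (never partial tables)
# on invalid ones.

#' Read a FASTA file into a named character vector
#'
#' Sequence ids are the first whitespace-delimited token of each header and
#' must be unique; sequences are uppercased and validated against the
#' alphabet for `kind`.
#'
#' @param path Path to a FASTA file.
#' @param kind `"nucleotide"` (A/C/G/T) or `"protein"` (20 standard residues,
#'   optional terminal `*`).
#' @return Named character vector id -> sequence.
#' @export
read_fasta <- function(path, kind = c("nucleotide", "protein")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0)
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  pattern <- if (kind == "nucleotide") "[^ACGT]" else "[^ACDEFGHIKLMNPQRSTVWY*]"
  bad <- grepl(pattern, seqs)
  if (any(bad))
    stop("illegal ", kind, " characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  star <- grepl("\\*", sub("\\*$", "", seqs))
  if (any(star))
    stop("internal stop '*' in protein record(s): ", paste(ids[star], collapse = ", "))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector id -> sequence.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a gene-coordinate table
#'
#' Expects a delimited text file (comma or tab, sniffed from the header
#' line) with columns `gene_id`, `chromosome`, `start`, `end`, `strand`.
#' Coordinates are 1-based inclusive, as printed in genome-browser tables.
#' Conflicting rows (e.g. two genes printed with identical coordinates) are
#' loaded as-is; downstream operations rely only on the fields themselves.
#'
#' @param path Path to the table.
#' @return A `family_table`: data.frame with the five columns above plus
#'   optional `cds`/`protein` attached later via [attach_sequences()].
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", strip.white = TRUE)
  as_family_table(df)
}

#' Validate a data frame as a family table
#'
#' @param df Data frame with columns `gene_id`, `chromosome`, `start`,
#'   `end`, `strand` (and optionally `cds`, `protein`).
#' @return The validated `family_table`.
#' @export
as_family_table <- function(df) {
  need <- c("gene_id", "chromosome", "start", "end", "strand")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("gene table lacks column(s): ", paste(missing, collapse = ", "))
  df$start <- .as_coord(df$start, "start")
  df$end <- .as_coord(df$end, "end")
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup) > 0)
    stop("duplicate gene_id(s): ", paste(unique(dup), collapse = ", "))
  if (any(df$start < 1L))
    stop("coordinates are 1-based; start < 1 for: ",
         paste(df$gene_id[df$start < 1L], collapse = ", "))
  if (any(df$end < df$start))
    stop("end < start for: ", paste(df$gene_id[df$end < df$start], collapse = ", "))
  bad <- !df$strand %in% c("+", "-")
  if (any(bad))
    stop("unknown strand symbol for: ", paste(df$gene_id[bad], collapse = ", "))
  class(df) <- c("family_table", "data.frame")
  df
}

.as_coord <- function(x, what) {
  if (is.character(x)) x <- gsub("[ ,]", "", x)
  n <- suppressWarnings(as.numeric(x))
  if (any(is.na(n)) || any(n != floor(n)))
    stop("non-integer ", what, " coordinate(s)")
  as.integer(n)
}

#' Attach CDS and protein sequences to a family table
#'
#' Joins FASTA mappings onto the table by `gene_id` and enforces the gene
#' model invariants: CDS length divisible by 3, no internal stop codon, and
#' protein equal to the frame-1 translation (terminal stop trimmed).
#'
#' @param family A `family_table`.
#' @param cds Named nucleotide vector (optional).
#' @param protein Named amino-acid vector (optional). If omitted but `cds`
#'   is given, proteins are derived by translation.
#' @return The `family_table` with `cds`/`protein` columns.
#' @export
attach_sequences <- function(family, cds = NULL, protein = NULL) {
  stopifnot(inherits(family, "family_table"))
  if (!is.null(cds)) {
    missing <- setdiff(family$gene_id, names(cds))
    if (length(missing) > 0)
      stop("CDS FASTA missing id(s): ", paste(missing, collapse = ", "))
    family$cds <- unname(cds[family$gene_id])
    derived <- vapply(family$cds, translate_cds, character(1))
    if (is.null(protein)) {
      family$protein <- unname(derived)
    }
  }
  if (!is.null(protein)) {
    missing <- setdiff(family$gene_id, names(protein))
    if (length(missing) > 0)
      stop("protein FASTA missing id(s): ", paste(missing, collapse = ", "))
    family$protein <- sub("\\*$", "", unname(protein[family$gene_id]))
    if (!is.null(cds)) {
      derived <- vapply(family$cds, translate_cds, character(1))
      off <- which(family$protein != derived)
      if (length(off) > 0)
        stop("protein does not match CDS translation for: ",
             paste(family$gene_id[off], collapse = ", "))
    }
  }
  family
}

#' Read a qPCR Cq table
#'
#' CSV with columns `gene_id`, `line`, `temperature`, `time`, `replicate`,
#' `cq_target`, `cq_reference` (an optional `organ` column is carried
#' through). Cq values must be finite and positive. The calibrator group is
#' by convention the `time == calibrator_time` cell of each
#' (gene, line, temperature) stratum.
#'
#' @param path Path to the CSV.
#' @param calibrator_time Time point (h) used as calibrator; default 0.
#' @return A `cq_table` data.frame; the calibrator time is stored in
#'   `attr(, "calibrator_time")`.
#' @export
read_cq_table <- function(path, calibrator_time = 0) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_cq_table(df, calibrator_time = calibrator_time)
}

#' Validate a data frame as a Cq table
#' @rdname read_cq_table
#' @param df Data frame with the Cq table schema.
#' @export
as_cq_table <- function(df, calibrator_time = 0) {
  need <- c("gene_id", "line", "temperature", "time", "replicate",
            "cq_target", "cq_reference")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("Cq table lacks column(s): ", paste(missing, collapse = ", "),
         " (expected schema: ", paste(need, collapse = ", "), ")")
  for (col in c("cq_target", "cq_reference")) {
    v <- df[[col]]
    if (anyNA(v) || !is.numeric(v) || any(!is.finite(v)))
      stop("empty or non-finite values in ", col)
    if (any(v <= 0)) stop("Cq values must be > 0 in ", col)
  }
  strata <- unique(df[c("gene_id", "line", "temperature")])
  cal <- df[df$time == calibrator_time, c("gene_id", "line", "temperature")]
  key <- function(x) paste(x$gene_id, x$line, x$temperature, sep = "\r")
  lacking <- !key(strata) %in% key(cal)
  if (any(lacking))
    stop("no calibrator (time == ", calibrator_time, ") cell for: ",
         paste(strata$gene_id[lacking], strata$line[lacking],
               strata$temperature[lacking], sep = "/", collapse = ", "))
  structure(df, class = c("cq_table", "data.frame"),
            calibrator_time = calibrator_time)
}

#' Write a report table as TSV with a header row
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Bundled gene-coordinate and duplicate-pair tables for the pumpkin GST family
#'
#' Accessors for the transcribed printed data shipped with the package: the
#' 32-gene coordinate table (id, chromosome, start, end, strand) and the 16
#' published duplicate pairs with their published Ks, Ka, Ka/Ks and
#' duplication type. Sequences are not published and are not included.
#'
#' @return `cmagst_gene_table()`: a `family_table` of 32 genes.
#'   `cmagst_duplicate_pairs()`: data.frame of 16 pairs with published
#'   values (`Ks`, `Ka`, `ratio`, `dup_type`).
#' @export
cmagst_gene_table <- function() {
  read_gene_table(system.file("extdata", "cmagst_gene_table.tsv",
                              package = "famevol", mustWork = TRUE))
}

#' @rdname cmagst_gene_table
#' @export
cmagst_duplicate_pairs <- function() {
  path <- system.file("extdata", "cmagst_duplicate_pairs.tsv",
                      package = "famevol", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
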