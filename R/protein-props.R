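# Physicochemical properties of protein sequences: residue count, average
# molecular weight, and isoelectric point by bisection of the
# Henderson-Hasselbalch net charge with the Bjellqvist pKa set (the table
# used by the ExPASy Compute pI/Mw tool, including residue-specific
# N- and C-terminal values).

# Average (isotopically averaged) residue masses, Da.
.AA_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
.WATER_MASS <- 18.01524

# Bjellqvist pKa values: side chains, plus residue-specific termini
# (defaults 7.50 N-terminal, 3.55 C-terminal).
.PKA_SIDE <- c(C = 9.00, D = 4.05, E = 4.45, H = 5.98, K = 10.00,
               R = 12.00, Y = 10.00)
.PKA_NTERM <- c(A = 7.59, E = 7.70, M = 7.00, P = 8.36, S = 6.93,
                T = 6.82, V = 7.44)
.PKA_CTERM <- c(D = 4.55, E = 4.75)

.check_protein <- function(protein) {
  if (!is.character(protein) || length(protein) != 1 || !nzchar(protein))
    stop("protein must be a non-empty string")
  protein <- toupper(sub("\\*$", "", protein))
  res <- strsplit(protein, "")[[1]]
  bad <- setdiff(res, names(.AA_MASS))
  if (length(bad) > 0)
    stop("unknown residue(s): ", paste(unique(bad), collapse = ", "))
  res
}

#' Residue count of a protein
#'
#' @param protein Amino-acid string (terminal `*` tolerated and ignored).
#' @return Number of residues.
#' @export
residue_count <- function(protein) {
  length(.check_protein(protein))
}

#' Average molecular weight of a protein, in kDa
#'
#' Sum of average isotopic residue masses plus one water, divided by 1000.
#'
#' @inheritParams residue_count
#' @return Molecular weight in kilodaltons.
#' @export
#' @examples
#' molecular_weight("GG")  # 0.13212 kDa
molecular_weight <- function(protein) {
  res <- .check_protein(protein)
  (sum(.AA_MASS[res]) + .WATER_MASS) / 1000
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch over the termini and the ionizable side chains
#' (D, E, C, Y, K, R, H) with the Bjellqvist pKa set. Monotone decreasing
#' in pH.
#'
#' @inheritParams residue_count
#' @param ph pH value(s).
#' @return Net charge (elementary charges).
#' @export
protein_charge <- function(protein, ph) {
  res <- .check_protein(protein)
  nt <- res[1]
  pos_pka <- c(if (nt %in% names(.PKA_NTERM)) .PKA_NTERM[[nt]] else 7.50,
               unname(.PKA_SIDE[res[res %in% c("K", "R", "H")]]))
  ct <- res[length(res)]
  neg_pka <- c(if (ct %in% names(.PKA_CTERM)) .PKA_CTERM[[ct]] else 3.55,
               unname(.PKA_SIDE[res[res %in% c("D", "E", "C", "Y")]]))
  vapply(ph, function(p) {
    sum(1 / (1 + 10^(p - pos_pka))) - sum(1 / (1 + 10^(neg_pka - p)))
  }, numeric(1))
}

#' Isoelectric point of a protein
#'
#' pH at which the net charge crosses zero, found by bisection on \[0, 14\]
#' to a tolerance of 1e-3 pH units. The charge is positive at pH 0 and
#' negative at pH 14 for any sequence, so the bracket is always valid.
#'
#' @inheritParams residue_count
#' @param tol Bisection tolerance in pH units.
#' @return Isoelectric point (pH units).
#' @export
isoelectric_point <- function(protein, tol = 1e-3) {
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (protein_charge(protein, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Physicochemical properties report for a protein family
#'
#' @param proteins Named character vector id -> protein, or a
#'   `family_table` with a `protein` column.
#' @return Data frame: `gene_id`, `length` (aa), `mw` (kDa), `pi`.
#' @export
protein_properties <- function(proteins) {
  if (inherits(proteins, "family_table")) {
    if (is.null(proteins$protein)) stop("family table has no protein column")
    proteins <- stats::setNames(proteins$protein, proteins$gene_id)
  }
  data.frame(gene_id = names(proteins),
             length = vapply(proteins, residue_count, integer(1)),
             mw = vapply(proteins, molecular_weight, numeric(1)),
             pi = vapply(proteins, isoelectric_point, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
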