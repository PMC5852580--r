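#' @keywords internal
"_PACKAGE"

# Standard nuclear genetic code, shared by the Ka/Ks machinery and the
# sequence simulators. The table itself comes from Biostrings; everything
# derived from it (site counts, pathway-averaged difference counts) is
# computed here.

.codon_env <- new.env(parent = emptyenv())

.genetic_code <- function() {
  if (is.null(.codon_env$code)) {
    code <- Biostrings::GENETIC_CODE
    .codon_env$code <- code
    .codon_env$sense <- names(code)[code != "*"]
  }
  .codon_env$code
}

#' Sense codons of the standard genetic code
#'
#' @return Character vector of the 61 non-stop codons.
#' @keywords internal
sense_codons <- function() {
  .genetic_code()
  .codon_env$sense
}

#' Translate a coding sequence
#'
#' Translates in frame 1 with the standard genetic code. A terminal stop
#' codon is trimmed; an internal stop is an error (pseudogenes and
#' frame-shifted models are not valid family members here).
#'
#' @param cds Nucleotide string over A/C/G/T, length divisible by 3.
#' @return Amino-acid string.
#' @export
#' @examples
#' translate_cds("ATGAAATAA")  # "MK"
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  if (nchar(cds) == 0L || nchar(cds) %% 3L != 0L)
    stop("CDS length must be a positive multiple of 3, got ", nchar(cds))
  if (grepl("[^ACGT]", cds))
    stop("CDS contains non-ACGT characters")
  codons <- split_codons(cds)
  aa <- unname(.genetic_code()[codons])
  n <- length(aa)
  if (aa[n] == "*") aa <- aa[-n]
  if (any(aa == "*"))
    stop("internal stop codon at codon position ", which(aa == "*")[1])
  paste(aa, collapse = "")
}

#' @keywords internal
split_codons <- function(cds) {
  substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
}

.is_stop <- function(codon) unname(.genetic_code()[codon] == "*")
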