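# Nei-Gojobori (1986) codon-level evolutionary analysis: synonymous and
# nonsynonymous site/difference counting with pathway averaging, proportion
# correction by the Jukes-Cantor formula, selection-mode classification, and
# divergence-time dating under a fixed synonymous clock.

BASES <- c("A", "C", "G", "T")

#' Synonymous and nonsynonymous site counts for one codon
#'
#' For each of the nine single-nucleotide neighbors of the codon, the
#' fraction of changes that are synonymous accumulates into the synonymous
#' site count. Changes that would create a stop codon are excluded and the
#' position's fraction is renormalized over the remaining alternatives, so
#' the two counts always sum to 3.
#'
#' @param codon A sense codon (3-mer over A/C/G/T).
#' @return Named numeric vector `c(syn = S, nonsyn = N)` with `S + N == 3`.
#' @export
#' @examples
#' count_sites("TTT")  # syn = 1/3, nonsyn = 8/3
#' count_sites("ATG")  # methionine has no synonymous neighbor
count_sites <- function(codon) {
  m <- .site_table()
  codon <- toupper(codon)
  if (!codon %in% rownames(m))
    stop("not a sense codon: ", codon)
  m[codon, ]
}

.site_table <- function() {
  if (!is.null(.codon_env$sites)) return(.codon_env$sites)
  code <- .genetic_code()
  sc <- sense_codons()
  m <- matrix(0, nrow = length(sc), ncol = 2,
              dimnames = list(sc, c("syn", "nonsyn")))
  for (codon in sc) {
    aa <- code[[codon]]
    s <- 0
    for (pos in 1:3) {
      alts <- vapply(setdiff(BASES, substr(codon, pos, pos)), function(b) {
        x <- codon
        substr(x, pos, pos) <- b
        x
      }, character(1))
      legal <- alts[code[alts] != "*"]
      if (length(legal) > 0)
        s <- s + sum(code[legal] == aa) / length(legal)
    }
    m[codon, ] <- c(s, 3 - s)
  }
  .codon_env$sites <- m
  m
}

#' Pathway-averaged synonymous/nonsynonymous differences between two codons
#'
#' For k mismatched positions, all k! single-step mutational pathways from
#' `codon_a` to `codon_b` are enumerated; pathways passing through a stop
#' codon are excluded and the synonymous/nonsynonymous step counts are
#' averaged over the legal remainder. If every pathway passes through a stop,
#' all k steps are counted as nonsynonymous and a warning is raised.
#'
#' @param codon_a,codon_b Sense codons.
#' @return Named numeric vector `c(syn = Sd, nonsyn = Nd)`; `Sd + Nd` equals
#'   the number of mismatched positions when a legal pathway exists.
#' @export
#' @examples
#' count_differences("TTT", "TTC")  # one synonymous step (both Phe)
#' count_differences("TTT", "GTA")  # (0.5, 1.5), averaged over two pathways
count_differences <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  sc <- sense_codons()
  if (!codon_a %in% sc) stop("not a sense codon: ", codon_a)
  if (!codon_b %in% sc) stop("not a sense codon: ", codon_b)
  tabs <- .diff_tables()
  out <- c(syn = tabs$syn[codon_a, codon_b], nonsyn = tabs$nonsyn[codon_a, codon_b])
  if (tabs$blocked[codon_a, codon_b])
    warning("all mutational pathways between ", codon_a, " and ", codon_b,
            " pass through stop codons; counting all steps as nonsynonymous")
  out
}

# Memoized 61x61 lookup of pathway-averaged difference counts.
.diff_tables <- function() {
  if (!is.null(.codon_env$diffs)) return(.codon_env$diffs)
  code <- .genetic_code()
  sc <- sense_codons()
  n <- length(sc)
  syn <- matrix(0, n, n, dimnames = list(sc, sc))
  nonsyn <- syn
  blocked <- matrix(FALSE, n, n, dimnames = list(sc, sc))
  perms <- list(`1` = matrix(1L), `2` = rbind(c(1L, 2L), c(2L, 1L)),
                `3` = rbind(c(1L,2L,3L), c(1L,3L,2L), c(2L,1L,3L),
                            c(2L,3L,1L), c(3L,1L,2L), c(3L,2L,1L)))
  for (i in seq_len(n)) {
    a <- sc[i]
    for (j in seq_len(n)) {
      if (i == j) next
      b <- sc[j]
      pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
      k <- length(pos)
      pm <- perms[[as.character(k)]]
      sd_tot <- 0; nd_tot <- 0; legal <- 0L
      for (r in seq_len(nrow(pm))) {
        cur <- a; sd <- 0; nd <- 0; ok <- TRUE
        for (p in pos[pm[r, ]]) {
          nxt <- cur
          substr(nxt, p, p) <- substr(b, p, p)
          if (code[[nxt]] == "*") { ok <- FALSE; break }
          if (code[[nxt]] == code[[cur]]) sd <- sd + 1 else nd <- nd + 1
          cur <- nxt
        }
        if (ok) { sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd; legal <- legal + 1L }
      }
      if (legal > 0L) {
        syn[i, j] <- sd_tot / legal
        nonsyn[i, j] <- nd_tot / legal
      } else {
        syn[i, j] <- 0
        nonsyn[i, j] <- k
        blocked[i, j] <- TRUE
      }
    }
  }
  .codon_env$diffs <- list(syn = syn, nonsyn = nonsyn, blocked = blocked)
  .codon_env$diffs
}

#' Build a codon alignment by back-translating a protein alignment
#'
#' Maps every aligned amino-acid column back onto its source codon. A gap in
#' the protein alignment becomes a whole-codon gap (`"---"`). Columns gapped
#' in either sequence are excluded from downstream counting (complete
#' deletion at codon level).
#'
#' @param aln_a,aln_b Aligned amino-acid strings (equal length, `-` gaps).
#' @param cds_a,cds_b Ungapped coding sequences whose frame-1 translations
#'   equal the ungapped proteins (terminal stop codons tolerated).
#' @param ids Optional length-2 character vector of sequence ids.
#' @return An object of class `codon_alignment`: list with `ids`,
#'   `codons_a`, `codons_b` (per aligned column; `"---"` for gaps).
#' @export
back_translate <- function(aln_a, aln_b, cds_a, cds_b, ids = c("seq_a", "seq_b")) {
  if (nchar(aln_a) != nchar(aln_b))
    stop("aligned proteins must have equal length")
  map_one <- function(aln, cds, id) {
    cds <- toupper(cds)
    codons <- split_codons(cds)
    if (.is_stop(codons[length(codons)])) codons <- codons[-length(codons)]
    aa <- strsplit(aln, "")[[1]]
    res <- aa[aa != "-"]
    if (length(res) != length(codons))
      stop("protein/CDS length mismatch for ", id, ": ", length(res),
           " residues vs ", length(codons), " codons")
    trans <- unname(.genetic_code()[codons])
    bad <- which(trans != res)
    if (length(bad) > 0)
      stop("protein does not match CDS translation for ", id,
           " at residue ", bad[1], " (", res[bad[1]], " vs ", trans[bad[1]], ")")
    out <- character(length(aa))
    out[aa == "-"] <- "---"
    out[aa != "-"] <- codons
    out
  }
  structure(list(ids = ids,
                 codons_a = map_one(aln_a, cds_a, ids[1]),
                 codons_b = map_one(aln_b, cds_b, ids[2])),
            class = "codon_alignment")
}

#' Nei-Gojobori Ka/Ks with Jukes-Cantor correction
#'
#' Counts synonymous/nonsynonymous sites (averaged between the two
#' sequences) and pathway-averaged differences over all comparable codon
#' columns, forms the proportions pS and pN, and corrects each with
#' d = -(3/4) ln(1 - (4/3) p). The Ka/Ks ratio is undefined when Ks = 0, and
#' the correction is undefined (flagged `NA`) when a proportion reaches 3/4.
#'
#' @param aln A `codon_alignment` from [back_translate()], or a list with
#'   `codons_a`/`codons_b` character vectors of codons (`"---"` gaps allowed).
#' @param rate Synonymous substitution rate per site per year used for
#'   dating; default 1.5e-8 (dicotyledonous plants).
#' @return An object of class `kaks_result`: list with `S`, `N`, `Sd`, `Nd`,
#'   `pS`, `pN`, `Ks`, `Ka`, `ratio`, `selection`, `divergence_mya`,
#'   `n_codons`.
#' @export
compute_kaks <- function(aln, rate = 1.5e-8) {
  ca <- aln$codons_a
  cb <- aln$codons_b
  keep <- ca != "---" & cb != "---"
  ca <- ca[keep]; cb <- cb[keep]
  if (length(ca) == 0L) stop("no comparable codon columns")
  sites <- .site_table()
  bad <- setdiff(unique(c(ca, cb)), rownames(sites))
  if (length(bad) > 0) stop("non-sense codon in alignment: ", bad[1])
  S <- (sum(sites[ca, "syn"]) + sum(sites[cb, "syn"])) / 2
  N <- (sum(sites[ca, "nonsyn"]) + sum(sites[cb, "nonsyn"])) / 2
  tabs <- .diff_tables()
  idx <- cbind(match(ca, rownames(tabs$syn)), match(cb, colnames(tabs$syn)))
  Sd <- sum(tabs$syn[idx])
  Nd <- sum(tabs$nonsyn[idx])
  if (any(tabs$blocked[idx]))
    warning(sum(tabs$blocked[idx]), " codon column(s) had no stop-free ",
            "mutational pathway; their steps were counted as nonsynonymous")
  pS <- Sd / S
  pN <- Nd / N
  Ks <- jukes_cantor(pS)
  Ka <- jukes_cantor(pN)
  ratio <- if (is.na(Ks) || Ks == 0) NA_real_ else Ka / Ks
  res <- list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
              Ks = Ks, Ka = Ka, ratio = ratio,
              selection = classify_selection(ratio),
              divergence_mya = if (is.na(Ks)) NA_real_ else divergence_time(Ks, rate),
              n_codons = length(ca))
  class(res) <- "kaks_result"
  res
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("Nei-Gojobori Ka/Ks over %d codons\n", x$n_codons))
  cat(sprintf("  sites       S = %.2f, N = %.2f\n", x$S, x$N))
  cat(sprintf("  differences Sd = %.2f, Nd = %.2f (pS = %.4f, pN = %.4f)\n",
              x$Sd, x$Nd, x$pS, x$pN))
  cat(sprintf("  Ks = %.4f, Ka = %.4f, Ka/Ks = %s [%s]\n",
              x$Ks, x$Ka,
              if (is.na(x$ratio)) "undefined" else sprintf("%.4f", x$ratio),
              x$selection))
  cat(sprintf("  divergence time = %.2f Mya\n", x$divergence_mya))
  invisible(x)
}

#' Jukes-Cantor correction of an observed difference proportion
#'
#' d = -(3/4) ln(1 - (4/3) p). Undefined (returns `NA` with a warning) at
#' p >= 3/4 where the formula saturates.
#'
#' @param p Observed proportion of differences per site, in \[0, 3/4).
#' @return Estimated substitutions per site.
#' @export
jukes_cantor <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0 | is.na(p)))
  out <- ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3)) + 0
  if (any(!is.na(p) & p >= 0.75))
    warning("proportion >= 3/4: Jukes-Cantor correction undefined")
  out
}

#' Classify selection mode from a Ka/Ks ratio
#'
#' Ratios above 1 indicate positive selection, below 1 purifying selection,
#' and exactly 1 (within 1e-9) neutral evolution; an undefined ratio (Ks = 0)
#' stays `"undefined"`.
#'
#' @param ratio Ka/Ks value(s), `NA` for undefined.
#' @return Character vector over `{"positive","purifying","neutral","undefined"}`.
#' @export
#' @examples
#' classify_selection(c(0.593, 1.483, 1, NA))
classify_selection <- function(ratio) {
  vapply(ratio, function(r) {
    if (is.na(r)) return("undefined")
    if (abs(r - 1) <= 1e-9) return("neutral")
    if (r > 1) "positive" else "purifying"
  }, character(1))
}

#' Divergence time from synonymous divergence
#'
#' T = Ks / (2 r), reported in million years (Mya). The default rate is the
#' fixed dicot synonymous clock of 1.5e-8 substitutions per site per year.
#'
#' @param ks Synonymous substitutions per site (>= 0).
#' @param rate Synonymous substitution rate per site per year.
#' @return Divergence time in Mya.
#' @export
#' @examples
#' divergence_time(0.566)  # 18.87 Mya
divergence_time <- function(ks, rate = 1.5e-8) {
  stopifnot(is.numeric(ks), all(ks >= 0 | is.na(ks)), rate > 0)
  ks / (2 * rate) / 1e6
}

#' Ka/Ks for a pair of coding sequences
#'
#' Convenience wrapper: globally aligns the two translated proteins
#' (Needleman-Wunsch, BLOSUM62), back-translates onto the CDSs, and runs
#' [compute_kaks()].
#'
#' @param cds_a,cds_b Coding sequences (terminal stop tolerated).
#' @param ids Length-2 ids for reporting.
#' @inheritParams compute_kaks
#' @return A `kaks_result`.
#' @export
kaks_pair <- function(cds_a, cds_b, ids = c("seq_a", "seq_b"), rate = 1.5e-8) {
  prot_a <- translate_cds(cds_a)
  prot_b <- translate_cds(cds_b)
  pa <- Biostrings::pairwiseAlignment(prot_a, prot_b, type = "global",
                                      substitutionMatrix = .blosum62(),
                                      gapOpening = 11, gapExtension = 1)
  aln <- back_translate(as.character(Biostrings::alignedPattern(pa)),
                        as.character(Biostrings::alignedSubject(pa)),
                        cds_a, cds_b, ids = ids)
  compute_kaks(aln, rate = rate)
}

#' Table-2-style molecular evolution report for duplicate pairs
#'
#' @param pairs Data frame with columns `id_a`, `id_b` and optionally
#'   `dup_type`.
#' @param cds Named character vector of coding sequences covering all ids.
#' @inheritParams compute_kaks
#' @return Data frame: id_a, id_b, Ks, Ka, ratio, dup_type (if given),
#'   selection, divergence_mya.
#' @export
kaks_report <- function(pairs, cds, rate = 1.5e-8) {
  stopifnot(all(c("id_a", "id_b") %in% names(pairs)))
  missing <- setdiff(unique(c(pairs$id_a, pairs$id_b)), names(cds))
  if (length(missing) > 0)
    stop("no CDS for: ", paste(missing, collapse = ", "))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    r <- kaks_pair(cds[[pairs$id_a[i]]], cds[[pairs$id_b[i]]],
                   ids = c(pairs$id_a[i], pairs$id_b[i]), rate = rate)
    data.frame(id_a = pairs$id_a[i], id_b = pairs$id_b[i],
               Ks = r$Ks, Ka = r$Ka, ratio = r$ratio,
               selection = r$selection, divergence_mya = r$divergence_mya,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if ("dup_type" %in% names(pairs))
    out <- cbind(out[1:5], dup_type = pairs$dup_type, out[6:7])
  out
}
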