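# qPCR relative-expression analysis: 2^-ddCt fold-changes against a
# reference gene (carried per record as cq_reference) and a calibrator time
# point, one-way ANOVA with Tukey comparisons summarized as a compact
# letter display, and heatmap-ready log2 matrices.

#' 2^-ddCt fold-change from four Cq values
#'
#' ddCt = (Cq_target,treated - Cq_reference,treated) -
#' (Cq_target,calibrator - Cq_reference,calibrator); fold = 2^-ddCt.
#' Vectorized over its arguments.
#'
#' @param cq_target_t,cq_ref_t Treated-sample Cq of target and reference.
#' @param cq_target_c,cq_ref_c Calibrator-sample Cq of target and reference.
#' @return Fold-change (dimensionless, > 0).
#' @export
#' @examples
#' ddct_fold(25, 20, 24, 20)  # 0.5
ddct_fold <- function(cq_target_t, cq_ref_t, cq_target_c, cq_ref_c) {
  stopifnot(all(is.finite(c(cq_target_t, cq_ref_t, cq_target_c, cq_ref_c))))
  ddct <- (cq_target_t - cq_ref_t) - (cq_target_c - cq_ref_c)
  2^(-ddct)
}

#' Relative expression (2^-ddCt) for a Cq table
#'
#' Within each (gene, line, temperature, time) cell, replicate Cq values are
#' averaged before forming dCt = mean Cq_target - mean Cq_reference (Livak
#' convention); ddCt is taken against the calibrator cell (time ==
#' `attr(cq, "calibrator_time")`) of the same (gene, line, temperature)
#' stratum. Replicate-level folds (replicate dCt against the calibrator
#' mean dCt) are attached in `attr(, "replicates")` for downstream ANOVA.
#'
#' @param cq A `cq_table` from [read_cq_table()] / [as_cq_table()].
#' @return Data frame: `gene_id`, `line`, `temperature`, `time`, `n`,
#'   `fold`, `log2_fold`, `dct_sd` (replicate dCt dispersion). Calibrator
#'   rows have fold 1 by construction.
#' @export
relative_expression <- function(cq) {
  stopifnot(inherits(cq, "cq_table"))
  cal_time <- attr(cq, "calibrator_time")
  cq$dct <- cq$cq_target - cq$cq_reference
  cells <- stats::aggregate(
    cbind(cq_target, cq_reference) ~ gene_id + line + temperature + time,
    data = cq, FUN = mean)
  disp <- stats::aggregate(dct ~ gene_id + line + temperature + time,
                           data = cq,
                           FUN = function(x) if (length(x) > 1) stats::sd(x) else 0)
  nrep <- stats::aggregate(dct ~ gene_id + line + temperature + time,
                           data = cq, FUN = length)
  cells$dct <- cells$cq_target - cells$cq_reference
  key <- function(d) paste(d$gene_id, d$line, d$temperature, sep = "\r")
  cal <- cells[cells$time == cal_time, ]
  cal_dct <- stats::setNames(cal$dct, key(cal))
  cells$ddct <- cells$dct - cal_dct[key(cells)]
  cells$fold <- 2^(-cells$ddct)
  cells$log2_fold <- -cells$ddct
  cells$n <- nrep$dct[match(paste(key(cells), cells$time),
                            paste(key(nrep), nrep$time))]
  cells$dct_sd <- disp$dct[match(paste(key(cells), cells$time),
                                 paste(key(disp), disp$time))]
  reps <- cq
  reps$ddct <- reps$dct - cal_dct[key(reps)]
  reps$fold <- 2^(-reps$ddct)
  out <- cells[order(cells$gene_id, cells$line, cells$temperature, cells$time),
               c("gene_id", "line", "temperature", "time", "n",
                 "fold", "log2_fold", "dct_sd")]
  rownames(out) <- NULL
  attr(out, "replicates") <-
    reps[c("gene_id", "line", "temperature", "time", "replicate", "fold")]
  out
}

#' One-way ANOVA with Tukey comparisons and compact letter display
#'
#' Fits `value ~ group`, reports the F statistic and p-value, and summarizes
#' Tukey's pairwise comparisons at level `alpha` as letters (groups sharing
#' a letter are not significantly different). With zero within-group
#' variance the F statistic is undefined and flagged.
#'
#' @param values Numeric response (e.g. replicate fold-changes).
#' @param groups Grouping factor (>= 2 levels, >= 2 replicates each).
#' @param alpha Significance level for the letter display.
#' @return List with `means` (named group means), `df` (numerator,
#'   denominator), `F`, `p`, `letters` (named character vector), and
#'   `undefined` flag.
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("need at least 2 replicates per group")
  dat <- data.frame(value = values, group = groups)
  fit <- stats::aov(value ~ group, data = dat)
  # a perfect fit is detected and flagged below; silence stats's own warning
  an <- suppressWarnings(stats::anova(fit))
  means <- tapply(dat$value, dat$group, mean)
  if (an["Residuals", "Sum Sq"] <= .Machine$double.eps * sum(values^2)) {
    return(list(means = means, df = an$Df, F = NA_real_, p = NA_real_,
                letters = NULL, undefined = TRUE))
  }
  glht <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Tukey"))
  letters <- multcomp::cld(glht, level = alpha)$mcletters$Letters
  list(means = means, df = an$Df,
       F = an["group", "F value"], p = an["group", "Pr(>F)"],
       letters = letters, undefined = FALSE)
}

#' Gene-by-condition log2 fold-change matrix for heatmaps
#'
#' Builds the genes x (line/temperature/time) matrix of log2 fold-changes;
#' missing cells are imputed as 0 (no change) and flagged. With
#' `cluster = TRUE` rows are reordered by average-linkage hierarchical
#' clustering on correlation distance (1 - Pearson r; rows with zero
#' variance get distance 1 to everything).
#'
#' @param rel Output of [relative_expression()].
#' @param cluster Reorder rows by clustering?
#' @return Numeric matrix (rownames = gene ids, colnames =
#'   `line_temperature_time`); `attr(, "imputed")` marks filled cells,
#'   `attr(, "hclust")` carries the dendrogram when clustered.
#' @export
heatmap_matrix <- function(rel, cluster = FALSE) {
  if (nrow(rel) == 0) stop("empty expression grid")
  cond <- paste(rel$line, rel$temperature, rel$time, sep = "_")
  genes <- unique(rel$gene_id)
  conds <- unique(cond)
  m <- matrix(NA_real_, length(genes), length(conds),
              dimnames = list(genes, conds))
  m[cbind(match(rel$gene_id, genes), match(cond, conds))] <- rel$log2_fold
  imputed <- is.na(m)
  m[imputed] <- 0
  hc <- NULL
  if (cluster && nrow(m) > 2) {
    cc <- suppressWarnings(stats::cor(t(m)))
    cc[!is.finite(cc)] <- 0
    d <- stats::as.dist(1 - cc)
    hc <- stats::hclust(d, method = "average")
    m <- m[hc$order, , drop = FALSE]
    imputed <- imputed[hc$order, , drop = FALSE]
  }
  attr(m, "imputed") <- imputed
  attr(m, "hclust") <- hc
  m
}
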