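#' Differential immune-cell infiltration between risk groups
#'
#' Two-sided Mann-Whitney test per cell type between the two risk groups,
#' with Benjamini-Hochberg correction across cell types and the direction of
#' the shift (sign of the high-group minus low-group median difference).
#' Constant columns get p = 1 and are flagged.
#'
#' @param infiltration numeric matrix, samples in rows, cell types in
#'   columns.
#' @param groups factor with levels \code{c("low", "high")} (or any two
#'   levels), one per sample.
#' @return data.frame: cell_type, p, fdr, direction
#'   (\code{"higher_in_<level2>"} etc.), note.
#' @export
infiltration_diff <- function(infiltration, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2L) stop("need exactly 2 non-empty groups")
  lev <- levels(droplevels(groups))
  ia <- groups == lev[1]; ib <- groups == lev[2]
  rows <- lapply(colnames(infiltration), function(ct) {
    v <- infiltration[, ct]
    if (stats::sd(v) == 0)
      return(data.frame(cell_type = ct, p = 1, direction = "none",
                        note = "constant scores"))
    p <- suppressWarnings(stats::wilcox.test(v[ia], v[ib])$p.value)
    d <- stats::median(v[ib]) - stats::median(v[ia])
    data.frame(cell_type = ct, p = p,
               direction = if (d > 0) paste0("higher_in_", lev[2])
                           else if (d < 0) paste0("higher_in_", lev[1])
                           else "none",
               note = "")
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, "BH")
  out[, c("cell_type", "p", "fdr", "direction", "note")]
}

#' Correlation of risk scores with immune infiltration
#'
#' Spearman rank correlation (two-sided p) between the risk score and each
#' infiltration column. Constant vectors give an undefined rho and are
#' flagged.
#'
#' @param scores named numeric risk scores.
#' @param infiltration numeric matrix, samples in rows (names aligned with
#'   \code{scores}).
#' @return data.frame: cell_type, rho, p, note.
#' @export
infiltration_correlation <- function(scores, infiltration) {
  if (!is.null(rownames(infiltration)) && !is.null(names(scores)))
    infiltration <- infiltration[names(scores), , drop = FALSE]
  if (length(scores) < 4L) stop("need at least 4 paired observations")
  rows <- lapply(colnames(infiltration), function(ct) {
    v <- infiltration[, ct]
    if (stats::sd(v) == 0 || stats::sd(scores) == 0)
      return(data.frame(cell_type = ct, rho = NA_real_, p = NA_real_,
                        note = "constant vector"))
    ct_res <- suppressWarnings(
      stats::cor.test(scores, v, method = "spearman", exact = FALSE))
    data.frame(cell_type = ct, rho = unname(ct_res$estimate),
               p = ct_res$p.value, note = "")
  })
  do.call(rbind, rows)
}

#' Risk-group differential expression and correlations for a gene panel
#'
#' For each panel gene (e.g. immune-checkpoint or RNA-binding-protein
#' genes): a two-sided rank-sum test between risk groups, Pearson and
#' Spearman correlations against the risk score, and pairwise Pearson and
#' Spearman correlations among the panel genes. An optional covariate can
#' be regressed out of the rank correlations (rank-residual partial
#' Spearman).
#'
#' @param expr an \code{expr_matrix} containing the panel genes.
#' @param groups two-level risk-group factor over samples.
#' @param panel character vector of gene ids; absent genes are skipped and
#'   reported.
#' @param scores named risk-score vector.
#' @param covariate optional numeric vector to partial out of the Spearman
#'   correlations.
#' @return List: \code{diff} (gene, p, fdr, direction), \code{vs_score}
#'   (gene, pearson_r, pearson_p, spearman_rho, spearman_p),
#'   \code{pairwise} (gene_a, gene_b, pearson_r, spearman_rho),
#'   \code{skipped} (absent genes).
#' @export
gene_correlates <- function(expr, groups, panel, scores, covariate = NULL) {
  expr <- as_expr_matrix(expr, gene_biotype(expr))
  groups <- as.factor(groups)
  lev <- levels(droplevels(groups))
  present <- intersect(panel, rownames(expr))
  skipped <- setdiff(panel, present)
  if (!length(present)) stop("no panel gene present in the matrix")
  x <- unclass(expr)[present, , drop = FALSE]
  if (!is.null(names(scores))) scores <- scores[colnames(x)]

  spearman_partial <- function(a, b) {
    if (is.null(covariate)) return(stats::cor(a, b, method = "spearman"))
    ra <- stats::resid(stats::lm(rank(a) ~ rank(covariate)))
    rb <- stats::resid(stats::lm(rank(b) ~ rank(covariate)))
    stats::cor(ra, rb)
  }

  diff_rows <- lapply(present, function(g) {
    v <- x[g, ]
    p <- if (stats::sd(v) == 0) 1
         else suppressWarnings(stats::wilcox.test(v[groups == lev[1]],
                                                  v[groups == lev[2]])$p.value)
    d <- stats::median(v[groups == lev[2]]) - stats::median(v[groups == lev[1]])
    data.frame(gene = g, p = p,
               direction = if (d > 0) paste0("higher_in_", lev[2])
                           else if (d < 0) paste0("higher_in_", lev[1])
                           else "none")
  })
  diff <- do.call(rbind, diff_rows)
  diff$fdr <- stats::p.adjust(diff$p, "BH")

  vs_score <- do.call(rbind, lapply(present, function(g) {
    v <- x[g, ]
    pe <- suppressWarnings(stats::cor.test(v, scores))
    sp <- suppressWarnings(stats::cor.test(v, scores, method = "spearman",
                                           exact = FALSE))
    data.frame(gene = g, pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
               spearman_rho = if (is.null(covariate)) unname(sp$estimate)
                              else spearman_partial(v, scores),
               spearman_p = sp$p.value)
  }))

  pw <- list()
  if (length(present) > 1L) {
    cmb <- utils::combn(present, 2L)
    pw <- lapply(seq_len(ncol(cmb)), function(k) {
      a <- x[cmb[1, k], ]; b <- x[cmb[2, k], ]
      data.frame(gene_a = cmb[1, k], gene_b = cmb[2, k],
                 pearson_r = stats::cor(a, b),
                 spearman_rho = spearman_partial(a, b))
    })
  }
  list(diff = diff, vs_score = vs_score,
       pairwise = if (length(pw)) do.call(rbind, pw)
                  else data.frame(gene_a = character(), gene_b = character(),
                                  pearson_r = numeric(), spearman_rho = numeric()),
       skipped = skipped)
}

#' Four-group survival: risk group crossed with gene expression
#'
#' Splits patients by risk group and by a single gene's expression at the
#' cohort median (strictly above = "high"), yielding four groups, and runs
#' Kaplan-Meier curves with an overall log-rank test across the non-empty
#' groups. Empty subgroups are reported but do not abort the analysis.
#'
#' @param groups two-level risk-group factor.
#' @param gene_expr named numeric vector of one gene's expression.
#' @param surv survival table.
#' @return List: \code{labels} (4-level factor), \code{km} (see
#'   [km_logrank()]), \code{empty} (names of empty subgroups),
#'   \code{threshold} (the median split point).
#' @export
four_group_survival <- function(groups, gene_expr, surv) {
  surv <- validate_survival(surv)
  if (!is.null(names(gene_expr))) gene_expr <- gene_expr[surv$sample_id]
  groups <- as.factor(groups)
  thr <- stats::median(gene_expr)
  gexp <- ifelse(gene_expr > thr, "gene-high", "gene-low")
  lab <- factor(paste(as.character(groups), gexp, sep = "/"),
                levels = c(t(outer(levels(groups), c("gene-high", "gene-low"),
                                   paste, sep = "/"))))
  empty <- levels(lab)[table(lab) == 0]
  km <- if (nlevels(droplevels(lab)) >= 2L) km_logrank(droplevels(lab), surv)
        else list(skipped = "fewer than 2 non-empty groups")
  list(labels = lab, km = km, empty = empty, threshold = thr)
}

#' Drug-sensitivity comparison between risk groups
#'
#' Two-sided Mann-Whitney test per drug on predicted log-IC50 values, with
#' BH correction and a direction flag: lower IC50 means greater sensitivity,
#' so \code{"more_sensitive_in_<group>"} names the group with the lower
#' median IC50.
#'
#' @param ic50 numeric matrix, samples in rows, drugs in columns.
#' @param groups two-level risk-group factor.
#' @return data.frame: drug, p, fdr, direction.
#' @export
drug_sensitivity_diff <- function(ic50, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2L) stop("need exactly 2 non-empty groups")
  lev <- levels(droplevels(groups))
  ia <- groups == lev[1]; ib <- groups == lev[2]
  rows <- lapply(colnames(ic50), function(dr) {
    v <- ic50[, dr]
    p <- if (stats::sd(v) == 0) 1
         else suppressWarnings(stats::wilcox.test(v[ia], v[ib])$p.value)
    d <- stats::median(v[ia]) - stats::median(v[ib])
    data.frame(drug = dr, p = p,
               direction = if (d > 0) paste0("more_sensitive_in_", lev[2])
                           else if (d < 0) paste0("more_sensitive_in_", lev[1])
                           else "none")
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, "BH")
  out[, c("drug", "p", "fdr", "direction")]
}

#' Read a samples-by-columns numeric TSV (infiltration or IC50 tables)
#'
#' First column \code{sample_id}, remaining columns numeric.
#' @param path file path.
#' @return Numeric matrix with sample rownames.
#' @export
read_sample_table_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_sample_table_tsv
#' @param m numeric matrix, samples in rows.
#' @export
write_sample_table_tsv <- function(m, path) {
  utils::write.table(data.frame(sample_id = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
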