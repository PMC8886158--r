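#' Two-group differential expression with moderated variance
#'
#' Per-gene two-sample t-test on log2 expression with optional
#' empirical-Bayes variance moderation: gene-wise pooled variances are
#' shrunk toward a common prior fitted by method of moments on the
#' distribution of sample variances (a scaled-F hierarchical model), and the
#' t statistic uses the posterior variance with augmented degrees of
#' freedom. With \code{moderated = FALSE} an ordinary Welch t-test is used.
#'
#' logFC is defined as \code{mean(group A) - mean(group B)} on the log2
#' scale, where A is the first level of \code{groups}.
#'
#' @param m an \code{expr_matrix} (log2 scale).
#' @param groups two-level factor (or vector coercible to one), one label
#'   per sample; the first level is the "A" group of the logFC.
#' @param moderated logical, default \code{TRUE}.
#' @return A data.frame with one row per gene: \code{gene_id},
#'   \code{biotype}, \code{logfc}, \code{t}, \code{df}, \code{p},
#'   \code{fdr} (Benjamini-Hochberg).
#' @export
differential_expression <- function(m, groups, moderated = TRUE) {
  m <- as_expr_matrix(m, gene_biotype(m))
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("'groups' must have exactly two levels")
  if (length(groups) != ncol(m)) stop("one group label per sample required")
  ia <- which(groups == levels(groups)[1]); ib <- which(groups == levels(groups)[2])
  n1 <- length(ia); n2 <- length(ib)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 samples per group")
  x <- unclass(m)
  m1 <- rowMeans(x[, ia, drop = FALSE]); m2 <- rowMeans(x[, ib, drop = FALSE])
  v1 <- apply(x[, ia, drop = FALSE], 1L, stats::var)
  v2 <- apply(x[, ib, drop = FALSE], 1L, stats::var)
  logfc <- m1 - m2

  if (moderated) {
    s2 <- (v1 * (n1 - 1) + v2 * (n2 - 1)) / (n1 + n2 - 2)
    d <- n1 + n2 - 2
    prior <- .fit_variance_prior(s2, d)
    s2post <- (prior$d0 * prior$s02 + d * s2) / (prior$d0 + d)
    se <- sqrt(s2post * (1 / n1 + 1 / n2))
    df <- rep(d + prior$d0, length(s2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- ifelse(se > 0, logfc / se, ifelse(logfc == 0, 0, sign(logfc) * Inf))
  p <- ifelse(is.finite(tstat),
              2 * stats::pt(abs(tstat), df, lower.tail = FALSE),
              0)
  p[se == 0 & logfc == 0] <- 1  # gene constant within both groups, equal means
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  res <- data.frame(gene_id = rownames(m), biotype = gene_biotype(m),
                    logfc = logfc, t = tstat, df = df, p = p,
                    fdr = stats::p.adjust(p, "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("de_result", "data.frame")
  res
}

# Method-of-moments fit of the scaled-F model s2_g / s02 ~ F(d, d0).
# From mean mu and variance v of the gene-wise s2: the squared coefficient
# of variation of F(d, d0) is 2 (d + d0 - 2) / (d (d0 - 4)), solved for d0;
# s02 recovered from mu = s02 * d0 / (d0 - 2). Degenerate cases (too little
# dispersion) fall back to an infinite prior df, i.e. complete pooling.
.fit_variance_prior <- function(s2, d) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 3L) return(list(d0 = 4, s02 = stats::median(s2, na.rm = TRUE)))
  mu <- mean(s2); v <- stats::var(s2)
  cv2 <- v / mu^2
  denom <- cv2 * d - 2
  if (denom <= 0) {
    # variances under-dispersed relative to chi-square: complete pooling
    return(list(d0 = 1e6, s02 = mu))
  }
  d0 <- (2 * d - 4 + 4 * cv2 * d) / denom
  d0 <- max(d0, 4.01)
  list(d0 = d0, s02 = mu * (d0 - 2) / d0)
}

#' Select cell-type-specific lncRNAs from a differential-expression table
#'
#' Retains genes of biotype \code{lncRNA} with \code{|logFC|} strictly above
#' \code{lfc_threshold} and FDR strictly below \code{fdr_threshold} (both
#' boundaries excluded).
#'
#' @param de a \code{de_result} from [differential_expression()].
#' @param lfc_threshold positive log2 fold-change threshold (default 1).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @return Character vector of gene ids, sorted.
#' @export
select_specific_lncrnas <- function(de, lfc_threshold = 1, fdr_threshold = 0.05) {
  stopifnot(lfc_threshold >= 0, fdr_threshold > 0)
  keep <- de$biotype == "lncRNA" &
    abs(de$logfc) > lfc_threshold & de$fdr < fdr_threshold
  sort(de$gene_id[keep])
}

#' Rank-sum differential expression (tumor vs normal mRNAs)
#'
#' Per-gene two-sided Mann-Whitney test between the two groups with logFC
#' as the difference of group means on the log2 scale; genes passing strict
#' \code{|logFC| > lfc} and \code{fdr < fdr_threshold} form the reported
#' gene list.
#'
#' @param m an \code{expr_matrix} restricted to (or containing) mRNAs; only
#'   rows of biotype \code{mRNA} are tested unless \code{all_biotypes}.
#' @param groups two-level factor, first level = "A" of the logFC
#'   (conventionally tumor).
#' @param lfc log2 fold-change threshold (default 2).
#' @param fdr_threshold FDR threshold (default 0.05).
#' @param all_biotypes test all rows regardless of biotype.
#' @return List with \code{table} (gene_id, logfc, p, fdr) and \code{genes}
#'   (the selected, sorted gene list).
#' @export
de_mrna <- function(m, groups, lfc = 2, fdr_threshold = 0.05,
                    all_biotypes = FALSE) {
  m <- as_expr_matrix(m, gene_biotype(m))
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("'groups' must have exactly two levels")
  ia <- groups == levels(groups)[1]; ib <- groups == levels(groups)[2]
  if (sum(ia) < 3L || sum(ib) < 3L) stop("need at least 3 samples per group")
  if (!all_biotypes) {
    keep <- gene_biotype(m) == "mRNA"
    if (!any(keep)) stop("no mRNA-biotype genes in the matrix")
    m <- m[keep, , drop = FALSE]
  }
  x <- unclass(m)
  logfc <- rowMeans(x[, ia, drop = FALSE]) - rowMeans(x[, ib, drop = FALSE])
  p <- apply(x, 1L, function(v) {
    if (stats::sd(v) == 0) return(1)
    stats::wilcox.test(v[ia], v[ib], exact = FALSE, correct = TRUE)$p.value
  })
  tab <- data.frame(gene_id = rownames(m), logfc = logfc, p = p,
                    fdr = stats::p.adjust(p, "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  list(table = tab,
       genes = sort(tab$gene_id[abs(tab$logfc) > lfc & tab$fdr < fdr_threshold]))
}
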