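# Signal-to-noise ranking metric between two phenotype groups, with the
# conventional floor on the per-group standard deviation (at least 20% of
# the absolute mean, and at least 0.2 when the mean is ~0) so genes with
# vanishing variance do not dominate the ranking.
.signal_to_noise <- function(x, ia, ib) {
  m1 <- rowMeans(x[, ia, drop = FALSE]); m2 <- rowMeans(x[, ib, drop = FALSE])
  s1 <- apply(x[, ia, drop = FALSE], 1L, stats::sd)
  s2 <- apply(x[, ib, drop = FALSE], 1L, stats::sd)
  floor1 <- pmax(0.2 * abs(m1), 0.2 * (abs(m1) < .Machine$double.eps))
  floor2 <- pmax(0.2 * abs(m2), 0.2 * (abs(m2) < .Machine$double.eps))
  (m1 - m2) / (pmax(s1, floor1) + pmax(s2, floor2))
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Running-sum enrichment score of a gene set over a ranked gene list:
#' walking down the list ordered by decreasing metric, set members increment
#' the sum by \code{|metric|^weight} (normalized to total 1 over members)
#' and non-members decrement it by \code{1/(N - Nh)}; the ES is the signed
#' maximal deviation from zero.
#'
#' @param metric named numeric vector of per-gene ranking statistics (need
#'   not be sorted).
#' @param members character vector of set member gene ids.
#' @param weight weighting exponent (default 1).
#' @return List: \code{es}, \code{running} (the running sum in ranked
#'   order), \code{order} (gene ids in ranked order), \code{peak} (index of
#'   the extremum), \code{leading_edge} (member genes contributing to the
#'   ES).
#' @export
enrichment_score <- function(metric, members, weight = 1) {
  o <- order(metric, decreasing = TRUE)
  genes <- names(metric)[o]
  r <- metric[o]
  hit <- genes %in% members
  nh <- sum(hit)
  if (nh < 1L) stop("gene set has no member on the ranked list")
  n <- length(genes)
  if (nh == n) stop("gene set equals the ranked list")
  w <- abs(r)^weight * hit
  nr <- sum(w)
  inc <- if (nr > 0) w / nr else hit / nh
  dec <- (!hit) / (n - nh)
  running <- cumsum(inc - dec)
  peak <- which.max(abs(running))
  es <- running[peak]
  le <- if (es >= 0) genes[seq_len(peak)][hit[seq_len(peak)]]
        else genes[peak:n][hit[peak:n]]
  list(es = unname(es), running = unname(running), order = genes,
       peak = unname(peak), leading_edge = le)
}

#' Gene set enrichment analysis between two phenotypes
#'
#' Classic weighted Kolmogorov-Smirnov GSEA: genes are ranked by the
#' signal-to-noise ratio between the two phenotype groups (first factor
#' level minus second; a positive ES means enrichment among genes up in the
#' first level), the running-sum enrichment score is computed per gene set
#' with weight exponent 1, and significance is assessed by phenotype-label
#' permutations: NES = ES divided by the mean of same-sign permutation ES,
#' nominal p from the same-sign permutation tail, and FDR q from the pooled
#' permutation NES distribution across all tested sets.
#'
#' @param expr an \code{expr_matrix}.
#' @param phenotype two-level factor over samples; first level is the
#'   "positive" phenotype.
#' @param gene_sets named list of character vectors (or one character
#'   vector).
#' @param n_perm number of phenotype permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @param weight KS weight exponent (default 1).
#' @param min_size minimum overlap between set and matrix genes (default 2).
#' @return data.frame per set: set, size, es, nes, p, fdr_q, leading_edge
#'   (comma-separated).
#' @export
gsea <- function(expr, phenotype, gene_sets, n_perm = 1000, seed = 1,
                 weight = 1, min_size = 2) {
  expr <- as_expr_matrix(expr, gene_biotype(expr))
  phenotype <- as.factor(phenotype)
  if (nlevels(phenotype) != 2L) stop("'phenotype' must have two levels")
  if (length(phenotype) != ncol(expr)) stop("one phenotype label per sample")
  ia <- which(phenotype == levels(phenotype)[1])
  ib <- which(phenotype == levels(phenotype)[2])
  if (length(ia) < 3L || length(ib) < 3L)
    stop("need at least 3 samples per phenotype")
  if (!is.list(gene_sets)) gene_sets <- list(gene_set = gene_sets)
  x <- unclass(expr)
  sets <- lapply(gene_sets, function(g) intersect(unique(g), rownames(x)))
  small <- vapply(sets, length, 1L) < min_size
  if (all(small)) stop("no gene set overlaps the expression matrix (min_size)")
  sets <- sets[!small]

  metric <- stats::setNames(.signal_to_noise(x, ia, ib), rownames(x))
  obs <- lapply(sets, function(g) enrichment_score(metric, g, weight))
  obs_es <- vapply(obs, `[[`, numeric(1), "es")

  set.seed(seed)
  n_samp <- ncol(x)
  perm_es <- matrix(NA_real_, n_perm, length(sets),
                    dimnames = list(NULL, names(sets)))
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n_samp)
    pa <- idx[seq_along(ia)]; pb <- idx[-seq_along(ia)]
    pm <- stats::setNames(.signal_to_noise(x, pa, pb), rownames(x))
    for (k in seq_along(sets))
      perm_es[b, k] <- enrichment_score(pm, sets[[k]], weight)$es
  }

  # same-sign normalization: ES / mean(permutation ES of matching sign)
  norm_one <- function(e, perms) {
    if (e >= 0) {
      pos <- perms[perms >= 0]
      if (!length(pos)) return(NA_real_)
      e / mean(pos)
    } else {
      neg <- perms[perms < 0]
      if (!length(neg)) return(NA_real_)
      -e / mean(neg)  # negative NES: mean(neg) < 0 so this stays negative
    }
  }
  nes <- vapply(seq_along(sets), function(k)
    norm_one(obs_es[k], perm_es[, k]), numeric(1))
  perm_nes <- perm_es
  for (k in seq_along(sets))
    perm_nes[, k] <- vapply(perm_es[, k], norm_one, numeric(1),
                            perms = perm_es[, k])

  p <- vapply(seq_along(sets), function(k) {
    e <- obs_es[k]; pe <- perm_es[, k]
    if (e >= 0) {
      pos <- pe[pe >= 0]
      if (!length(pos)) return(1 / (n_perm + 1))
      (sum(pos >= e) + 1) / (length(pos) + 1)
    } else {
      neg <- pe[pe < 0]
      if (!length(neg)) return(1 / (n_perm + 1))
      (sum(neg <= e) + 1) / (length(neg) + 1)
    }
  }, numeric(1))

  pool <- as.numeric(perm_nes)
  pool <- pool[is.finite(pool)]
  fdr_q <- vapply(seq_along(sets), function(k) {
    ne <- nes[k]
    if (!is.finite(ne)) return(NA_real_)
    if (ne >= 0) {
      num <- mean(pool[pool >= 0] >= ne)
      den <- mean(nes[is.finite(nes) & nes >= 0] >= ne)
    } else {
      num <- mean(pool[pool < 0] <= ne)
      den <- mean(nes[is.finite(nes) & nes < 0] <= ne)
    }
    if (!is.finite(num) || !is.finite(den) || den == 0) return(NA_real_)
    min(1, num / den)
  }, numeric(1))

  data.frame(set = names(sets),
             size = vapply(sets, length, 1L),
             es = unname(obs_es), nes = nes, p = p, fdr_q = fdr_q,
             leading_edge = vapply(obs, function(o)
               paste(o$leading_edge, collapse = ","), character(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
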