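#' Binary lncRNA-pair indicator matrix
#'
#' The core rank-based feature transformation: for every unordered pair of
#' lncRNAs \{A, B\} (oriented lexicographically, A < B) and every sample s,
#' the indicator is 1 when A is expressed at a strictly higher level than B
#' in s, and 0 otherwise (ties score 0). The transformation depends only on
#' the within-sample ordering of the two genes, so it is invariant to any
#' strictly increasing per-sample transform of the expression values.
#'
#' @param indicator integer/numeric 0-1 matrix, one row per pair, one column
#'   per sample; rownames of the form \code{"lncA|lncB"} are (re)built from
#'   \code{lnc_a}/\code{lnc_b}.
#' @param lnc_a,lnc_b character vectors naming each pair's members, with
#'   \code{lnc_a < lnc_b} lexicographically.
#' @return An object of class \code{pair_matrix}: the 0/1 matrix with a
#'   \code{pairs} attribute (data.frame \code{lnc_a}, \code{lnc_b},
#'   \code{prevalence}).
#' @export
pair_matrix <- function(indicator, lnc_a, lnc_b) {
  indicator <- as.matrix(indicator)
  storage.mode(indicator) <- "integer"
  if (!all(indicator %in% c(0L, 1L))) stop("indicator entries must be 0 or 1")
  if (length(lnc_a) != nrow(indicator) || length(lnc_b) != nrow(indicator))
    stop("one (lnc_a, lnc_b) per indicator row required")
  if (any(lnc_a == lnc_b)) stop("a pair cannot contain the same gene twice")
  if (any(lnc_a > lnc_b)) stop("pairs must be oriented lnc_a < lnc_b")
  key <- paste(lnc_a, lnc_b, sep = "|")
  if (anyDuplicated(key)) stop("duplicate pairs")
  if (is.null(colnames(indicator))) stop("sample ids (colnames) required")
  rownames(indicator) <- key
  pairs <- data.frame(lnc_a = lnc_a, lnc_b = lnc_b,
                      prevalence = rowMeans(indicator),
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(indicator, pairs = pairs,
            class = c("pair_matrix", "matrix", "array"))
}

#' @export
print.pair_matrix <- function(x, ...) {
  cat(sprintf("pair_matrix: %d pairs x %d samples, prevalence range [%.3f, %.3f]\n",
              nrow(x), ncol(x),
              min(attr(x, "pairs")$prevalence), max(attr(x, "pairs")$prevalence)))
  invisible(x)
}

#' @rdname pair_matrix
#' @param x a \code{pair_matrix}.
#' @export
pair_info <- function(x) attr(x, "pairs")

#' Intersect cell-type-specific lncRNAs with a tumor cohort
#'
#' Keeps the specific lncRNAs that are measured in the tumor expression
#' matrix (any biotype filtering is assumed done upstream), sorted
#' lexicographically.
#'
#' @param specific_lncrnas character vector of gene ids.
#' @param tumor an \code{expr_matrix} for the tumor cohort.
#' @return Sorted character vector of shared ids (possibly empty, with a
#'   warning).
#' @export
intersect_with_cohort <- function(specific_lncrnas, tumor) {
  out <- sort(intersect(specific_lncrnas, rownames(tumor)))
  if (!length(out)) warning("no specific lncRNAs are present in the cohort")
  out
}

#' Build the 0-or-1 pair matrix from a tumor cohort
#'
#' @param tumor an \code{expr_matrix}.
#' @param lncrnas character vector of gene ids (all must be rows of
#'   \code{tumor}); at least 2.
#' @return A \code{pair_matrix} with exactly \code{choose(m, 2)} rows.
#' @export
build_pair_matrix <- function(tumor, lncrnas) {
  lncrnas <- sort(unique(lncrnas))
  if (length(lncrnas) < 2L) stop("need at least 2 lncRNAs to form pairs")
  missing <- setdiff(lncrnas, rownames(tumor))
  if (length(missing))
    stop("lncRNAs absent from cohort: ", paste(missing, collapse = ", "))
  x <- unclass(tumor)[lncrnas, , drop = FALSE]
  cmb <- utils::combn(length(lncrnas), 2L)
  ind <- (x[cmb[1L, ], , drop = FALSE] > x[cmb[2L, ], , drop = FALSE]) * 1L
  colnames(ind) <- colnames(x)
  pair_matrix(ind, lncrnas[cmb[1L, ]], lncrnas[cmb[2L, ]])
}

#' Prevalence filter for pair features
#'
#' Retains pairs whose indicator equals 1 in a fraction of samples between
#' \code{lower} and \code{upper} inclusive (defaults 20--80\%), removing
#' near-constant features. Idempotent; preserves row order.
#'
#' @param pm a \code{pair_matrix}.
#' @param lower,upper prevalence bounds, \code{0 <= lower < upper <= 1}.
#' @return The filtered \code{pair_matrix} (possibly with zero rows).
#' @export
prevalence_filter <- function(pm, lower = 0.20, upper = 0.80) {
  stopifnot(inherits(pm, "pair_matrix"), lower >= 0, upper <= 1, lower < upper)
  prev <- attr(pm, "pairs")$prevalence
  keep <- prev >= lower & prev <= upper
  pairs <- attr(pm, "pairs")[keep, , drop = FALSE]
  pair_matrix(unclass(pm)[keep, , drop = FALSE], pairs$lnc_a, pairs$lnc_b)
}

#' Serialize / read a pair matrix as TSV
#'
#' Rows are \code{"lncA|lncB"}, columns are samples, values 0/1.
#' @param pm a \code{pair_matrix}.
#' @param path file path.
#' @export
write_pair_tsv <- function(pm, path) {
  df <- data.frame(pair = rownames(pm), unclass(pm), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pair_tsv
#' @export
read_pair_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ab <- strsplit(df$pair, "|", fixed = TRUE)
  ind <- as.matrix(df[, -1, drop = FALSE])
  pair_matrix(ind, vapply(ab, `[`, "", 1L), vapply(ab, `[`, "", 2L))
}
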