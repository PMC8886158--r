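#' Expression matrix with gene biotypes
#'
#' Lightweight container for a log2-scale gene-by-sample expression matrix
#' together with a per-gene biotype annotation. All pipeline stages consume
#' and return this class.
#'
#' @param values numeric matrix, genes in rows, samples in columns; rownames
#'   and colnames must be unique and non-missing; all values finite.
#' @param biotype character vector of length \code{nrow(values)} with entries
#'   in \code{c("lncRNA", "mRNA", "other")}; recycled if length 1.
#' @return An object of class \code{expr_matrix}: the numeric matrix with a
#'   \code{biotype} attribute (named by gene).
#' @examples
#' m <- matrix(rnorm(12), 4, 3,
#'             dimnames = list(paste0("G", 1:4), paste0("S", 1:3)))
#' em <- expr_matrix(m, biotype = "lncRNA")
#' @export
expr_matrix <- function(values, biotype = "other") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have rownames (genes) and colnames (samples)")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (!all(is.finite(values))) stop("all expression values must be finite")
  if (length(biotype) == 1L) biotype <- rep(biotype, nrow(values))
  if (length(biotype) != nrow(values))
    stop("'biotype' must have one entry per gene")
  bad <- setdiff(unique(biotype), c("lncRNA", "mRNA", "other"))
  if (length(bad))
    stop("unknown biotype(s): ", paste(bad, collapse = ", "))
  names(biotype) <- rownames(values)
  structure(values, biotype = biotype, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  bt <- table(attr(x, "biotype"))
  cat(sprintf("expr_matrix: %d genes x %d samples (%s)\n",
              nrow(x), ncol(x),
              paste(sprintf("%s %d", names(bt), bt), collapse = ", ")))
  invisible(x)
}

#' @rdname expr_matrix
#' @param x object to coerce or query.
#' @export
as_expr_matrix <- function(x, biotype = "other") {
  if (inherits(x, "expr_matrix")) x else expr_matrix(as.matrix(x), biotype)
}

#' @rdname expr_matrix
#' @export
gene_biotype <- function(x) {
  bt <- attr(x, "biotype")
  if (is.null(bt)) stats::setNames(rep("other", nrow(x)), rownames(x)) else bt
}

# Subset rows/columns, keeping the biotype annotation in register.
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  bt <- gene_biotype(x)
  y <- NextMethod(drop = drop)
  if (!is.matrix(y)) return(y)
  expr_matrix(y, bt[rownames(y)])
}

#' Quantile normalization across samples
#'
#' Forces every sample (column) to share the same distribution: the
#' cross-sample mean of order statistics. Within-sample ranks are preserved
#' up to ties; tied values receive the mean of the reference values at the
#' tied positions.
#'
#' @param m an \code{expr_matrix} (or plain matrix).
#' @return An \code{expr_matrix} of the same shape; applying the function
#'   twice equals applying it once.
#' @examples
#' m <- expr_matrix(cbind(A = c(1, 2, 3), B = c(4, 5, 6)) |>
#'        (\(x) {rownames(x) <- paste0("g", 1:3); x})())
#' quantile_normalize(m)   # both columns become (2.5, 3.5, 4.5)
#' @export
quantile_normalize <- function(m) {
  m <- as_expr_matrix(m, gene_biotype(m))
  if (ncol(m) < 2L) {
    warning("fewer than 2 samples: returning input unchanged")
    return(m)
  }
  sorted <- apply(unclass(m), 2L, sort)
  ref <- rowMeans(sorted)
  out <- unclass(m)
  for (j in seq_len(ncol(out))) {
    # rank() with ties = "average" maps tied entries to the mean reference
    # value at their shared positions (interpolated via approx for .5 ranks)
    r <- rank(out[, j], ties.method = "average")
    out[, j] <- stats::approx(seq_along(ref), ref, xout = r, rule = 2)$y
  }
  expr_matrix(out, gene_biotype(m))
}

#' Location(/scale) batch adjustment
#'
#' Per gene, shifts each batch's mean to the gene's grand mean; optionally
#' also rescales each batch's residual standard deviation to the pooled
#' value. This is a deliberately simple additive/multiplicative adjustment:
#' no empirical-Bayes shrinkage of batch parameters is applied, because the
#' downstream pair features are rank-based within samples and insensitive to
#' that refinement.
#'
#' @param m an \code{expr_matrix}.
#' @param batch vector of batch labels, one per sample.
#' @param scale logical; also equalize per-batch standard deviations
#'   (default \code{FALSE}).
#' @return Adjusted \code{expr_matrix}.
#' @export
batch_adjust <- function(m, batch, scale = FALSE) {
  m <- as_expr_matrix(m, gene_biotype(m))
  if (length(batch) != ncol(m))
    stop("'batch' must have one label per sample")
  batch <- as.factor(batch)
  if (nlevels(batch) == 1L) return(m)
  out <- unclass(m)
  grand <- rowMeans(out)
  singletons <- names(which(table(batch) == 1L))
  if (length(singletons) && scale)
    warning("batch(es) with a single sample: mean-shift only for ",
            paste(singletons, collapse = ", "))
  for (b in levels(batch)) {
    idx <- which(batch == b)
    bm <- rowMeans(out[, idx, drop = FALSE])
    centred <- out[, idx, drop = FALSE] - bm
    if (scale && length(idx) > 1L) {
      bs <- apply(out[, idx, drop = FALSE], 1L, stats::sd)
      ps <- apply(unclass(m), 1L, stats::sd)
      fac <- ifelse(bs > 0, ps / bs, 1)
      centred <- centred * fac
    }
    out[, idx] <- centred + grand
  }
  expr_matrix(out, gene_biotype(m))
}

#' Read / write expression matrices as TSV or GCT 1.2
#'
#' The TSV layout is genes in rows: first column \code{gene_id}, optional
#' second column \code{biotype}, remaining columns one per sample. GCT 1.2
#' files carry the standard two header lines and a \code{Description} column
#' (used here to store the biotype).
#'
#' @param m an \code{expr_matrix}.
#' @param path file path.
#' @return \code{read_expr_tsv}/\code{read_expr_gct} return an
#'   \code{expr_matrix}; the writers return \code{path} invisibly.
#' @export
write_expr_tsv <- function(m, path) {
  m <- as_expr_matrix(m)
  df <- data.frame(gene_id = rownames(m), biotype = gene_biotype(m),
                   unclass(m), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expr_tsv
#' @export
read_expr_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  has_bt <- "biotype" %in% names(df)
  vals <- as.matrix(df[, setdiff(names(df), c("gene_id", "biotype")), drop = FALSE])
  rownames(vals) <- df$gene_id
  expr_matrix(vals, if (has_bt) df$biotype else "other")
}

#' @rdname write_expr_tsv
#' @export
write_expr_gct <- function(m, path) {
  m <- as_expr_matrix(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
  df <- data.frame(NAME = rownames(m), Description = gene_biotype(m),
                   unclass(m), check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expr_tsv
#' @export
read_expr_gct <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "#1.2")) stop("not a GCT 1.2 file")
  df <- utils::read.delim(text = paste(lines[-(1:2)], collapse = "\n"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(vals) <- df$NAME
  bt <- df$Description
  bt[!bt %in% c("lncRNA", "mRNA", "other")] <- "other"
  expr_matrix(vals, bt)
}

#' Read and write GMT gene-set files
#'
#' @param path GMT file path.
#' @return \code{read_gmt} returns a named list of character vectors
#'   (element names are set names, the description field is kept as the
#'   \code{"description"} attribute of each element).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 40))
    structure(unique(f[-(1:2)]), description = f[2])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- "na"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
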