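#' Interaction edge tables
#'
#' An interaction table is a data.frame with columns \code{source_id},
#' \code{target_id}, \code{source_db} and a single edge kind
#' (\code{"lncRNA-miRNA"} or \code{"miRNA-mRNA"}) stored as the
#' \code{"kind"} attribute. Duplicate (source, target, source_db) triples
#' are rejected.
#'
#' @param df data.frame with \code{source_id}, \code{target_id},
#'   \code{source_db}.
#' @param kind edge kind.
#' @return Validated data.frame with a \code{kind} attribute.
#' @export
interaction_table <- function(df, kind = c("lncRNA-miRNA", "miRNA-mRNA")) {
  kind <- match.arg(kind)
  need <- c("source_id", "target_id", "source_db")
  if (!all(need %in% names(df)))
    stop("interaction table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df[, need]))
    stop("duplicate (source, target, source_db) edges")
  structure(df[, need], kind = kind)
}

#' @rdname interaction_table
#' @param path TSV path.
#' @export
read_interaction_tsv <- function(path, kind = c("lncRNA-miRNA", "miRNA-mRNA")) {
  interaction_table(utils::read.delim(path, stringsAsFactors = FALSE), match.arg(kind))
}

#' @rdname interaction_table
#' @export
write_interaction_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Predict miRNA partners and consensus target mRNAs of a lncRNA list
#'
#' miRNAs are the interaction partners of the input lncRNAs in the
#' lncRNA-miRNA table; mRNAs are the targets of those miRNAs that appear in
#' all provided miRNA-target tables (\code{consensus = "all"}, default) or
#' in at least one (\code{"any"}). Results are deduplicated and sorted.
#'
#' @param lnc_list character vector of lncRNA ids.
#' @param lnc_mirna lncRNA-miRNA interaction table.
#' @param target_tables list of miRNA-mRNA interaction tables (e.g. from
#'   several prediction databases).
#' @param consensus \code{"all"} or \code{"any"}.
#' @return List: \code{mirnas}, \code{mrnas} (sorted character vectors).
#' @export
predict_targets <- function(lnc_list, lnc_mirna, target_tables,
                            consensus = c("all", "any")) {
  consensus <- match.arg(consensus)
  if (!length(lnc_list)) return(list(mirnas = character(), mrnas = character()))
  mirnas <- sort(unique(lnc_mirna$target_id[lnc_mirna$source_id %in% lnc_list]))
  if (!length(mirnas)) return(list(mirnas = character(), mrnas = character()))
  per_table <- lapply(target_tables, function(tb)
    unique(tb$target_id[tb$source_id %in% mirnas]))
  mrnas <- if (consensus == "all") Reduce(intersect, per_table)
           else Reduce(union, per_table)
  list(mirnas = mirnas, mrnas = sort(unique(mrnas)))
}

#' Hub mRNAs: consensus targets that are also differentially expressed
#'
#' @param predicted_mrnas character vector (consensus miRNA targets).
#' @param de_mrnas character vector (differentially expressed mRNAs).
#' @return Sorted intersection.
#' @export
hub_mrnas <- function(predicted_mrnas, de_mrnas) {
  sort(intersect(predicted_mrnas, de_mrnas))
}

#' Assemble the lncRNA-miRNA-mRNA ceRNA network around hub mRNAs
#'
#' Back-propagates from the hub mRNAs: keeps every miRNA whose edge to at
#' least one hub satisfies the consensus rule across target tables, then
#' every lncRNA interacting with a kept miRNA. Hubs with no consensus miRNA
#' are dropped with a warning; the result contains no orphan nodes.
#'
#' @param hubs character vector of hub mRNA ids.
#' @param lnc_mirna lncRNA-miRNA interaction table.
#' @param target_tables list of miRNA-mRNA tables.
#' @param consensus \code{"all"} or \code{"any"}.
#' @return Object of class \code{cerna_network}: list with \code{nodes}
#'   (data.frame id, type), \code{edges} (data.frame source, target,
#'   edge_type), \code{hubs}.
#' @export
assemble_network <- function(hubs, lnc_mirna, target_tables,
                             consensus = c("all", "any")) {
  consensus <- match.arg(consensus)
  # consensus miRNA->mRNA edges: present in all (or any) tables
  edge_key <- lapply(target_tables, function(tb)
    unique(paste(tb$source_id, tb$target_id, sep = "\r")))
  keys <- if (consensus == "all") Reduce(intersect, edge_key)
          else Reduce(union, edge_key)
  mm <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  mm_edges <- if (is.null(mm)) data.frame(source = character(), target = character())
              else data.frame(source = mm[, 1], target = mm[, 2])
  mm_edges <- mm_edges[mm_edges$target %in% hubs, , drop = FALSE]
  kept_hubs <- sort(unique(mm_edges$target))
  dropped <- setdiff(hubs, kept_hubs)
  if (length(dropped))
    warning("hub(s) without consensus miRNA dropped: ",
            paste(dropped, collapse = ", "))
  kept_mirnas <- sort(unique(mm_edges$source))
  lm_edges <- lnc_mirna[lnc_mirna$target_id %in% kept_mirnas, , drop = FALSE]
  # miRNAs kept only if they still connect both layers (no orphans)
  kept_mirnas <- intersect(kept_mirnas, lm_edges$target_id)
  mm_edges <- mm_edges[mm_edges$source %in% kept_mirnas, , drop = FALSE]
  kept_hubs <- sort(unique(mm_edges$target))
  kept_lncs <- sort(unique(lm_edges$source_id))
  nodes <- data.frame(
    id = c(kept_lncs, kept_mirnas, kept_hubs),
    type = rep(c("lncRNA", "miRNA", "mRNA"),
               c(length(kept_lncs), length(kept_mirnas), length(kept_hubs))),
    stringsAsFactors = FALSE)
  edges <- rbind(
    data.frame(source = lm_edges$source_id, target = lm_edges$target_id,
               edge_type = rep("lncRNA-miRNA", nrow(lm_edges)),
               stringsAsFactors = FALSE),
    data.frame(source = mm_edges$source, target = mm_edges$target,
               edge_type = rep("miRNA-mRNA", nrow(mm_edges)),
               stringsAsFactors = FALSE))
  edges <- unique(edges)
  edges <- edges[order(edges$edge_type, edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, hubs = kept_hubs),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  tt <- table(x$nodes$type)
  cat(sprintf("cerna_network: %s; %d edges; %d hub mRNAs\n",
              paste(sprintf("%d %s", tt, names(tt)), collapse = ", "),
              nrow(x$edges), length(x$hubs)))
  invisible(x)
}

#' Export a ceRNA network
#'
#' \code{write_network_sif} writes a Cytoscape SIF file,
#' \code{write_network_tsv} a plain edge list, and
#' \code{write_network_graphml} a GraphML file (requires the igraph
#' package).
#'
#' @param net a \code{cerna_network}.
#' @param path file path.
#' @export
write_network_sif <- function(net, path) {
  writeLines(sprintf("%s\t%s\t%s", net$edges$source, net$edges$edge_type,
                     net$edges$target), path)
  invisible(path)
}

#' @rdname write_network_sif
#' @export
write_network_tsv <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_sif
#' @export
write_network_graphml <- function(net, path) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("GraphML export requires the igraph package")
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Hypergeometric over-representation test of a gene list
#'
#' One-sided hypergeometric tail per annotation term: the probability of
#' drawing at least the observed overlap when sampling \code{length(hits)}
#' genes from the universe. Benjamini-Hochberg correction across terms.
#' Terms with no member in the universe are skipped.
#'
#' @param hits character vector (e.g. hub mRNAs); must be a subset of
#'   \code{universe}.
#' @param terms named list of character vectors (term -> gene set).
#' @param universe character vector of all candidate genes.
#' @return data.frame: term, overlap, term_size, p, fdr, fold_enrichment,
#'   genes (comma-separated overlap).
#' @export
enrichment_test <- function(hits, terms, universe) {
  universe <- unique(universe)
  if (!all(hits %in% universe)) stop("'hits' must be a subset of 'universe'")
  hits <- unique(hits)
  n_u <- length(universe); n_h <- length(hits)
  rows <- lapply(names(terms), function(nm) {
    tg <- intersect(unique(terms[[nm]]), universe)
    if (!length(tg)) return(NULL)
    k <- length(intersect(hits, tg))
    p <- stats::phyper(k - 1, length(tg), n_u - length(tg), n_h,
                       lower.tail = FALSE)
    fe <- if (n_h > 0 && length(tg) > 0)
      (k / n_h) / (length(tg) / n_u) else NA_real_
    data.frame(term = nm, overlap = k, term_size = length(tg), p = p,
               fold_enrichment = fe,
               genes = paste(sort(intersect(hits, tg)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out))
    return(data.frame(term = character(), overlap = integer(),
                      term_size = integer(), p = numeric(), fdr = numeric(),
                      fold_enrichment = numeric(), genes = character()))
  out$fdr <- stats::p.adjust(out$p, "BH")
  out[order(out$p), c("term", "overlap", "term_size", "p", "fdr",
                      "fold_enrichment", "genes")]
}
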