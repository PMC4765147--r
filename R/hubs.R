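# Hub-gene identification and edge export.

edges_to_igraph <- function(edges) {
  stopifnot(is.data.frame(edges),
            all(c("gene_a", "gene_b") %in% names(edges)))
  igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b")], directed = FALSE)
}

#' Rank hub genes in a network
#'
#' Two rankings are provided: plain degree (neighbour count) and Maximal
#' Clique Centrality, `MCC(v) = sum over maximal cliques C containing v of
#' (|C| - 1)!` -- the scoring popularised by network hub-detection
#' plugins.  Ties are broken lexicographically by gene id.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`.
#' @param method "degree" or "mcc".
#' @param top_k how many genes to return (all if larger than the node
#'   count).
#' @return character vector of the top-ranked gene ids.
#' @export
hub_genes <- function(edges, method = c("degree", "mcc"), top_k = 10) {
  method <- match.arg(method)
  top_k <- check_count(top_k, "top_k", min = 1L)
  if (nrow(edges) == 0L) stop_ipnet("edge list is empty")
  g <- edges_to_igraph(edges)
  nodes <- igraph::V(g)$name
  score <- if (method == "degree") {
    igraph::degree(g)
  } else {
    cliques <- igraph::max_cliques(g)
    s <- setNames(numeric(length(nodes)), nodes)
    for (cl in cliques) {
      members <- nodes[as.integer(cl)]
      s[members] <- s[members] + factorial(length(members) - 1L)
    }
    s
  }
  ord <- order(-score, nodes)
  head(nodes[ord], min(top_k, length(nodes)))
}

#' Export network edges above a weight threshold
#'
#' Builds the edge list of the upper triangle of a similarity matrix
#' (typically TOM), keeping edges whose weight strictly exceeds the
#' threshold -- the "network output threshold" applied before
#' visualisation and compression.
#'
#' @param similarity symmetric genes x genes matrix (e.g. TOM).
#' @param threshold edge-weight cutoff in \[0, 1\] (default 0.5; strict
#'   greater-than).
#' @param genes optional subset of genes to restrict to.
#' @return data.frame with columns `gene_a`, `gene_b`, `weight`.
#' @export
export_edges <- function(similarity, threshold = 0.5, genes = NULL) {
  m <- as_numeric_matrix(similarity, "similarity")
  check_number(threshold, "threshold", min = 0, max = 1)
  ids <- rownames(m) %||% sprintf("gene%05d", seq_len(nrow(m)))
  rownames(m) <- colnames(m) <- ids
  if (!is.null(genes)) {
    genes <- intersect(ids, genes)
    m <- m[genes, genes, drop = FALSE]
    ids <- genes
  }
  idx <- which(upper.tri(m) & m > threshold, arr.ind = TRUE)
  data.frame(gene_a = ids[idx[, 1L]], gene_b = ids[idx[, 2L]],
             weight = m[idx], stringsAsFactors = FALSE)
}
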