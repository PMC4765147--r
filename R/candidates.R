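# Rule-based candidate-gene screening around guide genes.

#' Minimum hop distance from each gene to a source set
#'
#' Breadth-first unweighted shortest-path distance to the nearest source
#' gene; unreachable genes get `Inf`.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`.
#' @param sources character vector of source gene ids (non-empty, present
#'   in the network).
#' @return named numeric vector gene -> distance.
#' @export
graph_distances <- function(edges, sources) {
  g <- edges_to_igraph(edges)
  nodes <- igraph::V(g)$name
  sources <- intersect(sources, nodes)
  if (length(sources) == 0L) {
    stop_ipnet("no source genes present in the network")
  }
  d <- igraph::distances(g, v = sources, to = igraph::V(g))
  setNames(apply(d, 2L, min), nodes)
}

#' Screen candidate genes around guide genes
#'
#' Applies three mandatory principles to every non-guide gene of a
#' network, then ranks the passing genes by bonus evidence:
#'
#' \itemize{
#'   \item \strong{shared hub}: some top-ranked hub gene is adjacent to
#'     both the gene and at least one guide (a gene that is itself a
#'     guide-adjacent hub also qualifies);
#'   \item \strong{distance}: the hop distance to the nearest guide is
#'     strictly below `distance_max` (default 4);
#'   \item \strong{power node}: the gene shares a committed power node
#'     with at least one other non-guide gene whose edge weight to a
#'     guide strictly exceeds `export_threshold` (a "guide correlate").
#' }
#'
#' Passing genes are ranked by the number of bonus marks (preferred
#' conserved domain, differential expression) descending, then guide
#' distance ascending, then maximum edge weight to a guide descending,
#' then gene id -- a total, deterministic order.
#'
#' @param edges network edge list (`gene_a`, `gene_b`, optional
#'   `weight`; weights default to 1).
#' @param pg `power_graph` from [pg_compress()] of the same edge list.
#' @param guides guide gene ids; ids absent from the network are dropped
#'   with a warning.
#' @param hubs ranked hub list from [hub_genes()] on the same edges.
#' @param annotations optional data.frame (`gene_id`, `interpro_ids`
#'   semicolon-separated, ...).
#' @param de optional data.frame (`gene_id`, `is_de`).
#' @param preferred_domains domain ids counting as a bonus (defaults to
#'   the carbohydrate-kinase and P-loop domains recurrent in inositol
#'   phosphate pathway proteins).
#' @param export_threshold edge-weight cutoff defining guide correlates.
#' @param distance_max exclusive distance gate.
#' @return data.frame (one row per non-guide gene, ranked genes first)
#'   with columns `gene`, `min_guide_distance`, `shared_hub`, `hub_id`,
#'   `in_power_node_with_guide_correlate`, `preferred_domain_hits`,
#'   `is_de`, `passes_mandatory`, `bonus_count`, `max_guide_weight`,
#'   `rank` (NA for non-passing genes).
#' @export
screen_candidates <- function(edges, pg, guides, hubs,
                              annotations = NULL, de = NULL,
                              preferred_domains = c("IPR011611",
                                                    "IPR005337",
                                                    "IPR027417"),
                              export_threshold = 0.5,
                              distance_max = 4) {
  stopifnot(is.data.frame(edges),
            all(c("gene_a", "gene_b") %in% names(edges)))
  if (!"weight" %in% names(edges)) edges$weight <- 1
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  extra <- setdiff(unlist(pg$power_nodes, use.names = FALSE), nodes)
  if (length(extra)) {
    stop_ipnet("power graph contains genes absent from the edge list: ",
               paste(head(extra, 5), collapse = ", "))
  }
  missing <- setdiff(guides, nodes)
  if (length(missing)) {
    warning("guide gene(s) not in the network, dropped: ",
            paste(missing, collapse = ", "))
    guides <- setdiff(guides, missing)
  }
  if (length(guides) == 0L) stop_ipnet("no guide genes in the network")

  adj <- lapply(setNames(nodes, nodes), function(v) character(0))
  for (i in seq_len(nrow(edges))) {
    a <- edges$gene_a[i]; b <- edges$gene_b[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  wkey <- setNames(edges$weight, edge_key(edges$gene_a, edges$gene_b))
  weight_of <- function(a, b) {
    w <- wkey[edge_key(a, b)]
    ifelse(is.na(w), 0, w)
  }
  dist_to_guide <- graph_distances(edges, guides)

  # guide correlates: non-guide genes tied to a guide above the threshold
  correlates <- unique(unlist(lapply(guides, function(gu) {
    nb <- adj[[gu]]
    nb[weight_of(gu, nb) > export_threshold]
  })))
  correlates <- setdiff(correlates, guides)

  guide_adjacent_hubs <- hubs[vapply(hubs, function(h) {
    any(guides %in% adj[[h]])
  }, logical(1))]

  domains_of <- function(gene) {
    if (is.null(annotations)) return(character(0))
    row <- annotations$interpro_ids[annotations$gene_id == gene]
    if (length(row) == 0L || is.na(row[1]) || row[1] == "") return(character(0))
    trimws(strsplit(row[1], ";")[[1]])
  }
  de_flag <- function(gene) {
    if (is.null(de)) return(FALSE)
    isTRUE(de$is_de[match(gene, de$gene_id)])
  }

  cand_genes <- setdiff(nodes, guides)
  rows <- lapply(cand_genes, function(g) {
    shared <- guide_adjacent_hubs[guide_adjacent_hubs %in% adj[[g]]]
    if (length(shared) == 0L && g %in% guide_adjacent_hubs) shared <- g
    in_pn <- any(vapply(pg$power_nodes, function(s) {
      g %in% s && length(intersect(setdiff(s, g), correlates)) > 0L
    }, logical(1)))
    dom_hits <- intersect(domains_of(g), preferred_domains)
    is_de <- de_flag(g)
    dist <- unname(dist_to_guide[g])
    passes <- length(shared) > 0L && dist < distance_max && in_pn
    data.frame(
      gene = g,
      min_guide_distance = dist,
      shared_hub = length(shared) > 0L,
      hub_id = if (length(shared)) shared[1L] else NA_character_,
      in_power_node_with_guide_correlate = in_pn,
      preferred_domain_hits = paste(dom_hits, collapse = ";"),
      is_de = is_de,
      passes_mandatory = passes,
      bonus_count = (length(dom_hits) > 0L) + is_de,
      max_guide_weight = max(c(0, weight_of(g, guides))),
      stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  ord <- order(!report$passes_mandatory, -report$bonus_count,
               report$min_guide_distance, -report$max_guide_weight,
               report$gene)
  report <- report[ord, , drop = FALSE]
  report$rank <- NA_integer_
  report$rank[report$passes_mandatory] <- seq_len(sum(report$passes_mandatory))
  rownames(report) <- NULL
  report
}
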