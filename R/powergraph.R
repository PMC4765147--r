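# Lossless power-graph compression.
#
# A power node is a set of genes; a power edge between two disjoint power
# nodes (S, T) states that every gene of S is connected to every gene of T
# in the original network (a biclique), and a power edge from a set to
# itself states that S is a clique.  Committed power nodes form a laminar
# family (pairwise disjoint or nested), decompression reproduces the
# original edge set exactly, and every power edge abstracts at least two
# original edges.

# collect every branch (including leaves) of an hclust tree as sets of
# label indices
hclust_branches <- function(h, labels) {
  merges <- h$merge
  sets <- vector("list", nrow(merges))
  out <- as.list(labels)
  for (i in seq_len(nrow(merges))) {
    grab <- function(j) if (j < 0) labels[-j] else sets[[j]]
    sets[[i]] <- sort(c(grab(merges[i, 1L]), grab(merges[i, 2L])))
    out[[length(out) + 1L]] <- sets[[i]]
  }
  unique(out)
}

# laminar compatibility of one set with a family of sets
laminar_ok <- function(s, family) {
  for (f in family) {
    inter <- length(intersect(s, f))
    if (inter > 0L && inter < length(s) && inter < length(f)) return(FALSE)
  }
  TRUE
}

validate_edge_frame <- function(edges) {
  stopifnot(is.data.frame(edges),
            all(c("gene_a", "gene_b") %in% names(edges)))
  a <- as.character(edges$gene_a); b <- as.character(edges$gene_b)
  if (any(a == b)) stop_ipnet("self-loops are not allowed")
  keys <- unique(edge_key(a, b))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(gene_a = vapply(parts, `[`, character(1), 1L),
             gene_b = vapply(parts, `[`, character(1), 2L),
             stringsAsFactors = FALSE)
}

#' Compress a network into a power graph
#'
#' Greedy lossless compression: candidate gene sets are taken from every
#' branch of an average-linkage clustering of the nodes by Jaccard
#' similarity of their neighbourhoods; candidate power edges are the
#' set pairs forming complete bicliques (and sets forming cliques) in the
#' original graph.  The candidate abstracting the most not-yet-covered
#' edges is committed repeatedly -- subject to laminarity of the power
#' node family -- until no candidate abstracts at least two uncovered
#' edges; remaining edges stay as residual (plain) edges.  Ties are
#' broken by the lexicographically smallest combined gene set, making the
#' result deterministic.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b` describing a
#'   simple undirected graph (no self-loops; duplicates collapsed).
#' @param min_degree optional pre-filter: nodes with degree below this
#'   are removed before compression (default 0, keep all).
#' @return an object of class `power_graph`: list with `power_nodes`
#'   (named list of gene sets), `power_edges` (data.frame `node_a`,
#'   `node_b` of power-node ids; `node_a == node_b` denotes a clique),
#'   `residual_edges` (data.frame `gene_a`, `gene_b`),
#'   `n_original_edges`, and `nodes`.
#' @examples
#' # K_{3,3} compresses to a single power edge
#' k33 <- expand.grid(gene_a = c("a1", "a2", "a3"),
#'                    gene_b = c("b1", "b2", "b3"),
#'                    stringsAsFactors = FALSE)
#' pg <- pg_compress(k33)
#' nrow(pg$power_edges)      # 1
#' pg_compression_ratio(pg)  # 1 - 1/9
#' @export
pg_compress <- function(edges, min_degree = 0) {
  min_degree <- check_count(min_degree, "min_degree")
  edges <- validate_edge_frame(edges)
  if (min_degree > 0L && nrow(edges) > 0L) {
    repeat {
      deg <- table(c(edges$gene_a, edges$gene_b))
      drop <- names(deg)[deg < min_degree]
      if (length(drop) == 0L) break
      edges <- edges[!(edges$gene_a %in% drop | edges$gene_b %in% drop), ,
                     drop = FALSE]
      if (nrow(edges) == 0L) break
    }
  }
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  empty <- list(power_nodes = list(),
                power_edges = data.frame(node_a = character(0),
                                         node_b = character(0),
                                         stringsAsFactors = FALSE),
                residual_edges = edges,
                n_original_edges = nrow(edges),
                nodes = nodes)
  class(empty) <- "power_graph"
  if (nrow(edges) == 0L || length(nodes) < 2L) return(empty)

  keys <- edge_key(edges$gene_a, edges$gene_b)
  edge_set <- new.env(parent = emptyenv())
  for (k in keys) assign(k, TRUE, envir = edge_set)
  has_edge <- function(a, b) {
    exists(edge_key(a, b), envir = edge_set, inherits = FALSE)
  }
  nbr <- lapply(setNames(nodes, nodes), function(v) {
    sort(unique(c(edges$gene_b[edges$gene_a == v],
                  edges$gene_a[edges$gene_b == v])))
  })

  # candidate sets from neighbourhood clustering
  if (length(nodes) == 2L) {
    branches <- c(as.list(nodes), list(nodes))
  } else {
    jac <- matrix(0, length(nodes), length(nodes),
                  dimnames = list(nodes, nodes))
    for (i in seq_along(nodes)) {
      for (j in seq_len(i - 1L)) {
        u <- length(union(nbr[[i]], nbr[[j]]))
        jac[i, j] <- jac[j, i] <-
          if (u == 0L) 0 else length(intersect(nbr[[i]], nbr[[j]])) / u
      }
    }
    branches <- hclust_branches(
      hclust(as.dist(1 - jac), method = "average"), nodes)
  }

  # candidate power edges: complete bicliques between disjoint branch
  # pairs, and cliques on single branches (>= 2 abstracted edges)
  full_biclique <- function(S, T) {
    for (s in S) for (t in T) if (!has_edge(s, t)) return(FALSE)
    TRUE
  }
  is_clique <- function(S) {
    for (i in seq_along(S)) {
      for (j in seq_len(i - 1L)) if (!has_edge(S[i], S[j])) return(FALSE)
    }
    TRUE
  }
  cands <- list()
  for (b in branches) {
    if (length(b) >= 3L && is_clique(b)) {
      cands[[length(cands) + 1L]] <- list(S = b, T = b, clique = TRUE)
    }
  }
  nb <- length(branches)
  for (i in seq_len(nb)) {
    for (j in seq_len(i - 1L)) {
      S <- branches[[i]]; T <- branches[[j]]
      if (length(S) * length(T) < 2L) next
      if (length(intersect(S, T)) > 0L) next
      if (full_biclique(S, T)) {
        cands[[length(cands) + 1L]] <- list(S = S, T = T, clique = FALSE)
      }
    }
  }
  expansions <- lapply(cands, function(cd) {
    if (cd$clique) {
      cmb <- combn(cd$S, 2L)
      edge_key(cmb[1L, ], cmb[2L, ])
    } else {
      grid <- expand.grid(a = cd$S, b = cd$T, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
      edge_key(grid$a, grid$b)
    }
  })
  tie_keys <- vapply(cands, function(cd) {
    paste(sort(unique(c(cd$S, cd$T))), collapse = ",")
  }, character(1))

  covered <- setNames(logical(length(keys)), keys)
  committed <- list()
  chosen <- list()
  active <- rep(TRUE, length(cands))
  while (any(active)) {
    gains <- rep(-1L, length(cands))
    for (ci in which(active)) {
      cd <- cands[[ci]]
      if (!laminar_ok(cd$S, committed) ||
          (!cd$clique && !laminar_ok(cd$T, committed))) {
        active[ci] <- FALSE
        next
      }
      gains[ci] <- sum(!covered[expansions[[ci]]])
    }
    best <- max(gains)
    if (best < 2L) break
    pick <- which(gains == best)
    pick <- pick[order(tie_keys[pick])][1L]
    cd <- cands[[pick]]
    covered[expansions[[pick]]] <- TRUE
    committed <- c(committed, list(cd$S), if (!cd$clique) list(cd$T))
    chosen[[length(chosen) + 1L]] <- cd
    active[pick] <- FALSE
  }

  # assemble: unique committed sets become named power nodes
  sets <- unique(committed)
  sets <- sets[order(-lengths(sets),
                     vapply(sets, paste, character(1), collapse = ","))]
  ids <- sprintf("pn%03d", seq_along(sets))
  set_id <- function(s) {
    ids[which(vapply(sets, identical, logical(1), y = s))[1L]]
  }
  power_edges <- if (length(chosen)) {
    data.frame(
      node_a = vapply(chosen, function(cd) set_id(cd$S), character(1)),
      node_b = vapply(chosen, function(cd)
        if (cd$clique) set_id(cd$S) else set_id(cd$T), character(1)),
      stringsAsFactors = FALSE)
  } else {
    data.frame(node_a = character(0), node_b = character(0),
               stringsAsFactors = FALSE)
  }
  residual <- edges[!covered[keys], , drop = FALSE]
  rownames(residual) <- NULL
  out <- list(power_nodes = setNames(sets, ids),
              power_edges = power_edges,
              residual_edges = residual,
              n_original_edges = nrow(edges),
              nodes = nodes)
  class(out) <- "power_graph"
  out
}

#' Decompress a power graph back to its edge list
#'
#' Expands every power edge (cross pairs for a biclique, 2-subsets for a
#' clique) and appends the residual edges; duplicates are collapsed.  By
#' construction of [pg_compress()] the result equals the original edge
#' set exactly.
#'
#' @param pg a `power_graph` object.
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
pg_decompress <- function(pg) {
  stopifnot(inherits(pg, "power_graph"))
  unknown <- setdiff(unique(c(pg$power_edges$node_a, pg$power_edges$node_b)),
                     names(pg$power_nodes))
  if (length(unknown)) {
    stop_ipnet("power edges reference unknown power nodes: ",
               paste(unknown, collapse = ", "))
  }
  pieces <- list(pg$residual_edges[, c("gene_a", "gene_b")])
  for (i in seq_len(nrow(pg$power_edges))) {
    S <- pg$power_nodes[[pg$power_edges$node_a[i]]]
    T <- pg$power_nodes[[pg$power_edges$node_b[i]]]
    if (identical(S, T)) {
      cmb <- combn(S, 2L)
      pieces[[length(pieces) + 1L]] <-
        data.frame(gene_a = cmb[1L, ], gene_b = cmb[2L, ],
                   stringsAsFactors = FALSE)
    } else {
      if (length(intersect(S, T))) {
        stop_ipnet("malformed hierarchy: overlapping power-edge endpoints")
      }
      grid <- expand.grid(gene_a = S, gene_b = T, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
      pieces[[length(pieces) + 1L]] <- grid
    }
  }
  validate_edge_frame(do.call(rbind, pieces))
}

#' Edge-reduction compression ratio of a power graph
#'
#' `1 - (number of power edges + number of residual edges) / number of
#' original edges`: the fraction of original edges eliminated by the
#' abstraction.
#'
#' @param pg a `power_graph` object.
#' @return a fraction in \[0, 1\].
#' @export
pg_compression_ratio <- function(pg) {
  stopifnot(inherits(pg, "power_graph"))
  if (pg$n_original_edges == 0L) {
    stop_ipnet("compression ratio undefined for an empty graph")
  }
  1 - (nrow(pg$power_edges) + nrow(pg$residual_edges)) / pg$n_original_edges
}

#' @export
print.power_graph <- function(x, ...) {
  cat("Power graph:", length(x$nodes), "nodes,", x$n_original_edges,
      "original edges\n")
  cat("  power nodes:", length(x$power_nodes),
      " power edges:", nrow(x$power_edges),
      " residual edges:", nrow(x$residual_edges), "\n")
  if (x$n_original_edges > 0L) {
    cat(sprintf("  compression ratio: %.3f\n", pg_compression_ratio(x)))
  }
  invisible(x)
}

#' Write a power graph to JSON
#'
#' @param pg a `power_graph` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_powergraph <- function(pg, path) {
  stopifnot(inherits(pg, "power_graph"))
  obj <- list(
    nodes = pg$nodes,
    power_nodes = pg$power_nodes,
    power_edges = pg$power_edges,
    residual_edges = pg$residual_edges,
    n_original_edges = pg$n_original_edges,
    compression_ratio = if (pg$n_original_edges > 0)
      pg_compression_ratio(pg) else NA,
    ratio_definition = "1 - (power_edges + residual_edges) / original_edges")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a power graph from JSON
#'
#' @param path file written by [write_powergraph()].
#' @return a `power_graph` object.
#' @export
read_powergraph <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pn <- lapply(obj$power_nodes, as.character)
  out <- list(power_nodes = pn,
              power_edges = as.data.frame(obj$power_edges,
                                          stringsAsFactors = FALSE),
              residual_edges = as.data.frame(obj$residual_edges,
                                             stringsAsFactors = FALSE),
              n_original_edges = as.integer(obj$n_original_edges),
              nodes = as.character(obj$nodes))
  if (nrow(out$power_edges) == 0L) {
    out$power_edges <- data.frame(node_a = character(0),
                                  node_b = character(0),
                                  stringsAsFactors = FALSE)
  }
  if (nrow(out$residual_edges) == 0L) {
    out$residual_edges <- data.frame(gene_a = character(0),
                                     gene_b = character(0),
                                     stringsAsFactors = FALSE)
  }
  class(out) <- "power_graph"
  out
}
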