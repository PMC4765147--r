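# Independent oracles and small fixture builders used across tests.

# brute-force O(n^3) topological overlap
tom_oracle <- function(a) {
  d <- a
  diag(d) <- 0
  n <- nrow(d)
  out <- diag(1, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- sum(vapply(seq_len(n), function(u) d[i, u] * d[u, j],
                      numeric(1)))
      out[i, j] <- (l + d[i, j]) /
        (min(sum(d[i, ]), sum(d[j, ])) + 1 - d[i, j])
    }
  }
  out
}

random_symmetric_adjacency <- function(n, seed) {
  set.seed(seed)
  a <- matrix(runif(n * n), n)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

# Erdos-Renyi edge list on n nodes
er_edges <- function(n, p, seed) {
  set.seed(seed)
  idx <- which(upper.tri(matrix(0, n, n)) & matrix(runif(n * n), n) < p,
               arr.ind = TRUE)
  data.frame(gene_a = sprintf("g%02d", idx[, 1L]),
             gene_b = sprintf("g%02d", idx[, 2L]),
             stringsAsFactors = FALSE)
}

complete_bipartite <- function(na, nb) {
  expand.grid(gene_a = sprintf("a%d", seq_len(na)),
              gene_b = sprintf("b%d", seq_len(nb)),
              stringsAsFactors = FALSE)
}

clique_edges <- function(ids) {
  cmb <- combn(ids, 2L)
  data.frame(gene_a = cmb[1L, ], gene_b = cmb[2L, ],
             stringsAsFactors = FALSE)
}

edge_set <- function(edges) {
  sort(paste(pmin(edges$gene_a, edges$gene_b),
             pmax(edges$gene_a, edges$gene_b)))
}

same_edge_set <- function(e1, e2) identical(edge_set(e1), edge_set(e2))

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# a 20-sample two-genotype design used by several network tests
design20 <- function() {
  simulate_design(stages = c("12DAP", "21DAP"), replicates = 5)
}

design24 <- function() simulate_design(replicates = 4)
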