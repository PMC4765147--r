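# RPKM normalisation, gene filtering, and differential-expression calling.

#' Reads per kilobase of exon per million mapped reads
#'
#' `RPKM[g, s] = counts[g, s] / (mapped_millions[s] * length_kb[g])`.
#'
#' @param counts genes x samples matrix of non-negative integer read
#'   counts.
#' @param length_kb per-gene exon length in kilobases (> 0).
#' @param mapped_millions per-sample total mapped reads in millions (> 0);
#'   defaults to the column sums of `counts` / 1e6.
#' @return genes x samples RPKM matrix.
#' @examples
#' compute_rpkm(matrix(10), length_kb = 1, mapped_millions = 1)  # 10
#' @export
compute_rpkm <- function(counts, length_kb,
                         mapped_millions = colSums(counts) / 1e6) {
  counts <- as_numeric_matrix(counts, "counts")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_ipnet("counts must be non-negative integers")
  }
  if (length(length_kb) != nrow(counts)) {
    stop_ipnet("`length_kb` must have one value per gene")
  }
  bad_g <- which(!is.finite(length_kb) | length_kb <= 0)
  if (length(bad_g)) {
    stop_ipnet("non-positive exon length for gene(s): ",
               paste(head(rownames(counts)[bad_g] %||% bad_g, 5),
                     collapse = ", "))
  }
  if (length(mapped_millions) != ncol(counts)) {
    stop_ipnet("`mapped_millions` must have one value per sample")
  }
  bad_s <- which(!is.finite(mapped_millions) | mapped_millions <= 0)
  if (length(bad_s)) {
    stop_ipnet("non-positive library size for sample(s): ",
               paste(head(colnames(counts)[bad_s] %||% bad_s, 5),
                     collapse = ", "))
  }
  counts / outer(as.numeric(length_kb), as.numeric(mapped_millions))
}

#' Filter uninformative genes
#'
#' Removes genes with more than `max_bad` entries that are missing or
#' zero, preserving the order of the surviving genes.  Missing means an
#' `NA`/`NaN` cell; zeros count identically.
#'
#' @param expr genes x samples expression matrix.
#' @param max_bad maximum tolerated number of missing-or-zero entries per
#'   gene (default 3; strict greater-than removal).
#' @return the filtered matrix.
#' @export
filter_genes <- function(expr, max_bad = 3) {
  expr <- as_numeric_matrix(expr, "expr")
  max_bad <- check_count(max_bad, "max_bad")
  bad <- rowSums(is.na(expr) | expr == 0)
  keep <- bad <= max_bad
  if (!any(keep)) message("filter_genes: no genes survive the filter")
  expr[keep, , drop = FALSE]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement, preserving input order (delegates to [stats::p.adjust()]
#' after validating the input).
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1)) {
    stop_ipnet("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

# method-of-moments NB dispersion, pooled across groups, floored
mom_dispersion <- function(q, group, floor = 1e-8) {
  groups <- unique(group)
  num <- 0; den <- 0
  for (g in groups) {
    sub <- q[, group == g, drop = FALSE]
    m <- rowMeans(sub)
    v <- apply(sub, 1L, var)
    a <- ifelse(m > 0, (v - m) / m^2, 0)
    w <- ncol(sub) - 1L
    num <- num + w * a
    den <- den + w
  }
  pmax(num / den, floor)
}

#' Call differentially expressed genes between two groups
#'
#' Counts are normalised by total library size; log2 fold changes come
#' from the normalised group means with a pseudo-count of 0.5 added to
#' both means.  P-values come from a two-sided exact negative-binomial
#' test on the group count sums, with a gene-wise method-of-moments
#' dispersion estimate floored at 1e-8 (a documented, simpler stand-in
#' for full DESeq-style dispersion shrinkage -- the decision gate here is
#' the fold-change / FDR rule, not the dispersion machinery).  A gene is
#' flagged differentially expressed when `|log2_fc| >= log2(fc_min)` and
#' `fdr < fdr_max`.
#'
#' @param counts genes x samples matrix of non-negative integer counts.
#' @param group length-`ncol(counts)` vector with exactly two levels; the
#'   fold change is group2 vs group1 (order of first appearance).
#' @param fc_min fold-change gate (default 2, inclusive).
#' @param fdr_max FDR gate (default 0.01, exclusive).
#' @return data.frame with columns `gene_id`, `log2_fc`, `p_value`,
#'   `fdr`, `is_de`.
#' @export
call_degs <- function(counts, group, fc_min = 2, fdr_max = 0.01) {
  counts <- as_numeric_matrix(counts, "counts")
  group <- as.character(group)
  if (length(group) != ncol(counts)) {
    stop_ipnet("`group` must have one label per sample")
  }
  levels <- unique(group)
  if (length(levels) != 2L) stop_ipnet("exactly two groups are required")
  i1 <- group == levels[1]; i2 <- group == levels[2]
  if (sum(i1) < 2L || sum(i2) < 2L) {
    stop_ipnet("at least 2 samples per group are required")
  }
  libsize <- colSums(counts)
  if (any(libsize == 0)) stop_ipnet("sample with zero total counts")
  sf <- libsize / mean(libsize)
  q <- sweep(counts, 2L, sf, "/")
  m1 <- rowMeans(q[, i1, drop = FALSE])
  m2 <- rowMeans(q[, i2, drop = FALSE])
  log2_fc <- log2((m2 + 0.5) / (m1 + 0.5))
  alpha <- mom_dispersion(q, group)
  mu0 <- rowMeans(q)
  s1 <- rowSums(counts[, i1, drop = FALSE])
  s2 <- rowSums(counts[, i2, drop = FALSE])
  sfa <- sum(sf[i1]); sfb <- sum(sf[i2])
  na <- sum(i1); nb <- sum(i2)
  p_value <- vapply(seq_len(nrow(counts)), function(g) {
    exact_nb_p(s1[g], s2[g], mu0[g] * sfa, mu0[g] * sfb,
               na / alpha[g], nb / alpha[g])
  }, numeric(1))
  fdr <- bh_fdr(p_value)
  data.frame(
    gene_id = rownames(counts) %||% sprintf("gene%05d", seq_len(nrow(counts))),
    log2_fc = log2_fc, p_value = p_value, fdr = fdr,
    is_de = abs(log2_fc) >= log2(fc_min) & fdr < fdr_max,
    stringsAsFactors = FALSE, row.names = NULL)
}

# two-sided exact NB test on group sums, conditional on the total:
# enumerate all splits (a, total - a) and sum the joint probabilities no
# larger than the observed one
exact_nb_p <- function(s1, s2, mu_a, mu_b, size_a, size_b) {
  total <- s1 + s2
  if (total == 0) return(1)
  ks <- 0:total
  pa <- dnbinom(ks, mu = mu_a, size = size_a)
  pb <- dnbinom(total - ks, mu = mu_b, size = size_b)
  joint <- pa * pb
  denom <- sum(joint)
  if (denom == 0) return(1)
  obs <- joint[s1 + 1L]
  min(1, sum(joint[joint <= obs * (1 + 1e-7)]) / denom)
}
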