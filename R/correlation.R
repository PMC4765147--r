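# Gene-gene correlation and soft thresholding.

# rank rows with average ties (Spearman preparation)
row_ranks <- function(x) {
  t(apply(x, 1L, rank, ties.method = "average"))
}

#' Gene-gene correlation matrix (blockwise)
#'
#' Computes the genes x genes correlation matrix, Spearman by default
#' (Pearson on within-gene ranks with average ranks for ties).  Genes
#' with zero variance across samples are excluded with a warning; their
#' ids are recorded in the `"excluded"` attribute.  The computation is
#' split into row blocks of at most `max_block_size` genes for memory
#' control; the result is identical to the whole-matrix computation.
#'
#' @param expr genes x samples matrix with at least 4 samples.
#' @param method "spearman" (default) or "pearson".
#' @param max_block_size maximum genes per block (default 3500).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(expr, method = c("spearman", "pearson"),
                               max_block_size = 3500) {
  method <- match.arg(method)
  expr <- as_numeric_matrix(expr, "expr")
  n <- ncol(expr)
  if (n < 4L) stop_ipnet("at least 4 samples are required (got ", n, ")")
  max_block_size <- check_count(max_block_size, "max_block_size", min = 1L)
  sds <- apply(expr, 1L, sd)
  zero_var <- !is.finite(sds) | sds == 0
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance gene(s) excluded from the ",
            "correlation matrix")
    expr <- expr[!zero_var, , drop = FALSE]
  }
  x <- if (method == "spearman") row_ranks(expr) else expr
  # standardise rows; Pearson of rows is then tcrossprod / (n - 1)
  x <- x - rowMeans(x)
  x <- x / sqrt(rowSums(x^2) / (n - 1))
  g <- nrow(x)
  blocks <- split(seq_len(g), ceiling(seq_len(g) / max_block_size))
  corr <- matrix(NA_real_, g, g, dimnames = list(rownames(x), rownames(x)))
  for (bi in blocks) {
    for (bj in blocks) {
      corr[bi, bj] <- tcrossprod(x[bi, , drop = FALSE],
                                 x[bj, , drop = FALSE]) / (n - 1)
    }
  }
  corr[corr > 1] <- 1
  corr[corr < -1] <- -1
  diag(corr) <- 1
  attr(corr, "excluded") <- names(zero_var)[zero_var] %||% character(0)
  corr
}

#' Soft-thresholded adjacency from a correlation matrix
#'
#' Unsigned weighted-network adjacency `|corr|^beta` (signed mode maps
#' correlation through `(1 + corr) / 2` before raising to `beta`).  The
#' diagonal is set to 1.
#'
#' @param corr symmetric correlation matrix.
#' @param beta soft-threshold power (>= 1).
#' @param signed use the signed transform.
#' @return adjacency matrix with entries in \[0, 1\].
#' @export
adjacency_matrix <- function(corr, beta = 6, signed = FALSE) {
  corr <- as_numeric_matrix(corr, "corr")
  check_number(beta, "beta", min = 1)
  check_flag(signed, "signed")
  a <- if (signed) ((1 + corr) / 2)^beta else abs(corr)^beta
  diag(a) <- 1
  a
}

# scale-free fit index: R^2 of log10(freq) ~ log10(mean k), 10 bins,
# WGCNA sign convention (index 0 when the slope is positive, since a
# scale-free degree distribution must decay)
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[is.finite(k) & k > 0]
  if (length(k) < n_bins || diff(range(k)) == 0) return(NA_real_)
  breaks <- seq(min(k), max(k), length.out = n_bins + 1L)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  freq <- tabulate(bin, nbins = n_bins)
  kmean <- tapply(k, bin, mean)
  ok <- freq > 0 & is.finite(kmean) & kmean > 0
  if (sum(ok) < 3L) return(NA_real_)
  fit <- lm(log10(freq[ok]) ~ log10(kmean[ok]))
  r2 <- summary(fit)$r.squared
  slope <- coef(fit)[2L]
  if (is.na(slope) || slope >= 0) 0 else r2
}

#' Conventional soft-threshold power for a given sample size
#'
#' The widely used rule of thumb for weighted co-expression networks:
#' with few samples the correlation noise floor rises, so a larger power
#' is needed to suppress spurious adjacency.  For unsigned networks the
#' convention is power 9 below 20 samples, 8 for 20-30, 7 for 30-40 and 6
#' above 40 (doubled for signed networks).
#'
#' @param n_samples number of samples.
#' @param signed signed network.
#' @return the conventional power.
#' @export
default_beta <- function(n_samples, signed = FALSE) {
  n_samples <- check_count(n_samples, "n_samples", min = 4L)
  b <- if (n_samples < 20) 9 else if (n_samples < 30) 8 else
    if (n_samples < 40) 7 else 6
  if (check_flag(signed, "signed")) 2 * b else b
}

#' Select the soft-threshold power for scale-free topology
#'
#' For each candidate power the unsigned adjacency is formed and the
#' scale-free fit index of its connectivity distribution computed (linear
#' regression of log10 frequency on log10 binned connectivity over 10
#' bins).  The smallest candidate whose index reaches `target_r2` is
#' returned; when none does (e.g. pure-noise expression), the
#' conventional default power 6 is returned with a warning.
#'
#' @param corr correlation matrix.
#' @param candidate_betas candidate powers, default 1:20.
#' @param target_r2 required fit index (default 0.8).
#' @param signed signed adjacency transform.
#' @return list with `beta` (the selected power) and `fits` (data.frame
#'   of candidate powers and their fit indices).
#' @export
pick_soft_threshold <- function(corr, candidate_betas = 1:20,
                                target_r2 = 0.8, signed = FALSE) {
  if (length(candidate_betas) == 0L) {
    stop_ipnet("`candidate_betas` must be non-empty")
  }
  candidate_betas <- sort(unique(candidate_betas))
  fits <- data.frame(beta = candidate_betas, fit_r2 = NA_real_)
  for (i in seq_along(candidate_betas)) {
    a <- adjacency_matrix(corr, candidate_betas[i], signed = signed)
    diag(a) <- 0
    fits$fit_r2[i] <- scale_free_fit(rowSums(a))
  }
  ok <- which(!is.na(fits$fit_r2) & fits$fit_r2 >= target_r2)
  if (length(ok) == 0L) {
    warning("no candidate power reached a scale-free fit of ", target_r2,
            "; falling back to beta = 6")
    return(list(beta = 6, fits = fits))
  }
  list(beta = fits$beta[ok[1L]], fits = fits)
}
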