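# Topological overlap, module detection, eigengenes.

#' Topological overlap matrix
#'
#' Unsigned topological overlap of a weighted adjacency:
#' `TOM_ij = (sum_u a_iu * a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j`, with connectivity `k_i = sum_u a_iu` taken over a
#' zero-diagonal adjacency, and `TOM_ii = 1`.  High overlap means two
#' genes are directly connected and share much of their neighbourhood.
#'
#' @param adjacency symmetric matrix with entries in \[0, 1\].
#' @return TOM matrix, symmetric, entries in \[0, 1\], unit diagonal.
#' @export
compute_tom <- function(adjacency) {
  a <- as_numeric_matrix(adjacency, "adjacency")
  if (nrow(a) != ncol(a)) stop_ipnet("adjacency must be square")
  if (any(a < 0 | a > 1)) stop_ipnet("adjacency entries must lie in [0, 1]")
  if (max(abs(a - t(a))) > 1e-12) stop_ipnet("adjacency must be symmetric")
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  dimnames(tom) <- dimnames(adjacency)
  tom
}

# fixed colour vocabulary in the WGCNA tradition: the classic head of the
# sequence, then every remaining distinct base colour (greys, whites and
# blacks stay reserved for unassigned genes)
module_colour_sequence <- function() {
  classic <- c("turquoise", "blue", "brown", "yellow", "green", "red",
               "pink", "magenta", "purple", "greenyellow", "tan",
               "salmon", "cyan", "midnightblue", "lightcyan",
               "lightgreen", "lightyellow", "royalblue", "darkred",
               "darkgreen", "darkturquoise", "orange", "darkorange",
               "skyblue", "saddlebrown", "steelblue", "paleturquoise",
               "violet", "darkolivegreen", "darkmagenta")
  pool <- grDevices::colors(distinct = TRUE)
  drop <- grepl("^(gr[ae]y|white|black|snow|ivory)", pool)
  c(classic, sort(setdiff(pool[!drop], classic)))
}

#' Detect co-expression modules from a topological overlap matrix
#'
#' Average-linkage hierarchical clustering on the dissimilarity
#' `1 - TOM`, cut statically at `cut_height`; branches with at least
#' `min_module_size` members become modules, everything else is assigned
#' to `"grey"`.  Modules are named by a fixed colour vocabulary in
#' decreasing size order (ties broken by lowest gene index), so module
#' names are deterministic given the input.  This static cut is a
#' deliberate simplification of the dynamic tree-cut family of
#' algorithms: it is deterministic, easily testable, and adequate for
#' well-separated modules.
#'
#' @param tom topological overlap (or other similarity) matrix in
#'   \[0, 1\].
#' @param min_module_size minimum genes per module (default 30).
#' @param cut_height static dendrogram cut height in \[0, 1\]
#'   (default 0.99).
#' @return named character vector mapping gene -> colour label.
#' @export
detect_modules <- function(tom, min_module_size = 30, cut_height = 0.99) {
  tom <- as_numeric_matrix(tom, "tom")
  min_module_size <- check_count(min_module_size, "min_module_size", 1L)
  check_number(cut_height, "cut_height", min = 0, max = 1)
  genes <- rownames(tom) %||% sprintf("gene%05d", seq_len(nrow(tom)))
  h <- hclust(as.dist(1 - tom), method = "average")
  # exact ties can leave numerically non-monotone merge heights, which
  # cutree rejects; enforce monotonicity before the static cut
  h$height <- cummax(h$height)
  cl <- cutree(h, h = cut_height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_module_size]
  module_of <- setNames(rep("grey", length(genes)), genes)
  if (length(keep)) {
    first_idx <- vapply(keep, function(id) min(which(cl == id)), integer(1))
    ord <- order(-as.integer(sizes[keep]), first_idx)
    colours <- module_colour_sequence()
    for (i in seq_along(ord)) {
      module_of[cl == as.integer(keep[ord[i]])] <- colours[i]
    }
  }
  module_of
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of its
#' gene-standardised expression submatrix across samples, scaled to unit
#' variance and sign-oriented so that its correlation with the module's
#' mean expression profile is non-negative.  Grey (unassigned) genes are
#' ignored.  A single-gene module returns that gene's standardised
#' profile (with a message).
#'
#' @param expr genes x samples expression matrix.
#' @param module_of named gene -> module label vector from
#'   [detect_modules()].
#' @return modules x samples matrix of eigengene values.
#' @export
module_eigengenes <- function(expr, module_of) {
  expr <- as_numeric_matrix(expr, "expr")
  genes <- intersect(names(module_of), rownames(expr))
  module_of <- module_of[genes]
  labels <- setdiff(unique(module_of), "grey")
  if (length(labels) == 0L) stop_ipnet("no non-grey modules")
  n <- ncol(expr)
  me <- matrix(NA_real_, length(labels), n,
               dimnames = list(labels, colnames(expr)))
  for (lab in labels) {
    members <- genes[module_of == lab]
    sub <- expr[members, , drop = FALSE]
    sds <- apply(sub, 1L, sd)
    sub <- sub[sds > 0, , drop = FALSE]
    if (nrow(sub) == 0L) stop_ipnet("module ", lab, " has no variable genes")
    z <- (sub - rowMeans(sub)) / apply(sub, 1L, sd)
    if (nrow(z) == 1L) {
      message("module ", lab, " has a single gene; returning its ",
              "standardised profile")
      eig <- as.numeric(z)
    } else {
      sv <- La.svd(t(z), nu = 1L, nv = 0L)
      eig <- sv$u[, 1L]
    }
    eig <- (eig - mean(eig)) / sd(eig)
    mean_profile <- colMeans(z)
    if (cor(eig, mean_profile) < 0) eig <- -eig
    me[lab, ] <- eig
  }
  me
}
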