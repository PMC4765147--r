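# Germplasm screening by the Q content-ratio statistic.

#' Absolute log2 content-ratio (Q) between two lines
#'
#' \eqn{Q = |log2(x_i / x_j)|} where `x_i` and `x_j` are the IP6 (phytic
#' acid phosphorus) contents of two inbred lines, in mg per g of seed.
#' Q is symmetric in its arguments and invariant to rescaling both
#' contents by a common constant.  A Q above 0.58 (= log2 1.5) marks a
#' pair with at least a 1.5-fold content contrast.
#'
#' @param x_i,x_j strictly positive contents (vectorised).
#' @return dimensionless Q values.
#' @examples
#' compute_q(4, 2)    # 1
#' compute_q(2.4, 4)  # |log2(0.6)| = 0.737
#' @export
compute_q <- function(x_i, x_j) {
  if (any(!is.finite(x_i) | x_i <= 0) || any(!is.finite(x_j) | x_j <= 0)) {
    stop_ipnet("contents must be strictly positive and finite")
  }
  abs(log2(x_i / x_j))
}

#' Screen line pairs with a large, environment-stable content contrast
#'
#' A pair is retained when (a) Q exceeds `q_threshold` in every
#' environment where both lines are measured, and (b) a one-sample,
#' one-sided t-test of the per-environment Q values against the threshold
#' (alternative: mean Q greater) gives p below `alpha`.  Pairs with fewer
#' than two usable environments are skipped with a warning.  When the
#' per-environment Q values are constant, the t statistic is undefined and
#' the test degenerates to the threshold comparison itself (p of 0 or 1).
#'
#' @param content lines x environments matrix of positive contents with
#'   line ids as row names (missing values allowed), or the list returned
#'   by [simulate_germplasm()].
#' @param pairs optional data.frame with columns `line_i`, `line_j` naming
#'   the pairs to evaluate (e.g. a declared high-group x low-group
#'   pairing); defaults to all unordered pairs of lines.
#' @param q_threshold Q cutoff (default 0.58 = log2 1.5).
#' @param alpha significance level for the stability test.
#' @param keep_all return all evaluated pairs (with a `stable` flag)
#'   rather than the stable subset.
#' @return data.frame with columns `line_i`, `line_j`, one `q_<env>`
#'   column per environment, `mean_q`, `stability_p`, `stable`.
#' @export
screen_stable_pairs <- function(content, pairs = NULL, q_threshold = 0.58,
                                alpha = 0.05, keep_all = FALSE) {
  if (is.list(content) && !is.data.frame(content) &&
      !is.matrix(content)) {
    content <- content$content
  }
  content <- as_numeric_matrix(content, "content")
  if (any(content <= 0, na.rm = TRUE)) {
    stop_ipnet("content values must be strictly positive where present")
  }
  if (ncol(content) < 2L) stop_ipnet("at least 2 environments required")
  lines <- rownames(content) %||% as.character(seq_len(nrow(content)))
  rownames(content) <- lines
  if (is.null(pairs)) {
    if (length(lines) > 1000L) {
      warning("enumerating all pairs over ", length(lines),
              " lines is quadratic; consider supplying `pairs`")
    }
    idx <- combn(lines, 2L)
    pairs <- data.frame(line_i = idx[1L, ], line_j = idx[2L, ],
                        stringsAsFactors = FALSE)
  }
  envs <- colnames(content) %||% sprintf("env%d", seq_len(ncol(content)))
  res <- vector("list", nrow(pairs))
  skipped <- 0L
  for (p in seq_len(nrow(pairs))) {
    li <- pairs$line_i[p]; lj <- pairs$line_j[p]
    xi <- content[li, ]; xj <- content[lj, ]
    usable <- is.finite(xi) & is.finite(xj)
    if (sum(usable) < 2L) {
      skipped <- skipped + 1L
      next
    }
    q <- rep(NA_real_, length(envs))
    q[usable] <- compute_q(xi[usable], xj[usable])
    mean_q <- mean(q[usable])
    if (sd(q[usable]) == 0) {
      p_val <- if (mean_q > q_threshold) 0 else 1
    } else {
      p_val <- t.test(q[usable], mu = q_threshold,
                      alternative = "greater")$p.value
    }
    stable <- all(q[usable] > q_threshold) && p_val < alpha
    row <- data.frame(line_i = li, line_j = lj, stringsAsFactors = FALSE)
    row[paste0("q_", envs)] <- as.list(q)
    row$mean_q <- mean_q
    row$stability_p <- p_val
    row$stable <- stable
    res[[p]] <- row
  }
  if (skipped > 0L) {
    warning(skipped, " pair(s) skipped: fewer than 2 environments with ",
            "both lines measured")
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(line_i = character(0), line_j = character(0),
                      mean_q = numeric(0), stability_p = numeric(0),
                      stable = logical(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  if (keep_all) out else out[out$stable, , drop = FALSE]
}
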