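# Module-metabolite correlation and selection.

#' Correlate module eigengenes with metabolite profiles
#'
#' Computes the correlation of every module eigengene with every
#' metabolite over the shared samples, with a two-sided p-value from the
#' t approximation `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees
#' of freedom.  A record is flagged `selected` when `|r| > r_min` (strict)
#' and `p < p_max` (strict) -- the usual gate for calling a module
#' metabolite-associated.
#'
#' @param eigengenes modules x samples matrix ([module_eigengenes()]).
#' @param metabolites metabolites x samples matrix; columns are matched to
#'   the eigengene samples by name (an error lists unmatched ids).
#' @param method correlation method ("pearson" default, or "spearman").
#' @param r_min correlation magnitude threshold (default 0.8).
#' @param p_max p-value threshold (default 0.01).
#' @return data.frame with columns `module`, `metabolite`, `r`, `p`,
#'   `selected`.
#' @export
module_trait_correlations <- function(eigengenes, metabolites,
                                      method = c("pearson", "spearman"),
                                      r_min = 0.8, p_max = 0.01) {
  method <- match.arg(method)
  eigengenes <- as_numeric_matrix(eigengenes, "eigengenes")
  metabolites <- as_numeric_matrix(metabolites, "metabolites")
  se <- colnames(eigengenes); sm <- colnames(metabolites)
  if (!is.null(se) || !is.null(sm)) {
    shared <- intersect(se, sm)
    unmatched <- c(setdiff(se, sm), setdiff(sm, se))
    if (length(unmatched)) {
      stop_ipnet("sample ids do not match between eigengenes and ",
                 "metabolites: ", paste(unmatched, collapse = ", "))
    }
    metabolites <- metabolites[, se, drop = FALSE]
  } else if (ncol(eigengenes) != ncol(metabolites)) {
    stop_ipnet("eigengenes and metabolites have different sample counts")
  }
  n <- ncol(eigengenes)
  if (n < 4L) stop_ipnet("at least 4 shared samples are required")
  r <- cor(t(eigengenes), t(metabolites), method = method)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  records <- expand.grid(module = rownames(eigengenes) %||%
                           seq_len(nrow(eigengenes)),
                         metabolite = rownames(metabolites) %||%
                           seq_len(nrow(metabolites)),
                         stringsAsFactors = FALSE,
                         KEEP.OUT.ATTRS = FALSE)
  records$r <- as.vector(r)
  records$p <- as.vector(p)
  records$selected <- abs(records$r) > r_min & records$p < p_max
  records
}

#' Distinct modules passing the module-metabolite selection gate
#'
#' Applies `|r| > r_min` and `p < p_max` (both strict) to a table of
#' module-metabolite correlation records and returns the distinct module
#' labels among the passing records, in first-appearance order.  The
#' operation is idempotent and order-stable.
#'
#' @param records data.frame with columns `module`, `r`, `p` (e.g. from
#'   [module_trait_correlations()], or a published correlation table).
#' @param r_min,p_max selection thresholds.
#' @return character vector of distinct selected module labels.
#' @examples
#' recs <- data.frame(module = c("a", "b"), r = c(0.9, 0.5),
#'                    p = c(1e-4, 0.2))
#' select_significant_modules(recs)
#' @export
select_significant_modules <- function(records, r_min = 0.8, p_max = 0.01) {
  stopifnot(all(c("module", "r", "p") %in% names(records)))
  sel <- abs(records$r) > r_min & records$p < p_max
  unique(as.character(records$module[sel]))
}
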