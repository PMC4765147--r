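# Synthetic-data generators with planted structure.
#
# Every generator is a pure function of its arguments including `seed`, so
# a fixed seed reproduces the output byte for byte.  Each generator emits a
# `truth` component holding the planted structure; downstream recovery
# tests read the truth, never re-derive it.

#' Sample design for a two-genotype developmental series
#'
#' Builds the sample-metadata table for a genotype x stage x replicate
#' design, emulating a kernel developmental RNA-Seq series (a high- and a
#' low-phytic-acid inbred line sampled at several days after pollination).
#'
#' @param genotypes character vector of genotype labels.
#' @param stages character vector of developmental-stage labels.
#' @param replicates number of replicates per genotype x stage cell.
#' @return data.frame with columns `sample_id`, `genotype`, `stage`,
#'   `replicate`; one row per sample.
#' @examples
#' simulate_design()
#' @export
simulate_design <- function(genotypes = c("HPA", "LPA"),
                            stages = c("12DAP", "21DAP", "30DAP"),
                            replicates = 2) {
  replicates <- check_count(replicates, "replicates", min = 1L)
  grid <- expand.grid(replicate = seq_len(replicates), stage = stages,
                      genotype = genotypes, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("genotype", "stage", "replicate")]
  grid$sample_id <- sprintf("%s_%s_r%d", grid$genotype, grid$stage,
                            grid$replicate)
  grid[, c("sample_id", "genotype", "stage", "replicate")]
}

#' Specify planted co-expression modules
#'
#' @param n_genes genes per module (recycled against `loading`).
#' @param loading correlation-scale factor loading in (0, 1]; every gene of
#'   the module is `loading * factor + sqrt(1 - loading^2) * noise`.
#' @return data.frame with columns `module_id`, `n_genes`, `loading`.
#' @export
module_spec <- function(n_genes = 50, loading = 0.9) {
  k <- max(length(n_genes), length(loading))
  n_genes <- rep_len(as.integer(n_genes), k)
  loading <- rep_len(as.numeric(loading), k)
  if (any(n_genes < 1L)) stop_ipnet("module `n_genes` must be >= 1")
  if (any(loading <= 0 | loading > 1)) {
    stop_ipnet("module `loading` must be in (0, 1]")
  }
  data.frame(module_id = sprintf("M%02d", seq_len(k)),
             n_genes = n_genes, loading = loading,
             stringsAsFactors = FALSE)
}

#' Simulate an expression matrix with planted co-expressed modules
#'
#' Each module is driven by one latent per-sample factor; gene `g` of a
#' module with loading `a` is `baseline + a * factor + sqrt(1 - a^2) * eps`
#' with `eps` i.i.d. standard normal.  Background genes are pure noise
#' around the baseline.  The single-factor model is the minimal generator
#' of block-correlated expression and makes eigengene recovery directly
#' interpretable: the population correlation of an eigengene with its
#' factor approaches 1 as the module grows.
#'
#' @param modules data.frame from [module_spec()].
#' @param n_background number of unstructured background genes.
#' @param design sample table from [simulate_design()]; at least 4 samples.
#' @param seed integer seed.
#' @param baseline additive expression baseline (log2-like units); keeps
#'   emitted values positive in practice.
#' @param factors optional matrix (modules x samples) of latent factor
#'   profiles; defaults to i.i.d. standard normal draws, standardised.
#' @return list with `expr` (genes x samples matrix), `samples` (the
#'   design), and `truth` (list: `module_of` named gene -> module_id vector
#'   with "background" for noise genes, `factors` modules x samples,
#'   `modules` the spec).
#' @examples
#' sim <- simulate_expression(module_spec(c(20, 20), 0.9),
#'                            n_background = 50, seed = 1)
#' dim(sim$expr)
#' @export
simulate_expression <- function(modules = module_spec(),
                                n_background = 400,
                                design = simulate_design(),
                                seed = 1,
                                baseline = 8,
                                factors = NULL) {
  n_background <- check_count(n_background, "n_background")
  n <- nrow(design)
  if (n < 4L) {
    stop_ipnet("at least 4 samples are required (got ", n,
               "); correlation is degenerate below that")
  }
  set.seed(seed)
  k <- nrow(modules)
  if (is.null(factors)) {
    factors <- matrix(rnorm(k * n), nrow = k)
  } else {
    factors <- as_numeric_matrix(factors, "factors")
    if (ncol(factors) != n || nrow(factors) != k) {
      stop_ipnet("`factors` must be ", k, " modules x ", n, " samples")
    }
  }
  # standardise each factor so loadings are on the correlation scale
  factors <- t(apply(factors, 1L, function(f) (f - mean(f)) / sd(f)))
  if (k == 1L) factors <- matrix(factors, nrow = 1L)
  rownames(factors) <- modules$module_id
  colnames(factors) <- design$sample_id

  blocks <- vector("list", k + 1L)
  module_of <- character(0)
  gene_ids <- character(0)
  g0 <- 0L
  for (m in seq_len(k)) {
    ng <- modules$n_genes[m]
    a <- modules$loading[m]
    eps <- matrix(rnorm(ng * n), nrow = ng)
    blocks[[m]] <- baseline + a * matrix(factors[m, ], nrow = ng,
                                         ncol = n, byrow = TRUE) +
      sqrt(1 - a^2) * eps
    ids <- sprintf("gene%05d", g0 + seq_len(ng))
    g0 <- g0 + ng
    gene_ids <- c(gene_ids, ids)
    module_of <- c(module_of, rep(modules$module_id[m], ng))
  }
  if (n_background > 0L) {
    blocks[[k + 1L]] <- baseline + matrix(rnorm(n_background * n),
                                          nrow = n_background)
    ids <- sprintf("gene%05d", g0 + seq_len(n_background))
    gene_ids <- c(gene_ids, ids)
    module_of <- c(module_of, rep("background", n_background))
  }
  expr <- do.call(rbind, blocks[lengths(lapply(blocks, length)) > 0])
  dimnames(expr) <- list(gene_ids, design$sample_id)
  names(module_of) <- gene_ids
  list(expr = expr, samples = design,
       truth = list(module_of = module_of, factors = factors,
                    modules = modules))
}

#' Simulate metabolite profiles tied to planted module factors
#'
#' A metabolite targeting module `m` with correlation `r0` is generated as
#' `r0 * factor_m + sqrt(1 - r0^2) * eps` over samples.  Metabolites are
#' generated against the latent factors, not the estimated eigengenes, so
#' any recovery test also absorbs eigengene estimation error.  Negative
#' `r0` plants a negatively correlated metabolite; `module_id = NA` plants
#' an independent (pure-noise) metabolite.
#'
#' @param truth the `truth` component of [simulate_expression()].
#' @param targets data.frame with columns `metabolite`, `module_id`, `r0`.
#' @param seed integer seed.
#' @return list with `metabolites` (metabolites x samples matrix) and
#'   `targets` (the planted mapping).
#' @export
simulate_metabolites <- function(truth, targets, seed = 1) {
  stopifnot(is.data.frame(targets),
            all(c("metabolite", "module_id", "r0") %in% names(targets)))
  if (any(abs(targets$r0) > 1, na.rm = TRUE)) stop_ipnet("|r0| must be <= 1")
  targets$r0[is.na(targets$module_id)] <- NA_real_
  factors <- truth$factors
  unknown <- setdiff(stats::na.omit(targets$module_id), rownames(factors))
  if (length(unknown)) {
    stop_ipnet("unknown module_id in targets: ",
               paste(unknown, collapse = ", "))
  }
  set.seed(seed)
  n <- ncol(factors)
  met <- matrix(NA_real_, nrow = nrow(targets), ncol = n,
                dimnames = list(targets$metabolite, colnames(factors)))
  for (i in seq_len(nrow(targets))) {
    eps <- rnorm(n)
    eps <- (eps - mean(eps)) / sd(eps)
    if (is.na(targets$module_id[i])) {
      met[i, ] <- eps
    } else {
      r0 <- targets$r0[i]
      met[i, ] <- r0 * factors[targets$module_id[i], ] +
        sqrt(1 - r0^2) * eps
    }
  }
  list(metabolites = met, targets = targets)
}

#' Simulate a read-count table with planted differential expression
#'
#' Gene-wise means are drawn log-uniform over `mean_range`; counts are
#' negative binomial with the given dispersion (`dispersion = 0` gives
#' Poisson counts).  Planted DE genes have group-2 mean equal to
#' `fold_change` times the group-1 mean.
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per group (>= 2).
#' @param de_fraction fraction of genes planted as differentially
#'   expressed.
#' @param fold_change multiplicative group-2/group-1 mean ratio for
#'   planted genes (> 0).
#' @param dispersion negative-binomial dispersion (>= 0; variance is
#'   `mu + dispersion * mu^2`).
#' @param seed integer seed.
#' @param mean_range range of gene-wise base means.
#' @return list with `counts` (genes x samples integer matrix), `group`
#'   (sample group labels), `length_kb` (gene exon lengths, kb), and
#'   `truth` (list: `de_genes`, `fold_change`).
#' @export
simulate_counts <- function(n_genes = 2000, n_per_group = 3,
                            de_fraction = 0, fold_change = 4,
                            dispersion = 0.05, seed = 1,
                            mean_range = c(10, 1000)) {
  n_genes <- check_count(n_genes, "n_genes", min = 1L)
  n_per_group <- check_count(n_per_group, "n_per_group")
  if (n_per_group < 2L) {
    stop_ipnet("`n_per_group` must be >= 2 (no within-group variance ",
               "otherwise)")
  }
  check_number(fold_change, "fold_change")
  if (fold_change <= 0) stop_ipnet("`fold_change` must be > 0")
  check_number(dispersion, "dispersion", min = 0)
  set.seed(seed)
  mu <- exp(runif(n_genes, log(mean_range[1]), log(mean_range[2])))
  n_de <- round(de_fraction * n_genes)
  de_idx <- if (n_de > 0) sort(sample.int(n_genes, n_de)) else integer(0)
  mu2 <- mu
  mu2[de_idx] <- mu[de_idx] * fold_change
  draw <- function(m, n) {
    if (dispersion == 0) {
      matrix(rpois(length(m) * n, rep(m, n)), ncol = n)
    } else {
      matrix(rnbinom(length(m) * n, mu = rep(m, n), size = 1 / dispersion),
             ncol = n)
    }
  }
  counts <- cbind(draw(mu, n_per_group), draw(mu2, n_per_group))
  gene_ids <- sprintf("gene%05d", seq_len(n_genes))
  group <- rep(c("g1", "g2"), each = n_per_group)
  dimnames(counts) <- list(gene_ids,
                           paste0(group, "_s", c(seq_len(n_per_group),
                                                 seq_len(n_per_group))))
  length_kb <- round(exp(runif(n_genes, log(0.3), log(5))), 3)
  names(length_kb) <- gene_ids
  list(counts = counts, group = group, length_kb = length_kb,
       truth = list(de_genes = gene_ids[de_idx], fold_change = fold_change))
}

#' Simulate a multi-environment germplasm panel with planted line pairs
#'
#' Emulates a collection of inbred lines whose seed IP6 content
#' (mg phytic-acid phosphorus per g) is measured in several environments.
#' Each planted pair consists of a high line whose log2 content exceeds
#' its low partner by `log2(ratio)`, plus per-line per-environment
#' log2-scale noise of standard deviation `noise_sd`.  Remaining lines are
#' fillers with jittered baseline content.
#'
#' @param n_lines total lines (must cover `2 * length(planted_pairs)`).
#' @param n_envs number of environments (>= 2).
#' @param planted_pairs list of `c(ratio, noise_sd)` pairs; `ratio` > 0.
#' @param seed integer seed.
#' @param base_content average panel content, mg/g.
#' @return list with `content` (lines x environments matrix), and `truth`
#'   (data.frame `line_high`, `line_low`, `ratio`, `noise_sd`).
#' @export
simulate_germplasm <- function(n_lines = 12, n_envs = 3,
                               planted_pairs = list(c(2, 0.02)),
                               seed = 1, base_content = 3.9) {
  n_envs <- check_count(n_envs, "n_envs")
  if (n_envs < 2L) stop_ipnet("`n_envs` must be >= 2")
  ratios <- vapply(planted_pairs, `[`, numeric(1), 1L)
  noise <- vapply(planted_pairs, `[`, numeric(1), 2L)
  if (any(ratios <= 0)) stop_ipnet("planted pair `ratio` must be > 0")
  n_pairs <- length(planted_pairs)
  if (n_lines < 2L * n_pairs) {
    stop_ipnet("`n_lines` too small for ", n_pairs, " planted pairs")
  }
  set.seed(seed)
  line_ids <- sprintf("line%03d", seq_len(n_lines))
  env_ids <- sprintf("env%d", seq_len(n_envs))
  # per-environment multiplicative effect, shared by all lines (cancels in Q)
  env_log2 <- rnorm(n_envs, 0, 0.1)
  log2_content <- matrix(NA_real_, n_lines, n_envs,
                         dimnames = list(line_ids, env_ids))
  hi <- seq_len(n_pairs) * 2L - 1L
  lo <- hi + 1L
  base_lo <- log2(base_content) + rnorm(n_pairs, 0, 0.05) -
    log2(ratios) / 2
  for (p in seq_len(n_pairs)) {
    log2_content[hi[p], ] <- base_lo[p] + log2(ratios[p]) + env_log2 +
      rnorm(n_envs, 0, noise[p])
    log2_content[lo[p], ] <- base_lo[p] + env_log2 +
      rnorm(n_envs, 0, noise[p])
  }
  fillers <- setdiff(seq_len(n_lines), c(hi, lo))
  for (f in fillers) {
    log2_content[f, ] <- log2(base_content) + rnorm(1, 0, 0.1) +
      env_log2 + rnorm(n_envs, 0, 0.05)
  }
  truth <- data.frame(line_high = line_ids[hi], line_low = line_ids[lo],
                      ratio = ratios, noise_sd = noise,
                      stringsAsFactors = FALSE)
  list(content = 2^log2_content, truth = truth)
}

# --- miRNA duplex simulation ----------------------------------------------

RNA_BASES <- c("A", "C", "G", "U")
RNA_COMPLEMENT <- c(A = "U", C = "G", G = "C", U = "A")
# the base that forms a G:U wobble opposite each miRNA base (NA if none)
GU_PARTNER <- c(A = NA, C = NA, G = "U", U = "G")

#' Simulate miRNA/target-site duplexes with controlled edits
#'
#' Generates a random miRNA of the given length, takes the target site as
#' its exact reverse complement, then introduces the planned edits: core
#' mismatches (miRNA positions 2--13, penalty 2 each under the plant
#' scoring scheme), tail mismatches (positions 1 and 14 onward, penalty 1
#' each) and tail G:U wobbles (penalty 0.5 each).  The recorded
#' `truth_score` is the score [score_duplex()] assigns to the pair.
#'
#' @param plans list of integer triples `c(n_core_mismatch,
#'   n_tail_mismatch, n_gu)`.
#' @param seed integer seed.
#' @param length duplex length in nucleotides.
#' @return data.frame with columns `mirna_id`, `mirna_seq`, `site_seq`
#'   (both 5'->3', RNA alphabet), `truth_score`.
#' @export
simulate_mirna_duplexes <- function(plans = list(c(0, 0, 0)), seed = 1,
                                    length = 21) {
  length <- check_count(length, "length", min = 2L)
  core <- intersect(2:13, seq_len(length))
  tail_pos <- setdiff(seq_len(length), core)
  set.seed(seed)
  out <- vector("list", base::length(plans))
  for (i in seq_along(plans)) {
    plan <- as.integer(plans[[i]])
    if (base::length(plan) != 3L || any(plan < 0L)) {
      stop_ipnet("each plan must be c(n_core_mismatch, n_tail_mismatch, ",
                 "n_gu) with non-negative counts")
    }
    if (plan[1] > base::length(core) ||
        plan[2] + plan[3] > base::length(tail_pos)) {
      stop_ipnet("plan (", paste(plan, collapse = ","),
                 ") is not realizable on a ", length, "-nt duplex")
    }
    core_mm <- if (plan[1] > 0) sample(core, plan[1]) else integer(0)
    tail_edit <- if (plan[2] + plan[3] > 0) {
      sample(tail_pos, plan[2] + plan[3])
    } else integer(0)
    tail_mm <- tail_edit[seq_len(plan[2])]
    gu_pos <- setdiff(tail_edit, tail_mm)
    mirna <- sample(RNA_BASES, length, replace = TRUE)
    # wobble positions need a miRNA G or U
    mirna[gu_pos] <- sample(c("G", "U"), base::length(gu_pos),
                            replace = TRUE)
    # site paired with miRNA position p sits at site index length + 1 - p
    paired <- RNA_COMPLEMENT[mirna]
    for (p in c(core_mm, tail_mm)) {
      bad <- c(RNA_COMPLEMENT[[mirna[p]]], GU_PARTNER[[mirna[p]]])
      paired[p] <- sample(setdiff(RNA_BASES, bad[!is.na(bad)]), 1L)
    }
    for (p in gu_pos) paired[p] <- GU_PARTNER[[mirna[p]]]
    site <- rev(paired)
    out[[i]] <- data.frame(
      mirna_id = sprintf("mir%03d", i),
      mirna_seq = paste(mirna, collapse = ""),
      site_seq = paste(site, collapse = ""),
      truth_score = 2 * plan[1] + plan[2] + 0.5 * plan[3],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Embed simulated target sites into random transcripts
#'
#' @param duplexes output of [simulate_mirna_duplexes()].
#' @param flank random flanking sequence length on each side.
#' @param seed integer seed.
#' @return data.frame with `target_id`, `transcript_seq`, `site_start`
#'   (0-based offset of the planted site).
#' @export
simulate_target_transcripts <- function(duplexes, flank = 50, seed = 1) {
  set.seed(seed)
  n <- nrow(duplexes)
  left <- vapply(seq_len(n), function(i) {
    paste(sample(RNA_BASES, flank, replace = TRUE), collapse = "")
  }, character(1))
  right <- vapply(seq_len(n), function(i) {
    paste(sample(RNA_BASES, flank, replace = TRUE), collapse = "")
  }, character(1))
  data.frame(target_id = sprintf("tx%03d", seq_len(n)),
             transcript_seq = paste0(left, duplexes$site_seq, right),
             site_start = flank,
             stringsAsFactors = FALSE)
}

#' Simulate a candidate-screening benchmark network
#'
#' Builds a small weighted network with one guide gene, one dominant hub,
#' a planted true candidate that satisfies all three mandatory screening
#' principles (shared hub, guide distance below 4, power-node
#' co-membership with a guide-correlated gene) and carries both bonus
#' marks (preferred domain, differential expression), plus decoys that
#' each violate a mandatory principle and a mandatory-passing competitor
#' without bonus marks.  Gene labels are permuted and edge weights
#' jittered by the seed; the topology is fixed.
#'
#' @param seed integer seed.
#' @return list with `edges` (data.frame `gene_a`, `gene_b`, `weight`),
#'   `guides`, `annotations` (data.frame `gene_id`, `interpro_ids`,
#'   `tf_family`, `description`), `de` (data.frame `gene_id`, `is_de`) and
#'   `truth` (list: `candidate`, `competitors`, `decoys`, `top_k`).
#' @export
simulate_candidate_benchmark <- function(seed = 1) {
  roles <- c("GUIDE", "HUB", "CAND", "COMP", "X1", "Y1", "Y2", "Y3",
             "DNOHUB", "C2", "X2", "W1", "W2", "W3",
             "HUB2", "DNOPOW", "DNOPOW2", "F1", "F2", "F3", "F4",
             "P1", "P2", "P3", "DFAR")
  set.seed(seed)
  ids <- sprintf("g%02d_%04d", seq_along(roles),
                 sample.int(9999, length(roles)))
  names(ids) <- roles
  e <- function(a, b) data.frame(gene_a = ids[[a]], gene_b = ids[[b]],
                                 stringsAsFactors = FALSE)
  biclique <- function(S, T) {
    do.call(rbind, lapply(S, function(a) do.call(rbind, lapply(T, e, a = a))))
  }
  edges <- rbind(
    biclique(c("CAND", "X1", "COMP"), c("Y1", "Y2", "Y3")),
    biclique(c("DNOHUB", "X2", "C2"), c("W1", "W2", "W3")),
    e("X1", "GUIDE"), e("X2", "GUIDE"),
    e("HUB", "GUIDE"), e("HUB", "CAND"), e("HUB", "COMP"),
    e("HUB", "X1"), e("HUB", "P1"),
    e("HUB2", "GUIDE"), e("HUB2", "DNOPOW"), e("HUB2", "DNOPOW2"),
    e("HUB2", "F1"), e("HUB2", "F2"), e("HUB2", "F3"), e("HUB2", "F4"),
    e("P1", "P2"), e("P2", "P3"), e("P3", "DFAR"))
  edges$weight <- round(runif(nrow(edges), 0.55, 0.95), 3)
  annotations <- data.frame(
    gene_id = unname(ids),
    interpro_ids = ifelse(roles == "CAND", "IPR027417",
                          ifelse(roles == "DNOHUB", "IPR011611", "")),
    tf_family = "",
    description = ifelse(roles == "GUIDE", "myo-inositol kinase", "protein"),
    stringsAsFactors = FALSE)
  de <- data.frame(gene_id = unname(ids),
                   is_de = roles %in% c("CAND", "DNOHUB"),
                   stringsAsFactors = FALSE)
  list(edges = edges,
       guides = unname(ids["GUIDE"]),
       annotations = annotations,
       de = de,
       truth = list(candidate = unname(ids[["CAND"]]),
                    competitors = unname(ids[["COMP"]]),
                    decoys = unname(ids[c("DNOHUB", "DNOPOW", "DFAR")]),
                    top_k = 2L))
}
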