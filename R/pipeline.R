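# End-to-end pipeline orchestration.

#' Pipeline parameters
#'
#' Collects every tunable threshold of the pipeline with its default:
#' Spearman correlation, blockwise computation capped at 3500 genes,
#' automatic soft-threshold selection, network output threshold 0.5,
#' module minimum size 30 at static cut height 0.99, module-metabolite
#' selection gate |r| > 0.8 & p < 0.01, top-10 degree hubs, and the
#' guide-distance gate < 4.
#'
#' @param correlation "spearman" or "pearson".
#' @param signed signed adjacency transform.
#' @param beta soft-threshold power, or "auto".
#' @param max_block_size blockwise correlation cap.
#' @param export_threshold network output threshold on TOM (strict >).
#' @param min_module_size minimum module size.
#' @param cut_height static tree-cut height.
#' @param r_min,p_max module-metabolite selection gate.
#' @param top_hubs hubs considered "key nodes".
#' @param hub_method hub ranking method.
#' @param distance_max exclusive guide-distance gate.
#' @param min_degree power-graph pre-filter.
#' @param max_bad gene-filter tolerance for missing-or-zero entries.
#' @return named list of validated parameters.
#' @export
pipeline_params <- function(correlation = "spearman", signed = FALSE,
                            beta = "auto", max_block_size = 3500,
                            export_threshold = 0.5, min_module_size = 30,
                            cut_height = 0.99, r_min = 0.8, p_max = 0.01,
                            top_hubs = 10, hub_method = "degree",
                            distance_max = 4, min_degree = 0,
                            max_bad = 3) {
  correlation <- match.arg(correlation, c("spearman", "pearson"))
  hub_method <- match.arg(hub_method, c("degree", "mcc"))
  if (!identical(beta, "auto")) check_number(beta, "beta", min = 1)
  check_number(export_threshold, "export_threshold", min = 0, max = 1)
  check_number(cut_height, "cut_height", min = 0, max = 1)
  check_number(r_min, "r_min", min = 0, max = 1)
  check_number(p_max, "p_max", min = 0, max = 1)
  list(correlation = correlation, signed = check_flag(signed, "signed"),
       beta = beta,
       max_block_size = check_count(max_block_size, "max_block_size", 1L),
       export_threshold = export_threshold,
       min_module_size = check_count(min_module_size, "min_module_size", 1L),
       cut_height = cut_height, r_min = r_min, p_max = p_max,
       top_hubs = check_count(top_hubs, "top_hubs", 1L),
       hub_method = hub_method,
       distance_max = check_number(distance_max, "distance_max", min = 1),
       min_degree = check_count(min_degree, "min_degree"),
       max_bad = check_count(max_bad, "max_bad"))
}

#' Simulate a complete input bundle for the pipeline
#'
#' Builds expression, metabolite, guide, annotation and
#' differential-expression inputs with a planted candidate gene: three
#' tightly co-regulated modules (the regime in which printed pairwise
#' gene correlations of 0.85-0.95 live), metabolites IP1-IP6 of which
#' four track module factors (two negatively) and two are independent,
#' two guide genes inside the first module, and one module-1 gene
#' carrying a preferred P-loop domain and a differential-expression flag
#' -- the planted candidate the screen should rank first.
#'
#' @param seed integer seed.
#' @param n_module_genes genes per planted module.
#' @param loading module factor loading.
#' @param n_background unstructured background genes.
#' @param replicates replicates per genotype x stage cell.
#' @return list with `expr`, `samples`, `metabolites`, `guides`,
#'   `annotations`, `de`, and `truth` (planted module map, factors,
#'   candidate id, metabolite targets).
#' @export
simulate_pipeline_inputs <- function(seed = 1, n_module_genes = 40,
                                     loading = 0.98, n_background = 200,
                                     replicates = 2) {
  design <- simulate_design(replicates = replicates)
  mods <- module_spec(rep(n_module_genes, 3), loading)
  sim <- simulate_expression(mods, n_background = n_background,
                             design = design, seed = seed)
  targets <- data.frame(
    metabolite = paste0("IP", 1:6),
    module_id = c("M01", NA, "M02", "M01", "M03", "M01"),
    r0 = c(0.95, NA, 0.95, -0.95, 0.95, -0.95),
    stringsAsFactors = FALSE)
  met <- simulate_metabolites(sim$truth, targets, seed = seed + 1000L)
  m1 <- names(sim$truth$module_of)[sim$truth$module_of == "M01"]
  guides <- m1[1:2]
  candidate <- m1[3]
  genes <- rownames(sim$expr)
  description <- rep("", length(genes))
  description[match(guides, genes)] <- c("myo-inositol kinase",
                                         "inositol tetrakisphosphate kinase")
  annotations <- data.frame(
    gene_id = genes,
    interpro_ids = ifelse(genes == candidate, "IPR027417", ""),
    tf_family = "",
    description = description,
    stringsAsFactors = FALSE)
  de <- data.frame(gene_id = genes, is_de = genes == candidate,
                   stringsAsFactors = FALSE)
  list(expr = sim$expr, samples = sim$samples,
       metabolites = met$metabolites, guides = guides,
       annotations = annotations, de = de,
       truth = c(sim$truth, list(candidate = candidate,
                                 metabolite_targets = targets)))
}

#' Run the full screening pipeline
#'
#' Executes the inference chain end to end: gene filter, (Spearman)
#' correlation, soft-threshold selection, adjacency and topological
#' overlap, module detection and eigengenes, module-metabolite
#' correlation and selection, per-selected-module edge export at the
#' network output threshold, power-graph compression, hub ranking and
#' candidate screening around the guide genes.  Given identical inputs
#' and parameters the run is fully deterministic.
#'
#' @param expr genes x samples expression matrix.
#' @param metabolites metabolites x samples matrix (sample names must
#'   match `expr`).
#' @param guides guide gene ids.
#' @param annotations,de optional evidence tables (see
#'   [screen_candidates()]).
#' @param params list from [pipeline_params()].
#' @param out_dir optional directory; when given, every intermediate
#'   table is written there (TSV / JSON) together with a machine-readable
#'   `run_report.json`.
#' @return list of class `ipnet_run`: `params`, `beta`, `module_of`,
#'   `eigengenes`, `module_trait`, `selected_modules`, `module_networks`
#'   (per-module list: `edges`, `powergraph`, `hubs`, `candidates`),
#'   `candidates` (combined ranked table with a `module` column), and
#'   `stages` (per-stage in/out counts and warnings).
#' @export
run_pipeline <- function(expr, metabolites, guides, annotations = NULL,
                         de = NULL, params = pipeline_params(),
                         out_dir = NULL) {
  if (is.null(metabolites)) stop_ipnet("metabolite input is missing")
  warnings <- character(0)
  note <- function(...) warnings <<- c(warnings, paste0(...))
  stages <- list()
  expr <- as_numeric_matrix(expr, "expr")

  kept <- filter_genes(expr, max_bad = params$max_bad)
  stages$filter <- c(genes_in = nrow(expr), genes_out = nrow(kept))

  corr <- correlation_matrix(kept, method = params$correlation,
                             max_block_size = params$max_block_size)
  excluded <- attr(corr, "excluded")
  if (length(excluded)) note(length(excluded), " zero-variance genes excluded")

  beta <- params$beta
  if (identical(beta, "auto")) {
    sel <- withCallingHandlers(
      pick_soft_threshold(corr, signed = params$signed),
      warning = function(w) {
        note(conditionMessage(w)); invokeRestart("muffleWarning")
      })
    beta <- sel$beta
  }
  adj <- adjacency_matrix(corr, beta, signed = params$signed)
  tom <- compute_tom(adj)

  module_of <- detect_modules(tom, min_module_size = params$min_module_size,
                              cut_height = params$cut_height)
  stages$modules <- c(genes_in = nrow(kept),
                      n_modules = length(setdiff(unique(module_of), "grey")),
                      grey = sum(module_of == "grey"))
  if (all(module_of == "grey")) stop_ipnet("module detection: no modules found")

  eig <- module_eigengenes(kept, module_of)
  records <- module_trait_correlations(eig, metabolites,
                                       r_min = params$r_min,
                                       p_max = params$p_max)
  selected <- select_significant_modules(records, r_min = params$r_min,
                                         p_max = params$p_max)
  stages$module_trait <- c(records = nrow(records),
                           selected_modules = length(selected))

  module_networks <- list()
  cand_tables <- list()
  for (mod in selected) {
    genes <- names(module_of)[module_of == mod]
    edges <- export_edges(tom, threshold = params$export_threshold,
                          genes = genes)
    if (nrow(edges) == 0L) {
      note("module ", mod, ": no edges above the output threshold")
      next
    }
    pg <- pg_compress(edges, min_degree = params$min_degree)
    hubs <- hub_genes(edges, method = params$hub_method,
                      top_k = params$top_hubs)
    net_nodes <- unique(c(edges$gene_a, edges$gene_b))
    if (!any(guides %in% net_nodes)) {
      note("module ", mod, ": no guide gene in the network; ",
           "candidate screen skipped")
      module_networks[[mod]] <- list(edges = edges, powergraph = pg,
                                     hubs = hubs, candidates = NULL)
      next
    }
    cands <- withCallingHandlers(
      screen_candidates(edges, pg, guides, hubs,
                        annotations = annotations, de = de,
                        export_threshold = params$export_threshold,
                        distance_max = params$distance_max),
      warning = function(w) {
        note("module ", mod, ": ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    module_networks[[mod]] <- list(edges = edges, powergraph = pg,
                                   hubs = hubs, candidates = cands)
    if (any(cands$passes_mandatory)) {
      tab <- cands
      tab$module <- mod
      cand_tables[[mod]] <- tab
    }
  }
  combined <- if (length(cand_tables)) {
    all_c <- do.call(rbind, cand_tables)
    all_c <- all_c[all_c$passes_mandatory, , drop = FALSE]
    ord <- order(-all_c$bonus_count, all_c$min_guide_distance,
                 -all_c$max_guide_weight, all_c$gene)
    all_c <- all_c[ord, , drop = FALSE]
    all_c$rank <- seq_len(nrow(all_c))
    rownames(all_c) <- NULL
    all_c
  } else {
    NULL
  }
  stages$candidates <- c(modules_screened = length(cand_tables),
                         ranked = if (is.null(combined)) 0L
                                  else nrow(combined))

  run <- list(params = params, beta = beta, module_of = module_of,
              eigengenes = eig, module_trait = records,
              selected_modules = selected,
              module_networks = module_networks,
              candidates = combined, stages = stages,
              warnings = warnings)
  class(run) <- "ipnet_run"
  if (!is.null(out_dir)) write_run_outputs(run, out_dir)
  run
}

#' @export
print.ipnet_run <- function(x, ...) {
  cat("ipnet pipeline run\n")
  cat("  soft-threshold beta:", x$beta, "\n")
  cat("  modules:", paste(setdiff(unique(x$module_of), "grey"),
                          collapse = ", "), "\n")
  cat("  selected (metabolite-correlated):",
      paste(x$selected_modules, collapse = ", "), "\n")
  if (!is.null(x$candidates)) {
    cat("  ranked candidates:", nrow(x$candidates),
        "; top:", x$candidates$gene[1L], "\n")
  } else {
    cat("  ranked candidates: none\n")
  }
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("    -", w, "\n")
  }
  invisible(x)
}

# write every intermediate of a run to a directory
write_run_outputs <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(data.frame(gene_id = names(run$module_of),
                       module = unname(run$module_of),
                       stringsAsFactors = FALSE),
            file.path(out_dir, "modules.tsv"))
  write_tsv(run$eigengenes, file.path(out_dir, "eigengenes.tsv"),
            rownames_as = "module")
  write_tsv(run$module_trait, file.path(out_dir, "module_trait.tsv"))
  for (mod in names(run$module_networks)) {
    net <- run$module_networks[[mod]]
    write_tsv(net$edges, file.path(out_dir, paste0("edges_", mod, ".tsv")))
    write_powergraph(net$powergraph,
                     file.path(out_dir, paste0("powergraph_", mod, ".json")))
  }
  if (!is.null(run$candidates)) {
    write_tsv(run$candidates, file.path(out_dir, "candidates.tsv"))
  }
  report <- list(parameters = run$params, beta = run$beta,
                 stages = run$stages, warnings = run$warnings,
                 selected_modules = run$selected_modules)
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
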