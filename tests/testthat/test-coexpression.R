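# Correlation, soft threshold, TOM, modules, eigengenes, module-trait.

test_that("Spearman correlation is monotone invariant and matches the rank oracle", {
  set.seed(5)
  x <- matrix(rnorm(10 * 20), 10, 20,
              dimnames = list(sprintf("g%02d", 1:10), NULL))
  cm <- correlation_matrix(x)
  oracle <- cor(apply(t(x), 2, rank))
  expect_lt(max(abs(cm - oracle)), 1e-12)
  pair <- correlation_matrix(rbind(a = x[1, ], b = exp(x[1, ])))
  expect_equal(pair["a", "b"], 1)
  neg <- correlation_matrix(rbind(a = x[1, ], b = -x[1, ]))
  expect_equal(neg["a", "b"], -1)
})

test_that("blockwise correlation equals the whole-matrix computation", {
  set.seed(6)
  x <- matrix(rnorm(25 * 12), 25, 12,
              dimnames = list(sprintf("g%02d", 1:25), NULL))
  expect_equal(correlation_matrix(x, max_block_size = 4),
               correlation_matrix(x, max_block_size = 3500))
})

test_that("correlation rejects degenerate inputs", {
  expect_error(correlation_matrix(matrix(rnorm(9), 3)), "4 samples")
  x <- matrix(rnorm(30), 3, 10,
              dimnames = list(c("a", "flat", "b"), NULL))
  x["flat", ] <- 7
  expect_warning(cm <- correlation_matrix(x), "zero-variance")
  expect_identical(rownames(cm), c("a", "b"))
  expect_identical(attr(cm, "excluded"), "flat")
})

test_that("soft-threshold selection honours its contract", {
  sim <- simulate_expression(module_spec(rep(50, 5), 0.85),
                             n_background = 350, design = design24(),
                             seed = 1)
  corr <- correlation_matrix(sim$expr)
  sel <- suppressWarnings(pick_soft_threshold(corr))
  reached <- sel$fits$beta[!is.na(sel$fits$fit_r2) & sel$fits$fit_r2 >= 0.8]
  if (length(reached)) {
    # returned power is minimal among candidates reaching the target
    expect_identical(sel$beta, min(reached))
  } else {
    expect_equal(sel$beta, 6)  # documented fallback
  }
  # restricted candidate set: result is inside it or the fallback
  one <- suppressWarnings(pick_soft_threshold(corr, candidate_betas = 4))
  expect_true(one$beta %in% c(4, 6))
  # degenerate connectivity (all equal) falls back with a warning
  flat <- matrix(0.5, 20, 20)
  diag(flat) <- 1
  expect_warning(fb <- pick_soft_threshold(flat), "falling back")
  expect_equal(fb$beta, 6)
})

test_that("raising beta weakly shrinks every off-diagonal adjacency", {
  set.seed(9)
  x <- matrix(rnorm(15 * 10), 15, 10)
  corr <- correlation_matrix(x)
  a6 <- adjacency_matrix(corr, 6)
  a7 <- adjacency_matrix(corr, 7)
  expect_true(all(a7[upper.tri(a7)] <= a6[upper.tri(a6)] + 1e-15))
})

test_that("TOM matches limiting cases and the brute-force oracle", {
  # complete graph: full shared neighbourhoods saturate overlap at 1
  full <- matrix(1, 4, 4)
  expect_true(all(compute_tom(full) == 1))
  # disconnected pair without common neighbours has zero overlap
  a <- diag(1, 4)
  a[1, 2] <- a[2, 1] <- 0.9
  a[3, 4] <- a[4, 3] <- 0.9
  expect_equal(compute_tom(a)[1, 3], 0)
  expect_lt(max(abs(compute_tom(random_symmetric_adjacency(8, 2)) -
                      tom_oracle(random_symmetric_adjacency(8, 2)))),
            1e-12)
  expect_error(compute_tom(matrix(2, 3, 3)), "\\[0, 1\\]")
})

test_that("TOM stays within [0, 1], symmetric, and oracle-consistent on random instances", {
  for (seed in 1:10) {
    n <- sample(6:10, 1)
    a <- random_symmetric_adjacency(n, seed)
    tom <- compute_tom(a)
    expect_true(all(tom >= 0 & tom <= 1))
    expect_equal(tom, t(tom))
    expect_lt(max(abs(tom - tom_oracle(a))), 1e-12)
  }
})

test_that("two planted blocks are recovered cleanly and named by colour", {
  sim <- simulate_expression(module_spec(c(50, 50), 0.9),
                             n_background = 400, design = design20(),
                             seed = 1)
  tom <- compute_tom(adjacency_matrix(correlation_matrix(sim$expr),
                                      default_beta(20)))
  mod <- detect_modules(tom)
  expect_identical(sort(setdiff(unique(mod), "grey")),
                   c("blue", "turquoise"))
  planted <- names(sim$truth$module_of)[sim$truth$module_of != "background"]
  # the planted blocks are intact and perfectly separated
  expect_false(any(mod[planted] == "grey"))
  expect_equal(adjusted_rand(mod[planted], sim$truth$module_of[planted]), 1)
})

test_that("nothing coheres in unstructured expression", {
  sim <- simulate_expression(module_spec(1, 0.5), n_background = 200,
                             design = design20(), seed = 2)
  tom <- compute_tom(adjacency_matrix(correlation_matrix(sim$expr), 8))
  expect_identical(setdiff(unique(detect_modules(tom)), "grey"),
                   character(0))
})

test_that("branches below the minimum module size stay grey", {
  # hand-built overlap: a tight 29-gene block in a sea of independence
  n <- 60
  tom <- diag(1, n)
  tom[1:29, 1:29] <- 0.8
  diag(tom) <- 1
  dimnames(tom) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  expect_identical(setdiff(unique(detect_modules(tom, min_module_size = 30)),
                           "grey"), character(0))
  got <- detect_modules(tom, min_module_size = 29)
  expect_identical(unname(got[1:29]), rep("turquoise", 29))
})

test_that("eigengenes summarise their module and recover the factor", {
  # identical profiles: eigengene is that profile
  prof <- rnorm(12)
  m <- rbind(a = prof, b = prof, c = prof)
  colnames(m) <- sprintf("s%02d", 1:12)
  eig <- module_eigengenes(m, c(a = "blue", b = "blue", c = "blue"))
  expect_equal(abs(cor(eig["blue", ], prof)), 1)
  z <- (m - rowMeans(m)) / apply(m, 1, sd)
  expect_gte(cor(eig["blue", ], colMeans(z)), 0)
  # factor recovery on a planted module
  d30 <- simulate_design(stages = c("a", "b", "c"), replicates = 5)
  sim <- simulate_expression(module_spec(50, 0.9), n_background = 0,
                             design = d30, seed = 4)
  mo <- sim$truth$module_of
  eig2 <- module_eigengenes(sim$expr, mo)
  expect_gte(abs(cor(eig2["M01", ], sim$truth$factors["M01", ])), 0.9)
  # orientation rule holds on every module of a multi-module fit
  sim3 <- simulate_expression(module_spec(c(30, 30), 0.85),
                              n_background = 0, design = d30, seed = 6)
  eig3 <- module_eigengenes(sim3$expr, sim3$truth$module_of)
  z <- t(scale(t(sim3$expr)))
  for (m3 in rownames(eig3)) {
    members <- names(sim3$truth$module_of)[sim3$truth$module_of == m3]
    expect_gte(cor(eig3[m3, ], colMeans(z[members, ])), 0)
  }
})

test_that("module-metabolite records apply the strict |r| and p gates", {
  eig <- matrix(rnorm(2 * 20), 2, 20,
                dimnames = list(c("blue", "red"), sprintf("s%02d", 1:20)))
  met <- rbind(IPx = eig["blue", ], IPy = rnorm(20))
  colnames(met) <- colnames(eig)
  rec <- module_trait_correlations(eig, met)
  hit <- rec[rec$module == "blue" & rec$metabolite == "IPx", ]
  expect_equal(hit$r, 1)
  expect_true(hit$selected)
  # r exactly at the threshold is not selected
  records <- data.frame(module = "m", metabolite = "ip", r = 0.8, p = 1e-6)
  expect_identical(select_significant_modules(records), character(0))
  expect_identical(select_significant_modules(
    data.frame(module = "m", metabolite = "ip", r = 0.79, p = 1e-6)),
    character(0))
  # sample mismatch is reported with the offending ids
  bad <- met
  colnames(bad)[1] <- "sXX"
  expect_error(module_trait_correlations(eig, bad), "sXX")
})

test_that("selection is idempotent and order-stable", {
  recs <- data.frame(module = c("b", "a", "b", "c"),
                     metabolite = c("i1", "i2", "i3", "i4"),
                     r = c(0.9, -0.85, 0.95, 0.5),
                     p = c(1e-4, 1e-3, 1e-5, 1e-6))
  sel <- select_significant_modules(recs)
  expect_identical(sel, c("b", "a"))
  expect_identical(select_significant_modules(recs[recs$module %in% sel, ]),
                   sel)
})

test_that("the bundled module-metabolite example yields six distinct modules", {
  path <- system.file("extdata", "ip_module_correlations.tsv",
                      package = "ipnet")
  records <- read_tsv(path)
  expect_identical(nrow(records), 9L)
  sel <- select_significant_modules(records)
  expect_length(sel, 6)
  expect_setequal(sel, c("dodgerblue4", "salmon1", "burlywood2",
                         "magenta2", "cornsilk", "steelblue4"))
})

test_that("hub ranking identifies centres under both methods", {
  star <- data.frame(gene_a = "hub", gene_b = paste0("leaf", 1:5))
  expect_identical(hub_genes(star, "degree", 1), "hub")
  expect_identical(hub_genes(star, "mcc", 1), "hub")
  # 4-clique plus pendant: clique members outrank the pendant under MCC
  ed <- rbind(clique_edges(c("a", "b", "c", "d")),
              data.frame(gene_a = "d", gene_b = "e"))
  ranked <- hub_genes(ed, "mcc", 5)
  expect_true(which(ranked == "e") > max(match(c("a", "b", "c", "d"),
                                               ranked)))
  # top_k beyond the node count returns everything
  expect_length(hub_genes(star, "degree", 50), 6)
})

test_that("edge export applies the strict output threshold", {
  m <- matrix(c(1, 0.6, 0.5, 0.6, 1, 0.2, 0.5, 0.2, 1), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  ed <- export_edges(m, threshold = 0.5)
  expect_identical(nrow(ed), 1L)  # the 0.5 edge itself is excluded
  expect_identical(ed$gene_a, "a")
  expect_identical(ed$gene_b, "b")
})
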