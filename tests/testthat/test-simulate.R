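# Synthetic-data generators: planted structure and seeded determinism.

test_that("planted modules produce the intended within-module correlation", {
  sim <- simulate_expression(module_spec(c(50, 50), 0.9),
                             n_background = 0, design = design20(),
                             seed = 1)
  for (m in c("M01", "M02")) {
    genes <- names(sim$truth$module_of)[sim$truth$module_of == m]
    cm <- cor(t(sim$expr[genes, ]), method = "spearman")
    expect_gte(mean(abs(cm[upper.tri(cm)])), 0.6)
  }
  # loading 1 means identical profiles up to noise-free scaling
  sim1 <- simulate_expression(module_spec(10, 1), n_background = 0,
                              design = design20(), seed = 2)
  expect_equal(min(cor(t(sim1$expr))), 1, tolerance = 1e-12)
})

test_that("every generator is a pure function of its seed", {
  a <- simulate_expression(module_spec(20, 0.8), n_background = 30,
                           design = design20(), seed = 5)
  b <- simulate_expression(module_spec(20, 0.8), n_background = 30,
                           design = design20(), seed = 5)
  expect_identical(a$expr, b$expr)
  expect_identical(simulate_germplasm(seed = 4), simulate_germplasm(seed = 4))
  expect_identical(simulate_counts(seed = 9, n_genes = 50)$counts,
                   simulate_counts(seed = 9, n_genes = 50)$counts)
  expect_identical(simulate_mirna_duplexes(list(c(1, 1, 1)), seed = 2),
                   simulate_mirna_duplexes(list(c(1, 1, 1)), seed = 2))
  expect_identical(simulate_candidate_benchmark(3)$edges,
                   simulate_candidate_benchmark(3)$edges)
})

test_that("generated expression is positive and passes the gene filter", {
  sim <- simulate_expression(module_spec(30, 0.9), n_background = 100,
                             design = design20(), seed = 7)
  expect_true(all(sim$expr > 0))
  expect_identical(nrow(filter_genes(sim$expr)), nrow(sim$expr))
})

test_that("expression generation rejects degenerate designs", {
  tiny <- simulate_design(genotypes = "g", stages = "s", replicates = 3)
  expect_error(simulate_expression(design = tiny, seed = 1),
               "at least 4 samples")
})

test_that("metabolites track their module factor at the planted r0", {
  d30 <- simulate_design(stages = c("a", "b", "c"), replicates = 5)
  sim <- simulate_expression(module_spec(30, 0.9), n_background = 0,
                             design = d30, seed = 7)
  met <- simulate_metabolites(
    sim$truth,
    data.frame(metabolite = "m1", module_id = "M01", r0 = -0.95),
    seed = 107)
  r <- cor(met$metabolites[1, ], sim$truth$factors["M01", ])
  expect_true(r >= -1 && r <= -0.8)
  # r0 = 1: metabolite equals the factor up to affine transform
  met1 <- simulate_metabolites(
    sim$truth, data.frame(metabolite = "m", module_id = "M01", r0 = 1),
    seed = 11)
  expect_equal(cor(met1$metabolites[1, ], sim$truth$factors["M01", ]), 1,
               tolerance = 1e-12)
  # r0 = 0 via an independent metabolite stays inside the n = 30 null band
  met0 <- simulate_metabolites(
    sim$truth, data.frame(metabolite = "m0", module_id = "M01", r0 = 0),
    seed = 13)
  expect_lt(abs(cor(met0$metabolites[1, ], sim$truth$factors["M01", ])),
            0.4)
  expect_error(
    simulate_metabolites(sim$truth,
                         data.frame(metabolite = "x", module_id = "nope",
                                    r0 = 0.5), seed = 1),
    "nope")
})

test_that("count tables carry the planted fold change and DE truth", {
  none <- simulate_counts(100, 3, de_fraction = 0, seed = 1)
  expect_length(none$truth$de_genes, 0)
  sim <- simulate_counts(200, 3, de_fraction = 0.2, fold_change = 4,
                         dispersion = 0.05, seed = 11)
  g2 <- sim$group == "g2"
  ratio <- rowMeans(sim$counts[sim$truth$de_genes, g2]) /
    rowMeans(sim$counts[sim$truth$de_genes, !g2])
  expect_true(mean(ratio) >= 3 && mean(ratio) <= 5)
  # dispersion 0 is the Poisson limit: variance tracks the mean
  pois <- simulate_counts(2000, 3, dispersion = 0, seed = 2)
  vm <- mean(apply(pois$counts, 1, var)) / mean(rowMeans(pois$counts))
  expect_true(vm > 0.8 && vm < 1.2)
  expect_error(simulate_counts(10, n_per_group = 1, seed = 1),
               "n_per_group")
})

test_that("germplasm panels plant the requested content contrast", {
  gp <- simulate_germplasm(n_lines = 6, n_envs = 3,
                           planted_pairs = list(c(2, 0.01)), seed = 1)
  q <- compute_q(gp$content[gp$truth$line_high, ],
                 gp$content[gp$truth$line_low, ])
  expect_true(all(q >= 0.9 & q <= 1.1))
  flat <- simulate_germplasm(n_lines = 4, n_envs = 3,
                             planted_pairs = list(c(1, 0.01)), seed = 2)
  qf <- compute_q(flat$content[flat$truth$line_high, ],
                  flat$content[flat$truth$line_low, ])
  expect_lt(mean(qf), 0.1)
  expect_error(simulate_germplasm(planted_pairs = list(c(-1, 0.1)),
                                  seed = 1), "ratio")
  expect_error(simulate_germplasm(n_envs = 1, seed = 1), "n_envs")
})

test_that("miRNA duplex plans yield the scored edits they claim", {
  d <- simulate_mirna_duplexes(list(c(0, 0, 0), c(1, 0, 0), c(0, 2, 1)),
                               seed = 1)
  expect_equal(d$truth_score, c(0, 2, 2.5))
  observed <- mapply(score_duplex, d$mirna_seq, d$site_seq)
  expect_equal(unname(observed), d$truth_score)
  expect_error(simulate_mirna_duplexes(list(c(13, 0, 0)), seed = 1),
               "not realizable")
  # truth scores hold across seeds and mixed plans
  for (seed in 1:5) {
    dd <- simulate_mirna_duplexes(list(c(2, 1, 0), c(0, 0, 2), c(1, 2, 1)),
                                  seed = seed)
    expect_equal(unname(mapply(score_duplex, dd$mirna_seq, dd$site_seq)),
                 dd$truth_score)
  }
})
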