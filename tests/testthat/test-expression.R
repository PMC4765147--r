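# RPKM, gene filtering, BH adjustment and DE calling.

test_that("RPKM follows its defining formula", {
  expect_equal(compute_rpkm(matrix(10), length_kb = 1,
                            mapped_millions = 1)[1, 1], 10)
  expect_equal(compute_rpkm(matrix(0), length_kb = 2,
                            mapped_millions = 3)[1, 1], 0)
  expect_equal(compute_rpkm(matrix(200), length_kb = 0.8,
                            mapped_millions = 2.5)[1, 1], 100)
})

test_that("RPKM errors name the offending gene or sample", {
  counts <- matrix(1:4, 2, dimnames = list(c("gA", "gB"), c("s1", "s2")))
  expect_error(compute_rpkm(counts, length_kb = c(0, 1),
                            mapped_millions = c(1, 1)), "gA")
  expect_error(compute_rpkm(counts, length_kb = c(1, 1),
                            mapped_millions = c(1, -2)), "s2")
})

test_that("RPKM is linear in reads across split libraries", {
  set.seed(3)
  counts <- 2 * matrix(rpois(40, 50), 10)
  lk <- runif(10, 0.5, 3)
  full <- compute_rpkm(counts, lk, mapped_millions = rep(2, 4))
  halves <- (compute_rpkm(counts / 2, lk, mapped_millions = rep(1, 4)) +
               compute_rpkm(counts / 2, lk, mapped_millions = rep(1, 4))) / 2
  expect_equal(full, halves)
})

test_that("gene filtering removes genes with more than max_bad zero/missing cells", {
  m <- matrix(1, 3, 12, dimnames = list(c("g4", "g3", "gok"), NULL))
  m["g4", 1:4] <- 0
  m["g3", 1:3] <- NA
  kept <- filter_genes(m)
  expect_identical(rownames(kept), c("g3", "gok"))  # exactly 3 bad stays
  all_pos <- matrix(runif(24) + 1, 2)
  expect_identical(filter_genes(all_pos), all_pos)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_fdr(0.01), 0.01)
  expect_equal(bh_fdr(c(0.004, 0.02, 0.03, 0.04)),
               c(0.016, 0.04, 0.04, 0.04))
  set.seed(8)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= 0 & q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone in rank
  perm <- sample(50)
  expect_equal(bh_fdr(p[perm]), q[perm])          # permutation equivariant
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("identical groups produce null DE calls", {
  set.seed(4)
  counts <- matrix(rpois(100 * 6, 50), 100)
  counts <- cbind(counts[, 1:3], counts[, 1:3])
  rownames(counts) <- sprintf("g%03d", 1:100)
  res <- call_degs(counts, rep(c("a", "b"), each = 3))
  expect_true(all(res$log2_fc == 0))
  expect_false(any(res$is_de))
})

test_that("swapping the group roles negates the log2 fold change", {
  sim <- simulate_counts(100, 3, de_fraction = 0.3, fold_change = 3,
                         seed = 21)
  ab <- call_degs(sim$counts, sim$group)
  swapped <- c(4:6, 1:3)  # present group 2 first
  ba <- call_degs(sim$counts[, swapped], sim$group[swapped])
  expect_equal(ab$log2_fc, -ba$log2_fc)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("the fold-change gate blocks significant genes below 2-fold", {
  # stable background keeps size factors near 1; target gene at 1.9x
  set.seed(12)
  bg <- matrix(rpois(50 * 6, 200), 50)
  target <- c(10000, 10000, 10000, 19000, 19000, 19000)
  counts <- rbind(bg, target)
  rownames(counts) <- c(sprintf("bg%02d", 1:50), "target")
  res <- call_degs(counts, rep(c("a", "b"), each = 3))
  trow <- res[res$gene_id == "target", ]
  expect_lt(trow$fdr, 0.01)              # overwhelmingly significant
  expect_lt(abs(trow$log2_fc), 1)        # but below the 2-fold gate
  expect_false(trow$is_de)
})

test_that("planted differential expression is recovered", {
  sim <- simulate_counts(n_genes = 1000, n_per_group = 3,
                         de_fraction = 0.1, fold_change = 4,
                         dispersion = 0.05, seed = 11)
  res <- call_degs(sim$counts, sim$group)
  planted <- res$gene_id %in% sim$truth$de_genes
  expect_gte(mean(res$is_de[planted]), 0.9)
  expect_lte(mean(res$is_de[!planted]), 0.02)
})

test_that("DE calling validates its inputs", {
  counts <- matrix(rpois(40, 20), 10)
  expect_error(call_degs(counts, rep("a", 4)), "two groups")
  expect_error(call_degs(counts, c("a", "a", "a", "b")), "2 samples")
})
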