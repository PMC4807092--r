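test_that("low-expression filter keeps genes with max count strictly above 20", {
  m <- rbind(boundary_in = c(0, 0, 21),
             boundary_out = c(20, 20, 20),
             zero = c(0, 0, 0),
             high = c(100, 5, 0))
  colnames(m) <- paste0("s", 1:3)
  kept <- filter_low_expression(m)
  expect_identical(rownames(kept), c("boundary_in", "high"))

  set.seed(30)
  r <- matrix(rpois(600, 15), 200, 3, dimnames = list(paste0("g", 1:200), paste0("s", 1:3)))
  expect_identical(rownames(filter_low_expression(r)),
                   rownames(r)[apply(r, 1, max) > 20])
})

test_that("TMM factors are 1 for identical libraries and invariant to uniform scaling", {
  set.seed(31)
  base <- matrix(rpois(4000, 200), 1000, 4,
                 dimnames = list(sprintf("g%04d", 1:1000), paste0("s", 1:4)))
  same <- cbind(base[, 1], base[, 1], base[, 1])
  colnames(same) <- paste0("s", 1:3)
  expect_true(all(abs(tmm_factors(same) - 1) < 1e-9))

  # sample 2 = 2 x sample 1: the factors absorb nothing (library size does),
  # so the recovered effective scaling is 2 and normalized values coincide
  two <- cbind(a = base[, 1], b = 2L * base[, 1])
  f <- tmm_factors(two)
  eff <- colSums(two) * f
  expect_lt(abs(eff[["b"]] / eff[["a"]] - 2), 0.02)
  norm <- normalize_counts(two, f)
  expect_lt(max(abs(norm[, "a"] - norm[, "b"]) / norm[, "a"]), 1e-8)
})

test_that("TMM factors stay near 1 under the null simulation", {
  truth <- make_truth(sim_config(seed = 32, n_genes = 4000L, frac_de_genes = 0,
                                 n_truncal = 5L, n_shared = 0L, n_private = 0L,
                                 n_germline_het = 0L, n_germline_hom = 0L))
  counts <- expression_matrix(simulate_tumor(truth))
  f <- tmm_factors(filter_low_expression(counts))
  expect_true(all(f > 0.9 & f < 1.1))
})

test_that("pairwise correlations are Pearson on log2 values and match a direct formula", {
  set.seed(33)
  m <- matrix(rpois(900, 300), 300, 3, dimnames = list(NULL, c("a", "b", "c")))
  m[, "b"] <- m[, "a"]  # duplicate sample
  cc <- pairwise_correlation(m)
  expect_equal(cc["a", "b"], 1.0)
  expect_true(isSymmetric(cc))
  expect_equal(unname(diag(cc)), rep(1, 3))

  la <- log2(m[, "a"] + 1); lc <- log2(m[, "c"] + 1)
  r_oracle <- sum((la - mean(la)) * (lc - mean(lc))) /
    sqrt(sum((la - mean(la))^2) * sum((lc - mean(lc))^2))
  expect_equal(cc["a", "c"], r_oracle, tolerance = 1e-10)
})

test_that("fold-change fractions count genes beyond each threshold", {
  m <- matrix(1000, 100, 2, dimnames = list(sprintf("g%03d", 1:100), c("r1", "r2")))
  expect_true(all(foldchange_fractions(m)$fraction == 0))

  m5 <- m
  m5["g001", "r2"] <- 5000  # one 5-fold gene among 100
  fc <- foldchange_fractions(m5, thresholds = c(2, 3, 4))
  expect_equal(fc$fraction, rep(0.01, 3), tolerance = 1e-6)

  set.seed(34)
  r <- matrix(rpois(1500, 50) + 1, 500, 3,
              dimnames = list(NULL, c("r1", "r2", "pool")))
  fr <- foldchange_fractions(r, pooled_id = "pool")
  expect_equal(unique(fr$group[fr$sample_b == "pool"]), "region_vs_pooled")
  # nested events: nonincreasing in threshold for every pair
  by_pair <- split(fr, paste(fr$sample_a, fr$sample_b))
  for (p in by_pair) {
    p <- p[order(p$threshold), ]
    expect_true(all(diff(p$fraction) <= 0))
  }
})

test_that("post-TMM correlations and fractions are invariant to scaling one sample", {
  set.seed(35)
  counts <- matrix(rnbinom(2000, mu = 800, size = 20), 500, 4,
                   dimnames = list(sprintf("g%04d", 1:500), paste0("s", 1:4)))
  scaled <- counts
  scaled[, 2] <- 3L * scaled[, 2]
  c1 <- compare_expression(counts, pooled_id = NULL)
  c2 <- compare_expression(scaled, pooled_id = NULL)
  expect_lt(max(abs(c1$correlations - c2$correlations)), 1e-3)
  expect_lt(max(abs(c1$foldchange$fraction - c2$foldchange$fraction)), 0.005)
})

test_that("the pooled sample is no more extreme than the most divergent region pair", {
  deltas <- sapply(1:5, function(seed) {
    truth <- make_truth(sim_config(seed = seed, n_genes = 3000L))
    regions <- simulate_tumor(truth)
    pooled <- pool_physical(regions, seed = seed + 500)
    cmp <- compare_expression(expression_matrix(c(regions, list(pooled = pooled))),
                              pooled_id = "pooled")
    fc2 <- cmp$foldchange[cmp$foldchange$threshold == 2, ]
    max(fc2$fraction[fc2$group == "region_vs_region"]) -
      mean(fc2$fraction[fc2$group == "region_vs_pooled"])
  })
  expect_gt(mean(deltas), 0)
})

test_that("the full expression comparison reproduces the high-correlation regional regime", {
  truth <- make_truth(sim_config(seed = 36, n_genes = 6000L))
  regions <- simulate_tumor(truth)
  pooled <- pool_physical(regions, seed = 37)
  cmp <- compare_expression(expression_matrix(c(regions, list(pooled = pooled))),
                            pooled_id = "pooled")
  g <- glance(cmp)
  expect_gt(g$mean_cor_regions, 0.95)
  expect_gt(g$n_genes_retained, 0.8 * 6000)
  expect_true(all(abs(exp(mean(log(cmp$factors))) - 1) < 1e-8))
})
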