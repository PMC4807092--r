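test_that("equal-weight pooling dilutes a single-region signal fourfold", {
  n <- 2000L
  regions <- list(
    manual_read_set(rep(1000L, n), rep(400L, n), "region_1"),
    manual_read_set(rep(1000L, n), rep(0L, n), "region_2"),
    manual_read_set(rep(1000L, n), rep(0L, n), "region_3"),
    manual_read_set(rep(1000L, n), rep(0L, n), "region_4")
  )
  pooled <- pool_physical(regions, pooled_depth = 1000L, seed = 1)
  expect_equal(pooled$kind, "pooled")
  vaf <- pooled$variants$alt_count / pooled$variants$depth
  se <- sqrt(0.1 * 0.9 / 1000 / n)
  expect_lt(abs(mean(vaf) - 0.10), 3 * se)
})

test_that("degenerate weights reproduce a single region; identical regions keep their VAF", {
  n <- 1500L
  set.seed(2)
  alt <- rbinom(n, 200, 0.3)
  r1 <- manual_read_set(rep(200L, n), alt, "region_1")
  r2 <- manual_read_set(rep(200L, n), rep(0L, n), "region_2")

  pooled <- pool_physical(list(r1, r2), weights = c(1, 0),
                          pooled_depth = 200L, seed = 3)
  d <- pooled$variants$alt_count / 200 - alt / 200
  expect_lt(abs(mean(d)), 3 * sqrt(2 * 0.3 * 0.7 / 200 / n))

  same <- pool_physical(list(r1, r1, r1, r1), pooled_depth = 200L, seed = 4)
  expect_lt(abs(mean(same$variants$alt_count / 200) - mean(alt / 200)),
            3 * sqrt(2 * 0.3 * 0.7 / 200 / n))
})

test_that("dilution law: expected pooled VAF equals the mean regional VAF", {
  truth <- make_truth(sim_config(n_truncal = 500L, n_shared = 300L,
                                 n_private = 400L, n_germline_het = 0L,
                                 n_germline_hom = 0L, n_genes = 10L, seed = 8L))
  regions <- simulate_tumor(truth)
  pooled <- pool_physical(regions, pooled_depth = 137L, seed = 5)
  frac <- sapply(regions, function(r) r$variants$alt_count / r$variants$depth)
  q <- rowMeans(frac)
  diff <- abs(pooled$variants$alt_count / 137 - q)
  tol <- 3 * sqrt(q * (1 - q) / 137)
  expect_gte(mean(diff <= tol), 0.99)
})

test_that("pooled expression is a weighted mixture of regional rates at mean library size", {
  set.seed(6)
  mu <- rlnorm(300, 5, 1)
  expr1 <- stats::setNames(rpois(300, mu), sprintf("gene%05d", 1:300))
  expr2 <- stats::setNames(rpois(300, mu), sprintf("gene%05d", 1:300))
  r1 <- manual_read_set(rep(100L, 5), rep(10L, 5), "region_1", expr = expr1)
  r2 <- manual_read_set(rep(100L, 5), rep(10L, 5), "region_2", expr = expr2)
  pooled <- pool_physical(list(r1, r2), pooled_depth = 100L, seed = 7)
  expect_equal(sum(pooled$expr_counts),
               round(mean(c(sum(expr1), sum(expr2)))))
  rate <- (expr1 / sum(expr1) + expr2 / sum(expr2)) / 2
  expect_gt(cor(pooled$expr_counts, rate), 0.95)
})

test_that("in-silico mixing of one region at fraction 1 is the identity", {
  set.seed(10)
  rs <- manual_read_set(rpois(50, 100), rbinom(50, 80, 0.3), "region_1",
                        expr = stats::setNames(rpois(20, 200),
                                               sprintf("gene%05d", 1:20)))
  mixed <- mix_in_silico(list(rs), fraction = 1, seed = 11)
  expect_equal(mixed$variants$depth, rs$variants$depth)
  expect_equal(mixed$variants$alt_count, rs$variants$alt_count)
  expect_equal(unname(mixed$expr_counts), unname(as.integer(rs$expr_counts)))
})

test_that("hypergeometric subsampling has mean fraction x alt and conserves depth exactly", {
  n <- 4000L
  rs <- manual_read_set(rep(100L, n), rep(40L, n), "region_1")
  mixed <- mix_in_silico(list(rs), fraction = 0.25, seed = 12)
  expect_true(all(mixed$variants$depth == 25L))
  sd_h <- sqrt(25 * 0.4 * 0.6 * (100 - 25) / 99)
  expect_lt(abs(mean(mixed$variants$alt_count) - 10), 3 * sd_h / sqrt(n))
})

test_that("mixing four identical regions preserves the VAF", {
  n <- 2000L
  set.seed(13)
  regions <- lapply(1:4, function(r)
    manual_read_set(rep(137L, n), rbinom(n, 137, 0.3), paste0("region_", r)))
  mixed <- mix_in_silico(regions, fraction = 0.25, seed = 14)
  vaf <- mixed$variants$alt_count / mixed$variants$depth
  expect_lt(abs(mean(vaf) - 0.3), 3 * sqrt(0.3 * 0.7 / 137 / n))
  # read conservation: mixed depth = sum of round(f * depth)
  expect_true(all(mixed$variants$depth == 4 * round(0.25 * 137)))
})

test_that("physical pooling and in-silico mixing estimate the same quantity", {
  truth <- make_truth(sim_config(n_truncal = 1200L, n_shared = 0L,
                                 n_private = 0L, n_germline_het = 0L,
                                 n_germline_hom = 0L, n_genes = 10L,
                                 depth_dispersion = 0, seed = 15L))
  regions <- simulate_tumor(truth)
  pooled <- pool_physical(regions, pooled_depth = 137L, seed = 16)
  mixed <- mix_in_silico(regions, 0.25, seed = 17)
  vp <- pooled$variants$alt_count / pooled$variants$depth
  vm <- mixed$variants$alt_count / mixed$variants$depth
  expect_lt(abs(mean(vp) - mean(vm)), 3 * sqrt(2 * 0.4 * 0.6 / 137 / 1200))
})

test_that("mismatched inputs are rejected with an informative message", {
  r1 <- manual_read_set(rep(100L, 3), rep(10L, 3), "region_1")
  r2 <- manual_read_set(rep(100L, 4), rep(10L, 4), "region_2")
  expect_error(pool_physical(list(r1, r2)), "disagree in size")

  r3 <- manual_read_set(rep(100L, 3), rep(10L, 3), "region_2")
  r3$variants$variant_id[2] <- "varXXXXX"
  expect_error(pool_physical(list(r1, r3)), "varXXXXX")

  expect_error(pool_physical(list(r1, r1), weights = c(0.6, 0.6)), "weights")
  expect_error(mix_in_silico(list(r1), fraction = 0), "fraction")
  expect_error(mix_in_silico(list(r1), fraction = 1.2), "fraction")
})
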