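test_that("detection vectors map to the common/shared/private/absent taxonomy", {
  vecs <- rbind(c(1, 1, 1, 1), c(1, 0, 0, 0), c(1, 1, 0, 0),
                c(1, 1, 1, 0), c(0, 0, 0, 0))
  callsets <- lapply(1:4, function(r)
    manual_call_set(vecs[, r] == 1, ifelse(vecs[, r] == 1, 0.4, 0),
                    sample_id = paste0("region_", r)))
  cls <- classify_variants(callsets)
  expect_equal(cls$class, c("common", "private", "shared", "shared", "absent"))
  expect_equal(cls$n_regions_detected, c(4L, 1L, 2L, 3L, 0L))
})

test_that("filtered calls do not count as detected for classification", {
  cs1 <- manual_call_set(c(TRUE, TRUE), c(0.95, 0.4), "region_1",
                         filter_status = c("HOM_FILTER", "PASS"))
  cs2 <- manual_call_set(c(TRUE, TRUE), c(0.4, 0.4), "region_2")
  cls <- classify_variants(list(cs1, cs2))
  expect_equal(cls$class, c("private", "common"))
})

test_that("classification partitions regionally detected variants", {
  for (seed in 1:20) {
    callsets <- random_call_sets(n_var = 50, n_regions = 4, seed = seed)
    cls <- classify_variants(callsets)
    det <- attr(cls, "detection")
    n_detected <- sum(rowSums(det) >= 1)
    counts <- table(factor(cls$class, c("common", "shared", "private", "absent")))
    expect_equal(unname(counts[["common"]] + counts[["shared"]] + counts[["private"]]),
                 n_detected)
  }
})

test_that("concordance fractions equal a brute-force tally", {
  # constructed set: 86 non-private + 16 private of 102 detected
  vecs <- rbind(matrix(1, 60, 4),                         # common
                cbind(1, 1, 0, matrix(0, 26, 1)),         # shared (2 regions)
                cbind(1, matrix(0, 16, 3)))               # private
  callsets <- lapply(1:4, function(r)
    manual_call_set(vecs[, r] == 1, ifelse(vecs[, r] == 1, 0.3, 0),
                    sample_id = paste0("region_", r)))
  cf <- concordance_fractions(classify_variants(callsets))
  expect_equal(sum(cf$n), 102L)
  expect_equal(cf$fraction[cf$class == "private"], 16 / 102)
  expect_equal(cf$fraction[cf$class == "common"], 60 / 102)
  expect_equal(sum(cf$fraction), 1)

  # random sets against an independent tally
  for (seed in 1:5) {
    callsets <- random_call_sets(40, 4, seed = seed + 50)
    cls <- classify_variants(callsets)
    cf <- concordance_fractions(cls)
    det <- attr(cls, "detection")
    k <- rowSums(det)
    expect_equal(cf$n[cf$class == "common"], sum(k == 4))
    expect_equal(cf$n[cf$class == "shared"], sum(k %in% 2:3))
    expect_equal(cf$n[cf$class == "private"], sum(k == 1))
  }
})

test_that("a pooled call set covering the regional union gives perfect detection", {
  callsets <- random_call_sets(80, 4, seed = 60)
  cls <- classify_variants(callsets)
  union_det <- rowSums(attr(cls, "detection")) >= 1
  pooled <- manual_call_set(union_det, ifelse(union_det, 0.2, 0), "pooled")
  st <- pooled_detection_stats(cls, pooled)
  expect_true(all(st$by_class$pooled_rate[st$by_class$n > 0] == 1))
  expect_equal(st$missed_moderate_fraction, 0)
})

test_that("uniformly spread private variants give a 25% single-biopsy expectation", {
  n_per <- 25L
  vecs <- do.call(rbind, lapply(1:4, function(r) {
    m <- matrix(0, n_per, 4); m[, r] <- 1; m
  }))
  callsets <- lapply(1:4, function(r)
    manual_call_set(vecs[, r] == 1, ifelse(vecs[, r] == 1, 0.3, 0),
                    sample_id = paste0("region_", r)))
  pooled <- manual_call_set(rep(TRUE, 100), rep(0.08, 100), "pooled")
  st <- pooled_detection_stats(classify_variants(callsets), pooled)
  expect_equal(st$single_biopsy_rate, 0.25)
})

test_that("missed-moderate-VAF fraction counts pool misses above the threshold", {
  # 4 variants detected regionally, max VAFs 0.5/0.3/0.25/0.1; pool misses
  # the 0.3 and the 0.1 -> 1 of 3 moderate variants missed
  vafs <- c(0.5, 0.3, 0.25, 0.1)
  callsets <- lapply(1:4, function(r)
    manual_call_set(rep(TRUE, 4), vafs, sample_id = paste0("region_", r)))
  pooled <- manual_call_set(c(TRUE, FALSE, TRUE, FALSE),
                            c(0.5, 0, 0.25, 0), "pooled")
  st <- pooled_detection_stats(classify_variants(callsets), pooled)
  expect_equal(st$missed_moderate_fraction, 1 / 3)
  # restricted mode: no shared variants here -> NA
  st2 <- pooled_detection_stats(classify_variants(callsets), pooled,
                                shared_only = TRUE)
  expect_true(is.na(st2$missed_moderate_fraction))
})

test_that("VAF correlation is exact in the noise-free limit and matches the textbook formula", {
  callsets <- random_call_sets(200, 4, seed = 70, p_detect = 0.7)
  cls <- classify_variants(callsets)
  exact <- manual_call_set(rep(TRUE, 200), cls$mean_regional_vaf, "pooled")
  expect_equal(vaf_correlation(cls, exact)$r, 1.0)

  set.seed(71)
  noisy_vaf <- pmin(pmax(cls$mean_regional_vaf + rnorm(200, 0, 0.03), 0), 1)
  noisy <- manual_call_set(rep(TRUE, 200), noisy_vaf, "pooled")
  r <- vaf_correlation(cls, noisy)$r
  keep <- cls$class != "absent"
  x <- cls$mean_regional_vaf[keep]; y <- noisy_vaf[keep]
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r, r_oracle, tolerance = 1e-12)
})

test_that("degenerate zero-variance VAFs give NA with a warning", {
  callsets <- lapply(1:4, function(r)
    manual_call_set(rep(TRUE, 5), rep(0.4, 5), paste0("region_", r)))
  pooled <- manual_call_set(rep(TRUE, 5), rep(0.4, 5), "pooled")
  cls <- classify_variants(callsets)
  expect_warning(out <- vaf_correlation(cls, pooled), "zero variance")
  expect_true(is.na(out$r))
})

test_that("per-class VAF quartiles match a sort-based oracle", {
  # five common variants with known max VAFs: type-7 quartiles at n = 5 are
  # exactly the 2nd, 3rd and 4th order statistics
  vals <- c(0.52, 0.31, 0.44, 0.38, 0.47)
  callsets <- lapply(1:4, function(r)
    manual_call_set(rep(TRUE, 5), vals, paste0("region_", r)))
  vd <- vaf_distribution_by_class(classify_variants(callsets), statistic = "max")
  s <- sort(vals)
  row <- vd[vd$class == "common", ]
  expect_equal(row$q25, s[2])
  expect_equal(row$median, s[3])
  expect_equal(row$q75, s[4])
  expect_equal(vd$n[vd$class == "shared"], 0L)
  expect_true(is.na(vd$median[vd$class == "private"]))
})

test_that("the default simulation reproduces the qualitative VAF ordering with common near 0.40", {
  exp <- run_experiment(sim_config(seed = 2, n_genes = 300))
  vd <- vaf_distribution_by_class(exp$classification)
  med <- setNames(vd$median, vd$class)
  expect_lt(abs(med["common"] - 0.40), 0.05)
  expect_gt(med["common"], med["shared"])
  expect_gt(med["common"], med["private"])
})

test_that("inconsistent loci across call sets are rejected", {
  cs1 <- manual_call_set(TRUE, 0.4, "region_1")
  cs2 <- manual_call_set(TRUE, 0.4, "region_2", ids = "other")
  expect_error(classify_variants(list(cs1, cs2)), "inconsistent loci")
})
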