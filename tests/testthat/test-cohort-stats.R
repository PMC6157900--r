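test_that("the rank test equals Friedman's chi-square on complete data", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(6:25, 1); K <- sample(3:6, 1)
    tab <- matrix(rnorm(n * K), n, K)
    wt <- wittkowski_test(tab)
    fr <- friedman.test(tab)
    expect_equal(wt$statistic, unname(fr$statistic), tolerance = 1e-10)
    expect_equal(wt$df, unname(fr$parameter))
  }
})

test_that("degenerate and strongly shifted tables behave as expected", {
  tab <- matrix(5, 12, 4)
  res <- wittkowski_test(tab)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)

  ## one condition shifted by 2 pooled SDs, 10% missing
  set.seed(202)
  tab <- matrix(rnorm(20 * 4), 20, 4)
  tab[, 2] <- tab[, 2] + 2
  tab[sample(length(tab), 8)] <- NA
  expect_lt(wittkowski_test(tab)$p.value, 0.01)

  expect_error(wittkowski_test(matrix(rnorm(10), 10, 1)), "2 conditions")
  all_na <- matrix(NA_real_, 5, 4); all_na[, 1] <- 1
  expect_error(wittkowski_test(all_na), "2 or more")
})

test_that("pairwise Scheffe contrasts are conservative and targeted", {
  ## identical conditions: everything non-significant
  tab <- matrix(rep(rnorm(15), 4), 15, 4)
  pw <- scheffe_pairwise(tab)
  expect_true(all(pw$p_adjusted > 0.99))

  ## adjusted >= unadjusted always
  set.seed(303)
  tab <- matrix(rnorm(18 * 5), 18, 5)
  pw <- scheffe_pairwise(tab)
  expect_true(all(pw$p_adjusted >= pw$p_unadjusted - 1e-12))

  ## only contrasts involving the one shifted condition are significant
  set.seed(304)
  tab <- matrix(rnorm(25 * 4, sd = 0.5), 25, 4)
  tab[, 3] <- tab[, 3] + 3
  pw <- scheffe_pairwise(tab)
  hit <- pw$p_adjusted < 0.05
  involves3 <- pw$cond_a == "C3" | pw$cond_b == "C3"
  expect_true(all(hit == involves3))
})

test_that("type-I error of the rank test is controlled under missingness", {
  ## 2000 null tables, n = 20 subjects x 4 conditions, 10% MCAR
  set.seed(1234)
  rej <- 0L; n_tab <- 2000L
  for (i in seq_len(n_tab)) {
    tab <- matrix(rnorm(20 * 4), 20, 4)
    tab[runif(80) < 0.1] <- NA
    ok <- rowSums(!is.na(tab)) >= 2
    p <- wittkowski_test(tab)$p.value
    if (p < 0.05) rej <- rej + 1L
  }
  rate <- rej / n_tab
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("correlation clustering recovers block structure and masks noise", {
  ## duplicated variable: R = 1 and first merge in the dendrogram
  set.seed(42)
  x <- rnorm(60)
  tab <- data.frame(a = x, b = x, c = rnorm(60), d = rnorm(60))
  cl <- correlation_cluster(tab)
  expect_equal(cl$R["a", "b"], 1)
  expect_equal(sort(cl$hclust$merge[1, ]), c(-2, -1))

  ## three latent factors, four noisy indicators each
  set.seed(77)
  n <- 200
  f <- matrix(rnorm(n * 3), n, 3)
  tab <- do.call(cbind, lapply(1:3, function(k)
    sapply(1:4, function(j) f[, k] + rnorm(n, sd = 0.4))))
  colnames(tab) <- paste0("v", rep(1:3, each = 4), "_", rep(1:4, 3))
  cl <- correlation_cluster(tab)
  blocks <- cutree(cl$hclust, k = 3)
  expect_equal(length(unique(blocks[1:4])), 1)
  expect_equal(length(unique(blocks[5:8])), 1)
  expect_equal(length(unique(blocks[9:12])), 1)
  expect_equal(length(unique(blocks[c(1, 5, 9)])), 3)

  ## independent Gaussians: small correlations, overwhelmingly masked
  set.seed(99)
  tab0 <- matrix(rnorm(200 * 6), 200, 6)
  cl0 <- correlation_cluster(tab0)
  off <- abs(cl0$R[upper.tri(cl0$R)])
  expect_lt(max(off), 0.25)
  expect_gt(mean(cl0$nonsig_mask[upper.tri(cl0$nonsig_mask)]), 0.8)

  ## constant variable is excluded, not fatal
  tabc <- data.frame(tab0, const = 1)
  clc <- correlation_cluster(tabc)
  expect_equal(clc$excluded, "const")
})

test_that("correlation clustering is invariant under monotone transforms", {
  set.seed(11)
  n <- 100
  a <- rnorm(n); b <- a + rnorm(n, sd = 0.5); c <- rnorm(n)
  t1 <- data.frame(a = a, b = b, c = c)
  t2 <- data.frame(a = exp(a), b = b^3, c = c) # strictly monotone maps
  c1 <- correlation_cluster(t1); c2 <- correlation_cluster(t2)
  expect_equal(c1$R, c2$R, tolerance = 1e-12)
  expect_equal(c1$order, c2$order)
})

test_that("two-group tests match their reference implementations", {
  set.seed(5)
  x <- rnorm(30); y <- rnorm(30)
  same <- two_group_tests(x, x)
  expect_gt(same$p.value, 0.9)
  ## strong shift is detected
  shifted <- two_group_tests(x, y + 3)
  expect_lt(shifted$p.value, 0.001)
  ## reconstructed gender table of the two cohorts: 15/35 vs 15/32 male
  g_hd <- rep(c("male", "female"), c(15, 20))
  g_ct <- rep(c("male", "female"), c(15, 17))
  gt <- two_group_tests(g_hd, g_ct)
  expect_equal(gt$method, "chisq_yates")
  expect_gt(gt$p.value, 0.05) # no gender imbalance between groups
  oracle <- suppressWarnings(chisq.test(rbind(c(15, 20), c(15, 17)),
                                        correct = TRUE))
  expect_equal(gt$p.value, oracle$p.value)
  expect_error(two_group_tests(numeric(0), y), "empty")
})

test_that("propensity matching handles degenerate designs", {
  ## identical covariate tables: everyone can be matched, balance p ~ 1
  subj <- data.frame(group = rep(c("hd", "control"), each = 12),
                     age = rep(40:51, 2),
                     gender = rep(rep(c("male", "female"), 6), 2))
  m <- propensity_score_match(subj, seed = 3)
  expect_equal(nrow(m$matched), 12)
  expect_gt(m$balance$p_after[m$balance$covariate == "age"], 0.9)

  ## disjoint age ranges with a tight caliper: explicit empty result
  subj2 <- data.frame(group = rep(c("hd", "control"), each = 10),
                      age = c(rnorm(10, 80, 1), rnorm(10, 20, 1)),
                      gender = rep("male", 20))
  m2 <- propensity_score_match(subj2, covariates = "age", caliper = 0.05,
                               seed = 3)
  expect_equal(nrow(m2$matched), 0)
})

test_that("matching the synthetic cohorts reproduces the before/after pattern", {
  ## seeded cohort drawn at the published age distributions
  spec <- population_spec()
  ds <- generate_cohort_dataset(35, 32, spec, seed = 7, waveforms = "none")
  subj <- ds$subjects
  pre <- two_group_tests(subj$age[subj$group == "hd"],
                         subj$age[subj$group == "control"])
  expect_lt(pre$p.value, 0.001)
  m <- propensity_score_match(subj, seed = 7)
  expect_gt(m$balance$p_after[m$balance$covariate == "age"], 0.05)
  expect_lt(nrow(m$matched), min(sum(subj$group == "hd"),
                                 sum(subj$group == "control")))
  ## standardized mean age difference never worsens
  expect_lte(abs(m$balance$smd_after[m$balance$covariate == "age"]),
             abs(m$balance$smd_before[m$balance$covariate == "age"]))
})
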