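test_that("Mann-Whitney examples and symmetry hold exactly", {
  r <- mwu(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1 / 3)
  expect_identical(r$method, "exact")
  # identical multisets: exact two-sided p = 1
  expect_equal(mwu(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
})

test_that("exact Mann-Whitney agrees with brute-force enumeration", {
  set.seed(50)
  for (rep in 1:50) {
    nx <- sample(2:6, 1)
    ny <- sample(2:6, 1)
    # draw from a small integer support so ties are common
    x <- sample(1:5, nx, replace = TRUE)
    y <- sample(1:5, ny, replace = TRUE)
    alt <- sample(c("two.sided", "greater", "less"), 1)
    expect_equal(mwu(x, y, alt)$p_value, brute_mwu_p(x, y, alt),
                 tolerance = 1e-12,
                 info = paste(alt, paste(x, collapse = ","),
                              paste(y, collapse = ",")))
  }
})

test_that("rank tests agree with the base-R implementations on tie-free data", {
  set.seed(53)
  for (rep in 1:10) {
    x <- rnorm(sample(4:9, 1))
    y <- rnorm(sample(4:9, 1))
    expect_equal(mwu(x, y)$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
    expect_equal(mwu(x, y, "greater")$statistic,
                 unname(wilcox.test(x, y, alternative = "greater")$statistic))
  }
  x <- rnorm(15)
  y <- rnorm(15)
  r <- spearman(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  expect_equal(r$statistic, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(r$p_value, ct$p.value, tolerance = 1e-6)
})

test_that("one-tailed p is at most the two-tailed p in the matching direction", {
  set.seed(51)
  for (rep in 1:10) {
    x <- rnorm(6, 1)
    y <- rnorm(6)
    two <- mwu(x, y, "two.sided")$p_value
    one <- mwu(x, y, if (median(x) > median(y)) "greater" else "less")$p_value
    expect_lte(one, two + 1e-12)
  }
})

test_that("Spearman handles monotone extremes and matches permutation p", {
  expect_equal(spearman(1:6, (1:6)^2)$statistic, 1)
  expect_equal(spearman(1:6, -(1:6))$statistic, -1)
  # n = 5 fixture vs the full 120-permutation enumeration
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  r <- spearman(x, y)
  perms <- steppekin:::all_perms(5)
  rhos <- apply(perms, 1, function(pm) cor(rank(x), rank(y[pm])))
  expect_equal(r$p_value, mean(abs(rhos) >= abs(r$statistic) - 1e-12))
  expect_identical(r$method, "exact permutation")
  expect_identical(spearman(rnorm(20), rnorm(20))$method, "t approximation")
})

test_that("Yates chi-squared matches the closed form and is transpose-invariant", {
  r0 <- chi2_yates(matrix(c(10, 10, 10, 10), 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  r <- chi2_yates(matrix(c(20, 0, 0, 20), 2))
  expect_equal(r$statistic, 4 * (10 - 0.5)^2 / 10, tolerance = 1e-10)
  expect_lt(r$p_value, 1e-8)
  tab <- matrix(c(12, 5, 3, 9), 2)
  expect_equal(chi2_yates(tab)$statistic, chi2_yates(t(tab))$statistic)
})

test_that("confounder regressions recover exact fits and decompose variance", {
  tab <- data.frame(out = 2 * (1:10), cov1 = 1:10,
                    cov2 = rnorm(10), eco = rep(c("a", "b"), 5))
  # the planted outcome is an exact linear function, so lm warns about a
  # perfect fit; that is the point of the fixture
  r <- suppressWarnings(regress_confounders(tab, "out",
                                            c("cov1", "cov2", "eco")))
  row <- r$single[r$single$covariate == "cov1", ]
  expect_equal(row$estimate, 2, tolerance = 1e-10)
  expect_equal(row$r_squared, 1, tolerance = 1e-10)
  # ANOVA sums of squares add to total SS
  m <- r$multiple[[1]]
  expect_equal(sum(m$anova[, "Sum Sq"]),
               sum((tab$out - mean(tab$out))^2), tolerance = 1e-8)
})

test_that("permuted covariates give uniform slope p-values", {
  set.seed(52)
  pvals <- vapply(1:60, function(i) {
    tab <- data.frame(out = rnorm(12), cov1 = rnorm(12))
    regress_confounders(tab, "out", "cov1")$single$p_value
  }, 0)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the distance-binned report joins losslessly and is deterministic", {
  coh <- simulate_cohort(n_per_pop = 15, populations = 2, n_snps = 400,
                         n_chrom = 4, total_cM = 300, seed = 9)
  fits <- data.frame(individual_id = coh$truth$individual_id,
                     population_code = coh$truth$population_code,
                     F_Median = coh$truth$f_true,
                     A_Median = 0.05, lrt_stat = 0, lrt_p = 1,
                     inbred = coh$truth$f_true > 0)
  rep1 <- exogamy_inbreeding_report(coh$survey, fits)
  expect_equal(nrow(rep1$data), nrow(fits))  # all ids joined
  expect_equal(rep1$n_excluded, 0)
  expect_equal(sum(rep1$bin_table$n[rep1$bin_table$measure == "F_Median"]),
               nrow(fits))
  rep2 <- exogamy_inbreeding_report(coh$survey, fits)
  expect_identical(rep1$bin_table, rep2$bin_table)
  # class-C ROH measures are picked up when provided
  roh <- data.frame(individual_id = fits$individual_id,
                    n_C = rpois(nrow(fits), 2),
                    kb_C = runif(nrow(fits), 0, 5e4))
  rep3 <- exogamy_inbreeding_report(coh$survey, fits, roh_summary = roh)
  expect_setequal(unique(rep3$bin_table$measure),
                  c("F_Median", "n_C", "kb_C"))
})

test_that("population-level correlates assemble and correlate", {
  fits <- data.frame(individual_id = as.character(1:40),
                     population_code = rep(c("A", "B", "C", "D"), each = 10),
                     F_Median = rep(c(0.0, 0.02, 0.04, 0.06), each = 10),
                     inbred = c(rep(FALSE, 10), rep(c(FALSE, TRUE), 5),
                                rep(c(FALSE, TRUE, TRUE, TRUE, TRUE), 2),
                                rep(TRUE, 10)))
  prof <- data.frame(population_code = c("A", "B", "C", "D"),
                     exogamy_rate = c(0.1, 0.3, 0.5, 0.7))
  pc <- population_correlates(prof, fits)
  expect_equal(nrow(pc$table), 4)
  expect_equal(pc$table$pct_lrt_inbred, c(0, 50, 80, 100))
  expect_equal(pc$correlations$pct_lrt_inbred$statistic, 1, tolerance = 1e-9)
})
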