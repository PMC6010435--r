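test_that("forward log-likelihood equals exhaustive path enumeration", {
  set.seed(40)
  for (rep in 1:6) {
    m <- sample(3:8, 1)
    calls <- sample(c(0:2, NA), m, replace = TRUE, prob = c(.3, .3, .3, .1))
    freqs <- runif(m, 0.1, 0.9)
    chrom <- sort(sample(1:2, m, replace = TRUE))
    cM <- unname(unlist(tapply(runif(m, 0, 10), chrom, sort)))
    f <- runif(1, 0.01, 0.4)
    a <- runif(1, 0.01, 0.5)
    eps <- sample(c(0, 0.001, 0.02), 1)
    expect_equal(hmm_loglik(calls, freqs, cM, chrom, f, a, eps),
                 brute_hmm_loglik(calls, freqs, cM, chrom, f, a, eps),
                 tolerance = 1e-8)
  }
})

test_that("single-state collapses: f = 0 gives Hardy-Weinberg, f = 1 per-site IBD", {
  calls <- c(0L, 1L, 2L, 2L, 0L)
  freqs <- c(0.2, 0.5, 0.7, 0.9, 0.4)
  cM <- c(0, 1, 2, 3, 4)
  chrom <- rep(1L, 5)
  hw <- sum(log(c((1 - 0.2)^2, 2 * 0.5 * 0.5, 0.7^2, 0.9^2, (1 - 0.4)^2)))
  expect_equal(hmm_loglik(calls, freqs, cM, chrom, 0, 0.05, 0), hw,
               tolerance = 1e-10)
  hom <- c(0L, 2L, 2L, 0L)
  fh <- c(0.3, 0.6, 0.8, 0.2)
  ibd <- sum(log(c(1 - 0.3, 0.6, 0.8, 1 - 0.2)))
  # at f = 1 every path stays in the IBD state (the user-facing wrapper caps
  # f at 0.5, so evaluate the forward pass directly)
  e <- steppekin:::ibd_emissions(hom, fh, 0)
  ll1 <- steppekin:::cpp_hmm_loglik(e$eN, e$eI, c(0, 1, 1, 1),
                                    c(1L, 0L, 0L, 0L), 1, 1e-3)
  expect_equal(ll1, ibd, tolerance = 1e-8)
})

test_that("likelihood is invariant to chromosome processing order", {
  set.seed(41)
  m <- 30
  calls <- sample(0:2, m, replace = TRUE)
  freqs <- runif(m, 0.2, 0.8)
  chrom <- rep(1:3, each = 10)
  cM <- rep(seq(0, 18, 2), 3)
  ll <- hmm_loglik(calls, freqs, cM, chrom, 0.1, 0.06)
  perm <- c(21:30, 1:10, 11:20)  # chromosomes in order 3, 1, 2
  ll2 <- hmm_loglik(calls[perm], freqs[perm], cM[perm], chrom[perm],
                    0.1, 0.06)
  expect_equal(ll, ll2, tolerance = 1e-10)
})

test_that("invalid inputs are rejected", {
  expect_error(hmm_loglik(c(0L, 1L), c(0.5, 0.5), c(2, 1), c(1, 1),
                          0.1, 0.05), "ordered")
  expect_error(hmm_loglik(c(0L, 1L), c(0, 0.5), c(1, 2), c(1, 1),
                          0.1, 0.05), "frequencies")
})

test_that("a fully heterozygous individual is driven to the f lower bound", {
  panel <- small_panel(n_snps = 300, n_chrom = 2, total_cM = 300)
  calls <- rep(1L, 300)
  freqs <- pmin(pmax(panel$snps$freq_alt, 0.05), 0.95)
  fit <- fit_festim(calls, freqs, panel$snps$pos_cM, panel$snps$chrom,
                    eps = 0)
  expect_lt(fit$f, 1e-5)
})

test_that("the optimum is never below the best grid start", {
  panel <- small_panel(n_snps = 400, n_chrom = 4, total_cM = 400)
  snps <- panel$snps
  freqs <- pmin(pmax(snps$freq_alt, 1e-3), 1 - 1e-3)
  for (s in 1:3) {
    gd <- gene_drop(pedigree_spec("1C"), simulate_founders(8, snps), snps,
                    seed = 50 + s)
    fit <- fit_festim(gd$genotype, freqs, snps$pos_cM, snps$chrom)
    expect_gte(fit$logL, fit$logL_grid_best - 1e-9)
  }
})

test_that("submaps respect spacing, determinism and the all-markers case", {
  snps <- data.frame(chrom = rep(1:2, each = 30),
                     pos_cM = rep(seq(0, 29), 2))
  subs <- sample_submaps(snps, n_submaps = 10, min_spacing_cM = 0.5,
                         seed = 60)
  for (sm in subs) {
    d <- diff(snps$pos_cM[sm])
    same <- snps$chrom[sm][-1] == snps$chrom[sm][-length(sm)]
    expect_true(all(d[same] > 0.5))
  }
  # markers 1 cM apart: every submap keeps all markers from its start
  expect_true(all(vapply(subs, length, 0L) == 60))
  expect_identical(subs, sample_submaps(snps, 10, 0.5, seed = 60))
  # denser panel: spacing still respected
  snps2 <- data.frame(chrom = 1, pos_cM = sort(runif(200, 0, 20)))
  subs2 <- sample_submaps(snps2, 5, 0.5, seed = 61)
  for (sm in subs2) expect_true(all(diff(snps2$pos_cM[sm]) > 0.5))
})

test_that("F-Median is a submap median with the expected invariances", {
  panel <- small_panel(n_snps = 600, n_chrom = 4, total_cM = 600)
  snps <- panel$snps
  freqs <- pmin(pmax(snps$freq_alt, 1e-3), 1 - 1e-3)
  gd <- gene_drop(pedigree_spec("1C"), simulate_founders(8, snps), snps,
                  seed = 70)
  fm <- f_median(gd$genotype, snps, freqs, n_submaps = 9, seed = 71)
  expect_equal(fm$F_Median, median(fm$fits$f))
  expect_equal(fm$A_Median, median(fm$fits$a))
  # median is invariant to submap order
  expect_equal(fm$F_Median, median(rev(fm$fits$f)))
  # the consensus submap's f is the (odd-count) median
  expect_equal(fm$fits$f[fm$consensus], fm$F_Median)
})

test_that("LRT collapses to p = 1 at the boundary and flags strong inbreeding", {
  fake <- structure(list(fits = data.frame(f = 1e-6, a = 0.05, logL = -100,
                                           logL0 = -100),
                         F_Median = 1e-6, A_Median = 0.05, consensus = 1),
                    class = "ibd_fit")
  l <- lrt_inbred(fake)
  expect_equal(l$stat, 0)
  expect_equal(l$p, 1)
  expect_false(l$inbred)
  # sib-mating offspring on a modest panel are confidently inbred
  panel <- small_panel(n_snps = 800, n_chrom = 6, total_cM = 900)
  snps <- panel$snps
  freqs <- pmin(pmax(snps$freq_alt, 1e-3), 1 - 1e-3)
  hits <- vapply(1:10, function(s) {
    gd <- gene_drop(pedigree_spec("SIB"), simulate_founders(4, snps), snps,
                    seed = 80 + s)
    fm <- f_median(gd$genotype, snps, freqs, n_submaps = 7, seed = 80 + s)
    lrt_inbred(fm)$inbred
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("reference clouds order by pedigree F and by segment turnover", {
  panel <- small_panel(n_snps = 900, n_chrom = 6, total_cM = 1500)
  ref <- reference_distributions(panel$snps,
                                 types = c("AV", "1C", "2C", "OUT"),
                                 n_sims = 25, n_submaps = 6, seed = 90)
  mF <- tapply(ref$F_Median, ref$mating_type, mean)
  expect_lt(mF["OUT"], mF["2C"])
  expect_lt(mF["2C"], mF["1C"])
  expect_lte(mF["1C"], mF["AV"] + 0.01)
  # shorter loops -> longer segments -> smaller a (among truly inbred sims)
  inb <- ref[ref$f_true > 0.01, ]
  mA <- tapply(inb$A_Median, inb$mating_type, mean)
  expect_lt(mA["AV"], mA["2C"])
})

test_that("mating-type classification is sane at cloud centroids", {
  set.seed(91)
  ref <- do.call(rbind, lapply(c("AV", "2x1C", "1C", "2C"), function(ty) {
    ctr <- switch(ty, AV = c(0.125, 0.045), `2x1C` = c(0.125, 0.065),
                  `1C` = c(0.0625, 0.06), `2C` = c(0.0156, 0.08))
    data.frame(mating_type = ty, sim = 1:40,
               F_Median = pmax(rnorm(40, ctr[1], 0.01), 1e-4),
               A_Median = pmax(rnorm(40, ctr[2], 0.008), 1e-3))
  }))
  class(ref) <- c("ibd_reference", "data.frame")
  cl <- classify_mating_type(0.0625, 0.06, ref, inbred = TRUE)
  expect_identical(cl$mating_type, "1C")
  expect_equal(sum(cl$posteriors), 1, tolerance = 1e-9)
  # LRT-outbred individuals are OUT regardless of position
  cl2 <- classify_mating_type(0.0625, 0.06, ref, inbred = FALSE)
  expect_identical(cl2$mating_type, "OUT")
  expect_equal(unname(cl2$posteriors["OUT"]), 1)
})
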