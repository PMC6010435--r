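test_that("ASD matches direct allele counting and its boundary cases", {
  snps <- small_panel(n_snps = 50, n_chrom = 1, total_cM = 50)$snps
  # identical individuals -> 0; opposite homozygotes -> 1
  calls <- rbind(rep(0L, 50), rep(0L, 50), rep(2L, 50))
  gt <- genotype_table(c("a", "b", "c"), snps, calls)
  asd <- asd_matrix(gt)
  expect_equal(asd["a", "b"], 0)
  expect_equal(asd["a", "c"], 1)
  # random fixture vs the brute-force counting oracle
  set.seed(20)
  calls <- matrix(sample(c(0:2, NA), 10 * 50, replace = TRUE,
                         prob = c(.3, .3, .3, .1)), 10, 50)
  snps50 <- snps
  gt <- genotype_table(paste0("s", 1:10), snps50, calls)
  expect_equal(unname(asd_matrix(gt)), brute_asd(calls), tolerance = 1e-12)
  expect_true(all(diag(asd_matrix(gt)) == 0))
})

test_that("kinship estimator recovers parent-offspring and unrelated pairs", {
  set.seed(21)
  panel <- small_panel(n_snps = 2000, n_chrom = 4, total_cM = 400)
  snps <- panel$snps
  p <- snps$freq_alt
  n <- 40
  haps <- simulate_founders(2 * n + 10, snps)
  calls <- haps[seq(1, 2 * n, 2), ] + haps[seq(2, 2 * n, 2), ]
  # samples 1..5 each get an offspring inheriting their first haplotype
  kids <- t(vapply(1:5, function(k) haps[2 * k - 1, ] + haps[2 * n + k, ],
                   integer(ncol(haps))))
  gt <- genotype_table(c(paste0("s", 1:n), paste0("kid", 1:5)), snps,
                       rbind(calls, kids))
  phi <- pairwise_kinship(gt, freqs = p)
  po <- vapply(1:5, function(k) phi[paste0("s", k), paste0("kid", k)], 0)
  expect_equal(mean(po), 0.25, tolerance = 0.03)
  unrel <- phi[paste0("s", 11:20), paste0("s", 21:30)]
  expect_equal(mean(unrel), 0, tolerance = 0.01)
  expect_true(max(abs(unrel)) < 0.1)
  expect_equal(phi, t(phi))
})

test_that("relative exclusion is greedy, deterministic and complete", {
  ids <- c("a", "b", "c", "d")
  k <- matrix(0, 4, 4, dimnames = list(ids, ids))
  expect_identical(exclude_relatives(k), ids)  # nothing to do
  # one sib pair: exactly one of the two removed
  k["a", "b"] <- k["b", "a"] <- 0.25
  kept <- exclude_relatives(k)
  expect_equal(length(kept), 3)
  expect_identical(kept, c("b", "c", "d"))  # tie broken by id order
  # trio of mutual relatives: exhaustive search says removing any 2 works,
  # greedy keeps exactly one of the trio
  k2 <- matrix(0, 4, 4, dimnames = list(ids, ids))
  k2[1:3, 1:3] <- 0.2
  diag(k2) <- 0
  kept2 <- exclude_relatives(k2)
  expect_identical(kept2, c("c", "d"))
  # post-condition: no retained pair above threshold
  sub <- k2[kept2, kept2]
  diag(sub) <- 0
  expect_true(all(sub <= 1 / 16 + 0.02))
})

test_that("low-recombination blocks reproduce a direct scan", {
  snps <- data.frame(snp_id = paste0("s", 1:20), chrom = 1,
                     pos_bp = seq(1e5, 2e6, length.out = 20),
                     pos_cM = seq(0.1, 2, length.out = 20),
                     a1 = "A", a2 = "G")
  snps$pos_bp <- as.integer(snps$pos_bp)
  # rate high everywhere -> no blocks
  gm_hi <- genetic_map(data.frame(chrom = 1, pos_bp = c(1, 3e6),
                                  rate = 2, pos_cM = c(0, 3)))
  expect_equal(nrow(low_recombination_blocks(snps, gm_hi)), 0)
  # one planted low-rate region covering SNPs 6..14
  gm <- genetic_map(data.frame(chrom = 1,
                               pos_bp = c(1, snps$pos_bp[6] - 1,
                                          snps$pos_bp[14] + 1, 3e6),
                               rate = c(2, 0.1, 2, 2),
                               pos_cM = c(0, 0.5, 0.6, 3)))
  bl <- low_recombination_blocks(snps, gm, rate_cutoff = 0.5, min_snps = 5)
  expect_equal(nrow(bl), 1)
  expect_equal(bl$start_idx, 6)
  expect_equal(bl$end_idx, 14)
  expect_equal(bl$n_snps, 9)
  # brute scan oracle over random rate maps
  set.seed(22)
  for (rep in 1:5) {
    rates <- sample(c(0.1, 1), 10, replace = TRUE)
    knots <- c(1, snps$pos_bp[seq(2, 20, 2)] + 1)
    gm2 <- genetic_map(data.frame(chrom = 1, pos_bp = knots,
                                  rate = c(rates, 1)[1:11],
                                  pos_cM = seq(0, 2, length.out = 11)))
    bl2 <- low_recombination_blocks(snps, gm2, 0.5, 2)
    k <- gm2[["1"]]
    local_rate <- k$rate[pmax(1, findInterval(snps$pos_bp, k$pos_bp))]
    runs <- rle(local_rate < 0.5)
    expected_n <- sum(runs$values & runs$lengths >= 2)
    expect_equal(nrow(bl2), expected_n)
  }
})

test_that("block haplotype heterozygosity matches closed forms", {
  snps <- small_panel(n_snps = 40, n_chrom = 1, total_cM = 40)$snps
  blocks <- data.frame(chrom = 1, start_bp = snps$pos_bp[1],
                       end_bp = snps$pos_bp[10], n_snps = 10,
                       start_idx = 1, end_idx = 10)
  # all haplotypes identical -> H = 0
  haps <- matrix(0L, 8, 40)
  h0 <- block_haplotype_heterozygosity(haps, blocks, rep("P", 4))
  expect_equal(h0$mean_het, 0)
  # two equally frequent haplotypes among n = 8: H = n/(n-1) * 0.5
  haps[seq(2, 8, 2), 1:10] <- 1L
  h1 <- block_haplotype_heterozygosity(haps, blocks, rep("P", 4))
  expect_equal(h1$mean_het, 8 / 7 * 0.5)
})

test_that("higher founder diversity raises haplotypic heterozygosity", {
  make_pop <- function(freq_range, seed) {
    panel <- make_snp_panel(300, 2, 100, freq_range = freq_range,
                            seed = seed)
    haps <- simulate_founders(40, panel$snps, seed = seed + 1)
    blocks <- data.frame(chrom = c(1, 2), start_idx = c(1, 151),
                         end_idx = c(20, 170))
    block_haplotype_heterozygosity(haps, blocks, rep("P", 20))$mean_het
  }
  hi <- vapply(1:4, function(s) make_pop(c(0.4, 0.6), 30 + s), 0)
  lo <- vapply(1:4, function(s) make_pop(c(0.01, 0.08), 30 + s), 0)
  expect_true(all(hi > lo))
})

test_that("lower founder diversity lowers median ASD", {
  asd_of <- function(freq_range, seed) {
    panel <- make_snp_panel(400, 2, 100, freq_range = freq_range,
                            seed = seed)
    haps <- simulate_founders(30, panel$snps, seed = seed + 1)
    calls <- haps[seq(1, 29, 2), ] + haps[seq(2, 30, 2), ]
    gt <- genotype_table(paste0("s", 1:15), panel$snps, calls)
    m <- asd_matrix(gt)
    median(m[upper.tri(m)])
  }
  for (s in c(41, 52, 63)) {
    expect_gt(asd_of(c(0.35, 0.65), s), asd_of(c(0.02, 0.1), s))
  }
})
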