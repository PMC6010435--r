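# Shared fixtures and independent oracles, built in code at test time.

# small genotype fixture: 3 samples x 5 SNPs with a missing call
tiny_gt <- function() {
  snps <- data.frame(snp_id = paste0("rs", 1:5), chrom = c(1, 1, 1, 2, 2),
                     pos_bp = c(100L, 200L, 300L, 100L, 250L),
                     pos_cM = c(0.1, 0.2, 0.3, 0.1, 0.25),
                     a1 = c("A", "C", "G", "T", "A"),
                     a2 = c("G", "T", "A", "C", "G"),
                     stringsAsFactors = FALSE)
  calls <- matrix(c(0L, 1L, 2L, NA, 0L,
                    2L, 0L, 1L, 1L, 2L,
                    1L, 1L, 0L, 2L, NA), 3, 5, byrow = TRUE)
  genotype_table(c("s1", "s2", "s3"), snps, calls)
}

# small SNP panel reused across tests (deterministic)
small_panel <- function(n_snps = 1200, n_chrom = 6, total_cM = 900,
                        rate = 1, seed = 424) {
  make_snp_panel(n_snps, n_chrom, total_cM, rate_cM_per_Mb = rate,
                 seed = seed)
}

# exhaustive hidden-path enumeration oracle for the IBD HMM log-likelihood
brute_hmm_loglik <- function(calls, freqs, cM, chrom, f, a, eps) {
  m <- length(calls)
  e <- steppekin:::ibd_emissions(calls, freqs, eps)
  states <- as.matrix(expand.grid(rep(list(0:1), m)))
  tot <- 0
  for (r in seq_len(nrow(states))) {
    s <- states[r, ]
    pr <- 1
    for (i in seq_len(m)) {
      if (i == 1 || chrom[i] != chrom[i - 1]) {
        pr <- pr * if (s[i] == 1) f else 1 - f
      } else {
        d <- cM[i] - cM[i - 1]
        q <- 1 - exp(-a * d)
        pII <- (1 - q) + q * f
        pNI <- q * f
        pr <- pr * if (s[i - 1] == 1) {
          if (s[i] == 1) pII else 1 - pII
        } else {
          if (s[i] == 1) pNI else 1 - pNI
        }
      }
      pr <- pr * if (s[i] == 1) e$eI[i] else e$eN[i]
    }
    tot <- tot + pr
  }
  log(tot)
}

# brute-force exact Mann-Whitney p by enumerating all group assignments
brute_mwu_p <- function(x, y, alternative) {
  nx <- length(x)
  all_v <- c(x, y)
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(nx)])
  combs <- combn(length(all_v), nx)
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  eps <- 1e-9
  p_ge <- mean(ws >= w_obs - eps)
  p_le <- mean(ws <= w_obs + eps)
  switch(alternative,
         greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}

# per-site allele-sharing counting oracle for ASD
brute_asd <- function(calls) {
  n <- nrow(calls)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- 0
    den <- 0
    for (k in seq_len(ncol(calls))) {
      g1 <- calls[i, k]
      g2 <- calls[j, k]
      if (is.na(g1) || is.na(g2)) next
      shared <- 2 - abs(g1 - g2)
      num <- num + shared
      den <- den + 2
    }
    out[i, j] <- 1 - num / den
  }
  out
}
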