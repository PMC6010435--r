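# Per-individual inbreeding: two-state IBD HMM likelihood, (f, a) estimation
# over random sparse submaps, F-Median/A-Median, the inbred/outbred
# likelihood-ratio test, and five-way parental mating-type classification.

# Emission probabilities per marker for both hidden states. p = alt-allele
# frequency; calls are alt counts. Non-IBD emits Hardy-Weinberg genotype
# probabilities; IBD emits {hom ref: 1-p, het: 0, hom alt: p}. With error
# rate eps, the observed genotype equals the true one with probability
# 1 - eps, otherwise one of the two others (eps/2 each). Missing calls emit
# 1 in both states.
ibd_emissions <- function(calls, freqs, eps) {
  p <- freqs
  baseN <- cbind((1 - p)^2, 2 * p * (1 - p), p^2)
  baseI <- cbind(1 - p, 0, p)
  g <- calls + 1L
  i <- seq_along(calls)
  eN <- eI <- rep(1, length(calls))
  ok <- !is.na(g)
  pick <- cbind(i[ok], g[ok])
  eN[ok] <- (1 - eps) * baseN[pick] + (eps / 2) * (1 - baseN[pick])
  eI[ok] <- (1 - eps) * baseI[pick] + (eps / 2) * (1 - baseI[pick])
  list(eN = eN, eI = eI)
}

check_hmm_inputs <- function(calls, freqs, pos_cM, chrom) {
  m <- length(calls)
  stopifnot(length(freqs) == m, length(pos_cM) == m, length(chrom) == m)
  if (any(freqs <= 0 | freqs >= 1))
    stop("allele frequencies must be strictly inside (0, 1)")
  d <- diff(pos_cM)
  same <- chrom[-1] == chrom[-m]
  if (any(d[same] < 0))
    stop("markers must be ordered by cM within chromosome (negative distance)")
  invisible(TRUE)
}

hmm_dist_newchrom <- function(pos_cM, chrom) {
  m <- length(pos_cM)
  nw <- c(1L, as.integer(chrom[-1] != chrom[-m]))
  d <- c(0, diff(pos_cM))
  d[nw == 1] <- 0
  list(d = d, newchrom = nw)
}

#' IBD-HMM forward log-likelihood
#'
#' Log-likelihood of a genotype vector under the two-state autozygosity
#' hidden Markov model. States: IBD (autozygous) and non-IBD. Stationary
#' P(IBD) = f; over a genetic distance of d cM the transition probabilities
#' are P(IBD to IBD) = exp(-a d) + (1 - exp(-a d)) f and P(non-IBD to IBD) =
#' (1 - exp(-a d)) f. The chain restarts at stationarity on each chromosome.
#'
#' @param calls genotype vector (0/1/2 alt counts, NA = missing).
#' @param freqs alt-allele frequencies, strictly in (0, 1).
#' @param pos_cM genetic positions, non-decreasing within chromosome.
#' @param chrom chromosome of each marker.
#' @param f probability a marker is autozygous, in [0, 0.5].
#' @param a per-cM IBD segment turnover rate, > 0.
#' @param eps genotyping-error rate in [0, 0.05].
#' @return Log-likelihood (scalar).
#' @export
hmm_loglik <- function(calls, freqs, pos_cM, chrom, f, a, eps = 0.001) {
  stopifnot(f >= 0, f <= 0.5, a > 0, eps >= 0, eps <= 0.05)
  check_hmm_inputs(calls, freqs, pos_cM, chrom)
  e <- ibd_emissions(calls, freqs, eps)
  dn <- hmm_dist_newchrom(pos_cM, chrom)
  cpp_hmm_loglik(e$eN, e$eI, dn$d, dn$newchrom, f, a)
}

FESTIM_BOUNDS <- list(fl = 1e-6, fu = 0.5, al = 1e-3, au = 1)
FESTIM_STARTS <- list(f = c(0.005, 0.05, 0.2), a = c(0.01, 0.06, 0.3))

#' Maximum-likelihood (f, a) fit
#'
#' Maximises the \code{\link{hmm_loglik}} over f in [1e-6, 0.5] and a in
#' [1e-3, 1] per cM, starting from a 3 x 3 grid of (f, a) values and
#' refining the best starts by direct search. The returned log-likelihood is
#' never below the best grid value.
#'
#' @inheritParams hmm_loglik
#' @param n_refine number of grid starts refined by the optimiser.
#' @return list: \code{f}, \code{a}, \code{logL}, \code{logL0} (the f = 0
#'   null log-likelihood), \code{logL_grid_best}, \code{boundary} (TRUE if
#'   the fit sits on the f boundary).
#' @export
fit_festim <- function(calls, freqs, pos_cM, chrom, eps = 0.001,
                       n_refine = 3) {
  check_hmm_inputs(calls, freqs, pos_cM, chrom)
  if (sum(!is.na(calls)) < 50)
    stop("need at least 50 informative markers")
  e <- ibd_emissions(calls, freqs, eps)
  dn <- hmm_dist_newchrom(pos_cM, chrom)
  b <- FESTIM_BOUNDS
  r <- cpp_fit_festim(e$eN, e$eI, dn$d, dn$newchrom,
                      FESTIM_STARTS$f, FESTIM_STARTS$a,
                      b$fl, b$fu, b$al, b$au, n_refine, 200L, 1e-8)
  list(f = unname(r["f"]), a = unname(r["a"]), logL = unname(r["logL"]),
       logL0 = sum(log(e$eN)),
       logL_grid_best = unname(r["logL_grid_best"]),
       boundary = unname(r["f"]) >= b$fu * 0.999)
}

#' Random sparse submaps
#'
#' Each submap starts at a random marker near the beginning of each
#' chromosome and then greedily accepts, left to right, the next marker
#' strictly more than \code{min_spacing_cM} away from the last accepted one,
#' giving subsets of approximately independent SNPs.
#'
#' @param snps SNP metadata with \code{chrom} and \code{pos_cM}.
#' @param n_submaps number of subsets.
#' @param min_spacing_cM minimum spacing between consecutive accepted
#'   markers.
#' @param seed optional RNG seed (same seed, same subsets).
#' @return list of integer index vectors into \code{snps}.
#' @export
sample_submaps <- function(snps, n_submaps = 100, min_spacing_cM = 0.5,
                           seed = NULL) {
  chrom_idx <- split(seq_len(nrow(snps)), snps$chrom)
  with_seed(seed, {
    lapply(seq_len(n_submaps), function(s) {
      unlist(lapply(chrom_idx, function(idx) {
        cm <- snps$pos_cM[idx]
        # random start among markers in the first spacing window
        in_win <- which(cm <= cm[1] + min_spacing_cM)
        start <- sample(length(in_win), 1)
        keep <- start
        last <- cm[start]
        for (i in seq_along(idx)[-seq_len(start)]) {
          if (cm[i] - last > min_spacing_cM) {
            keep <- c(keep, i)
            last <- cm[i]
          }
        }
        idx[keep]
      }), use.names = FALSE)
    })
  })
}

#' F-Median and A-Median over submaps
#'
#' Fits the IBD HMM on each of \code{n_submaps} random sparse marker
#' subsets and takes the medians of the per-submap estimates. The submap
#' whose f estimate sits at the per-submap median (the consensus submap) is
#' recorded for the likelihood-ratio test.
#'
#' @param calls genotype vector for one individual.
#' @param snps SNP metadata (chrom, pos_cM).
#' @param freqs alt-allele frequencies in (0, 1).
#' @param n_submaps number of submaps.
#' @param min_spacing_cM submap spacing.
#' @param eps genotyping-error rate.
#' @param seed optional RNG seed for submap sampling.
#' @return Object of class \code{"ibd_fit"}: \code{fits} (per-submap f, a,
#'   logL, logL0), \code{F_Median}, \code{A_Median}, \code{consensus} (row
#'   index of the consensus submap).
#' @export
f_median <- function(calls, snps, freqs, n_submaps = 100,
                     min_spacing_cM = 0.5, eps = 0.001, seed = NULL) {
  if (any(freqs <= 0 | freqs >= 1))
    stop("allele frequencies must be strictly inside (0, 1)")
  submaps <- sample_submaps(snps, n_submaps, min_spacing_cM, seed = seed)
  e <- ibd_emissions(calls, freqs, eps)
  b <- FESTIM_BOUNDS
  fits <- cpp_fit_submaps(e$eN, e$eI, snps$pos_cM, snps$chrom, submaps,
                          FESTIM_STARTS$f, FESTIM_STARTS$a,
                          b$fl, b$fu, b$al, b$au, 3L, 200L, 1e-8)
  fits <- as.data.frame(fits)
  Fm <- median(fits$f)
  Am <- median(fits$a)
  consensus <- which.min(abs(fits$f - Fm))
  structure(list(fits = fits, F_Median = Fm, A_Median = Am,
                 consensus = consensus, eps = eps),
            class = "ibd_fit")
}

#' Likelihood-ratio test for inbreeding
#'
#' Compares the fitted model against the f = 0 (outbred) null on the
#' consensus submap (the submap whose f estimate is the per-submap median).
#' The statistic 2 (logL1 - logL0) is referred to the boundary mixture
#' 0.5 chi2_0 + 0.5 chi2_1.
#'
#' @param fit an \code{"ibd_fit"} from \code{\link{f_median}}.
#' @param alpha significance level for the inbred call.
#' @return list: \code{stat}, \code{p}, \code{inbred}.
#' @export
lrt_inbred <- function(fit, alpha = 0.05) {
  row <- fit$fits[fit$consensus, ]
  stat <- max(0, 2 * (row$logL - row$logL0))
  p <- if (stat <= 0) 1 else 0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
  list(stat = stat, p = p, inbred = p < alpha)
}

#' Leave-one-out allele frequencies
#'
#' Alt-allele frequencies within a population excluding the focal
#' individual, clamped away from 0 and 1 so they are usable as HMM emission
#' frequencies.
#'
#' @param calls genotype matrix (individuals x SNPs) of the population.
#' @param focal row index of the focal individual.
#' @return Frequency vector in (0, 1).
#' @export
loo_freqs <- function(calls, focal) {
  other <- calls[-focal, , drop = FALSE]
  n2 <- 2 * colSums(!is.na(other))
  cnt <- colSums(other, na.rm = TRUE)
  lo <- 0.5 / pmax(n2, 2)
  p <- cnt / pmax(n2, 2)
  pmin(pmax(p, lo), 1 - lo)
}

#' Per-individual inbreeding estimates for a cohort
#'
#' Runs \code{\link{f_median}} and \code{\link{lrt_inbred}} for every sample
#' with leave-one-out within-population allele frequencies.
#'
#' @param gt a \code{\link{genotype_table}}.
#' @param populations population code per sample (single population assumed
#'   when missing).
#' @param freqs optional fixed frequency vector overriding the leave-one-out
#'   estimate (e.g. known simulation frequencies).
#' @inheritParams f_median
#' @return data frame: \code{individual_id}, \code{population_code},
#'   \code{F_Median}, \code{A_Median}, \code{lrt_stat}, \code{lrt_p},
#'   \code{inbred}.
#' @export
estimate_inbreeding <- function(gt, populations = NULL, freqs = NULL,
                                n_submaps = 100, min_spacing_cM = 0.5,
                                eps = 0.001, seed = NULL) {
  n <- length(gt$samples)
  populations <- populations %||% rep("pop", n)
  res <- vector("list", n)
  seeds <- if (is.null(seed)) rep(list(NULL), n) else
    as.list(seed + seq_len(n))
  for (i in seq_len(n)) {
    p <- freqs %||% {
      rows <- which(populations == populations[i])
      loo_freqs(gt$calls[rows, , drop = FALSE], match(i, rows))
    }
    fit <- f_median(gt$calls[i, ], gt$snps, p, n_submaps = n_submaps,
                    min_spacing_cM = min_spacing_cM, eps = eps,
                    seed = seeds[[i]])
    lrt <- lrt_inbred(fit)
    res[[i]] <- data.frame(individual_id = gt$samples[i],
                           population_code = populations[i],
                           F_Median = fit$F_Median, A_Median = fit$A_Median,
                           lrt_stat = lrt$stat, lrt_p = lrt$p,
                           inbred = lrt$inbred, stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Simulated (F-Median, A-Median) reference clouds
#'
#' Simulates offspring of each requested mating type by gene dropping and
#' pushes each through \code{\link{f_median}}, yielding the empirical
#' reference distribution used by \code{\link{classify_mating_type}}.
#'
#' @param snps SNP panel with \code{freq_alt}.
#' @param types mating types to simulate.
#' @param n_sims pedigree simulations per type.
#' @param n_submaps submaps per simulated individual.
#' @param eps genotyping-error rate used in the fits.
#' @param seed RNG seed (stored in the result).
#' @return data frame of class \code{"ibd_reference"}: \code{mating_type},
#'   \code{sim}, \code{F_Median}, \code{A_Median}, \code{f_true}.
#' @export
reference_distributions <- function(snps, types = c("AV", "2x1C", "1C",
                                                    "2C", "OUT"),
                                    n_sims = 100, n_submaps = 100,
                                    eps = 0.001, seed = NULL) {
  freqs <- pmin(pmax(snps$freq_alt, 1e-4), 1 - 1e-4)
  with_seed(seed, {
    rows <- list()
    for (ty in types) {
      spec <- pedigree_spec(ty)
      nf <- sum(is.na(spec$pedigree$father))
      for (s in seq_len(n_sims)) {
        fh <- simulate_founders(2 * nf, snps)
        gd <- gene_drop(spec, fh, snps)
        fit <- f_median(gd$genotype, snps, freqs, n_submaps = n_submaps,
                        eps = eps)
        rows[[length(rows) + 1]] <- data.frame(
          mating_type = ty, sim = s, F_Median = fit$F_Median,
          A_Median = fit$A_Median, f_true = gd$f_true,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    attr(out, "seed") <- seed
    class(out) <- c("ibd_reference", "data.frame")
    out
  })
}

# product-Gaussian kernel density of a 2D cloud evaluated at one point
kde2_eval <- function(x, y, px, py) {
  bx <- max(bw.nrd0(x), 1e-4)
  by <- max(bw.nrd0(y), 1e-4)
  mean(dnorm(px, x, bx) * dnorm(py, y, by))
}

#' Classify the parental mating type
#'
#' Two-step rule: individuals whose likelihood-ratio test is not
#' significant are assigned OUT directly. Otherwise the (F-Median,
#' log10 A-Median) point is scored against a 2D Gaussian kernel density of
#' each inbred reference cloud; posteriors are the normalised densities
#' under a uniform prior over \{AV, 2x1C, 1C, 2C\}.
#'
#' @param F_Median,A_Median the individual's estimates.
#' @param reference an \code{"ibd_reference"} from
#'   \code{\link{reference_distributions}}.
#' @param inbred logical: the LRT call for this individual (when FALSE the
#'   type is OUT).
#' @return list: \code{mating_type}, \code{posteriors} (named, sum 1).
#' @export
classify_mating_type <- function(F_Median, A_Median, reference,
                                 inbred = TRUE) {
  inbred_types <- intersect(c("AV", "2x1C", "1C", "2C"),
                            unique(reference$mating_type))
  if (!inbred) {
    post <- setNames(rep(0, length(inbred_types) + 1),
                     c(inbred_types, "OUT"))
    post["OUT"] <- 1
    return(list(mating_type = "OUT", posteriors = post))
  }
  dens <- vapply(inbred_types, function(ty) {
    cl <- reference[reference$mating_type == ty, ]
    kde2_eval(cl$F_Median, log10(cl$A_Median), F_Median, log10(A_Median))
  }, 0)
  if (all(dens == 0)) dens[] <- 1  # point outside every cloud: flat posterior
  post <- dens / sum(dens)
  list(mating_type = names(which.max(post)), posteriors = post)
}
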