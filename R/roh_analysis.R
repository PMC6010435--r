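# Runs of homozygosity: sliding-window calling, fixed-threshold and
# per-population mixture-based length classification, and the excess
# homozygosity statistic.

#' Call runs of homozygosity
#'
#' Sliding-window scan in the PLINK style: windows of \code{window_snps}
#' SNPs pass if they contain at most \code{window_het} heterozygous and
#' \code{window_missing} missing calls; a SNP is ROH material when the
#' fraction of windows covering it that pass exceeds \code{hit_frac}.
#' Maximal runs of such SNPs are reported when they hold at least
#' \code{min_snps} SNPs, span at least \code{min_kb}, have at least one SNP
#' per \code{max_kb_per_snp} kb, and contain no inter-SNP gap above
#' \code{max_gap_kb} (runs are split at larger gaps).
#'
#' @param gt a \code{\link{genotype_table}}.
#' @param window_snps,window_het,window_missing,hit_frac window parameters.
#' @param min_snps,min_kb,max_kb_per_snp,max_gap_kb run filters.
#' @return data frame: \code{individual_id}, \code{chrom}, \code{start_bp},
#'   \code{end_bp} (closed), \code{length_kb} = (end - start + 1)/1000,
#'   \code{n_snps}.
#' @export
call_rohs <- function(gt, window_snps = 50, window_het = 1,
                      window_missing = 5, hit_frac = 0.05, min_snps = 50,
                      min_kb = 500, max_kb_per_snp = 50, max_gap_kb = 1000) {
  validate_genotype_table(gt)
  snps <- gt$snps
  out <- list()
  for (ch in unique(snps$chrom)) {
    idx <- which(snps$chrom == ch)
    bp <- snps$pos_bp[idx]
    m <- length(idx)
    for (s in seq_along(gt$samples)) {
      g <- gt$calls[s, idx]
      inroh <- roh_snp_flags(g, window_snps, window_het, window_missing,
                             hit_frac)
      segs <- roh_runs(inroh, bp, min_snps, min_kb, max_kb_per_snp,
                       max_gap_kb)
      if (nrow(segs)) {
        segs$individual_id <- gt$samples[s]
        segs$chrom <- ch
        out[[length(out) + 1]] <- segs
      }
    }
  }
  if (!length(out))
    return(data.frame(individual_id = character(), chrom = integer(),
                      start_bp = integer(), end_bp = integer(),
                      length_kb = numeric(), n_snps = integer()))
  res <- do.call(rbind, out)
  res[, c("individual_id", "chrom", "start_bp", "end_bp", "length_kb",
          "n_snps")]
}

# per-SNP "in a ROH" flags from the sliding-window vote
roh_snp_flags <- function(g, window_snps, window_het, window_missing,
                          hit_frac) {
  m <- length(g)
  if (m < window_snps) return(rep(FALSE, m))
  het <- cumsum(c(0, !is.na(g) & g == 1L))
  mis <- cumsum(c(0, is.na(g)))
  nw <- m - window_snps + 1
  st <- seq_len(nw)
  pass <- (het[st + window_snps] - het[st]) <= window_het &
    (mis[st + window_snps] - mis[st]) <= window_missing
  cpass <- cumsum(c(0, pass))
  i <- seq_len(m)
  lo <- pmax(1L, i - window_snps + 1L)
  hi <- pmin(i, nw)
  cover <- hi - lo + 1L
  hits <- cpass[pmax(hi, lo) + 1] - cpass[lo]
  ok <- hi >= lo
  flags <- rep(FALSE, m)
  flags[ok] <- (hits[ok] / cover[ok]) > hit_frac
  flags
}

roh_runs <- function(inroh, bp, min_snps, min_kb, max_kb_per_snp,
                     max_gap_kb) {
  empty <- data.frame(start_bp = integer(), end_bp = integer(),
                      length_kb = numeric(), n_snps = integer())
  if (!any(inroh)) return(empty)
  r <- rle(inroh)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  segs <- list()
  for (k in which(r$values)) {
    lo <- starts[k]
    hi <- ends[k]
    # split at large gaps
    pos <- bp[lo:hi]
    cutafter <- which(diff(pos) > max_gap_kb * 1000)
    bounds <- c(0, cutafter, length(pos))
    for (b in seq_len(length(bounds) - 1)) {
      i0 <- lo + bounds[b]
      i1 <- lo + bounds[b + 1] - 1
      n <- i1 - i0 + 1
      len_kb <- (bp[i1] - bp[i0] + 1) / 1000
      if (n >= min_snps && len_kb >= min_kb &&
          len_kb / n <= max_kb_per_snp)
        segs[[length(segs) + 1]] <- data.frame(
          start_bp = bp[i0], end_bp = bp[i1], length_kb = len_kb,
          n_snps = n)
    }
  }
  if (!length(segs)) return(empty)
  do.call(rbind, segs)
}

#' Fixed-threshold ROH classification
#'
#' Classical literature thresholds: intermediate ROHs span 500--1,500 kb
#' (closed range) and long ROHs are strictly above 1,500 kb.
#'
#' @param segments a \code{\link{call_rohs}} data frame.
#' @param samples optional sample ids to guarantee all-zero rows for
#'   segment-free individuals.
#' @return data frame per individual: \code{n_intermediate},
#'   \code{kb_intermediate}, \code{n_long}, \code{kb_long}.
#' @export
classify_fixed <- function(segments, samples = NULL) {
  samples <- samples %||% unique(segments$individual_id)
  if (nrow(segments) == 0)
    return(data.frame(individual_id = samples, n_intermediate = 0,
                      kb_intermediate = 0, n_long = 0, kb_long = 0,
                      stringsAsFactors = FALSE))
  inter <- segments$length_kb >= 500 & segments$length_kb <= 1500
  long <- segments$length_kb > 1500
  agg <- function(flag, fun) {
    v <- tapply(ifelse(flag, fun(segments), 0), segments$individual_id, sum)
    out <- setNames(rep(0, length(samples)), samples)
    out[names(v)] <- v
    out
  }
  data.frame(
    individual_id = samples,
    n_intermediate = agg(inter, function(s) rep(1, nrow(s))),
    kb_intermediate = agg(inter, function(s) s$length_kb),
    n_long = agg(long, function(s) rep(1, nrow(s))),
    kb_long = agg(long, function(s) s$length_kb),
    row.names = NULL, stringsAsFactors = FALSE)
}

# ---- Gaussian mixture on log10 ROH length ---------------------------------

# EM for a k-component univariate Gaussian mixture with unequal variances.
# Returns parameters and the (monotone non-decreasing) log-likelihood trace.
gmm_em <- function(x, k, max_iter = 500, tol = 1e-6, seed_init = 1) {
  n <- length(x)
  best <- NULL
  for (r in seq_len(10)) {
    cand <- with_seed(seed_init + r, {
      mu <- sort(sample(x, k))
      sdv <- rep(sd(x) / k, k)
      w <- rep(1 / k, k)
      trace <- numeric(0)
      ll_old <- -Inf
      for (it in seq_len(max_iter)) {
        dens <- vapply(seq_len(k),
                       function(j) w[j] * dnorm(x, mu[j], sdv[j]),
                       numeric(n))
        rowsum_ <- pmax(rowSums(dens), 1e-300)
        ll <- sum(log(rowsum_))
        trace <- c(trace, ll)
        resp <- dens / rowsum_
        nk <- colSums(resp)
        w <- nk / n
        mu <- colSums(resp * x) / nk
        sdv <- sqrt(pmax(colSums(resp * (x - rep(mu, each = n))^2) / nk,
                         1e-8))
        if (abs(ll - ll_old) < tol) break
        ll_old <- ll
      }
      list(w = w, mu = mu, sd = sdv, logLik = ll, trace = trace)
    })
    if (is.null(best) || cand$logLik > best$logLik) best <- cand
  }
  ord <- order(best$mu)
  list(w = best$w[ord], mu = best$mu[ord], sd = best$sd[ord],
       logLik = best$logLik, trace = best$trace)
}

# crossing point of two weighted Gaussian densities between their means
density_crossing <- function(w1, m1, s1, w2, m2, s2, tol = 1e-8) {
  h <- function(x) w1 * dnorm(x, m1, s1) - w2 * dnorm(x, m2, s2)
  lo <- m1
  hi <- m2
  if (h(lo) * h(hi) > 0) return((m1 + m2) / 2)  # no crossing between means
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (h(lo) * h(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Per-population ROH length mixture and class boundaries
#'
#' Fits a three-component Gaussian mixture (unequal variances, EM to
#' tolerance 1e-6, best of 10 seeded restarts) to log10 ROH lengths (kb).
#' Components ranked by mean define classes A (short), B (intermediate) and
#' C (long); the A/B and B/C boundaries are the points between adjacent
#' component means where their weighted densities cross. If a component
#' degenerates (weight < 0.01) the mixture is refit with two components and
#' flagged.
#'
#' @param segments ROH segments of one population (>= 50 required).
#' @param population_code label stored in the result.
#' @return list of class \code{"roh_boundaries"}: \code{population_code},
#'   \code{boundary_AB_kb}, \code{boundary_BC_kb}, \code{mixture} (w, mu,
#'   sd on log10 kb), \code{logLik_trace}, \code{degenerate}.
#' @export
fit_length_mixture <- function(segments, population_code = "pop") {
  if (nrow(segments) < 50)
    stop("need at least 50 segments to fit the length mixture")
  x <- log10(segments$length_kb)
  fit <- gmm_em(x, 3)
  degenerate <- any(fit$w < 0.01)
  if (degenerate) fit <- gmm_em(x, 2)
  k <- length(fit$mu)
  bnd <- vapply(seq_len(k - 1), function(j) {
    density_crossing(fit$w[j], fit$mu[j], fit$sd[j],
                     fit$w[j + 1], fit$mu[j + 1], fit$sd[j + 1])
  }, 0)
  bnd_kb <- 10^bnd
  if (k == 2) bnd_kb <- c(bnd_kb[1], Inf)
  structure(list(population_code = population_code,
                 boundary_AB_kb = bnd_kb[1], boundary_BC_kb = bnd_kb[2],
                 mixture = fit[c("w", "mu", "sd")],
                 logLik = fit$logLik, logLik_trace = fit$trace,
                 degenerate = degenerate),
            class = "roh_boundaries")
}

#' Population-specific ROH classification
#'
#' Classes: A below \code{boundary_AB_kb}; B from \code{boundary_AB_kb}
#' (inclusive) up to \code{boundary_BC_kb} (exclusive); C at or above
#' \code{boundary_BC_kb} — boundaries are closed on the upper class.
#'
#' @param segments a \code{\link{call_rohs}} data frame.
#' @param boundaries a \code{"roh_boundaries"} (or a list with
#'   \code{boundary_AB_kb}, \code{boundary_BC_kb}).
#' @param samples optional ids to include as all-zero rows.
#' @return data frame per individual: \code{n_A}, \code{kb_A}, \code{n_B},
#'   \code{kb_B}, \code{n_C}, \code{kb_C}.
#' @export
classify_population <- function(segments, boundaries, samples = NULL) {
  samples <- samples %||% unique(segments$individual_id)
  if (nrow(segments) == 0)
    return(data.frame(individual_id = samples, n_A = 0, kb_A = 0, n_B = 0,
                      kb_B = 0, n_C = 0, kb_C = 0, stringsAsFactors = FALSE))
  cls <- ifelse(segments$length_kb < boundaries$boundary_AB_kb, "A",
                ifelse(segments$length_kb < boundaries$boundary_BC_kb, "B",
                       "C"))
  out <- data.frame(individual_id = samples, n_A = 0, kb_A = 0, n_B = 0,
                    kb_B = 0, n_C = 0, kb_C = 0, stringsAsFactors = FALSE)
  for (cl in c("A", "B", "C")) {
    sel <- cls == cl
    if (!any(sel)) next
    n <- tapply(rep(1, sum(sel)), segments$individual_id[sel], sum)
    kb <- tapply(segments$length_kb[sel], segments$individual_id[sel], sum)
    i <- match(names(n), out$individual_id)
    out[[paste0("n_", cl)]][i] <- n
    out[[paste0("kb_", cl)]][i] <- kb
  }
  out
}

#' Genomic excess of homozygosity
#'
#' Per individual, (O_hom - E_hom) / N over the individual's non-missing
#' sites, where E_hom sums 1 - 2 p (1 - p) 2n/(2n - 1) with p the
#' within-population alt frequency and 2n the number of non-missing alleles
#' at the site (small-sample correction). Negative values mean fewer
#' homozygotes than expected under panmixia.
#'
#' @param gt a \code{\link{genotype_table}}.
#' @param populations population code per sample (single population when
#'   missing).
#' @return data frame: \code{individual_id}, \code{population_code},
#'   \code{excess_hom}.
#' @export
excess_homozygosity <- function(gt, populations = NULL) {
  n <- length(gt$samples)
  populations <- populations %||% rep("pop", n)
  out <- data.frame(individual_id = gt$samples,
                    population_code = populations,
                    excess_hom = NA_real_, stringsAsFactors = FALSE)
  for (pc in unique(populations)) {
    rows <- which(populations == pc)
    calls <- gt$calls[rows, , drop = FALSE]
    n2 <- 2 * colSums(!is.na(calls))
    p <- colSums(calls, na.rm = TRUE) / pmax(n2, 1)
    corr <- ifelse(n2 > 1, n2 / (n2 - 1), 1)
    ehet_site <- 2 * p * (1 - p) * corr
    for (r in seq_along(rows)) {
      g <- calls[r, ]
      ok <- !is.na(g) & n2 > 1
      O <- sum(g[ok] != 1L)
      E <- sum(1 - ehet_site[ok])
      out$excess_hom[rows[r]] <- (O - E) / sum(ok)
    }
  }
  out
}
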