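# Population diversity: allele-sharing dissimilarity, kinship-based
# relative exclusion, and haplotypic heterozygosity over low-recombination
# blocks.

#' Allele-sharing dissimilarity matrix
#'
#' For each pair of individuals, ASD = 1 - (shared alleles) / (2 x
#' overlapping sites), where the number of shared alleles at a site with
#' calls g1, g2 in \{0, 1, 2\} is 2 - |g1 - g2|. Sites missing in either
#' member of a pair are excluded (pairwise-complete). A pair with no
#' overlapping sites gets \code{NA}.
#'
#' @param gt a \code{\link{genotype_table}} with at least two samples.
#' @return Symmetric matrix in [0, 1] with zero diagonal, dimnames = sample
#'   ids.
#' @export
asd_matrix <- function(gt) {
  validate_genotype_table(gt)
  n <- length(gt$samples)
  if (n < 2) stop("need at least 2 samples")
  X <- gt$calls
  out <- matrix(0, n, n, dimnames = list(gt$samples, gt$samples))
  for (i in seq_len(n - 1)) {
    gi <- X[i, ]
    for (j in (i + 1):n) {
      gj <- X[j, ]
      ok <- !is.na(gi) & !is.na(gj)
      m <- sum(ok)
      out[i, j] <- out[j, i] <- if (m == 0) NA_real_ else
        1 - sum(2 - abs(gi[ok] - gj[ok])) / (2 * m)
    }
  }
  out
}

#' Method-of-moments pairwise kinship
#'
#' Kinship coefficient phi for each pair from centred genotype products
#' scaled by total heterozygosity:
#' phi_jk = sum_i (g_ji - 2 p_i)(g_ki - 2 p_i) / (4 sum_i p_i (1 - p_i)),
#' with allele frequencies estimated from the samples provided (pass one
#' population at a time for within-population frequencies). Expected values:
#' 0.25 for parent-offspring, 1/16 for first cousins, ~0 for unrelated.
#'
#' @param gt a \code{\link{genotype_table}}.
#' @param freqs optional alt-allele frequencies (one per SNP); estimated
#'   from \code{gt} when missing.
#' @return Symmetric kinship matrix (diagonal \code{NA}).
#' @export
pairwise_kinship <- function(gt, freqs = NULL) {
  X <- gt$calls
  n <- nrow(X)
  p <- freqs %||% (colMeans(X, na.rm = TRUE) / 2)
  use <- which(p > 0.01 & p < 0.99)
  Xc <- sweep(X[, use, drop = FALSE], 2, 2 * p[use])
  het <- p[use] * (1 - p[use])
  out <- matrix(NA_real_, n, n, dimnames = list(gt$samples, gt$samples))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !is.na(Xc[i, ]) & !is.na(Xc[j, ])
      out[i, j] <- out[j, i] <-
        sum(Xc[i, ok] * Xc[j, ok]) / (4 * sum(het[ok]))
    }
  }
  out
}

#' Exclude close relatives
#'
#' Greedy removal of individuals involved in pairs more related than the
#' threshold: repeatedly drop the sample participating in the most
#' over-threshold pairs (ties broken by sample-id sort order) until no pair
#' exceeds the threshold. With the default, pairs closer than first cousins
#' (phi = 1/16) are broken up, allowing \code{tolerance} for estimation
#' noise.
#'
#' @param kinship symmetric kinship matrix with sample-id dimnames.
#' @param threshold_phi relatedness limit; default first-cousin kinship.
#' @param tolerance slack added to the threshold.
#' @return Character vector of retained sample ids (original order).
#' @export
exclude_relatives <- function(kinship, threshold_phi = 1 / 16,
                              tolerance = 0.02) {
  ids <- rownames(kinship)
  keep <- ids
  lim <- threshold_phi + tolerance
  repeat {
    k <- kinship[keep, keep, drop = FALSE]
    over <- !is.na(k) & k > lim
    diag(over) <- FALSE
    counts <- rowSums(over)
    if (all(counts == 0)) break
    worst <- keep[counts == max(counts)]
    drop_id <- sort(worst)[1]
    keep <- setdiff(keep, drop_id)
  }
  ids[ids %in% keep]
}

#' Low-recombination blocks
#'
#' Maximal runs of consecutive SNPs (within a chromosome) whose local
#' recombination rate is below the cutoff, kept if they contain at least
#' \code{min_snps} SNPs. Each SNP's local rate is the map rate of the
#' interval containing it.
#'
#' @param snps SNP metadata (chrom, pos_bp ordered).
#' @param gmap a \code{"genetic_map"} with per-knot rates.
#' @param rate_cutoff cM/Mb; SNPs with local rate strictly below this are
#'   block material.
#' @param min_snps minimum SNPs per block.
#' @return data frame: \code{chrom}, \code{start_bp}, \code{end_bp} (closed,
#'   1-based), \code{n_snps}, \code{start_idx}, \code{end_idx} (column
#'   indices into \code{snps}).
#' @export
low_recombination_blocks <- function(snps, gmap, rate_cutoff = 0.5,
                                     min_snps = 5) {
  out <- list()
  for (ch in unique(snps$chrom)) {
    idx <- which(snps$chrom == ch)
    k <- gmap[[as.character(ch)]]
    if (is.null(k)) stop("map does not cover chromosome ", ch)
    ri <- pmax(1L, findInterval(snps$pos_bp[idx], k$pos_bp))
    low <- k$rate[ri] < rate_cutoff
    r <- rle(low)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (b in which(r$values & r$lengths >= min_snps)) {
      i0 <- idx[starts[b]]
      i1 <- idx[ends[b]]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start_bp = snps$pos_bp[i0], end_bp = snps$pos_bp[i1],
        n_snps = ends[b] - starts[b] + 1L, start_idx = i0, end_idx = i1)
    }
  }
  if (!length(out))
    return(data.frame(chrom = integer(), start_bp = integer(),
                      end_bp = integer(), n_snps = integer(),
                      start_idx = integer(), end_idx = integer()))
  do.call(rbind, out)
}

#' Haplotypic heterozygosity over blocks
#'
#' Per block, the unbiased haplotype heterozygosity
#' H = n/(n-1) (1 - sum_h p_h^2) over the distinct haplotypes observed in
#' the block (n = number of haplotypes in the population). Block values are
#' averaged per autosome, then across autosomes, per population. Requires
#' phase, so it is defined on simulator-provided haplotypes (real-data
#' phasing is out of scope).
#'
#' @param haplotypes 0/1 matrix with two consecutive rows per individual.
#' @param blocks a \code{\link{low_recombination_blocks}} data frame.
#' @param populations population code per individual (length
#'   \code{nrow(haplotypes)/2}).
#' @return data frame: \code{population_code}, \code{mean_het} in [0, 1],
#'   \code{n_blocks}; per-autosome means in attribute
#'   \code{"per_autosome"}.
#' @export
block_haplotype_heterozygosity <- function(haplotypes, blocks, populations) {
  stopifnot(nrow(haplotypes) %% 2 == 0,
            length(populations) == nrow(haplotypes) / 2)
  hap_pop <- rep(populations, each = 2)
  pops <- unique(populations)
  per_aut <- list()
  res <- lapply(pops, function(pc) {
    rows <- which(hap_pop == pc)
    if (length(rows) < 2) return(NULL)
    hvals <- vapply(seq_len(nrow(blocks)), function(b) {
      cols <- blocks$start_idx[b]:blocks$end_idx[b]
      keys <- apply(haplotypes[rows, cols, drop = FALSE], 1, paste,
                    collapse = "")
      n <- length(keys)
      ph <- table(keys) / n
      n / (n - 1) * (1 - sum(ph^2))
    }, 0)
    aut <- tapply(hvals, blocks$chrom, mean)
    per_aut[[pc]] <<- aut
    data.frame(population_code = pc, mean_het = mean(aut),
               n_blocks = nrow(blocks), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "per_autosome") <- per_aut
  out
}
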