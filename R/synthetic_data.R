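# Synthetic cohorts with known ground truth: founder haplotypes, pedigree
# gene dropping (exact autozygous tracks), and full cohort generation with
# a bimodal spousal-distance geography.

#' Canonical consanguineous pedigrees
#'
#' Returns the pedigree for one of the five parental mating types used
#' throughout the package: \code{OUT} (parents less related than second
#' cousins), \code{2C} (second cousins, expected F = 1/64), \code{1C} (first
#' cousins, F = 1/16), \code{2x1C} (double first cousins, F = 1/8) and
#' \code{AV} (avuncular, F = 1/8). \code{loop_meioses} is the number of
#' meioses along the inbreeding loop(s), which governs the expected length
#' of autozygous segments (roughly 100/loop_meioses cM).
#'
#' @param type one of \code{"OUT"}, \code{"2C"}, \code{"1C"}, \code{"2x1C"},
#'   \code{"AV"}; \code{"SIB"} (full-sib mating, F = 1/4) is also available
#'   for power and calibration studies, although it is outside the five-way
#'   classification alphabet.
#' @return A list with \code{type}, \code{expected_f}, \code{loop_meioses}
#'   and \code{pedigree} (a data frame \code{id}, \code{father},
#'   \code{mother}; founders have \code{NA} parents; the focal individual is
#'   the last row).
#' @export
pedigree_spec <- function(type = c("OUT", "2C", "1C", "2x1C", "AV", "SIB")) {
  type <- match.arg(type)
  ped <- switch(type,
    OUT = data.frame(
      id     = c("P1", "P2", "X"),
      father = c(NA, NA, "P1"),
      mother = c(NA, NA, "P2")),
    SIB = data.frame(
      id     = c("A", "B", "C", "D", "X"),
      father = c(NA, NA, "A", "A", "C"),
      mother = c(NA, NA, "B", "B", "D")),
    `1C` = data.frame(
      id     = c("A", "B", "D", "F", "C", "E", "G", "H", "X"),
      father = c(NA, NA, NA, NA, "A", "A", "C", "E", "G"),
      mother = c(NA, NA, NA, NA, "B", "B", "D", "F", "H")),
    `2C` = data.frame(
      id     = c("A", "B", "D", "F", "I", "J", "C", "E", "G", "H", "K", "L",
                 "X"),
      father = c(NA, NA, NA, NA, NA, NA, "A", "A", "C", "E", "G", "H", "K"),
      mother = c(NA, NA, NA, NA, NA, NA, "B", "B", "D", "F", "I", "J", "L")),
    `2x1C` = data.frame(
      id     = c("A", "B", "C", "D", "E", "F", "G", "H", "P1", "P2", "X"),
      father = c(NA, NA, NA, NA, "A", "A", "C", "C", "E", "F", "P1"),
      mother = c(NA, NA, NA, NA, "B", "B", "D", "D", "G", "H", "P2")),
    AV = data.frame(
      id     = c("A", "B", "E", "C", "D", "F", "X"),
      father = c(NA, NA, NA, "A", "A", "D", "C"),
      mother = c(NA, NA, NA, "B", "B", "E", "F")))
  list(type = type,
       expected_f = switch(type, OUT = 0, `2C` = 1 / 64, `1C` = 1 / 16,
                           `2x1C` = 1 / 8, AV = 1 / 8, SIB = 1 / 4),
       loop_meioses = switch(type, OUT = NA_integer_, `2C` = 8L, `1C` = 6L,
                             `2x1C` = 6L, AV = 5L, SIB = 4L),
       pedigree = ped)
}

#' Build a synthetic SNP panel and matching genetic map
#'
#' Markers are placed uniformly at random along equal-length chromosomes
#' with a constant recombination rate, so pos_bp = pos_cM / rate * 1e6.
#' Alt-allele frequencies are drawn uniformly on \code{freq_range}.
#'
#' @param n_snps total number of SNPs.
#' @param n_chrom number of chromosomes (1--22).
#' @param total_cM total genetic map length summed over chromosomes.
#' @param rate_cM_per_Mb constant recombination rate.
#' @param freq_range range of alt-allele frequencies.
#' @param seed optional RNG seed.
#' @return list(snps, gmap): a SNP metadata data frame (with
#'   \code{freq_alt}) and a \code{"genetic_map"}.
#' @export
make_snp_panel <- function(n_snps = 5000, n_chrom = 22, total_cM = 3500,
                           rate_cM_per_Mb = 1, freq_range = c(0.1, 0.9),
                           seed = NULL) {
  stopifnot(n_chrom >= 1, n_chrom <= 22, n_snps >= n_chrom)
  with_seed(seed, {
    chrom_cM <- total_cM / n_chrom
    per <- diff(round(seq(0, n_snps, length.out = n_chrom + 1)))
    snps <- do.call(rbind, lapply(seq_len(n_chrom), function(ch) {
      cm <- sort(runif(per[ch], 0, chrom_cM))
      bp <- as.integer(round(cm / rate_cM_per_Mb * 1e6)) + 1L
      # enforce strictly increasing bp after rounding
      bp <- bp + seq_along(bp) - 1L
      data.frame(snp_id = sprintf("snp%d_%d", ch, seq_along(cm)),
                 chrom = ch, pos_bp = bp, pos_cM = cm,
                 a1 = "A", a2 = "G",
                 freq_alt = runif(per[ch], freq_range[1], freq_range[2]),
                 stringsAsFactors = FALSE)
    }))
    gmap <- genetic_map(do.call(rbind, lapply(seq_len(n_chrom), function(ch) {
      data.frame(chrom = ch, pos_bp = c(1L, as.integer(chrom_cM / rate_cM_per_Mb * 1e6)),
                 rate = rate_cM_per_Mb, pos_cM = c(0, chrom_cM))
    })))
    list(snps = snps, gmap = gmap)
  })
}

#' Simulate founder haplotypes
#'
#' Haplotypes are drawn site-wise as Bernoulli(freq_alt), optionally with a
#' first-order copying process (\code{ld_rho}: probability that a site copies
#' the previous site's allele instead of a fresh draw) to induce short-range
#' LD. The copying model perturbs marginal frequencies slightly; it is a
#' free knob, not a claim of realism.
#'
#' @param n_haplotypes number of haplotypes (rows).
#' @param snps SNP metadata with \code{freq_alt} in [0, 1] and \code{chrom}.
#' @param ld_rho first-order LD decay parameter in [0, 1); 0 = linkage
#'   equilibrium.
#' @param seed optional RNG seed (same seed, same haplotypes).
#' @return 0/1 integer matrix, \code{n_haplotypes} x \code{nrow(snps)}.
#' @export
simulate_founders <- function(n_haplotypes, snps, ld_rho = 0, seed = NULL) {
  p <- snps$freq_alt
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("freq_alt must be set and in [0, 1] for every SNP")
  m <- nrow(snps)
  with_seed(seed, {
    haps <- matrix(rbinom(n_haplotypes * m, 1L, rep(p, each = n_haplotypes)),
                   n_haplotypes, m)
    if (ld_rho > 0) {
      new_chrom <- c(TRUE, snps$chrom[-1] != snps$chrom[-m])
      for (j in seq_len(m)[-1]) {
        if (new_chrom[j]) next
        copy <- runif(n_haplotypes) < ld_rho
        haps[copy, j] <- haps[copy, j - 1]
      }
    }
    storage.mode(haps) <- "integer"
    haps
  })
}

# chromosome spans (cM) implied by a SNP panel: list chrom -> c(start, end)
chrom_spans <- function(snps) {
  lapply(split(snps$pos_cM, snps$chrom), range)
}

# clip an interval matrix (cols start, end, lab; half-open) to [a, b)
clip_iv <- function(iv, a, b) {
  keep <- iv[, 2] > a & iv[, 1] < b
  out <- iv[keep, , drop = FALSE]
  if (nrow(out)) {
    out[1, 1] <- max(out[1, 1], a)
    out[nrow(out), 2] <- min(out[nrow(out), 2], b)
  }
  out
}

# one meiosis on one chromosome: recombine two interval-haplotypes.
# Crossovers are a Poisson process on the cM scale (no interference).
meiosis_chrom <- function(h1, h2, span) {
  len <- span[2] - span[1]
  ncross <- rpois(1, len / 100)
  cuts <- sort(runif(ncross, span[1], span[2]))
  bounds <- c(span[1], cuts, span[2])
  phase <- sample(1:2, 1)
  segs <- vector("list", length(bounds) - 1)
  for (k in seq_along(segs)) {
    src <- if ((k + phase) %% 2 == 0) h1 else h2
    segs[[k]] <- clip_iv(src, bounds[k], bounds[k + 1])
  }
  out <- do.call(rbind, segs)
  # merge adjacent pieces with the same founder label
  if (nrow(out) > 1) {
    same <- out[-1, 3] == out[-nrow(out), 3] &
      abs(out[-1, 1] - out[-nrow(out), 2]) < 1e-12
    if (any(same)) {
      grp <- cumsum(c(TRUE, !same))
      out <- cbind(tapply(out[, 1], grp, min), tapply(out[, 2], grp, max),
                   tapply(out[, 3], grp, function(x) x[1]))
    }
  }
  out
}

meiosis <- function(haps1, haps2, spans) {
  lapply(names(spans), function(ch) {
    meiosis_chrom(haps1[[ch]], haps2[[ch]], spans[[ch]])
  }) |> setNames(names(spans))
}

# label lookup for positions on one chromosome's interval haplotype
iv_labels <- function(iv, pos) {
  iv[pmax(1L, findInterval(pos, iv[, 1])), 3]
}

#' Drop genes through a pedigree
#'
#' Simulates transmission of founder haplotypes through one pedigree with
#' Poisson (no-interference) recombination on the cM scale and returns the
#' focal individual's genotype together with the exact autozygous track
#' (intervals where both transmitted haplotypes descend from the same
#' founder haplotype). No mutation or genotyping error is added here; see
#' \code{\link{add_genotype_errors}}.
#'
#' @param spec a \code{\link{pedigree_spec}}.
#' @param founder_haps 0/1 matrix of founder haplotypes; at least two rows
#'   per pedigree founder. Founder k uses rows 2k-1 and 2k.
#' @param snps SNP metadata (must cover every chromosome in the map sense:
#'   positions in cM).
#' @param seed optional RNG seed.
#' @return list with \code{genotype} (0/1/2 vector over SNPs),
#'   \code{haplotypes} (2 x n_snps 0/1 matrix), \code{ibd} (data frame
#'   \code{chrom}, \code{start_cM}, \code{end_cM} of autozygous segments)
#'   and \code{f_true} (autozygous fraction of the genome, cM scale).
#' @export
gene_drop <- function(spec, founder_haps, snps, seed = NULL) {
  ped <- spec$pedigree
  founders <- ped$id[is.na(ped$father)]
  if (nrow(founder_haps) < 2 * length(founders))
    stop("need at least ", 2 * length(founders), " founder haplotypes")
  spans <- chrom_spans(snps)
  with_seed(seed, {
    haps <- list()
    fi <- 0
    for (r in seq_len(nrow(ped))) {
      id <- ped$id[r]
      if (is.na(ped$father[r])) {
        fi <- fi + 1
        h <- lapply(spans, function(sp) NULL)
        haps[[id]] <- list(
          h1 = lapply(spans, function(sp) matrix(c(sp[1], sp[2], 2 * fi - 1),
                                                 1, 3)),
          h2 = lapply(spans, function(sp) matrix(c(sp[1], sp[2], 2 * fi),
                                                 1, 3)))
      } else {
        fa <- haps[[ped$father[r]]]
        mo <- haps[[ped$mother[r]]]
        haps[[id]] <- list(h1 = meiosis(fa$h1, fa$h2, spans),
                           h2 = meiosis(mo$h1, mo$h2, spans))
      }
    }
    focal <- haps[[ped$id[nrow(ped)]]]
    # genotype + phased haplotypes of the focal individual
    m <- nrow(snps)
    hap_alleles <- matrix(0L, 2, m)
    ibd <- list()
    for (ch in names(spans)) {
      idx <- which(snps$chrom == as.integer(ch))
      pos <- snps$pos_cM[idx]
      l1 <- iv_labels(focal$h1[[ch]], pos)
      l2 <- iv_labels(focal$h2[[ch]], pos)
      hap_alleles[1, idx] <- founder_haps[cbind(l1, idx)]
      hap_alleles[2, idx] <- founder_haps[cbind(l2, idx)]
      ibd[[ch]] <- autozygous_intervals(focal$h1[[ch]], focal$h2[[ch]],
                                        as.integer(ch))
    }
    ibd <- do.call(rbind, ibd)
    rownames(ibd) <- NULL
    total <- sum(vapply(spans, function(sp) sp[2] - sp[1], 0))
    f_true <- if (nrow(ibd)) sum(ibd$end_cM - ibd$start_cM) / total else 0
    list(genotype = hap_alleles[1, ] + hap_alleles[2, ],
         haplotypes = hap_alleles,
         ibd = ibd, f_true = f_true)
  })
}

# intersect two interval-haplotypes; keep stretches with equal founder label
autozygous_intervals <- function(iv1, iv2, chrom) {
  bp <- sort(unique(c(iv1[, 1], iv1[, 2], iv2[, 1], iv2[, 2])))
  if (length(bp) < 2)
    return(data.frame(chrom = integer(), start_cM = numeric(),
                      end_cM = numeric()))
  mid <- (bp[-length(bp)] + bp[-1]) / 2
  eq <- iv_labels(iv1, mid) == iv_labels(iv2, mid)
  if (!any(eq))
    return(data.frame(chrom = integer(), start_cM = numeric(),
                      end_cM = numeric()))
  r <- rle(eq)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(chrom = chrom, start_cM = bp[starts[keep]],
             end_cM = bp[ends[keep] + 1])
}

#' Flip genotype calls at a fixed error rate
#'
#' Post-hoc genotyping-error process: each non-missing call is replaced,
#' with probability \code{rate}, by one of the two other genotypes (chosen
#' uniformly). Keeps signal generation and noise separate.
#'
#' @param gt a \code{\link{genotype_table}} (or a plain 0/1/2 vector).
#' @param rate per-call error probability.
#' @param seed optional RNG seed.
#' @return Object of the same shape with errors applied.
#' @export
add_genotype_errors <- function(gt, rate = 0.001, seed = NULL) {
  flip <- function(calls) {
    ok <- which(!is.na(calls))
    hit <- ok[runif(length(ok)) < rate]
    if (length(hit)) {
      shift <- sample(1:2, length(hit), replace = TRUE)
      calls[hit] <- (calls[hit] + shift) %% 3L
    }
    calls
  }
  with_seed(seed, {
    if (inherits(gt, "genotype_table")) {
      gt$calls <- matrix(flip(as.vector(gt$calls)), nrow(gt$calls),
                         ncol(gt$calls))
      storage.mode(gt$calls) <- "integer"
      gt
    } else flip(gt)
  })
}

#' Geography model for spousal distances
#'
#' Bimodal distance distribution: with probability
#' \code{endogamous_fraction} the couple is endogamous (distance exactly 0
#' with probability \code{zero_fraction}, else exponential with mean
#' \code{endogamous_scale_km}); otherwise the distance is lognormal
#' (\code{exogamous_logmean}, \code{exogamous_logsd}, natural-log scale).
#' Defaults emulate the study region: roughly half of couples endogamous,
#' exogamous distances centred near 30 km with a tail past 1,000 km.
#'
#' @param endogamous_fraction probability of an endogamous couple.
#' @param endogamous_scale_km mean of the endogamous exponential component.
#' @param zero_fraction fraction of endogamous couples at exactly 0 km
#'   (spouses born in the same village).
#' @param exogamous_logmean,exogamous_logsd lognormal parameters of the
#'   exogamous distance (km).
#' @return list of class \code{"geography_model"}.
#' @export
geography_model <- function(endogamous_fraction = 0.5,
                            endogamous_scale_km = 1,
                            zero_fraction = 0.5,
                            exogamous_logmean = log(30),
                            exogamous_logsd = 1) {
  stopifnot(endogamous_fraction >= 0, endogamous_fraction <= 1,
            endogamous_scale_km > 0, exogamous_logsd > 0)
  structure(list(endogamous_fraction = endogamous_fraction,
                 endogamous_scale_km = endogamous_scale_km,
                 zero_fraction = zero_fraction,
                 exogamous_logmean = exogamous_logmean,
                 exogamous_logsd = exogamous_logsd),
            class = "geography_model")
}

draw_couple_distances <- function(n, gm) {
  endo <- runif(n) < gm$endogamous_fraction
  d <- rlnorm(n, gm$exogamous_logmean, gm$exogamous_logsd)
  ne <- sum(endo)
  if (ne) {
    de <- rexp(ne, 1 / gm$endogamous_scale_km)
    de[runif(ne) < gm$zero_fraction] <- 0
    d[endo] <- de
  }
  d
}

# place a point d km due east of (lat, lon) on the sphere used by
# haversine_km, so that haversine_km recovers d
place_at_distance <- function(lat, lon, d_km) {
  p <- geosphere::destPoint(cbind(lon, lat), 90, d_km * 1000, r = 6371008.8)
  list(lat = p[, 2], lon = p[, 1])
}

#' Simulate a full study cohort
#'
#' Generates a multi-population cohort emulating the study design: per
#' population, genotyped individuals whose parental mating type is drawn
#' from \code{mixture}, genotypes gene-dropped through the corresponding
#' pedigree, parental and spousal birthplace distances drawn from a
#' \code{\link{geography_model}}, and birthplaces placed in a 40--50 degree
#' N latitude band so that great-circle distance recovers the drawn
#' distance. Optionally, kinship endogamy can be planted in a distance band
#' (\code{band_mixture} applies to parental couples whose distance falls in
#' \code{band_km}).
#'
#' @param n_per_pop genotyped individuals per population (> 0).
#' @param populations data frame with columns \code{population_code},
#'   \code{group} and optionally \code{ecosystem}, \code{lifestyle}; or an
#'   integer number of populations (codes generated, groups alternating
#'   TurkoMongol/IndoIranian).
#' @param mixture named probabilities over mating types
#'   \code{c(OUT, 2C, 1C, 2x1C, AV)}; must sum to 1. The default mirrors the
#'   mating-type proportions reported for the study region (about 36 percent
#'   inbred, mostly second cousins).
#' @param geography a \code{\link{geography_model}}.
#' @param band_mixture optional mixture used instead of \code{mixture} when
#'   the parental distance falls inside \code{band_km} (kinship-endogamy
#'   planting).
#' @param band_km numeric length-2: the kinship-endogamy distance band, km.
#' @param panel optional list(snps, gmap) from \code{\link{make_snp_panel}};
#'   built with the remaining arguments when missing.
#' @param n_snps,n_chrom,total_cM panel parameters when \code{panel} is NULL.
#' @param error_rate post-hoc genotype error rate (see
#'   \code{\link{add_genotype_errors}}).
#' @param seed RNG seed; the same seed gives identical output.
#' @return list: \code{genotypes} (a \code{\link{genotype_table}}),
#'   \code{haplotypes} (2n x m phased 0/1 matrix, rows 2i-1/2i = individual
#'   i), \code{survey} (a survey data frame including non-genotyped spouse
#'   rows), \code{truth} (per genotyped individual: \code{individual_id},
#'   \code{population_code}, \code{group}, \code{mating_type},
#'   \code{f_true}, \code{parental_distance_km},
#'   \code{couple_distance_km}), \code{snps}, \code{gmap}.
#' @export
simulate_cohort <- function(n_per_pop = 27, populations = 2,
                            mixture = c(OUT = 0.64, `2C` = 0.29, `1C` = 0.06,
                                        `2x1C` = 0.01, AV = 0),
                            geography = geography_model(),
                            band_mixture = NULL, band_km = c(4, 40),
                            panel = NULL, n_snps = 5000, n_chrom = 22,
                            total_cM = 3500, error_rate = 0, seed = NULL) {
  if (n_per_pop <= 0) stop("n_per_pop must be > 0")
  types <- c("OUT", "2C", "1C", "2x1C", "AV")
  mixture <- mixture[types]
  mixture[is.na(mixture)] <- 0
  names(mixture) <- types
  if (abs(sum(mixture) - 1) > 1e-8) stop("mixture weights must sum to 1")
  if (!is.null(band_mixture)) {
    band_mixture <- band_mixture[types]
    band_mixture[is.na(band_mixture)] <- 0
    names(band_mixture) <- types
    if (abs(sum(band_mixture) - 1) > 1e-8)
      stop("band_mixture weights must sum to 1")
  }
  if (is.numeric(populations) && length(populations) == 1) {
    k <- populations
    populations <- data.frame(
      population_code = sprintf("P%02d", seq_len(k)),
      group = rep(c("TurkoMongol", "IndoIranian"), length.out = k))
  }
  if (is.null(populations$ecosystem))
    populations$ecosystem <- rep(c("steppe", "forest", "mountain"),
                                 length.out = nrow(populations))
  if (is.null(populations$lifestyle))
    populations$lifestyle <- rep(c("nomadic", "sedentary"),
                                 length.out = nrow(populations))

  with_seed(seed, {
    if (is.null(panel))
      panel <- make_snp_panel(n_snps = n_snps, n_chrom = n_chrom,
                              total_cM = total_cM)
    snps <- panel$snps
    specs <- lapply(setNames(types, types), pedigree_spec)
    n_pop <- nrow(populations)
    n_tot <- n_pop * n_per_pop
    calls <- matrix(NA_integer_, n_tot, nrow(snps))
    haplo <- matrix(NA_integer_, 2 * n_tot, nrow(snps))
    survey_rows <- list()
    truth_rows <- list()
    idx <- 0
    for (p in seq_len(n_pop)) {
      pop <- populations[p, ]
      center_lat <- runif(1, 41, 49)
      center_lon <- runif(1, 62, 98)
      for (i in seq_len(n_per_pop)) {
        idx <- idx + 1
        id <- sprintf("%s_I%03d", pop$population_code, i)
        sid <- sprintf("%s_S%03d", pop$population_code, i)
        parental_d <- draw_couple_distances(1, geography)
        mix <- mixture
        if (!is.null(band_mixture) && parental_d > band_km[1] &&
            parental_d <= band_km[2]) mix <- band_mixture
        mt <- sample(types, 1, prob = mix)
        spec <- specs[[mt]]
        nf <- sum(is.na(spec$pedigree$father))
        fh <- simulate_founders(2 * nf, snps)
        gd <- gene_drop(spec, fh, snps)
        calls[idx, ] <- gd$genotype
        haplo[2 * idx - 1, ] <- gd$haplotypes[1, ]
        haplo[2 * idx, ] <- gd$haplotypes[2, ]
        couple_d <- draw_couple_distances(1, geography)
        # individual born near the population centre; parents' and spouse's
        # birthplaces placed east at the drawn distances
        own <- place_at_distance(center_lat, center_lon, runif(1, 0, 2))
        mother_bp <- place_at_distance(own$lat, own$lon, parental_d)
        spouse_bp <- place_at_distance(own$lat, own$lon, couple_d)
        age <- round(runif(1, 25, 70))
        survey_rows[[length(survey_rows) + 1]] <- data.frame(
          individual_id = id, sex = sample(c("M", "F"), 1),
          population_code = pop$population_code, group = pop$group,
          birth_lat = own$lat, birth_lon = own$lon, spouse_id = sid,
          father_birth_lat = own$lat, father_birth_lon = own$lon,
          mother_birth_lat = mother_bp$lat, mother_birth_lon = mother_bp$lon,
          age = age, ecosystem = pop$ecosystem, lifestyle = pop$lifestyle,
          stringsAsFactors = FALSE)
        survey_rows[[length(survey_rows) + 1]] <- data.frame(
          individual_id = sid, sex = "F",
          population_code = pop$population_code, group = pop$group,
          birth_lat = spouse_bp$lat, birth_lon = spouse_bp$lon,
          spouse_id = id,
          father_birth_lat = NA_real_, father_birth_lon = NA_real_,
          mother_birth_lat = NA_real_, mother_birth_lon = NA_real_,
          age = age, ecosystem = pop$ecosystem, lifestyle = pop$lifestyle,
          stringsAsFactors = FALSE)
        truth_rows[[idx]] <- data.frame(
          individual_id = id, population_code = pop$population_code,
          group = pop$group, mating_type = mt, f_true = gd$f_true,
          parental_distance_km = parental_d,
          couple_distance_km = couple_d, stringsAsFactors = FALSE)
      }
    }
    ids <- vapply(truth_rows, function(r) r$individual_id, "")
    gt <- genotype_table(ids, snps, calls)
    if (error_rate > 0) gt <- add_genotype_errors(gt, error_rate)
    list(genotypes = gt, haplotypes = haplo,
         survey = as_survey(do.call(rbind, survey_rows)),
         truth = do.call(rbind, truth_rows),
         snps = snps, gmap = panel$gmap)
  })
}
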