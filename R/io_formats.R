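# Shared data model and external-format I/O: PLINK text PED/MAP genotypes,
# SHAPEIT-style genetic maps, and ethno-demographic survey CSVs.

#' Construct a genotype table
#'
#' The central genotype container: biallelic autosomal SNP calls coded as
#' alt-allele counts (0, 1, 2; \code{NA} = missing) for a set of samples.
#'
#' @param samples character vector of sample ids.
#' @param snps data frame of SNP metadata with columns \code{snp_id},
#'   \code{chrom} (integer 1--22), \code{pos_bp} (1-based, strictly
#'   increasing within chromosome), \code{pos_cM} (non-decreasing within
#'   chromosome), \code{a1}, \code{a2} (ref/alt allele characters) and
#'   optionally \code{freq_alt}.
#' @param calls integer matrix, \code{length(samples)} rows by
#'   \code{nrow(snps)} columns, values in \code{c(0, 1, 2, NA)}.
#' @return An object of class \code{"genotype_table"}.
#' @export
genotype_table <- function(samples, snps, calls) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  gt <- structure(list(samples = as.character(samples),
                       snps = as.data.frame(snps),
                       calls = calls),
                  class = "genotype_table")
  validate_genotype_table(gt)
  gt
}

validate_genotype_table <- function(gt) {
  stopifnot(inherits(gt, "genotype_table"))
  snps <- gt$snps
  req <- c("snp_id", "chrom", "pos_bp", "pos_cM", "a1", "a2")
  if (!all(req %in% names(snps)))
    stop("snps must have columns: ", paste(req, collapse = ", "))
  if (any(snps$chrom < 1 | snps$chrom > 22))
    stop("only autosomes (chrom 1-22) are supported")
  if (any(snps$pos_bp < 1)) stop("pos_bp must be >= 1")
  if (any(snps$pos_cM < 0)) stop("pos_cM must be >= 0")
  for (ch in unique(snps$chrom)) {
    i <- snps$chrom == ch
    if (is.unsorted(snps$pos_bp[i], strictly = TRUE))
      stop("pos_bp must be strictly increasing within chromosome ", ch)
    if (is.unsorted(snps$pos_cM[i]))
      stop("pos_cM must be non-decreasing within chromosome ", ch)
  }
  if (!identical(dim(gt$calls), c(length(gt$samples), nrow(snps))))
    stop("calls must be |samples| x |snps|")
  bad <- !(gt$calls %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("calls must be 0, 1, 2 or NA")
  invisible(gt)
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d samples x %d SNPs (%d chromosomes)\n",
              length(x$samples), nrow(x$snps), length(unique(x$snps$chrom))))
  invisible(x)
}

#' Read PLINK text PED/MAP files
#'
#' Calls are coded as counts of the alt allele. The alt allele is taken from
#' \code{alt_alleles} when supplied; otherwise it is the minor allele in the
#' dataset (ties broken so that the first-seen allele is ref). The chosen
#' orientation is recorded in the returned SNP table. PLINK's \code{"0 0"}
#' means a missing genotype.
#'
#' @param ped_path,map_path paths to the .ped and .map files.
#' @param alt_alleles optional character vector (one per SNP) naming the alt
#'   allele; overrides the minor-allele rule.
#' @return A \code{\link{genotype_table}}. Monomorphic SNPs get alt allele
#'   \code{"0"} (PLINK's missing-allele code).
#' @export
read_ped_map <- function(ped_path, map_path, alt_alleles = NULL) {
  map <- read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "snp_id", "pos_cM", "pos_bp"))
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  samples <- character(n)
  al1 <- matrix("0", n, m)
  al2 <- matrix("0", n, m)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(tok) != 6 + 2 * m)
      stop(sprintf("PED line %d has %d genotype fields, MAP has %d SNPs",
                   i, (length(tok) - 6) %/% 2, m))
    samples[i] <- tok[2]
    g <- tok[-(1:6)]
    al1[i, ] <- g[seq(1, 2 * m, by = 2)]
    al2[i, ] <- g[seq(2, 2 * m, by = 2)]
  }
  calls <- matrix(NA_integer_, n, m)
  a1 <- character(m)
  a2 <- character(m)
  for (j in seq_len(m)) {
    obs <- c(al1[, j], al2[, j])
    seen <- unique(obs[obs != "0"])
    if (length(seen) > 2)
      stop("non-biallelic SNP: ", map$snp_id[j])
    if (!is.null(alt_alleles)) {
      alt <- alt_alleles[j]
      ref <- setdiff(seen, alt)
      if (length(ref) == 0) ref <- "0"
      if (length(ref) > 1)
        stop("alt allele ", alt, " inconsistent with data at ", map$snp_id[j])
    } else if (length(seen) == 0) {
      ref <- "0"; alt <- "0"
    } else if (length(seen) == 1) {
      ref <- seen; alt <- "0"
    } else {
      cnt <- c(sum(obs == seen[1]), sum(obs == seen[2]))
      if (cnt[2] < cnt[1] || (cnt[1] == cnt[2])) {
        ref <- seen[1]; alt <- seen[2]  # tie: first-seen allele is ref
      } else {
        ref <- seen[2]; alt <- seen[1]
      }
    }
    a1[j] <- ref
    a2[j] <- alt
    miss <- al1[, j] == "0" | al2[, j] == "0"
    calls[, j] <- (al1[, j] == alt) + (al2[, j] == alt)
    calls[miss, j] <- NA_integer_
  }
  snps <- data.frame(snp_id = map$snp_id, chrom = as.integer(map$chrom),
                     pos_bp = as.integer(map$pos_bp), pos_cM = map$pos_cM,
                     a1 = a1, a2 = a2, stringsAsFactors = FALSE)
  gt <- genotype_table(samples, snps, calls)
  attr(gt, "allele_orientation") <-
    if (is.null(alt_alleles)) "minor-allele alt" else "supplied alt alleles"
  gt
}

#' Write PLINK text PED/MAP files
#'
#' Inverse of \code{\link{read_ped_map}}: missing calls are emitted as
#' \code{"0 0"}; homozygous ref, het and homozygous alt as the corresponding
#' allele-letter pairs.
#'
#' @param gt a \code{\link{genotype_table}}.
#' @param ped_path,map_path output paths.
#' @export
write_ped_map <- function(gt, ped_path, map_path) {
  validate_genotype_table(gt)
  snps <- gt$snps
  write.table(data.frame(snps$chrom, snps$snp_id,
                         format(snps$pos_cM, digits = 10, trim = TRUE,
                                scientific = FALSE),
                         snps$pos_bp),
              map_path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  n <- length(gt$samples)
  m <- nrow(snps)
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (i in seq_len(n)) {
    g <- gt$calls[i, ]
    a <- character(2 * m)
    odd <- seq(1, 2 * m, by = 2)
    a[odd] <- ifelse(is.na(g), "0", ifelse(g >= 1, snps$a2, snps$a1))
    a[odd + 1] <- ifelse(is.na(g), "0", ifelse(g == 2, snps$a2, snps$a1))
    writeLines(paste(c(gt$samples[i], gt$samples[i], "0", "0", "0", "-9", a),
                     collapse = " "), con)
  }
  invisible(NULL)
}

#' Read a genetic map
#'
#' Whitespace-separated columns \code{chrom pos_bp rate_cM_per_Mb pos_cM}
#' (one row per map knot; a header line is skipped if present).
#'
#' @param path map file path.
#' @return A \code{"genetic_map"}: a list, one element per chromosome, each
#'   with numeric vectors \code{pos_bp}, \code{rate} and \code{pos_cM}.
#' @export
read_genetic_map <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(trimws(first),
                                                           "[ \t]+")[[1]][1])))
  tab <- read.table(path, header = has_header, stringsAsFactors = FALSE)
  names(tab) <- c("chrom", "pos_bp", "rate", "pos_cM")
  genetic_map(tab)
}

#' Build a genetic map from a data frame
#'
#' @param tab data frame with columns \code{chrom}, \code{pos_bp},
#'   \code{rate} (cM/Mb, >= 0) and \code{pos_cM} (non-decreasing in
#'   \code{pos_bp} within chromosome).
#' @return A \code{"genetic_map"} object.
#' @export
genetic_map <- function(tab) {
  stopifnot(all(c("chrom", "pos_bp", "rate", "pos_cM") %in% names(tab)))
  if (any(tab$rate < 0)) stop("recombination rate must be >= 0")
  gm <- lapply(split(tab, tab$chrom), function(d) {
    d <- d[order(d$pos_bp), ]
    if (is.unsorted(d$pos_cM))
      stop("pos_cM must be non-decreasing in pos_bp (chrom ",
           d$chrom[1], ")")
    list(pos_bp = d$pos_bp, rate = d$rate, pos_cM = d$pos_cM)
  })
  structure(gm, class = "genetic_map")
}

#' Write a genetic map
#' @param gmap a \code{"genetic_map"}.
#' @param path output path.
#' @export
write_genetic_map <- function(gmap, path) {
  rows <- do.call(rbind, lapply(names(gmap), function(ch) {
    data.frame(chrom = as.integer(ch), pos_bp = gmap[[ch]]$pos_bp,
               rate = gmap[[ch]]$rate, pos_cM = gmap[[ch]]$pos_cM)
  }))
  write.table(rows, path, quote = FALSE, row.names = FALSE,
              col.names = c("chrom", "pos_bp", "rate_cM_per_Mb", "pos_cM"))
  invisible(NULL)
}

#' Interpolate genetic position
#'
#' Piecewise-linear interpolation of cM at a physical position, clamped to
#' the first/last map knot outside the mapped range. Monotone non-decreasing
#' in \code{pos_bp}.
#'
#' @param gmap a \code{"genetic_map"}.
#' @param chrom chromosome (must be covered by the map).
#' @param pos_bp physical position(s), bp.
#' @return Genetic position(s) in cM.
#' @export
interpolate_cM <- function(gmap, chrom, pos_bp) {
  ch <- as.character(chrom)
  if (is.null(gmap[[ch]])) stop("map does not cover chromosome ", chrom)
  k <- gmap[[ch]]
  if (length(k$pos_bp) == 1) return(rep(k$pos_cM, length(pos_bp)))
  approx(k$pos_bp, k$pos_cM, xout = pos_bp, rule = 2)$y
}

# ---- survey ----------------------------------------------------------------

survey_columns <- c("individual_id", "sex", "population_code", "group",
                    "birth_lat", "birth_lon", "spouse_id",
                    "father_birth_lat", "father_birth_lon",
                    "mother_birth_lat", "mother_birth_lon")

check_latlon <- function(lat, lon, where) {
  bad <- which(!is.na(lat) & (lat < -90 | lat > 90))
  if (length(bad))
    stop(sprintf("invalid latitude %s at row %d (%s)", lat[bad[1]], bad[1],
                 where))
  bad <- which(!is.na(lon) & (lon < -180 | lon > 180))
  if (length(bad))
    stop(sprintf("invalid longitude %s at row %d (%s)", lon[bad[1]], bad[1],
                 where))
}

#' Read an ethno-demographic survey CSV
#'
#' Required columns: \code{individual_id}, \code{sex} (M/F/unknown),
#' \code{population_code}, \code{group}, \code{birth_lat}, \code{birth_lon},
#' \code{spouse_id} (may be empty), \code{father_birth_lat/lon},
#' \code{mother_birth_lat/lon}. Extra columns (age, ecosystem, lifestyle,
#' ...) are kept. Coordinates are validated row by row; asymmetric spouse
#' links (A names B but B names C) raise an error.
#'
#' @param path CSV path.
#' @return A data frame of class \code{"survey"}.
#' @export
read_survey <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(survey_columns, names(tab))
  if (length(missing_cols))
    stop("survey is missing columns: ", paste(missing_cols, collapse = ", "))
  as_survey(tab)
}

#' Validate a survey data frame
#' @param tab data frame with the survey columns.
#' @return The validated data frame, class \code{"survey"}.
#' @export
as_survey <- function(tab) {
  for (col in c("spouse_id", "individual_id"))
    tab[[col]] <- as.character(tab[[col]])
  tab$spouse_id[!is.na(tab$spouse_id) & tab$spouse_id == ""] <- NA
  check_latlon(tab$birth_lat, tab$birth_lon, "birthplace")
  check_latlon(tab$father_birth_lat, tab$father_birth_lon, "father birthplace")
  check_latlon(tab$mother_birth_lat, tab$mother_birth_lon, "mother birthplace")
  has_sp <- !is.na(tab$spouse_id)
  idx <- match(tab$spouse_id[has_sp], tab$individual_id)
  back <- tab$spouse_id[idx]
  bad <- which(!is.na(idx) & (is.na(back) | back != tab$individual_id[has_sp]))
  if (length(bad))
    stop("asymmetric spouse link for individual ",
         tab$individual_id[has_sp][bad[1]])
  class(tab) <- c("survey", "data.frame")
  tab
}

#' Write a survey CSV
#' @param survey a survey data frame.
#' @param path output path.
#' @export
write_survey <- function(survey, path) {
  write.csv(as.data.frame(survey), path, row.names = FALSE, na = "")
  invisible(NULL)
}
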