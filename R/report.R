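# The comparison layer: confounder regressions and the distance-binned
# exogamy-versus-inbreeding report.

#' Single- and multi-covariate confounder regressions
#'
#' Fits the per-population outcome (e.g. percent inbred, mean haplotypic
#' heterozygosity) against each covariate alone, then against user-selected
#' covariate combinations with a multiple linear regression and its ANOVA
#' table. Character covariates (ecosystem, lifestyle, ...) are treated as
#' factors with the first level as reference.
#'
#' @param tab per-population data frame.
#' @param outcome name of the outcome column.
#' @param covariates names of candidate covariate columns.
#' @param combinations optional list of character vectors, each a covariate
#'   combination for a multiple regression; defaults to the single
#'   combination of all covariates.
#' @return list: \code{single} (data frame: covariate, estimate, p_value,
#'   r_squared), \code{multiple} (per combination: \code{coefficients},
#'   \code{anova}, \code{r_squared}).
#' @export
regress_confounders <- function(tab, outcome, covariates,
                                combinations = NULL) {
  stopifnot(outcome %in% names(tab), all(covariates %in% names(tab)))
  tab <- as.data.frame(tab)
  for (cv in covariates)
    if (is.character(tab[[cv]])) tab[[cv]] <- factor(tab[[cv]])
  single <- do.call(rbind, lapply(covariates, function(cv) {
    fit <- lm(as.formula(paste(outcome, "~", cv)), data = tab)
    sm <- summary(fit)
    co <- sm$coefficients
    data.frame(covariate = cv,
               estimate = co[2, 1],
               p_value = co[2, 4],
               r_squared = sm$r.squared, stringsAsFactors = FALSE)
  }))
  combinations <- combinations %||% list(covariates)
  multiple <- lapply(combinations, function(cvs) {
    fit <- lm(as.formula(paste(outcome, "~", paste(cvs, collapse = " + "))),
              data = tab)
    sm <- summary(fit)
    list(covariates = cvs, coefficients = sm$coefficients,
         anova = anova(fit), r_squared = sm$r.squared)
  })
  list(single = single, multiple = multiple)
}

#' Distance-binned exogamy-versus-inbreeding report
#'
#' Joins per-individual inbreeding measures to the distance between their
#' parents' birthplaces, bins individuals into the four parental-distance
#' classes, and compares each exogamous class against the endogamous
#' (\code{"<4"}) class with a Mann-Whitney U test per measure. Among
#' descendants of exogamous couples only, Spearman correlations of each
#' measure with log10 parental distance are also reported.
#'
#' @param survey a survey data frame (parental birthplaces are used).
#' @param fits per-individual inbreeding table from
#'   \code{\link{estimate_inbreeding}} (column \code{F_Median}; more
#'   measure columns are picked up via \code{measures}).
#' @param roh_summary optional per-individual class summary (e.g. from
#'   \code{\link{classify_population}}); its \code{n_C} and \code{kb_C}
#'   columns are added as measures when present.
#' @param measures names of the inbreeding measure columns to analyse.
#' @param threshold_km exogamy limit separating endogamous from exogamous
#'   parental couples.
#' @param mwu_alternative direction of the class-versus-endogamous test
#'   (\code{"greater"}: exogamous class more inbred).
#' @return list of class \code{"exogamy_inbreeding_report"}:
#'   \code{bin_table} (per class and measure: n, median, q25, q75, MWU p
#'   vs the \code{"<4"} class), \code{spearman} (per measure among
#'   exogamous individuals), \code{data} (the joined per-individual table),
#'   \code{n_excluded} (individuals lacking parental birthplaces or fits).
#' @export
exogamy_inbreeding_report <- function(survey, fits, roh_summary = NULL,
                                      measures = NULL, threshold_km = 4,
                                      mwu_alternative = "greater") {
  pd <- couple_distances(survey, "parental")
  tab <- merge(fits,
               pd[, c("couple_id", "distance_km")],
               by.x = "individual_id", by.y = "couple_id")
  if (!is.null(roh_summary))
    tab <- merge(tab, roh_summary, by = "individual_id")
  measures <- measures %||% intersect(c("F_Median", "n_C", "kb_C"),
                                      names(tab))
  n_excluded <- nrow(fits) - nrow(tab)
  tab$distance_class <- distance_class(tab$distance_km)
  classes <- levels(tab$distance_class)
  bin_rows <- list()
  sp_rows <- list()
  for (ms in measures) {
    ref <- tab[[ms]][tab$distance_class == "<4"]
    for (cl in classes) {
      v <- tab[[ms]][tab$distance_class == cl]
      p <- if (cl == "<4" || !length(v) || !length(ref)) NA_real_ else
        mwu(v, ref, alternative = mwu_alternative)$p_value
      qs <- if (length(v)) quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
            else rep(NA_real_, 3)
      bin_rows[[length(bin_rows) + 1]] <- data.frame(
        measure = ms, distance_class = cl, n = length(v), q25 = qs[1],
        median = qs[2], q75 = qs[3], mwu_p_vs_endogamous = p,
        stringsAsFactors = FALSE)
    }
    exo <- tab[tab$distance_km > threshold_km, ]
    if (nrow(exo) >= 3) {
      sp <- spearman(log10(exo$distance_km), exo[[ms]])
      if (!is.na(sp$statistic))
        sp_rows[[length(sp_rows) + 1]] <- data.frame(
          measure = ms, rho = sp$statistic, p_value = sp$p_value,
          n = nrow(exo), stringsAsFactors = FALSE)
    }
  }
  structure(list(bin_table = do.call(rbind, bin_rows),
                 spearman = if (length(sp_rows)) do.call(rbind, sp_rows),
                 data = tab, n_excluded = n_excluded,
                 threshold_km = threshold_km),
            class = "exogamy_inbreeding_report")
}

#' Per-population exogamy/inbreeding correlation set
#'
#' Population-scale companion to the individual-scale report: correlates
#' the per-population exogamy rate with the percent of inbred individuals
#' (both definitions: F-Median > 0 and LRT-inbred) and, optionally, with
#' mean haplotypic heterozygosity.
#'
#' @param profile an \code{\link{exogamy_rate}} profile.
#' @param fits an \code{\link{estimate_inbreeding}} table.
#' @param het optional \code{\link{block_haplotype_heterozygosity}} table.
#' @return list: \code{table} (per population: exogamy_rate,
#'   pct_f_positive, pct_lrt_inbred, mean_het), \code{correlations}
#'   (Spearman results per outcome).
#' @export
population_correlates <- function(profile, fits, het = NULL) {
  pct <- do.call(rbind, lapply(split(fits, fits$population_code),
    function(d) data.frame(
      population_code = d$population_code[1],
      pct_f_positive = 100 * mean(d$F_Median > 1e-4),
      pct_lrt_inbred = 100 * mean(d$inbred), stringsAsFactors = FALSE)))
  tab <- merge(profile[, c("population_code", "exogamy_rate")], pct,
               by = "population_code")
  if (!is.null(het))
    tab <- merge(tab, het[, c("population_code", "mean_het")],
                 by = "population_code")
  outs <- intersect(c("pct_f_positive", "pct_lrt_inbred", "mean_het"),
                    names(tab))
  cors <- lapply(setNames(outs, outs), function(o) {
    if (nrow(tab) >= 3) spearman(tab$exogamy_rate, tab[[o]]) else NULL
  })
  list(table = tab, correlations = cors)
}
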