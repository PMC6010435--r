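# Geographical exogamy: spousal birthplace distances, log-scale kernel
# densities, the antimode-based exogamy threshold, rates and distance
# classes.

EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance between birthplaces
#'
#' Haversine distance on a sphere of radius 6,371.0088 km (IUGG mean Earth
#' radius). Symmetric, non-negative, and zero only for identical points.
#'
#' @param lat1,lon1,lat2,lon2 coordinates in decimal degrees (vectorised).
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE))
    stop("latitude out of [-90, 90]")
  if (any(abs(c(lon1, lon2)) > 180, na.rm = TRUE))
    stop("longitude out of [-180, 180]")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM)
}

#' Couple distances from a survey
#'
#' For \code{generation = "current"}, one record per spouse pair (pairs
#' listed from both spouses' rows are deduplicated); for
#' \code{"parental"}, one record per individual with both parental
#' birthplaces set (the distance between the father's and mother's
#' birthplaces). Couples with a missing birthplace are skipped; the number
#' skipped is attached as attribute \code{"n_skipped"}.
#'
#' @param survey a survey data frame (see \code{\link{read_survey}}).
#' @param generation \code{"current"} or \code{"parental"}.
#' @return data frame: \code{couple_id}, \code{population_code},
#'   \code{group}, \code{generation}, \code{distance_km}.
#' @export
couple_distances <- function(survey, generation = c("current", "parental")) {
  generation <- match.arg(generation)
  if (generation == "current") {
    has <- !is.na(survey$spouse_id)
    sub <- survey[has, ]
    j <- match(sub$spouse_id, survey$individual_id)
    ok <- !is.na(j)
    sub <- sub[ok, ]
    sp <- survey[j[ok], ]
    key <- ifelse(sub$individual_id < sp$individual_id,
                  paste(sub$individual_id, sp$individual_id),
                  paste(sp$individual_id, sub$individual_id))
    first <- !duplicated(key)
    sub <- sub[first, ]
    sp <- sp[first, ]
    complete <- !is.na(sub$birth_lat) & !is.na(sub$birth_lon) &
      !is.na(sp$birth_lat) & !is.na(sp$birth_lon)
    n_skipped <- sum(!complete) + sum(!ok)
    sub <- sub[complete, ]
    sp <- sp[complete, ]
    out <- data.frame(
      couple_id = paste(sub$individual_id, sp$individual_id, sep = "+"),
      population_code = sub$population_code, group = sub$group,
      generation = "current",
      distance_km = haversine_km(sub$birth_lat, sub$birth_lon,
                                 sp$birth_lat, sp$birth_lon),
      stringsAsFactors = FALSE)
  } else {
    complete <- !is.na(survey$father_birth_lat) &
      !is.na(survey$father_birth_lon) &
      !is.na(survey$mother_birth_lat) & !is.na(survey$mother_birth_lon)
    n_skipped <- sum(!complete)
    sub <- survey[complete, ]
    out <- data.frame(
      couple_id = sub$individual_id,
      population_code = sub$population_code, group = sub$group,
      generation = "parental",
      distance_km = haversine_km(sub$father_birth_lat, sub$father_birth_lon,
                                 sub$mother_birth_lat, sub$mother_birth_lon),
      stringsAsFactors = FALSE)
  }
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Gaussian kernel density of log10 distances
#'
#' Density of log10(distance km) with a Gaussian kernel of standard
#' deviation \code{bandwidth} (the R \code{bw} convention). Distances of
#' exactly 0 km (strictly endogamous couples) cannot enter a log-scale
#' density; they are replaced by 0.1 km for density estimation only, which
#' keeps the endogamous mode visible below any plausible antimode. The
#' evaluation grid has 512 points spanning [log10 0.1, log10 2000] padded by
#' four bandwidths on each side so that the density integrates to one.
#'
#' @param distances_km couple distances (km); at least two must be nonzero.
#' @param bandwidth Gaussian kernel SD on the log10 scale.
#' @param zero_km replacement value for 0-km distances.
#' @return list of class \code{"log_kde"}: \code{x} (log10 km grid),
#'   \code{y} (density), \code{bandwidth}, \code{n}.
#' @export
kde_log_distance <- function(distances_km, bandwidth = 0.2, zero_km = 0.1) {
  if (all(distances_km == 0)) stop("no exogamous component")
  if (sum(distances_km > 0) < 2)
    stop("need at least two nonzero distances")
  d <- pmax(distances_km, zero_km)
  pad <- 4 * bandwidth
  dens <- density(log10(d), bw = bandwidth, from = log10(0.1) - pad,
                  to = log10(2000) + pad, n = 512)
  structure(list(x = dens$x, y = dens$y, bandwidth = bandwidth,
                 n = length(d)),
            class = "log_kde")
}

local_extrema <- function(y) {
  dy <- diff(y)
  s <- sign(dy)
  # collapse flat stretches
  s[s == 0] <- NA
  s <- zoo_na_locf(s)
  turn <- diff(s)
  list(maxima = which(turn < 0) + 1L, minima = which(turn > 0) + 1L)
}

# minimal last-observation-carried-forward (avoids a zoo dependency)
zoo_na_locf <- function(x) {
  i <- cumsum(!is.na(x))
  v <- x[!is.na(x)]
  out <- rep(NA_real_, length(x))
  out[i > 0] <- v[i[i > 0]]
  out[is.na(out)] <- out[which(!is.na(out))[1]]
  out
}

#' Exogamy threshold from per-population distance densities
#'
#' For each population's \code{\link{kde_log_distance}}, finds the antimode:
#' the lowest local minimum of the density strictly between the two highest
#' local maxima (searched inside the nominal [0.1, 2000] km window).
#' Unimodal densities are excluded with a warning. The returned threshold is
#' the average of the per-population antimodes, in km.
#'
#' @param kdes a single \code{"log_kde"} or a (possibly named) list of them.
#' @return Threshold in km, with attribute \code{"per_population"} (the
#'   per-population antimodes in km).
#' @export
find_exogamy_threshold <- function(kdes) {
  if (inherits(kdes, "log_kde")) kdes <- list(kdes)
  anti <- vapply(seq_along(kdes), function(i) {
    k <- kdes[[i]]
    win <- k$x >= log10(0.1) - 1e-9 & k$x <= log10(2000) + 1e-9
    x <- k$x[win]
    y <- k$y[win]
    ex <- local_extrema(y)
    # ignore negligible wiggles: a mode must reach 5% of the main peak
    ex$maxima <- ex$maxima[y[ex$maxima] >= 0.05 * max(y)]
    if (length(ex$maxima) < 2) {
      warning("population ", names(kdes)[i] %||% i,
              ": unimodal distance density, excluded from threshold")
      return(NA_real_)
    }
    top2 <- sort(ex$maxima[order(y[ex$maxima], decreasing = TRUE)][1:2])
    mins <- ex$minima[ex$minima > top2[1] & ex$minima < top2[2]]
    if (!length(mins)) return(NA_real_)
    10^x[mins[which.min(y[mins])]]
  }, 0)
  if (all(is.na(anti))) stop("no bimodal population density found")
  structure(mean(anti, na.rm = TRUE), per_population = anti)
}

#' Per-population exogamy profile
#'
#' Exogamy rate = share of couples with distance strictly above the
#' threshold; also reports the median distance restricted to exogamous
#' couples. Computed per population, with per-group and overall rows
#' attached as attributes.
#'
#' @param distances a \code{\link{couple_distances}} data frame.
#' @param threshold_km exogamy limit in km (> 0).
#' @return data frame of class \code{"exogamy_profile"}:
#'   \code{population_code}, \code{group}, \code{n_couples},
#'   \code{threshold_km}, \code{exogamy_rate}, \code{median_exogamous_km};
#'   attributes \code{"by_group"} and \code{"overall"}. Distances are
#'   great-circle km (recorded in attribute \code{"distance_metric"}).
#' @export
exogamy_rate <- function(distances, threshold_km = 4) {
  if (threshold_km <= 0) stop("threshold_km must be > 0")
  one <- function(d) {
    exo <- d$distance_km > threshold_km
    data.frame(n_couples = nrow(d), threshold_km = threshold_km,
               exogamy_rate = mean(exo),
               median_exogamous_km = if (any(exo))
                 median(d$distance_km[exo]) else NA_real_)
  }
  pieces <- split(distances, distances$population_code)
  prof <- do.call(rbind, lapply(names(pieces), function(pc) {
    cbind(data.frame(population_code = pc,
                     group = pieces[[pc]]$group[1],
                     stringsAsFactors = FALSE),
          one(pieces[[pc]]))
  }))
  by_group <- do.call(rbind, lapply(split(distances, distances$group),
                                    one))
  by_group$group <- rownames(by_group)
  rownames(prof) <- rownames(by_group) <- NULL
  structure(prof, by_group = by_group, overall = one(distances),
            distance_metric = "great-circle (haversine, R = 6371.0088 km)",
            class = c("exogamy_profile", "data.frame"))
}

#' Parental-distance classes
#'
#' Bins a distance into the four classes used for the distance-binned
#' inbreeding comparison: \code{"<4"} (0--4 km, closed at 4), \code{"4-20"},
#' \code{"20-40"} and \code{">40"}. Boundaries are closed on the left
#' class, so 4.0 km is endogamous and 40.0 km falls in \code{"20-40"}.
#'
#' @param distance_km non-negative distance(s), km.
#' @return factor with levels \code{"<4"}, \code{"4-20"}, \code{"20-40"},
#'   \code{">40"}.
#' @export
distance_class <- function(distance_km) {
  if (any(distance_km < 0, na.rm = TRUE)) stop("distance must be >= 0")
  cut(distance_km, breaks = c(-Inf, 4, 20, 40, Inf),
      labels = c("<4", "4-20", "20-40", ">40"), right = TRUE)
}
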