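#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371.0088 km (mean Earth
#' radius). Vectorized over coordinate pairs.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees.
#' @return distance(s) in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = EARTH_RADIUS_KM * 1000) / 1000
}

# All-pairs haversine distance matrix (km) for a set of points.
haversine_matrix_km <- function(lon, lat) {
  geosphere::distm(cbind(lon, lat), fun = function(a, b) {
    geosphere::distHaversine(a, b, r = EARTH_RADIUS_KM * 1000)
  }) / 1000
}

#' Spatially thin occurrence records
#'
#' Rarefies records so that no two retained records of the same population
#' lie within `radius_km` of each other (great-circle distance), mitigating
#' sampling-bias effects on downstream models. The algorithm repeatedly
#' deletes the record with the most within-radius neighbours (ties broken
#' uniformly at random from the seed), then reinstates any removed record
#' that no longer conflicts with the retained set, so the result is maximal:
#' no removed record could be re-added without violating the constraint.
#'
#' @param occurrences occurrence data frame (`species`, `lon`, `lat`).
#' @param radius_km minimum pairwise distance among retained records
#'   (default 5 km).
#' @param seed integer seed for tie-breaking.
#' @param per_population thin each population independently (default), or
#'   all records jointly.
#' @return list with `kept` (thinned `occurrence_set`) and `report`
#'   (data frame of removed records with the population and reason).
#' @export
thin_occurrences <- function(occurrences, radius_km = 5, seed = 1L,
                             per_population = TRUE) {
  stopifnot(radius_km > 0, nrow(occurrences) >= 1)
  groups <- if (per_population) split(seq_len(nrow(occurrences)),
                                      occurrences$species)
            else list(all = seq_len(nrow(occurrences)))
  keep_idx <- integer(); removed_idx <- integer()
  gi <- 0L
  for (g in groups) {
    gi <- gi + 1L
    res <- with_seed(spawn_seed(seed, gi),
                     thin_group(occurrences$lon[g], occurrences$lat[g],
                                radius_km))
    keep_idx <- c(keep_idx, g[res$keep])
    removed_idx <- c(removed_idx, g[res$removed])
  }
  kept <- occurrences[sort(keep_idx), , drop = FALSE]
  rownames(kept) <- NULL
  report <- if (length(removed_idx)) {
    data.frame(record = sort(removed_idx),
               population = occurrences$species[sort(removed_idx)],
               reason = sprintf("within %g km of a retained record",
                                radius_km),
               stringsAsFactors = FALSE)
  } else {
    data.frame(record = integer(), population = character(),
               reason = character(), stringsAsFactors = FALSE)
  }
  list(kept = kept, report = report)
}

# Greedy most-neighbours deletion followed by a reinstatement pass that
# guarantees maximality of the retained set. Indices are relative to the
# group. Assumes the caller has seeded the RNG.
thin_group <- function(lon, lat, radius_km) {
  n <- length(lon)
  if (n == 1) return(list(keep = 1L, removed = integer()))
  d <- haversine_matrix_km(lon, lat)
  conflict <- d < radius_km
  diag(conflict) <- FALSE
  alive <- rep(TRUE, n)
  repeat {
    counts <- rowSums(conflict[, alive, drop = FALSE]) * alive
    mx <- max(counts)
    if (mx == 0) break
    worst <- which(counts == mx)
    drop <- if (length(worst) > 1) worst[sample.int(length(worst), 1)] else worst
    alive[drop] <- FALSE
    conflict[drop, ] <- FALSE
    conflict[, drop] <- FALSE
  }
  # reinstatement: re-add removed records that now conflict with nothing
  repeat {
    added <- FALSE
    for (i in which(!alive)) {
      if (!any(d[i, alive] < radius_km)) {
        alive[i] <- TRUE
        added <- TRUE
      }
    }
    if (!added) break
  }
  list(keep = which(alive), removed = which(!alive))
}
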