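#' Specification of a synthetic region
#'
#' Describes a rectangular lon/lat region on which predictor layers are
#' simulated. Each simulated predictor is a deterministic spatial gradient
#' plus spatially autocorrelated noise (a moving-average-smoothed white-noise
#' field), with a small fraction of cells masked as nodata so that masking
#' logic is exercised downstream.
#'
#' @param name region label.
#' @param lon_min,lon_max,lat_min,lat_max region bounds in degrees.
#' @param cell_size cell edge in degrees (default 2.5 arc-min).
#' @param predictors named character vector mapping predictor name to
#'   category (`climate`, `landuse`, `topography`).
#' @param noise_smoothing moving-average radius in cells (0 = white noise).
#' @param noise_amplitude standard deviation of the pre-smoothing noise
#'   relative to the gradient amplitude; 0 gives a pure gradient.
#' @param nodata_fraction fraction of cells masked as nodata.
#' @param seed integer seed controlling every random element of the region.
#' @return an object of class `region_spec`.
#' @export
region_spec <- function(name, lon_min, lon_max, lat_min, lat_max,
                        cell_size = 2.5 / 60,
                        predictors = c(bio1 = "climate", bio4 = "climate",
                                       bio12 = "climate",
                                       cropland = "landuse",
                                       elevation = "topography"),
                        noise_smoothing = 2, noise_amplitude = 1,
                        nodata_fraction = 0.02, seed = 1L) {
  if (lon_min >= lon_max || lat_min >= lat_max) {
    stop_invrisk("region bounds must satisfy lon_min < lon_max and ",
                 "lat_min < lat_max")
  }
  if (cell_size <= 0) stop_invrisk("cell_size must be positive")
  ncols <- round((lon_max - lon_min) / cell_size)
  nrows <- round((lat_max - lat_min) / cell_size)
  if (ncols < 10 || nrows < 10) {
    stop_invrisk("degenerate region: grid must be at least 10 x 10 cells, ",
                 "got ", nrows, " x ", ncols)
  }
  structure(list(name = name, lon_min = lon_min, lon_max = lon_max,
                 lat_min = lat_min, lat_max = lat_max,
                 cell_size = cell_size, predictors = predictors,
                 noise_smoothing = as.integer(noise_smoothing),
                 noise_amplitude = noise_amplitude,
                 nodata_fraction = nodata_fraction,
                 seed = as.integer(seed), nrows = nrows, ncols = ncols),
            class = "region_spec")
}

# Edge-aware 2-D moving average with square window of radius k, computed
# with integral images so edges are normalized by the true window size.
box_smooth <- function(m, k) {
  if (k <= 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  S <- rbind(0, cbind(0, t(apply(apply(m, 2, cumsum), 1, cumsum))))
  i1 <- pmax(seq_len(nr) - k, 1); i2 <- pmin(seq_len(nr) + k, nr)
  j1 <- pmax(seq_len(nc) - k, 1); j2 <- pmin(seq_len(nc) + k, nc)
  I1 <- matrix(i1, nr, nc); I2 <- matrix(i2, nr, nc)
  J1 <- matrix(j1, nr, nc, byrow = TRUE); J2 <- matrix(j2, nr, nc, byrow = TRUE)
  sums <- S[cbind(as.vector(I2) + 1L, as.vector(J2) + 1L)] -
    S[cbind(as.vector(I1), as.vector(J2) + 1L)] -
    S[cbind(as.vector(I2) + 1L, as.vector(J1))] +
    S[cbind(as.vector(I1), as.vector(J1))]
  counts <- (I2 - I1 + 1) * (J2 - J1 + 1)
  matrix(sums, nr, nc) / counts
}

#' Simulate the predictor stack of a synthetic region
#'
#' Each predictor is built as `gradient + noise_amplitude * smoothed noise`,
#' where the gradient is linear in normalized latitude (always with a
#' non-zero latitudinal slope, so a noise-free predictor is strictly
#' monotone in latitude along any column) plus a smaller longitudinal term,
#' and the noise is white Gaussian noise smoothed by a moving average of the
#' region's `noise_smoothing` cell radius. Land-use predictors are rescaled
#' to `[0, 1]` (fractions of a land type). A common random `nodata_fraction`
#' of cells is masked across all layers. Everything is reproducible from the
#' region seed.
#'
#' @param region a [region_spec()].
#' @return a [predictor_stack()].
#' @export
generate_predictor_stack <- function(region) {
  stopifnot(inherits(region, "region_spec"))
  nr <- region$nrows; nc <- region$ncols
  origin_lat <- region$lat_min + nr * region$cell_size
  latn <- matrix((grid_lats_for(region) - region$lat_min) /
                   (region$lat_max - region$lat_min), nr, nc)
  lonn <- matrix((grid_lons_for(region) - region$lon_min) /
                   (region$lon_max - region$lon_min), nr, nc, byrow = TRUE)
  with_seed(region$seed, {
    names_p <- names(region$predictors)
    grids <- vector("list", length(names_p)); names(grids) <- names_p
    for (i in seq_along(names_p)) {
      # one gradient orientation per predictor, fanned over +/-60 degrees
      # from the latitude axis so layers are correlated but not collinear;
      # the latitudinal component never vanishes
      theta <- (-60 + 30 * ((i - 1) %% 5)) / 180
      a <- cospi(theta) * if (i %% 2 == 0) -1 else 1
      b <- sinpi(theta)
      gradient <- 2.2 * (a * latn + b * lonn)
      noise <- matrix(stats::rnorm(nr * nc), nr, nc)
      noise <- box_smooth(noise, region$noise_smoothing)
      vals <- gradient + region$noise_amplitude * noise
      if (region$predictors[[i]] == "landuse") {
        rng <- range(vals)
        vals <- if (diff(rng) > 0) (vals - rng[1]) / diff(rng) else vals * 0
      }
      grids[[i]] <- vals
    }
    n_nodata <- floor(region$nodata_fraction * nr * nc)
    mask_idx <- if (n_nodata > 0) sample.int(nr * nc, n_nodata) else integer()
    grids <- lapply(grids, function(v) {
      v[mask_idx] <- NA_real_
      raster_grid(v, region$lon_min, origin_lat, region$cell_size)
    })
    predictor_stack(grids, region$predictors)
  })
}

grid_lats_for <- function(region) {
  region$lat_min + region$nrows * region$cell_size -
    (seq_len(region$nrows) - 0.5) * region$cell_size
}

grid_lons_for <- function(region) {
  region$lon_min + (seq_len(region$ncols) - 0.5) * region$cell_size
}

#' Specification of a virtual species
#'
#' A virtual species' true habitat suitability is a logistic function of
#' standardized predictors: `logistic(intercept + sum(coef * z))`. Its true
#' range is the set of cells with suitability at or above
#' `occupancy_threshold`.
#'
#' @param name species/population label.
#' @param coefficients named numeric vector of logistic slopes per
#'   standardized predictor.
#' @param intercept logistic intercept.
#' @param occupancy_threshold suitability defining the true range, in
#'   `[0, 1]`.
#' @param n_occurrences number of occurrence points to sample.
#' @param sampling_bias_strength exponent (>= 0) of the longitudinal bias
#'   surface applied when sampling occurrences; 0 = unbiased.
#' @return an object of class `virtual_species`.
#' @export
virtual_species <- function(name, coefficients, intercept = 0,
                            occupancy_threshold = 0.5, n_occurrences = 500L,
                            sampling_bias_strength = 0) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
            n_occurrences >= 1, sampling_bias_strength >= 0)
  if (occupancy_threshold < 0 || occupancy_threshold > 1) {
    stop_invrisk("occupancy_threshold must lie in [0, 1]")
  }
  structure(list(name = name, coefficients = coefficients,
                 intercept = intercept,
                 occupancy_threshold = occupancy_threshold,
                 n_occurrences = as.integer(n_occurrences),
                 sampling_bias_strength = sampling_bias_strength),
            class = "virtual_species")
}

#' True suitability surface of a virtual species
#'
#' Standardizes each predictor named in the species' coefficients over the
#' valid cells of its layer (z-scores; a constant layer standardizes to 0)
#' and applies the logistic model cell-wise. Cells that are nodata in any
#' used layer are nodata in the output.
#'
#' @param stack a [predictor_stack()].
#' @param species a [virtual_species()].
#' @return a [raster_grid()] of suitabilities in `[0, 1]`.
#' @export
true_suitability <- function(stack, species) {
  miss <- setdiff(names(species$coefficients), names(stack$grids))
  if (length(miss)) {
    stop_invrisk("coefficients name predictors absent from the stack: ",
                 paste(miss, collapse = ", "))
  }
  tmpl <- stack_template(stack)
  eta <- matrix(species$intercept, nrow(tmpl$values), ncol(tmpl$values))
  for (nm in names(species$coefficients)) {
    v <- stack$grids[[nm]]$values
    mu <- mean(v, na.rm = TRUE)
    sd_ <- stats::sd(as.vector(v), na.rm = TRUE)
    z <- if (is.finite(sd_) && sd_ > 0) (v - mu) / sd_ else v * 0
    eta <- eta + species$coefficients[[nm]] * z
  }
  raster_grid(stats::plogis(eta), tmpl$origin_lon, tmpl$origin_lat,
              tmpl$cell_size)
}

#' Sample occurrence points from a suitability surface
#'
#' Cells are drawn with probability proportional to
#' `suitability * bias^sampling_bias_strength`, where the bias surface is a
#' fixed west-to-east longitudinal gradient in `(0, 1]`. Cells are drawn
#' without replacement when the requested count does not exceed the number
#' of habitable cells, with replacement otherwise. Each point is placed
#' uniformly within its cell.
#'
#' @param suitability a [raster_grid()] of suitabilities.
#' @param species a [virtual_species()] (supplies `n_occurrences` and
#'   `sampling_bias_strength`).
#' @param seed integer seed.
#' @return an `occurrence_set` data frame (`species`, `lon`, `lat`, `source`).
#' @export
sample_occurrences <- function(suitability, species, seed = 1L) {
  w <- as.vector(suitability$values)
  w[is.na(w)] <- 0
  if (species$sampling_bias_strength > 0) {
    co <- grid_coords(suitability)
    width <- ncol(suitability$values) * suitability$cell_size
    bias <- (co[, "lon"] - suitability$origin_lon) / width
    w <- w * bias^species$sampling_bias_strength
  }
  pos <- which(w > 0)
  if (!length(pos)) stop_invrisk("no habitable cells")
  n <- species$n_occurrences
  with_seed(seed, {
    idx <- pos[sample.int(length(pos), n, replace = n > length(pos),
                          prob = w[pos])]
    co <- grid_coords(suitability)
    cs <- suitability$cell_size
    occurrence_set(data.frame(
      species = species$name,
      lon = co[idx, "lon"] + stats::runif(n, -cs / 2, cs / 2),
      lat = co[idx, "lat"] + stats::runif(n, -cs / 2, cs / 2),
      source = "synthetic",
      stringsAsFactors = FALSE))
  })
}

#' Build the default two-region virtual-species scenario
#'
#' Generates two geographically disjoint "continents" with the same predictor
#' set, and two virtual species with partially shared niches: a *native*
#' species sampled on the source continent and an *introduced* species
#' sampled on the target continent. Both species' true suitability and true
#' range are computed on both regions, so every downstream estimate (ranges,
#' expansion/stabilization/unfilling, RR, IRS) has an exact ground truth.
#'
#' The introduced species shares its main climatic coefficients with the
#' native one but has a lower intercept and a divergent secondary predictor,
#' so its true target-region range is smaller than, and largely nested in,
#' the native species' transferred range — the situation the range-shift
#' indices are designed to quantify.
#'
#' Coefficient magnitudes are deliberately steep, giving near-binary
#' suitability surfaces: the virtual species have sharp physiological
#' tolerance edges, so their true ranges are insensitive to the exact
#' occupancy threshold and form a well-posed recovery target for the
#' threshold-based pipeline.
#'
#' @param seed master seed; region and sampling seeds derive from it.
#' @param n_occurrences occurrences per species (default 500).
#' @param cell_size region resolution in degrees (default 0.25, giving
#'   100 x 50-cell continents).
#' @param noise_amplitude predictor noise level (default 2, giving
#'   predictor pairs spanning weak to strong collinearity).
#' @return an object of class `synthetic_scenario`: regions, stacks, species,
#'   nested `true_suitability[[species]][[region]]` and `true_range` maps,
#'   and an `occurrences` table labelled by population.
#' @export
synthetic_scenario <- function(seed = 1L, n_occurrences = 500L,
                               cell_size = 0.25, noise_amplitude = 2) {
  source_region <- region_spec("source_continent", 0, 12.5, 25, 50,
                               cell_size = cell_size,
                               noise_amplitude = noise_amplitude,
                               seed = spawn_seed(seed, 1))
  target_region <- region_spec("target_continent", 40, 52.5, 25, 50,
                               cell_size = cell_size,
                               noise_amplitude = noise_amplitude,
                               seed = spawn_seed(seed, 2))
  regions <- list(source_continent = source_region,
                  target_continent = target_region)
  stacks <- lapply(regions, generate_predictor_stack)
  species <- list(
    native = virtual_species(
      "native",
      coefficients = c(bio1 = -24, bio12 = 12, elevation = -6),
      intercept = -16, occupancy_threshold = 0.5,
      n_occurrences = n_occurrences),
    introduced = virtual_species(
      "introduced",
      coefficients = c(bio1 = -24, bio12 = 12, cropland = 6),
      intercept = -28, occupancy_threshold = 0.5,
      n_occurrences = n_occurrences))
  suit <- lapply(species, function(sp) lapply(stacks, true_suitability,
                                              species = sp))
  ranges <- lapply(species, function(sp) {
    lapply(suit[[sp$name]], binarize, threshold = sp$occupancy_threshold)
  })
  occ <- rbind(
    sample_occurrences(suit$native$source_continent, species$native,
                       seed = spawn_seed(seed, 3)),
    sample_occurrences(suit$introduced$target_continent, species$introduced,
                       seed = spawn_seed(seed, 4)))
  structure(list(regions = regions, stacks = stacks, species = species,
                 true_suitability = suit, true_range = ranges,
                 occurrences = occurrence_set(as.data.frame(occ)),
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

#' Write a synthetic scenario to disk
#'
#' Writes one ASCII grid per (region, predictor) and per (species, region)
#' truth layer, the occurrence CSV, and a YAML manifest naming every
#' artifact together with the seeds that generated it.
#'
#' @param scenario a [synthetic_scenario()].
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = scenario$seed, regions = list(), species = list())
  for (rn in names(scenario$stacks)) {
    st <- scenario$stacks[[rn]]
    files <- list()
    for (pn in names(st$grids)) {
      f <- file.path(dir, sprintf("%s_%s.asc", rn, pn))
      write_raster(st$grids[[pn]], f)
      files[[pn]] <- basename(f)
    }
    manifest$regions[[rn]] <- list(
      seed = scenario$regions[[rn]]$seed,
      predictors = files,
      categories = as.list(st$category))
  }
  for (sn in names(scenario$true_suitability)) {
    for (rn in names(scenario$true_suitability[[sn]])) {
      f <- file.path(dir, sprintf("truth_%s_%s.asc", sn, rn))
      write_raster(scenario$true_suitability[[sn]][[rn]], f)
      manifest$species[[sn]][[rn]] <- basename(f)
    }
  }
  occ_file <- file.path(dir, "occurrences.csv")
  write_occurrences(scenario$occurrences, occ_file)
  manifest$occurrences <- basename(occ_file)
  manifest_path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  invisible(manifest_path)
}
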