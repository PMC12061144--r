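#' Binarize a suitability surface into a range map
#'
#' Applies a presence threshold cell-wise (`suitability >= threshold` means
#' presence). Nodata cells are absent and counted as excluded. The per-cell
#' spherical area map is attached so that range areas in km^2 follow
#' directly.
#'
#' @param suitability a [raster_grid()] with values in `[0, 1]`.
#' @param threshold presence threshold in `[0, 1]`, typically the MSS
#'   threshold of the calibrated model.
#' @param label optional text label for reports.
#' @return an object of class `binary_range`: logical `presence` matrix,
#'   `nodata_mask`, `threshold_used`, `area_map`, `template`, `label`.
#' @export
binarize <- function(suitability, threshold, label = "") {
  stopifnot(inherits(suitability, "raster_grid"))
  if (threshold < 0 || threshold > 1) {
    stop_invrisk("threshold must lie in [0, 1]")
  }
  mask <- suitability$nodata_mask
  presence <- !mask & suitability$values >= threshold
  presence[is.na(presence)] <- FALSE
  structure(list(presence = presence, nodata_mask = mask,
                 threshold_used = threshold,
                 area_map = cell_area_km2(suitability),
                 template = raster_grid(suitability$values * NA_real_,
                                        suitability$origin_lon,
                                        suitability$origin_lat,
                                        suitability$cell_size),
                 label = label),
            class = "binary_range")
}

#' @export
print.binary_range <- function(x, ...) {
  cat(sprintf("binary_range%s: %d presence cells (%.2f x 10^4 km^2), threshold %.3g, %d nodata\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              sum(x$presence), range_area_km2(x) / 1e4, x$threshold_used,
              sum(x$nodata_mask)))
  invisible(x)
}

#' Total area of a binary range
#'
#' @param range a `binary_range`.
#' @return area in km^2 summed over presence cells.
#' @export
range_area_km2 <- function(range) {
  sum(range$area_map$values[range$presence])
}

#' Decompose an introduced-vs-native pair of ranges
#'
#' Cell-wise decomposition of two aligned binary range maps into
#' *expansion* (introduced only), *stabilization* (both), and *unfilling*
#' (native only). Cells that are nodata in either map are excluded from all
#' three components and counted. Areas are latitude-corrected km^2 sums, and
#' all derived indices are filled in:
#' `IR = expansion + stabilization` (introduced range),
#' `NR = unfilling + stabilization` (native range),
#' `RR = IR / NR` plus its inverse, and
#' `IRS = 2 RS / (IR + NR)` plus the `RS / (IR + NR)` variant, where `RS`
#' is the stabilization area.
#'
#' @param introduced,native `binary_range` maps on the same template (the
#'   introduced population's calibrated range and the native population's
#'   transferred range).
#' @return an object of class `range_shift` (see [range_shift_from_areas()]
#'   for the fields).
#' @export
range_shift <- function(introduced, native) {
  stopifnot(inherits(introduced, "binary_range"),
            inherits(native, "binary_range"))
  if (!same_geometry(introduced$template, native$template)) {
    a <- introduced$template; b <- native$template
    stop_invrisk(sprintf(
      "misaligned range maps: %dx%d @ %.6g (%.4f, %.4f) vs %dx%d @ %.6g (%.4f, %.4f)",
      nrow(a$values), ncol(a$values), a$cell_size, a$origin_lon, a$origin_lat,
      nrow(b$values), ncol(b$values), b$cell_size, b$origin_lon, b$origin_lat))
  }
  excluded <- introduced$nodata_mask | native$nodata_mask
  ip <- introduced$presence & !excluded
  np <- native$presence & !excluded
  area <- introduced$area_map$values
  res <- range_shift_from_areas(
    expansion = sum(area[ip & !np]),
    stabilization = sum(area[ip & np]),
    unfilling = sum(area[np & !ip]))
  res$excluded_cells <- sum(excluded)
  res$cells <- c(expansion = sum(ip & !np), stabilization = sum(ip & np),
                 unfilling = sum(np & !ip))
  res$labels <- c(introduced = introduced$label, native = native$label)
  res
}

#' Range-shift indices from component areas
#'
#' Builds a `range_shift` result directly from the three component areas —
#' the entry point for worked examples where the areas are known numbers
#' rather than maps.
#'
#' @param expansion,stabilization,unfilling component areas (any common
#'   unit; km^2 in pipeline output).
#' @param unit `"km2"` (default) or `"1e4km2"`, recording the unit the
#'   areas are expressed in; indices are unit-free, printing adapts.
#' @return an object of class `range_shift` with fields `area_expansion`,
#'   `area_stabilization`, `area_unfilling`, `IR`, `NR`, `RR`
#'   (introduced/native), `RR_native_over_introduced`, `IRS`
#'   (`2RS/(IR+NR)`), `IRS_reported_variant` (`RS/(IR+NR)`), and
#'   `excluded_cells`.
#' @export
range_shift_from_areas <- function(expansion, stabilization, unfilling,
                                   unit = c("km2", "1e4km2")) {
  unit <- match.arg(unit)
  stopifnot(expansion >= 0, stabilization >= 0, unfilling >= 0)
  IR <- expansion + stabilization
  NR <- unfilling + stabilization
  rr <- if (IR > 0 && NR > 0) range_ratio(IR, NR) else
    list(RR = NA_real_, RR_native_over_introduced = NA_real_)
  irs <- if (IR + NR > 0) range_similarity(stabilization, IR, NR) else
    list(IRS = NA_real_, IRS_reported_variant = NA_real_)
  structure(list(area_expansion = expansion,
                 area_stabilization = stabilization,
                 area_unfilling = unfilling,
                 IR = IR, NR = NR,
                 RR = rr$RR,
                 RR_native_over_introduced = rr$RR_native_over_introduced,
                 IRS = irs$IRS,
                 IRS_reported_variant = irs$IRS_reported_variant,
                 excluded_cells = 0L, unit = unit),
            class = "range_shift")
}

#' Range ratio in both directions
#'
#' `RR = IR / NR` compares the introduced range to the native range
#' (`RR > 1` means the introduced range is larger). The inverse direction
#' `NR / IR` — how many times larger the native range is — is returned
#' alongside, and is the direction used when echoing results phrased as
#' "the native range is x times larger".
#'
#' @param IR,NR introduced and native range areas (same unit, both > 0).
#' @return list with `RR` (= IR/NR) and `RR_native_over_introduced` (= NR/IR).
#' @export
range_ratio <- function(IR, NR) {
  if (IR <= 0 || NR <= 0) stop_invrisk("IR and NR must both be positive")
  list(RR = IR / NR, RR_native_over_introduced = NR / IR)
}

#' Index of range similarity in both variants
#'
#' `IRS = 2 RS / (IR + NR)` is the area-weighted Sorensen coincidence of the
#' two ranges (1 = identical, 0 = disjoint). The halved variant
#' `RS / (IR + NR)` is also returned and labelled, since published analyses
#' sometimes report that form.
#'
#' @param RS shared (stabilization) area.
#' @param IR,NR introduced and native range areas; `RS` cannot exceed either.
#' @return list with `IRS` and `IRS_reported_variant` (= IRS/2).
#' @export
range_similarity <- function(RS, IR, NR) {
  if (IR + NR <= 0) stop_invrisk("IR + NR must be positive")
  if (RS > min(IR, NR) + 1e-9 * max(IR, NR, 1)) {
    stop_invrisk("impossible overlap: RS exceeds min(IR, NR)")
  }
  list(IRS = 2 * RS / (IR + NR), IRS_reported_variant = RS / (IR + NR))
}

#' @export
print.range_shift <- function(x, digits = 2, ...) {
  div <- if (identical(x$unit %||% "km2", "km2")) 1e4 else 1
  cat("Range-shift decomposition (areas in 10^4 km^2):\n")
  f <- function(a) formatC(a / div, format = "f", digits = digits)
  cat(sprintf("  expansion     %s\n", f(x$area_expansion)))
  cat(sprintf("  stabilization %s\n", f(x$area_stabilization)))
  cat(sprintf("  unfilling     %s\n", f(x$area_unfilling)))
  cat(sprintf("  IR %s   NR %s\n", f(x$IR), f(x$NR)))
  cat(sprintf("  RR (IR/NR) %.3g   NR/IR %.3g\n",
              x$RR, x$RR_native_over_introduced))
  cat(sprintf("  IRS (2RS/(IR+NR)) %.3g   RS/(IR+NR) %.3g\n",
              x$IRS, x$IRS_reported_variant))
  if (x$excluded_cells > 0) {
    cat(sprintf("  excluded nodata cells: %d\n", x$excluded_cells))
  }
  invisible(x)
}

#' Per-population occurrence and predictor summary
#'
#' Summarizes each population's latitudinal extent (min, max, span) and,
#' when a predictor stack is supplied, the distribution of each predictor at
#' the occurrence cells (min, max, quartiles) together with pairwise Welch
#' t-tests of predictor values between populations.
#'
#' @param occurrences an occurrence data frame (`species`, `lon`, `lat`).
#' @param stack optional [predictor_stack()] for predictor summaries.
#' @return list with `latitude` (data frame: population, n, lat_min,
#'   lat_max, lat_span), `predictors` (long data frame of per-population
#'   descriptives, or NULL), `tests` (pairwise Welch comparisons, or NULL).
#' @export
occurrence_summary <- function(occurrences, stack = NULL) {
  pops <- split(occurrences, occurrences$species)
  if (!length(pops)) stop_invrisk("no occurrence records")
  latitude <- do.call(rbind, lapply(names(pops), function(p) {
    la <- pops[[p]]$lat
    data.frame(population = p, n = length(la), lat_min = min(la),
               lat_max = max(la), lat_span = max(la) - min(la),
               stringsAsFactors = FALSE)
  }))
  predictors <- NULL; tests <- NULL
  if (!is.null(stack)) {
    vals <- lapply(pops, function(p) extract_values(p, stack)$X)
    predictors <- do.call(rbind, lapply(names(vals), function(p) {
      X <- vals[[p]]
      do.call(rbind, lapply(colnames(X), function(v) {
        q <- stats::quantile(X[, v], c(0, .25, .5, .75, 1), names = FALSE)
        data.frame(population = p, predictor = v, min = q[1], q25 = q[2],
                   median = q[3], q75 = q[4], max = q[5], iqr = q[4] - q[2],
                   stringsAsFactors = FALSE)
      }))
    }))
    prs <- utils::combn(names(vals), 2, simplify = FALSE)
    tests <- do.call(rbind, lapply(prs, function(pr) {
      do.call(rbind, lapply(colnames(vals[[1]]), function(v) {
        tt <- welch_t_test(vals[[pr[1]]][, v], vals[[pr[2]]][, v])
        data.frame(population_a = pr[1], population_b = pr[2], predictor = v,
                   mean_a = mean(vals[[pr[1]]][, v]),
                   mean_b = mean(vals[[pr[2]]][, v]),
                   t = tt$t, df = tt$df, p = tt$p, stringsAsFactors = FALSE)
      }))
    }))
  }
  list(latitude = latitude, predictors = predictors, tests = tests)
}
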