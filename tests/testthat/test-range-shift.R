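test_that("binarization applies the threshold over valid cells", {
  m <- matrix(runif(25), 5, 5)
  m[2, 2] <- NA
  suit <- raster_grid(m, 0, 5, 1)
  all_in <- binarize(suit, 0)
  expect_equal(sum(all_in$presence), 24)   # everywhere valid
  expect_equal(sum(binarize(suit, 1)$presence), 0)
  hand <- binarize(suit, 0.6)
  expected <- matrix(FALSE, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    expected[i, j] <- !is.na(m[i, j]) && m[i, j] >= 0.6
  }
  expect_identical(hand$presence, expected)
  expect_equal(sum(hand$nodata_mask), 1)
  expect_error(binarize(suit, 1.2), "\\[0, 1\\]")
})

test_that("identical and disjoint ranges give the boundary index values", {
  m <- matrix(runif(36), 6, 6)
  suit <- raster_grid(m, 0, 3, 0.5)
  a <- binarize(suit, 0.5)
  res <- range_shift(a, a)
  expect_equal(res$area_expansion, 0)
  expect_equal(res$area_unfilling, 0)
  expect_equal(res$RR, 1)
  expect_equal(res$IRS, 1)
  b <- binarize(suit, 0.5)
  b$presence <- !a$presence & !a$nodata_mask
  res2 <- range_shift(a, b)
  expect_equal(res2$area_stabilization, 0)
  expect_equal(res2$IRS, 0)
})

test_that("decomposition equals a brute-force per-cell loop", {
  set.seed(31)
  for (rep in 1:5) {
    suit <- raster_grid(matrix(runif(100), 10, 10), 0, 45, 0.5)
    a <- binarize(suit, runif(1))
    b <- binarize(raster_grid(matrix(runif(100), 10, 10), 0, 45, 0.5),
                  runif(1))
    res <- range_shift(a, b)
    area <- cell_area_km2(suit)$values
    exp_bf <- stab_bf <- unf_bf <- 0
    for (i in 1:10) for (j in 1:10) {
      ia <- a$presence[i, j]; ib <- b$presence[i, j]
      if (ia && !ib) exp_bf <- exp_bf + area[i, j]
      if (ia && ib) stab_bf <- stab_bf + area[i, j]
      if (!ia && ib) unf_bf <- unf_bf + area[i, j]
    }
    expect_equal(res$area_expansion, exp_bf)
    expect_equal(res$area_stabilization, stab_bf)
    expect_equal(res$area_unfilling, unf_bf)
  }
})

test_that("swapping the maps swaps expansion and unfilling only", {
  set.seed(17)
  suit1 <- raster_grid(matrix(runif(64), 8, 8), 0, 40, 0.5)
  suit2 <- raster_grid(matrix(runif(64), 8, 8), 0, 40, 0.5)
  suit1$values[3, 4] <- NA; suit1$nodata_mask[3, 4] <- TRUE
  a <- binarize(suit1, 0.4); b <- binarize(suit2, 0.6)
  ab <- range_shift(a, b); ba <- range_shift(b, a)
  expect_equal(ab$area_expansion, ba$area_unfilling)
  expect_equal(ab$area_unfilling, ba$area_expansion)
  expect_equal(ab$area_stabilization, ba$area_stabilization)
  expect_equal(ab$IRS, ba$IRS)
  expect_equal(ab$RR, 1 / ba$RR)
  expect_equal(ab$excluded_cells, ba$excluded_cells)
})

test_that("IRS equals the area-weighted Sorensen coincidence", {
  set.seed(23)
  suit <- raster_grid(matrix(runif(144), 12, 12), -5, 30, 0.25)
  a <- binarize(suit, 0.3)
  b <- binarize(raster_grid(matrix(runif(144), 12, 12), -5, 30, 0.25), 0.5)
  res <- range_shift(a, b)
  area <- cell_area_km2(suit)$values
  sorensen <- 2 * sum(area[a$presence & b$presence]) /
    (sum(area[a$presence]) + sum(area[b$presence]))
  expect_equal(res$IRS, sorensen, tolerance = 1e-12)
  expect_equal(res$IRS_reported_variant, sorensen / 2, tolerance = 1e-12)
})

test_that("misaligned maps are rejected with both geometries", {
  a <- binarize(raster_grid(matrix(1, 4, 4), 0, 4, 1), 0.5)
  b <- binarize(raster_grid(matrix(1, 4, 4), 0, 4, 0.5), 0.5)
  expect_error(range_shift(a, b), "misaligned")
})

test_that("range indices reproduce the published worked examples", {
  # Asia-native vs North-America-introduced: expansion 0, shared 112.16,
  # unfilling 1202.68 (10^4 km^2)
  asia <- range_shift_from_areas(expansion = 0, stabilization = 112.16,
                                 unfilling = 1202.68)
  expect_equal(asia$IR, 112.16)
  expect_equal(asia$NR, 1314.84)
  expect_lt(abs(asia$RR_native_over_introduced - 11.72), 5e-3)
  expect_lt(abs(asia$IRS_reported_variant - 0.079), 5e-4)
  # Europe-native comparison: expansion 0.15, shared 112.00, unfilling 962.52
  europe <- range_shift_from_areas(expansion = 0.15, stabilization = 112,
                                   unfilling = 962.52)
  expect_equal(europe$IR, 112.15)
  expect_equal(europe$NR, 1074.52)
  expect_lt(abs(europe$RR_native_over_introduced - 9.58), 5e-3)
  expect_lt(abs(europe$IRS_reported_variant - 0.094), 5e-4)
  # the native ranges' mutual ratio
  expect_lt(abs(asia$NR / europe$NR - 1.22), 5e-3)
  # the defined-direction identities
  expect_equal(asia$RR, asia$IR / asia$NR)
  expect_equal(asia$IRS, 2 * asia$IRS_reported_variant)
})

test_that("degenerate index inputs are rejected", {
  expect_error(range_ratio(0, 10), "positive")
  expect_error(range_similarity(5, 2, 10), "impossible overlap")
  eq <- range_ratio(7, 7)
  expect_equal(eq$RR, 1)
  expect_equal(eq$RR_native_over_introduced, 1)
  expect_equal(range_similarity(0, 3, 4)$IRS, 0)
  expect_equal(range_similarity(3, 3, 3)$IRS, 1)
})

test_that("occurrence summaries report latitudinal spans and tests", {
  occ <- occurrence_set(data.frame(
    species = c(rep("asia", 3), rep("europe", 2), "single"),
    lon = c(100, 110, 120, 10, 20, 0),
    lat = c(7.10, 30, 64.44, 35.14, 62.00, 45),
    stringsAsFactors = FALSE))
  s <- occurrence_summary(occ)
  lat <- s$latitude
  expect_equal(lat$lat_span[lat$population == "asia"], 57.34)
  expect_equal(lat$lat_span[lat$population == "europe"], 26.86)
  expect_equal(lat$lat_span[lat$population == "single"], 0)
  # with a stack: per-predictor descriptives and pairwise Welch tests
  st <- random_stack(30, 30, 2, seed = 2)
  tmpl <- st$grids[[1]]
  set.seed(4)
  occ2 <- occurrence_set(data.frame(
    species = rep(c("a", "b"), each = 20),
    lon = runif(40, 0, 30 * tmpl$cell_size),
    lat = runif(40, 10 - 30 * tmpl$cell_size, 10),
    stringsAsFactors = FALSE))
  s2 <- occurrence_summary(occ2, st)
  expect_equal(nrow(s2$predictors), 4)  # 2 populations x 2 predictors
  expect_true(all(c("t", "df", "p") %in% names(s2$tests)))
  expect_true(all(s2$predictors$iqr >= 0))
})
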