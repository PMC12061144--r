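test_that("predictor generation is deterministic from the seed", {
  rs <- region_spec("r", 0, 5, 40, 45, cell_size = 0.25, noise_smoothing = 0,
                    seed = 99)
  s1 <- generate_predictor_stack(rs)
  s2 <- generate_predictor_stack(rs)
  expect_identical(s1$grids$bio1$values, s2$grids$bio1$values)
  expect_identical(s1$grids$cropland$values, s2$grids$cropland$values)
  expect_identical(s1$grids$bio1$nodata_mask, s2$grids$bio1$nodata_mask)
})

test_that("noise-free predictors are strictly monotone in latitude", {
  rs <- region_spec("r", 0, 5, 40, 45, cell_size = 0.25,
                    noise_amplitude = 0, nodata_fraction = 0, seed = 1)
  st <- generate_predictor_stack(rs)
  for (nm in c("bio1", "bio4", "bio12")) {
    v <- st$grids[[nm]]$values
    for (j in c(1, ncol(v))) {
      expect_true(all(diff(v[, j]) > 0) || all(diff(v[, j]) < 0))
    }
  }
})

test_that("moving-average smoothing raises lag-1 spatial autocorrelation", {
  lag1 <- function(v) stats::cor(as.vector(v[-1, ]), as.vector(v[-nrow(v), ]))
  base <- list(lon_min = 0, lon_max = 25, lat_min = 20, lat_max = 45,
               cell_size = 0.5, noise_amplitude = 50, nodata_fraction = 0)
  smooth <- generate_predictor_stack(do.call(region_spec, c(
    list("s"), base, list(noise_smoothing = 2, seed = 5))))
  rough <- generate_predictor_stack(do.call(region_spec, c(
    list("r"), base, list(noise_smoothing = 0, seed = 5))))
  expect_gt(lag1(smooth$grids$bio1$values), lag1(rough$grids$bio1$values))
  expect_gt(lag1(smooth$grids$bio1$values), 0.5)
})

test_that("land-use fractions are rescaled into [0, 1]", {
  st <- generate_predictor_stack(region_spec("r", 0, 5, 40, 45,
                                             cell_size = 0.25, seed = 3))
  v <- st$grids$cropland$values
  expect_gte(min(v, na.rm = TRUE), 0)
  expect_lte(max(v, na.rm = TRUE), 1)
})

test_that("a degenerate region is rejected", {
  expect_error(region_spec("tiny", 0, 1, 0, 1, cell_size = 0.5),
               "at least 10 x 10")
  expect_error(region_spec("flip", 5, 0, 0, 10), "lon_min < lon_max")
})

test_that("true suitability follows the standardized logistic model", {
  st <- random_stack(6, 6, 2, seed = 11)
  # zero model: 0.5 everywhere
  sp0 <- virtual_species("s", c(v1 = 0, v2 = 0), intercept = 0)
  expect_true(all(true_suitability(st, sp0)$values == 0.5))
  # saturated intercept
  sp1 <- virtual_species("s", c(v1 = 0), intercept = 50)
  expect_equal(max(abs(true_suitability(st, sp1)$values - 1)), 0,
               tolerance = 1e-9)
  # closed-form logistic of the independently standardized predictor
  sp2 <- virtual_species("s", c(v1 = 1), intercept = 0)
  suit <- true_suitability(st, sp2)
  v <- st$grids$v1$values
  z <- (v - mean(v)) / sd(as.vector(v))
  expect_equal(suit$values, 1 / (1 + exp(-z)), tolerance = 1e-12)
  # a cell standardizing to z = 1 scores 1/(1 + e^-1)
  i <- which.min(abs(z - 1))
  expect_equal(suit$values[i], plogis(z[i]))
  expect_equal(plogis(1), 0.7311, tolerance = 1e-4)
  # unknown coefficient names are reported
  spx <- virtual_species("s", c(nope = 1))
  expect_error(true_suitability(st, spx), "nope")
})

test_that("suitability propagates nodata", {
  m <- matrix(rnorm(25), 5, 5)
  m[3, 3] <- NA
  st <- make_stack(v1 = m)
  suit <- true_suitability(st, virtual_species("s", c(v1 = 2)))
  expect_true(is.na(suit$values[3, 3]))
  expect_true(suit$nodata_mask[3, 3])
})

test_that("occurrence sampling concentrates on habitable cells", {
  # single habitable cell captures every point
  m <- matrix(0, 4, 4)
  m[2, 3] <- 1
  suit <- raster_grid(m, 0, 2, 0.5)
  sp <- virtual_species("s", c(v1 = 1), n_occurrences = 5)
  occ <- sample_occurrences(suit, sp, seed = 1)
  expect_equal(nrow(occ), 5)
  rc <- invrisk:::point_cell(suit, occ$lon, occ$lat)
  expect_true(all(rc[, 1] == 2 & rc[, 2] == 3))
  # all-zero suitability is an error
  expect_error(
    sample_occurrences(raster_grid(matrix(0, 4, 4), 0, 2, 0.5), sp),
    "no habitable cells")
})

test_that("uniform suitability yields uniform multinomial cell counts", {
  suit <- raster_grid(matrix(1, 10, 10), 0, 10, 1)
  sp <- virtual_species("s", c(v1 = 1), n_occurrences = 10000)
  occ <- sample_occurrences(suit, sp, seed = 7)
  rc <- invrisk:::point_cell(suit, occ$lon, occ$lat)
  counts <- table(factor((rc[, 2] - 1) * 10 + rc[, 1], levels = 1:100))
  expect_gt(stats::chisq.test(as.vector(counts))$p.value, 0.001)
})

test_that("sampling odds follow relative suitability", {
  suit <- raster_grid(matrix(c(0.8, 0.2), 1, 2), 0, 1, 1)
  sp <- virtual_species("s", c(v1 = 1), n_occurrences = 10000)
  occ <- sample_occurrences(suit, sp, seed = 3)
  p_hat <- mean(occ$lon < 1)            # first (0.8) cell
  se <- sqrt(0.8 * 0.2 / 10000)
  expect_lt(abs(p_hat - 0.8), 3 * se)
})

test_that("longitudinal sampling bias shifts points eastward", {
  suit <- raster_grid(matrix(1, 10, 10), 0, 10, 1)
  unbiased <- sample_occurrences(
    suit, virtual_species("s", c(v1 = 1), n_occurrences = 2000), seed = 5)
  biased <- sample_occurrences(
    suit, virtual_species("s", c(v1 = 1), n_occurrences = 2000,
                          sampling_bias_strength = 2), seed = 5)
  expect_gt(mean(biased$lon), mean(unbiased$lon) + 0.5)
})

test_that("true ranges match suitability thresholding exactly", {
  scen <- synthetic_scenario(seed = 2, n_occurrences = 50)
  for (sp in names(scen$species)) {
    thr <- scen$species[[sp]]$occupancy_threshold
    for (rg in names(scen$stacks)) {
      suit <- scen$true_suitability[[sp]][[rg]]
      expect_identical(sum(scen$true_range[[sp]][[rg]]$presence),
                       sum(suit$values >= thr, na.rm = TRUE))
    }
  }
})

test_that("true-range indices for a hand-built overlap are exact", {
  # 2x2 equal-area-ish grid: species A occupies 3 cells, B occupies 2,
  # sharing 2 -> RS = area(shared), IR = area(B), NR = area(A)
  sa <- raster_grid(matrix(c(1, 1, 1, 0), 2, 2), 0, 0.02, 0.01)
  sb <- raster_grid(matrix(c(1, 1, 0, 0), 2, 2), 0, 0.02, 0.01)
  ra <- binarize(sa, 0.5); rb <- binarize(sb, 0.5)
  res <- range_shift(rb, ra)    # B introduced, A native
  area <- cell_area_km2(sa)$values
  expect_equal(res$IR, sum(area[c(1, 2)]), tolerance = 1e-12)
  expect_equal(res$NR, sum(area[c(1, 2, 3)]), tolerance = 1e-12)
  expect_equal(res$RR, sum(area[c(1, 2)]) / sum(area[c(1, 2, 3)]),
               tolerance = 1e-12)
  expect_equal(res$IRS, 2 * sum(area[c(1, 2)]) /
                 (sum(area[c(1, 2)]) + sum(area[c(1, 2, 3)])),
               tolerance = 1e-12)
})

test_that("scenarios serialize deterministically", {
  scen <- synthetic_scenario(seed = 4, n_occurrences = 20)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_scenario(scen, d1)
  write_scenario(synthetic_scenario(seed = 4, n_occurrences = 20), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # round trip of a truth layer
  back <- read_raster(file.path(d1, "truth_native_source_continent.asc"))
  expect_identical(back$values, scen$true_suitability$native$source_continent$values)
})
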