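# Shared fixtures, all built in code.

# A small aligned predictor stack from plain matrices.
make_stack <- function(..., origin_lon = 0, origin_lat = 10, cell_size = 0.5,
                       category = NULL) {
  mats <- list(...)
  if (is.null(names(mats))) names(mats) <- paste0("p", seq_along(mats))
  grids <- lapply(mats, raster_grid, origin_lon = origin_lon,
                  origin_lat = origin_lat, cell_size = cell_size)
  if (is.null(category)) {
    category <- stats::setNames(rep("climate", length(mats)), names(mats))
  }
  predictor_stack(grids, category)
}

# Random stack of `k` layers on an nr x nc grid.
random_stack <- function(nr = 20, nc = 20, k = 3, seed = 1,
                         nodata_frac = 0) {
  set.seed(seed)
  mats <- lapply(seq_len(k), function(i) {
    m <- matrix(rnorm(nr * nc), nr, nc)
    if (nodata_frac > 0) m[sample(nr * nc, floor(nodata_frac * nr * nc))] <- NA
    m
  })
  names(mats) <- paste0("v", seq_len(k))
  do.call(make_stack, mats)
}

occ_df <- function(lon, lat, species = "sp") {
  occurrence_set(data.frame(species = species, lon = lon, lat = lat,
                            stringsAsFactors = FALSE))
}

jaccard_ranges <- function(a, b) {
  ex <- a$nodata_mask | b$nodata_mask
  sum(a$presence & b$presence & !ex) / sum((a$presence | b$presence) & !ex)
}

# A dataset where presence is (noisily or exactly) determined by x1 > 0.
separable_data <- function(n = 500, seed = 1, noise = 0) {
  set.seed(seed)
  x1 <- runif(n, -1, 1)
  x2 <- rnorm(n)
  y <- as.integer(x1 + rnorm(n, sd = noise) > 0)
  list(X = cbind(x1 = x1, x2 = x2), y = y)
}

# Construct columns with an exact sample correlation matrix (whiten the
# empirical sample, then color with the Cholesky factor of the target).
exact_correlated <- function(n, target_r, seed = 1) {
  set.seed(seed)
  k <- nrow(target_r)
  Z <- matrix(rnorm(n * k), n, k)
  Z <- scale(Z, scale = FALSE)
  W <- Z %*% solve(chol(stats::cov(Z)))
  X <- W %*% chol(target_r)
  colnames(X) <- rownames(target_r)
  X
}
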