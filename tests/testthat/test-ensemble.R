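test_that("pseudo-absence counts follow the 1000-or-n rule", {
  st <- random_stack(80, 80, 1, seed = 2)
  tmpl <- st$grids[[1]]
  mk_occ <- function(n, seed) {
    set.seed(seed)
    occ_df(runif(n, tmpl$origin_lon, tmpl$origin_lon + 80 * tmpl$cell_size),
           runif(n, tmpl$origin_lat - 80 * tmpl$cell_size, tmpl$origin_lat))
  }
  # fewer than 1000 records: one pseudo-absence per record
  expect_equal(nrow(generate_pseudo_absences(st, mk_occ(637, 1), seed = 1)),
               637)
  # at least 1000 records: capped at 1000
  expect_equal(nrow(generate_pseudo_absences(st, mk_occ(3039, 2), seed = 1)),
               1000)
})

test_that("pseudo-absences avoid occupied cells and exhaust exactly", {
  m <- matrix(1, 4, 4)
  st <- make_stack(v1 = m, cell_size = 1, origin_lat = 4, origin_lon = 0)
  # occupy 6 cells, ask for the remaining 10
  occ <- occ_df(c(0.5, 1.5, 2.5, 3.5, 0.5, 1.5), c(3.5, 3.5, 3.5, 3.5, 2.5, 2.5))
  pa <- generate_pseudo_absences(st, occ, seed = 9)
  expect_equal(nrow(pa), 6)  # n rule: 6 occurrences -> 6 PAs
  rc_occ <- invrisk:::point_cell(st$grids[[1]], occ$lon, occ$lat)
  rc_pa <- invrisk:::point_cell(st$grids[[1]], pa$lon, pa$lat)
  expect_equal(length(intersect(paste(rc_pa[, 1], rc_pa[, 2]),
                                paste(rc_occ[, 1], rc_occ[, 2]))), 0)
  expect_equal(anyDuplicated(paste(rc_pa[, 1], rc_pa[, 2])), 0)
  # asking for more than the available cells fails with counts
  occ11 <- occ_df(runif(11, 0, 4), runif(11, 0, 4))
  rc11 <- invrisk:::point_cell(st$grids[[1]], occ11$lon, occ11$lat)
  n_free <- 16 - length(unique(paste(rc11[, 1], rc11[, 2])))
  if (n_free < 11) {
    expect_error(generate_pseudo_absences(st, occ11, seed = 1), "valid")
  }
})

test_that("stratified splits carry 70/30 of each class and partition", {
  y <- rep(c(0, 1), each = 100)
  sp <- cv_splits(y, train_frac = 0.7, repeats = 5, seed = 3)
  expect_length(sp, 5)
  for (s in sp) {
    expect_equal(sum(y[s$train] == 1), 70)
    expect_equal(sum(y[s$train] == 0), 70)
    expect_equal(sum(y[s$test] == 1), 30)
    expect_equal(sort(c(s$train, s$test)), seq_along(y))
  }
  expect_identical(cv_splits(y, repeats = 1, seed = 5),
                   cv_splits(y, repeats = 1, seed = 5))
  expect_error(cv_splits(c(0, 1, rep(0, 20)), train_frac = 0.7),
               "absent")
})

test_that("every registered algorithm learns a separable toy problem", {
  d <- separable_data(n = 500, seed = 6)
  train <- 1:300; test <- 301:500
  for (alg in sdm_algorithms()) {
    fit <- suppressWarnings(fit_member(alg, d$X[train, ], d$y[train],
                                       seed = 4))
    p <- predict_scores(fit, d$X[test, ])
    expect_true(all(p >= 0 & p <= 1), info = alg)
    expect_gte(auc_score(p, d$y[test]), 0.95)
  }
})

test_that("members are deterministic given spec and seed", {
  d <- separable_data(n = 200, seed = 2)
  for (alg in c("rf", "gbm", "ann")) {
    f1 <- fit_member(alg, d$X, d$y, seed = 11)
    f2 <- fit_member(alg, d$X, d$y, seed = 11)
    expect_identical(predict_scores(f1, d$X), predict_scores(f2, d$X),
                     info = alg)
  }
})

test_that("a constant predictor yields chance-level constant predictions", {
  set.seed(8)
  X <- cbind(k = rep(1, 100))
  y <- rep(c(0, 1), 50)
  fit <- fit_member("maxent", X, y, seed = 1)
  p <- predict_scores(fit, X)
  expect_equal(diff(range(p)), 0)
  expect_equal(auc_score(p, y), 0.5)
})

test_that("the ensemble averages surviving members and gates candidates", {
  d <- separable_data(n = 300, seed = 9)
  ens <- ensemble_sdm(d$X, d$y, algorithms = c("rf", "maxent"), repeats = 2,
                      seed = 5)
  # every surviving member passed both gates
  for (m in ens$members) {
    expect_gte(m$eval$tss, 0.7)
    expect_gte(m$eval$auc, 0.8)
  }
  # the TSS identity holds for every candidate evaluation
  ok <- !is.na(ens$evals$tss)
  expect_equal(ens$evals$tss[ok],
               ens$evals$sensitivity[ok] + ens$evals$specificity[ok] - 1,
               tolerance = 1e-12)
  # ensemble prediction is the unweighted mean of member scores
  Xnew <- d$X[1:20, ]
  P <- sapply(ens$members, function(m) predict_scores(m$fit, Xnew))
  expect_equal(predict(ens, Xnew), rowMeans(P), tolerance = 1e-12)
  # and pure noise leaves no survivors, reporting per-member metrics
  set.seed(10)
  Xn <- cbind(a = rnorm(80), b = rnorm(80))
  yn <- rbinom(80, 1, 0.5)
  expect_error(
    ensemble_sdm(Xn, yn, algorithms = c("rf", "maxent"), repeats = 2,
                 seed = 2),
    "no ensemble member passed")
})

test_that("fewer than two algorithm families is rejected", {
  d <- separable_data(100)
  expect_error(ensemble_sdm(d$X, d$y, algorithms = "rf"), "two distinct")
})

test_that("ensemble held-out skill is near the best member's", {
  set.seed(13)
  n <- 500
  X <- cbind(x1 = runif(n, -1, 1), x2 = runif(n, -1, 1))
  y <- rbinom(n, 1, plogis(4 * X[, 1] - 2 * X[, 2]))
  train <- 1:350; test <- 351:500
  ens <- ensemble_sdm(X[train, ], y[train], algorithms = c("rf", "maxent", "gam"),
                      repeats = 3, gates = c(tss_min = 0, auc_min = 0.5),
                      seed = 21)
  auc_members <- sapply(ens$members, function(m) {
    auc_score(predict_scores(m$fit, X[test, ]), y[test])
  })
  auc_ens <- auc_score(predict(ens, X[test, ]), y[test])
  expect_gte(auc_ens, max(auc_members) - 0.05)
})

test_that("raster prediction equals the per-cell loop and point predicts", {
  d <- separable_data(n = 300, seed = 3)
  ens <- ensemble_sdm(d$X, d$y, algorithms = c("rf", "maxent"), repeats = 2,
                      seed = 7)
  st <- random_stack(20, 20, 2, seed = 5, nodata_frac = 0.03)
  names(st$grids) <- c("x1", "x2")
  names(st$category) <- c("x1", "x2")
  suit <- predict_raster(ens, st)
  for (idx in list(c(1, 1), c(7, 13), c(20, 20), c(3, 9))) {
    v <- c(x1 = st$grids$x1$values[idx[1], idx[2]],
           x2 = st$grids$x2$values[idx[1], idx[2]])
    if (any(is.na(v))) {
      expect_true(is.na(suit$values[idx[1], idx[2]]))
    } else {
      expect_equal(suit$values[idx[1], idx[2]],
                   predict(ens, matrix(v, 1, dimnames = list(NULL, names(v)))),
                   tolerance = 1e-12)
    }
  }
  # nodata propagates, constants stay constant
  expect_identical(is.na(suit$values),
                   st$grids$x1$nodata_mask | st$grids$x2$nodata_mask)
  stc <- make_stack(x1 = matrix(0.3, 5, 5), x2 = matrix(-0.2, 5, 5))
  sc <- predict_raster(ens, stc)
  expect_equal(diff(range(sc$values)), 0)
  # a missing layer is reported by name
  expect_error(predict_raster(ens, make_stack(x1 = matrix(0, 5, 5))), "x2")
})
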