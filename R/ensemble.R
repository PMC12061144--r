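#' Prediction scores from a fitted object
#'
#' Common predict contract used across the package: scores in `[0, 1]`, one
#' per row of the design matrix. Methods exist for single fitted members,
#' ensembles, and plain functions (useful in tests).
#'
#' @param object fitted object.
#' @param X design matrix.
#' @return numeric vector of scores in `[0, 1]`.
#' @export
predict_scores <- function(object, X) UseMethod("predict_scores")

#' @export
predict_scores.function <- function(object, X) object(X)

#' Registered SDM algorithms
#'
#' The seven ensemble slots: artificial neural network (`ann`),
#' classification tree (`cta`), discriminant analysis on a quadratic basis
#' (`fda` slot), maximum-entropy-style regularized logistic regression
#' (`maxent`), random forest (`rf`), generalized additive model (`gam`),
#' and gradient boosting (`gbm`). Any subset of two or more families forms a
#' valid ensemble.
#'
#' @return character vector of algorithm ids.
#' @export
sdm_algorithms <- function() {
  c("ann", "cta", "fda", "maxent", "rf", "gam", "gbm")
}

# Quadratic feature basis used by the discriminant and maxent members.
quad_basis <- function(X) {
  Xq <- cbind(X, X^2)
  colnames(Xq) <- c(colnames(X), paste0(colnames(X), "_sq"))
  Xq
}

#' Fit a single SDM member
#'
#' Fits one algorithm on presence/pseudo-absence data. Predictors are
#' standardized internally (centering and scaling are stored with the
#' member). Fitting is reproducible from the seed; all learners run
#' single-threaded.
#'
#' @param algorithm one of [sdm_algorithms()].
#' @param X design matrix (rows = presences and pseudo-absences).
#' @param y 0/1 labels (1 = presence).
#' @param seed integer seed.
#' @param params optional list of hyperparameters (`size`, `decay` for ann;
#'   `cp` for cta; `lambda` for maxent; `num_trees` for rf; `k` for gam;
#'   `nrounds`, `max_depth`, `eta` for gbm).
#' @return an object of class `sdm_member`.
#' @export
fit_member <- function(algorithm, X, y, seed = 1L, params = list()) {
  algorithm <- match.arg(algorithm, sdm_algorithms())
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  colnames(X) <- make.names(colnames(X))
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2) {
    stop_invrisk("training data must contain both classes")
  }
  center <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  degenerate <- all(scl == 0)
  scl[scl == 0] <- 1
  Xs <- scale(X, center, scl)
  if (degenerate) {
    # every predictor is constant: no learner can discriminate, so the
    # member degenerates to the observed presence rate
    fit <- structure(list(p = mean(y)), class = "constant_fit")
    return(structure(list(algorithm = algorithm, fit = fit, center = center,
                          scale = scl, vars = colnames(X),
                          seed = as.integer(seed), params = params),
                     class = "sdm_member"))
  }
  fit <- with_seed(seed, switch(
    algorithm,
    ann = nnet::nnet(x = Xs, y = y, size = params$size %||% 5L,
                     decay = params$decay %||% 0.01, maxit = 200,
                     entropy = TRUE, trace = FALSE),
    cta = {
      df <- data.frame(.y = factor(y, levels = c(0, 1)), Xs)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(cp = params$cp %||% 0.01))
    },
    fda = MASS::lda(quad_basis(Xs), grouping = factor(y, levels = c(0, 1))),
    maxent = glmnet::glmnet(quad_basis(Xs), y, family = "binomial",
                            alpha = 1, lambda = params$lambda %||% 1e-3),
    rf = ranger::ranger(x = data.frame(Xs), y = factor(y, levels = c(0, 1)),
                        probability = TRUE,
                        num.trees = params$num_trees %||% 300L,
                        num.threads = 1L, seed = seed),
    gam = {
      df <- data.frame(.y = y, Xs)
      terms <- vapply(colnames(Xs), function(v) {
        nu <- length(unique(Xs[, v]))
        if (nu < 4) v else sprintf("s(%s, k = %d)", v,
                                   min(params$k %||% 5L, nu - 1L))
      }, character(1))
      mgcv::gam(stats::as.formula(paste(".y ~", paste(terms, collapse = "+"))),
                family = stats::binomial(), data = df, method = "REML")
    },
    gbm = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth %||% 3L,
                    eta = params$eta %||% 0.1, nthread = 1L,
                    seed = seed),
      data = xgboost::xgb.DMatrix(Xs, label = y, nthread = 1L),
      nrounds = params$nrounds %||% 80L)))
  structure(list(algorithm = algorithm, fit = fit, center = center,
                 scale = scl, vars = colnames(X), seed = as.integer(seed),
                 params = params),
            class = "sdm_member")
}

#' @export
predict_scores.sdm_member <- function(object, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- object$vars
  colnames(X) <- make.names(colnames(X))
  miss <- setdiff(object$vars, colnames(X))
  if (length(miss)) {
    stop_invrisk("missing predictor(s): ", paste(miss, collapse = ", "))
  }
  Xs <- scale(X[, object$vars, drop = FALSE], object$center, object$scale)
  if (inherits(object$fit, "constant_fit")) {
    return(rep(object$fit$p, nrow(Xs)))
  }
  p <- switch(
    object$algorithm,
    ann = as.vector(stats::predict(object$fit, Xs)),
    cta = stats::predict(object$fit, data.frame(Xs), type = "prob")[, "1"],
    fda = stats::predict(object$fit, quad_basis(Xs))$posterior[, "1"],
    maxent = as.vector(stats::predict(object$fit, quad_basis(Xs),
                                      type = "response")),
    rf = stats::predict(object$fit, data.frame(Xs),
                        num.threads = 1L)$predictions[, "1"],
    gam = as.vector(stats::predict(object$fit, data.frame(Xs),
                                   type = "response")),
    gbm = stats::predict(object$fit, Xs))
  pmin(pmax(as.numeric(p), 0), 1)
}

#' @export
print.sdm_member <- function(x, ...) {
  cat(sprintf("sdm_member: %s on %d predictors (seed %d)\n", x$algorithm,
              length(x$vars), x$seed))
  invisible(x)
}

#' Generate pseudo-absences
#'
#' Draws background cells to stand in for absences: 1000 pseudo-absences,
#' or as many as there are occurrence records when fewer than 1000. Cells
#' are sampled uniformly without replacement from the valid (non-nodata in
#' every layer) cells of the stack, excluding cells that contain an
#' occurrence. Points are placed at cell centers.
#'
#' @param stack a [predictor_stack()].
#' @param occurrences occurrence data frame for one population.
#' @param seed integer seed.
#' @param exclude_occupied drop occupied cells from the candidate set
#'   (default TRUE).
#' @return an `occurrence_set` of pseudo-absence points
#'   (`species = "pseudo-absence"`).
#' @export
generate_pseudo_absences <- function(stack, occurrences, seed = 1L,
                                     exclude_occupied = TRUE) {
  n_occ <- nrow(occurrences)
  n_pa <- if (n_occ >= 1000) 1000L else n_occ
  tmpl <- stack_template(stack)
  valid <- stack_valid_mask(stack)
  candidates <- which(as.vector(valid))
  if (exclude_occupied && n_occ > 0) {
    rc <- point_cell(tmpl, occurrences$lon, occurrences$lat)
    rc <- rc[!is.na(rc[, 1]), , drop = FALSE]
    occupied <- unique((rc[, 2] - 1L) * nrow(tmpl$values) + rc[, 1])
    candidates <- setdiff(candidates, occupied)
  }
  if (length(candidates) < n_pa) {
    stop_invrisk("need ", n_pa, " pseudo-absence cells but only ",
                 length(candidates), " valid unoccupied cells are available")
  }
  idx <- with_seed(seed, candidates[sample.int(length(candidates), n_pa)])
  co <- grid_coords(tmpl)
  occurrence_set(data.frame(species = "pseudo-absence",
                            lon = co[idx, "lon"], lat = co[idx, "lat"],
                            source = "pseudo-absence",
                            stringsAsFactors = FALSE))
}

#' Repeated stratified 70/30 splits
#'
#' Generates `repeats` independent random train/test partitions, stratified
#' by class so every split carries both presences and pseudo-absences in
#' both folds.
#'
#' @param labels 0/1 class labels.
#' @param train_frac fraction of each class assigned to training
#'   (default 0.7).
#' @param repeats number of random splits (default 5).
#' @param seed integer seed.
#' @return list of `repeats` lists with integer `train` and `test` indices.
#' @export
cv_splits <- function(labels, train_frac = 0.7, repeats = 5L, seed = 1L) {
  labels <- as.integer(as.logical(labels))
  n <- length(labels)
  if (n < 10) stop_invrisk("need at least 10 records to split")
  if (train_frac <= 0 || train_frac >= 1) {
    stop_invrisk("train_frac must lie strictly between 0 and 1")
  }
  with_seed(seed, lapply(seq_len(repeats), function(r) {
    train <- integer()
    for (cl in c(0L, 1L)) {
      idx <- which(labels == cl)
      n_tr <- round(train_frac * length(idx))
      if (n_tr < 1 || n_tr >= length(idx)) {
        stop_invrisk("class ", cl, " would be absent from a fold")
      }
      train <- c(train, sample(idx, n_tr))
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_len(n), train))
  }))
}

#' Fit a gated ensemble species distribution model
#'
#' The central fitting function. For each of `repeats` random stratified
#' 70/30 splits and each requested algorithm, a candidate member is fitted
#' on the training fold and evaluated on its test fold (AUC, and TSS at the
#' fold's MSS threshold). Candidates failing the quality gates
#' (TSS >= 0.7, AUC >= 0.8 by default) are excluded; the ensemble predicts
#' the unweighted mean (optionally TSS-weighted mean) of the surviving
#' members' scores. The ensemble MSS threshold is calibrated on the pooled
#' presence/pseudo-absence set from the ensemble scores.
#'
#' @param X design matrix of predictor values at presences and
#'   pseudo-absences.
#' @param y 0/1 labels (1 = presence).
#' @param algorithms character vector of at least two distinct
#'   [sdm_algorithms()] ids.
#' @param train_frac,repeats validation design (default five random 70/30
#'   splits).
#' @param gates named vector `c(tss_min = , auc_min = )`.
#' @param combination `"mean"` or `"tss_weighted"`.
#' @param seed master seed; member seeds derive from it.
#' @param params optional named list of per-algorithm hyperparameter lists.
#' @return an object of class `ensemble_sdm` with components `members`
#'   (surviving fitted members with their evaluations), `evals` (all
#'   candidate evaluations), `gates`, `combination`,
#'   `ensemble_mss_threshold`, `ensemble_auc`, `ensemble_tss`, `vars`.
#' @export
ensemble_sdm <- function(X, y, algorithms = c("rf", "maxent", "gam"),
                         train_frac = 0.7, repeats = 5L,
                         gates = c(tss_min = 0.7, auc_min = 0.8),
                         combination = c("mean", "tss_weighted"),
                         seed = 1L, params = list()) {
  combination <- match.arg(combination)
  algorithms <- match.arg(algorithms, sdm_algorithms(), several.ok = TRUE)
  if (length(unique(algorithms)) < 2) {
    stop_invrisk("an ensemble needs at least two distinct algorithm families")
  }
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.integer(as.logical(y))
  splits <- cv_splits(y, train_frac = train_frac, repeats = repeats,
                      seed = spawn_seed(seed, 1))
  members <- list()
  evals <- data.frame()
  k <- 0L
  for (s in seq_along(splits)) {
    tr <- splits[[s]]$train; te <- splits[[s]]$test
    for (alg in algorithms) {
      k <- k + 1L
      member_seed <- spawn_seed(seed, 100 + k)
      fit <- tryCatch(
        fit_member(alg, X[tr, , drop = FALSE], y[tr], seed = member_seed,
                   params = params[[alg]] %||% list()),
        error = function(e) e)
      if (inherits(fit, "error")) {
        evals <- rbind(evals, data.frame(
          split = s, algorithm = alg, auc = NA_real_, tss = NA_real_,
          mss_threshold = NA_real_, sensitivity = NA_real_,
          specificity = NA_real_, passed = FALSE,
          note = paste("fit failed:", conditionMessage(fit)),
          stringsAsFactors = FALSE))
        next
      }
      p <- predict_scores(fit, X[te, , drop = FALSE])
      auc <- auc_score(p, y[te])
      mss <- mss_threshold(p, y[te])
      passed <- mss$tss >= gates[["tss_min"]] && auc >= gates[["auc_min"]]
      evals <- rbind(evals, data.frame(
        split = s, algorithm = alg, auc = auc, tss = mss$tss,
        mss_threshold = mss$threshold, sensitivity = mss$sensitivity,
        specificity = mss$specificity, passed = passed, note = "",
        stringsAsFactors = FALSE))
      if (passed) {
        members[[length(members) + 1L]] <- list(
          spec = list(algorithm_id = alg,
                      hyperparameters = params[[alg]] %||% list()),
          fit = fit,
          eval = evals[nrow(evals), ])
      }
    }
  }
  if (!length(members)) {
    stop_invrisk("no ensemble member passed the quality gates (TSS >= ",
                 gates[["tss_min"]], ", AUC >= ", gates[["auc_min"]],
                 ").\nPer-candidate metrics:\n",
                 paste(utils::capture.output(print(evals)), collapse = "\n"))
  }
  obj <- structure(
    list(members = members, evals = evals, gates = gates,
         combination = combination, vars = colnames(X), seed = as.integer(seed),
         n_presence = sum(y == 1), n_absence = sum(y == 0)),
    class = "ensemble_sdm")
  pooled <- predict_scores(obj, X)
  mss <- mss_threshold(pooled, y)
  obj$ensemble_mss_threshold <- mss$threshold
  obj$ensemble_tss <- mss$tss
  obj$ensemble_sensitivity <- mss$sensitivity
  obj$ensemble_specificity <- mss$specificity
  obj$ensemble_auc <- auc_score(pooled, y)
  obj
}

#' @export
predict_scores.ensemble_sdm <- function(object, X) {
  P <- vapply(object$members, function(m) predict_scores(m$fit, X),
              numeric(nrow(as.matrix(X))))
  P <- matrix(P, nrow = nrow(as.matrix(X)))
  w <- if (object$combination == "tss_weighted") {
    vapply(object$members, function(m) m$eval$tss, numeric(1))
  } else {
    rep(1, length(object$members))
  }
  as.vector(P %*% (w / sum(w)))
}

#' @rdname ensemble_sdm
#' @param object,x an `ensemble_sdm`.
#' @param newdata design matrix of new predictor values.
#' @param ... ignored.
#' @export
predict.ensemble_sdm <- function(object, newdata, ...) {
  predict_scores(object, newdata)
}

#' @export
print.ensemble_sdm <- function(x, ...) {
  cat(sprintf("ensemble_sdm: %d member(s) of %d candidate(s) passed gates (TSS >= %.2f, AUC >= %.2f)\n",
              length(x$members), nrow(x$evals), x$gates[["tss_min"]],
              x$gates[["auc_min"]]))
  cat(sprintf("  algorithms: %s\n",
              paste(unique(vapply(x$members, function(m) m$spec$algorithm_id,
                                  character(1))), collapse = ", ")))
  cat(sprintf("  combination: %s; pooled AUC %.3f, TSS %.3f, MSS threshold %.3f\n",
              x$combination, x$ensemble_auc, x$ensemble_tss,
              x$ensemble_mss_threshold))
  invisible(x)
}

#' @export
summary.ensemble_sdm <- function(object, ...) {
  structure(list(evals = object$evals,
                 n_members = length(object$members),
                 gates = object$gates,
                 ensemble = c(auc = object$ensemble_auc,
                              tss = object$ensemble_tss,
                              mss_threshold = object$ensemble_mss_threshold,
                              sensitivity = object$ensemble_sensitivity,
                              specificity = object$ensemble_specificity),
                 n_presence = object$n_presence,
                 n_absence = object$n_absence),
            class = "summary.ensemble_sdm")
}

#' @export
print.summary.ensemble_sdm <- function(x, ...) {
  cat("Candidate evaluations (per split x algorithm):\n")
  print(x$evals, row.names = FALSE)
  cat(sprintf("\n%d member(s) passed gates (TSS >= %.2f, AUC >= %.2f)\n",
              x$n_members, x$gates[["tss_min"]], x$gates[["auc_min"]]))
  cat(sprintf("Ensemble (pooled %d presences, %d pseudo-absences): AUC %.3f, TSS %.3f, MSS %.3f\n",
              x$n_presence, x$n_absence, x$ensemble[["auc"]],
              x$ensemble[["tss"]], x$ensemble[["mss_threshold"]]))
  invisible(x)
}

#' @export
plot.ensemble_sdm <- function(x, ...) {
  ev <- x$evals[!is.na(x$evals$auc), ]
  graphics::plot(ev$auc, ev$tss, pch = ifelse(ev$passed, 19, 1),
                 col = as.integer(factor(ev$algorithm,
                                         levels = sdm_algorithms())),
                 xlab = "test AUC", ylab = "test TSS", xlim = c(0.4, 1),
                 ylim = c(-0.1, 1),
                 main = "Candidate members vs quality gates", ...)
  graphics::abline(v = x$gates[["auc_min"]], h = x$gates[["tss_min"]],
                   lty = 2, col = "grey40")
  graphics::legend("bottomright", legend = unique(ev$algorithm),
                   col = as.integer(factor(unique(ev$algorithm),
                                           levels = sdm_algorithms())),
                   pch = 19, cex = 0.8, bty = "n")
  invisible(x)
}

#' Project an ensemble onto a predictor stack
#'
#' Evaluates the ensemble in every valid cell of the stack, producing a
#' suitability surface. Cells that are nodata in any predictor the model
#' uses are nodata in the output.
#'
#' @param ensemble an [ensemble_sdm()].
#' @param stack a [predictor_stack()] containing every retained predictor.
#' @return a [raster_grid()] of ensemble suitability scores in `[0, 1]`.
#' @export
predict_raster <- function(ensemble, stack) {
  miss <- setdiff(ensemble$vars, names(stack$grids))
  if (length(miss)) {
    stop_invrisk("stack is missing predictor(s): ",
                 paste(miss, collapse = ", "))
  }
  X <- stack_matrix(stack)[, ensemble$vars, drop = FALSE]
  valid <- !apply(is.na(X), 1, any)
  tmpl <- stack_template(stack)
  out <- rep(NA_real_, nrow(X))
  if (any(valid)) {
    out[valid] <- predict_scores(ensemble, X[valid, , drop = FALSE])
  }
  raster_grid(matrix(out, nrow(tmpl$values), ncol(tmpl$values)),
              tmpl$origin_lon, tmpl$origin_lat, tmpl$cell_size)
}
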