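#' Predictor importance by permutation (jackknife-style)
#'
#' Scores each predictor by how much a fitted model's predictions change
#' when that predictor's column is permuted: importance(v) is the mean over
#' replicates of `1 - max(0, cor(predictions, predictions with v permuted))`
#' — 0 for a predictor the model ignores, approaching 1 when predictions
#' track that predictor alone. A refit-based leave-one-variable-out
#' delta-AUC variant is available via `method = "loo_auc"`.
#'
#' @param model any object for which [predict_scores()] returns scores in
#'   `[0, 1]` (an `sdm_member`, `ensemble_sdm`, or a plain function of the
#'   design matrix).
#' @param X design matrix (columns = predictors).
#' @param replicates number of permutation replicates (default 5).
#' @param seed integer seed.
#' @param method `"permutation"` (default) or `"loo_auc"`.
#' @param labels 0/1 labels, required for `"loo_auc"`.
#' @param refit for `"loo_auc"`: `function(X) -> model` refitting on a
#'   reduced design matrix.
#' @return an `importance_table`: data frame with columns `predictor`,
#'   `importance`; the method, replicate count, and seed as attributes.
#' @export
permutation_importance <- function(model, X, replicates = 5L, seed = 1L,
                                   method = c("permutation", "loo_auc"),
                                   labels = NULL, refit = NULL) {
  method <- match.arg(method)
  X <- as.matrix(X)
  vars <- colnames(X)
  stopifnot(!is.null(vars))
  base_scores <- predict_scores(model, X)
  scores <- if (method == "permutation") {
    if (stats::sd(base_scores) == 0) {
      warning("model predictions are constant; importance undefined, set to 0")
      stats::setNames(rep(0, length(vars)), vars)
    } else {
      with_seed(seed, {
        vapply(vars, function(v) {
          mean(vapply(seq_len(replicates), function(r) {
            Xp <- X
            Xp[, v] <- Xp[sample.int(nrow(X)), v]
            p <- predict_scores(model, Xp)
            if (stats::sd(p) == 0) return(1)
            1 - max(0, stats::cor(base_scores, p))
          }, numeric(1)))
        }, numeric(1))
      })
    }
  } else {
    if (is.null(labels) || is.null(refit)) {
      stop_invrisk("method 'loo_auc' needs labels and a refit function")
    }
    auc_full <- auc_score(base_scores, labels)
    vapply(vars, function(v) {
      reduced <- refit(X[, setdiff(vars, v), drop = FALSE])
      max(0, auc_full - auc_score(
        predict_scores(reduced, X[, setdiff(vars, v), drop = FALSE]), labels))
    }, numeric(1))
  }
  out <- data.frame(predictor = vars, importance = pmin(pmax(scores, 0), 1),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "method") <- method
  attr(out, "replicates") <- as.integer(replicates)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Pearson correlation matrix of a design matrix
#'
#' Symmetric with unit diagonal; constant columns correlate 0 with
#' everything (with a warning) rather than propagating `NA`.
#'
#' @param X design matrix with at least 3 rows.
#' @return correlation matrix.
#' @export
pearson_matrix <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 3) stop_invrisk("need at least 3 rows")
  const <- apply(X, 2, function(v) stats::sd(v) == 0)
  r <- suppressWarnings(stats::cor(X))
  if (any(const)) {
    warning("constant column(s) yield undefined correlations, set to 0: ",
            paste(colnames(X)[const], collapse = ", "))
    r[const, ] <- 0
    r[, const] <- 0
  }
  diag(r) <- 1
  r
}

#' Collinearity-pruning predictor selection
#'
#' Iteratively removes the lower-importance member of the most strongly
#' correlated predictor pair until no surviving pair's absolute Pearson
#' correlation exceeds the threshold. Importance ties remove the
#' lexicographically later name, making selection invariant to column
#' order.
#'
#' @param X design matrix.
#' @param importance an `importance_table` (or data frame with `predictor`
#'   and `importance` columns) covering every column of `X`.
#' @param threshold collinearity threshold on |r| (default 0.7).
#' @return list of class `selection_result`: `retained` (character vector),
#'   `removed` (data frame: name, partner, correlation, reason),
#'   `threshold`.
#' @export
select_predictors <- function(X, importance, threshold = 0.7) {
  X <- as.matrix(X)
  vars <- colnames(X)
  imp <- stats::setNames(importance$importance, importance$predictor)
  if (!all(vars %in% names(imp))) {
    stop_invrisk("importance table must cover every column of X")
  }
  r <- pearson_matrix(X)
  alive <- vars
  removed <- data.frame(name = character(), partner = character(),
                        correlation = numeric(), reason = character(),
                        stringsAsFactors = FALSE)
  repeat {
    ra <- abs(r[alive, alive, drop = FALSE])
    diag(ra) <- 0
    if (max(ra) <= threshold) break
    ij <- which(ra == max(ra), arr.ind = TRUE)[1, ]
    a <- alive[ij[1]]; b <- alive[ij[2]]
    drop <- if (imp[a] < imp[b]) a
            else if (imp[b] < imp[a]) b
            else max(a, b)            # tie: lexicographically later goes
    partner <- if (drop == a) b else a
    removed <- rbind(removed, data.frame(
      name = drop, partner = partner, correlation = r[a, b],
      reason = sprintf("|r| = %.3f > %.2f with '%s', lower importance",
                       abs(r[a, b]), threshold, partner),
      stringsAsFactors = FALSE))
    alive <- setdiff(alive, drop)
  }
  # contract check: no retained pair above threshold
  ra <- abs(r[alive, alive, drop = FALSE]); diag(ra) <- 0
  stopifnot(max(ra, 0) <= threshold)
  structure(list(retained = alive, removed = removed, threshold = threshold),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("predictor selection (|r| threshold %.2f): %d retained, %d removed\n",
              x$threshold, length(x$retained), nrow(x$removed)))
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$removed)) {
    for (i in seq_len(nrow(x$removed))) {
      cat(sprintf("  removed %s (%s)\n", x$removed$name[i], x$removed$reason[i]))
    }
  }
  invisible(x)
}
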