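#' Null SDMs from random virtual occurrences
#'
#' Calibrates the no-signal skill distribution against which real model
#' skill is judged. Per replicate: virtual presence records equal in number
#' to 70% of the actual occurrences (rounded half away from zero) are drawn
#' uniformly from the valid cells of the stack, a model is fitted on them
#' with fresh pseudo-absences, and it is evaluated against a freshly drawn
#' held-out 30% of the *real* records (plus pseudo-absences as the absence
#' class).
#'
#' @param stack a [predictor_stack()] of the population's region.
#' @param occurrences the population's real occurrence records (>= 10).
#' @param algorithm single algorithm id used for the null fits
#'   (default `"maxent"`, the cheapest member).
#' @param replicates number of null replicates (default 10).
#' @param seed integer seed.
#' @param virtual_frac fraction of the actual record count drawn as virtual
#'   presences (default 0.7).
#' @return data frame with one row per replicate: `replicate`, `n_virtual`,
#'   `auc`, `tss`, `mss_threshold`.
#' @export
build_null_models <- function(stack, occurrences, algorithm = "maxent",
                              replicates = 10L, seed = 1L,
                              virtual_frac = 0.7) {
  n_actual <- nrow(occurrences)
  if (n_actual < 10) stop_invrisk("need at least 10 real occurrence records")
  if (replicates < 2) stop_invrisk("need at least 2 replicates")
  n_virtual <- as.integer(round_half_away(virtual_frac * n_actual))
  tmpl <- stack_template(stack)
  valid_idx <- which(as.vector(stack_valid_mask(stack)))
  co <- grid_coords(tmpl)
  out <- lapply(seq_len(replicates), function(r) {
    rs <- spawn_seed(seed, r)
    with_seed(rs, {
      vi <- valid_idx[sample.int(length(valid_idx), n_virtual,
                                 replace = n_virtual > length(valid_idx))]
      virt <- occurrence_set(data.frame(
        species = "virtual", lon = co[vi, "lon"], lat = co[vi, "lat"],
        source = "virtual", stringsAsFactors = FALSE))
      test_idx <- sample(n_actual, max(1L, round(0.3 * n_actual)))
    })
    pa_train <- generate_pseudo_absences(stack, virt,
                                         seed = spawn_seed(rs, 1))
    Xtr <- rbind(extract_values(virt, stack)$X,
                 extract_values(pa_train, stack)$X)
    ytr <- c(rep(1L, nrow(Xtr) - nrow(pa_train)), rep(0L, nrow(pa_train)))
    fit <- fit_member(algorithm, Xtr, ytr, seed = spawn_seed(rs, 2))
    real_test <- occurrences[test_idx, , drop = FALSE]
    pa_test <- generate_pseudo_absences(stack, real_test,
                                        seed = spawn_seed(rs, 3))
    ex_p <- extract_values(real_test, stack)$X
    ex_a <- extract_values(pa_test, stack)$X
    Xte <- rbind(ex_p, ex_a)
    yte <- c(rep(1L, nrow(ex_p)), rep(0L, nrow(ex_a)))
    p <- predict_scores(fit, Xte)
    mss <- mss_threshold(p, yte)
    data.frame(replicate = r, n_virtual = n_virtual,
               auc = auc_score(p, yte), tss = mss$tss,
               mss_threshold = mss$threshold)
  })
  do.call(rbind, out)
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value (via [stats::t.test()]). When both samples have
#' zero variance and equal means the comparison is vacuous and `p = 1` is
#' returned by convention.
#'
#' @param sample_a,sample_b numeric vectors of length >= 2.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t_test <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) >= 2, length(sample_b) >= 2)
  if (stats::sd(sample_a) == 0 && stats::sd(sample_b) == 0) {
    if (mean(sample_a) == mean(sample_b)) {
      return(list(t = 0, df = length(sample_a) + length(sample_b) - 2, p = 1))
    }
    return(list(t = sign(mean(sample_a) - mean(sample_b)) * Inf,
                df = length(sample_a) + length(sample_b) - 2, p = 0))
  }
  tt <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Compare real against null model skill
#'
#' One-sided Welch t-tests (real > null) of the AUC and TSS replicate
#' distributions. The verdict per metric is whether real skill exceeds null
#' skill at level `alpha`; full distributions are retained in the result.
#'
#' @param real_evals data frame with `auc` and `tss` columns (e.g. the
#'   `evals` table of an [ensemble_sdm()]).
#' @param null_evals data frame from [build_null_models()].
#' @param alpha significance level (default 0.05).
#' @return list of class `null_comparison`: per-metric `t`, `df`, `p`,
#'   `verdict`, and the raw value lists.
#' @export
compare_real_vs_null <- function(real_evals, null_evals, alpha = 0.05) {
  stopifnot(nrow(real_evals) > 0, nrow(null_evals) > 0)
  one_sided <- function(a, b) {
    tt <- stats::t.test(a, b, alternative = "greater", var.equal = FALSE)
    list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
  }
  ra <- real_evals$auc[!is.na(real_evals$auc)]
  rt <- real_evals$tss[!is.na(real_evals$tss)]
  a <- one_sided(ra, null_evals$auc)
  t <- one_sided(rt, null_evals$tss)
  structure(list(real_auc = ra, null_auc = null_evals$auc,
                 real_tss = rt, null_tss = null_evals$tss,
                 t_auc = a$t, p_auc = a$p, df_auc = a$df,
                 t_tss = t$t, p_tss = t$p, df_tss = t$df,
                 alpha = alpha,
                 verdict = c(auc = a$p < alpha, tss = t$p < alpha)),
            class = "null_comparison")
}

#' @export
print.null_comparison <- function(x, ...) {
  cat("Real vs null model skill (one-sided Welch t, real > null):\n")
  cat(sprintf("  AUC: real mean %.3f vs null mean %.3f, t = %.2f (df %.1f), p = %.3g %s\n",
              mean(x$real_auc), mean(x$null_auc), x$t_auc, x$df_auc, x$p_auc,
              if (x$verdict[["auc"]]) "*" else ""))
  cat(sprintf("  TSS: real mean %.3f vs null mean %.3f, t = %.2f (df %.1f), p = %.3g %s\n",
              mean(x$real_tss), mean(x$null_tss), x$t_tss, x$df_tss, x$p_tss,
              if (x$verdict[["tss"]]) "*" else ""))
  invisible(x)
}
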