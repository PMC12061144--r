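#' Area under the ROC curve (rank formulation)
#'
#' AUC as the probability that a randomly drawn presence is scored above a
#' randomly drawn absence, with ties counted one half — the Mann-Whitney
#' rank form, computed without constructing the ROC curve.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 (or logical) class labels; 1 = presence.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop_invrisk("both classes must be present to compute AUC")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Maximum sensitivity-plus-specificity (MSS) threshold
#'
#' Scans candidate thresholds — the midpoints between consecutive sorted
#' unique scores plus the extreme scores themselves — for the cut-off
#' maximizing sensitivity + specificity under the rule
#' `score >= threshold` implies presence. Objective ties are broken toward
#' the lowest threshold. The returned TSS is sensitivity + specificity - 1
#' at the selected threshold; binarizing a suitability surface at this
#' threshold calibrates the range map.
#'
#' @inheritParams auc_score
#' @return list with `threshold`, `sensitivity`, `specificity`, `tss`.
#' @export
mss_threshold <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop_invrisk("both classes must be present to compute the MSS threshold")
  }
  su <- sort(unique(scores))
  cand <- sort(unique(c(su, if (length(su) > 1) (su[-1] + su[-length(su)]) / 2)))
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  sens <- vapply(cand, function(th) mean(pos >= th), numeric(1))
  spec <- vapply(cand, function(th) mean(neg < th), numeric(1))
  obj <- sens + spec
  best <- which.max(obj)   # which.max takes the first (lowest) maximizer
  list(threshold = cand[best], sensitivity = sens[best],
       specificity = spec[best], tss = obj[best] - 1)
}
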