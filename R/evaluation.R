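#' ROC curve of a score map against an observed distribution
#'
#' Sweeps every unique valid score value as a candidate presence threshold
#' (rule: `score >= threshold` predicts presence), plus a sentinel above the
#' maximum so the curve starts at `(fpr, tpr) = (0, 0)`; it always ends at
#' `(1, 1)`.
#'
#' @param scores A [score_map()] of continuous model output.
#' @param observed A co-registered [binary_map()] of the observed
#'   presence/absence distribution, with at least one presence and one
#'   absence among valid cells.
#' @return A tibble of class `roc_curve` with columns `threshold`, `fpr`,
#'   `tpr`, thresholds strictly decreasing. Attributes `n_pos`, `n_neg`
#'   carry the class counts.
#' @seealso [auc()], [spt_threshold()], [dichotomize()]
#' @examples
#' meta <- grid_meta(1, 4)
#' s <- score_map(meta, matrix(c(0.9, 0.4, 0.8, 0.1), 1))
#' o <- binary_map(meta, matrix(c(1, 1, 0, 0), 1))
#' roc_curve(s, o)
#' @export
roc_curve <- function(scores, observed) {
  stopifnot(inherits(scores, "score_map"), inherits(observed, "binary_map"))
  assert_coregistered(scores, observed)
  s <- scores$values[scores$mask]
  y <- observed$values[observed$mask]
  n_pos <- sum(y == 1)
  n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop(
      "observed distribution has a single class among valid cells; ",
      "ROC is undefined",
      call. = FALSE
    )
  }
  thresholds <- c(Inf, sort(unique(s), decreasing = TRUE))
  # cumulative class counts at score >= threshold
  ord <- order(s, decreasing = TRUE)
  s_sorted <- s[ord]
  y_sorted <- y[ord]
  cum_tp <- cumsum(y_sorted == 1)
  cum_fp <- cumsum(y_sorted == 0)
  # index of the last score >= each finite threshold
  idx <- findInterval(-thresholds[-1], -s_sorted)
  out <- tibble::tibble(
    threshold = thresholds,
    fpr = c(0, cum_fp[idx] / n_neg),
    tpr = c(0, cum_tp[idx] / n_pos)
  )
  structure(out,
    class = c("roc_curve", class(tibble::tibble())),
    n_pos = n_pos, n_neg = n_neg
  )
}

#' Area under the ROC curve
#'
#' Trapezoidal area under `(fpr, tpr)`; equals the Mann-Whitney concordance
#' probability with ties counted 1/2. A single threshold-independent measure
#' of model discrimination. Reported raw even when below 0.5.
#'
#' @param curve A [roc_curve()].
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
}

#' Species presence threshold (SPT)
#'
#' The score cutoff at the ROC point farthest from the 1:1 line, i.e. the
#' candidate threshold maximising Youden's J = tpr - fpr. Ties are broken
#' toward the smallest threshold (the more inclusive presence range), which
#' makes the choice deterministic.
#'
#' @param curve A [roc_curve()].
#' @return A single threshold value.
#' @export
spt_threshold <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  j <- curve$tpr - curve$fpr
  best <- which(j >= max(j) - 1e-12)
  min(curve$threshold[best])
}

#' Dichotomise a score map at a threshold
#'
#' Valid cells with `score >= threshold` become presence (1); the closed
#' lower bound keeps the threshold value itself classified as present.
#'
#' @param scores A [score_map()].
#' @param threshold Presence threshold.
#' @return A [binary_map()] with the same mask.
#' @export
dichotomize <- function(scores, threshold) {
  stopifnot(inherits(scores, "score_map"), length(threshold) == 1)
  v <- scores$values
  v[scores$mask] <- as.numeric(v[scores$mask] >= threshold)
  binary_map(scores$meta, v, scores$mask)
}

#' Confusion counts between two binary maps
#'
#' Counts of true/false presences and absences over valid cells only.
#'
#' @param pred,obs Co-registered [binary_map()] objects (prediction and
#'   observation).
#' @return A one-row tibble with columns `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(pred, obs) {
  stopifnot(inherits(pred, "binary_map"), inherits(obs, "binary_map"))
  assert_coregistered(pred, obs)
  p <- pred$values[pred$mask]
  o <- obs$values[obs$mask]
  tibble::tibble(
    tp = sum(p == 1 & o == 1),
    fp = sum(p == 1 & o == 0),
    fn = sum(p == 0 & o == 1),
    tn = sum(p == 0 & o == 0)
  )
}

#' Cohen's kappa from confusion counts
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` with observed
#' agreement `p_o = (tp + tn) / n` and chance agreement
#' `p_e = ((tp + fp)(tp + fn) + (fn + tn)(fp + tn)) / n^2`. Ranges over
#' `[-1, 1]`. When both maps are constant (`p_e = 1`) the statistic is
#' defined as 1 for identical maps and 0 otherwise; this keeps small
#' moving-window comparisons finite instead of propagating NaN.
#'
#' @param counts A list, one-row data frame or named vector with elements
#'   `tp`, `fp`, `fn`, `tn` (as returned by [confusion()]).
#' @return Kappa in `[-1, 1]`.
#' @examples
#' cohen_kappa(list(tp = 40, fp = 10, fn = 10, tn = 40)) # 0.6
#' @export
cohen_kappa <- function(counts) {
  counts <- as.list(counts)
  tp <- counts$tp
  fp <- counts$fp
  fn <- counts$fn
  tn <- counts$tn
  n <- tp + fp + fn + tn
  stopifnot(n >= 1)
  p_o <- (tp + tn) / n
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  if (p_e >= 1 - 1e-15) {
    return(if (p_o >= 1 - 1e-15) 1 else 0)
  }
  (p_o - p_e) / (1 - p_e)
}

#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("ROC curve (AUC = %.3f)", auc(object))
    )
}
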