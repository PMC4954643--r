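# ranking metrics and the held-out-family evaluation harness

#' Ranking metrics for score-separated classes
#'
#' `auroc` is the Mann-Whitney statistic with ties counted 1/2. `aupr`
#' integrates the precision-recall step curve over the full recall range
#' (precision of a tied-score block applies to the whole block; no linear
#' interpolation). `aupr50` integrates precision over recall in `[0, 0.5]`
#' only and is normalized by 0.5 so its range is `[0, 1]`.
#'
#' @param scores_pos,scores_neg numeric score vectors, both non-empty.
#' @return numeric scalar in `[0, 1]`.
#' @export
auroc <- function(scores_pos, scores_neg) {
  np <- length(scores_pos)
  nn <- length(scores_neg)
  if (!np || !nn) stopf("auroc needs both classes non-empty")
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

pr_curve <- function(scores_pos, scores_neg) {
  np <- length(scores_pos)
  if (!np || !length(scores_neg)) stopf("PR curve needs both classes")
  sc <- c(scores_pos, scores_neg)
  lab <- c(rep(1L, np), rep(0L, length(scores_neg)))
  vals <- sort(unique(sc), decreasing = TRUE)
  tp <- cumsum(vapply(vals, function(v) sum(lab[sc == v]), numeric(1)))
  n_at <- cumsum(vapply(vals, function(v) sum(sc == v), numeric(1)))
  data.frame(recall = tp / np, precision = tp / n_at)
}

#' @rdname auroc
#' @export
aupr <- function(scores_pos, scores_neg) {
  pr <- pr_curve(scores_pos, scores_neg)
  sum(diff(c(0, pr$recall)) * pr$precision)
}

#' @rdname auroc
#' @export
aupr50 <- function(scores_pos, scores_neg) {
  pr <- pr_curve(scores_pos, scores_neg)
  prev <- c(0, pr$recall[-nrow(pr)])
  lo <- pmin(prev, 0.5)
  hi <- pmin(pr$recall, 0.5)
  sum((hi - lo) * pr$precision) / 0.5
}

#' Paired two-sided Wilcoxon signed-rank p-value
#'
#' Convenience wrapper used when comparing per-family metrics of two score
#' sources.
#'
#' @param x,y paired metric vectors.
#' @return p-value.
#' @export
paired_signed_rank <- function(x, y) {
  if (all(x == y)) return(1)
  stats::wilcox.test(x, y, paired = TRUE, exact = FALSE)$p.value
}

#' Held-out-family evaluation of the duplex model
#'
#' For each miRNA seed family with at least one positive example, removes
#' the family (and every example sharing a site with it) from training,
#' fits the duplex model on the remainder, and scores the held-out
#' positives against the held-out negative pool.
#'
#' @param examples labeled-site data frame.
#' @param mirnas,utrs catalogs.
#' @param control a [duplex_control()].
#' @param families families to evaluate (default: all with a positive).
#' @return data frame of class `ranking_eval`: `family, n_pos, n_neg,
#'   auroc, aupr, aupr50, source`.
#' @export
evaluate_heldout <- function(examples, mirnas, utrs,
                             control = duplex_control(), families = NULL) {
  families <- families %||%
    unique(examples$family[examples$label == "positive"])
  if (length(unique(examples$family)) < 2L) {
    stopf("held-out evaluation needs at least two families")
  }
  rows <- list()
  for (fam in families) {
    split <- holdout_by_family(examples, fam,
                               known_families = unique(c(examples$family, fam)))
    tp <- split$test[split$test$label == "positive" &
                       split$test$family == fam, , drop = FALSE]
    tn <- split$test[split$test$label == "negative", , drop = FALSE]
    if (!nrow(tp) || !nrow(tn)) {
      message(sprintf("family %s skipped: no held-out positives or negatives",
                      fam))
      next
    }
    if (length(unique(split$train$label)) < 2L) {
      message(sprintf("family %s skipped: degenerate training split", fam))
      next
    }
    fit <- duplex_svm(split$train, mirnas, utrs, control = control)
    sp <- predict(fit, tp, mirnas, utrs)
    sn <- predict(fit, tn, mirnas, utrs)
    rows[[fam]] <- data.frame(family = fam, n_pos = nrow(tp), n_neg = nrow(tn),
                              auroc = auroc(sp, sn), aupr = aupr(sp, sn),
                              aupr50 = aupr50(sp, sn), source = "duplex",
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("no family produced an evaluation")
  rownames(out) <- NULL
  class(out) <- c("ranking_eval", "data.frame")
  out
}
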