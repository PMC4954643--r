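# brute-force metric oracles: pairwise counting for auROC, explicit
# per-threshold recomputation for the PR step curve

oracle_auroc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + (p > n) + 0.5 * (p == n)
  }
  wins / (length(pos) * length(neg))
}

oracle_pr_points <- function(pos, neg) {
  all <- c(pos, neg)
  thr <- sort(unique(all), decreasing = TRUE)
  t(vapply(thr, function(v) {
    tp <- sum(pos >= v)
    fp <- sum(neg >= v)
    c(recall = tp / length(pos), precision = tp / (tp + fp))
  }, numeric(2)))
}

oracle_aupr <- function(pos, neg, cap = 1) {
  pts <- oracle_pr_points(pos, neg)
  area <- 0
  prev <- 0
  for (i in seq_len(nrow(pts))) {
    lo <- min(prev, cap)
    hi <- min(pts[i, "recall"], cap)
    area <- area + (hi - lo) * pts[i, "precision"]
    prev <- pts[i, "recall"]
  }
  unname(area / cap)
}
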