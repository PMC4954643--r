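# AGO binding classifier: weighted-degree string kernels on seed-match
# flanks + RBF kernel on 3'UTR-isoform positional features, with optional
# multi-task coupling across cell types / data sets

PAD <- "."

#' Default weighted-degree k-mer weights
#'
#' `beta_k = 2 (d - k + 1) / (d (d + 1))`, the standard length-decaying
#' weighting of the weighted-degree kernel.
#'
#' @param degree maximum k-mer length d.
#' @return numeric vector `beta[1..d]`.
#' @export
wd_beta <- function(degree = 6L) {
  k <- seq_len(degree)
  2 * (degree - k + 1) / (degree * (degree + 1))
}

#' Extract the 30-nt flanks of a seed match
#'
#' The upstream flank is the `width` bases ending at `match_start`, the
#' downstream flank the `width` bases starting at `match_end`, both stored
#' in UTR 5'->3' order. Positions outside the UTR are filled with a pad
#' symbol that carries no k-mer contribution. The downstream base nearest
#' the seed lies opposite miRNA nucleotide 1; the upstream base nearest the
#' seed lies opposite miRNA nucleotide 8.
#'
#' @param utr a UTR catalog row.
#' @param seed_match a row with `match_start`, `match_end` (or `site_start`,
#'   `site_end`) in UTR coordinates.
#' @param width flank width (default 30).
#' @return list with `upstream` and `downstream` strings of length `width`.
#' @export
extract_flanks <- function(utr, seed_match, width = 30L) {
  s <- seed_match$match_start %||% seed_match$site_start
  e <- seed_match$match_end %||% seed_match$site_end
  L <- nchar(utr$sequence)
  stopifnot(s >= 0, e <= L, s < e)
  up_start <- s - width
  up <- paste0(strrep(PAD, max(0L, -up_start)),
               utr_substr(utr$sequence, max(0L, up_start), s))
  down <- paste0(utr_substr(utr$sequence, e, min(L, e + width)),
                 strrep(PAD, max(0L, e + width - L)))
  list(upstream = up, downstream = down)
}

# integer code matrix (n x L) of flank strings; pads and N are NA so any
# k-mer touching them never matches
flank_code_matrix <- function(seqs) {
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stopf("flank sequences must have equal length")
  m <- matrix(match(unlist(strsplit(seqs, "", fixed = TRUE)), RNA_BASES),
              nrow = length(seqs), ncol = L, byrow = TRUE)
  m
}

kmer_code_matrix <- function(codes, k) {
  L <- ncol(codes)
  n <- nrow(codes)
  out <- matrix(0, n, L - k + 1L)
  for (i in seq_len(k)) {
    out <- out + (codes[, i:(L - k + i), drop = FALSE] - 1L) * 4^(k - i)
  }
  out
}

wd_kernel_codes <- function(codesA, codesB, degree, beta) {
  K <- matrix(0, nrow(codesA), nrow(codesB))
  for (k in seq_len(degree)) {
    ka <- kmer_code_matrix(codesA, k)
    kb <- kmer_code_matrix(codesB, k)
    for (j in seq_len(ncol(ka))) {
      e <- outer(ka[, j], kb[, j], "==")
      e[is.na(e)] <- FALSE
      K <- K + beta[k] * e
    }
  }
  K
}

#' Weighted-degree string kernel between two equal-length sequences
#'
#' `k(a, z) = sum_k beta_k sum_j 1[a and z share the k-mer starting at j]`;
#' k-mers containing pads or `N` never match.
#'
#' @param a,z sequences of equal length (pad symbol `.` allowed).
#' @param degree maximum k-mer length.
#' @param beta per-k weights (default [wd_beta()]).
#' @return numeric scalar.
#' @export
wd_kernel <- function(a, z, degree = 6L, beta = wd_beta(degree)) {
  if (nchar(a) != nchar(z)) stopf("wd_kernel: length mismatch")
  stopifnot(degree <= nchar(a), length(beta) == degree)
  ca <- flank_code_matrix(a)
  cz <- flank_code_matrix(z)
  drop(wd_kernel_codes(ca, cz, degree, beta))
}

#' Positional context of a site within its 3'UTR isoforms
#'
#' Distances are measured from the anchor (the UTR position opposite miRNA
#' nucleotide 2): `d_stop` to the UTR start, `d_next_end` to the nearest
#' isoform 3' end at or beyond the anchor, and `d_prev_end` to the nearest
#' 3' end before it. When no upstream isoform end exists `d_prev_end` falls
#' back to `d_stop` and a sentinel indicator is set.
#'
#' @param utr a UTR catalog row (with `three_prime_ends`).
#' @param anchor 0-based anchor position.
#' @return list `d_stop`, `d_next_end`, `d_prev_end`, `prev_is_sentinel`.
#' @export
positional_context <- function(utr, anchor) {
  ends <- utr$three_prime_ends
  if (is.list(ends)) ends <- ends[[1L]]
  stopifnot(anchor >= 0, anchor < nchar(utr$sequence))
  nxt <- ends[ends >= anchor]
  prv <- ends[ends < anchor]
  d_stop <- anchor
  d_next <- if (length(nxt)) min(nxt) - anchor else 0L
  sentinel <- !length(prv)
  d_prev <- if (sentinel) d_stop else anchor - max(prv)
  list(d_stop = d_stop, d_next_end = d_next, d_prev_end = d_prev,
       prev_is_sentinel = sentinel)
}

# log-compressed distance transform feeding the RBF kernel
context_transform <- function(ctx) {
  c(log10(1 + ctx$d_stop), log10(1 + ctx$d_next_end),
    log10(1 + ctx$d_prev_end), as.numeric(ctx$prev_is_sentinel))
}

context_matrix <- function(contexts) {
  t(vapply(contexts, context_transform, numeric(4L)))
}

#' Positional RBF kernel between two site contexts
#'
#' `exp(-gamma ||t(c1) - t(c2)||^2)` on log10-compressed distances (plus a
#' sentinel indicator component).
#'
#' @param c1,c2 contexts from [positional_context()].
#' @param gamma RBF width, `> 0`.
#' @return numeric scalar in `(0, 1]`.
#' @export
positional_kernel <- function(c1, c2, gamma = 1) {
  stopifnot(gamma > 0)
  d <- context_transform(c1) - context_transform(c2)
  exp(-gamma * sum(d^2))
}

rbf_kernel_matrix <- function(T1, T2, gamma) {
  d2 <- outer(rowSums(T1^2), rowSums(T2^2), "+") - 2 * tcrossprod(T1, T2)
  exp(-gamma * pmax(d2, 0))
}

#' Combined flank-sequence and positional kernel matrix
#'
#' `K = K_wd_up + K_wd_down + K_pos`. Components are trace-normalized
#' (divided by their mean diagonal) before summation by default so that no
#' component dominates by scale; raw summation is available via
#' `normalize = "none"`.
#'
#' @param flanks list of flank pairs from [extract_flanks()].
#' @param contexts list of contexts from [positional_context()] (or `NULL`
#'   for a sequence-only kernel).
#' @param degree,beta,gamma kernel parameters.
#' @param normalize `"trace"` or `"none"`.
#' @return list of class `combined_kernel`: `K`, per-component matrices in
#'   `components`, and the normalization constants in `scales`.
#' @export
combined_kernel <- function(flanks, contexts = NULL, degree = 6L,
                            beta = wd_beta(degree), gamma = 1,
                            normalize = c("trace", "none")) {
  normalize <- match.arg(normalize)
  up <- flank_code_matrix(vapply(flanks, `[[`, "", "upstream"))
  down <- flank_code_matrix(vapply(flanks, `[[`, "", "downstream"))
  comp <- list(wd_up = wd_kernel_codes(up, up, degree, beta),
               wd_down = wd_kernel_codes(down, down, degree, beta))
  if (!is.null(contexts)) {
    Tm <- context_matrix(contexts)
    comp$positional <- rbf_kernel_matrix(Tm, Tm, gamma)
  }
  scales <- vapply(comp, function(K) {
    s <- mean(diag(K))
    if (normalize == "trace" && s > 0) s else 1
  }, numeric(1L))
  K <- Reduce(`+`, Map(function(Kc, s) Kc / s, comp, scales))
  structure(list(K = K, components = comp, scales = scales, degree = degree,
                 beta = beta, gamma = gamma, normalize = normalize),
            class = "combined_kernel")
}

#' Multi-task kernel
#'
#' `K_st(x, z) = (mu + 1[task_x = task_z]) K(x, z)`: examples from the same
#' task get an extra unit of similarity; `mu` controls how strongly tasks
#' share a common model (`mu = 0` makes tasks independent,
#' block-diagonal).
#'
#' @param K base kernel matrix.
#' @param tasks task identifier per row/column of `K`.
#' @param mu non-negative task-coupling weight.
#' @return weighted kernel matrix.
#' @export
multitask_kernel <- function(K, tasks, mu) {
  stopifnot(mu >= 0, length(tasks) == nrow(K), nrow(K) == ncol(K))
  (mu + outer(tasks, tasks, "==")) * K
}

#' Control parameters for [binding_svm()]
#'
#' @param C soft-margin cost. The default 0.1 regularizes strongly: the
#'   positional k-mer kernels carry ~165 mostly uninformative comparisons
#'   per flank, and at a few hundred training sites larger C overfits
#'   that kernel noise (large train/held-out gaps).
#' @param mu task-coupling weight, or `"auto"` for 5-fold CV over
#'   `{0.1, 0.25, 0.5, 1, 2, 4}` maximizing mean held-out auROC.
#' @param gamma positional RBF width, or `"auto"` for the same CV over
#'   `{0.1, 0.5, 1, 2, 4}`.
#' @param degree weighted-degree kernel order (positional k-mers up to
#'   6-mers).
#' @param flank_width flank length in nt.
#' @param cv_folds folds for the `"auto"` grid searches.
#' @param rng_seed seed for CV fold assignment.
#' @param use_positional include the positional RBF component.
#' @param normalize kernel component normalization, see
#'   [combined_kernel()].
#' @return a list of class `binding_control`.
#' @export
binding_control <- function(C = 0.1, mu = 1, gamma = 1, degree = 6L,
                            flank_width = 30L, cv_folds = 5L, rng_seed = 1L,
                            use_positional = TRUE,
                            normalize = c("trace", "none")) {
  structure(list(C = C, mu = mu, gamma = gamma, degree = as.integer(degree),
                 flank_width = as.integer(flank_width),
                 cv_folds = as.integer(cv_folds),
                 rng_seed = as.integer(rng_seed),
                 use_positional = isTRUE(use_positional),
                 normalize = match.arg(normalize)),
            class = "binding_control")
}

binding_features <- function(examples, utrs, control) {
  idx <- match(examples$transcript_id, utrs$transcript_id)
  if (anyNA(idx)) stopf("examples reference unknown transcripts")
  flanks <- vector("list", nrow(examples))
  contexts <- vector("list", nrow(examples))
  for (i in seq_len(nrow(examples))) {
    u <- utrs[idx[i], ]
    flanks[[i]] <- extract_flanks(u, examples[i, ], control$flank_width)
    anchor <- examples$anchor[i]
    if (is.null(anchor) || is.na(anchor)) anchor <- examples$site_end[i] - 1L
    contexts[[i]] <- positional_context(u, anchor)
  }
  list(flanks = flanks, contexts = contexts)
}

# dual fit on a precomputed kernel; returns alpha*y over all examples and
# the intercept, oriented so positives score higher
fit_kernel_svm <- function(K, y, C) {
  yy <- ifelse(y == "positive", 1, -1)
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K), factor(yy, c(-1, 1)),
                       type = "C-svc", C = C)
  ay <- numeric(length(yy))
  ay[kernlab::SVindex(fit)] <- kernlab::coef(fit)[[1L]]
  b <- -kernlab::b(fit)
  f <- drop(K %*% ay) + b
  if (mean(f[yy == 1]) < mean(f[yy == -1])) {
    ay <- -ay
    b <- -b
  }
  list(alpha_y = ay, bias = b)
}

#' Train the AGO binding model (kernel SVM, optionally multi-task)
#'
#' Fits a kernelized maximum-margin classifier on AGO-bound versus unbound
#' canonical seed sites. The kernel sums two weighted-degree string kernels
#' over the upstream and downstream 30-nt flanks and a radial basis kernel
#' on positions within 3'UTR isoforms; with more than one task (cell type /
#' data set) the kernel is modulated as `(mu + delta_st) K`, learning
#' task-specific deviations around a shared common model.
#'
#' @param examples labeled-site data frame (both classes present in every
#'   task); `task` tags the cell type.
#' @param utrs UTR catalog.
#' @param control a [binding_control()].
#' @return an object of class `binding_svm` storing dual coefficients, the
#'   support examples' flanks and contexts, kernel parameters and the task
#'   registry. Methods: `print`, `predict` (`mode = "common"` or a task
#'   id), `coef` (effective linear flank weights).
#' @export
binding_svm <- function(examples, utrs, control = binding_control()) {
  stopifnot(inherits(control, "binding_control"))
  tasks <- unique(examples$task)
  for (tk in tasks) {
    if (length(unique(examples$label[examples$task == tk])) < 2L) {
      stopf("task '%s' lacks one of the classes", tk)
    }
  }
  multitask <- length(tasks) > 1L
  if (!multitask && (identical(control$mu, "auto") || control$mu != 1)) {
    warnf("single-task input: falling back to a single-task fit")
  }
  feats <- binding_features(examples, utrs, control)
  tune <- function(param_grid, apply_param) {
    rng <- local_rng(control$rng_seed)
    strat <- paste(examples$task, examples$label)
    fold <- integer(nrow(examples))
    for (ix in split(seq_len(nrow(examples)), strat)) {
      fold[ix] <- rng$sample(rep_len(seq_len(control$cv_folds),
                                     length(ix)))
    }
    vapply(param_grid, function(p) {
      Kall <- apply_param(p)
      mean(vapply(seq_len(control$cv_folds), function(k) {
        tr <- fold != k
        if (length(unique(examples$label[tr])) < 2L ||
            length(unique(examples$label[!tr])) < 2L) return(NA_real_)
        fit <- fit_kernel_svm(Kall[tr, tr, drop = FALSE], examples$label[tr],
                              control$C)
        f <- drop(Kall[!tr, tr, drop = FALSE] %*% fit$alpha_y) + fit$bias
        auroc(f[examples$label[!tr] == "positive"],
              f[examples$label[!tr] == "negative"])
      }, numeric(1L)), na.rm = TRUE)
    }, numeric(1L))
  }

  gamma <- control$gamma
  if (identical(gamma, "auto")) {
    grid <- c(0.1, 0.5, 1, 2, 4)
    perf <- tune(grid, function(g) {
      ck <- combined_kernel(feats$flanks,
                            if (control$use_positional) feats$contexts,
                            degree = control$degree, gamma = g,
                            normalize = control$normalize)
      if (multitask) multitask_kernel(ck$K, examples$task, 1) else ck$K
    })
    gamma <- grid[which.max(perf)]
  }
  ck <- combined_kernel(feats$flanks,
                        if (control$use_positional) feats$contexts,
                        degree = control$degree, gamma = gamma,
                        normalize = control$normalize)
  mu <- if (multitask) control$mu else 1
  if (multitask && identical(control$mu, "auto")) {
    grid <- c(0.1, 0.25, 0.5, 1, 2, 4)
    perf <- tune(grid, function(m) multitask_kernel(ck$K, examples$task, m))
    mu <- grid[which.max(perf)]
  }
  K <- if (multitask) multitask_kernel(ck$K, examples$task, mu) else ck$K
  fit <- fit_kernel_svm(K, examples$label, control$C)
  structure(list(alpha_y = fit$alpha_y, bias = fit$bias,
                 examples = examples[, intersect(labeled_site_cols,
                                                 names(examples))],
                 flanks = feats$flanks, contexts = feats$contexts,
                 tasks = examples$task, task_registry = tasks,
                 multitask = multitask, mu = mu, gamma = gamma,
                 degree = control$degree, beta = wd_beta(control$degree),
                 scales = ck$scales, control = control,
                 train_kernel = ck$K),
            class = "binding_svm")
}

# cross-kernel between new feature sets and the training examples, on the
# training normalization constants
binding_cross_kernel <- function(model, flanks, contexts) {
  upN <- flank_code_matrix(vapply(flanks, `[[`, "", "upstream"))
  upT <- flank_code_matrix(vapply(model$flanks, `[[`, "", "upstream"))
  dnN <- flank_code_matrix(vapply(flanks, `[[`, "", "downstream"))
  dnT <- flank_code_matrix(vapply(model$flanks, `[[`, "", "downstream"))
  K <- wd_kernel_codes(upN, upT, model$degree, model$beta) /
    model$scales[["wd_up"]] +
    wd_kernel_codes(dnN, dnT, model$degree, model$beta) /
      model$scales[["wd_down"]]
  if (model$control$use_positional) {
    K <- K + rbf_kernel_matrix(context_matrix(contexts),
                               context_matrix(model$contexts), model$gamma) /
      model$scales[["positional"]]
  }
  K
}

#' Score examples under a trained binding model
#'
#' `mode = "common"` gives the cell-type-agnostic discriminant
#' `f(x) = sum_i alpha_i y_i mu K(x_i, x) + b`; `mode = <task id>` adds the
#' task-specific component `sum_{i in task} alpha_i y_i K(x_i, x)`.
#'
#' @param model a fitted `binding_svm`.
#' @param examples labeled-site rows to score.
#' @param utrs UTR catalog.
#' @param mode `"common"` or a registered task id.
#' @return numeric score vector.
#' @export
predict_binding <- function(model, examples, utrs, mode = "common") {
  feats <- binding_features(examples, utrs, model$control)
  predict_binding_features(model, feats$flanks, feats$contexts, mode)
}

predict_binding_features <- function(model, flanks, contexts,
                                     mode = "common") {
  K <- binding_cross_kernel(model, flanks, contexts)
  if (!model$multitask) {
    return(drop(K %*% model$alpha_y) + model$bias)
  }
  if (identical(mode, "common")) {
    wts <- rep(model$mu, length(model$alpha_y))
  } else {
    if (!mode %in% model$task_registry) stopf("unknown task id '%s'", mode)
    wts <- model$mu + (model$tasks == mode)
  }
  drop(K %*% (model$alpha_y * wts)) + model$bias
}

#' @export
predict.binding_svm <- function(object, examples, utrs, mode = "common",
                                ...) {
  predict_binding(object, examples, utrs, mode)
}

#' @export
print.binding_svm <- function(x, ...) {
  cat("AGO binding model (kernel SVM)\n")
  cat(sprintf("  %d examples (%d SV), tasks: %s%s\n", length(x$alpha_y),
              sum(x$alpha_y != 0), paste(x$task_registry, collapse = ", "),
              if (x$multitask) sprintf(" (multi-task, mu = %g)", x$mu) else ""))
  cat(sprintf("  degree = %d, gamma = %g, positional kernel: %s\n",
              x$degree, x$gamma,
              if (x$control$use_positional) "yes" else "no"))
  invisible(x)
}

#' Combine duplex and binding scores into one ranking
#'
#' Default `sum_z` z-scores each component against its training calibration
#' and adds them; `min_rank` and `product_rank` combine within-set fractional
#' ranks (higher = better) and need no calibration.
#'
#' @param duplex,binding numeric score vectors.
#' @param scheme `"sum_z"`, `"min_rank"` or `"product_rank"`.
#' @param calibration for `sum_z`: list with `d_mean, d_sd, b_mean, b_sd`
#'   fitted on training scores (see [fit_score_calibration()]).
#' @return combined numeric scores.
#' @export
combine_scores <- function(duplex, binding,
                           scheme = c("sum_z", "min_rank", "product_rank"),
                           calibration = NULL) {
  scheme <- match.arg(scheme)
  if (scheme == "sum_z") {
    if (is.null(calibration)) {
      stopf("sum_z combination needs a fitted calibration")
    }
    return((duplex - calibration$d_mean) / calibration$d_sd +
             (binding - calibration$b_mean) / calibration$b_sd)
  }
  rd <- rank(duplex) / length(duplex)
  rb <- rank(binding) / length(binding)
  if (scheme == "min_rank") pmin(rd, rb) else rd * rb
}

#' @rdname combine_scores
#' @param duplex_train,binding_train training-score vectors.
#' @export
fit_score_calibration <- function(duplex_train, binding_train) {
  list(d_mean = mean(duplex_train), d_sd = stats::sd(duplex_train),
       b_mean = mean(binding_train), b_sd = stats::sd(binding_train))
}

#' Aggregate site scores to gene level
#'
#' A gene with multiple sites gets its highest site score.
#'
#' @param scores numeric site scores.
#' @param genes gene identifier per site.
#' @return named numeric vector of per-gene scores.
#' @export
gene_level_score <- function(scores, genes) {
  stopifnot(length(scores) == length(genes))
  tapply(scores, genes, max)
}
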