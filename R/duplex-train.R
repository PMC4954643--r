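# iterative structural-SVM training of the duplex alignment model

#' Control parameters for [duplex_svm()]
#'
#' @param C soft-margin cost of the linear SVM (hinge loss). The default
#'   0.05 keeps the alternating realign/refit loop stable; larger values
#'   let the realignment step over-fit transient weight signs and can
#'   prevent convergence.
#' @param iterations alternating realign/refit iterations (default 12, by
#'   which point the weight vector has converged on typical inputs).
#' @param clash_neg_ratio,clip_neg_ratio negatives sampled per positive from
#'   each source in every iteration (defaults 15 and 1).
#' @param rng_seed base seed; the per-iteration negative sample uses an
#'   iteration-indexed seed derived from it.
#' @param initializer how iteration-1 duplex structures are produced
#'   (`"builtin"`: alignment under [duplex_init_weights()]).
#' @param anchor alignment locality, see [align_duplex()].
#' @param p_max maximum miRNA length (weight-vector dimension).
#' @param tune_C grid-search C over `{0.01, 0.1, 1, 10}` by internal 5-fold
#'   CV on the initializer alignments.
#' @return a list of class `duplex_control`.
#' @export
duplex_control <- function(C = 0.05, iterations = 12L, clash_neg_ratio = 15,
                           clip_neg_ratio = 1, rng_seed = 1L,
                           initializer = "builtin",
                           anchor = c("local", "anchored"), p_max = 27L,
                           tune_C = FALSE) {
  structure(list(C = C, iterations = as.integer(iterations),
                 clash_neg_ratio = clash_neg_ratio,
                 clip_neg_ratio = clip_neg_ratio,
                 rng_seed = as.integer(rng_seed),
                 initializer = match.arg(initializer, "builtin"),
                 anchor = match.arg(anchor), p_max = as.integer(p_max),
                 tune_C = isTRUE(tune_C)),
            class = "duplex_control")
}

site_sequence <- function(examples, utrs) {
  idx <- match(examples$transcript_id, utrs$transcript_id)
  if (anyNA(idx)) {
    stopf("examples reference unknown transcript(s): %s",
          paste(unique(examples$transcript_id[is.na(idx)]), collapse = ", "))
  }
  mapply(function(i, s, e) utr_substr(utrs$sequence[i], s, e),
         idx, examples$site_start, examples$site_end, USE.NAMES = FALSE)
}

# fit a linear hinge-loss classifier and return (w, b) oriented so that
# positives score higher
fit_linear_svm <- function(phi, y, C) {
  fit <- e1071::svm(x = phi, y = factor(y, levels = c("positive", "negative")),
                    scale = FALSE, kernel = "linear", cost = C)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  f <- drop(phi %*% w) + b
  if (mean(f[y == "positive"]) < mean(f[y == "negative"])) {
    w <- -w
    b <- -b
  }
  list(w = w, b = b)
}

#' Train the duplex alignment model (structural SVM)
#'
#' Learns the duplex alignment scoring vector from labeled (miRNA, site)
#' examples by alternating two steps: realign every retained example under
#' the current weights (iteration 1 uses the initializer alignments), then
#' refit a linear maximum-margin classifier with hinge loss on the
#' alignment event-count features. Negatives are resampled from the pool in
#' every iteration at the configured per-source ratios with an
#' iteration-indexed seed, so a run is fully deterministic given
#' `control$rng_seed`.
#'
#' Because an example's model score is the maximum of `w . phi` over all
#' its alignments, the trainer keeps a working set of every distinct
#' negative alignment encountered across iterations (a cutting-plane
#' realization of the max in the negative hinge loss); positives
#' contribute only their currently imputed alignment. Once no new negative
#' alignments appear the refit becomes stationary and the weight trace
#' converges.
#'
#' @param examples labeled-site data frame (both labels present); positives
#'   from CLASH must carry non-chimeric support upstream (see
#'   [build_clash_positives()]).
#' @param mirnas miRNA catalog.
#' @param utrs UTR catalog supplying the site sequences.
#' @param control a [duplex_control()] list.
#' @return an object of class `duplex_svm` with elements `weights`
#'   ([duplex_weights()], bias included), `trace` (per-iteration
#'   `||w_t - w_{t-1}||`), `control`, and training metadata. Methods:
#'   `print`, `summary`, `coef` (the weight object), `predict`, `plot`
#'   (convergence trace).
#' @export
duplex_svm <- function(examples, mirnas, utrs, control = duplex_control()) {
  stopifnot(inherits(control, "duplex_control"))
  pos <- examples[examples$label == "positive", , drop = FALSE]
  negpool <- examples[examples$label == "negative", , drop = FALSE]
  if (!nrow(pos) || !nrow(negpool)) {
    stopf("duplex_svm needs at least one positive and one negative example")
  }
  p_max <- control$p_max
  mseq <- mirnas$sequence[match(c(pos$mirna, negpool$mirna), mirnas$name)]
  if (anyNA(mseq)) stopf("examples reference miRNAs absent from the catalog")
  if (any(nchar(mirnas$sequence) > p_max)) {
    stopf("miRNA longer than p_max = %d in catalog", p_max)
  }
  all_ex <- rbind(pos, negpool)
  all_ex$.mirna_seq <- mseq
  all_ex$.site_seq <- site_sequence(all_ex, utrs)
  pos <- all_ex[seq_len(nrow(pos)), , drop = FALSE]
  negpool <- all_ex[nrow(pos) + seq_len(nrow(negpool)), , drop = FALSE]

  featurize_set <- function(set, w) {
    t(vapply(seq_len(nrow(set)), function(i) {
      align_featurize(w, set$.mirna_seq[i], set$.site_seq[i], p_max,
                      anchor = control$anchor)
    }, numeric(10L * p_max + 1L)))
  }

  w_init <- duplex_init_weights(p_max)
  C <- control$C
  if (control$tune_C) {
    C <- tune_duplex_C(pos, negpool, w_init, control)
  }

  w_cur <- w_init
  w_vec_prev <- duplex_weights_to_vector(w_cur)
  trace <- numeric(control$iterations)
  bias <- 0
  # working set of distinct negative-alignment feature vectors, keyed by
  # negative-pool row
  neg_cache_rows <- list()
  neg_cache_keys <- new.env(hash = TRUE)
  add_constraints <- function(phi_neg, ids) {
    added <- FALSE
    for (i in seq_len(nrow(phi_neg))) {
      nz <- which(phi_neg[i, ] != 0)
      key <- paste(ids[i], paste(nz, phi_neg[i, nz], collapse = ";"))
      if (is.null(neg_cache_keys[[key]])) {
        neg_cache_keys[[key]] <- TRUE
        neg_cache_rows[[length(neg_cache_rows) + 1L]] <<- phi_neg[i, ]
        added <- TRUE
      }
    }
    added
  }
  prev_neg_ids <- NULL
  for (it in seq_len(control$iterations)) {
    negs <- sample_negatives(pos, negpool,
                             clash_ratio = control$clash_neg_ratio,
                             clip_ratio = control$clip_neg_ratio,
                             rng_seed = (control$rng_seed * 131L + it) %%
                               .Machine$integer.max)
    # impute the positives' latent alignments under the current weights
    phi_pos <- featurize_set(pos, w_cur)
    add_constraints(featurize_set(negs, w_cur), rownames(negs))
    # solve the convex subproblem: the negative hinge loss is a max over
    # alignments, handled by constraint generation until no negative
    # alignment under the refit weights is new
    fit <- NULL
    complete <- FALSE
    for (inner in seq_len(5L)) {
      phi <- rbind(phi_pos, do.call(rbind, neg_cache_rows))
      lab <- c(rep("positive", nrow(phi_pos)),
               rep("negative", length(neg_cache_rows)))
      fit <- fit_linear_svm(phi, lab, C)
      w_fit <- duplex_weights_from_vector(fit$w, p_max = p_max, bias = fit$b)
      if (!add_constraints(featurize_set(negs, w_fit), rownames(negs))) {
        complete <- TRUE
        break
      }
    }
    trace[it] <- sqrt(sum((fit$w - w_vec_prev)^2))
    w_vec_prev <- fit$w
    bias <- fit$b
    w_cur <- duplex_weights_from_vector(fit$w, p_max = p_max, bias = fit$b)
    # exact fixed point with an unchanged negative sample: the remaining
    # iterations are provably identical, so their trace entries are zero
    if (complete && trace[it] == 0 &&
        identical(rownames(negs), prev_neg_ids)) {
      break
    }
    prev_neg_ids <- rownames(negs)
  }
  structure(list(weights = w_cur, trace = trace, control = control, C = C,
                 n_pos = nrow(pos), n_neg_pool = nrow(negpool),
                 converged = trace[control$iterations] <=
                   0.01 * sqrt(sum(w_vec_prev^2))),
            class = "duplex_svm")
}

tune_duplex_C <- function(pos, negpool, w_init, control) {
  grid <- c(0.01, 0.1, 1, 10)
  negs <- sample_negatives(pos, negpool,
                           clash_ratio = control$clash_neg_ratio,
                           clip_ratio = control$clip_neg_ratio,
                           rng_seed = control$rng_seed)
  set <- rbind(pos, negs)
  phi <- t(vapply(seq_len(nrow(set)), function(i) {
    featurize(align_duplex(w_init, set$.mirna_seq[i], set$.site_seq[i],
                           anchor = control$anchor), p_max = control$p_max)
  }, numeric(10L * control$p_max + 1L)))
  rng <- local_rng(control$rng_seed)
  fold <- rng$sample(rep_len(seq_len(5L), nrow(set)))
  perf <- vapply(grid, function(C) {
    mean(vapply(seq_len(5L), function(k) {
      tr <- fold != k
      if (length(unique(set$label[tr])) < 2L ||
          length(unique(set$label[!tr])) < 2L) return(NA_real_)
      fit <- fit_linear_svm(phi[tr, , drop = FALSE], set$label[tr], C)
      f <- drop(phi[!tr, , drop = FALSE] %*% fit$w) + fit$b
      auroc(f[set$label[!tr] == "positive"], f[set$label[!tr] == "negative"])
    }, numeric(1L)), na.rm = TRUE)
  }, numeric(1L))
  grid[which.max(perf)]
}

#' Score a single (miRNA, site) pair under a trained duplex model
#'
#' The score is the optimal alignment score under the learned weights plus
#' the model bias.
#'
#' @param model a fitted `duplex_svm`.
#' @param mirna miRNA sequence.
#' @param site site sequence.
#' @return numeric scalar.
#' @export
score_pair <- function(model, mirna, site) {
  stopifnot(inherits(model, "duplex_svm"))
  align_duplex(model$weights, mirna, site,
               anchor = model$control$anchor)$score + model$weights$bias
}

#' Rank candidate miRNAs against one site
#'
#' @param model a fitted `duplex_svm`.
#' @param mirnas miRNA catalog.
#' @param site site sequence.
#' @return catalog rows ordered by descending score (ties stable by name),
#'   with a `score` column.
#' @export
rank_mirnas <- function(model, mirnas, site) {
  sc <- vapply(mirnas$sequence, function(m) score_pair(model, m, site),
               numeric(1L), USE.NAMES = FALSE)
  out <- mirnas
  out$score <- sc
  out[order(-sc, mirnas$name), , drop = FALSE]
}

#' @export
predict.duplex_svm <- function(object, examples, mirnas, utrs, ...) {
  mseq <- mirnas$sequence[match(examples$mirna, mirnas$name)]
  sseq <- site_sequence(examples, utrs)
  vapply(seq_along(mseq), function(i) score_pair(object, mseq[i], sseq[i]),
         numeric(1L))
}

#' @export
coef.duplex_svm <- function(object, ...) object$weights

#' @export
print.duplex_svm <- function(x, ...) {
  cat("Duplex alignment model (structural SVM)\n")
  cat(sprintf("  %d positives, negative pool of %d; C = %g; %d iterations\n",
              x$n_pos, x$n_neg_pool, x$C, x$control$iterations))
  cat(sprintf("  final ||w_t - w_(t-1)|| = %.4g (%s)\n",
              x$trace[length(x$trace)],
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
summary.duplex_svm <- function(object, ...) {
  print(object)
  w <- object$weights
  cat("  seed-region (pos 2-8) mean pair scores:\n")
  print(round(rowMeans(w$pair[, 2:min(8, w$p_max)]), 3))
  cat(sprintf("  m1A = %.3f\n", w$m1A))
  invisible(object)
}

#' @export
plot.duplex_svm <- function(x, ...) {
  graphics::plot(seq_along(x$trace), x$trace, type = "b", xlab = "iteration",
                 ylab = expression("||" * w[t] - w[t - 1] * "||"),
                 main = "Duplex model convergence", ...)
  invisible(x)
}

#' Serialize / restore a fitted duplex model
#'
#' @param model a `duplex_svm`.
#' @param path JSON file path.
#' @export
write_duplex_model <- function(model, path) {
  w <- model$weights
  obj <- list(format = "mirduplex/duplex_model", version = 1L,
              p_max = w$p_max, pair = as.data.frame(t(w$pair)), m1A = w$m1A,
              open = w$open, sym = w$sym, asym = w$asym, paired = w$paired,
              bias = w$bias, trace = model$trace, C = model$C,
              n_pos = model$n_pos, n_neg_pool = model$n_neg_pool,
              rng_seed = model$control$rng_seed,
              iterations = model$control$iterations,
              anchor = model$control$anchor)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_duplex_model
#' @export
read_duplex_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "mirduplex/duplex_model")) {
    stopf("%s is not a duplex model file", path)
  }
  pair <- t(as.matrix(obj$pair))
  dimnames(pair) <- list(PAIR_TYPES, NULL)
  w <- duplex_weights(p_max = obj$p_max, pair = pair, m1A = obj$m1A,
                      open = obj$open, sym = obj$sym, asym = obj$asym,
                      paired = obj$paired, bias = obj$bias)
  ctl <- duplex_control(C = obj$C, iterations = obj$iterations,
                        rng_seed = obj$rng_seed, anchor = obj$anchor)
  structure(list(weights = w, trace = obj$trace, control = ctl, C = obj$C,
                 n_pos = obj$n_pos, n_neg_pool = obj$n_neg_pool,
                 converged = obj$trace[length(obj$trace)] <=
                   0.01 * sqrt(sum(duplex_weights_to_vector(w)^2))),
            class = "duplex_svm")
}
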