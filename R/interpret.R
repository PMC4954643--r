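# model interpretation: explicit positional k-mer weights, POIMs,
# per-position score decomposition, probe-set motif enrichment with
# label-permutation FDR

#' Explicit positional k-mer weights of a binding model
#'
#' The weighted-degree kernel's feature map is finite, so the dual solution
#' can be expanded into explicit weights: the weight of k-mer `z` at flank
#' position `j` is `beta_k sum_i alpha_i y_i tau_i 1[x_i carries z at j]`
#' (per flank, divided by the component's trace-normalization constant),
#' where `tau_i` is `mu` for the common model or `mu + 1[task_i = t]` for a
#' task model.
#'
#' @param model a fitted `binding_svm`.
#' @param mode `"common"` or a task id.
#' @return list with data frames `up` and `down` (`k, j, kmer, weight`) and
#'   attribute `flank_width`.
#' @export
effective_linear_weights <- function(model, mode = "common") {
  coefw <- model$alpha_y * task_weights(model, mode)
  sv <- which(coefw != 0)
  out <- list()
  for (flank in c("up", "down")) {
    key <- if (flank == "up") "upstream" else "downstream"
    codes <- flank_code_matrix(vapply(model$flanks, `[[`, "", key))
    scale <- model$scales[[paste0("wd_", flank)]]
    rows <- list()
    if (length(sv)) {
      for (k in seq_len(model$degree)) {
        km <- kmer_code_matrix(codes[sv, , drop = FALSE], k)
        for (j in seq_len(ncol(km))) {
          cj <- km[, j]
          ok <- !is.na(cj)
          if (!any(ok)) next
          w <- rowsum(coefw[sv][ok], cj[ok])
          rows[[length(rows) + 1L]] <- data.frame(
            k = k, j = j, code = as.integer(rownames(w)),
            weight = model$beta[k] * as.vector(w) / scale)
        }
      }
    }
    df <- if (length(rows)) do.call(rbind, rows) else {
      data.frame(k = integer(), j = integer(), code = integer(),
                 weight = numeric())
    }
    df <- df[df$weight != 0, , drop = FALSE]
    df$kmer <- kmer_from_code(df$code, df$k)
    rownames(df) <- NULL
    out[[flank]] <- df
  }
  attr(out, "flank_width") <- model$control$flank_width
  attr(out, "mode") <- mode
  out
}

task_weights <- function(model, mode) {
  if (!model$multitask) return(rep(1, length(model$alpha_y)))
  if (identical(mode, "common")) return(rep(model$mu, length(model$alpha_y)))
  if (!mode %in% model$task_registry) stopf("unknown task id '%s'", mode)
  model$mu + (model$tasks == mode)
}

kmer_from_code <- function(code, k) {
  if (!length(code)) return(character())
  vapply(seq_along(code), function(i) {
    d <- integer(k[i])
    c0 <- code[i]
    for (pos in seq_len(k[i])) {
      d[pos] <- (c0 %/% 4^(k[i] - pos)) %% 4
    }
    paste(RNA_BASES[d + 1L], collapse = "")
  }, character(1L))
}

all_kmers <- function(k) {
  kmer_from_code(seq_len(4^k) - 1L, rep(k, 4^k))
}

# flank score of one sequence under an explicit weight table
flank_score_from_weights <- function(wdf, flank_seq) {
  codes <- flank_code_matrix(flank_seq)
  total <- 0
  for (k in unique(wdf$k)) {
    km <- kmer_code_matrix(codes, k)
    sub <- wdf[wdf$k == k, , drop = FALSE]
    hit <- km[1L, sub$j]
    total <- total + sum(sub$weight[!is.na(hit) & hit == sub$code])
  }
  total
}

#' Positional oligomer importance matrix
#'
#' For each k-mer `z` and position `j`, `Q(z, j)` is the expected change of
#' the model's effective linear flank score when `z` is clamped at `j`,
#' relative to the unconditional expectation under a uniform i.i.d.
#' background over `{A, C, G, U}`. Computed exactly from the explicit
#' positional k-mer weights (sub-, super- and partially overlapping k-mers
#' all contribute through their conditional match probabilities). The
#' differential summary `D[j] = max_z Q(z, j) - min_z Q(z, j)` ranks
#' positions.
#'
#' @param model a fitted `binding_svm` (or a weight table from
#'   [effective_linear_weights()]).
#' @param k oligomer length, 1-6.
#' @param flank `"up"` or `"down"`.
#' @param mode `"common"` or a task id.
#' @return object of class `poim`: list with matrix `Q` (rows = k-mers,
#'   columns = positions), vector `D`, `k` and `flank`.
#' @export
compute_poim <- function(model, k, flank = c("up", "down"), mode = "common") {
  flank <- match.arg(flank)
  stopifnot(k >= 1L, k <= 6L)
  if (inherits(model, "binding_svm")) {
    wdf <- effective_linear_weights(model, mode)[[flank]]
    L <- model$control$flank_width
  } else {
    wdf <- model[[flank]]
    L <- attr(model, "flank_width")
  }
  Q <- poim_matrix(wdf, k, L)
  structure(list(Q = Q, D = apply(Q, 2, max) - apply(Q, 2, min), k = k,
                 flank = flank), class = "poim")
}

poim_matrix <- function(wdf, k, L, cols = NULL) {
  ncell <- 4^k
  ncols <- L - k + 1L
  cols <- cols %||% seq_len(ncols)
  Q <- matrix(0, ncell, ncols,
              dimnames = list(all_kmers(k), seq_len(ncols)))
  if (!nrow(wdf)) return(Q)
  groups <- split(seq_len(nrow(wdf)), paste(wdf$j, wdf$k))
  for (g in groups) {
    jp <- wdf$j[g[1L]]
    kp <- wdf$k[g[1L]]
    wts <- wdf$weight[g]
    codes <- wdf$code[g]
    # letters matrix of the group's k-mers (g x kp), digits 0..3
    letters <- matrix(0L, length(g), kp)
    c0 <- codes
    for (pos in seq_len(kp)) {
      letters[, pos] <- (c0 %/% 4^(kp - pos)) %% 4
    }
    for (j in cols) {
      # overlap between the clamped window [j, j+k) and the feature window
      a <- max(1L, jp - j + 1L)
      b <- min(k, jp + kp - 1L - j + 1L)
      if (a > b) next  # disjoint windows cancel in Q
      ov <- b - a + 1L
      # fixed digit block: z positions a..b must equal feature letters
      v <- numeric(length(g))
      for (i in a:b) {
        v <- v + letters[, i + (j - jp)] * 4^(k - i)
      }
      nP <- 4^(a - 1L)
      nS <- 4^(k - b)
      offs <- as.vector(outer((seq_len(nP) - 1L) * 4^(k - a + 1L),
                              seq_len(nS) - 1L, "+"))
      idx <- as.vector(outer(v, offs, "+")) + 1
      add <- rowsum(rep(wts * 4^(-(kp - ov)), times = length(offs)), idx)
      ii <- as.integer(rownames(add))
      Q[ii, j] <- Q[ii, j] + as.vector(add)
      Q[, j] <- Q[, j] - sum(wts) * 4^(-kp)
    }
  }
  Q
}

#' @export
print.poim <- function(x, ...) {
  cat(sprintf("POIM: %d-mers, %s flank, %d positions\n", x$k, x$flank,
              ncol(x$Q)))
  j <- which.max(x$D)
  cat(sprintf("  max differential %.4g at position %d (top k-mer %s)\n",
              x$D[j], j, rownames(x$Q)[which.max(x$Q[, j])]))
  invisible(x)
}

#' Top POIM k-mers at the most discriminative position
#'
#' Chooses the positional 5- or 6-mer (by default) with the highest
#' differential POIM weight over the supplied POIMs and returns the
#' `n_top` k-mers with highest importance at that position, descending
#' (ties lexicographic).
#'
#' @param poims list of `poim` objects (any mix of k and flank).
#' @param n_top number of k-mers to return (default 15).
#' @return list `k, flank, position, kmers, weights`.
#' @export
top_kmers <- function(poims, n_top = 15L) {
  if (inherits(poims, "poim")) poims <- list(poims)
  best <- NULL
  for (p in poims) {
    j <- which.max(p$D)
    if (is.null(best) || p$D[j] > best$D) {
      best <- list(poim = p, j = j, D = p$D[j])
    }
  }
  p <- best$poim
  q <- p$Q[, best$j]
  ord <- order(-q, names(q))
  take <- utils::head(ord, n_top)
  list(k = p$k, flank = p$flank, position = best$j,
       kmers = names(q)[take], weights = unname(q[take]))
}

#' Per-position decomposition of a binding-model score
#'
#' Splits the discriminant of one example into flank-position
#' contributions: by default position `j` receives the summed weights of
#' all k-mers starting at `j` that occur in the flank
#' (`position = "cover"` instead spreads each k-mer's weight uniformly over
#' the positions it covers). Contributions plus the positional-kernel part
#' and the bias reproduce the full discriminant.
#'
#' @param model a fitted `binding_svm`.
#' @param example one labeled-site row.
#' @param utrs UTR catalog.
#' @param mode `"common"` or a task id.
#' @param position attribution convention, `"start"` or `"cover"`.
#' @param weights optional precomputed [effective_linear_weights()] for
#'   `mode` (avoids re-deriving them when decomposing many examples).
#' @return list `up`, `down` (per-position contribution vectors),
#'   `positional`, `bias`, `total`.
#' @export
decompose_score <- function(model, example, utrs, mode = "common",
                            position = c("start", "cover"),
                            weights = NULL) {
  position <- match.arg(position)
  ew <- weights %||% effective_linear_weights(model, mode)
  feats <- binding_features(example, utrs, model$control)
  L <- model$control$flank_width
  out <- list()
  for (flank in c("up", "down")) {
    key <- if (flank == "up") "upstream" else "downstream"
    seqs <- feats$flanks[[1L]][[key]]
    codes <- flank_code_matrix(seqs)
    contrib <- numeric(L)
    wdf <- ew[[flank]]
    for (k in unique(wdf$k)) {
      km <- kmer_code_matrix(codes, k)
      sub <- wdf[wdf$k == k, , drop = FALSE]
      hit <- km[1L, sub$j]
      m <- !is.na(hit) & hit == sub$code
      if (!any(m)) next
      if (position == "start") {
        add <- rowsum(sub$weight[m], sub$j[m])
        contrib[as.integer(rownames(add))] <-
          contrib[as.integer(rownames(add))] + as.vector(add)
      } else {
        for (i in which(m)) {
          span <- sub$j[i]:(sub$j[i] + k - 1L)
          contrib[span] <- contrib[span] + sub$weight[i] / k
        }
      }
    }
    out[[flank]] <- contrib
  }
  coefw <- model$alpha_y * task_weights(model, mode)
  pos_part <- if (model$control$use_positional) {
    drop(rbf_kernel_matrix(context_matrix(feats$contexts),
                           context_matrix(model$contexts), model$gamma) %*%
           coefw) / model$scales[["positional"]]
  } else 0
  out$positional <- pos_part
  out$bias <- model$bias
  out$total <- sum(out$up) + sum(out$down) + pos_part + model$bias
  out
}

#' Rank-sum enrichment of k-mers in high-intensity probes
#'
#' Selects the `n_top_probes` highest-intensity probes of one experiment
#' and compares, by a one-sided Wilcoxon rank-sum test, the intensities of
#' probes containing at least one of the k-mers against probes containing
#' none (alternative: containing probes have higher intensity). The exact
#' null distribution is used when both groups have fewer than 50 probes
#' (falling back to the normal approximation under ties), the
#' continuity-corrected normal approximation otherwise. With
#' `restrict_to_top = FALSE` the groups are formed over all probes
#' instead.
#'
#' @param probe_table data frame `probe_sequence, intensity` (one
#'   RNAcompete-style experiment).
#' @param kmers character vector of RNA k-mers.
#' @param n_top_probes number of top probes selected (default 1000).
#' @param restrict_to_top test within the top probe set (default) or over
#'   all probes.
#' @param experiment_id carried through to the result.
#' @return object of class `enrichment_result`: `experiment_id, statistic,
#'   p, n_with, n_without, kmers, degenerate`.
#' @export
kmer_enrichment <- function(probe_table, kmers, n_top_probes = 1000L,
                            restrict_to_top = TRUE, experiment_id = NA) {
  if (nrow(probe_table) < n_top_probes) {
    stopf("probe table has %d probes, need at least %d", nrow(probe_table),
          n_top_probes)
  }
  ord <- order(-probe_table$intensity)
  top <- probe_table[ord[seq_len(n_top_probes)], , drop = FALSE]
  pool <- if (restrict_to_top) top else probe_table
  has <- Reduce(`|`, lapply(kmers, function(z) {
    grepl(z, pool$probe_sequence, fixed = TRUE)
  }))
  x <- pool$intensity[has]
  y <- pool$intensity[!has]
  if (!length(x) || !length(y)) {
    return(structure(list(experiment_id = experiment_id, statistic = NA_real_,
                          p = 1, n_with = length(x), n_without = length(y),
                          kmers = kmers, degenerate = TRUE),
                     class = "enrichment_result"))
  }
  exact <- length(x) < 50L && length(y) < 50L
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "greater", exact = exact,
                       correct = TRUE))
  structure(list(experiment_id = experiment_id,
                 statistic = unname(wt$statistic), p = wt$p.value,
                 n_with = length(x), n_without = length(y), kmers = kmers,
                 degenerate = FALSE),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("k-mer enrichment [%s]: W = %s, p = %.4g (%d with / %d without)%s\n",
              x$experiment_id, format(x$statistic), x$p, x$n_with,
              x$n_without, if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

# refit the binding SVM on the stored training kernel with new labels
refit_binding_labels <- function(model, labels) {
  K <- if (model$multitask) {
    multitask_kernel(model$train_kernel, model$tasks, model$mu)
  } else model$train_kernel
  fit <- fit_kernel_svm(K, labels, model$control$C)
  m2 <- model
  m2$alpha_y <- fit$alpha_y
  m2$bias <- fit$bias
  m2
}

#' Label-permutation empirical FDR for a POIM enrichment p-value
#'
#' Re-trains the binding SVM `n_perm` times with permuted class labels,
#' extracts the top POIM k-mers at the same (k, position, flank) as the
#' real model, tests their enrichment in the same probe table, and converts
#' the observed p-value to its empirical quantile in the null p
#' distribution: `FDR = (1 + #{null p <= observed p}) / (n_perm + 1)`.
#'
#' @param observed_p enrichment p-value of the real model's k-mers.
#' @param model the fitted `binding_svm` (its stored training kernel is
#'   reused; the kernel does not depend on the labels).
#' @param probe_table the probe table tested.
#' @param k,position,flank the POIM coordinates of the real top k-mer set.
#' @param n_perm number of permutations (1000 for full runs; smaller values
#'   for quick checks).
#' @param rng_seed seed for the permutations.
#' @param n_top k-mers extracted per null model.
#' @param n_top_probes probe-set size for the enrichment test.
#' @param mode scoring mode used for the null POIMs.
#' @return list `fdr`, `null_p` (length `n_perm`).
#' @export
empirical_fdr <- function(observed_p, model, probe_table, k, position, flank,
                          n_perm = 1000L, rng_seed = 1L, n_top = 15L,
                          n_top_probes = 1000L, mode = "common") {
  stopifnot(n_perm >= 1L)
  rng <- local_rng(rng_seed)
  labels <- model$examples$label
  # precompute the positional k-mer codes once: only features overlapping
  # the clamped window [position, position + k) contribute to that POIM
  # column, and label permutations change only the dual coefficients
  key <- if (flank == "up") "upstream" else "downstream"
  codes <- flank_code_matrix(vapply(model$flanks, `[[`, "", key))
  scale <- model$scales[[paste0("wd_", flank)]]
  km_by_k <- lapply(seq_len(model$degree), function(kp) {
    km <- kmer_code_matrix(codes, kp)
    js <- max(1L, position - kp + 1L):min(ncol(km), position + k - 1L)
    list(js = js, km = km[, js, drop = FALSE])
  })
  weights_for <- function(coefw) {
    rows <- list()
    for (kp in seq_len(model$degree)) {
      km <- km_by_k[[kp]]
      for (ci in seq_along(km$js)) {
        cj <- km$km[, ci]
        ok <- !is.na(cj) & coefw != 0
        if (!any(ok)) next
        w <- rowsum(coefw[ok], cj[ok])
        rows[[length(rows) + 1L]] <- data.frame(
          k = kp, j = km$js[ci], code = as.integer(rownames(w)),
          weight = model$beta[kp] * as.vector(w) / scale)
      }
    }
    if (!length(rows)) {
      return(data.frame(k = integer(), j = integer(), code = integer(),
                        weight = numeric()))
    }
    do.call(rbind, rows)
  }
  null_p <- vapply(seq_len(n_perm), function(i) {
    perm <- rng$sample(labels)
    m2 <- refit_binding_labels(model, perm)
    wdf <- weights_for(m2$alpha_y * task_weights(m2, mode))
    Q <- poim_matrix(wdf, k, model$control$flank_width, cols = position)
    q <- Q[, position]
    take <- utils::head(order(-q, names(q)), n_top)
    kmer_enrichment(probe_table, names(q)[take],
                    n_top_probes = n_top_probes)$p
  }, numeric(1L))
  list(fdr = (1 + sum(null_p <= observed_p)) / (n_perm + 1), null_p = null_p)
}

#' Positional distribution of sites within 3'UTR isoforms
#'
#' For each class, distances from the anchor (position opposite miRNA
#' nucleotide 2) to the UTR start, to the next isoform 3' end and to the
#' previous one, with a two-sample Kolmogorov-Smirnov comparison between
#' classes per axis.
#'
#' @param examples labeled-site data frame with anchors.
#' @param utrs UTR catalog.
#' @param breaks histogram breaks (passed to [graphics::hist()] logic via
#'   [base::cut()]); default 20 equal bins per axis.
#' @return list with `distances` (long data frame: `label, axis, value`),
#'   `histograms` (per axis, per class bin counts), and `ks` (per-axis KS
#'   statistic and p-value).
#' @export
site_position_profile <- function(examples, utrs, breaks = 20L) {
  idx <- match(examples$transcript_id, utrs$transcript_id)
  rows <- lapply(seq_len(nrow(examples)), function(i) {
    ctx <- positional_context(utrs[idx[i], ], examples$anchor[i])
    data.frame(label = examples$label[i],
               axis = c("d_stop", "d_next_end", "d_prev_end"),
               value = c(ctx$d_stop, ctx$d_next_end,
                         if (ctx$prev_is_sentinel) NA_real_ else
                           ctx$d_prev_end),
               stringsAsFactors = FALSE)
  })
  dist <- do.call(rbind, rows)
  dist <- dist[!is.na(dist$value), , drop = FALSE]
  axes <- unique(dist$axis)
  hist_out <- list()
  ks_rows <- list()
  for (ax in axes) {
    d <- dist[dist$axis == ax, ]
    brks <- pretty(range(d$value), n = breaks)
    tab <- table(d$label, cut(d$value, brks, include.lowest = TRUE))
    hist_out[[ax]] <- tab
    pos <- d$value[d$label == "positive"]
    neg <- d$value[d$label == "negative"]
    if (length(pos) && length(neg)) {
      if (all(pos == neg[1]) && all(neg == neg[1])) {
        ks_rows[[ax]] <- data.frame(axis = ax, statistic = 0, p = 1)
      } else {
        kt <- suppressWarnings(stats::ks.test(pos, neg))
        ks_rows[[ax]] <- data.frame(axis = ax,
                                    statistic = unname(kt$statistic),
                                    p = kt$p.value)
      }
    }
  }
  list(distances = dist, histograms = hist_out,
       ks = do.call(rbind, ks_rows))
}
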