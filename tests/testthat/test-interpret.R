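# interpretation: effective linear weights, POIM exactness, decomposition,
# enrichment test and permutation FDR

# direct scorer over an explicit positional k-mer weight table (oracle)
oracle_flank_scores <- function(wdf, seqs) {
  total <- numeric(length(seqs))
  for (r in seq_len(nrow(wdf))) {
    km <- wdf$kmer[r]
    hit <- substr(seqs, wdf$j[r], wdf$j[r] + wdf$k[r] - 1L) == km
    total <- total + wdf$weight[r] * hit
  }
  total
}

small_weight_table <- function(seed = 5, L = 8L, n_feat = 12L) {
  set.seed(seed)
  rows <- lapply(seq_len(n_feat), function(i) {
    k <- sample(1:3, 1)
    j <- sample(L - k + 1L, 1)
    kmer <- random_rna_string(k)
    data.frame(k = k, j = j, kmer = kmer, weight = rnorm(1))
  })
  empty <- data.frame(k = integer(), j = integer(), kmer = character(),
                      weight = numeric())
  df <- if (length(rows)) do.call(rbind, rows) else empty
  df$code <- vapply(seq_len(nrow(df)), function(i) {
    sum((match(strsplit(df$kmer[i], "")[[1]], c("A", "C", "G", "U")) - 1L) *
          4^((df$k[i] - 1L):0))
  }, numeric(1))
  out <- list(up = df, down = df[0, ])
  attr(out, "flank_width") <- L
  out
}

test_that("POIM of a single positional 6-mer weight peaks at that feature", {
  wdf <- list(up = data.frame(k = 6L, j = 11L, code = 0L, weight = 2.5,
                              kmer = "AAAAAA"),
              down = data.frame(k = integer(), j = integer(),
                                code = integer(), weight = numeric(),
                                kmer = character()))
  attr(wdf, "flank_width") <- 30L
  p <- compute_poim(wdf, 6L, "up")
  idx <- which(p$Q == max(p$Q), arr.ind = TRUE)
  expect_equal(rownames(p$Q)[idx[1]], "AAAAAA")
  expect_equal(unname(idx[2]), 11L)
  expect_equal(unname(which.max(p$D)), 11L)
  # all-zero weights give the all-zero POIM
  p0 <- compute_poim(small_weight_table(n_feat = 0L), 2L, "up")
  expect_true(all(p0$Q == 0))
})

test_that("POIM columns are centered and match Monte-Carlo estimates", {
  wdf <- small_weight_table()
  for (k in 1:2) {
    p <- compute_poim(wdf, k, "up")
    expect_lt(max(abs(colSums(p$Q) / 4^k)), 1e-9)
    set.seed(99)
    n <- 40000L
    seqs <- vapply(seq_len(n), function(i) random_rna_string(8L), "")
    f_free <- oracle_flank_scores(wdf$up, seqs)
    for (j in c(1L, 3L)) {
      for (z in sample(rownames(p$Q), 3L)) {
        planted <- seqs
        substr(planted, j, j + k - 1L) <- z
        fz <- oracle_flank_scores(wdf$up, planted)
        est <- mean(fz) - mean(f_free)
        se <- sqrt(var(fz) / n + var(f_free) / n)
        expect_lt(abs(p$Q[z, j] - est), 3 * se + 1e-6)
      }
    }
  }
})

test_that("top k-mer extraction picks the max-differential position", {
  wdf <- list(up = data.frame(k = 5L, j = 3L, code = 77L, weight = 1,
                              kmer = kmer_from_code_test(77L, 5L)),
              down = data.frame(k = 6L, j = 9L, code = 1234L, weight = 4,
                                kmer = kmer_from_code_test(1234L, 6L)))
  attr(wdf, "flank_width") <- 30L
  poims <- list(compute_poim(wdf, 5L, "up"), compute_poim(wdf, 6L, "up"),
                compute_poim(wdf, 5L, "down"), compute_poim(wdf, 6L, "down"))
  top <- top_kmers(poims)
  expect_equal(top$k, 6L)
  expect_equal(top$flank, "down")
  expect_equal(unname(top$position), 9L)
  expect_equal(top$kmers[1], kmer_from_code_test(1234L, 6L))
  expect_length(top$kmers, 15L)  # default n_top
  # deterministic under exact ties: lexicographic among equal weights
  expect_identical(top$kmers, top_kmers(poims)$kmers)
  expect_false(is.unsorted(rev(top$weights)))
})

test_that("effective weights reconstruct the discriminant and scale in alpha", {
  mm <- make_binding_model(seed = 31)
  fx <- mm$fx
  fit <- mm$fit
  ew <- effective_linear_weights(fit, "common")
  sub <- fx$examples[seq(1, nrow(fx$examples), by = 11), ]
  feats <- mirduplex:::binding_features(sub, fx$utrs, fit$control)
  up <- vapply(feats$flanks, `[[`, "", "upstream")
  down <- vapply(feats$flanks, `[[`, "", "downstream")
  coefw <- fit$alpha_y * fit$mu
  pos_part <- drop(mirduplex:::rbf_kernel_matrix(
    mirduplex:::context_matrix(feats$contexts),
    mirduplex:::context_matrix(fit$contexts), fit$gamma) %*% coefw) /
    fit$scales[["positional"]]
  manual <- oracle_flank_scores(ew$up, up) + oracle_flank_scores(ew$down, down) +
    pos_part + fit$bias
  expect_equal(manual, predict_binding(fit, sub, fx$utrs, "common"),
               tolerance = 1e-6)
  # linear scaling in the dual coefficients
  f2 <- fit
  f2$alpha_y <- 2 * fit$alpha_y
  ew2 <- effective_linear_weights(f2, "common")
  expect_equal(ew2$up$weight, 2 * ew$up$weight)
  # zero coefficients give an empty weight map
  f0 <- fit
  f0$alpha_y <- 0 * fit$alpha_y
  expect_equal(nrow(effective_linear_weights(f0, "common")$up), 0L)
})

test_that("score decomposition reproduces the discriminant per example", {
  mm <- make_binding_model(seed = 31)
  fx <- mm$fx
  fit <- mm$fit
  sub <- fx$examples[seq(1, nrow(fx$examples), by = 17), ]
  f <- predict_binding(fit, sub, fx$utrs, "common")
  for (i in seq_len(nrow(sub))) {
    dec <- decompose_score(fit, sub[i, ], fx$utrs, mode = "common")
    expect_lt(abs(dec$total - f[i]), 1e-9)
    dec2 <- decompose_score(fit, sub[i, ], fx$utrs, mode = "common",
                            position = "cover")
    expect_lt(abs(dec2$total - f[i]), 1e-9)
  }
  # planted motif shows up as a positive contribution block at its offset
  posx <- fx$examples[fx$examples$label == "positive", ]
  feats <- mirduplex:::binding_features(posx, fx$utrs, fit$control)
  down <- vapply(feats$flanks, `[[`, "", "downstream")
  carriers <- which(substr(down, 8, 13) == fx$cfg$motif)
  contrib <- vapply(carriers[1:10], function(i) {
    sum(decompose_score(fit, posx[i, ], fx$utrs)$down[8:13])
  }, numeric(1))
  expect_true(all(contrib > 0))
})

test_that("rank-sum enrichment matches exact permutation enumeration", {
  set.seed(6)
  # 24 probes, k-mer present only among the high-intensity ones
  motif <- "UGUACA"
  seqs <- vapply(1:24, function(i) random_rna_string(20), "")
  hot <- 1:6
  for (i in hot) substr(seqs[i], 5, 10) <- motif
  intens <- c(sort(runif(6, 2, 3), TRUE), runif(18, 0, 1))
  tab <- data.frame(probe_sequence = seqs, intensity = intens)
  res <- kmer_enrichment(tab, motif, n_top_probes = 24L)
  expect_false(res$degenerate)
  expect_lt(res$p, 0.01)
  # exact oracle: enumerate all assignments of the 6 'with' labels
  r <- rank(intens)
  obs <- sum(r[hot])
  combos <- combn(24, 6)
  null <- colSums(matrix(r[combos], nrow = 6))
  expect_equal(res$p, mean(null >= obs), tolerance = 1e-12)
  # k-mers absent from every probe: flagged, p = 1
  res2 <- kmer_enrichment(tab, "AAAAAAAAAAAA", n_top_probes = 24L)
  expect_true(res2$degenerate)
  expect_equal(res2$p, 1)
  expect_error(kmer_enrichment(tab, motif, n_top_probes = 100L),
               "at least")
})

test_that("empirical FDR is the null quantile and is seed-deterministic", {
  fx <- make_binding_fixture(seed = 41)
  ex <- fx$examples[seq(1, nrow(fx$examples), by = 3), ]
  fit <- binding_svm(ex, fx$utrs, binding_control(rng_seed = 1))
  tab <- simulate_probe_table(fx$cfg, n_probes = 300L, effect = 1)
  r1 <- empirical_fdr(1e-12, fit, tab, k = 6L, position = 8L,
                      flank = "down", n_perm = 5L, rng_seed = 3L,
                      n_top_probes = 200L)
  expect_equal(r1$fdr, 1 / 6)  # observed below every null p
  r2 <- empirical_fdr(1e-12, fit, tab, k = 6L, position = 8L,
                      flank = "down", n_perm = 5L, rng_seed = 3L,
                      n_top_probes = 200L)
  expect_identical(r1$null_p, r2$null_p)
  expect_equal(empirical_fdr(1, fit, tab, k = 6L, position = 8L,
                             flank = "down", n_perm = 5L, rng_seed = 3L,
                             n_top_probes = 200L)$fdr, 1)
})

test_that("site position profiles detect planted positional bias", {
  fx <- make_binding_fixture(seed = 51)
  prof <- site_position_profile(fx$examples, fx$utrs)
  # bin counts sum to the class sizes on the sentinel-free axes
  n_by_class <- table(fx$examples$label)
  expect_equal(sum(prof$histograms$d_stop),
               sum(n_by_class))
  expect_equal(sum(prof$histograms$d_next_end["positive", ]),
               unname(n_by_class["positive"]))
  ks <- prof$ks
  expect_lt(ks$p[ks$axis == "d_next_end"], 0.01)
  # identical class distributions give KS statistic 0
  ex0 <- fx$examples[fx$examples$label == "positive", ]
  ex0 <- rbind(ex0, transform(ex0, label = "negative"))
  prof0 <- site_position_profile(ex0, fx$utrs)
  expect_true(all(prof0$ks$statistic == 0))
})
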