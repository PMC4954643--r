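# binding model: flank extraction, kernels, multi-task structure,
# prediction identities, score combination

test_that("flanks are sliced with boundary padding and correct orientation", {
  u <- toy_utr(paste(rep(c("A", "C", "G", "U"), 25), collapse = ""))
  fl <- extract_flanks(u, list(match_start = 40L, match_end = 46L))
  expect_equal(fl$upstream, utr_substr(u$sequence, 10L, 40L))
  expect_equal(fl$downstream, utr_substr(u$sequence, 46L, 76L))
  expect_equal(nchar(fl$upstream), 30L)
  # near the UTR start: 27 pads then 3 real bases
  fl2 <- extract_flanks(u, list(match_start = 3L, match_end = 9L))
  expect_equal(fl2$upstream, paste0(strrep(".", 27), substr(u$sequence, 1, 3)))
  # geometry: the downstream base nearest the seed is opposite miRNA nt 1,
  # the upstream base nearest the seed opposite miRNA nt 8
  m <- toy_mirna_catalog()[1, ]
  site <- rna_revcomp(substr(m$sequence, 1L, 8L))  # pairs miRNA nt 1-8
  useq <- paste0(strrep("G", 20), site, strrep("C", 20))
  u3 <- toy_utr(useq)
  sm <- list(match_start = 21L, match_end = 27L)  # the seed hexamer part
  expect_equal(utr_substr(useq, 20L, 28L), site)
  fl3 <- extract_flanks(u3, sm)
  expect_equal(substr(fl3$downstream, 1L, 1L),
               rna_revcomp(substr(m$sequence, 1L, 1L)))
  expect_equal(substr(fl3$upstream, 30L, 30L),
               rna_revcomp(substr(m$sequence, 8L, 8L)))
})

test_that("wd kernel matches the closed self-match form and the oracle", {
  s <- paste(sample(c("A", "C", "G", "U"), 30, TRUE), collapse = "")
  expect_equal(wd_kernel(s, s), sum(wd_beta(6) * (31 - 1:6)))
  s2 <- chartr("ACGU", "UGCA", s)  # differs everywhere
  expect_equal(wd_kernel(s, s2), 0)
  expect_error(wd_kernel("ACGU", "ACG"), "length mismatch")
  set.seed(88)
  for (i in 1:60) {
    L <- 12L
    a <- random_rna_string(L)
    z <- random_rna_string(L)
    # force some shared k-mers
    if (i %% 2 == 0) substr(z, 3, 8) <- substr(a, 3, 8)
    expect_equal(wd_kernel(a, z, degree = 3L),
                 oracle_wd(a, z, degree = 3L), tolerance = 1e-12)
  }
  # pads never match, even against themselves
  expect_equal(wd_kernel(paste0("..", strrep("A", 10)),
                         paste0("..", strrep("A", 10)), degree = 2L),
               sum(wd_beta(2) * c(10, 9)))
})

test_that("positional kernel follows the RBF on log distances", {
  c1 <- list(d_stop = 0, d_next_end = 0, d_prev_end = 0,
             prev_is_sentinel = FALSE)
  expect_equal(positional_kernel(c1, c1, gamma = 2), 1.0)
  c2 <- list(d_stop = 9, d_next_end = 0, d_prev_end = 0,
             prev_is_sentinel = FALSE)  # log10(1+9) = 1
  expect_equal(positional_kernel(c1, c2, gamma = 0.5), exp(-0.5))
  expect_equal(positional_kernel(c1, c2, gamma = 1e-12), 1.0,
               tolerance = 1e-9)
  # sentinel flag separates otherwise identical transforms
  c3 <- c1
  c3$prev_is_sentinel <- TRUE
  expect_equal(positional_kernel(c1, c3, gamma = 1), exp(-1))
})

test_that("positional context distances derive from anchors and isoform ends", {
  u <- toy_utr(strrep("A", 500), ends = c(200L))
  ctx <- positional_context(u, 150L)
  expect_equal(ctx$d_stop, 150L)
  expect_equal(ctx$d_next_end, 50L)
  expect_true(ctx$prev_is_sentinel)
  expect_equal(ctx$d_prev_end, 150L)  # sentinel falls back to d_stop
  ctx2 <- positional_context(u, 350L)
  expect_equal(ctx2$d_next_end, 150L)
  expect_equal(ctx2$d_prev_end, 150L)
  expect_false(ctx2$prev_is_sentinel)
})

test_that("combined kernel is symmetric PSD with recoverable components", {
  set.seed(19)
  n <- 200L
  flanks <- lapply(seq_len(n), function(i) {
    list(upstream = random_rna_string(30), downstream = random_rna_string(30))
  })
  contexts <- lapply(seq_len(n), function(i) {
    list(d_stop = sample(0:2000, 1), d_next_end = sample(0:500, 1),
         d_prev_end = sample(0:500, 1), prev_is_sentinel = runif(1) < 0.3)
  })
  ck <- combined_kernel(flanks, contexts, normalize = "none")
  expect_named(ck$components, c("wd_up", "wd_down", "positional"))
  expect_equal(ck$K, ck$components$wd_up + ck$components$wd_down +
                 ck$components$positional)
  expect_equal(ck$K, t(ck$K))
  expect_gte(min(eigen(ck$K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  # unnormalized diagonal: self-wd(up) + self-wd(down) + 1
  i <- 7L
  expect_equal(ck$K[i, i],
               wd_kernel(flanks[[i]]$upstream, flanks[[i]]$upstream) +
                 wd_kernel(flanks[[i]]$downstream, flanks[[i]]$downstream) +
                 1)
  # trace normalization rescales each component to mean diagonal 1
  ckn <- combined_kernel(flanks, contexts, normalize = "trace")
  expect_equal(mean(diag(ckn$K)), 3, tolerance = 1e-9)
})

test_that("multi-task kernel weighting is exact and mu = 0 decouples tasks", {
  set.seed(3)
  K <- crossprod(matrix(rnorm(100), 10))
  tasks <- rep(c("a", "b"), each = 5)
  for (mu in c(0, 0.5, 1, 4)) {
    Km <- multitask_kernel(K, tasks, mu)
    same <- outer(tasks, tasks, "==")
    expect_equal(Km[same], (mu + 1) * K[same])
    expect_equal(Km[!same], mu * K[!same])
  }
  K0 <- multitask_kernel(K, tasks, 0)
  expect_true(all(K0[1:5, 6:10] == 0))
  expect_gte(min(eigen(multitask_kernel(K, tasks, 0.7), symmetric = TRUE,
                       only.values = TRUE)$values), -1e-8)
})

test_that("binding SVM prediction identities hold and are deterministic", {
  mm <- make_binding_model()
  fx <- mm$fx
  ex <- fx$examples
  fit <- mm$fit
  sub <- ex[seq(1, nrow(ex), by = 7), ]
  fc <- predict_binding(fit, sub, fx$utrs, mode = "common")
  expect_identical(fc, predict_binding(fit, sub, fx$utrs, mode = "common"))
  # f_t(x) - f_common(x) = sum over task-t support of alpha_i y_i K(x_i, x)
  t1 <- fit$task_registry[1]
  ft <- predict_binding(fit, sub, fx$utrs, mode = t1)
  feats <- mirduplex:::binding_features(sub, fx$utrs, fit$control)
  K <- mirduplex:::binding_cross_kernel(fit, feats$flanks, feats$contexts)
  intask <- fit$tasks == t1
  expect_equal(ft - fc, drop(K[, intask] %*% fit$alpha_y[intask]),
               tolerance = 1e-9)
  expect_error(predict_binding(fit, sub, fx$utrs, mode = "no-such-task"),
               "unknown task")
  # serialized model reproduces predictions exactly
  f <- tempfile(fileext = ".json")
  write_binding_model(fit, f)
  back <- read_binding_model(f)
  expect_equal(predict_binding(back, sub, fx$utrs, mode = "common"), fc,
               tolerance = 1e-12)
})

test_that("large mu makes task and common rankings converge", {
  fx <- make_binding_fixture()
  ex <- fx$examples
  sub <- ex[seq(1, nrow(ex), by = 5), ]
  cors <- vapply(c(0.25, 100), function(mu) {
    fit <- binding_svm(ex, fx$utrs, binding_control(mu = mu, rng_seed = 1))
    fc <- predict_binding(fit, sub, fx$utrs, mode = "common")
    ft <- predict_binding(fit, sub, fx$utrs, mode = fit$task_registry[1])
    cor(fc, ft, method = "spearman")
  }, numeric(1))
  expect_gt(cors[2], cors[1])
  expect_gt(cors[2], 0.99)
})

test_that("single-task input falls back with a warning", {
  fx <- make_binding_fixture()
  ex <- fx$examples[fx$examples$task == "task-1", ]
  expect_warning(fit <- binding_svm(ex, fx$utrs,
                                    binding_control(mu = 4, rng_seed = 1)),
                 "single-task")
  expect_false(fit$multitask)
  # degenerate single-class task errors
  expect_error(binding_svm(ex[ex$label == "positive", ], fx$utrs),
               "lacks one of the classes")
})

test_that("score combination schemes behave as documented", {
  cal <- list(d_mean = 1, d_sd = 2, b_mean = 0, b_sd = 1)
  expect_equal(combine_scores(3, 1, "sum_z", cal), 2)  # z = (1, 1)
  expect_error(combine_scores(1, 1, "sum_z"), "calibration")
  d <- c(3, 1, 2)
  b <- c(0.1, 0.9, 0.5)
  expect_equal(combine_scores(d, b, "min_rank"), pmin(rank(d), rank(b)) / 3)
  expect_equal(combine_scores(d, b, "product_rank"),
               rank(d) * rank(b) / 9)
  cal2 <- fit_score_calibration(c(0, 2), c(1, 3))
  expect_equal(cal2$d_mean, 1)
  expect_equal(cal2$b_sd, sd(c(1, 3)))
})

test_that("gene-level score is the maximum over the gene's sites", {
  s <- c(2.0, 3.5, -1, 0.7)
  g <- c("g1", "g1", "g1", "g2")
  out <- gene_level_score(s, g)
  expect_equal(unname(out["g1"]), 3.5)
  expect_equal(unname(out["g2"]), 0.7)
  expect_equal(unname(gene_level_score(c(1, 1), c("a", "a"))["a"]), 1)
})
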