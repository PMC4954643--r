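# shared binding-model fixture built from the synthetic generator;
# memoized because several test files reuse the same configurations

.fixture_cache <- new.env(parent = emptyenv())

make_binding_fixture <- function(seed = 21, motif_prob = 0.9) {
  key <- sprintf("fx_%d_%g", seed, motif_prob)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  .fixture_cache[[key]] <- make_binding_fixture_impl(seed, motif_prob)
  .fixture_cache[[key]]
}

make_binding_fixture_impl <- function(seed = 21, motif_prob = 0.9) {
  cfg <- sim_config(rng_seed = seed, motif_prob = motif_prob)
  cat0 <- simulate_catalog(cfg)
  sim <- simulate_interactions(cfg, cat0$mirnas, cat0$utrs)
  clip <- do.call(rbind, lapply(names(sim$peaks_by_task), function(tk) {
    u <- sim$utrs[sim$utr_tasks$task == tk, ]
    build_clip_examples(u, sim$peaks_by_task[[tk]], cat0$mirnas, task = tk)
  }))
  pos <- clip[clip$label == "positive", ]
  neg <- sample_negatives(pos, clip[clip$label == "negative", ],
                          rng_seed = seed)
  list(cfg = cfg, mirnas = cat0$mirnas, utrs = sim$utrs,
       examples = rbind(pos, neg), sim = sim)
}

# fitted binding model on a memoized fixture, itself memoized
make_binding_model <- function(seed = 21, motif_prob = 0.9, ...) {
  key <- sprintf("bm_%d_%g_%s", seed, motif_prob,
                 paste(unlist(list(...)), collapse = "_"))
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  fx <- make_binding_fixture(seed, motif_prob)
  fit <- binding_svm(fx$examples, fx$utrs,
                     binding_control(rng_seed = 1, ...))
  .fixture_cache[[key]] <- list(fx = fx, fit = fit)
  .fixture_cache[[key]]
}

kmer_from_code_test <- function(code, k) {
  d <- integer(k)
  for (pos in seq_len(k)) d[pos] <- (code %/% 4^(k - pos)) %% 4
  paste(c("A", "C", "G", "U")[d + 1L], collapse = "")
}

# explicit positional k-mer feature expansion; oracle for the WD kernel
oracle_wd <- function(a, z, degree, beta = wd_beta(degree)) {
  total <- 0
  valid <- function(x) !grepl("[^ACGU]", x)
  for (k in seq_len(degree)) {
    for (j in seq_len(nchar(a) - k + 1L)) {
      ka <- substr(a, j, j + k - 1L)
      kz <- substr(z, j, j + k - 1L)
      if (valid(ka) && valid(kz) && ka == kz) total <- total + beta[k]
    }
  }
  total
}
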