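# independent brute-force oracle for the duplex alignment score: exhaustive
# depth-first enumeration of every legal event sequence under the grammar
# (first/last events PAIRs, loops = one open + extension events, m1A rule)

oracle_duplex_score <- function(w, mirna, site) {
  m <- strsplit(mirna, "")[[1]]
  s <- rev(strsplit(site, "")[[1]])  # antiparallel: walk the site 3'->5'
  P <- length(m)
  Tn <- length(s)
  pair_types <- c("AU", "UA", "GC", "CG", "GU", "UG")
  psc <- function(p, t) {
    if (p == 1L) {
      if (s[t] != "A") return(NA_real_)
      return(w$m1A + w$paired[1L])
    }
    tp <- paste0(m[p], s[t])
    if (!tp %in% pair_types) return(NA_real_)
    w$pair[tp, p] + w$paired[p]
  }
  best <- 0
  pair_state <- function(p, t, sc) {
    best <<- max(best, sc)  # alignments may end at any PAIR
    if (p < P && t < Tn) {
      ps <- psc(p + 1L, t + 1L)
      if (!is.na(ps)) pair_state(p + 1L, t + 1L, sc + ps)
      loop_state(p + 1L, t + 1L, sc + w$open[p] + w$sym[p + 1L])
    }
    if (p < P) loop_state(p + 1L, t, sc + w$open[p] + w$asym[p + 1L])
    if (t < Tn) loop_state(p, t + 1L, sc + w$open[p] + w$asym[p])
  }
  loop_state <- function(p, t, sc) {
    if (p < P && t < Tn) {
      ps <- psc(p + 1L, t + 1L)
      if (!is.na(ps)) pair_state(p + 1L, t + 1L, sc + ps)
      loop_state(p + 1L, t + 1L, sc + w$sym[p + 1L])
    }
    if (p < P) loop_state(p + 1L, t, sc + w$asym[p + 1L])
    if (t < Tn) loop_state(p, t + 1L, sc + w$asym[p])
  }
  for (p in seq_len(P)) {
    for (t in seq_len(Tn)) {
      ps <- psc(p, t)
      if (!is.na(ps)) pair_state(p, t, ps)
    }
  }
  best
}

random_duplex_weights <- function(p_max = 10L, scale = 1.5) {
  duplex_weights(
    p_max = p_max,
    pair = matrix(stats::rnorm(6L * p_max, 0.5, scale), 6L, p_max),
    m1A = stats::rnorm(1L, 0.5, scale),
    open = stats::rnorm(p_max, -0.5, scale),
    sym = stats::rnorm(p_max, -0.3, scale),
    asym = stats::rnorm(p_max, -0.3, scale),
    paired = stats::rnorm(p_max, 0, scale))
}

random_rna_string <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
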