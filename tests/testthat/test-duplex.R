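# duplex alignment: DP vs exhaustive oracle, feature identity, grammar
# constraints, initializers, serialization

test_that("zero weights give the empty alignment with score 0", {
  w <- duplex_weights(p_max = 10L)
  al <- align_duplex(w, "UGAGGUAGUA", "ACGUACGUAC")
  expect_equal(al$score, 0)
  expect_equal(nrow(al$events), 0L)
  expect_equal(sum(featurize(al)), 0)
})

test_that("DP equals the exhaustive oracle on random small instances", {
  set.seed(2024)
  for (i in 1:50) {
    P <- sample(3:8, 1)
    Tn <- sample(4:10, 1)
    w <- random_duplex_weights(P)
    mi <- random_rna_string(P)
    si <- random_rna_string(Tn)
    expect_equal(align_duplex(w, mi, si)$score,
                 oracle_duplex_score(w, mi, si), tolerance = 1e-12,
                 info = paste(mi, si))
  }
})

test_that("score equals w . phi and position-1 pairs only opposite A", {
  set.seed(71)
  for (i in 1:150) {
    P <- sample(12:22, 1)
    Tn <- sample(10:35, 1)
    w <- random_duplex_weights(P)
    mi <- random_rna_string(P)
    si <- random_rna_string(Tn)
    al <- align_duplex(w, mi, si)
    phi <- featurize(al, p_max = P)
    expect_lt(abs(sum(duplex_weights_to_vector(w) * phi) - al$score), 1e-9)
    p1 <- al$events[al$events$event == "PAIR" & al$events$p == 1L, ]
    if (nrow(p1)) {
      expect_true(all(substr(si, p1$q, p1$q) == "A"))
      expect_true(all(p1$pair_type == "m1A"))
    }
  }
})

test_that("alignments respect the event grammar invariants", {
  set.seed(12)
  for (i in 1:100) {
    w <- random_duplex_weights(12L)
    al <- align_duplex(w, random_rna_string(12), random_rna_string(20))
    ev <- al$events
    if (!nrow(ev)) next
    expect_equal(ev$event[1], "PAIR")
    expect_equal(ev$event[nrow(ev)], "PAIR")
    pr <- ev[ev$event == "PAIR", ]
    # p strictly increasing; q strictly decreasing in site 5'->3' terms
    expect_true(all(diff(pr$p) > 0))
    expect_true(all(diff(pr$q) < 0))
    # each loop starts with exactly one LOOP_OPEN
    runs <- rle(ev$event != "PAIR")
    loops <- which(runs$values)
    starts <- cumsum(c(1, runs$lengths))[loops]
    expect_true(all(ev$event[starts] == "LOOP_OPEN"))
    expect_equal(sum(ev$event == "LOOP_OPEN"), length(loops))
  }
})

test_that("increasing a pair score never decreases the optimal score", {
  set.seed(55)
  for (i in 1:60) {
    w <- random_duplex_weights(10L)
    mi <- random_rna_string(10)
    si <- random_rna_string(14)
    s0 <- align_duplex(w, mi, si)$score
    w2 <- w
    b <- sample(6, 1)
    p <- sample(10, 1)
    w2$pair[b, p] <- w2$pair[b, p] + runif(1, 0, 2)
    expect_gte(align_duplex(w2, mi, si)$score, s0 - 1e-12)
  }
})

test_that("alignment is deterministic and tie-broken toward fewer events", {
  w <- duplex_init_weights(10L)
  a1 <- align_duplex(w, "UGAGGUAGUA", "UACUACCUCA")
  a2 <- align_duplex(w, "UGAGGUAGUA", "UACUACCUCA")
  expect_identical(a1$events, a2$events)
  # uniform weights create many score ties; the result must not contain
  # zero-gain loops that a shorter alignment avoids
  expect_false(any(duplicated(a1$events[a1$events$event == "PAIR", "p"])))
})

test_that("builtin initializer reproduces the DP under default weights", {
  # fully paired 8-mer: positions 2-8 complementary, A opposite position 1
  al <- init_alignment("ACGUACGG", "CCGUACGA")
  expect_equal(sum(al$events$event == "PAIR"), 8L)
  expect_equal(sum(al$events$event != "PAIR"), 0L)
  expect_equal(al$events$pair_type[al$events$p == 1L], "m1A")
  set.seed(9)
  for (i in 1:50) {
    mi <- random_rna_string(sample(3:7, 1))
    si <- random_rna_string(sample(4:9, 1))
    expect_equal(init_alignment(mi, si)$score,
                 oracle_duplex_score(duplex_init_weights(), mi, si),
                 tolerance = 1e-12)
  }
})

test_that("external dot-bracket structures convert to the event grammar", {
  # site-side bulge: miRNA positions 2-6 paired, one extra site base
  mi <- "ACGUAC"
  si <- "GUAACG"  # revcomp of positions 2-6 with an A bulge inserted
  al <- init_alignment(mi, si, initializer = "external",
                       structure = ".(((((&))).))")
  expect_equal(sum(al$events$event == "PAIR"), 5L)
  expect_equal(sum(al$events$event == "LOOP_OPEN"), 1L)
  expect_equal(sum(al$events$event == "ASYM_EXT_SITE"), 1L)
  phi <- featurize(al, p_max = 6L)
  expect_equal(sum(phi[grepl("^pair_", names(phi))]), 5)
  expect_error(init_alignment(mi, si, initializer = "external",
                              structure = "((((((&)))"),
               "one '&'|lengths")
})

test_that("duplex weights serialize round-trip exactly", {
  set.seed(31)
  w <- random_duplex_weights(27L)
  w$bias <- -1.25
  f <- tempfile(fileext = ".json")
  write_duplex_weights(w, f)
  back <- read_duplex_weights(f)
  expect_equal(back, w)
  # vector round trip is the identity too
  v <- duplex_weights_to_vector(w)
  expect_equal(duplex_weights_from_vector(v, bias = w$bias), w)
})

test_that("scores are invariant to catalog order and ranking is stable", {
  cat0 <- toy_mirna_catalog()
  cfg <- duplex_control(iterations = 1L)
  # a tiny trained model via the builtin path is not needed: scoring only
  # uses weights, so construct one directly
  model <- structure(list(weights = duplex_init_weights(),
                          control = cfg, C = cfg$C,
                          trace = 0, n_pos = 1, n_neg_pool = 1,
                          converged = TRUE),
                     class = "duplex_svm")
  site <- "UAUACAACCUACUACCUCAA"
  r1 <- rank_mirnas(model, cat0, site)
  r2 <- rank_mirnas(model, cat0[c(3, 1, 2), ], site)
  expect_equal(r1$name, r2$name)
  expect_equal(r1$score, r2$score)
  expect_equal(score_pair(model, cat0$sequence[1], site),
               align_duplex(model$weights, cat0$sequence[1], site)$score +
                 model$weights$bias)
})

test_that("N bases in the site are never paired", {
  w <- duplex_init_weights(8L)
  al <- align_duplex(w, "ACGUACGU", "ANGNNACGNNUN")
  pr <- al$events[al$events$event == "PAIR", ]
  if (nrow(pr)) {
    expect_false(any(substr("ANGNNACGNNUN", pr$q, pr$q) == "N"))
  }
  expect_error(align_duplex(w, "ACGNACGU", "ACGUACGU"), "N")
})
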