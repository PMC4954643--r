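# training-set construction: seed scanning, CLASH/CLIP filters, mispairing,
# sampling, family holdout

test_that("seed matches are found by reverse complement of miRNA nt 2-7", {
  m <- toy_mirna_catalog()[1, ]  # seed GAGGUA -> site UACCUC
  u <- toy_utr("AAUACCUCAA")
  sm <- scan_seed_matches(u, m, max_edit = 0L)
  expect_equal(nrow(sm), 1L)
  expect_equal(sm$match_start, 2L)
  expect_equal(sm$match_end, 8L)
  expect_equal(sm$edit_distance, 0L)
  expect_equal(sm$anchor, 7L)  # 3'-most base, opposite miRNA nt 2

  # one substitution found only at max_edit = 1
  u2 <- toy_utr("AAUACGUCAA")
  expect_equal(nrow(scan_seed_matches(u2, m, max_edit = 0L)), 0L)
  sm2 <- scan_seed_matches(u2, m, max_edit = 1L)
  expect_true(any(sm2$match_start == 2L & sm2$edit_distance == 1L))

  # no complement anywhere
  expect_equal(nrow(scan_seed_matches(toy_utr(strrep("G", 30)), m, 0L)), 0L)
  # indel matches may give 5- or 7-nt windows
  u3 <- toy_utr("AAUACCCUCAA")  # insertion inside the complement
  sm3 <- scan_seed_matches(u3, m, max_edit = 1L)
  expect_true(any(sm3$match_end - sm3$match_start == 7L))
  expect_true(all(sm3$match_end - sm3$match_start %in% 5:7))
  # miRNA shorter than 8 nt is rejected
  short <- list(name = "tiny", family = "f", sequence = "UGAGGUA")
  expect_error(scan_seed_matches(u, short, 0L), "shorter")
})

test_that("CLASH positives survive exactly the three filters", {
  fx <- toy_trainset_fixture()
  pos <- build_clash_positives(fx$interactions, fx$utrs, fx$mirnas)
  expect_equal(attr(pos, "filter_counts"), fx$expected_filter_counts)
  expect_equal(nrow(pos), 3L)
  expect_true(all(pos$label == "positive" & pos$source == "clash"))
  # unknown miRNA/transcript is skipped with a warning, not an error
  ia_bad <- rbind(fx$interactions,
                  data.frame(mirna_name = "miR-999", transcript_id = "tx1",
                             site_start = 0L, site_end = 30L,
                             chimeric_count = 1L, nonchimeric_support = 1L))
  expect_warning(p2 <- build_clash_positives(ia_bad, fx$utrs, fx$mirnas),
                 "skipping")
  expect_equal(nrow(p2), 3L)
})

test_that("CLIP labeling follows the peak/read overlap rules", {
  fx <- toy_trainset_fixture()
  ex <- build_clip_examples(fx$utrs, fx$peaks, fx$mirnas, reads = fx$reads)
  # seed match in a peak -> positive; no reads -> negative; reads but no
  # peak -> neither class
  expect_equal(nrow(ex), 2L)
  pos <- ex[ex$label == "positive", ]
  neg <- ex[ex$label == "negative", ]
  expect_equal(pos$transcript_id, "tx1")
  expect_equal(pos$site_start, 20L)
  expect_equal(pos$family, "let-7")
  expect_equal(neg$site_start, 60L)
  expect_equal(neg$family, "miR-30")
  # order independence w.r.t. peak input order and idempotence
  ex2 <- build_clip_examples(fx$utrs, fx$peaks[rev(seq_len(nrow(fx$peaks))), ],
                             fx$mirnas, reads = fx$reads)
  expect_equal(ex, ex2)
  # without a separate read track, peaks stand in for read evidence:
  # the tx2 match now counts as negative
  ex3 <- build_clip_examples(fx$utrs, fx$peaks, fx$mirnas)
  expect_equal(sum(ex3$label == "negative"), 2L)
})

test_that("multi-family peaks are dropped when a unique family is required", {
  # one peak covering seed matches of two families
  seq <- strrep("G", 60)
  substr(seq, 21, 26) <- "UACCUC"  # let-7
  substr(seq, 31, 36) <- "GUUUAC"  # miR-30
  utr <- toy_utr(seq)
  peaks <- data.frame(transcript_id = "tx1", start = 18L, end = 40L,
                      name = "pk", read_count = 8L, stringsAsFactors = FALSE)
  mir <- toy_mirna_catalog()[1:2, ]
  ex_loose <- build_clip_examples(utr, peaks, mir)
  expect_equal(sum(ex_loose$label == "positive"), 2L)
  ex_strict <- build_clip_examples(utr, peaks, mir,
                                   require_unique_family = TRUE)
  expect_equal(sum(ex_strict$label == "positive"), 0L)
})

test_that("mispaired negatives come from non-interacting families only", {
  fx <- toy_trainset_fixture()
  pos <- build_clash_positives(fx$interactions, fx$utrs, fx$mirnas)
  neg <- build_mispaired_negatives(pos, fx$mirnas, rng_seed = 7,
                                   per_positive = 5L)
  expect_true(all(neg$label == "negative" & neg$source == "clash"))
  key <- paste(neg$transcript_id, neg$site_start, neg$site_end)
  poskey <- paste(pos$transcript_id, pos$site_start, pos$site_end)
  for (i in seq_len(nrow(neg))) {
    interacting <- pos$family[poskey == key[i]]
    expect_false(neg$family[i] %in% interacting)
  }
  # deterministic under a fixed seed
  neg2 <- build_mispaired_negatives(pos, fx$mirnas, rng_seed = 7,
                                    per_positive = 5L)
  expect_identical(neg, neg2)
  # single-family catalogs cannot provide decoys
  expect_error(build_mispaired_negatives(pos, fx$mirnas[1, , drop = FALSE]),
               "two seed families")
})

test_that("negative sampling respects per-source ratios and pool limits", {
  mk <- function(n, label, source) {
    data.frame(mirna = "m", family = "f", transcript_id = sprintf("t%d", 1:n),
               site_start = 0L, site_end = 6L, anchor = 5L, label = label,
               source = source, task = "t", stringsAsFactors = FALSE)
  }
  pos <- rbind(mk(100, "positive", "clash"), mk(200, "positive", "clip"))
  neg <- rbind(mk(3000, "negative", "clash"), mk(500, "negative", "clip"))
  s <- sample_negatives(pos, neg, rng_seed = 1)
  expect_equal(sum(s$source == "clash"), 1500L)  # 15x CLASH positives
  expect_equal(sum(s$source == "clip"), 200L)    # 1x CLIP positives
  expect_false(any(duplicated(rownames(s))))
  # pool smaller than the request: take all, with a log message
  expect_message(
    s2 <- sample_negatives(mk(10, "positive", "clip"),
                           mk(5, "negative", "clip"), rng_seed = 1),
    "smaller than requested")
  expect_equal(nrow(s2), 5L)
})

test_that("family holdout partitions without leakage", {
  fx <- toy_trainset_fixture()
  pos <- build_clash_positives(fx$interactions, fx$utrs, fx$mirnas)
  neg <- build_mispaired_negatives(pos, fx$mirnas, rng_seed = 1,
                                   per_positive = 1L)
  ex <- rbind(pos, neg)
  sp <- holdout_by_family(ex, "let-7")
  # partition property
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(ex))
  expect_length(intersect(rownames(sp$train), rownames(sp$test)), 0L)
  expect_false("let-7" %in% sp$train$family)
  # sites bound by the held family are fully excluded from training
  heldkey <- with(sp$test[sp$test$label == "positive" &
                            sp$test$family == "let-7", ],
                  paste(transcript_id, site_start, site_end))
  trainkey <- with(sp$train, paste(transcript_id, site_start, site_end))
  expect_length(intersect(heldkey, trainkey), 0L)
  expect_error(holdout_by_family(ex, "no-such-family"), "unknown family")
  expect_warning(holdout_by_family(ex, "miR-1",
                                   known_families = c(ex$family, "miR-1")),
                 "no examples")
})

test_that("no site carries both labels for the same family", {
  fx <- toy_trainset_fixture()
  pos <- build_clash_positives(fx$interactions, fx$utrs, fx$mirnas)
  neg <- build_mispaired_negatives(pos, fx$mirnas, rng_seed = 3)
  clip <- build_clip_examples(fx$utrs, fx$peaks, fx$mirnas, reads = fx$reads)
  ex <- rbind(pos, neg, clip)
  key <- paste(ex$family, ex$transcript_id, ex$site_start, ex$site_end)
  tab <- table(key, ex$label)
  expect_true(all(rowSums(tab > 0) <= 1L))
})
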