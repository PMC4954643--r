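# small deterministic fixtures built in code

# let-7a-like miRNA; seed (nt 2-7) GAGGUA, seed-complement site UACCUC
LET7 <- "UGAGGUAGUAGGUUGUAUAGUU"

toy_mirna_catalog <- function() {
  out <- data.frame(
    name = c("let-7a", "miR-30a", "miR-1"),
    family = c("let-7", "miR-30", "miR-1"),
    sequence = c(LET7, "UGUAAACAUCCUCGACUGGAAG", "UGGAAUGUAAAGAAGUAUGUAU"),
    stringsAsFactors = FALSE)
  class(out) <- c("mirna_catalog", "data.frame")
  out
}

toy_utr <- function(sequence, transcript_id = "tx1", ends = NULL) {
  out <- data.frame(transcript_id = transcript_id, sequence = sequence,
                    stringsAsFactors = FALSE)
  out$three_prime_ends <- list(unique(c(ends, nchar(sequence))))
  class(out) <- c("utr_catalog", "data.frame")
  out
}

# a deterministic UTR catalog whose seed matches are placed by hand
toy_trainset_fixture <- function() {
  # UTR layout (0-based):
  #   tx1 (len 100): let-7 seed complement UACCUC at [20,26); peak [15,30)
  #   tx1: miR-30 seed complement GUUUAC at [60,66); no peak, no reads
  #   tx2 (len 80): let-7 seed complement at [10,16); read coverage but no
  #        peak at [5,25) -> discarded from both classes
  base1 <- strrep("G", 100)
  substr(base1, 21, 26) <- "UACCUC"
  substr(base1, 61, 66) <- "GUUUAC"
  base2 <- strrep("G", 80)
  substr(base2, 11, 16) <- "UACCUC"
  utrs <- rbind(toy_utr(base1, "tx1"), toy_utr(base2, "tx2"))
  mirnas <- toy_mirna_catalog()[1:2, ]
  peaks <- data.frame(transcript_id = "tx1", start = 15L, end = 30L,
                      name = "pk1", read_count = 10L,
                      stringsAsFactors = FALSE)
  reads <- rbind(peaks[, ],
                 data.frame(transcript_id = "tx2", start = 5L, end = 25L,
                            name = "rd1", read_count = 3L,
                            stringsAsFactors = FALSE))
  # interactions: 5 records, 3 pass the CLASH filters
  interactions <- data.frame(
    mirna_name = c("let-7a", "let-7a", "let-7a", "let-7a", "miR-30a"),
    transcript_id = c("tx1", "tx2", "tx1", "tx1", "tx1"),
    site_start = c(15L, 5L, 15L, 40L, 55L),
    site_end = c(30L, 25L, 30L, 50L, 70L),
    chimeric_count = c(3L, 2L, 1L, 4L, 2L),
    nonchimeric_support = c(5L, 1L, 0L, 2L, 1L),
    stringsAsFactors = FALSE)
  # hand-derived: row 1 passes all filters; row 2 passes; row 3 fails
  # non-chimeric support; row 4 has no edit<=1 let-7 seed match in
  # [40,50) (all G); row 5 passes (miR-30 seed at [60,66) within
  # [55,70)) -> 3 positives
  list(mirnas = mirnas, utrs = utrs, peaks = peaks, reads = reads,
       interactions = interactions,
       expected_filter_counts = c(input = 5L, known = 5L, in_utr = 5L,
                                  seed_match = 4L, supported = 3L))
}
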