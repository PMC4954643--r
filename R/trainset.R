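# construction of labeled (miRNA, site) examples from CLASH interactions and
# CLIP peaks

labeled_site_cols <- c("mirna", "family", "transcript_id", "site_start",
                       "site_end", "anchor", "label", "source", "task")

empty_labeled_sites <- function() {
  out <- data.frame(mirna = character(), family = character(),
                    transcript_id = character(), site_start = integer(),
                    site_end = integer(), anchor = integer(),
                    label = character(), source = character(),
                    task = character(), stringsAsFactors = FALSE)
  out
}

#' Scan a 3'UTR for seed-complementary matches
#'
#' The seed is the reverse complement of miRNA positions 2-7 (1-based on the
#' miRNA). Matches are UTR windows within the requested edit distance
#' (substitutions or indels) of that hexamer: length-6 windows at edit 0,
#' length 5-7 windows at edit 1. At each start position the minimal-edit
#' window is reported once (window length closest to 6 on ties). The anchor
#' is the UTR position opposite miRNA nucleotide 2, i.e. the 3'-most base of
#' the matched window (ties in the window-to-seed alignment are broken
#' toward the 3'-most anchor). Windows containing `N` are skipped.
#'
#' @param utr one row of a [read_utr_atlas()] catalog (or a list with
#'   `transcript_id` and `sequence`).
#' @param mirna one row of a [read_mirna_catalog()] catalog.
#' @param max_edit 0 or 1.
#' @return data frame: `transcript_id, match_start, match_end, family,
#'   edit_distance, anchor` (0-based half-open UTR coordinates).
#' @export
scan_seed_matches <- function(utr, mirna, max_edit = 0L) {
  stopifnot(max_edit %in% c(0L, 1L))
  if (nchar(mirna$sequence) < 8L) {
    stopf("miRNA %s shorter than 8 nt", mirna$name)
  }
  seed_site <- rna_revcomp(substr(mirna$sequence, 2L, 7L))
  seq <- utr$sequence
  L <- nchar(seq)
  hits <- data.frame(match_start = integer(), match_end = integer(),
                     edit_distance = integer())
  if (max_edit == 0L) {
    # exact matches via fixed-string search
    at <- gregexpr(seed_site, seq, fixed = TRUE)[[1L]]
    at <- at[at > 0L]
    return(data.frame(transcript_id = rep(utr$transcript_id, length(at)),
                      match_start = at - 1L, match_end = at + 5L,
                      family = rep(mirna$family, length(at)),
                      edit_distance = rep(0L, length(at)),
                      anchor = at + 4L, stringsAsFactors = FALSE))
  }
  if (L >= 5L) {
    lens <- c(6L, 7L, 5L)  # preference order
    found_edit <- rep(NA_integer_, L)
    found_len <- rep(NA_integer_, L)
    for (len in lens) {
      starts <- seq_len(max(L - len + 1L, 0L)) - 1L
      if (!length(starts)) next
      wins <- substring(seq, starts + 1L, starts + len)
      ok <- !grepl("N", wins, fixed = TRUE)
      d <- rep(NA_integer_, length(starts))
      d[ok] <- as.integer(utils::adist(wins[ok], seed_site))
      sel <- which(!is.na(d) & d <= max_edit)
      for (i in sel) {
        s <- starts[i] + 1L
        if (is.na(found_edit[s]) || d[i] < found_edit[s]) {
          found_edit[s] <- d[i]
          found_len[s] <- len
        }
      }
    }
    sel <- which(!is.na(found_edit))
    hits <- data.frame(match_start = sel - 1L,
                       match_end = sel - 1L + found_len[sel],
                       edit_distance = found_edit[sel])
  }
  data.frame(transcript_id = rep(utr$transcript_id, nrow(hits)),
             match_start = hits$match_start, match_end = hits$match_end,
             family = rep(mirna$family, nrow(hits)),
             edit_distance = hits$edit_distance,
             anchor = hits$match_end - 1L, stringsAsFactors = FALSE)
}

#' Positive duplex examples from CLASH chimeric interactions
#'
#' Applies the three filters used to compile chimera-supported positives:
#' (1) the site lies within a cataloged 3'UTR; (2) the site contains a match
#' to the interacting miRNA's 6-mer seed within edit distance 1
#' (substitutions or indels); (3) the interaction has non-chimeric read
#' support. Interactions naming unknown transcripts or miRNAs are skipped
#' with a warning.
#'
#' @param interactions data frame from [read_interactions()].
#' @param utrs UTR catalog.
#' @param mirnas miRNA catalog.
#' @param task task (cell type / data set) tag for the resulting examples.
#' @return labeled-site data frame (`label = "positive"`, `source =
#'   "clash"`), with per-filter survivor counts in
#'   `attr(, "filter_counts")`.
#' @export
build_clash_positives <- function(interactions, utrs, mirnas, task = "clash") {
  known <- interactions$transcript_id %in% utrs$transcript_id &
    interactions$mirna_name %in% mirnas$name
  if (any(!known)) {
    warnf("skipping %d interaction(s) with unknown transcript or miRNA",
          sum(!known))
  }
  ia <- interactions[known, , drop = FALSE]
  utr_len <- nchar(utrs$sequence)[match(ia$transcript_id, utrs$transcript_id)]
  in_utr <- ia$site_end <= utr_len & ia$site_start >= 0
  ia1 <- ia[in_utr, , drop = FALSE]
  has_seed <- logical(nrow(ia1))
  anchors <- rep(NA_integer_, nrow(ia1))
  for (i in seq_len(nrow(ia1))) {
    u <- utrs[utrs$transcript_id == ia1$transcript_id[i], ]
    m <- mirnas[mirnas$name == ia1$mirna_name[i], ]
    win <- list(transcript_id = u$transcript_id,
                sequence = utr_substr(u$sequence, ia1$site_start[i],
                                      ia1$site_end[i]))
    sm <- scan_seed_matches(win, m, max_edit = 1L)
    if (nrow(sm)) {
      has_seed[i] <- TRUE
      best <- sm[order(sm$edit_distance, -sm$anchor), ][1L, ]
      anchors[i] <- ia1$site_start[i] + best$anchor
    }
  }
  ia2 <- ia1[has_seed, , drop = FALSE]
  anchors <- anchors[has_seed]
  supported <- ia2$nonchimeric_support >= 1
  ia3 <- ia2[supported, , drop = FALSE]
  out <- data.frame(
    mirna = ia3$mirna_name,
    family = mirnas$family[match(ia3$mirna_name, mirnas$name)],
    transcript_id = ia3$transcript_id, site_start = ia3$site_start,
    site_end = ia3$site_end, anchor = anchors[supported],
    label = rep("positive", nrow(ia3)), source = rep("clash", nrow(ia3)),
    task = rep(task, nrow(ia3)), stringsAsFactors = FALSE)
  attr(out, "filter_counts") <- c(input = nrow(interactions),
                                  known = nrow(ia), in_utr = nrow(ia1),
                                  seed_match = nrow(ia2),
                                  supported = nrow(ia3))
  out
}

#' AGO-bound and unbound seed-site examples from CLIP peaks
#'
#' Every exact (edit-0) 6-mer seed match of a cataloged family is labeled
#' positive if it overlaps (shares >= 1 base with) an AGO peak, negative if
#' it overlaps no read evidence, and discarded if it overlaps read coverage
#' that was not called as a peak. When no separate read-coverage track is
#' supplied, peaks stand in for the read evidence. With
#' `require_unique_family`, a positive is kept only when its peak contains
#' exact seed matches for exactly one cataloged family (used to build
#' unambiguous duplex training examples).
#'
#' @param utrs UTR catalog.
#' @param peaks peak data frame from [read_peaks()].
#' @param mirnas miRNA catalog (defines the expressed families).
#' @param require_unique_family keep only single-family peaks as positives.
#' @param min_read_count minimum peak read count for a positive.
#' @param reads optional read-coverage intervals (same columns as peaks)
#'   distinguishing "no reads" from "reads but no peak".
#' @param task task tag.
#' @return labeled-site data frame (`source = "clip"`).
#' @export
build_clip_examples <- function(utrs, peaks, mirnas,
                                require_unique_family = FALSE,
                                min_read_count = 1L, reads = NULL,
                                task = "clip") {
  reads <- reads %||% peaks
  fams <- unique(mirnas$family)
  rep_mirna <- mirnas[match(fams, mirnas$family), , drop = FALSE]
  all_matches <- list()
  for (i in seq_len(nrow(utrs))) {
    u <- utrs[i, ]
    for (j in seq_along(fams)) {
      sm <- scan_seed_matches(u, rep_mirna[j, ], max_edit = 0L)
      if (nrow(sm)) all_matches[[length(all_matches) + 1L]] <- sm
    }
  }
  if (!length(all_matches)) return(empty_labeled_sites())
  sm <- do.call(rbind, all_matches)
  # overlap = >= 1 shared base between the match window and the interval
  overlap_idx <- function(df, iv) {
    which(iv$transcript_id == df$transcript_id &
            iv$start < df$match_end & iv$end > df$match_start)
  }
  keep <- logical(nrow(sm))
  label <- character(nrow(sm))
  for (i in seq_len(nrow(sm))) {
    pk <- overlap_idx(sm[i, ], peaks)
    pk <- pk[peaks$read_count[pk] >= min_read_count]
    if (length(pk)) {
      if (require_unique_family) {
        # families with an exact seed match inside the overlapping peak
        p <- peaks[pk[1L], ]
        fam_in_peak <- unique(sm$family[sm$transcript_id == p$transcript_id &
                                          sm$match_start < p$end &
                                          sm$match_end > p$start])
        if (length(fam_in_peak) != 1L) next
      }
      keep[i] <- TRUE
      label[i] <- "positive"
    } else if (!length(overlap_idx(sm[i, ], reads))) {
      keep[i] <- TRUE
      label[i] <- "negative"
    }
  }
  sm <- sm[keep, , drop = FALSE]
  label <- label[keep]
  out <- data.frame(
    mirna = rep_mirna$name[match(sm$family, rep_mirna$family)],
    family = sm$family, transcript_id = sm$transcript_id,
    site_start = sm$match_start, site_end = sm$match_end,
    anchor = sm$anchor, label = label,
    source = rep("clip", nrow(sm)), task = rep(task, nrow(sm)),
    stringsAsFactors = FALSE)
  out[order(out$transcript_id, out$site_start, out$family), , drop = FALSE]
}

#' Mispaired CLASH negatives
#'
#' Pairs each chimera-supported positive site with decoy miRNAs drawn from
#' seed families other than any family observed to interact with that site,
#' yielding negatives for the duplex model.
#'
#' @param positives CLASH positive labeled sites.
#' @param mirnas miRNA catalog.
#' @param rng_seed integer seed; output is deterministic given the seed.
#' @param per_positive decoys drawn per positive site.
#' @return labeled-site data frame (`label = "negative"`, `source =
#'   "clash"`).
#' @export
build_mispaired_negatives <- function(positives, mirnas, rng_seed = 1L,
                                      per_positive = 15L) {
  if (length(unique(mirnas$family)) < 2L) {
    stopf("mispaired negatives need at least two seed families")
  }
  key <- paste(positives$transcript_id, positives$site_start,
               positives$site_end)
  site_fams <- split(positives$family, key)
  rng <- local_rng(rng_seed)
  rows <- vector("list", nrow(positives))
  for (i in seq_len(nrow(positives))) {
    excluded <- site_fams[[key[i]]]
    pool <- which(!(mirnas$family %in% excluded))
    if (!length(pool)) next
    take <- rng$sample_vec(pool, min(per_positive, length(pool)))
    rows[[i]] <- data.frame(
      mirna = mirnas$name[take], family = mirnas$family[take],
      transcript_id = positives$transcript_id[i],
      site_start = positives$site_start[i],
      site_end = positives$site_end[i], anchor = positives$anchor[i],
      label = "negative", source = "clash", task = positives$task[i],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out %||% empty_labeled_sites()
}

#' Sample negatives at the configured per-source ratios
#'
#' Draws a uniform sample without replacement from the negative pool of each
#' source: 15 CLASH negatives per CLASH positive and one CLIP negative per
#' CLIP positive by default. If a pool is smaller than requested all of it
#' is taken and a message is logged.
#'
#' @param positives,negatives labeled-site data frames.
#' @param clash_ratio,clip_ratio negatives drawn per positive, by source.
#' @param rng_seed integer seed.
#' @return sampled negative labeled sites.
#' @export
sample_negatives <- function(positives, negatives, clash_ratio = 15,
                             clip_ratio = 1, rng_seed = 1L) {
  stopifnot(clash_ratio > 0, clip_ratio > 0)
  rng <- local_rng(rng_seed)
  out <- list()
  for (src in c("clash", "clip")) {
    ratio <- if (src == "clash") clash_ratio else clip_ratio
    want <- round(ratio * sum(positives$source == src &
                                positives$label == "positive"))
    pool <- which(negatives$source == src & negatives$label == "negative")
    if (!want || !length(pool)) next
    if (length(pool) <= want) {
      if (length(pool) < want) {
        message(sprintf("%s negative pool (%d) smaller than requested (%d); using all",
                        src, length(pool), want))
      }
      take <- pool
    } else {
      take <- rng$sample_vec(pool, want)
    }
    out[[src]] <- negatives[take, , drop = FALSE]
  }
  out <- do.call(rbind, out)
  if (is.null(out)) empty_labeled_sites() else {
    rownames(out) <- NULL
    out
  }
}

#' Partition examples by held-out miRNA seed family
#'
#' All examples of the held family go to the test split; for duplex
#' evaluation every example sharing a site with a held-family example is
#' also removed from training, so no family or site leaks between splits.
#'
#' @param examples labeled-site data frame.
#' @param held_family the family to hold out.
#' @param known_families families considered valid (defaults to those
#'   present in `examples`).
#' @param exclude_shared_sites also move same-site examples of other
#'   families into the test split.
#' @return list with `train` and `test` data frames.
#' @export
holdout_by_family <- function(examples, held_family, known_families = NULL,
                              exclude_shared_sites = TRUE) {
  known_families <- known_families %||% unique(examples$family)
  if (!held_family %in% known_families) {
    stopf("unknown family '%s'", held_family)
  }
  in_fam <- examples$family == held_family
  if (!any(in_fam)) warnf("held-out family '%s' has no examples", held_family)
  test <- in_fam
  if (exclude_shared_sites && any(in_fam)) {
    key <- paste(examples$transcript_id, examples$site_start,
                 examples$site_end)
    held_sites <- key[in_fam & examples$label == "positive"]
    test <- test | key %in% held_sites
  }
  list(train = examples[!test, , drop = FALSE],
       test = examples[test, , drop = FALSE])
}

#' Read or write labeled sites as TSV
#'
#' @param path file path.
#' @return for the reader, a labeled-site data frame.
#' @export
read_labeled_sites <- function(path) {
  df <- read_tsv_file(path, labeled_site_cols)
  stopifnot(all(df$label %in% c("positive", "negative")),
            all(df$source %in% c("clash", "clip")))
  df
}

#' @rdname read_labeled_sites
#' @param x labeled-site data frame.
#' @export
write_labeled_sites <- function(x, path) write_tsv_file(x, path)

# self-contained RNG stream so package functions never disturb (or depend
# on) the caller's .Random.seed
local_rng <- function(seed) {
  env <- new.env()
  run <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      else suppressWarnings(rm(".Random.seed", envir = globalenv()))
    })
    if (!is.null(env$state)) assign(".Random.seed", env$state, globalenv())
    else set.seed(seed)
    res <- f()
    env$state <- get(".Random.seed", globalenv())
    res
  }
  list(
    sample = function(x, size = length(x), replace = FALSE, prob = NULL) {
      run(function() sample(x, size, replace = replace, prob = prob))
    },
    # sample elements of x even when length(x) == 1
    sample_vec = function(x, size = length(x), replace = FALSE) {
      run(function() x[sample.int(length(x), size, replace = replace)])
    },
    runif = function(n, ...) run(function() stats::runif(n, ...)),
    rnorm = function(n, ...) run(function() stats::rnorm(n, ...)),
    rpois = function(n, ...) run(function() stats::rpois(n, ...)),
    rbinom = function(n, ...) run(function() stats::rbinom(n, ...)),
    with = run)
}
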