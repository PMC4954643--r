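# optimal local duplex alignment under a duplex_weights vector

EVENT_CODES <- c("PAIR", "LOOP_OPEN", "SYM_EXT", "ASYM_EXT_MIRNA",
                 "ASYM_EXT_SITE")

#' Align a miRNA to a candidate site under duplex weights
#'
#' Computes the maximum-score local antiparallel duplex alignment between a
#' miRNA (traversed 5'->3') and a site sequence, under the additive event
#' grammar: the first and last events are base PAIRs, PAIR positions are
#' strictly increasing along the miRNA and strictly decreasing along the site
#' in its 5'->3' coordinates, and internal loops decompose into one
#' `LOOP_OPEN` plus symmetric / asymmetric extension events. Pairing at miRNA
#' position 1 is permitted only opposite an adenosine (the m1A rule) and is
#' scored by the dedicated m1A weight. If no legal alignment has a positive
#' score, the empty alignment (score 0) is returned. Ties are broken toward
#' fewer events, then the 5'-most miRNA start, then the 5'-most site start.
#'
#' @param weights a [duplex_weights()] object.
#' @param mirna miRNA sequence, RNA alphabet, length `>= 2` and `<= p_max`.
#' @param site site sequence 5'->3'; `N` bases are unpairable but may be
#'   consumed by loop extensions.
#' @param anchor `"local"` (default; alignment may start at any miRNA
#'   position) or `"anchored"` (first PAIR at miRNA position `<= 2`, a
#'   seed-anchored variant for sensitivity analysis).
#' @return an object of class `duplex_alignment`: a list with `score` and an
#'   `events` data frame (`event`, `p` = miRNA position, `q` = site position
#'   in 5'->3' 1-based coordinates or `NA`, `pair_type`).
#' @export
align_duplex <- function(weights, mirna, site, anchor = c("local", "anchored")) {
  anchor <- match.arg(anchor)
  stopifnot(inherits(weights, "duplex_weights"))
  mirna <- rna_normalize(mirna, "miRNA")
  if (grepl("N", mirna, fixed = TRUE)) stopf("miRNA sequence contains N")
  site <- rna_normalize(site, "site")
  M <- nchar(mirna)
  if (M > weights$p_max) {
    stopf("miRNA length %d exceeds p_max = %d", M, weights$p_max)
  }
  if (M < 2L || nchar(site) < 1L) stopf("miRNA or site too short to align")
  m <- encode_rna(mirna)
  s <- rev(encode_rna(site))  # antiparallel: index t runs 3'->5' on the site
  res <- .duplex_dp(m, s, weights$pair[, seq_len(M), drop = FALSE],
                    weights$m1A, weights$open[seq_len(M)],
                    weights$sym[seq_len(M)], weights$asym[seq_len(M)],
                    weights$paired[seq_len(M)],
                    if (anchor == "anchored") 2L else 0L)
  ev <- res$events
  Ls <- nchar(site)
  if (nrow(ev) == 0L) {
    out <- empty_alignment(mirna, site)
    out$anchor <- anchor
    return(out)
  }
  events <- data.frame(
    event = EVENT_CODES[ev[, "code"]],
    p = ev[, "p"],
    q = ifelse(ev[, "t"] > 0L, Ls - ev[, "t"] + 1L, NA_integer_),
    pair_type = ifelse(ev[, "code"] == 1L,
                       c(PAIR_TYPES, "m1A")[pmax(ev[, "pairtype"], 1L)],
                       NA_character_),
    stringsAsFactors = FALSE)
  structure(list(score = res$score, events = events, mirna = mirna,
                 site = site, anchor = anchor),
            class = "duplex_alignment")
}

empty_alignment <- function(mirna = "", site = "") {
  structure(list(score = 0,
                 events = data.frame(event = character(), p = integer(),
                                     q = integer(), pair_type = character(),
                                     stringsAsFactors = FALSE),
                 mirna = mirna, site = site, anchor = "local"),
            class = "duplex_alignment")
}

#' Event-count feature vector of a duplex alignment
#'
#' Maps an alignment to the sparse count vector phi such that
#' `w . phi(alignment)` reproduces the alignment score exactly: counts of
#' each pair type at each miRNA position (m1A separately), loop opening and
#' extension counts per position, and binary paired indicators.
#'
#' @param alignment a `duplex_alignment`.
#' @param p_max weight-vector dimension (default 27).
#' @return named numeric vector of length `10 * p_max + 1`.
#' @export
featurize <- function(alignment, p_max = 27L) {
  stopifnot(inherits(alignment, "duplex_alignment"))
  p_max <- as.integer(p_max)
  v <- numeric(10L * p_max + 1L)
  names(v) <- duplex_feature_names(p_max)
  ev <- alignment$events
  if (nrow(ev) == 0L) return(v)
  if (ev$event[1L] != "PAIR" || ev$event[nrow(ev)] != "PAIR") {
    stopf("malformed alignment: first and last events must be PAIRs")
  }
  off_m1a <- 6L * p_max + 1L
  for (i in seq_len(nrow(ev))) {
    p <- ev$p[i]
    if (p < 1L || p > p_max) stopf("event position %d out of range", p)
    switch(ev$event[i],
      PAIR = {
        if (identical(ev$pair_type[i], "m1A")) {
          if (p != 1L) stopf("m1A pair away from position 1")
          v[off_m1a] <- v[off_m1a] + 1
        } else {
          b <- match(ev$pair_type[i], PAIR_TYPES)
          if (is.na(b)) stopf("unknown pair type '%s'", ev$pair_type[i])
          v[(p - 1L) * 6L + b] <- v[(p - 1L) * 6L + b] + 1
        }
        idx <- off_m1a + 3L * p_max + p
        if (v[idx] != 0) stopf("miRNA position %d paired twice", p)
        v[idx] <- 1
      },
      LOOP_OPEN = { v[off_m1a + p] <- v[off_m1a + p] + 1 },
      SYM_EXT = { v[off_m1a + p_max + p] <- v[off_m1a + p_max + p] + 1 },
      ASYM_EXT_MIRNA = ,
      ASYM_EXT_SITE = {
        v[off_m1a + 2L * p_max + p] <- v[off_m1a + 2L * p_max + p] + 1
      },
      stopf("unknown event '%s'", ev$event[i]))
  }
  v
}

# fast path for training: optimal alignment -> feature vector without
# materializing the events data frame
align_featurize <- function(weights, mirna, site, p_max,
                            anchor = "local") {
  M <- nchar(mirna)
  m <- encode_rna(mirna)
  s <- rev(encode_rna(site))
  res <- .duplex_dp(m, s, weights$pair[, seq_len(M), drop = FALSE],
                    weights$m1A, weights$open[seq_len(M)],
                    weights$sym[seq_len(M)], weights$asym[seq_len(M)],
                    weights$paired[seq_len(M)],
                    if (anchor == "anchored") 2L else 0L)
  ev <- res$events
  d <- 10L * p_max + 1L
  if (nrow(ev) == 0L) return(numeric(d))
  code <- ev[, 1L]
  p <- ev[, 2L]
  off <- 6L * p_max + 1L
  idx <- integer(nrow(ev))
  is_pair <- code == 1L
  pt <- ev[is_pair, 4L]
  pp <- p[is_pair]
  idx[is_pair] <- ifelse(pt == 7L, off, (pp - 1L) * 6L + pt)
  idx[code == 2L] <- off + p[code == 2L]
  idx[code == 3L] <- off + p_max + p[code == 3L]
  asym <- code >= 4L
  idx[asym] <- off + 2L * p_max + p[asym]
  phi <- tabulate(idx, nbins = d)
  phi[off + 3L * p_max + pp] <- 1
  phi
}

#' Initial duplex structure for a (miRNA, site) pair
#'
#' `builtin` aligns under the fixed thermodynamic-like default weights of
#' [duplex_init_weights()]. `external` converts a dot-bracket duplex
#' structure (two strands separated by `&`, as produced by RNA duplex
#' folding tools) into the event grammar.
#'
#' @param mirna,site RNA sequences.
#' @param initializer `"builtin"` or `"external"`.
#' @param structure for `external`: dot-bracket string
#'   `mirna_struct&site_struct` in the two sequences' 5'->3' orientations.
#' @return a `duplex_alignment` (score under the builtin initializer weights
#'   for `builtin`; event counts only, score `NA`, for `external`).
#' @export
init_alignment <- function(mirna, site,
                           initializer = c("builtin", "external"),
                           structure = NULL) {
  initializer <- match.arg(initializer)
  if (initializer == "builtin") {
    return(align_duplex(duplex_init_weights(), mirna, site))
  }
  if (is.null(structure)) stopf("external initializer needs a structure")
  parse_dotbracket_duplex(mirna, site, structure)
}

# convert "((..((&))..))"-style duplex structure to the event grammar
parse_dotbracket_duplex <- function(mirna, site, structure) {
  mirna <- rna_normalize(mirna, "miRNA")
  site <- rna_normalize(site, "site")
  halves <- strsplit(structure, "&", fixed = TRUE)[[1]]
  if (length(halves) != 2L) stopf("structure must contain one '&'")
  sm <- strsplit(halves[1L], "")[[1]]
  ss <- strsplit(halves[2L], "")[[1]]
  if (length(sm) != nchar(mirna) || length(ss) != nchar(site)) {
    stopf("structure lengths do not match the sequences")
  }
  pm <- which(sm == "(")
  ps <- rev(which(ss == ")"))  # pairs nest: first '(' pairs last ')'
  if (length(pm) != length(ps)) stopf("unbalanced duplex structure")
  if (length(pm) == 0L) return(empty_alignment(mirna, site))
  mb <- strsplit(mirna, "")[[1]]
  sb <- strsplit(site, "")[[1]]
  events <- list()
  add <- function(event, p, q = NA_integer_, pair_type = NA_character_) {
    events[[length(events) + 1L]] <<- data.frame(
      event = event, p = p, q = q, pair_type = pair_type,
      stringsAsFactors = FALSE)
  }
  for (i in seq_along(pm)) {
    p <- pm[i]; q <- ps[i]
    if (i > 1L) {
      a <- pm[i] - pm[i - 1L] - 1L  # unpaired miRNA bases in between
      b <- ps[i - 1L] - ps[i] - 1L  # unpaired site bases in between
      if (a + b > 0L) {
        add("LOOP_OPEN", pm[i - 1L])
        nsym <- min(a, b)
        for (j in seq_len(nsym)) add("SYM_EXT", pm[i - 1L] + j)
        for (j in seq_len(a - nsym)) add("ASYM_EXT_MIRNA", pm[i - 1L] + nsym + j)
        for (j in seq_len(b - nsym)) add("ASYM_EXT_SITE", pm[i] - 1L)
      }
    }
    tp <- if (p == 1L) {
      if (sb[q] != "A") stopf("position-1 pair opposite non-A in structure")
      "m1A"
    } else {
      t <- paste0(mb[p], sb[q])
      if (!t %in% PAIR_TYPES) stopf("non-complementary pair %s at position %d",
                                    t, p)
      t
    }
    add("PAIR", p, q, tp)
  }
  structure(list(score = NA_real_, events = do.call(rbind, events),
                 mirna = mirna, site = site, anchor = "local"),
            class = "duplex_alignment")
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat(format_duplex(x), sep = "\n")
  invisible(x)
}

#' Three-line text rendering of a duplex alignment
#'
#' miRNA on top (5'->3'), pair bars in the middle, the site below (3'->5').
#'
#' @param alignment a `duplex_alignment`.
#' @return character vector of display lines.
#' @export
format_duplex <- function(alignment) {
  ev <- alignment$events
  if (nrow(ev) == 0L) {
    return(c(sprintf("miRNA 5' %s 3'", alignment$mirna),
             "   (no duplex: empty alignment, score 0)"))
  }
  mb <- strsplit(alignment$mirna, "")[[1]]
  sb <- strsplit(alignment$site, "")[[1]]
  top <- mid <- bot <- character()
  qcur <- ev$q[1L]
  for (i in seq_len(nrow(ev))) {
    switch(ev$event[i],
      PAIR = {
        top <- c(top, mb[ev$p[i]])
        mid <- c(mid, if (ev$pair_type[i] %in% c("GU", "UG")) ":" else "|")
        bot <- c(bot, sb[ev$q[i]])
        qcur <- ev$q[i]
      },
      SYM_EXT = {
        qcur <- qcur - 1L
        top <- c(top, mb[ev$p[i]]); mid <- c(mid, " "); bot <- c(bot, sb[qcur])
      },
      ASYM_EXT_MIRNA = {
        top <- c(top, mb[ev$p[i]]); mid <- c(mid, " "); bot <- c(bot, "-")
      },
      ASYM_EXT_SITE = {
        qcur <- qcur - 1L
        top <- c(top, "-"); mid <- c(mid, " "); bot <- c(bot, sb[qcur])
      },
      LOOP_OPEN = NULL)
  }
  c(sprintf("miRNA 5' %s 3'  (score %.3f)",
            paste(top, collapse = ""), alignment$score),
    sprintf("         %s", paste(mid, collapse = "")),
    sprintf("site  3' %s 5'", paste(bot, collapse = "")))
}
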