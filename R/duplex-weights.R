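# duplex weight vector: the scoring parameters w for local duplex alignment

#' Construct a duplex weight set
#'
#' The additive duplex score is a dot product of these weights with event
#' counts of an alignment: position-dependent scores for the six
#' complementary pair types (AU, UA, GC, CG, GU, UG), a single m1A score for
#' the only permissible pairing at miRNA position 1 (opposite adenosine),
#' per-position penalties for loop opening and symmetric/asymmetric loop
#' extension, and per-position paired indicators. The bias is not part of the
#' alignment score; it is added when scoring (miRNA, site) pairs.
#'
#' @param p_max maximum miRNA length supported (positions `1..p_max`).
#' @param pair 6 x `p_max` matrix of pair scores, rows named by pair type
#'   (miRNA base first).
#' @param m1A score of an adenosine paired opposite miRNA position 1.
#' @param open,sym,asym numeric length-`p_max` loop event weights.
#' @param paired numeric length-`p_max` paired-position indicator weights.
#' @param bias intercept added to pair scores at prediction time.
#' @return an object of class `duplex_weights`.
#' @export
duplex_weights <- function(p_max = 27L,
                           pair = matrix(0, 6, p_max,
                                         dimnames = list(PAIR_TYPES, NULL)),
                           m1A = 0, open = numeric(p_max),
                           sym = numeric(p_max), asym = numeric(p_max),
                           paired = numeric(p_max), bias = 0) {
  p_max <- as.integer(p_max)
  stopifnot(nrow(pair) == 6L, ncol(pair) == p_max,
            length(open) == p_max, length(sym) == p_max,
            length(asym) == p_max, length(paired) == p_max,
            length(m1A) == 1L, length(bias) == 1L)
  vals <- c(pair, m1A, open, sym, asym, paired, bias)
  if (!all(is.finite(vals))) stopf("duplex weights must all be finite")
  dimnames(pair) <- list(PAIR_TYPES, NULL)
  structure(list(p_max = p_max, pair = pair, m1A = unname(m1A),
                 open = unname(open), sym = unname(sym),
                 asym = unname(asym), paired = unname(paired),
                 bias = unname(bias)),
            class = "duplex_weights")
}

#' Flatten duplex weights to the feature-vector layout (and back)
#'
#' The flat layout (bias excluded) matches [featurize()]: pair scores
#' (pair type fastest, then miRNA position), m1A, loop opening, symmetric
#' and asymmetric extension weights, paired indicators — length
#' `10 * p_max + 1`.
#'
#' @param w a [duplex_weights()] object.
#' @return numeric vector of length `10 * p_max + 1`.
#' @export
duplex_weights_to_vector <- function(w) {
  c(as.vector(w$pair), w$m1A, w$open, w$sym, w$asym, w$paired)
}

#' @rdname duplex_weights_to_vector
#' @param v flat weight vector.
#' @param p_max maximum miRNA length.
#' @param bias intercept to attach.
#' @export
duplex_weights_from_vector <- function(v, p_max = 27L, bias = 0) {
  p_max <- as.integer(p_max)
  stopifnot(length(v) == 10L * p_max + 1L)
  pair <- matrix(v[seq_len(6L * p_max)], 6, p_max,
                 dimnames = list(PAIR_TYPES, NULL))
  i <- 6L * p_max
  duplex_weights(p_max = p_max, pair = pair, m1A = v[i + 1L],
                 open = v[i + 1L + seq_len(p_max)],
                 sym = v[i + 1L + p_max + seq_len(p_max)],
                 asym = v[i + 1L + 2L * p_max + seq_len(p_max)],
                 paired = v[i + 1L + 3L * p_max + seq_len(p_max)],
                 bias = bias)
}

duplex_feature_names <- function(p_max = 27L) {
  c(paste0("pair_", rep(PAIR_TYPES, p_max), "_", rep(seq_len(p_max), each = 6)),
    "m1A",
    paste0("open_", seq_len(p_max)), paste0("sym_", seq_len(p_max)),
    paste0("asym_", seq_len(p_max)), paste0("paired_", seq_len(p_max)))
}

#' Default thermodynamic-like initialization weights
#'
#' A fixed, hand-set weight vector used to produce initial duplex structures
#' before any learning: GC pairs 3, AU pairs 2, GU wobbles 1 at every
#' position, loop opening -3, symmetric extension -1, asymmetric extension
#' -2, paired indicators 0, m1A 2.
#'
#' @param p_max maximum miRNA length.
#' @return a `duplex_weights` object.
#' @export
duplex_init_weights <- function(p_max = 27L) {
  pair <- matrix(0, 6, p_max, dimnames = list(PAIR_TYPES, NULL))
  pair[c("GC", "CG"), ] <- 3
  pair[c("AU", "UA"), ] <- 2
  pair[c("GU", "UG"), ] <- 1
  duplex_weights(p_max = p_max, pair = pair, m1A = 2,
                 open = rep(-3, p_max), sym = rep(-1, p_max),
                 asym = rep(-2, p_max))
}

#' @export
print.duplex_weights <- function(x, ...) {
  cat(sprintf("Duplex alignment weights (p_max = %d)\n", x$p_max))
  cat(sprintf("  m1A = %.4g, bias = %.4g\n", x$m1A, x$bias))
  cat(sprintf("  mean pair score (pos 2-8): %.4g\n",
              mean(x$pair[, 2:min(8, x$p_max)])))
  cat(sprintf("  mean open/sym/asym: %.4g / %.4g / %.4g\n",
              mean(x$open), mean(x$sym), mean(x$asym)))
  invisible(x)
}

#' Serialize duplex weights to JSON
#'
#' @param w a `duplex_weights` object.
#' @param path output file path.
#' @export
write_duplex_weights <- function(w, path) {
  obj <- list(format = "mirduplex/duplex_weights", version = 1L,
              p_max = w$p_max, pair = as.data.frame(t(w$pair)), m1A = w$m1A,
              open = w$open, sym = w$sym, asym = w$asym, paired = w$paired,
              bias = w$bias)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read duplex weights from JSON
#'
#' @param path file written by [write_duplex_weights()].
#' @return a `duplex_weights` object.
#' @export
read_duplex_weights <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "mirduplex/duplex_weights")) {
    stopf("%s is not a duplex weights file", path)
  }
  pair <- t(as.matrix(obj$pair))
  dimnames(pair) <- list(PAIR_TYPES, NULL)
  duplex_weights(p_max = obj$p_max, pair = pair, m1A = obj$m1A,
                 open = obj$open, sym = obj$sym, asym = obj$asym,
                 paired = obj$paired, bias = obj$bias)
}
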