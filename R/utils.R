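# shared sequence helpers; RNA alphabet {A,C,G,U,N} everywhere internally

RNA_BASES <- c("A", "C", "G", "U")
PAIR_TYPES <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U. Any character outside `{A,C,G,U,N}` is an
#' error.
#'
#' @param x character vector of sequences.
#' @param what label used in error messages.
#' @return character vector over `{A,C,G,U,N}`.
#' @export
rna_normalize <- function(x, what = "sequence") {
  x <- toupper(x)
  x <- gsub("T", "U", x, fixed = TRUE)
  bad <- grepl("[^ACGUN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,U,N,T}: %s",
                 what, paste(utils::head(which(bad), 5), collapse = ", ")))
  }
  x
}

# integer encoding A=1 C=2 G=3 U=4, N=0
encode_rna <- function(seq) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  code <- match(v, RNA_BASES)
  code[is.na(code)] <- 0L
  as.integer(code)
}

decode_rna <- function(code) {
  paste(ifelse(code == 0L, "N", RNA_BASES[pmax(code, 1L)]), collapse = "")
}

#' Reverse complement of an RNA string
#'
#' N maps to N. Used to derive seed-complementary site sequences.
#'
#' @param seq RNA string.
#' @return RNA string, reverse complement.
#' @export
rna_revcomp <- function(seq) {
  v <- rev(strsplit(seq, "", fixed = TRUE)[[1]])
  comp <- c(A = "U", C = "G", G = "C", U = "A", N = "N")
  paste(comp[v], collapse = "")
}

# substring helpers operating on 0-based half-open UTR coordinates
utr_substr <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
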