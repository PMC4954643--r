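# typed readers/writers for the external tables and sequence files
#
# Coordinate convention, used everywhere in the package: 0-based, half-open
# intervals in UTR space, where UTR position 0 is the first base 3' of the
# stop codon. Isoform 3' ends are stored as the position of the last
# transcribed base + 1, so the longest isoform's end equals the UTR length.

read_tsv_file <- function(path, col_names) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE, col.names = col_names,
                          blank.lines.skip = TRUE)
  df
}

read_fasta_rna <- function(path, what) {
  if (!file.exists(path)) stopf("%s FASTA not found: %s", what, path)
  ss <- Biostrings::readBStringSet(path)
  seqs <- rna_normalize(as.character(ss), what)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(names(seqs))) {
    stopf("duplicate %s names in %s: %s", what, path,
          paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  }
  seqs
}

#' Read a miRNA catalog (FASTA + family table)
#'
#' @param fasta_path miRNA sequences (RNA or DNA alphabet; T is converted
#'   to U).
#' @param family_table_path tab-separated table `name, family` assigning each
#'   miRNA to a seed family; `#` lines are comments.
#' @return data frame with columns `name`, `family`, `sequence` (class
#'   `mirna_catalog`), input order preserved.
#' @export
read_mirna_catalog <- function(fasta_path, family_table_path) {
  seqs <- read_fasta_rna(fasta_path, "miRNA")
  fam <- read_tsv_file(family_table_path, c("name", "family"))
  missing <- setdiff(names(seqs), fam$name)
  if (length(missing)) {
    stopf("no family mapping for miRNA(s): %s", paste(missing, collapse = ", "))
  }
  lens <- nchar(seqs)
  if (any(lens < 18L | lens > 27L)) {
    stopf("miRNA length outside 18-27 nt: %s",
          paste(names(seqs)[lens < 18L | lens > 27L], collapse = ", "))
  }
  if (any(grepl("N", seqs, fixed = TRUE))) stopf("miRNA sequences contain N")
  out <- data.frame(name = names(seqs),
                    family = fam$family[match(names(seqs), fam$name)],
                    sequence = unname(seqs), stringsAsFactors = FALSE)
  if (any(!nzchar(out$family))) stopf("empty family labels in %s",
                                      family_table_path)
  class(out) <- c("mirna_catalog", "data.frame")
  out
}

#' Read a 3'UTR catalog with isoform 3'-end atlas
#'
#' @param fasta_path UTR sequences (first base after the stop codon first).
#' @param ends_bed_path tab-separated atlas `transcript_id, end_position`
#'   (UTR coordinates); may be `NULL`, in which case every transcript is
#'   single-isoform.
#' @return data frame with columns `transcript_id`, `sequence`, and a list
#'   column `three_prime_ends` (sorted, deduplicated, final entry = UTR
#'   length). Class `utr_catalog`.
#' @export
read_utr_atlas <- function(fasta_path, ends_bed_path = NULL) {
  seqs <- read_fasta_rna(fasta_path, "UTR")
  ends <- if (!is.null(ends_bed_path)) {
    read_tsv_file(ends_bed_path, c("transcript_id", "end_position"))
  } else {
    data.frame(transcript_id = character(), end_position = integer())
  }
  build_utr_catalog(names(seqs), unname(seqs), ends)
}

build_utr_catalog <- function(ids, seqs, ends) {
  lens <- nchar(seqs)
  tpe <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    e <- sort(unique(as.integer(ends$end_position[ends$transcript_id == ids[i]])))
    if (length(e) && (any(e > lens[i]) || any(e < 1L))) {
      stopf("atlas 3' end beyond UTR bounds for transcript %s", ids[i])
    }
    # the longest isoform's end is the full UTR
    e <- unique(c(e, lens[i]))
    tpe[[i]] <- e
  }
  unknown <- setdiff(unique(ends$transcript_id), ids)
  if (length(unknown)) {
    stopf("atlas rows for unknown transcript(s): %s",
          paste(unknown, collapse = ", "))
  }
  out <- data.frame(transcript_id = ids, sequence = seqs,
                    stringsAsFactors = FALSE)
  out$three_prime_ends <- tpe
  class(out) <- c("utr_catalog", "data.frame")
  out
}

#' Read CLASH-style chimeric interaction records
#'
#' Columns: `mirna_name, transcript_id, site_start, site_end,
#' chimeric_count, nonchimeric_support` (tab-separated, `#` comments).
#'
#' @param tsv_path input path.
#' @return validated data frame of interactions.
#' @export
read_interactions <- function(tsv_path) {
  df <- read_tsv_file(tsv_path, c("mirna_name", "transcript_id", "site_start",
                                  "site_end", "chimeric_count",
                                  "nonchimeric_support"))
  bad <- which(df$site_start >= df$site_end | df$site_start < 0)
  if (length(bad)) stopf("invalid site interval at interaction row(s): %s",
                         paste(bad, collapse = ", "))
  bad <- which(df$chimeric_count < 1 | df$nonchimeric_support < 0)
  if (length(bad)) stopf("invalid read counts at interaction row(s): %s",
                         paste(bad, collapse = ", "))
  df
}

#' Read AGO CLIP peaks (BED4 + read count)
#'
#' Columns: `transcript_id, start, end, name, read_count` in UTR coordinates
#' (0-based half-open).
#'
#' @param bed_path input path.
#' @return validated data frame of peaks.
#' @export
read_peaks <- function(bed_path) {
  df <- read_tsv_file(bed_path, c("transcript_id", "start", "end", "name",
                                  "read_count"))
  bad <- which(df$start >= df$end | df$start < 0)
  if (length(bad)) stopf("invalid peak interval at row(s): %s",
                         paste(bad, collapse = ", "))
  bad <- which(df$read_count < 0)
  if (length(bad)) stopf("negative read_count at peak row(s): %s",
                         paste(bad, collapse = ", "))
  df
}

#' Read RNAcompete-style probe intensity tables
#'
#' One tab-separated file per experiment (`probe_sequence, intensity`); the
#' experiment id is the file name without extension.
#'
#' @param dir_path directory of `.tsv` files (or a single file path).
#' @return named list of data frames (`probe_sequence`, `intensity`).
#' @export
read_probe_tables <- function(dir_path) {
  files <- if (dir.exists(dir_path)) {
    list.files(dir_path, pattern = "\\.tsv$", full.names = TRUE)
  } else dir_path
  if (!length(files)) stopf("no probe tables found in %s", dir_path)
  out <- lapply(files, function(f) {
    df <- read_tsv_file(f, c("probe_sequence", "intensity"))
    df$probe_sequence <- rna_normalize(df$probe_sequence, "probe")
    if (any(!nzchar(df$probe_sequence))) stopf("empty probe sequence in %s", f)
    bad <- which(!is.finite(df$intensity))
    if (length(bad)) stopf("non-finite intensity in %s at row(s): %s", f,
                           paste(bad, collapse = ", "))
    df
  })
  names(out) <- sub("\\.tsv$", "", basename(files))
  out
}

#' Write typed tables back to their on-disk formats
#'
#' Writers matching the readers above, used by the synthetic-data generator
#' and the pipeline commands; write-then-read is the identity on the typed
#' records.
#'
#' @param x typed records as returned by the corresponding reader.
#' @param path output path.
#' @name iokit-writers
NULL

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

write_fasta <- function(seqs, names, path) {
  writeLines(paste0(">", names, "\n", seqs), path)
  invisible(path)
}

#' @rdname iokit-writers
#' @export
write_mirna_catalog <- function(x, fasta_path, family_table_path) {
  write_fasta(x$sequence, x$name, fasta_path)
  write_tsv_file(x[, c("name", "family")], family_table_path)
}

#' @rdname iokit-writers
#' @param fasta_path,ends_bed_path,tsv_path,bed_path output locations.
#' @export
write_utr_atlas <- function(x, fasta_path, ends_bed_path) {
  write_fasta(x$sequence, x$transcript_id, fasta_path)
  rows <- do.call(rbind, lapply(seq_len(nrow(x)), function(i) {
    data.frame(transcript_id = x$transcript_id[i],
               end_position = x$three_prime_ends[[i]])
  }))
  write_tsv_file(rows, ends_bed_path)
}

#' @rdname iokit-writers
#' @export
write_interactions <- function(x, tsv_path) write_tsv_file(x, tsv_path)

#' @rdname iokit-writers
#' @export
write_peaks <- function(x, bed_path) write_tsv_file(x, bed_path)
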