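# synthetic fixture generator: miRNA catalogs, UTR atlases, CLASH/CLIP-style
# records and probe tables with planted, known structure

#' Simulation configuration
#'
#' Defines the study conditions every planted quantity is generated under:
#' catalog sizes, background base composition, the planted duplex scoring
#' vector `w_star`, the planted flank motif and positional bias of bound
#' sites, noise rates, and the number of tasks (cell types).
#'
#' @param rng_seed integer seed; fixed seed gives byte-identical outputs.
#' @param n_families,mirnas_per_family miRNA catalog shape.
#' @param n_utrs number of 3'UTRs.
#' @param utr_len_meanlog,utr_len_sdlog,utr_len_range log-normal UTR length
#'   distribution (clipped).
#' @param base_comp background base probabilities (A, C, G, U).
#' @param w_star planted duplex weights (default: seed-emphasized
#'   thermodynamic-like weights, see [sim_default_wstar()]).
#' @param n_clash_pos planted chimera-supported interactions.
#' @param frac_noncanonical fraction of planted interactions whose seed
#'   pairing carries one edit (substitution or indel).
#' @param score_quantile background-score quantile a planted site must
#'   exceed under `w_star`.
#' @param n_bound,n_unbound planted AGO-bound / unbound canonical seed
#'   sites (split across tasks).
#' @param motif,motif_flank,motif_offset,motif_prob planted flank motif of
#'   bound sites: a 6-mer written into the downstream flank at a fixed
#'   offset with the given probability.
#' @param pos_bias_window,pos_bias_odds positional bias: bound sites fall
#'   within `pos_bias_window` nt upstream of an isoform 3' end with odds
#'   `pos_bias_odds : 1`.
#' @param peak_fp_rate,peak_fn_rate peak-calling noise: fraction of
#'   spurious peaks added and of bound sites whose peak is dropped.
#' @param n_tasks number of tasks (cell types).
#' @param task_motifs optional per-task extra motifs (character vector of
#'   length `n_tasks`, `""` for none) written alongside the common motif.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(rng_seed = 1L, n_families = 8L, mirnas_per_family = 2L,
                       n_utrs = 300L, utr_len_meanlog = log(600),
                       utr_len_sdlog = 0.35, utr_len_range = c(250L, 2000L),
                       base_comp = c(A = 0.3, C = 0.2, G = 0.2, U = 0.3),
                       w_star = sim_default_wstar(),
                       n_clash_pos = 120L, frac_noncanonical = 0.4,
                       score_quantile = 0.95, n_bound = 150L,
                       n_unbound = 150L, motif = "UGUACA",
                       motif_flank = "down", motif_offset = 8L,
                       motif_prob = 0.8, pos_bias_window = 150L,
                       pos_bias_odds = 4, peak_fp_rate = 0.05,
                       peak_fn_rate = 0.02, n_tasks = 2L,
                       task_motifs = NULL) {
  stopifnot(all(abs(sum(base_comp) - 1) < 1e-9), frac_noncanonical >= 0,
            frac_noncanonical <= 1, motif_prob >= 0, motif_prob <= 1,
            peak_fp_rate >= 0, peak_fn_rate >= 0, peak_fn_rate <= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Planted duplex weights used by the generator
#'
#' The thermodynamic-like initializer weights with the pairing scores of
#' miRNA positions 2-8 doubled (seed emphasis) and a positive m1A score,
#' so that high-scoring sites are seed-driven duplexes with optional 3'
#' pairing, as in real AGO-loaded interactions.
#'
#' @param p_max weight dimension.
#' @return a `duplex_weights` object.
#' @export
sim_default_wstar <- function(p_max = 27L) {
  w <- duplex_init_weights(p_max)
  w$pair[, 2:8] <- 2 * w$pair[, 2:8]
  w$m1A <- 3
  w
}

random_rna <- function(rng, n_bases, comp) {
  paste(rng$sample(RNA_BASES, n_bases, replace = TRUE, prob = comp),
        collapse = "")
}

#' Simulate a miRNA catalog and UTR atlas
#'
#' Family members share positions 2-7 exactly (a common seed); UTRs are
#' drawn from the background composition and carry 1-3 isoform 3' ends,
#' the last at the full UTR length.
#'
#' @param cfg a [sim_config()].
#' @return list with `mirnas` (catalog data frame) and `utrs` (catalog with
#'   `three_prime_ends`).
#' @export
simulate_catalog <- function(cfg) {
  rng <- local_rng(cfg$rng_seed)
  mirnas <- list()
  for (f in seq_len(cfg$n_families)) {
    seed <- random_rna(rng, 6L, cfg$base_comp)
    for (m in seq_len(cfg$mirnas_per_family)) {
      len <- rng$sample(21:22, 1L)
      seq <- paste0(random_rna(rng, 1L, cfg$base_comp), seed,
                    random_rna(rng, len - 7L, cfg$base_comp))
      mirnas[[length(mirnas) + 1L]] <- data.frame(
        name = sprintf("sim-miR-%d%s", f, letters[m]),
        family = sprintf("fam-%d", f), sequence = seq,
        stringsAsFactors = FALSE)
    }
  }
  mirnas <- do.call(rbind, mirnas)
  lens <- pmin(pmax(round(exp(rng$rnorm(cfg$n_utrs, cfg$utr_len_meanlog,
                                        cfg$utr_len_sdlog))),
                    cfg$utr_len_range[1L]), cfg$utr_len_range[2L])
  seqs <- vapply(lens, function(L) random_rna(rng, L, cfg$base_comp), "")
  ends <- lapply(seq_len(cfg$n_utrs), function(i) {
    n_int <- rng$sample(0:2, 1L)
    if (n_int > 0 && lens[i] > 200L) {
      internal <- sort(rng$sample(100:(lens[i] - 50L), n_int))
      unique(c(internal, lens[i]))
    } else lens[i]
  })
  utrs <- data.frame(transcript_id = sprintf("sim-utr-%03d",
                                             seq_len(cfg$n_utrs)),
                     sequence = seqs, stringsAsFactors = FALSE)
  utrs$three_prime_ends <- ends
  class(utrs) <- c("utr_catalog", "data.frame")
  class(mirnas) <- c("mirna_catalog", "data.frame")
  list(mirnas = mirnas, utrs = utrs)
}

# mutate one position of the seed-complement region to edit distance 1
mutate_seed <- function(rng, site_chars, lo, hi) {
  op <- rng$sample(c("sub", "del", "ins"), 1L, prob = c(0.6, 0.2, 0.2))
  pos <- rng$sample(lo:hi, 1L)
  if (op == "sub") {
    site_chars[pos] <- rng$sample(setdiff(RNA_BASES, site_chars[pos]), 1L)
    site_chars
  } else if (op == "del") {
    site_chars[-pos]
  } else {
    append(site_chars, rng$sample(RNA_BASES, 1L), after = pos)
  }
}

# a site sequence that aligns strongly to `mirna` under w_star
planted_site <- function(rng, mirna, w_star, frac_noncanonical, comp) {
  rc <- strsplit(rna_revcomp(mirna), "")[[1]]
  Lm <- length(rc)
  # rc index opposite miRNA position p is Lm - p + 1
  rc[Lm] <- "A"  # m1A
  # degrade some of the 3'-supplementary pairing (opposite positions 9..Lm)
  supp <- seq_len(Lm - 8L)
  flip <- supp[rng$runif(length(supp)) < 0.3]
  for (i in flip) rc[i] <- rng$sample(RNA_BASES, 1L)
  if (rng$runif(1L) < frac_noncanonical) {
    # one edit inside the seed complement (opposite positions 2..7)
    rc <- mutate_seed(rng, rc, Lm - 6L, Lm - 1L)
  }
  paste0(random_rna(rng, 2L, comp), paste(rc, collapse = ""),
         random_rna(rng, 2L, comp))
}

# background score quantile of w_star alignments against random windows
background_threshold <- function(rng, mirnas, utrs, w_star, quantile,
                                 n_draws = 50L) {
  thr <- numeric(nrow(mirnas))
  for (i in seq_len(nrow(mirnas))) {
    sc <- vapply(seq_len(n_draws), function(j) {
      u <- rng$sample(nrow(utrs), 1L)
      L <- nchar(utrs$sequence[u])
      s <- rng$sample(L - 30L, 1L)
      align_duplex(w_star, mirnas$sequence[i],
                   utr_substr(utrs$sequence[u], s, s + 26L))$score
    }, numeric(1L))
    thr[i] <- stats::quantile(sc, quantile, names = FALSE)
  }
  thr
}

#' Simulate interactions, peaks and ground-truth labels
#'
#' Plants chimera-supported (miRNA, site) interactions whose duplex
#' alignment under the configured `w_star` scores above a background
#' quantile (a configurable fraction with a one-edit, non-canonical seed),
#' and AGO-bound versus unbound canonical seed sites with the configured
#' flank motif and positional bias. Peaks cover bound sites (minus a
#' false-negative rate) plus spurious background peaks. UTR sequences are
#' modified in place by the planting, so the returned `utrs` replace the
#' input catalog.
#'
#' @param cfg a [sim_config()].
#' @param mirnas,utrs catalogs from [simulate_catalog()].
#' @return list with `utrs` (updated), `interactions`, `peaks_by_task`
#'   (list of peak data frames), `binding_sites` (planted bound/unbound
#'   site table with task and motif annotations) and `ground_truth` (one
#'   row per planted element).
#' @export
simulate_interactions <- function(cfg, mirnas, utrs) {
  rng <- local_rng(cfg$rng_seed + 1L)
  if (cfg$pos_bias_window >= min(nchar(utrs$sequence))) {
    stopf("pos_bias_window larger than the shortest UTR")
  }
  occupied <- lapply(seq_len(nrow(utrs)), function(i) {
    matrix(numeric(), 0L, 2L)
  })
  margin <- 36L
  claim <- function(u, s, e) {
    occ <- occupied[[u]]
    if (nrow(occ) && any(occ[, 1L] < e + margin & occ[, 2L] + margin > s)) {
      return(FALSE)
    }
    occupied[[u]] <<- rbind(occ, c(s, e))
    TRUE
  }
  seqs <- utrs$sequence
  write_into <- function(u, s, frag) {
    substr(seqs[u], s + 1L, s + nchar(frag)) <<- frag
  }

  thr <- background_threshold(rng, mirnas, utrs, cfg$w_star,
                              cfg$score_quantile)
  # ---- CLASH-style chimeric interactions -------------------------------
  interactions <- list()
  truth <- list()
  n_placed <- 0L
  guard <- 0L
  while (n_placed < cfg$n_clash_pos && guard < 50L * cfg$n_clash_pos) {
    guard <- guard + 1L
    mi <- rng$sample(nrow(mirnas), 1L)
    frag <- planted_site(rng, mirnas$sequence[mi], cfg$w_star,
                         cfg$frac_noncanonical, cfg$base_comp)
    if (align_duplex(cfg$w_star, mirnas$sequence[mi], frag)$score < thr[mi]) {
      next
    }
    u <- rng$sample(nrow(utrs), 1L)
    L <- nchar(seqs[u])
    if (L < nchar(frag) + 80L) next
    s <- rng$sample((L - nchar(frag) - 40L), 1L) + 30L
    if (!claim(u, s, s + nchar(frag))) next
    write_into(u, s, frag)
    n_placed <- n_placed + 1L
    interactions[[n_placed]] <- data.frame(
      mirna_name = mirnas$name[mi], transcript_id = utrs$transcript_id[u],
      site_start = s, site_end = s + nchar(frag),
      chimeric_count = 1L + rng$rpois(1L, 2),
      nonchimeric_support = 1L + rng$rpois(1L, 3),
      stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      kind = "clash_positive", family = mirnas$family[mi],
      transcript_id = utrs$transcript_id[u], start = s,
      end = s + nchar(frag), task = "clash", has_motif = FALSE,
      stringsAsFactors = FALSE)
  }
  interactions <- do.call(rbind, interactions)

  # ---- bound / unbound canonical seed sites ----------------------------
  fams <- unique(mirnas$family)
  seed_site_of <- vapply(fams, function(f) {
    m <- mirnas$sequence[match(f, mirnas$family)]
    rna_revcomp(substr(m, 2L, 7L))
  }, "")
  tasks <- sprintf("task-%d", seq_len(cfg$n_tasks))
  # each task (cell type) expresses its own transcript set, so sites of
  # one task are never scanned against another task's peaks
  utr_task <- rep(tasks, length.out = nrow(utrs))
  task_motifs <- cfg$task_motifs %||% rep("", cfg$n_tasks)
  n_sites <- cfg$n_bound + cfg$n_unbound
  bound_flag <- rep(c(TRUE, FALSE), c(cfg$n_bound, cfg$n_unbound))
  sites <- list()
  placed <- 0L
  guard <- 0L
  p_bias <- cfg$pos_bias_odds / (1 + cfg$pos_bias_odds)
  while (placed < n_sites && guard < 50L * n_sites) {
    guard <- guard + 1L
    bound <- bound_flag[placed + 1L]
    fam <- rng$sample_vec(fams, 1L)
    task <- tasks[1L + (placed %% cfg$n_tasks)]
    u <- rng$sample_vec(which(utr_task == task), 1L)
    L <- nchar(seqs[u])
    if (L < 140L) next
    biased <- bound && rng$runif(1L) < p_bias
    if (biased) {
      e3 <- rng$sample_vec(utrs$three_prime_ends[[u]], 1L)
      lo <- max(40L, e3 - cfg$pos_bias_window)
      hi <- min(e3 - 6L, L - 46L)
      if (lo >= hi) next
      s <- rng$sample(lo:hi, 1L)
    } else {
      s <- rng$sample(40:(L - 46L), 1L)
    }
    if (!claim(u, s, s + 6L)) next
    write_into(u, s, seed_site_of[[fam]])
    placed <- placed + 1L
    has_motif <- FALSE
    if (bound && rng$runif(1L) < cfg$motif_prob) {
      has_motif <- TRUE
      if (cfg$motif_flank == "down") {
        write_into(u, s + 6L + cfg$motif_offset - 1L, cfg$motif)
      } else {
        write_into(u, s - cfg$motif_offset - nchar(cfg$motif) + 1L,
                   cfg$motif)
      }
    }
    tm <- task_motifs[match(task, tasks)]
    if (bound && nzchar(tm)) {
      write_into(u, s + 6L + cfg$motif_offset + 7L, tm)
    }
    sites[[placed]] <- data.frame(
      kind = if (bound) "bound" else "unbound", family = fam,
      transcript_id = utrs$transcript_id[u], start = s, end = s + 6L,
      task = task, has_motif = has_motif, stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, sites)

  # ---- peaks -----------------------------------------------------------
  peaks_by_task <- list()
  for (tk in tasks) {
    st <- sites[sites$task == tk & sites$kind == "bound", , drop = FALSE]
    keep <- rng$runif(nrow(st)) >= cfg$peak_fn_rate
    st <- st[keep, , drop = FALSE]
    pk <- data.frame(transcript_id = st$transcript_id,
                     start = pmax(0L, st$start - rng$sample(3:10, nrow(st),
                                                            replace = TRUE)),
                     end = st$end + rng$sample(3:10, nrow(st),
                                               replace = TRUE),
                     name = sprintf("%s-peak-%d", tk, seq_len(nrow(st))),
                     read_count = 5L + rng$rpois(nrow(st), 20),
                     stringsAsFactors = FALSE)
    n_fp <- round(cfg$peak_fp_rate * nrow(pk))
    if (n_fp > 0) {
      fp_u <- rng$sample(nrow(utrs), n_fp, replace = TRUE)
      fp_s <- vapply(fp_u, function(u) {
        rng$sample(nchar(seqs[u]) - 40L, 1L)
      }, numeric(1L))
      pk <- rbind(pk, data.frame(
        transcript_id = utrs$transcript_id[fp_u], start = fp_s,
        end = fp_s + rng$sample(15:30, n_fp, replace = TRUE),
        name = sprintf("%s-fp-%d", tk, seq_len(n_fp)),
        read_count = 1L + rng$rpois(n_fp, 5), stringsAsFactors = FALSE))
    }
    peaks_by_task[[tk]] <- pk
  }

  utrs$sequence <- seqs
  ground_truth <- rbind(do.call(rbind, truth), sites)
  list(utrs = utrs, interactions = interactions,
       peaks_by_task = peaks_by_task, binding_sites = sites,
       utr_tasks = data.frame(transcript_id = utrs$transcript_id,
                              task = utr_task, stringsAsFactors = FALSE),
       ground_truth = ground_truth)
}

#' Simulate an RNAcompete-style probe intensity table
#'
#' Probes are random RNA of fixed length; the motif is written into a
#' fraction of them, and motif-carrying probes get their intensity shifted
#' by `effect` standard deviations.
#'
#' @param cfg a [sim_config()] (supplies the seed and base composition).
#' @param motif planted motif (default the config's flank motif).
#' @param n_probes number of probes.
#' @param probe_len probe length in nt.
#' @param effect intensity shift of motif-carrying probes (0 = null
#'   table).
#' @param plant_frac fraction of probes the motif is written into.
#' @param rng_seed optional seed override.
#' @return data frame `probe_sequence, intensity`.
#' @export
simulate_probe_table <- function(cfg, motif = cfg$motif, n_probes = 1500L,
                                 probe_len = 38L, effect = 1,
                                 plant_frac = 0.25,
                                 rng_seed = cfg$rng_seed + 2L) {
  stopifnot(nchar(motif) <= probe_len)
  rng <- local_rng(rng_seed)
  seqs <- vapply(seq_len(n_probes), function(i) {
    random_rna(rng, probe_len, cfg$base_comp)
  }, "")
  plant <- rng$runif(n_probes) < plant_frac
  for (i in which(plant)) {
    at <- rng$sample(probe_len - nchar(motif) + 1L, 1L)
    substr(seqs[i], at, at + nchar(motif) - 1L) <- motif
  }
  has <- grepl(motif, seqs, fixed = TRUE)
  data.frame(probe_sequence = seqs,
             intensity = rng$rnorm(n_probes) + effect * has,
             stringsAsFactors = FALSE)
}

#' Simulate a complete dataset, optionally writing it to disk
#'
#' Runs [simulate_catalog()] and [simulate_interactions()] and, when `dir`
#' is given, writes every input format the readers accept (miRNA FASTA +
#' family table, UTR FASTA + isoform-end atlas, interaction TSV, per-task
#' peak BEDs, a probe table) plus a `ground_truth.tsv`.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory or `NULL`.
#' @return list with all simulated objects (invisible when writing).
#' @export
simulate_dataset <- function(cfg, dir = NULL) {
  cat0 <- simulate_catalog(cfg)
  sim <- simulate_interactions(cfg, cat0$mirnas, cat0$utrs)
  probe <- simulate_probe_table(cfg)
  out <- list(mirnas = cat0$mirnas, utrs = sim$utrs,
              interactions = sim$interactions,
              peaks_by_task = sim$peaks_by_task,
              binding_sites = sim$binding_sites,
              utr_tasks = sim$utr_tasks,
              ground_truth = sim$ground_truth, probe_table = probe,
              config = cfg)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_mirna_catalog(out$mirnas, file.path(dir, "mirnas.fa"),
                        file.path(dir, "mirna_families.tsv"))
    write_utr_atlas(out$utrs, file.path(dir, "utrs.fa"),
                    file.path(dir, "utr_ends.tsv"))
    write_interactions(out$interactions, file.path(dir, "interactions.tsv"))
    write_tsv_file(out$utr_tasks, file.path(dir, "utr_tasks.tsv"))
    for (tk in names(out$peaks_by_task)) {
      write_peaks(out$peaks_by_task[[tk]],
                  file.path(dir, sprintf("peaks_%s.bed", tk)))
    }
    dir.create(file.path(dir, "probes"), showWarnings = FALSE)
    write_tsv_file(out$probe_table,
                   file.path(dir, "probes", "sim-rbp-1.tsv"))
    write_tsv_file(out$ground_truth, file.path(dir, "ground_truth.tsv"))
    return(invisible(out))
  }
  out
}
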