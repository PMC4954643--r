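# end-to-end pipeline steps wiring the modules together; each step is the
# body behind one CLI subcommand and writes its resolved configuration next
# to its outputs

write_run_config <- function(params, out_path) {
  cfg_path <- paste0(out_path, ".run.json")
  params$package_version <- as.character(utils::packageVersion("mirduplex"))
  jsonlite::write_json(params, cfg_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(cfg_path)
}

#' Load a simulated or user-assembled input directory
#'
#' Reads the miRNA catalog, UTR atlas, interactions, per-task peak files
#' (`peaks_<task>.bed`) and, when present, the transcript-to-task table
#' from one directory laid out as [run_simulate()] writes it.
#'
#' @param dir input directory.
#' @return list with `mirnas`, `utrs`, `interactions`, `peaks_by_task`
#'   and `utr_tasks` (`NULL` when absent).
#' @export
load_fixture_dir <- function(dir) {
  mirnas <- read_mirna_catalog(file.path(dir, "mirnas.fa"),
                               file.path(dir, "mirna_families.tsv"))
  utrs <- read_utr_atlas(file.path(dir, "utrs.fa"),
                         file.path(dir, "utr_ends.tsv"))
  interactions <- read_interactions(file.path(dir, "interactions.tsv"))
  peak_files <- list.files(dir, pattern = "^peaks_.*\\.bed$",
                           full.names = TRUE)
  peaks_by_task <- lapply(peak_files, read_peaks)
  names(peaks_by_task) <- sub("^peaks_(.*)\\.bed$", "\\1",
                              basename(peak_files))
  tasks_file <- file.path(dir, "utr_tasks.tsv")
  utr_tasks <- if (file.exists(tasks_file)) {
    read_tsv_file(tasks_file, c("transcript_id", "task"))
  }
  list(mirnas = mirnas, utrs = utrs, interactions = interactions,
       peaks_by_task = peaks_by_task, utr_tasks = utr_tasks)
}

#' Pipeline step: simulate a fixture directory
#'
#' @param out_dir output directory.
#' @param rng_seed seed for the generator.
#' @param ... overrides passed to [sim_config()].
#' @return the output directory, invisibly.
#' @export
run_simulate <- function(out_dir, rng_seed = 1L, ...) {
  cfg <- sim_config(rng_seed = rng_seed, ...)
  simulate_dataset(cfg, out_dir)
  write_run_config(cfg[setdiff(names(cfg), "w_star")],
                   file.path(out_dir, "fixture"))
  invisible(out_dir)
}

#' Pipeline step: build the labeled training set
#'
#' CLASH positives (three-filter rule), mispaired CLASH negatives, and
#' per-task CLIP positive/negative seed-site examples.
#'
#' @param data_dir fixture/input directory (see [run_simulate()] for the
#'   layout).
#' @param out_path output TSV of labeled sites.
#' @param rng_seed seed for the mispairing draw.
#' @param mispair_per_positive decoy miRNAs per CLASH positive.
#' @return the labeled-site data frame, invisibly.
#' @export
run_build_trainset <- function(data_dir, out_path, rng_seed = 1L,
                               mispair_per_positive = 15L) {
  d <- load_fixture_dir(data_dir)
  pos <- build_clash_positives(d$interactions, d$utrs, d$mirnas)
  neg <- build_mispaired_negatives(pos, d$mirnas, rng_seed = rng_seed,
                                   per_positive = mispair_per_positive)
  clip <- do.call(rbind, lapply(names(d$peaks_by_task), function(tk) {
    u <- d$utrs
    if (!is.null(d$utr_tasks)) {
      u <- u[u$transcript_id %in%
               d$utr_tasks$transcript_id[d$utr_tasks$task == tk], ,
             drop = FALSE]
    }
    build_clip_examples(u, d$peaks_by_task[[tk]], d$mirnas, task = tk)
  }))
  out <- rbind(pos, neg, clip %||% empty_labeled_sites())
  write_labeled_sites(out, out_path)
  write_run_config(list(data_dir = data_dir, rng_seed = rng_seed,
                        mispair_per_positive = mispair_per_positive),
                   out_path)
  invisible(out)
}

#' Pipeline step: train the duplex model
#'
#' @param data_dir input directory.
#' @param trainset_path labeled-site TSV from [run_build_trainset()].
#' @param out_model output model JSON.
#' @param control a [duplex_control()].
#' @return the fitted `duplex_svm`, invisibly.
#' @export
run_train_duplex <- function(data_dir, trainset_path, out_model,
                             control = duplex_control()) {
  d <- load_fixture_dir(data_dir)
  ex <- read_labeled_sites(trainset_path)
  ex <- ex[ex$source == "clash", , drop = FALSE]
  fit <- duplex_svm(ex, d$mirnas, d$utrs, control = control)
  write_duplex_model(fit, out_model)
  write_run_config(unclass(control), out_model)
  invisible(fit)
}

#' Pipeline step: train the binding model
#'
#' @inheritParams run_train_duplex
#' @param control a [binding_control()].
#' @return the fitted `binding_svm`, invisibly.
#' @export
run_train_binding <- function(data_dir, trainset_path, out_model,
                              control = binding_control()) {
  d <- load_fixture_dir(data_dir)
  ex <- read_labeled_sites(trainset_path)
  ex <- ex[ex$source == "clip", , drop = FALSE]
  fit <- binding_svm(ex, d$utrs, control = control)
  write_binding_model(fit, out_model)
  write_run_config(unclass(control), out_model)
  invisible(fit)
}

#' Pipeline step: score sites with both models
#'
#' Emits one row per scored site: duplex score, common and task binding
#' scores, and the combined score (z-sum calibrated on the scored set).
#'
#' @param data_dir input directory.
#' @param sites_path labeled-site TSV of sites to score.
#' @param duplex_model_path,binding_model_path model JSON files.
#' @param out_path output score TSV.
#' @return the score data frame, invisibly.
#' @export
run_score <- function(data_dir, sites_path, duplex_model_path,
                      binding_model_path, out_path) {
  d <- load_fixture_dir(data_dir)
  sites <- read_labeled_sites(sites_path)
  dm <- read_duplex_model(duplex_model_path)
  bm <- read_binding_model(binding_model_path)
  ds <- predict(dm, sites, d$mirnas, d$utrs)
  bs <- predict_binding(bm, sites, d$utrs, mode = "common")
  bt <- vapply(seq_len(nrow(sites)), function(i) {
    if (sites$task[i] %in% bm$task_registry) {
      predict_binding(bm, sites[i, ], d$utrs, mode = sites$task[i])
    } else NA_real_
  }, numeric(1L))
  cal <- fit_score_calibration(ds, bs)
  out <- data.frame(transcript_id = sites$transcript_id,
                    site_start = sites$site_start,
                    site_end = sites$site_end, family = sites$family,
                    duplex_score = ds, binding_score_common = bs,
                    binding_score_task = bt,
                    combined = combine_scores(ds, bs, "sum_z", cal),
                    stringsAsFactors = FALSE)
  utils::write.table(out, out_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}

#' Pipeline step: interpret a binding model
#'
#' Writes POIM tables for the requested k and flanks, the top k-mer set at
#' the most discriminative 5-/6-mer position, and (when a probe directory
#' is present) the per-experiment enrichment report.
#'
#' @param data_dir input directory (probe tables under `probes/`).
#' @param binding_model_path model JSON.
#' @param out_dir report directory.
#' @param k_choices POIM orders considered for the top position.
#' @param n_perm label permutations for the empirical FDR (0 disables).
#' @param rng_seed seed for the permutations.
#' @return list of report paths, invisibly.
#' @export
run_interpret <- function(data_dir, binding_model_path, out_dir,
                          k_choices = c(5L, 6L), n_perm = 100L,
                          rng_seed = 1L) {
  bm <- read_binding_model(binding_model_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  poims <- list()
  for (flank in c("up", "down")) {
    for (k in k_choices) {
      p <- compute_poim(bm, k, flank)
      poims[[sprintf("%s_%d", flank, k)]] <- p
      utils::write.table(p$Q, file.path(out_dir,
                                        sprintf("poim_%s_%dmer.tsv", flank,
                                                k)),
                         sep = "\t", quote = FALSE)
    }
  }
  top <- top_kmers(poims)
  jsonlite::write_json(top, file.path(out_dir, "top_kmers.json"),
                       auto_unbox = TRUE, digits = NA)
  probe_dir <- file.path(data_dir, "probes")
  reports <- NULL
  if (dir.exists(probe_dir)) {
    tabs <- read_probe_tables(probe_dir)
    n_top_probes <- min(1000L, min(vapply(tabs, nrow, integer(1L))))
    reports <- do.call(rbind, lapply(names(tabs), function(id) {
      enr <- kmer_enrichment(tabs[[id]], top$kmers,
                             n_top_probes = n_top_probes,
                             experiment_id = id)
      fdr <- if (n_perm > 0) {
        empirical_fdr(enr$p, bm, tabs[[id]], top$k, top$position, top$flank,
                      n_perm = n_perm, rng_seed = rng_seed,
                      n_top_probes = n_top_probes)$fdr
      } else NA_real_
      data.frame(experiment_id = id, statistic = enr$statistic, p = enr$p,
                 fdr = fdr, kmers = paste(top$kmers, collapse = ","),
                 k = top$k, position = top$position,
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(reports, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_run_config(list(k_choices = k_choices, n_perm = n_perm,
                        rng_seed = rng_seed),
                   file.path(out_dir, "interpret"))
  invisible(list(out_dir = out_dir, top = top, reports = reports))
}

#' Pipeline step: held-out-family evaluation
#'
#' @param data_dir input directory.
#' @param trainset_path labeled-site TSV.
#' @param out_path report TSV.
#' @param control a [duplex_control()].
#' @return the `ranking_eval` data frame, invisibly.
#' @export
run_evaluate <- function(data_dir, trainset_path, out_path,
                         control = duplex_control()) {
  d <- load_fixture_dir(data_dir)
  ex <- read_labeled_sites(trainset_path)
  ex <- ex[ex$source == "clash", , drop = FALSE]
  ev <- evaluate_heldout(ex, d$mirnas, d$utrs, control = control)
  utils::write.table(ev, out_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_run_config(unclass(control), out_path)
  invisible(ev)
}

#' Serialize / restore a fitted binding model
#'
#' The JSON stores the dual coefficients, bias, kernel parameters,
#' normalization constants and the support examples' flanks and positional
#' contexts, so predictions are reproducible from the file alone; the
#' training kernel is recomputed from the stored features on read.
#'
#' @param model a `binding_svm`.
#' @param path JSON file path.
#' @export
write_binding_model <- function(model, path) {
  obj <- list(format = "mirduplex/binding_model", version = 1L,
              alpha_y = model$alpha_y, bias = model$bias,
              examples = model$examples,
              upstream = vapply(model$flanks, `[[`, "", "upstream"),
              downstream = vapply(model$flanks, `[[`, "", "downstream"),
              contexts = do.call(rbind, lapply(model$contexts, function(c) {
                data.frame(d_stop = c$d_stop, d_next_end = c$d_next_end,
                           d_prev_end = c$d_prev_end,
                           prev_is_sentinel = c$prev_is_sentinel)
              })),
              tasks = model$tasks, task_registry = model$task_registry,
              multitask = model$multitask, mu = model$mu,
              gamma = model$gamma, degree = model$degree,
              scales = as.list(model$scales),
              control = unclass(model$control))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_binding_model
#' @export
read_binding_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "mirduplex/binding_model")) {
    stopf("%s is not a binding model file", path)
  }
  ctl <- do.call(binding_control, obj$control[setdiff(names(obj$control),
                                                      NULL)])
  flanks <- Map(function(u, d) list(upstream = u, downstream = d),
                obj$upstream, obj$downstream)
  names(flanks) <- NULL
  contexts <- lapply(seq_len(nrow(obj$contexts)), function(i) {
    as.list(obj$contexts[i, ])
  })
  ck <- combined_kernel(flanks, if (ctl$use_positional) contexts,
                        degree = obj$degree, gamma = obj$gamma,
                        normalize = ctl$normalize)
  structure(list(alpha_y = obj$alpha_y, bias = obj$bias,
                 examples = obj$examples, flanks = flanks,
                 contexts = contexts, tasks = obj$tasks,
                 task_registry = obj$task_registry,
                 multitask = obj$multitask, mu = obj$mu, gamma = obj$gamma,
                 degree = obj$degree, beta = wd_beta(obj$degree),
                 scales = unlist(obj$scales), control = ctl,
                 train_kernel = ck$K),
            class = "binding_svm")
}

#' @export
coef.binding_svm <- function(object, mode = "common", ...) {
  effective_linear_weights(object, mode)
}
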