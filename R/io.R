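#' Write a region x time matrix as tab-separated text
#'
#' Regions as rows, a header row of frame indices, first column the region
#' label. Round-trips through [read_matrix_tsv()] at full double precision.
#'
#' @param series a [region_ts()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(series, path) {
  stopifnot(inherits(series, "region_ts"))
  df <- data.frame(region = series$region_labels,
                   format(series$values, digits = 17, scientific = TRUE,
                          trim = TRUE),
                   check.names = FALSE)
  names(df) <- c("region", seq_len(ncol(series$values)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a region x time matrix written by [write_matrix_tsv()]
#'
#' @param path file path.
#' @param tr repetition time in seconds to attach.
#' @return a [region_ts()].
#' @export
read_matrix_tsv <- function(path, tr) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE,
                          colClasses = c("character"))
  labels <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "double"
  region_ts(vals, tr = tr, region_labels = labels)
}

#' Write a cohort dataset as a plain-text fixture
#'
#' One tab-separated matrix file per subject-run plus a comma-separated
#' manifest (`manifest.csv`: subject_id, group, run, tr_seconds, path) and
#' a run-log recording the master seed.
#'
#' @param dataset a `cohort_dataset`.
#' @param directory output directory (must exist).
#' @return manifest path, invisibly.
#' @export
write_fixture <- function(dataset, directory) {
  if (!dir.exists(directory))
    stop("directory does not exist: ", directory)
  rows <- lapply(dataset$subjects, function(su) {
    fn <- sprintf("%s_run%d.tsv", su$subject_id, su$run)
    write_matrix_tsv(su$series, file.path(directory, fn))
    data.frame(subject_id = su$subject_id, group = su$group, run = su$run,
               tr_seconds = su$series$tr, path = fn)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(directory, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE, quote = FALSE)
  seed <- if (!is.null(dataset$config)) dataset$config$seed else NA
  writeLines(c(sprintf("master_seed: %s", seed),
               sprintf("written: %s", format(Sys.time(), "%Y-%m-%d"))),
             file.path(directory, "runlog.txt"))
  invisible(mpath)
}

#' Read a cohort dataset from a manifest
#'
#' @param manifest_path path to a `manifest.csv` with columns subject_id,
#'   group, run, tr_seconds, path (paths relative to the manifest).
#' @return a `cohort_dataset`.
#' @export
read_manifest <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("manifest not found: ", manifest_path)
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "run", "tr_seconds", "path")
  if (!all(need %in% names(man)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (nrow(man) == 0L) stop("empty manifest: ", manifest_path)
  bad <- setdiff(unique(man$group), c("control", "case"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  base <- dirname(manifest_path)
  subjects <- vector("list", nrow(man))
  labels <- NULL
  ref_subject <- NULL
  for (i in seq_len(nrow(man))) {
    series <- read_matrix_tsv(file.path(base, man$path[i]),
                              tr = man$tr_seconds[i])
    if (is.null(labels)) {
      labels <- series$region_labels
      ref_subject <- man$subject_id[i]
    } else if (!identical(series$region_labels, labels)) {
      stop("region mismatch between subjects '", ref_subject, "' and '",
           man$subject_id[i], "'")
    }
    subjects[[i]] <- list(subject_id = man$subject_id[i],
                          group = man$group[i], run = man$run[i],
                          series = series, phases = NULL)
  }
  structure(list(subjects = subjects, region_labels = labels,
                 config = NULL),
            class = "cohort_dataset")
}

#' Pipeline configuration
#'
#' Collects every analysis parameter with the field-standard defaults:
#' 0.01-0.08 Hz band, k-means over k = 2-10 with 300 restarts and 400
#' iterations, half-switch smoothing off, 0.01 threshold grid, 20 Louvain
#' restarts, 9999 permutations, 10-fold x 20-rep cross-validation with
#' down-sampling.
#'
#' @param f_lo,f_hi band edges (Hz).
#' @param k_range candidate mode counts.
#' @param k_select fixed k (default 5) or NULL for silhouette argmax.
#' @param kmeans_reps,kmeans_iters k-means restarts / iteration cap.
#' @param half_switch,half_switch_delta smoothing flag and hysteresis width.
#' @param threshold_step integration threshold grid step.
#' @param louvain_restarts Louvain restarts.
#' @param n_perm Monte Carlo permutations.
#' @param cv_folds,cv_reps cross-validation folds and repetitions.
#' @param balance_mode "down" or "up".
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(f_lo = 0.01, f_hi = 0.08,
                            k_range = 2:10, k_select = 5L,
                            kmeans_reps = 300L, kmeans_iters = 400L,
                            half_switch = FALSE, half_switch_delta = 0.05,
                            threshold_step = 0.01, louvain_restarts = 20L,
                            n_perm = 9999L, cv_folds = 10L, cv_reps = 20L,
                            balance_mode = "down", seed = 1L) {
  stopifnot(f_lo > 0, f_lo < f_hi, all(k_range >= 2L),
            kmeans_reps >= 1L, kmeans_iters >= 1L,
            threshold_step > 0, threshold_step <= 1,
            louvain_restarts >= 1L, n_perm >= 1L,
            cv_folds >= 2L, cv_reps >= 1L,
            balance_mode %in% c("down", "up"))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> band-pass -> Hilbert phases -> per-dataset mode
#' extraction (modes are never fit across groups: per-dataset clustering
#' avoids leakage) -> metrics -> group statistics on global VAR -> VAR
#' classification. Writes per-stage artifacts, the config snapshot and the
#' seed into `out_dir`; identical config + seed reproduce all outputs.
#'
#' @param config a [pipeline_config()].
#' @param dataset a `cohort_dataset`; `NULL` simulates one from `sim_cfg`.
#' @param sim_cfg a [sim_config()] used when `dataset` is NULL.
#' @param out_dir output directory (created if missing).
#' @return list with `metrics`, `modes` (per group), `stats`, `classify`,
#'   `out_dir`, invisibly writes artifacts.
#' @export
run_pipeline <- function(config = pipeline_config(), dataset = NULL,
                         sim_cfg = NULL, out_dir = tempfile("phasemeta_")) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(dataset)) {
    if (is.null(sim_cfg)) sim_cfg <- sim_config(seed = config$seed)
    # validate band against the simulated TR before any computation
    if (config$f_hi >= 1 / (2 * sim_cfg$tr))
      stop("f_hi (", config$f_hi, " Hz) at or above Nyquist ",
           1 / (2 * sim_cfg$tr), " Hz")
    dataset <- generate_cohorts(sim_cfg)
  } else {
    trs <- unique(vapply(dataset$subjects, function(s) s$series$tr, 0))
    if (config$f_hi >= 1 / (2 * max(trs)))
      stop("f_hi (", config$f_hi, " Hz) at or above Nyquist ",
           1 / (2 * max(trs)), " Hz")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # preprocessing: phases per subject
  for (i in seq_along(dataset$subjects)) {
    su <- dataset$subjects[[i]]
    filt <- bandpass_fft(su$series, config$f_lo, config$f_hi)
    dataset$subjects[[i]]$phase_hat <- analytic_signal(filt)$phase
  }

  # per-dataset (group x run) mode extraction
  groups <- unique(vapply(dataset$subjects, `[[`, "", "group"))
  modes <- list()
  for (g in groups) {
    idx <- which(vapply(dataset$subjects, `[[`, "", "group") == g)
    eig_list <- lapply(idx, function(i)
      eigen_series(dataset$subjects[[i]]$phase_hat)$vectors)
    eigs <- do.call(cbind, eig_list)
    ms <- extract_modes(eigs, k_range = config$k_range,
                        reps = config$kmeans_reps,
                        max_iter = config$kmeans_iters,
                        seed = config$seed)
    sel <- select_k_silhouette(ms, k_override = config$k_select)
    modes[[g]] <- list(mode_sets = ms, selected_k = sel$k,
                       silhouette = sel$table,
                       mode_set = ms[[as.character(sel$k)]])
    centro <- modes[[g]]$mode_set$centroids
    utils::write.table(centro,
                       file.path(out_dir, paste0("centroids_", g, ".tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }

  # metrics against the control-dataset communities (shared yardstick)
  communities <- modes[[groups[1L]]]$mode_set$communities
  rows <- lapply(dataset$subjects, function(su)
    cbind(data.frame(subject = su$subject_id, group = su$group,
                     run = su$run),
          subject_metrics(su$phase_hat, communities,
                          louvain_restarts = config$louvain_restarts,
                          seed = config$seed)))
  metrics <- do.call(rbind, rows)
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)

  # statistics on global VAR
  stats_tab <- data.frame(subject = metrics$subject, group = metrics$group,
                          run = metrics$run, value = metrics$global_var)
  report <- flowchart(stats_tab)
  jsonlite::write_json(
    list(trace = report$trace,
         contrasts = report$contrasts,
         run_drivers = report$run_drivers),
    file.path(out_dir, "stats_global_var.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # classification on VAR in the largest non-global community
  comm_sizes <- vapply(communities, length, 0L)
  feat_col <- if (any(comm_sizes < length(dataset$region_labels))) {
    cand <- which(comm_sizes < length(dataset$region_labels))
    paste0("var_c", cand[which.max(comm_sizes[cand])])
  } else "global_var"
  first_run <- metrics[metrics$run == min(metrics$run), ]
  perf <- repeated_kfold(first_run[[feat_col]], first_run$group,
                         k = min(config$cv_folds,
                                 floor(nrow(first_run) / 2)),
                         reps = config$cv_reps,
                         balance_mode = config$balance_mode,
                         seed = config$seed)
  jsonlite::write_json(
    list(feature = feat_col, auc = perf$auc,
         balanced_accuracy = perf$balanced_accuracy,
         sensitivity = perf$sensitivity, specificity = perf$specificity,
         binomial_p = perf$binomial_p),
    file.path(out_dir, "classification.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cfg_out <- config
  cfg_out$k_range <- as.integer(cfg_out$k_range)
  jsonlite::write_json(unclass(cfg_out), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(sprintf("seed: %d", config$seed),
               sprintf("phasemeta version: %s",
                       as.character(utils::packageVersion("phasemeta")))),
             file.path(out_dir, "runlog.txt"))
  invisible(list(metrics = metrics, modes = modes, stats = report,
                 classify = perf, out_dir = out_dir))
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `pipeline`. Example:
#' `Rscript -e 'phasemeta::pm_cli()' simulate --seed 1 --out dir`
#'
#' @param args character vector (defaults to `commandArgs(TRUE)`).
#' @return exit status, invisibly.
#' @export
pm_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    message("usage: pm_cli <simulate|pipeline> [options]")
    return(invisible(1L))
  }
  cmd <- args[1L]
  rest <- args[-1L]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character", default = "phasemeta_out"),
    optparse::make_option("--manifest", type = "character", default = NULL),
    optparse::make_option("--band", type = "character", default = "0.01:0.08"),
    optparse::make_option("--k-range", type = "character", default = "2:10",
                          dest = "k_range"),
    optparse::make_option("--k", type = "integer", default = 5L),
    optparse::make_option("--kmeans-reps", type = "integer", default = 300L,
                          dest = "kmeans_reps"),
    optparse::make_option("--kmeans-iters", type = "integer", default = 400L,
                          dest = "kmeans_iters"),
    optparse::make_option("--half-switch", action = "store_true",
                          default = FALSE, dest = "half_switch"),
    optparse::make_option("--n-perm", type = "integer", default = 9999L,
                          dest = "n_perm"),
    optparse::make_option("--cv-folds", type = "integer", default = 10L,
                          dest = "cv_folds"),
    optparse::make_option("--cv-reps", type = "integer", default = 20L,
                          dest = "cv_reps"),
    optparse::make_option("--balance", type = "character", default = "down"),
    optparse::make_option("--subjects", type = "integer", default = 20L),
    optparse::make_option("--regions", type = "integer", default = 30L),
    optparse::make_option("--frames", type = "integer", default = 150L),
    optparse::make_option("--tr", type = "double", default = 2)
  ))
  opt <- optparse::parse_args(parser, args = rest)
  band <- as.numeric(strsplit(opt$band, ":")[[1L]])
  krange <- as.integer(strsplit(opt$k_range, ":")[[1L]])
  if (cmd == "simulate") {
    cfg <- sim_config(n_regions = opt$regions,
                      n_subjects_per_group = opt$subjects,
                      n_frames = opt$frames, tr = opt$tr, seed = opt$seed)
    ds <- generate_cohorts(cfg)
    dir.create(opt$out, showWarnings = FALSE, recursive = TRUE)
    write_fixture(ds, opt$out)
    message("fixture written to ", opt$out)
  } else if (cmd == "pipeline") {
    cfg <- pipeline_config(f_lo = band[1L], f_hi = band[2L],
                           k_range = krange[1L]:krange[2L],
                           k_select = opt$k,
                           kmeans_reps = opt$kmeans_reps,
                           kmeans_iters = opt$kmeans_iters,
                           half_switch = opt$half_switch,
                           n_perm = opt$n_perm, cv_folds = opt$cv_folds,
                           cv_reps = opt$cv_reps,
                           balance_mode = opt$balance, seed = opt$seed)
    ds <- if (!is.null(opt$manifest)) read_manifest(opt$manifest) else NULL
    sim <- if (is.null(ds))
      sim_config(n_regions = opt$regions,
                 n_subjects_per_group = opt$subjects,
                 n_frames = opt$frames, tr = opt$tr, seed = opt$seed)
    else NULL
    run_pipeline(cfg, dataset = ds, sim_cfg = sim, out_dir = opt$out)
    message("pipeline artifacts written to ", opt$out)
  } else {
    message("unknown subcommand: ", cmd)
    return(invisible(1L))
  }
  invisible(0L)
}
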