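# -- Recording interchange: CSV matrix + JSON sidecar -------------------------

#' Write a recording as CSV + JSON sidecar
#'
#' Writes `<prefix>_semg.csv` (channels x time, one row per channel,
#' first column the channel id), `<prefix>_force.csv` (one `force`
#' column) and `<prefix>_meta.json` (sampling rate, grid layout, gesture,
#' subject, group, repetition, force mode). The formats are plain text so
#' recordings are diff-able and toolable.
#'
#' @param rec a `recording`.
#' @param prefix path prefix (directories are created as needed).
#' @return invisibly, the three file paths.
#' @export
write_recording <- function(rec, prefix) {
  stopifnot(inherits(rec, "recording"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  paths <- paste0(prefix, c("_semg.csv", "_force.csv", "_meta.json"))
  semg <- data.table::data.table(channel = rec$channel_ids, rec$semg)
  data.table::fwrite(semg, paths[1])
  data.table::fwrite(data.table::data.table(force = rec$force$values),
                     paths[2])
  meta <- list(
    fs = rec$fs, n_channels = nrow(rec$semg), n_samples = ncol(rec$semg),
    grid = list(rows = rec$grid$rows, cols = rec$grid$cols,
                n_grids = rec$grid$n_grids),
    gesture = rec$gesture, subject_id = rec$subject_id,
    repetition = rec$repetition, group = rec$group,
    force_mode = rec$force$mode, force_params = rec$force$params,
    units = "arbitrary (mV-scale sEMG, normalized-MVC force)"
  )
  jsonlite::write_json(meta, paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a recording written by [write_recording()]
#'
#' @param prefix the path prefix used when writing.
#' @return a `recording`.
#' @export
read_recording <- function(prefix) {
  paths <- paste0(prefix, c("_semg.csv", "_force.csv", "_meta.json"))
  if (!file.exists(paths[3])) {
    stop_named("unreadable_file", sprintf("missing sidecar %s", paths[3]))
  }
  meta <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
  if (!file.exists(paths[1])) {
    stop_named("unreadable_file", sprintf("missing %s", paths[1]))
  }
  if (!file.exists(paths[2])) {
    stop_named("missing_force_channel", sprintf("missing %s", paths[2]))
  }
  semg_dt <- data.table::fread(paths[1])
  semg <- as.matrix(semg_dt[, -1L])
  dimnames(semg) <- NULL
  if (nrow(semg) != meta$n_channels) {
    stop_named("channel_count_mismatch",
               sprintf("%s has %d channels, sidecar declares %d",
                       paths[1], nrow(semg), meta$n_channels))
  }
  force_v <- data.table::fread(paths[2])$force
  grid <- grid_layout(meta$grid$rows, meta$grid$cols, meta$grid$n_grids)
  force <- structure(
    list(values = force_v, fs = meta$fs, mode = meta$force_mode,
         params = as.list(meta$force_params)),
    class = "force_trace"
  )
  structure(
    list(semg = semg, force = force, fs = meta$fs, grid = grid,
         gesture = meta$gesture, subject_id = meta$subject_id,
         repetition = as.integer(meta$repetition), group = meta$group,
         channel_ids = seq_len(nrow(semg))),
    class = "recording"
  )
}

#' Write a sample set as CSV + JSON
#'
#' `<prefix>_windows.csv` holds one window per row; `<prefix>_meta.csv`
#' the targets and provenance; `<prefix>_meta.json` the window geometry.
#'
#' @param ss a `sample_set`.
#' @param prefix path prefix.
#' @return invisibly, the file paths.
#' @export
write_samples <- function(ss, prefix) {
  stopifnot(inherits(ss, "sample_set"))
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  paths <- paste0(prefix, c("_windows.csv", "_meta.csv", "_meta.json"))
  data.table::fwrite(data.table::as.data.table(ss$windows), paths[1])
  data.table::fwrite(cbind(data.table::as.data.table(ss$provenance),
                           target = ss$targets), paths[2])
  jsonlite::write_json(list(L = ss$L, step = ss$step,
                            n_windows = nrow(ss$windows)),
                       paths[3], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a sample set written by [write_samples()]
#' @param prefix the path prefix used when writing.
#' @return a `sample_set`.
#' @export
read_samples <- function(prefix) {
  paths <- paste0(prefix, c("_windows.csv", "_meta.csv", "_meta.json"))
  meta <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
  windows <- as.matrix(data.table::fread(paths[1]))
  dimnames(windows) <- NULL
  tab <- data.table::fread(paths[2], data.table = FALSE)
  structure(
    list(windows = windows, targets = tab$target, L = as.integer(meta$L),
         step = as.integer(meta$step),
         provenance = tab[, setdiff(names(tab), "target"), drop = FALSE]),
    class = "sample_set"
  )
}

# -- Run configuration --------------------------------------------------------

.config_defaults <- list(
  # simulator
  n_ha = 3L, n_hc = 4L, n_cp = 3L, gestures = 2L, reps = 4L,
  fs = 1000, duration_s = 6, snr_db = 10, pathology_strength = 1,
  # preprocessing
  rank = 2L, window = 500L, step = 500L, bp_low = 20, bp_high = 500,
  bp_order = 100L, env_cutoff = 5, env_order = 100L,
  # estimator
  layer_units = c(32L, 16L), dropout = 0.4, batch_size = 100L,
  learning_rate = 0.001, patience = 20L, source_epochs = 40L,
  input_stride = 10L,
  # transfer
  strategy = "TL1", calib_epochs = 30L,
  # global
  seed = 1L
)

#' Build a validated run configuration
#'
#' All tunables of the pipeline in one serializable list. Values the
#' experimental protocol states are the defaults of the corresponding
#' stage (window 500/step 500, band-pass 20-500 Hz order 100, envelope
#' cutoff 5 Hz, dropout 0.4, batch 100, learning rate 0.001); the cohort
#' sizes default to a desk-scale study. Unknown keys are rejected.
#'
#' @param ... overrides of the defaults (see
#'   `emgforce:::.config_defaults`).
#' @return a `run_config`.
#' @export
run_config <- function(...) {
  over <- list(...)
  unknown <- setdiff(names(over), names(.config_defaults))
  if (length(unknown) > 0) {
    stop_named("bad_config",
               sprintf("unknown config key(s): %s",
                       paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(.config_defaults, over)
  if (cfg$window < 1L) stop_named("bad_config", "window must be >= 1")
  if (cfg$step < 1L) stop_named("bad_config", "step must be >= 1")
  structure(cfg, class = "run_config")
}

#' Save / load a run configuration (lossless JSON round-trip)
#' @param config a `run_config`.
#' @param path JSON file path.
#' @return `save_config`: the path, invisibly. `load_config`: the
#'   `run_config`.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  ints <- c("n_ha", "n_hc", "n_cp", "gestures", "reps", "rank", "window",
            "step", "bp_order", "env_order", "layer_units", "batch_size",
            "patience", "source_epochs", "calib_epochs", "seed")
  for (k in intersect(names(raw), ints)) raw[[k]] <- as.integer(raw[[k]])
  do.call(run_config, raw)
}

# FNV-1a hash of the serialized config, stamped on artifacts so any
# output can be traced to the exact configuration and seed producing it.
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  h <- 2166136261
  for (code in utf8ToInt(as.character(s))) {
    h <- bitwXor(as.integer(h %% 2^31), code) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

# -- End-to-end pipeline ------------------------------------------------------

#' Run the full pipeline: simulate, preprocess, train, transfer, assess
#'
#' Executes the three-part study on synthetic cohorts sized by the
#' configuration: trains a source network on a healthy-adult cohort
#' spanning several force modes, calibrates a gesture-specific target
#' network per gesture on a healthy-child cohort via the configured
#' transfer strategy, and assesses a cerebral-palsy cohort against the
#' healthy children with deviation scores and rank tests. Every artifact
#' carries the config hash and seed needed to regenerate it.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, reports are written as
#'   JSON/CSV.
#' @return list with `source` (trained estimator), `targets` (per
#'   gesture), `report` (an `assessment_report`), `timings` (seconds per
#'   stage), `config`, `config_hash`, `seed`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  gestures <- paste0("G", seq_len(config$gestures))
  pp_args <- list(low = config$bp_low, high = config$bp_high,
                  bp_order = config$bp_order,
                  env_cutoff = config$env_cutoff,
                  env_order = config$env_order, rank = config$rank,
                  L = config$window, step = config$step)

  t0 <- tic()
  ha <- make_cohort(config$n_ha, "HA", gestures = "G1",
                    reps = config$reps, seed = derive_seed(seed, "ha"),
                    fs = config$fs, duration_s = config$duration_s,
                    grid = grid_layout(4L, 4L, 4L), snr_db = config$snr_db)
  hc <- make_cohort(config$n_hc, "HC", gestures = gestures,
                    reps = config$reps, seed = derive_seed(seed, "hc"),
                    fs = config$fs, duration_s = config$duration_s,
                    snr_db = config$snr_db)
  cp <- make_cohort(config$n_cp, "CP", gestures = gestures,
                    reps = config$reps, seed = derive_seed(seed, "cp"),
                    fs = config$fs, duration_s = config$duration_s,
                    snr_db = config$snr_db,
                    pathology_strength = config$pathology_strength)
  timings["simulate"] <- tic() - t0
  message(sprintf("[simulate] %d recordings in %.1fs",
                  length(ha) + length(hc) + length(cp),
                  timings["simulate"]))

  t0 <- tic()
  ss_ha <- do.call(preprocess_cohort, c(list(ha), pp_args))
  ss_hc <- do.call(preprocess_cohort, c(list(hc), pp_args))
  timings["preprocess"] <- tic() - t0
  message(sprintf("[preprocess] %d + %d windows in %.1fs",
                  nrow(ss_ha$windows), nrow(ss_hc$windows),
                  timings["preprocess"]))

  t0 <- tic()
  cfg <- estimator_config(layer_units = config$layer_units,
                          dropout = config$dropout,
                          batch_size = config$batch_size,
                          learning_rate = config$learning_rate,
                          patience = config$patience,
                          input_stride = config$input_stride,
                          seed = derive_seed(seed, "model"))
  sp <- split_samples(ss_ha, c(8, 1, 1), seed = derive_seed(seed, "split"))
  source <- build_estimator(cfg, input_len = config$window)
  source <- train_estimator(source, sp$train, val = sp$val,
                            max_epochs = config$source_epochs,
                            seed = derive_seed(seed, "fit"))
  src_rmse <- rmse_pct(sp$test$targets, predict(source, sp$test))
  timings["train"] <- tic() - t0
  message(sprintf("[train] source test RMSE %.2f%% in %.1fs",
                  src_rmse, timings["train"]))

  t0 <- tic()
  targets <- list()
  for (g in gestures) {
    ss_g <- subset_samples(ss_hc, ss_hc$provenance$gesture == g)
    targets[[g]] <- calibrate(source, config$strategy, ss_g,
                              seed = derive_seed(seed, "calib", g),
                              epochs = config$calib_epochs)
  }
  timings["transfer"] <- tic() - t0
  message(sprintf("[transfer] %d target network(s) in %.1fs",
                  length(targets), timings["transfer"]))

  t0 <- tic()
  report <- do.call(cohort_report,
                    c(list(targets, c(hc, cp), grouping = "HCvsCP"),
                      pp_args))
  timings["assess"] <- tic() - t0
  message(sprintf("[assess] %d deviation score(s) in %.1fs",
                  nrow(report$scores), timings["assess"]))

  out <- list(source = source, targets = targets, report = report,
              source_test_rmse = src_rmse, timings = timings,
              config = config, config_hash = config_hash(config),
              seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(report$scores, file.path(out_dir, "scores.csv"))
    data.table::fwrite(report$summaries,
                       file.path(out_dir, "summaries.csv"))
    jsonlite::write_json(
      list(config_hash = out$config_hash, seed = seed,
           source_test_rmse = src_rmse,
           summaries = report$summaries),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    save_config(config, file.path(out_dir, "config.json"))
  }
  out
}
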