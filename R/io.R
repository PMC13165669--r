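## Segment store: one directory per subject, one delimited text file per
## segment (columns t,i,q,x,ecg plus any derived columns), a JSON sidecar
## with metadata, and a dataset-level manifest.

segment_filename <- function(subject_id, k) {
  sprintf("%s_seg%04d.csv", subject_id, k)
}

## CSV writer with %.17g formatting so doubles round-trip exactly
write_csv17 <- function(df, path) {
  cols <- lapply(df, function(v) {
    if (is.double(v)) sprintf("%.17g", v) else as.character(v)
  })
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path)
}

#' Write a dataset to a segment store
#'
#' @param dataset a `radar_dataset`.
#' @param path output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_segment_store <- function(dataset, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  counter <- list()
  for (seg in dataset$segments) {
    sid <- seg$subject_id
    counter[[sid]] <- (counter[[sid]] %||% 0L) + 1L
    subj_dir <- file.path(path, sid)
    dir.create(subj_dir, showWarnings = FALSE)
    fn <- segment_filename(sid, counter[[sid]])
    df <- list(t = seg$t, i = seg$i_chan, q = seg$q_chan,
               x = seg$x, ecg = as.numeric(seg$ecg))
    for (extra in c("x_rec", "x_card", "ecg_clean"))
      if (!is.null(seg[[extra]])) df[[extra]] <- as.numeric(seg[[extra]])
    write_csv17(df, file.path(subj_dir, fn))
    meta <- list(subject_id = sid, scenario = seg$scenario, fs = seg$fs,
                 seed = dataset$seed, r_peak_times = seg$r_peak_times)
    jsonlite::write_json(meta, file.path(subj_dir, paste0(fn, ".json")),
                         digits = I(17), auto_unbox = TRUE)
    entries[[length(entries) + 1]] <- list(file = file.path(sid, fn),
                                           subject_id = sid,
                                           scenario = seg$scenario)
  }
  manifest <- list(n_segments = length(entries), seed = dataset$seed,
                   fs = dataset$cfg$fs,
                   wavelength_mm = dataset$cfg$wavelength_mm,
                   segments = entries)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a dataset from a segment store
#'
#' Validates the manifest against the files: every referenced file must
#' exist, hold the expected columns and have the expected segment length.
#'
#' @param path store directory containing `manifest.json`.
#' @param segment_len expected samples per segment.
#' @return A `radar_dataset`.
#' @export
read_segment_store <- function(path, segment_len = 1000) {
  mf_path <- file.path(path, "manifest.json")
  if (!file.exists(mf_path)) stop_format("missing manifest: ", mf_path)
  manifest <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  files <- manifest$segments$file
  missing <- files[!file.exists(file.path(path, files))]
  if (length(missing))
    stop_format("manifest references missing file(s): ",
                paste(missing, collapse = ", "))
  segments <- lapply(files, function(fn) {
    df <- data.table::fread(file.path(path, fn))
    required <- c("t", "i", "q", "x", "ecg")
    absent <- setdiff(required, names(df))
    if (length(absent))
      stop_format(fn, ": missing column(s) ", paste(absent, collapse = ", "))
    if (nrow(df) != segment_len)
      stop_format(fn, ": ", nrow(df), " rows, expected ", segment_len)
    meta <- jsonlite::read_json(file.path(path, paste0(fn, ".json")),
                                simplifyVector = TRUE)
    seg <- list(subject_id = meta$subject_id, scenario = meta$scenario,
                t = df$t, i_chan = df$i, q_chan = df$q, x = df$x,
                ecg = df$ecg, r_peak_times = meta$r_peak_times,
                fs = meta$fs)
    for (extra in c("x_rec", "x_card", "ecg_clean"))
      if (extra %in% names(df)) seg[[extra]] <- df[[extra]]
    seg
  })
  ord <- order(vapply(segments, `[[`, character(1), "subject_id"),
               seq_along(segments))
  structure(list(segments = segments[ord],
                 cfg = radar_sim_config(
                   wavelength_mm = manifest$wavelength_mm %||% 3,
                   fs = manifest$fs %||% 100,
                   segment_len = segment_len),
                 seed = manifest$seed,
                 scenario_counts = table(manifest$segments$scenario)),
            class = "radar_dataset")
}

#' Run the full pipeline on synthetic data
#'
#' simulate -> demodulate -> preprocess -> train -> evaluate, chained on
#' disk artifacts under `out_dir` (each stage skipped when its output
#' already exists, making reruns idempotent and resumable). Returns the
#' held-out evaluation report.
#'
#' @param out_dir working directory for stage artifacts.
#' @param n_subjects,n_segments dataset size.
#' @param sim_cfg a [radar_sim_config()].
#' @param train_cfg a [train_config()].
#' @param model_cfg a [model_config()].
#' @param seed integer master seed.
#' @param verbose print stage progress.
#' @return An `eval_report` (also written to `out_dir/report.json`).
#' @export
run_pipeline <- function(out_dir, n_subjects = 4, n_segments = 40,
                         sim_cfg = radar_sim_config(),
                         train_cfg = train_config(epochs = 2, batch_size = 8,
                                                  k_folds = 2),
                         model_cfg = desk_model_config(),
                         seed = 1, verbose = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, file, producer) {
    fp <- file.path(out_dir, file)
    if (file.exists(fp)) {
      if (verbose) message("stage ", name, ": reusing ", fp)
      return(fp)
    }
    t0 <- Sys.time()
    producer(fp)
    if (verbose)
      message(sprintf("stage %s: %.1f s", name,
                      as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    fp
  }

  raw_dir <- stage("simulate", "raw", function(fp) {
    ds <- generate_dataset(n_subjects, n_segments, cfg = sim_cfg, seed = seed)
    write_segment_store(ds, fp)
  })
  prep_dir <- stage("preprocess", "prep", function(fp) {
    ds <- read_segment_store(raw_dir, sim_cfg$segment_len)
    ds <- demodulate_dataset(ds)
    ds <- preprocess_dataset(ds)
    write_segment_store(ds, fp)
  })
  report_path <- stage("train+evaluate", "report.json", function(fp) {
    ds <- read_segment_store(prep_dir, sim_cfg$segment_len)
    ids <- unique(vapply(ds$segments, `[[`, character(1), "subject_id"))
    folds <- split_subject_kfold(ids, train_cfg$k_folds, train_cfg$seed)
    fit <- train_fold(ds, folds[[1]], train_cfg, model_cfg, verbose)
    te <- segment_matrices(ds, fit$test_ids)
    yhat <- predict_batches(fit$model, te$X)
    rep <- evaluate_reconstructions(yhat, te$Y, te$scenarios, fs = te$fs)
    jsonlite::write_json(
      list(overall = rep$overall,
           per_scenario = rep$per_scenario,
           localization = rep$localization),
      fp, digits = NA, auto_unbox = TRUE, dataframe = "rows")
  })
  report <- jsonlite::read_json(report_path, simplifyVector = TRUE)
  class(report) <- "pipeline_report"
  invisible(report)
}
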