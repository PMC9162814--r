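#' Default end-to-end pipeline configuration
#'
#' Returns the nested configuration list consumed by [run_pipeline()]:
#' synthetic-data settings, filter settings, dataset windowing, model and
#' training hyperparameters, detection and intensity-classification settings.
#' Any element can be overridden before the run; `seed` feeds every
#' stochastic stage.
#'
#' @param seed Global integer seed.
#' @return A named list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    synthetic = list(
      n_train_records = 4L, n_test_records = 2L, duration_s = 60,
      fs = 360, mean_hr_bpm = 75, hr_sd_bpm = 3,
      noise = list(emg_amplitude = 0.05, powerline_amplitude = 0.1,
                   powerline_freq = 50, baseline_amplitude = 0.3,
                   baseline_freq = 0.3)),
    filters = list(lowpass_cutoff = 40, notch_freq = 50,
                   baseline_cutoff = 0.5),
    dataset = list(half_width = 75L, negatives_per_positive = 1,
                   min_distance = 25L),
    training = list(epochs = 15L, batch_size = 128L, learning_rate = 1e-3),
    detection = list(stride = 2L, prob_threshold = 0.5, refractory_ms = 200,
                     tolerance_ms = 75),
    intensity = list(n_epochs = 150L, epoch_s = 30, rest_hr = 60, slope = 10,
                     hr_sd_bpm = 2, holdout_fraction = 0.5)
  ), class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it over [default_pipeline_config()], so a
#' config file only needs to state what it changes.
#'
#' @param path YAML file path.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  usr <- yaml::read_yaml(path)
  base <- default_pipeline_config(seed = usr$seed %||% 1L)
  merge_into <- function(base, usr) {
    for (nm in names(usr)) {
      base[[nm]] <- if (is.list(usr[[nm]]) && is.list(base[[nm]])) {
        merge_into(base[[nm]], usr[[nm]])
      } else {
        usr[[nm]]
      }
    }
    base
  }
  structure(merge_into(unclass(base), usr), class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic pipeline end to end
#'
#' Generates noisy synthetic training and test records, applies the
#' three-filter preprocessing chain, builds the labelled window dataset,
#' trains the residual CNN window classifier, runs sliding-window detection
#' on the held-out records, computes detection metrics at the configured
#' tolerance, then generates labelled intensity sessions, extracts HRV
#' features from the *detected* peaks, trains the RBF intensity SVM on half
#' the epochs and scores the other half. All artifacts (signals, detections,
#' history, metrics) are written under `out_dir`; the returned summary is
#' also saved as JSON.
#'
#' @param config A [default_pipeline_config()]-shaped list.
#' @param out_dir Output directory for artifacts (created if needed). `NULL`
#'   skips writing.
#' @param verbose Print stage progress.
#' @return A list summary: `detection` (confusion counts and metrics),
#'   `intensity` (hold-out accuracy and per-class rates), `history` (training
#'   curve), plus the effective seed.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = NULL, verbose = interactive()) {
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  set.seed(config$seed)
  seeds <- sample.int(2^30, 10)

  ncfg <- do.call(noise_config, config$synthetic$noise)
  syn <- config$synthetic
  make_record <- function(seed, id) {
    out <- generate_clean_ecg(synthetic_config(
      duration_s = syn$duration_s, fs = syn$fs,
      mean_hr_bpm = syn$mean_hr_bpm, hr_sd_bpm = syn$hr_sd_bpm,
      seed = seed))
    noisy <- add_noise(out$signal, ncfg, seed = seed)
    noisy$record_id <- id
    list(signal = noisy, annotation = out$annotation, clean = out$signal)
  }

  say("simulate: %d train + %d test records",
      syn$n_train_records, syn$n_test_records)
  train_recs <- stage("simulate", lapply(seq_len(syn$n_train_records),
    function(i) make_record(seeds[1] + i, sprintf("train%02d", i))))
  test_recs <- stage("simulate", lapply(seq_len(syn$n_test_records),
    function(i) make_record(seeds[2] + i, sprintf("test%02d", i))))

  say("preprocess: three-filter chain")
  fcfg <- filter_config(lowpass_cutoff = config$filters$lowpass_cutoff,
                        notch_freq = config$filters$notch_freq,
                        baseline_cutoff = config$filters$baseline_cutoff)
  prep <- function(recs) lapply(recs, function(r) {
    r$signal <- preprocess_chain(r$signal, fcfg)
    r
  })
  train_recs <- stage("preprocess", prep(train_recs))
  test_recs <- stage("preprocess", prep(test_recs))

  say("build-dataset: half-width %d", config$dataset$half_width)
  ds <- stage("build-dataset", build_window_dataset(
    train_recs, half_width = config$dataset$half_width,
    negatives_per_positive = config$dataset$negatives_per_positive,
    min_distance = config$dataset$min_distance, seed = seeds[3]))

  say("train: %d epochs on %d windows", config$training$epochs, nrow(ds$x))
  model <- stage("train", build_model(2L * config$dataset$half_width + 1L,
                                      seed = seeds[4]))
  trained <- stage("train", train_model(model, ds, train_config(
    epochs = config$training$epochs,
    batch_size = config$training$batch_size,
    learning_rate = config$training$learning_rate, seed = seeds[5])))

  say("detect: %d held-out record(s)", length(test_recs))
  dcfg <- detection_config(stride = config$detection$stride,
                           prob_threshold = config$detection$prob_threshold,
                           refractory_ms = config$detection$refractory_ms)
  tot <- c(tp = 0L, fp = 0L, fn = 0L)
  detections <- list()
  for (r in test_recs) {
    det <- stage("detect", detect_rpeaks(trained$model, r$signal,
                                         config$dataset$half_width, dcfg))
    ref <- interior_peaks(r$annotation, length(r$signal$samples),
                          config$dataset$half_width)
    cc <- match_peaks(det, ref,
                      tolerance_ms = config$detection$tolerance_ms)
    tot <- tot + c(tp = cc$tp, fp = cc$fp, fn = cc$fn)
    detections[[r$signal$record_id]] <- det
  }
  det_metrics <- classification_metrics(
    confusion_counts(tp = tot[["tp"]], tn = 0, fp = tot[["fp"]],
                     fn = tot[["fn"]]))

  say("intensity: %d epochs", config$intensity$n_epochs)
  icfg <- config$intensity
  sessions <- stage("featurize", generate_intensity_sessions(
    n_epochs = icfg$n_epochs, fs = syn$fs, epoch_s = icfg$epoch_s,
    hr_model = list(rest_hr = icfg$rest_hr, slope = icfg$slope),
    hr_sd_bpm = icfg$hr_sd_bpm, seed = seeds[6]))
  feats <- stage("featurize", t(vapply(sessions, function(s) {
    hrv_features(rr_from_peaks(s$annotation))
  }, numeric(6))))
  labs <- factor(vapply(sessions, function(s) as.character(s$label),
                        character(1)), levels = c("low", "medium", "high"))
  n_ep <- nrow(feats)
  set.seed(seeds[7])
  tr_idx <- sort(sample.int(n_ep, round(n_ep * (1 - icfg$holdout_fraction))))
  te_idx <- setdiff(seq_len(n_ep), tr_idx)
  clf <- stage("intensity", train_intensity_svm(feats[tr_idx, , drop = FALSE],
                                                labs[tr_idx],
                                                seed = seeds[8]))
  pred <- stage("intensity", predict_intensity(clf,
                                               feats[te_idx, , drop = FALSE]))
  int_eval <- evaluate_intensity(pred, labs[te_idx])

  summary <- list(
    seed = config$seed,
    n_train_windows = nrow(ds$x),
    detection = list(tp = tot[["tp"]], fp = tot[["fp"]], fn = tot[["fn"]],
                     f_score = det_metrics$f_score,
                     precision = det_metrics$precision,
                     recall = det_metrics$recall),
    intensity = list(holdout_accuracy = int_eval$overall_accuracy_pct / 100,
                     mean_fn_rate_pct = int_eval$mean_fn_rate_pct,
                     mean_fp_rate_pct = int_eval$mean_fp_rate_pct),
    final_train_loss = utils::tail(trained$history$loss, 1),
    final_train_accuracy = utils::tail(trained$history$accuracy, 1))

  if (!is.null(out_dir)) {
    utils::write.csv(trained$history,
                     file.path(out_dir, "train_history.csv"),
                     row.names = FALSE)
    for (id in names(detections)) {
      write_detections(detections[[id]],
                       file.path(out_dir, paste0(id, "_detections.csv")))
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  summary
}

#' Window-classification benchmark on MIT-BIH records
#'
#' Optional harness for anyone with a local copy of the MIT-BIH arrhythmia
#' database (WFDB `.hea`/`.dat`/`.atr` files): reads every available record's
#' first channel, splits records cross-patient into DS1 (train) and DS2
#' (validate), builds R-centred/non-R window datasets, trains the residual
#' CNN and reports window-classification metrics on DS2. Records 102 and 104
#' are excluded (first channel not MLII). The database itself is not shipped;
#' pointing this at synthetic WFDB records written by [write_wfdb_record()]
#' exercises the same code path.
#'
#' @param dir Directory containing the WFDB files.
#' @param half_width Window half-width (50/75/100).
#' @param epochs Training epochs (the full study uses 100).
#' @param max_minutes_per_record Optional cap on the signal length read per
#'   record, to bound runtime; `Inf` uses full records.
#' @param seed Integer seed.
#' @param record_ids Record names to use; defaults to whatever subset of the
#'   48-record roster is present in `dir`.
#' @return A list with `split`, the training `history`, and a
#'   `metrics_report` on DS2 windows.
#' @export
run_mitbih_benchmark <- function(dir, half_width = 75, epochs = 100L,
                                 max_minutes_per_record = Inf, seed = 1L,
                                 record_ids = NULL) {
  if (is.null(record_ids)) {
    hea <- list.files(dir, pattern = "\\.hea$")
    record_ids <- intersect(sub("\\.hea$", "", hea), MITBIH_ALL_RECORDS)
  }
  if (length(record_ids) == 0) {
    stop("no MIT-BIH records found in ", dir,
         " (expected <record>.hea/.dat/.atr files)", call. = FALSE)
  }
  split <- split_ds1_ds2(record_ids)
  load_rec <- function(id) {
    sig <- read_wfdb_record(file.path(dir, id), channel_index = 0L)
    ann <- read_rpeak_annotations(file.path(dir, paste0(id, ".atr")), sig$fs)
    if (is.finite(max_minutes_per_record)) {
      n_keep <- min(length(sig$samples),
                    round(max_minutes_per_record * 60 * sig$fs))
      sig$samples <- sig$samples[seq_len(n_keep)]
      ann <- rpeak_annotation(ann$indices[ann$indices < n_keep], sig$fs)
    }
    list(signal = preprocess_chain(sig), annotation = ann)
  }
  ds1 <- lapply(split$ds1, load_rec)
  ds2 <- lapply(split$ds2, load_rec)
  if (length(ds1) == 0 || length(ds2) == 0) {
    stop("need records on both sides of the DS1/DS2 split", call. = FALSE)
  }
  train_ds <- build_window_dataset(ds1, half_width = half_width, seed = seed)
  test_ds <- build_window_dataset(ds2, half_width = half_width,
                                  seed = seed + 1L)
  model <- build_model(2L * half_width + 1L, seed = seed)
  trained <- train_model(model, train_ds,
                         train_config(epochs = epochs, seed = seed))
  p <- predict_proba(trained$model, test_ds$x)
  pred_pos <- p >= 0.5
  ref_pos <- test_ds$label == "R"
  cc <- confusion_counts(tp = sum(pred_pos & ref_pos),
                         tn = sum(!pred_pos & !ref_pos),
                         fp = sum(pred_pos & !ref_pos),
                         fn = sum(!pred_pos & ref_pos))
  list(split = split, history = trained$history,
       metrics = classification_metrics(cc))
}
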