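#' Pipeline configuration
#'
#' Nested configuration for the full simulate -> preprocess -> featurize ->
#' evaluate -> ablate -> explain pipeline, with every stage default
#' pre-filled (128 Hz sampling, 0.5-45 Hz bandpass, Savitzky-Golay frame 127
#' order 5, 5-mode decomposition, 3 s windows with 50% overlap, 80/20 split,
#' 6-fold cross-validation). One global `seed` deterministically derives
#' per-stage seeds. Unknown keys in `...` (or in a YAML file loaded with
#' [load_config()]) are rejected.
#'
#' @param ... Overrides, named after the fields below (nested lists for
#'   sections, e.g. `window = list(length_s = 2)`).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  base <- list(
    seed = 1,
    out_dir = tempfile("vmdeeg_run_"),
    format = "csv",
    n_sessions = 6,
    input_recordings = NULL,          # paths; skips the simulate stage
    paradigm = list(fs = 128, n_channels = 32, relax_initial_s = 10,
                    image_duration_s = 5, images_per_emotion = 3,
                    inter_emotion_relax_s = 5,
                    emotion_order = c("happy", "sad", "fear"), n_phases = 2),
    effects = list(noise_pink_scale = 2,
                   drift = list(degree = 3, amplitude = 20),
                   blink = list(rate_per_min = 4, amplitude = 80,
                                duration_s = 0.3,
                                channels = c("Fp1", "Fp2"), leak = 0.2)),
    filter = list(low_hz = 0.5, high_hz = 45, transition_hz = 0.5),
    sg = list(frame_length = 127, poly_order = 5),
    ica = list(threshold = 0.7, frontal = c("Fp1", "Fp2"), skip = FALSE),
    vmd = list(K = 5, alpha = 2000, tau = 0, tol = 1e-7, max_iter = 500,
               init = "uniform"),
    window = list(length_s = 3, overlap_frac = 0.5),
    split = list(train_frac = 0.8, stratified = TRUE, grouping = "none"),
    cv = list(n_folds = 6, shuffled = TRUE),
    models = c("knn", "svm", "dt", "rf"),
    sweep = list(enabled = FALSE, lengths_s = c(1, 2, 3, 4, 15)),
    explain = list(method = "tree", n_repeats = 20)
  )
  cfg <- merge_config(base, list(...), path = "")
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

merge_config <- function(base, override, path) {
  if (length(override) == 0) return(base)
  nm <- names(override)
  if (is.null(nm) || any(nm == ""))
    stop("configuration overrides must be named (at '", path, "')")
  for (k in nm) {
    if (!k %in% names(base))
      stop("unknown configuration key: ", sub("^\\.", "", paste0(path, ".", k)))
    if (is.list(base[[k]]) && !is.null(names(base[[k]])) && is.list(override[[k]]))
      base[[k]] <- merge_config(base[[k]], override[[k]], paste0(path, ".", k))
    else base[[k]] <- override[[k]]
  }
  base
}

validate_config <- function(cfg) {
  w <- cfg$window
  if (w$overlap_frac < 0 || w$overlap_frac >= 1)
    stop("invalid configuration: window.overlap_frac must be in [0, 1), got ",
         w$overlap_frac)
  if (w$length_s <= 0) stop("invalid configuration: window.length_s must be positive")
  if (cfg$split$train_frac <= 0 || cfg$split$train_frac >= 1)
    stop("invalid configuration: split.train_frac must be in (0, 1)")
  if (!all(cfg$models %in% c("knn", "svm", "dt", "rf")))
    stop("invalid configuration: unknown model kind")
  if (!cfg$format %in% c("csv", "edf"))
    stop("invalid configuration: format must be csv or edf")
  invisible(cfg)
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror [pipeline_config()]; unknown keys
#'   are rejected with the offending field named.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the whole pipeline
#'
#' Executes simulate -> preprocess -> featurize -> train/evaluate ->
#' ablation -> explain, writing each stage's artifact under
#' `config$out_dir` and recording seeds, durations and md5 checksums in a
#' run manifest (`manifest.json`). Re-running with an identical configuration
#' and seed reproduces identical checksums for every artifact. If
#' `config$input_recordings` is set, those files are read instead of
#' simulating.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (list; also written as JSON).
#' @export
run_all <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config, seed = config$seed, stages = list())
  t_all <- Sys.time()

  stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      seed = derive_seed(config$seed, name),
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  pspec <- do.call(paradigm_spec, config$paradigm)
  effects <- do.call(class_effects,
                     c(list(components = default_components()), config$effects))

  recs <- stage("simulate", function() {
    if (!is.null(config$input_recordings)) {
      lapply(config$input_recordings, read_recording, fs = config$paradigm$fs)
    } else {
      ds <- generate_dataset(config$n_sessions, pspec, effects,
                             seed = derive_seed(config$seed, "simulate"))
      for (i in seq_along(ds$recordings))
        write_recording(ds$recordings[[i]],
                        file.path(config$out_dir,
                                  sprintf("session%02d.%s", i, config$format)),
                        config$format)
      ds$recordings
    }
  })

  cleaned <- stage("preprocess", function() {
    fspec <- do.call(filter_spec, config$filter)
    sspec <- do.call(sg_spec, config$sg)
    out <- lapply(seq_along(recs), function(i) {
      pp <- preprocess_recording(recs[[i]], fspec, sspec,
                                 ica_threshold = config$ica$threshold,
                                 frontal = config$ica$frontal,
                                 skip_ica = isTRUE(config$ica$skip),
                                 ica_seed = derive_seed(config$seed, "ica"))
      jsonlite::write_json(
        pp$ica_report,
        file.path(config$out_dir, sprintf("ica_report%02d.json", i)),
        auto_unbox = TRUE, digits = 10)
      pp$recording
    })
    out
  })

  feats <- stage("featurize", function() {
    vspec <- do.call(vmd_config, config$vmd)
    wspec <- do.call(window_spec, config$window)
    f <- extract_features_multi(cleaned, wspec, vspec)
    write.csv(f, file.path(config$out_dir, "features.csv"), row.names = FALSE)
    f
  })

  reports <- stage("train", function() {
    sp <- do.call(split_spec,
                  c(config$split, list(seed = derive_seed(config$seed, "split"))))
    cvp <- do.call(cv_spec,
                   c(config$cv, list(seed = derive_seed(config$seed, "cv"))))
    reports <- lapply(config$models, function(kind) {
      r <- train_eval(feats, model_spec(kind, seed = derive_seed(config$seed, kind)),
                      sp, cvp)
      jsonlite::write_json(report_summary(r),
                           file.path(config$out_dir,
                                     paste0("report_", kind, ".json")),
                           auto_unbox = TRUE, digits = 10)
      r
    })
    names(reports) <- config$models
    reports
  })

  if (isTRUE(config$sweep$enabled)) {
    stage("sweep", function() {
      sp <- do.call(split_spec,
                    c(config$split, list(seed = derive_seed(config$seed, "split"))))
      cvp <- do.call(cv_spec,
                     c(config$cv, list(seed = derive_seed(config$seed, "cv"))))
      tab <- sweep_windows(cleaned, config$sweep$lengths_s, config$models,
                           overlap_frac = config$window$overlap_frac,
                           vmd = do.call(vmd_config, config$vmd),
                           split = sp, cv = cvp)
      write.csv(tab, file.path(config$out_dir, "sweep.csv"), row.names = FALSE)
      tab
    })
  }

  stage("ablation", function() {
    sp <- do.call(split_spec,
                  c(config$split, list(seed = derive_seed(config$seed, "split"))))
    cvp <- do.call(cv_spec,
                   c(config$cv, list(seed = derive_seed(config$seed, "cv"))))
    best <- if ("rf" %in% config$models) "rf" else config$models[[1]]
    tab <- ablation_table(feats, model_spec(best, seed = derive_seed(config$seed, best)),
                          sp, cvp)
    write.csv(as.data.frame(tab), file.path(config$out_dir, "ablation.csv"))
    tab
  })

  stage("explain", function() {
    best <- if ("rf" %in% config$models) "rf" else config$models[[1]]
    imp <- explain(reports[[best]], method = config$explain$method,
                   n_repeats = config$explain$n_repeats,
                   seed = derive_seed(config$seed, "explain"))
    jsonlite::write_json(
      list(method = imp$method, ranking = imp$ranking,
           overall = as.list(imp$overall),
           attributions = as.data.frame(imp$attributions)),
      file.path(config$out_dir, "importance.json"),
      auto_unbox = TRUE, digits = 10)
    imp
  })

  cfg_path <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  artifacts <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
  manifest$config_hash <- unname(tools::md5sum(cfg_path))
  manifest$checksums <- as.list(tools::md5sum(file.path(config$out_dir, artifacts)))
  names(manifest$checksums) <- artifacts
  manifest$total_seconds <- as.numeric(difftime(Sys.time(), t_all, units = "secs"))
  manifest$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  manifest$config <- unclass(config)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, force = TRUE)
  invisible(manifest)
}

report_summary <- function(r) {
  list(model = r$model$kind,
       validation_accuracy = r$validation_accuracy,
       fold_scores = r$fold_scores,
       test_accuracy = r$test_accuracy,
       precision = r$precision, recall = r$recall, f1 = r$f1,
       confusion = as.data.frame.matrix(unclass(r$confusion)),
       n_train = r$n_train, n_test = r$n_test)
}
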