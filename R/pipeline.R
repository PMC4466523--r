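# End-to-end orchestration: simulate -> extract velum curve -> align ->
# zone -> featurize -> classify -> report, writing every intermediate
# artifact plus a run manifest with input hashes, seeds, package version
# and per-stage timings.

default_pipeline_config <- function() {
  list(
    pipeline = list(out = tempfile("nasemg_run_"), seed = 1L),
    emg = list(rate = 600),
    mri = list(fps = 14, use_stack = FALSE, threshold = 0.5),
    audio = list(rate_mri = 16000, rate_emg = 8000, resample_rate = 12000),
    scenario = list(n_utterances = 10, burst_snr = 4),
    features = list(frame_length = 0.100, frame_shift = 0.020,
                    features_on = "raw"),
    classify = list(channel = 3, folds = 10, cost = 1, gamma = NULL,
                    part = c(0, 100)),
    zones_file = NULL)
}

#' Validate a pipeline configuration
#'
#' Fills unset fields from the defaults and errors, naming the field, on
#' structurally required entries.
#'
#' @param config Nested list (or path to a YAML file with the same
#'   structure).
#' @return The completed configuration list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- default_pipeline_config()
  merged <- utils::modifyList(def, config, keep.null = TRUE)
  required <- c("emg.rate", "mri.fps", "audio.rate_mri", "audio.rate_emg",
                "pipeline.seed", "classify.folds")
  for (key in required) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    v <- merged[[parts[1L]]][[parts[2L]]]
    if (is.null(v) || !is.numeric(v)) {
      stop(sprintf("config field '%s' is missing or non-numeric", key))
    }
  }
  if (merged$features$features_on %in% c("raw", "preprocessed") == FALSE) {
    stop("config field 'features.features_on' must be raw or preprocessed")
  }
  merged
}

max_abs_normalize <- function(channels) {
  apply(channels, 2L, function(x) {
    m <- max(abs(x))
    if (m > 0) x / m else x
  })
}

#' Run the full pipeline on a synthetic scenario
#'
#' Executes simulate, velum-curve extraction (from the toy MRI stack when
#' `mri$use_stack` is set, from the generator's curve otherwise), audio
#' resampling to a common rate, DTW alignment, mapping of the velum curve
#' onto the EMG clock, nasal/non-nasal zoning (or precomputed zones from
#' `zones_file`), framing and feature extraction, stratified
#' cross-validated SVM classification, zone-majority classification and
#' zone-wise mutual information, writing all artifacts under
#' `pipeline$out`.
#'
#' @param config Configuration list or YAML path; see
#'   [validate_config()].
#' @return An object of class `run_manifest`: configuration echo, input
#'   hashes, seeds, package version, per-stage timings, output paths, and
#'   the in-memory `results` (cv, zone majority, dependence table,
#'   detected zones).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  out_dir <- cfg$pipeline$out
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  stamp <- function(t0, stage) {
    timings[[stage]] <<- round(tic() - t0, 3)
  }

  t0 <- tic()
  scn_args <- cfg$scenario
  scn_args$emg_rate <- cfg$emg$rate
  scn_args$mri_fps <- cfg$mri$fps
  scn_args$audio_rate_mri <- cfg$audio$rate_mri
  scn_args$audio_rate_emg <- cfg$audio$rate_emg
  scn_args$seed <- cfg$pipeline$seed
  scn <- make_scenario(do.call(scenario_config, scn_args),
                       with_mri = isTRUE(cfg$mri$use_stack))
  write_scenario(scn, file.path(out_dir, "scenario"))
  stamp(t0, "simulate")

  t0 <- tic()
  vel_mri <- if (isTRUE(cfg$mri$use_stack)) {
    seed_frame <- which.max(scn$true_velum$values) - 1L
    ctr <- round(dim(scn$mri$frames)[2:3] / 2) - 1L
    areas <- segment_sagittal(scn$mri, scn$roi,
                              c(seed_frame, ctr[1L], ctr[2L]),
                              cfg$mri$threshold)
    area_to_velum_curve(areas)
  } else {
    scn$true_velum
  }
  write_curve_csv(vel_mri$values, vel_mri$rate,
                  file.path(out_dir, "velum_mri.csv"))
  stamp(t0, "extract_velum")

  t0 <- tic()
  fs <- cfg$audio$resample_rate
  a_mri <- resample_audio(scn$audio_mri, fs)
  a_emg <- resample_audio(scn$audio_emg, fs)
  path <- dtw_align(a_mri, a_emg)
  warped <- warp_curve(vel_mri, path, cfg$emg$rate)
  write_curve_csv(warped$values, warped$rate,
                  file.path(out_dir, "velum_warped.csv"))
  stamp(t0, "align")

  t0 <- tic()
  zones <- if (!is.null(cfg$zones_file)) {
    read_zones_tsv(cfg$zones_file, cfg$emg$rate)
  } else {
    detect_zones(warped)
  }
  write_zones_tsv(zones, file.path(out_dir, "zones.tsv"))
  stamp(t0, "zone")

  t0 <- tic()
  n_emg <- nrow(scn$emg$channels)
  sigs <- if (cfg$features$features_on == "preprocessed") {
    preprocess(scn$emg)$channels
  } else {
    max_abs_normalize(scn$emg$channels)
  }
  span_end <- max(zones$zones$end)
  n_usable <- min(n_emg, floor(span_end * cfg$emg$rate))
  channel <- cfg$classify$channel
  ft <- feature_table(sigs[seq_len(n_usable), channel], cfg$emg$rate,
                      channel = channel, zones = zones,
                      frame_length = cfg$features$frame_length,
                      frame_shift = cfg$features$frame_shift)
  utils::write.table(ft, file.path(out_dir, "features.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  stamp(t0, "featurize")

  t0 <- tic()
  cv <- crossvalidate(ft[, FEATURE_NAMES], ft$label,
                      k = cfg$classify$folds, seed = cfg$pipeline$seed,
                      cost = cfg$classify$cost, gamma = cfg$classify$gamma)
  fi <- attr(ft, "frame_index")
  zm <- zone_majority(cv$predictions, fi$times, zones,
                      part = cfg$classify$part)
  dep <- zone_dependence(warped, sigs[seq_len(n_usable), channel], zones)
  utils::write.table(cv$folds, file.path(out_dir, "cv_folds.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(dep, file.path(out_dir, "dependence.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  stamp(t0, "classify")

  paths <- file.path(out_dir, c("scenario", "velum_mri.csv",
                                "velum_warped.csv", "zones.tsv",
                                "features.tsv", "cv_folds.tsv",
                                "dependence.tsv"))
  hash_files <- setdiff(list.files(out_dir, recursive = TRUE,
                                   full.names = TRUE),
                        file.path(out_dir, "manifest.json"))
  hashes <- as.list(tools::md5sum(hash_files))
  names(hashes) <- basename(names(hashes))

  manifest <- structure(list(
    package_version = as.character(utils::packageVersion("nasemg")),
    config = cfg, seed = cfg$pipeline$seed,
    hashes = hashes, timings = as.list(timings), paths = paths,
    results = list(cv = cv, zone_majority = zm, dependence = dep,
                   zones = zones)),
    class = "run_manifest")
  json <- manifest[c("package_version", "config", "seed", "hashes",
                     "timings")]
  jsonlite::write_json(json, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> nasemg %s, seed %d\n", x$package_version,
              x$seed))
  cat(sprintf("  frame error %.1f%%, zone-majority error %.1f%%\n",
              x$results$cv$mean["error"], x$results$zone_majority$error))
  invisible(x)
}
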