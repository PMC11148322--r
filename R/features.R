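# Assembly of the 60-feature vector per speech sample and the cohort runner.

#' The frozen feature inventory
#'
#' The 60 features in canonical order, grouped by construct: prosody (3),
#' pause (3), functional connectivity (9), amplitude (4), rhythm (21),
#' complexity (16), regularity (4).
#'
#' @param as_table return the full manifest data.frame (name, construct,
#'   modality) instead of the name vector
#' @return character vector of 60 names, or a data.frame
#' @export
feature_manifest <- function(as_table = FALSE) {
  chans <- c("RTEMP", "RMAS", "RABD")
  cbn <- names(critical_bands())
  rows <- rbind(
    data.frame(name = c("sdevF0.st", "iqrF0.st", "meanF0.st"),
               construct = "prosody", modality = "acoustic"),
    data.frame(name = c("MeanDur_intrapause", "SdevDur_intrapause",
                        "pct_intrapause"),
               construct = "pause", modality = "acoustic"),
    data.frame(name = as.vector(t(outer(
      c("theta_alpha", "beta", "gamma"),
      c("RTEMP_RMAS", "RTEMP_RABD", "RABD_RMAS"),
      function(b, p) paste0("IMC_", p, "_", b)))),
      construct = "connectivity", modality = "sEMG"),
    data.frame(name = c(paste0("density_", chans), "density_audio"),
               construct = "amplitude",
               modality = c(rep("sEMG", 3), "acoustic")),
    data.frame(name = c(paste0("mod_depth_theta_", chans),
                        paste0("PSI_delta_theta_", chans),
                        paste0("PSI_theta_beta.gamma_", chans)),
               construct = "rhythm", modality = "sEMG"),
    data.frame(name = c(paste0("hbenvlp_mod_depth_theta_", cbn),
                        paste0("hbenvlp_PSI_delta_theta_", cbn),
                        paste0("hbenvlp_PSI_theta_beta.gamma_", cbn)),
               construct = "rhythm", modality = "acoustic"),
    data.frame(name = paste0("DET_", chans),
               construct = "complexity", modality = "sEMG"),
    data.frame(name = paste0("DET_mfcc", 1:13),
               construct = "complexity", modality = "acoustic"),
    data.frame(name = paste0("ShanEn_", chans),
               construct = "regularity", modality = "sEMG"),
    data.frame(name = "ShanEn_audio",
               construct = "regularity", modality = "acoustic"))
  if (as_table) rows else rows$name
}

#' Extraction configuration
#'
#' Every numeric constant of the pipeline in one structured list, so that a
#' run is fully described by its configuration.
#'
#' @param seg [seg_params()] for pause/speech segmentation
#' @param burst [burst_config()] for sEMG epoching
#' @param coherence [coherence_params()] for the Welch analysis
#' @param bands_imc coherence bands, see [imc_bands()]
#' @param local_sd_L `c(audio, semg)` block lengths of the local-SD series
#' @param rqa_semg,rqa_mfcc [rqa_params()] of the two RQA parameterizations
#' @param rqa_max_segments cap on 1-s RQA segments per sEMG channel (reduce
#'   for large cohort runs)
#' @param wpd [wpd_config()]
#' @param env_fs envelope rate for the rhythm analysis (Hz)
#' @param max_missing_frac hard-failure threshold on the fraction of missing
#'   features
#' @return nested configuration list
#' @export
extract_config <- function(seg = seg_params(), burst = burst_config(),
                           coherence = coherence_params(),
                           bands_imc = imc_bands(),
                           local_sd_L = c(audio = 1103, semg = 100),
                           rqa_semg = rqa_params(30, 5, 0.1),
                           rqa_mfcc = rqa_params(3, 15, 0.2),
                           rqa_max_segments = Inf,
                           wpd = wpd_config(), env_fs = 100,
                           max_missing_frac = 0.2) {
  as.list(environment())
}

#' Extract the full 60-feature vector from one recording
#'
#' Orchestrates the whole pipeline: sEMG preprocessing, pause/speech
#' segmentation, then the per-construct feature blocks (prosody, pause,
#' intermuscular coherence, visibility-graph density, envelope rhythm,
#' recurrence determinism, wavelet-packet entropy). Deterministic for a
#' fixed input and configuration. A failing stage records its features as
#' `NA` with a reason; the call fails hard only when more than
#' `max_missing_frac` of the features are missing.
#'
#' @param rec an [multimodal_recording()]
#' @param config an [extract_config()]
#' @return named numeric vector of 60 features (class `mmb_features`) with
#'   attribute `missing_reasons`
#' @export
extract_all_features <- function(rec, config = extract_config()) {
  stopifnot(inherits(rec, "mmb_recording"))
  feats <- stats::setNames(rep(NA_real_, 60), feature_manifest())
  reasons <- character(0)
  put <- function(v) feats[names(v)] <<- unname(v)
  fail <- function(block_names, e) {
    reasons[block_names] <<- conditionMessage(e)
  }
  # --- preprocessing & segmentation (shared) ---
  semg_pre <- lapply(rec$semg, preprocess_semg)
  seg <- segment_speech_pauses(rec$audio, config$seg, rec$speaking_rate_wpm)

  # prosody
  pros_names <- c("sdevF0.st", "iqrF0.st", "meanF0.st")
  tryCatch(put(prosody_features(extract_f0(rec$audio, rec$sex))),
           error = function(e) fail(pros_names, e))
  # pause
  tryCatch(put(pause_features(seg)),
           error = function(e) fail(c("MeanDur_intrapause",
                                      "SdevDur_intrapause",
                                      "pct_intrapause"), e))
  # functional connectivity: rectified, burst-epoched coherence. Epoch
  # centres are detected on the mean rectified envelope so the three
  # channels stay sample-aligned.
  imc_names <- grep("^IMC_", names(feats), value = TRUE)
  tryCatch({
    rect <- lapply(semg_pre, rectify)
    mean_rect <- time_series(Reduce(`+`, lapply(rect, `[[`, "samples")) / 3,
                             rect[[1]]$fs, "mean_rect")
    ref <- burst_epoch_concat(mean_rect, config$burst)
    log <- attr(ref, "epoch_log")
    # slice every channel by the same accepted epochs so the pair spectra
    # stay sample-aligned
    fs_e <- mean_rect$fs
    ep <- lapply(rect, function(ch) {
      idx <- unlist(lapply(seq_len(nrow(log)), function(i)
        (round(log$onset_s[i] * fs_e) + 1):(round(log$offset_s[i] * fs_e))))
      out <- time_series(ch$samples[idx], fs_e, ch$label)
      attr(out, "epoch_log") <- log
      out
    })
    specs <- list(
      RTEMP_RMAS = coherence_spectrum(ep$RTEMP, ep$RMAS, config$coherence),
      RTEMP_RABD = coherence_spectrum(ep$RTEMP, ep$RABD, config$coherence),
      RABD_RMAS = coherence_spectrum(ep$RABD, ep$RMAS, config$coherence))
    put(band_coherence_features(specs, config$bands_imc))
  }, error = function(e) fail(imc_names, e))
  # amplitude (visibility-graph density)
  for (ch in c("RTEMP", "RMAS", "RABD")) {
    nm <- paste0("density_", ch)
    tryCatch(feats[nm] <- density_feature(semg_pre[[ch]],
                                          config$local_sd_L[["semg"]]),
             error = function(e) fail(nm, e))
  }
  tryCatch(feats["density_audio"] <- density_feature(
    rec$audio, config$local_sd_L[["audio"]]),
    error = function(e) fail("density_audio", e))
  # rhythm
  rhy_names <- grep("mod_depth_theta|PSI_", names(feats), value = TRUE)
  tryCatch({
    semg_envs <- lapply(semg_pre, envelope_100hz, segmentation = seg,
                        fs_out = config$env_fs)
    crit_envs <- cochlear_critical_envelopes(rec$audio, seg,
                                             fs_out = config$env_fs)
    put(rhythm_feature_block(semg_envs, crit_envs))
  }, error = function(e) fail(rhy_names, e))
  # complexity
  det_semg <- paste0("DET_", c("RTEMP", "RMAS", "RABD"))
  tryCatch(put(semg_determinism_features(
    semg_pre, config$rqa_semg, max_segments = config$rqa_max_segments)),
    error = function(e) fail(det_semg, e))
  det_mfcc <- paste0("DET_mfcc", 1:13)
  tryCatch(put(mfcc_determinism_features(rec$audio, config$rqa_mfcc)),
           error = function(e) fail(det_mfcc, e))
  # regularity
  for (ch in c("RTEMP", "RMAS", "RABD")) {
    nm <- paste0("ShanEn_", ch)
    tryCatch(feats[nm] <- as.numeric(
      shannon_entropy_feature(semg_pre[[ch]], config$wpd)),
      error = function(e) fail(nm, e))
  }
  tryCatch(feats["ShanEn_audio"] <- as.numeric(
    shannon_entropy_feature(rec$audio, config$wpd)),
    error = function(e) fail("ShanEn_audio", e))

  n_missing <- sum(is.na(feats))
  if (n_missing > config$max_missing_frac * length(feats))
    stop(sprintf("extraction failed: %d/%d features missing (%s)",
                 n_missing, length(feats),
                 paste(unique(reasons), collapse = "; ")))
  structure(feats, missing_reasons = reasons, class = "mmb_features")
}

#' @export
print.mmb_features <- function(x, ...) {
  cat(sprintf("<mmb_features> %d features, %d missing\n",
              length(x), sum(is.na(x))))
  print(round(unclass(x), 4))
  invisible(x)
}

#' Run the extraction over a cohort of recordings
#'
#' @param recordings list of [multimodal_recording()]
#' @param config an [extract_config()]
#' @param progress print one line per sample
#' @return data.frame: `participant_id`, `sentence_id`, `group`,
#'   `speaking_rate_wpm`, plus the 60 features; failures are reported in
#'   attribute `run_report`
#' @export
run_cohort <- function(recordings, config = extract_config(),
                       progress = FALSE) {
  if (length(recordings) == 0) stop("empty cohort")
  keys <- vapply(recordings, function(r)
    paste(r$participant_id, r$sentence_id, sep = "/"), character(1))
  if (anyDuplicated(keys))
    stop("duplicate (participant, sentence) keys: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  report <- character(0)
  rows <- lapply(seq_along(recordings), function(i) {
    r <- recordings[[i]]
    if (progress)
      message(sprintf("[%d/%d] %s sentence %d", i, length(recordings),
                      r$participant_id, r$sentence_id))
    fv <- tryCatch(extract_all_features(r, config), error = function(e) {
      report[keys[i]] <<- conditionMessage(e)
      stats::setNames(rep(NA_real_, 60), feature_manifest())
    })
    data.frame(participant_id = r$participant_id, sentence_id = r$sentence_id,
               group = r$group, speaking_rate_wpm = r$speaking_rate_wpm,
               t(as.numeric(fv)))
  })
  out <- do.call(rbind, rows)
  names(out)[-(1:4)] <- feature_manifest()
  attr(out, "run_report") <- report
  out
}

#' Write a feature table to CSV (full precision)
#' @param table data.frame from [run_cohort()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_feature_table <- function(table, path) {
  tab <- table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) format(v, digits = 15,
                                                  trim = TRUE))
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path
#' @return data.frame
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, check.names = FALSE)
}
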