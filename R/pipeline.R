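# Session plan, pipeline configuration, a session-level simulator, and the
# end-to-end driver from raw recordings to features, statistics and models.

#' Session plan: ordered, labeled protocol stages
#'
#' Defaults to the stress protocol: Stroop (S1), rest (R1), mental
#' arithmetic (S2), rest (R2), 360 s each, back to back. Stage windows are
#' half-open `[start, start + duration)`.
#'
#' @param labels Stage labels (unique).
#' @param durations Stage durations in seconds (recycled).
#' @param starts Stage start times in seconds; default back-to-back from 0.
#' @return A data.frame of class `session_plan` with columns `label`,
#'   `start`, `duration`.
#' @export
session_plan <- function(labels = c("S1", "R1", "S2", "R2"),
                         durations = 360, starts = NULL) {
  durations <- rep_len(durations, length(labels))
  if (is.null(starts)) starts <- cumsum(c(0, durations[-length(durations)]))
  stopifnot(length(starts) == length(labels), all(durations > 0))
  if (anyDuplicated(labels)) stop("stage labels must be unique", call. = FALSE)
  if (is.unsorted(starts, strictly = TRUE) ||
      any(starts[-1] < (starts + durations)[-length(starts)])) {
    stop("stages must be ordered and non-overlapping", call. = FALSE)
  }
  structure(
    data.frame(label = labels, start = starts, duration = durations,
               stringsAsFactors = FALSE),
    class = c("session_plan", "data.frame")
  )
}

#' Pipeline configuration
#'
#' All defaults follow the recorder and protocol: 250 Hz sampling, 1-35 Hz
#' EEG analysis band, 100 uV EOG threshold, 1 s epochs, LF 0.04-0.15 Hz and
#' HF 0.15-0.4 Hz, 2 Hz tachogram resampling, linear SVM with cost 1 and
#' five stratified folds.
#'
#' @param fs Sampling rate, Hz.
#' @param eeg_band EEG analysis band, Hz.
#' @param eog_threshold EOG rejection threshold, uV.
#' @param epoch_len Epoch length, s.
#' @param lf_band,hf_band HRV spectral bands, Hz.
#' @param resample_rate Tachogram rate, Hz.
#' @param svm_cost SVM regularization constant.
#' @param folds CV folds.
#' @param seed RNG seed used for fold assignment.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(fs = 250, eeg_band = c(1, 35),
                            eog_threshold = 100, epoch_len = 1,
                            lf_band = c(0.04, 0.15), hf_band = c(0.15, 0.4),
                            resample_rate = 2, svm_cost = 1, folds = 5,
                            seed = 1L) {
  structure(
    list(fs = fs, eeg_band = eeg_band, eog_threshold = eog_threshold,
         epoch_len = epoch_len, lf_band = lf_band, hf_band = hf_band,
         resample_rate = resample_rate, svm_cost = svm_cost, folds = folds,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Simulate a full multi-stage session recording
#'
#' Builds one continuous three-channel recording by concatenating per-stage
#' synthetic ECG (from an RR spec) and EEG (from an EEG spec). The default
#' stage parameters emulate the qualitative stress pattern of the reference
#' cohort: stressor stages get a shorter mean RR, stronger LF and weaker HF
#' modulation, and a right-suppressed alpha band; rest stages the opposite.
#'
#' @param plan A [session_plan()].
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed; per-stage seeds are derived from it.
#' @param stage_params Optional named list (by stage label) of lists with
#'   elements `rr` (arguments for [rr_spec()], minus duration/seed) and
#'   `eeg` (arguments for [eeg_spec()], minus duration/seed) overriding the
#'   defaults.
#' @return A list with `record` (the concatenated [signal_record()]) and
#'   `truth` (per-stage ground-truth lists).
#' @export
simulate_session <- function(plan = session_plan(), fs = 250, seed = 1L,
                             stage_params = NULL) {
  stressed <- function(lbl) startsWith(lbl, "S")
  default_par <- function(lbl) {
    if (stressed(lbl)) {
      list(
        rr = list(mean_rr = 720, lf_amp = 35, lf_freq = 0.1,
                  hf_amp = 25, hf_freq = 0.25, jitter_sd = 15),
        eeg = list(band_power = list(delta = c(40, 40), theta = c(20, 20),
                                     alpha = c(16, 13), beta = c(28, 26)),
                   eog_rate = 2, eog_amp = 300)
      )
    } else {
      list(
        rr = list(mean_rr = 780, lf_amp = 25, lf_freq = 0.1,
                  hf_amp = 35, hf_freq = 0.25, jitter_sd = 25),
        eeg = list(band_power = list(delta = c(40, 40), theta = c(20, 20),
                                     alpha = c(14, 13.5), beta = c(21, 20)),
                   eog_rate = 2, eog_amp = 300)
      )
    }
  }
  left <- right <- ecg <- numeric(0)
  truth <- list()
  for (i in seq_len(nrow(plan))) {
    lbl <- plan$label[i]
    dur <- plan$duration[i]
    par <- if (!is.null(stage_params[[lbl]])) stage_params[[lbl]] else default_par(lbl)
    s_rr <- (seed * 131L + i * 7L) %% .Machine$integer.max
    s_eeg <- (seed * 131L + i * 7L + 3L) %% .Machine$integer.max
    rr <- generate_rr_series(do.call(rr_spec, c(par$rr, list(duration = dur, seed = s_rr))))
    keep <- rr$beat_times < dur - 0.3
    ecg_i <- generate_ecg(rr$beat_times[keep], qrs_amp = 25, noise_sd = 2,
                          fs = fs, duration = dur, seed = s_rr + 1L)
    eeg_i <- generate_eeg(do.call(eeg_spec, c(par$eeg, list(duration = dur, seed = s_eeg))),
                          fs = fs)
    n_i <- round(dur * fs)
    offset <- length(ecg)
    left <- c(left, eeg_i$record$eeg_left[seq_len(n_i)])
    right <- c(right, eeg_i$record$eeg_right[seq_len(n_i)])
    ecg <- c(ecg, ecg_i$record$ecg[seq_len(n_i)])
    truth[[lbl]] <- list(rr = rr$truth, ecg = ecg_i$truth, eeg = eeg_i$truth,
                         offset_samples = offset)
  }
  list(record = signal_record(left, right, ecg, fs = fs), truth = truth)
}

#' Run the full analysis pipeline
#'
#' Slices each subject's recording by the session plan, extracts the six
#' HRV and eight EEG features per stage, assembles the feature table, runs
#' the per-feature ANOVA with stress-vs-rest contrasts and, when requested,
#' the three published SVM models under cross-validation.
#'
#' @param records Named list of [signal_record()] objects, one per subject.
#' @param plan A [session_plan()].
#' @param config A [pipeline_config()].
#' @param classify Fit the EEG / HRV / EEG+HRV models (default `TRUE`;
#'   needs at least `config$folds` rows per class).
#' @return A list of class `pipeline_result`: `features` (feature table),
#'   `anova` ([anova_by_feature()] result), `cv` (named list of
#'   [crossvalidate_svm()] results or `NULL`), `report` (model comparison
#'   or `NULL`) and `log` (per subject-stage beat counts, epoch counts, and
#'   a provenance record echoing the config and seeds).
#' @export
run_pipeline <- function(records, plan = session_plan(),
                         config = pipeline_config(), classify = TRUE) {
  stopifnot(is.list(records), length(records) > 0)
  if (is.null(names(records)) || any(names(records) == "")) {
    names(records) <- paste0("subj", seq_along(records))
  }
  feats <- list()
  log <- list()
  for (subj in names(records)) {
    rec <- records[[subj]]
    stopifnot(inherits(rec, "signal_record"))
    feats[[subj]] <- list()
    for (i in seq_len(nrow(plan))) {
      lbl <- plan$label[i]
      ctx <- sprintf("subject %s, stage %s", subj, lbl)
      seg <- tryCatch(
        slice_record(rec, plan$start[i], plan$duration[i]),
        error = function(e) stop(ctx, ": ", conditionMessage(e), call. = FALSE)
      )
      res <- tryCatch({
        rr <- detect_r_peaks(seg)
        hrv <- hrv_features(rr, rate = config$resample_rate)
        eeg <- eeg_features(seg, band = config$eeg_band,
                            threshold = config$eog_threshold,
                            epoch_len = config$epoch_len)
        list(hrv = hrv, eeg = eeg, n_beats = length(rr$peak_indices))
      }, error = function(e) stop(ctx, ": ", conditionMessage(e), call. = FALSE))
      feats[[subj]][[lbl]] <- c(res$hrv, res$eeg)
      log[[paste(subj, lbl, sep = ".")]] <- list(
        subject = subj, stage = lbl, n_beats = res$n_beats,
        epochs_used = attr(res$eeg, "n_epochs_used"),
        epochs_total = attr(res$eeg, "n_epochs_total")
      )
    }
  }
  table <- build_feature_table(feats)
  anv <- if (length(records) >= 2) anova_by_feature(table) else NULL
  cv <- rep_ <- NULL
  if (isTRUE(classify)) {
    cv <- lapply(
      stats::setNames(nm = c("EEG", "HRV", "EEG+HRV")),
      function(nm) crossvalidate_svm(table, model_spec(nm, cost = config$svm_cost),
                                     folds = config$folds, seed = config$seed)
    )
    rep_ <- report_models(cv)
  }
  structure(
    list(features = table, anova = anv, cv = cv, report = rep_,
         log = list(
           stages = log,
           provenance = list(config = unclass(config),
                             n_subjects = length(records),
                             package_version = as.character(utils::packageVersion("earstress")))
         )),
    class = "pipeline_result"
  )
}
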