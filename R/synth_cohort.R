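# Feature-level synthetic cohorts: per-condition Gaussian draws of the 14
# stress features, for testing the statistics and classification stages.

#' Names of the 14 stress features
#'
#' Six HRV features (`mRR`, `SDRR`, `RMSSD` in ms; `nLF_HRV`, `nHF_HRV` in
#' percent of total power; `LF_HF` the normalized-power ratio on a x100
#' scale) and eight EEG features (`nLAP`, `nRAP`, `nLBP`, `nRBP` normalized
#' band powers in percent; `DPA`, `TPA`, `APA`, `BPA` hemispheric band-power
#' asymmetries on a -100..100 scale).
#'
#' @return Character vector of length 14.
#' @export
feature_names <- function() {
  c("nLAP", "nRAP", "nLBP", "nRBP", "DPA", "TPA", "APA", "BPA",
    "mRR", "SDRR", "RMSSD", "nLF_HRV", "nHF_HRV", "LF_HF")
}

#' Protocol stages and their class labels
#'
#' The session alternates stressors and rest: Stroop test (S1), rest (R1),
#' mental arithmetic (S2), rest (R2). S-stages are labeled `stress`,
#' R-stages `rest`.
#'
#' @return Named character vector mapping stage to label.
#' @export
stage_labels <- function() {
  c(S1 = "stress", R1 = "rest", S2 = "stress", R2 = "rest")
}

#' Published group-level feature parameters of the reference stress cohort
#'
#' Per-condition means and standard deviations of all 14 features, as
#' reported for a cohort of 14 healthy young adults who underwent the
#' Stroop / rest / mental-arithmetic / rest protocol with the wearable
#' ear-EEG + head-ECG recorder. These serve as generative ground truth for
#' simulated cohorts.
#'
#' @return A data.frame with columns `feature`, `condition`, `mean`, `sd`.
#' @export
stress_cohort_params <- function() {
  path <- system.file("extdata", "stress_cohort_params.csv",
                      package = "earstress", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Specification of a feature-level synthetic cohort
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param params A data.frame with columns `feature`, `condition`, `mean`,
#'   `sd` covering every (feature, condition) cell; defaults to
#'   [stress_cohort_params()]. Conditions must be exactly S1, R1, S2, R2.
#' @param seed Integer RNG seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 14, params = stress_cohort_params(),
                        seed = 1L) {
  stopifnot(n_subjects >= 1, is.data.frame(params),
            all(c("feature", "condition", "mean", "sd") %in% names(params)))
  if (!setequal(unique(params$condition), names(stage_labels()))) {
    stop("conditions must be exactly S1, R1, S2, R2", call. = FALSE)
  }
  bad <- setdiff(unique(params$feature), feature_names())
  if (length(bad)) {
    stop("unknown feature(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(params$sd < 0)) stop("sd must be >= 0", call. = FALSE)
  structure(
    list(n_subjects = as.integer(n_subjects), params = params,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Generate a feature-level synthetic cohort
#'
#' Draws each feature independently from `N(mean, sd^2)` of its
#' (condition, feature) cell — features are independent because the
#' reference parameters report no covariances. Produces one row per
#' (subject, stage), `4 * n_subjects` rows in total, with the fixed
#' stage-to-label mapping.
#'
#' @param spec A [cohort_spec()].
#' @return A feature table: data.frame with columns `subject`, `stage`,
#'   `label` and one column per feature present in `spec$params`.
#' @examples
#' tab <- generate_feature_cohort(cohort_spec(n_subjects = 4, seed = 7))
#' table(tab$label)
#' @export
generate_feature_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  stages <- names(stage_labels())
  feats <- intersect(feature_names(), unique(spec$params$feature))
  grid <- expand.grid(stage = stages, subject = seq_len(spec$n_subjects),
                      stringsAsFactors = FALSE)
  tab <- data.frame(
    subject = grid$subject,
    stage = grid$stage,
    label = unname(stage_labels()[grid$stage]),
    stringsAsFactors = FALSE
  )
  with_seed(spec$seed, {
    for (f in feats) {
      vals <- numeric(nrow(tab))
      for (s in stages) {
        cell <- spec$params[spec$params$feature == f & spec$params$condition == s, ]
        idx <- tab$stage == s
        vals[idx] <- stats::rnorm(sum(idx), cell$mean, cell$sd)
      }
      tab[[f]] <- vals
    }
  })
  tab <- tab[order(tab$subject, match(tab$stage, stages)), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
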