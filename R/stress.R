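# Condition-wise statistics and stress-vs-rest classification:
# feature table assembly, per-feature ANOVA with stress-vs-rest contrasts,
# separation-based feature ranking, and linear-SVM five-fold CV.

#' Assemble the per-stage feature table
#'
#' One row per (subject, stage) with the fixed stage-to-label mapping
#' (S1, S2 -> stress; R1, R2 -> rest). Missing stages yield rows of `NA`
#' features with a warning.
#'
#' @param features A named list: `features[[subject]][[stage]]` is a named
#'   numeric vector combining the HRV and EEG features of that stage (as
#'   returned by [hrv_features()] and [eeg_features()]).
#' @return A feature table data.frame (`subject`, `stage`, `label`, one
#'   column per feature).
#' @export
build_feature_table <- function(features) {
  stopifnot(is.list(features), length(features) > 0)
  stages <- names(stage_labels())
  feats <- feature_names()
  rows <- list()
  for (subj in names(features)) {
    for (st in stages) {
      v <- features[[subj]][[st]]
      if (is.null(v)) {
        warning("subject ", subj, " is missing stage ", st,
                "; emitting NA row", call. = FALSE)
        v <- stats::setNames(rep(NA_real_, length(feats)), feats)
      }
      row <- data.frame(subject = subj, stage = st,
                        label = unname(stage_labels()[st]),
                        stringsAsFactors = FALSE)
      for (f in feats) row[[f]] <- if (f %in% names(v)) unname(v[f]) else NA_real_
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

feature_columns <- function(table) intersect(feature_names(), names(table))

#' Per-feature ANOVA across the four stages, with stress-vs-rest contrasts
#'
#' One-way ANOVA (stage as a four-level factor) per feature, followed by
#' the four pairwise Welch t-tests contrasting each stressor with each rest
#' stage (S1 vs R1, S1 vs R2, S2 vs R1, S2 vs R2). When the within-group
#' variance is zero everywhere the F statistic is reported as `Inf` (or
#' `NaN` if the between-group variance is zero too) with a note.
#'
#' @param table A feature table (see [build_feature_table()]).
#' @param features Features to analyze; defaults to all present.
#' @return A list of class `anova_result` with elements:
#'   * `anova` - data.frame (`feature`, `F`, `p`, `note`),
#'   * `contrasts` - data.frame (`feature`, `contrast`, `estimate`, `p`).
#' @export
anova_by_feature <- function(table, features = feature_columns(table)) {
  stage <- factor(table$stage, levels = names(stage_labels()))
  if (any(table(stage) < 2)) {
    stop("need at least 2 subjects per stage", call. = FALSE)
  }
  pairs <- list(c("S1", "R1"), c("S1", "R2"), c("S2", "R1"), c("S2", "R2"))
  an <- list(); ct <- list()
  for (f in features) {
    y <- table[[f]]
    ok <- !is.na(y)
    within_var <- stats::ave(y[ok], stage[ok], FUN = stats::var)
    if (all(within_var == 0)) {
      gm <- tapply(y[ok], stage[ok], mean)
      Fv <- if (stats::var(gm) > 0) Inf else NaN
      an[[f]] <- data.frame(feature = f, F = Fv, p = NA_real_,
                            note = "zero within-group variance")
    } else {
      fit <- stats::aov(y[ok] ~ stage[ok])
      s <- summary(fit)[[1]]
      an[[f]] <- data.frame(feature = f, F = s[["F value"]][1],
                            p = s[["Pr(>F)"]][1], note = "")
    }
    for (pr in pairs) {
      a <- y[table$stage == pr[1] & ok]
      b <- y[table$stage == pr[2] & ok]
      tt <- tryCatch(stats::t.test(a, b), error = function(e) NULL)
      ct[[paste(f, pr[1], pr[2])]] <- data.frame(
        feature = f, contrast = paste(pr[1], "vs", pr[2]),
        estimate = mean(a) - mean(b),
        p = if (is.null(tt)) NA_real_ else tt$p.value
      )
    }
  }
  structure(
    list(anova = do.call(rbind, c(an, make.row.names = FALSE)),
         contrasts = do.call(rbind, c(ct, make.row.names = FALSE))),
    class = "anova_result"
  )
}

#' Rank features by stress-rest separation
#'
#' Orders candidate features by the absolute difference between the stress
#' and rest class means, computed on z-scored features so the criterion is
#' scale-free. Ties break in candidate-list order; the top `n_select` are
#' returned (all of them, with a warning, when fewer are available).
#'
#' @param table A feature table.
#' @param candidates Candidate feature names (default: all present).
#' @param n_select How many to select (default 4).
#' @return Character vector of selected features, best first, with the full
#'   ranking attached as attribute `ranking` (data.frame
#'   `feature`, `separation`).
#' @export
rank_features <- function(table, candidates = feature_columns(table),
                          n_select = 4) {
  stopifnot(all(candidates %in% names(table)))
  if (anyNA(table[, candidates])) {
    stop("candidates contain missing values", call. = FALSE)
  }
  sep <- vapply(candidates, function(f) {
    z <- as.numeric(scale(table[[f]]))
    abs(mean(z[table$label == "stress"]) - mean(z[table$label == "rest"]))
  }, numeric(1))
  ord <- order(-sep)  # stable: ties keep candidate order
  ranking <- data.frame(feature = candidates[ord], separation = sep[ord],
                        row.names = NULL)
  if (length(candidates) < n_select) {
    warning("fewer than ", n_select, " candidates; using all", call. = FALSE)
    n_select <- length(candidates)
  }
  out <- ranking$feature[seq_len(n_select)]
  attr(out, "ranking") <- ranking
  out
}

#' Classifier model specification
#'
#' The three published feature selections are available by name:
#' EEG = (APA, nLAP, nRAP, BPA), HRV = (LF_HF, nHF_HRV, nLF_HRV, mRR),
#' EEG+HRV = (nLAP, APA, nHF_HRV, LF_HF).
#'
#' @param name One of `"EEG"`, `"HRV"`, `"EEG+HRV"`, or any label when
#'   `features` is given explicitly.
#' @param features Feature names to use; defaults to the published
#'   selection for the named model.
#' @param cost SVM regularization constant (default 1).
#' @param standardize Z-score features using training-fold statistics
#'   (default `TRUE`).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(name, features = NULL, cost = 1, standardize = TRUE) {
  defaults <- list(
    "EEG" = c("APA", "nLAP", "nRAP", "BPA"),
    "HRV" = c("LF_HF", "nHF_HRV", "nLF_HRV", "mRR"),
    "EEG+HRV" = c("nLAP", "APA", "nHF_HRV", "LF_HF")
  )
  if (is.null(features)) {
    if (!name %in% names(defaults)) {
      stop("no default feature set for model '", name, "'", call. = FALSE)
    }
    features <- defaults[[name]]
  }
  stopifnot(all(features %in% feature_names()), cost > 0)
  structure(list(name = name, features = features, cost = cost,
                 standardize = standardize),
            class = "model_spec")
}

# Stratified fold assignment: within each class, shuffle then deal round-robin.
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Linear-SVM five-fold cross-validation
#'
#' Rows (subject-stage samples) are partitioned into `folds` stratified
#' folds under the seed. Per fold, z-scoring parameters and the linear SVM
#' are fit on the training folds only and applied to the held-out fold.
#' Sensitivity is stress recall, specificity rest recall; AUC comes from
#' the SVM decision values; the fold ROC curves are vertically averaged
#' (mean TPR on a common FPR grid).
#'
#' @param table A feature table with no missing values in the model's
#'   features.
#' @param model A [model_spec()].
#' @param folds Number of folds (default 5).
#' @param seed Integer RNG seed for the fold assignment.
#' @param group_by_subject If `TRUE`, folds are assigned at the subject
#'   level so no subject contributes to both train and test. Default
#'   `FALSE`: rows are the sampling unit.
#' @return A list of class `cv_result`: `per_fold` (data.frame with
#'   sensitivity/specificity/accuracy in percent and AUC per fold), `mean`
#'   (named vector of the four averaged metrics), `roc` (data.frame `fpr`,
#'   `tpr` of the averaged curve), `model`, `folds`, `seed`.
#' @export
crossvalidate_svm <- function(table, model, folds = 5, seed = 1L,
                              group_by_subject = FALSE) {
  stopifnot(inherits(model, "model_spec"))
  feats <- model$features
  if (anyNA(table[, feats])) stop("missing feature values", call. = FALSE)
  y <- factor(table$label, levels = c("rest", "stress"))
  if (min(table(y)) < folds) {
    stop("need at least `folds` samples per class", call. = FALSE)
  }
  fold <- with_seed(seed, {
    repeat {
      f <- if (group_by_subject) {
        subj <- unique(table$subject)
        sf <- stats::setNames(rep_len(seq_len(folds), length(subj))[
          sample(length(subj))], subj)
        unname(sf[as.character(table$subject)])
      } else {
        stratified_folds(as.character(y), folds)
      }
      bad <- any(vapply(seq_len(folds), function(k) {
        length(unique(y[f != k])) < 2
      }, logical(1)))
      if (!bad) break
      warning("a training split lacked both classes; re-drawing folds",
              call. = FALSE)
    }
    f
  })

  fpr_grid <- seq(0, 1, by = 0.01)
  per_fold <- list()
  tpr_sum <- numeric(length(fpr_grid))
  for (k in seq_len(folds)) {
    tr <- fold != k
    te <- !tr
    xtr <- as.matrix(table[tr, feats])
    xte <- as.matrix(table[te, feats, drop = FALSE])
    if (model$standardize) {
      mu <- colMeans(xtr)
      sg <- apply(xtr, 2, stats::sd)
      sg[sg == 0] <- 1
      xtr <- sweep(sweep(xtr, 2, mu), 2, sg, "/")
      xte <- sweep(sweep(xte, 2, mu), 2, sg, "/")
    }
    fit <- e1071::svm(xtr, y[tr], kernel = "linear", cost = model$cost,
                      scale = FALSE)
    pred <- stats::predict(fit, xte, decision.values = TRUE)
    dec <- as.numeric(attr(pred, "decision.values"))
    # orient decision values so larger means "stress"
    if (colnames(attr(pred, "decision.values"))[1] == "rest/stress") {
      dec <- -dec
    }
    yte <- y[te]
    sens <- mean(pred[yte == "stress"] == "stress") * 100
    spec <- mean(pred[yte == "rest"] == "rest") * 100
    acc <- mean(pred == yte) * 100
    roc <- pROC::roc(response = yte, predictor = dec,
                     levels = c("rest", "stress"), direction = "<",
                     quiet = TRUE)
    auc <- as.numeric(pROC::auc(roc))
    # step-interpolated TPR at each grid FPR (max TPR achievable at <= FPR)
    fp <- rev(1 - roc$specificities)
    tp <- rev(roc$sensitivities)
    tpr_k <- vapply(fpr_grid, function(g) max(c(0, tp[fp <= g + 1e-12])),
                    numeric(1))
    tpr_sum <- tpr_sum + tpr_k
    per_fold[[k]] <- data.frame(fold = k, sensitivity = sens,
                                specificity = spec, accuracy = acc,
                                auc = auc)
  }
  per_fold <- do.call(rbind, per_fold)
  structure(
    list(
      per_fold = per_fold,
      mean = c(sensitivity = mean(per_fold$sensitivity),
               specificity = mean(per_fold$specificity),
               accuracy = mean(per_fold$accuracy),
               auc = mean(per_fold$auc)),
      roc = data.frame(fpr = c(0, fpr_grid),       # explicit (0, 0) origin
                       tpr = c(0, tpr_sum / folds)),
      fold_assignment = fold,
      model = model, folds = folds, seed = as.integer(seed)
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  m <- x$mean
  cat(sprintf(
    "<cv_result> %s model, %d-fold CV: sens %.1f%%, spec %.1f%%, acc %.1f%%, AUC %.4f\n",
    x$model$name, x$folds, m["sensitivity"], m["specificity"],
    m["accuracy"], m["auc"]
  ))
  invisible(x)
}

#' Model comparison report
#'
#' @param results Named list of [crossvalidate_svm()] results.
#' @return A list with `table` (one row per model: sensitivity, specificity,
#'   accuracy in percent, AUC) and `roc` (long data.frame `model`, `fpr`,
#'   `tpr` for plotting the averaged ROC curves).
#' @export
report_models <- function(results) {
  stopifnot(length(results) > 0)
  tab <- do.call(rbind, lapply(names(results), function(nm) {
    m <- results[[nm]]$mean
    data.frame(model = nm, sensitivity = m[["sensitivity"]],
               specificity = m[["specificity"]],
               accuracy = m[["accuracy"]], auc = m[["auc"]])
  }))
  roc <- do.call(rbind, lapply(names(results), function(nm) {
    cbind(model = nm, results[[nm]]$roc)
  }))
  rownames(tab) <- rownames(roc) <- NULL
  list(table = tab, roc = roc)
}
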