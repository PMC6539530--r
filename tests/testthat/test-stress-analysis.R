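fake_stage_features <- function(seed = 1) {
  set.seed(seed)
  stats::setNames(as.list(rnorm(14)), feature_names())
}

test_that("the feature table has one labeled row per subject-stage", {
  feats <- lapply(stats::setNames(nm = paste0("s", 1:14)), function(s) {
    lapply(stats::setNames(nm = c("S1", "R1", "S2", "R2")), function(st) {
      unlist(fake_stage_features(match(s, paste0("s", 1:14))))
    })
  })
  tab <- build_feature_table(feats)
  expect_equal(nrow(tab), 56)
  expect_true(all(tab$label[tab$stage %in% c("S1", "S2")] == "stress"))
  expect_false(anyNA(tab[, feature_names()]))
})

test_that("missing stages yield flagged NA rows", {
  feats <- list(s1 = list(S1 = unlist(fake_stage_features())))
  w <- capture_warnings(tab <- build_feature_table(feats))
  expect_length(w, 3)
  expect_match(w, "missing stage", all = TRUE)
  expect_equal(nrow(tab), 4)
  expect_false(anyNA(tab[tab$stage == "S1", feature_names()]))
  expect_true(all(is.na(tab[tab$stage != "S1", "APA"])))
})

test_that("ANOVA F matches the brute-force sum-of-squares oracle", {
  for (s in 1:20) {
    tab <- generate_feature_cohort(cohort_spec(8, seed = 100 + s))
    a <- anova_by_feature(tab, features = c("APA", "mRR", "LF_HF"))
    for (f in c("APA", "mRR", "LF_HF")) {
      expect_equal(a$anova$F[a$anova$feature == f],
                   oracle_anova_f(tab[[f]], tab$stage), tolerance = 1e-9)
    }
  }
})

test_that("degenerate and null ANOVA inputs behave correctly", {
  pars <- stress_cohort_params()
  pars$sd <- 0
  tab <- generate_feature_cohort(cohort_spec(5, pars, seed = 1))
  a <- anova_by_feature(tab, features = "APA")
  expect_true(is.infinite(a$anova$F))
  expect_match(a$anova$note, "zero within-group")
  # equal means, nonzero noise: omnibus p rejects at ~ the nominal rate
  null_pars <- stress_cohort_params()
  for (f in unique(null_pars$feature)) {
    null_pars$mean[null_pars$feature == f] <-
      mean(null_pars$mean[null_pars$feature == f])
    null_pars$sd[null_pars$feature == f] <-
      mean(null_pars$sd[null_pars$feature == f])
  }
  ps <- vapply(1:100, function(s) {
    t0 <- generate_feature_cohort(cohort_spec(10, null_pars, seed = 300 + s))
    anova_by_feature(t0, features = "APA")$anova$p
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0.005)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("feature ranking is separation-ordered and scale-free", {
  tab <- generate_feature_cohort(cohort_spec(20, seed = 5))
  tab$synthetic_marker <- ifelse(tab$label == "stress", 3, 0) +
    rnorm(nrow(tab), 0, 0.05)
  cand <- c("SDRR", "DPA", "mRR")
  ranked <- rank_features(cbind(tab, marker = tab$synthetic_marker),
                          candidates = c(cand, "marker"), n_select = 1)
  expect_equal(unname(ranked[1]), "marker")
  # rescaling a feature by a positive constant cannot change the order
  tab2 <- tab
  tab2$mRR <- tab2$mRR * 1000
  r1 <- rank_features(tab, candidates = feature_names())
  r2 <- rank_features(tab2, candidates = feature_names())
  expect_identical(as.character(r1), as.character(r2))
  expect_warning(rank_features(tab, candidates = c("APA", "mRR")), "fewer")
})

test_that("reference-cohort ranking tends to recover the published selection", {
  hits <- vapply(1:10, function(s) {
    tab <- generate_feature_cohort(cohort_spec(14, seed = 400 + s))
    sel <- rank_features(tab, candidates = feature_names())
    length(intersect(sel, c("nLAP", "APA", "nHF_HRV", "LF_HF")))
  }, numeric(1))
  expect_gte(mean(hits >= 2), 0.8)
})

test_that("cross-validation partitions rows and reproduces under a seed", {
  tab <- generate_feature_cohort(cohort_spec(14, seed = 2))
  cv <- crossvalidate_svm(tab, model_spec("EEG+HRV"), seed = 11)
  f <- cv$fold_assignment
  expect_length(f, nrow(tab))
  expect_setequal(unique(f), 1:5)
  # stratification: both classes in every fold
  for (k in 1:5) expect_setequal(unique(tab$label[f == k]), c("stress", "rest"))
  cv2 <- crossvalidate_svm(tab, model_spec("EEG+HRV"), seed = 11)
  expect_identical(cv$per_fold, cv2$per_fold)
  expect_identical(cv$mean, cv2$mean)
  # metric consistency within each fold
  for (k in 1:5) {
    ns <- sum(tab$label[f == k] == "stress")
    nr <- sum(tab$label[f == k] == "rest")
    pf <- cv$per_fold[k, ]
    expect_equal(pf$accuracy,
                 (pf$sensitivity * ns + pf$specificity * nr) / (ns + nr),
                 tolerance = 1e-9)
  }
})

test_that("fold AUC agrees with a brute-force Mann-Whitney oracle", {
  tab <- generate_feature_cohort(cohort_spec(10, seed = 3))
  model <- model_spec("HRV")
  cv <- crossvalidate_svm(tab, model, folds = 2, seed = 4)
  # refit fold 1 by hand and compare its AUC against the rank statistic
  f <- cv$fold_assignment
  feats <- model$features
  xtr <- as.matrix(tab[f != 1, feats])
  mu <- colMeans(xtr); sg <- apply(xtr, 2, sd)
  xtr <- sweep(sweep(xtr, 2, mu), 2, sg, "/")
  xte <- sweep(sweep(as.matrix(tab[f == 1, feats]), 2, mu), 2, sg, "/")
  y <- factor(tab$label, levels = c("rest", "stress"))
  fit <- e1071::svm(xtr, y[f != 1], kernel = "linear", cost = 1, scale = FALSE)
  pr <- predict(fit, xte, decision.values = TRUE)
  dec <- as.numeric(attr(pr, "decision.values"))
  if (colnames(attr(pr, "decision.values"))[1] == "rest/stress") dec <- -dec
  expect_equal(cv$per_fold$auc[1], oracle_auc(dec, tab$label[f == 1]),
               tolerance = 1e-9)
})

test_that("mean AUC never decreases along a class-separation grid", {
  base <- stress_cohort_params()
  auc_at <- function(shift) {
    pars <- base
    stress_cells <- pars$condition %in% c("S1", "S2") & pars$feature == "APA"
    pars$mean[stress_cells] <- pars$mean[stress_cells] - shift
    mean(vapply(1:5, function(s) {
      tab <- generate_feature_cohort(cohort_spec(14, pars, seed = 500 + s))
      crossvalidate_svm(tab, model_spec("sep", features = c("APA", "mRR")),
                        seed = s)$mean[["auc"]]
    }, numeric(1)))
  }
  aucs <- vapply(c(0, 4, 12), auc_at, numeric(1))
  expect_true(all(diff(aucs) >= -0.01))
})

test_that("the model report emits the comparison table and a valid mean ROC", {
  tab <- generate_feature_cohort(cohort_spec(14, seed = 6))
  cvs <- lapply(stats::setNames(nm = c("EEG", "HRV", "EEG+HRV")), function(nm) {
    crossvalidate_svm(tab, model_spec(nm), seed = 7)
  })
  rep_ <- report_models(cvs)
  expect_equal(nrow(rep_$table), 3)
  expect_true(all(rep_$table$auc >= 0 & rep_$table$auc <= 1))
  for (nm in names(cvs)) {
    roc <- cvs[[nm]]$roc
    expect_equal(roc$tpr[roc$fpr == 0][1], 0, tolerance = 1e-9)
    expect_equal(roc$tpr[nrow(roc)], 1)
    expect_true(all(diff(roc$tpr) >= 0))
  }
})
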