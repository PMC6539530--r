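# Independent brute-force oracles, kept deliberately naive (explicit loops,
# no shared code with the implementation).

oracle_time_domain <- function(iv) {
  n <- length(iv)
  m <- 0
  for (x in iv) m <- m + x
  m <- m / n
  ss <- 0
  for (x in iv) ss <- ss + (x - m)^2
  sdrr <- sqrt(ss / (n - 1))
  sd2 <- 0
  for (i in 1:(n - 1)) sd2 <- sd2 + (iv[i + 1] - iv[i])^2
  c(mRR = m, SDRR = sdrr, RMSSD = sqrt(sd2 / (n - 1)))
}

# direct evaluation of the normalized-power and asymmetry formulas from
# absolute band powers and totals
oracle_eeg_features <- function(pl, pr, tl, tr) {
  nl <- sapply(c("delta", "theta", "alpha", "beta"), function(b) 100 * pl[[b]] / tl)
  nr <- sapply(c("delta", "theta", "alpha", "beta"), function(b) 100 * pr[[b]] / tr)
  asym <- sapply(c("delta", "theta", "alpha", "beta"),
                 function(b) 100 * (nr[[b]] - nl[[b]]) / (nr[[b]] + nl[[b]]))
  c(nLAP = nl[["alpha"]], nRAP = nr[["alpha"]],
    nLBP = nl[["beta"]], nRBP = nr[["beta"]],
    DPA = asym[["delta"]], TPA = asym[["theta"]],
    APA = asym[["alpha"]], BPA = asym[["beta"]])
}

oracle_anova_f <- function(y, g) {
  g <- as.character(g)
  groups <- unique(g)
  grand <- mean(y)
  ssb <- 0
  ssw <- 0
  for (gr in groups) {
    yi <- y[g == gr]
    ssb <- ssb + length(yi) * (mean(yi) - grand)^2
    for (v in yi) ssw <- ssw + (v - mean(yi))^2
  }
  dfb <- length(groups) - 1
  dfw <- length(y) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}

# Mann-Whitney AUC: P(score_stress > score_rest) + 0.5 P(tie)
oracle_auc <- function(scores, labels, positive = "stress") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# matched R-R comparison: nearest-truth matching of detected peaks, then
# interval-by-interval absolute error in ms
matched_rr_errors <- function(det_idx, true_idx, fs) {
  matched <- vapply(det_idx, function(i) true_idx[which.min(abs(true_idx - i))],
                    numeric(1))
  abs(diff(det_idx) - diff(matched)) * 1000 / fs
}
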