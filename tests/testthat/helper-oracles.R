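# Independent oracles used across the suite.  Each is a deliberately
# naive implementation (loops, exhaustive enumeration) kept separate from
# the package's code paths.

# inner products by explicit summation
oracle_matched_filter <- function(Phi, r) {
  out <- numeric(ncol(Phi))
  for (j in seq_len(ncol(Phi))) {
    acc <- 0
    for (i in seq_len(nrow(Phi))) acc <- acc + Phi[i, j] * r[i]
    out[j] <- acc
  }
  out
}

# AUROC as the Mann-Whitney statistic by exhaustive pair enumeration
oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# AUPR by stepping through the ranked list one tie-group at a time
oracle_aupr <- function(scores, labels) {
  P <- sum(labels == 1)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  area <- 0
  prev_recall <- 0
  for (th in thresholds) {
    called <- scores >= th
    tp <- sum(labels == 1 & called)
    recall <- tp / P
    precision <- tp / sum(called)
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

# confusion counts by explicit cell-by-cell loop (off-diagonal only)
oracle_confusion <- function(truth, estimate, tol = 1e-8) {
  n <- nrow(truth)
  TP <- FP <- TN <- FN <- FS <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    t_nz <- abs(truth[i, j]) > tol
    e_nz <- abs(estimate[i, j]) > tol
    if (t_nz && e_nz) {
      TP <- TP + 1
      if (sign(truth[i, j]) != sign(estimate[i, j])) FS <- FS + 1
    } else if (!t_nz && e_nz) FP <- FP + 1
    else if (t_nz && !e_nz) FN <- FN + 1
    else TN <- TN + 1
  }
  list(TP = TP, FP = FP, TN = TN, FN = FN, FS = FS)
}

# total least squares via the eigendecomposition of the Gram matrix of
# [Phi b] (independent of the svd() route used by the package)
oracle_tls <- function(Phi, b) {
  M <- cbind(Phi, b)
  eg <- eigen(crossprod(M), symmetric = TRUE)
  v <- eg$vectors[, ncol(M)]
  -v[seq_len(ncol(Phi))] / v[ncol(M)]
}

# fixed point of the outlier-deletion iteration on a pure standard
# normal: sigma^2 = Var[N(0,1) | |N(0,1)| < t * sigma]
oracle_deletion_fixed_point <- function(t, iters = 200) {
  sigma <- 1
  for (i in seq_len(iters)) {
    a <- t * sigma
    mass <- 2 * pnorm(a) - 1
    sigma <- sqrt(1 - 2 * a * dnorm(a) / mass)
  }
  sigma
}

rel_err <- function(x, truth) sqrt(sum((x - truth)^2)) / sqrt(sum(truth^2))
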