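#' Confusion summary of a network estimate against the truth
#'
#' Counts over the off-diagonal cells only (self-regulation is excluded
#' from the model).  A cell is called nonzero when its absolute value
#' exceeds \code{zero_tol}.  Besides the usual TP/FP/TN/FN counts the
#' false-sign count FS (both nonzero, opposite sign) is reported; FS does
#' not enter the rates.
#'
#' @param truth n x n true adjacency.
#' @param estimate n x n estimated adjacency.
#' @param zero_tol magnitude below which a value counts as zero.
#' @return an object of class \code{"confusion_summary"} with counts
#'   (TP, FP, TN, FN, FS, P, N) and rates (tpr, fpr, fnr, tnr, ppv).
#' @export
confusion <- function(truth, estimate, zero_tol = 1e-8) {
  truth <- as.matrix(truth); estimate <- as.matrix(estimate)
  if (!all(dim(truth) == dim(estimate)))
    stop("'truth' and 'estimate' must have equal dimensions")
  off <- row(truth) != col(truth)
  tv <- truth[off]; ev <- estimate[off]
  t_nz <- abs(tv) > zero_tol
  e_nz <- abs(ev) > zero_tol
  TP <- sum(t_nz & e_nz)
  FP <- sum(!t_nz & e_nz)
  TN <- sum(!t_nz & !e_nz)
  FN <- sum(t_nz & !e_nz)
  FS <- sum(t_nz & e_nz & sign(tv) != sign(ev))
  P <- sum(t_nz); N <- sum(!t_nz)
  structure(
    list(TP = TP, FP = FP, TN = TN, FN = FN, FS = FS, P = P, N = N,
         tpr = if (P > 0) TP / P else NA_real_,
         fpr = if (N > 0) FP / N else NA_real_,
         fnr = if (P > 0) FN / P else NA_real_,
         tnr = if (N > 0) TN / N else NA_real_,
         ppv = if (TP + FP > 0) TP / (TP + FP) else NA_real_),
    class = "confusion_summary"
  )
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("Confusion: TP %d  FP %d  TN %d  FN %d  FS %d\n",
              x$TP, x$FP, x$TN, x$FN, x$FS))
  cat(sprintf("  TPR %.4f  FPR %.4f  TNR %.4f  PPV %s\n",
              x$tpr, x$fpr, x$tnr,
              ifelse(is.na(x$ppv), "NA", sprintf("%.4f", x$ppv))))
  invisible(x)
}

#' ROC and precision-recall curves with areas
#'
#' Sweeps every distinct score value as a decision threshold (tied scores
#' grouped at a single threshold).  AUROC is computed by trapezoidal
#' integration of the ROC points, which equals the Mann-Whitney statistic
#' \eqn{P(s^+ > s^-) + \frac{1}{2} P(s^+ = s^-)}.  AUPR uses step-wise
#' integration (precision held at its achieved value over each recall
#' increment), the standard choice for class-imbalanced edge ranking.
#'
#' @param scores numeric ranking scores (higher = more confident edge).
#' @param labels binary truth (0/1 or logical), same length.
#' @return an object of class \code{"curve_set"} with \code{roc_points}
#'   (fpr, tpr), \code{pr_points} (recall, precision), \code{auroc},
#'   \code{aupr}.
#' @export
roc_pr <- function(scores, labels) {
  labels <- as.numeric(labels != 0)
  if (length(scores) != length(labels))
    stop("'scores' and 'labels' must have equal length")
  P <- sum(labels == 1); N <- sum(labels == 0)
  if (P == 0 || N == 0)
    stop("both a positive and a negative label are required")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  grp_end <- which(c(s[-1] != s[-length(s)], TRUE))  # last index per tie group
  tp <- cumsum(l)[grp_end]
  fp <- grp_end - tp
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  auroc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  recall <- tp / P
  precision <- tp / (tp + fp)
  aupr <- sum(diff(c(0, recall)) * precision)
  structure(
    list(roc_points = cbind(fpr = fpr, tpr = tpr),
         pr_points = cbind(recall = c(0, recall),
                           precision = c(precision[1], precision)),
         auroc = auroc, aupr = aupr),
    class = "curve_set"
  )
}

#' @export
print.curve_set <- function(x, ...) {
  cat(sprintf("ROC/PR curves: AUROC %.4f, AUPR %.4f (%d threshold points)\n",
              x$auroc, x$aupr, nrow(x$roc_points) - 1L))
  invisible(x)
}

#' Vertically average curves from replicate runs
#'
#' Interpolates each replicate's curve onto a common uniform grid of the
#' x coordinate (fpr for ROC, recall for PR) and averages the y values
#' pointwise.  Averaging identical replicates reproduces the single
#' curve on the grid.
#'
#' @param curves list of \code{\link{roc_pr}} results.
#' @param type \code{"roc"} or \code{"pr"}.
#' @param grid_size number of grid points (default 201).
#' @return two-column matrix (grid x, mean y).
#' @export
average_curves <- function(curves, type = c("roc", "pr"), grid_size = 201L) {
  type <- match.arg(type)
  grid <- seq(0, 1, length.out = grid_size)
  ys <- vapply(curves, function(cv) {
    pts <- if (type == "roc") cv$roc_points else cv$pr_points
    stats::approx(pts[, 1], pts[, 2], xout = grid, method = "linear",
                  ties = "ordered", rule = 2)$y
  }, numeric(grid_size))
  cbind(x = grid, y = rowMeans(ys))
}

#' Permutation p-value for an AUROC or AUPR observation
#'
#' Probability that a random ordering of the potential network links
#' attains an area at least as large as the observed one, estimated over
#' \code{n_perm} random score orderings against the fixed gold-standard
#' labels, with add-one smoothing so the p-value is always positive:
#' \eqn{p = (1 + \#\{perm \ge obs\}) / (n_{perm} + 1)}.
#'
#' @param observed observed metric value.
#' @param labels binary truth over the potential links (at least one
#'   positive and one negative).
#' @param metric \code{"auroc"} or \code{"aupr"}.
#' @param n_perm number of random orderings (>= 1).
#' @return p-value in (0, 1].
#' @export
dream_pvalue <- function(observed, labels, metric = c("auroc", "aupr"),
                         n_perm = 1000L) {
  metric <- match.arg(metric)
  labels <- as.numeric(labels != 0)
  if (sum(labels == 1) == 0 || sum(labels == 0) == 0)
    stop("gold standard must contain both positives and negatives")
  if (n_perm < 1) stop("'n_perm' must be >= 1")
  nlinks <- length(labels)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    cv <- roc_pr(sample.int(nlinks), labels)
    val <- if (metric == "auroc") cv$auroc else cv$aupr
    if (val >= observed) hits <- hits + 1L
  }
  (1 + hits) / (n_perm + 1)
}

#' Overall significance score from AUROC and AUPR p-values
#'
#' \deqn{Score = -\tfrac{1}{2} \log_{10}\left[
#'   \left(\prod_i p_i^{AUROC}\right)^{1/n}
#'   \left(\prod_i p_i^{AUPR}\right)^{1/n}\right]}
#' i.e. minus half the log of the product of the two geometric-mean
#' p-values.  Larger scores indicate greater statistical significance of
#' the network prediction; in the DREAM benchmarks n = 5 networks per
#' challenge.
#'
#' @param p_auroc vector of AUROC p-values in (0, 1].
#' @param p_aupr vector of AUPR p-values in (0, 1], same length.
#' @return the score (>= 0).
#' @export
dream_score <- function(p_auroc, p_aupr) {
  if (length(p_auroc) != length(p_aupr))
    stop("'p_auroc' and 'p_aupr' must have equal length")
  if (any(p_auroc <= 0) || any(p_aupr <= 0) ||
      any(p_auroc > 1) || any(p_aupr > 1))
    stop("all p-values must lie in (0, 1]")
  gm <- function(p) exp(mean(log(p)))
  -0.5 * log10(gm(p_auroc) * gm(p_aupr))
}

#' Mean squared error and squared bias of replicate estimates
#'
#' For M replicate estimates \eqn{\hat{x}^{[h]}} of a coefficient vector
#' x: \deqn{MSE = \frac{1}{M}\sum_h (\hat{x}^{[h]} - x)^T(\hat{x}^{[h]} - x)}
#' \deqn{bias^2 = (\bar{\hat{x}} - x)^T(\bar{\hat{x}} - x)}
#' MSE decomposes exactly as bias^2 plus the mean within-replicate
#' variance trace.
#'
#' @param estimates M x p matrix of replicate estimates (rows).
#' @param truth length-p true coefficient vector.
#' @return list with \code{mse} and \code{bias2}.
#' @export
mse_bias <- function(estimates, truth) {
  estimates <- as.matrix(estimates)
  if (ncol(estimates) != length(truth))
    stop("'estimates' columns must match length of 'truth'")
  dev <- sweep(estimates, 2, truth, "-")
  mse <- mean(rowSums(dev^2))
  mean_dev <- colMeans(dev)
  list(mse = mse, bias2 = sum(mean_dev^2))
}

#' Error and bias convergence curves over data lengths
#'
#' @param estimates_by_length named list; element i is the M x p matrix
#'   of replicate estimates at the i-th data length.
#' @param truth length-p true coefficient vector.
#' @param lengths optional numeric data lengths (defaults to names or
#'   sequence).
#' @return data.frame with columns \code{length}, \code{mse},
#'   \code{bias2}.
#' @export
error_bias_curves <- function(estimates_by_length, truth, lengths = NULL) {
  if (is.null(lengths)) {
    lengths <- suppressWarnings(as.numeric(names(estimates_by_length)))
    if (length(lengths) == 0 || anyNA(lengths))
      lengths <- seq_along(estimates_by_length)
  }
  res <- lapply(estimates_by_length, mse_bias, truth = truth)
  data.frame(length = lengths,
             mse = vapply(res, `[[`, numeric(1), "mse"),
             bias2 = vapply(res, `[[`, numeric(1), "bias2"))
}
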