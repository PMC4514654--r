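test_that("confusion counts match an exhaustive cell-by-cell oracle", {
  truth <- matrix(c(0, 1, 0, 0,
                    -2, 0, 0, 3,
                    0, 0, 0, 0,
                    1, 0, -1, 0), 4, 4, byrow = TRUE)
  expect_perfect <- confusion(truth, truth)
  expect_equal(expect_perfect$tpr, 1)
  expect_equal(expect_perfect$fpr, 0)
  expect_equal(expect_perfect$ppv, 1)
  expect_equal(expect_perfect$FS, 0)

  empty <- confusion(truth, matrix(0, 4, 4))
  expect_equal(empty$tpr, 0)
  expect_equal(empty$tnr, 1)

  set.seed(31)
  for (i in 1:20) {
    tr <- matrix(sample(c(-1, 0, 0, 1), 16, TRUE), 4, 4); diag(tr) <- 0
    es <- matrix(rnorm(16) * rbinom(16, 1, 0.5), 4, 4); diag(es) <- 0
    got <- confusion(tr, es)
    want <- oracle_confusion(tr, es)
    expect_equal(got[c("TP", "FP", "TN", "FN", "FS")], want)
    expect_equal(got$TP + got$FN, got$P)
    expect_equal(got$FP + got$TN, got$N)
    if (got$P > 0) expect_equal(got$tpr, got$TP / got$P)
    if (got$TP + got$FP > 0) expect_equal(got$ppv, got$TP / (got$TP + got$FP))
  }
  expect_error(confusion(truth, matrix(0, 3, 3)), "dimensions")
})

test_that("ROC/PR areas agree with enumeration oracles including ties", {
  # perfect separation
  cv <- roc_pr(c(9, 8, 7, 1, 2), c(1, 1, 1, 0, 0))
  expect_equal(cv$auroc, 1)
  expect_equal(cv$aupr, 1)

  set.seed(32)
  for (i in 1:20) {
    labels <- c(rep(1, 10), rep(0, 40))
    scores <- round(rnorm(50, mean = labels), 1)  # rounding induces ties
    cv <- roc_pr(scores, labels)
    expect_equal(cv$auroc, oracle_auroc(scores, labels), tolerance = 1e-12)
    expect_equal(cv$aupr, oracle_aupr(scores, labels), tolerance = 1e-12)
    expect_true(all(diff(cv$roc_points[, 1]) >= 0))
    expect_true(all(diff(cv$roc_points[, 2]) >= 0))
  }
  expect_error(roc_pr(1:5, rep(1, 5)), "label")
})

test_that("label-independent scores give chance-level AUROC", {
  set.seed(33)
  labels <- rbinom(1e4, 1, 0.05)
  scores <- rnorm(1e4)
  cv <- roc_pr(scores, labels)
  P <- sum(labels); N <- sum(1 - labels)
  se <- sqrt((P + N + 1) / (12 * P * N))   # Mann-Whitney null SE
  expect_lt(abs(cv$auroc - 0.5), 3 * se)
})

test_that("ROC areas agree with an established implementation", {
  set.seed(34)
  for (i in 1:100) {
    labels <- c(rep(1, 15), rep(0, 60))
    scores <- rnorm(75, mean = 1.2 * labels)
    got <- roc_pr(scores, labels)$auroc
    ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
      response = labels, predictor = scores, quiet = TRUE,
      direction = "<"))))
    expect_equal(got, ref, tolerance = 1e-6)
  }
})

test_that("vertical curve averaging of identical replicates is the identity", {
  set.seed(35)
  labels <- c(rep(1, 20), rep(0, 80))
  scores <- rnorm(100, mean = labels)
  cv <- roc_pr(scores, labels)
  avg <- average_curves(list(cv, cv, cv), type = "roc")
  single <- approx(cv$roc_points[, 1], cv$roc_points[, 2],
                   xout = avg[, 1], ties = "ordered", rule = 2)$y
  expect_equal(avg[, 2], single, tolerance = 1e-12)
  avg_pr <- average_curves(list(cv, cv), type = "pr", grid_size = 101)
  expect_equal(nrow(avg_pr), 101L)
})

test_that("permutation p-values behave at the extremes and the median", {
  set.seed(36)
  labels <- c(rep(1, 8), rep(0, 42))
  # a perfect observation beats every random ordering
  expect_equal(dream_pvalue(1.0, labels, "auroc", n_perm = 999), 1 / 1000)
  # an observation below every permutation has p = 1
  expect_equal(dream_pvalue(-1, labels, "aupr", n_perm = 199), 1)
  # rank symmetry: the null median lands near p = 0.5
  set.seed(37)
  null_val <- median(replicate(201, roc_pr(sample(50), labels)$auroc))
  set.seed(38)
  p_med <- dream_pvalue(null_val, labels, "auroc", n_perm = 499)
  expect_gt(p_med, 0.35)
  expect_lt(p_med, 0.65)
  expect_error(dream_pvalue(0.5, rep(1, 10), "auroc", 10), "positives")
})

test_that("the overall significance score matches its closed forms", {
  expect_equal(dream_score(rep(1, 5), rep(1, 5)), 0)
  expect_equal(dream_score(rep(0.1, 5), rep(0.1, 5)), 1.0, tolerance = 1e-12)
  expect_equal(dream_score(rep(1e-10, 5), rep(1e-10, 5)), 10.0,
               tolerance = 1e-12)
  # monotone decreasing in every argument
  base <- dream_score(rep(0.05, 5), rep(0.2, 5))
  worse <- dream_score(c(0.5, rep(0.05, 4)), rep(0.2, 5))
  expect_lt(worse, base)
  expect_error(dream_score(c(0, rep(0.1, 4)), rep(0.1, 5)), "p-values")
})

test_that("error and bias summaries satisfy the variance decomposition", {
  truth <- c(1, -2, 0.5)
  perfect <- matrix(truth, 4, 3, byrow = TRUE)
  mb <- mse_bias(perfect, truth)
  expect_equal(mb$mse, 0)
  expect_equal(mb$bias2, 0)

  single <- matrix(c(2, -1, 1), 1, 3)
  mb1 <- mse_bias(single, truth)
  expect_equal(mb1$mse, sum((single - truth)^2))
  expect_equal(mb1$mse, mb1$bias2)   # M = 1 identity

  set.seed(39)
  est <- matrix(rnorm(60), 20, 3)
  mb2 <- mse_bias(est, truth)
  centered <- sweep(est, 2, colMeans(est), "-")
  expect_equal(mb2$mse, mb2$bias2 + mean(rowSums(centered^2)),
               tolerance = 1e-10)

  curves <- error_bias_curves(list(`50` = perfect, `100` = est), truth)
  expect_equal(curves$length, c(50, 100))
  expect_equal(curves$mse[1], 0)
})

test_that("success frequency decays with sparsity at fixed undersampling", {
  freq <- phase_experiment(n = 100, delta_grid = 0.5,
                           rho_grid = c(0.1, 0.3, 0.6), trials = 15,
                           solver = "smomp", seed = 40)
  f <- freq[1, ]
  se <- sqrt(pmax(f * (1 - f), 0.25 / 15) / 15)
  expect_true(all(diff(f) <= 2 * (se[-1] + se[-3])))
  expect_equal(f[["0.100"]], 1)      # deep success phase
  expect_lt(f[["0.600"]], 0.5)       # deep failure phase
  # infeasible cells are flagged NA
  bad <- phase_experiment(n = 20, delta_grid = 0.1, rho_grid = 0.1,
                          trials = 2, solver = "stomp", seed = 1)
  expect_true(is.na(bad[1, 1]))      # k rounds to 0
})
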