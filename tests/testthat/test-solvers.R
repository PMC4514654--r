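test_that("matched filter equals direct inner products", {
  set.seed(1)
  Phi <- matrix(rnorm(8 * 12), 8, 12)
  r <- rnorm(8)
  expect_equal(matched_filter(Phi, r), oracle_matched_filter(Phi, r),
               tolerance = 1e-12)
  expect_equal(matched_filter(Phi, rep(0, 8)), rep(0, 12))
  # orthonormal square system: filter inverts exactly
  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))
  x <- rnorm(6)
  expect_equal(matched_filter(Q, drop(Q %*% x)), x, tolerance = 1e-12)
  expect_error(matched_filter(Phi, rnorm(5)), "dimension")
})

test_that("outlier-deletion sigma converges to the truncated-normal fixed point", {
  # deterministic analogue of the iteration, same stopping rule
  fixed_point <- function(t, tol = 1e-3) {
    sigma <- 1
    repeat {
      a <- t * sigma
      s_new <- sqrt(1 - 2 * a * dnorm(a) / (2 * pnorm(a) - 1))
      if (abs(s_new - sigma) / sigma < tol) return(s_new)
      sigma <- s_new
    }
  }
  set.seed(3)
  x <- rnorm(1e5)
  est <- estimate_null_sigma(x, t = 2.5, variance_tol = 1e-3)
  expect_lt(abs(est$sigma - fixed_point(2.5)), 0.015)
  expect_gt(est$iterations, 0)

  set.seed(8)
  est2 <- estimate_null_sigma(rnorm(1e5), t = 2.0, variance_tol = 1e-3)
  expect_lt(abs(est2$sigma - fixed_point(2.0)), 0.02)
})

test_that("outlier deletion recovers the null scale under heavy contamination", {
  set.seed(4)
  y <- c(rnorm(1e4), rep(100, 50))
  est <- estimate_null_sigma(y, t = 2.5, variance_tol = 1e-3)
  expect_lt(abs(est$sigma - 1), 0.1)      # within 10% of the generating sd
  expect_gt(sqrt(mean(y^2)), 5)           # the naive estimate is useless
  # degenerate all-zero input flagged rather than crashed
  ez <- estimate_null_sigma(rep(0, 10), t = 2)
  expect_true(ez$degenerate)
  expect_equal(ez$sigma, 0)
})

test_that("false-alarm-control threshold computes, clamps and validates", {
  t1 <- fac_threshold(80, 99, alpha0_override = 0.3)
  expect_equal(as.numeric(t1), 2.0)               # raw 1.036 clamped up
  expect_equal(attr(t1, "alpha0"), 0.3)
  expect_equal(as.numeric(fac_threshold(80, 99, alpha0_override = 0.3,
                                        threshold_range = NULL)),
               qnorm(0.85), tolerance = 1e-12)    # unclamped quantile

  # an interior quantile passes through unchanged
  a_int <- 2 * (1 - pnorm(2.5))
  expect_equal(as.numeric(fac_threshold(50, 200, alpha0_override = a_int)),
               2.5, tolerance = 1e-12)

  # formula oracle: alpha0 from (m-k)/(S(n-k)), quantile via root finding
  m <- 100; n <- 1000; k <- 5; S <- 10
  t3 <- fac_threshold(m, n, k_hint = k, S = S, threshold_range = NULL)
  a0 <- (m - k) / (S * (n - k))
  expect_equal(attr(t3, "alpha0"), a0, tolerance = 1e-12)
  q <- uniroot(function(z) pnorm(z) - (1 - a0 / 2), c(0, 10),
               tol = 1e-12)$root
  expect_equal(as.numeric(t3), q, tolerance = 1e-8)

  # overdetermined settings can push alpha0 past 1: the formula errors
  expect_error(fac_threshold(1000, 99, k_hint = 5, S = 10), "alpha0")
})

test_that("nonnull fit is a signed Gaussian ML with floored spread", {
  one <- estimate_nonnull_params(4.2)
  expect_equal(one$mu, 4.2)
  expect_equal(one$sigma, 1e-8)      # single point: floor applies
  pair <- estimate_nonnull_params(c(3, -3))
  expect_equal(pair$mu, 0)           # signed fit straddles zero
  expect_equal(pair$sigma, 3)
  set.seed(6)
  z <- rnorm(1e5, mean = 5, sd = 1)
  fit <- estimate_nonnull_params(z)
  expect_lt(abs(fit$mu - 5) / 5, 0.02)
  expect_lt(abs(fit$sigma - 1), 0.05)
  expect_error(estimate_nonnull_params(numeric(0)), "nonempty")
})

test_that("stage true-positive rate matches the two-tail closed form", {
  expect_equal(tpr_beta(10, 1, 2, 1), 1, tolerance = 1e-6)  # far-separated
  expect_equal(tpr_beta(0, 1, 2, 1), 2 * pnorm(2, lower.tail = FALSE),
               tolerance = 1e-12)                           # 2*Q(2) ~ 0.0455
  set.seed(9)
  for (i in 1:5) {
    mu <- runif(1, 0, 3); s2 <- runif(1, 0.5, 2)
    t_s <- runif(1, 2, 3); s1 <- runif(1, 0.5, 2)
    beta <- tpr_beta(mu, s2, t_s, s1)
    draws <- abs(rnorm(1e6, mu, s2)) > t_s * s1
    mc <- mean(draws)
    se <- sqrt(mc * (1 - mc) / 1e6)
    expect_lt(abs(beta - mc), max(3 * se, 1e-5))
  }
  expect_error(tpr_beta(1, -1, 2, 1), "positive")
})

test_that("support refinement keeps the largest amplitudes with a floor", {
  expect_equal(refine_support(c(1, -2, 3), c(4L, 7L, 9L), beta = 1),
               c(4L, 7L, 9L))
  # floor(3 * 0.2) = 0 raised to min_keep: single largest magnitude kept
  expect_equal(refine_support(c(1, -2, 0.5), c(4L, 7L, 9L), beta = 0.2),
               7L)
  set.seed(10)
  x <- rnorm(20); cand <- sample(100L, 20)
  kept <- refine_support(x, cand, beta = 0.5)
  brute <- sort(cand[order(-abs(x), cand)][1:10])
  expect_equal(kept, brute)
})

test_that("noise-free sparse systems are recovered exactly by both solvers", {
  set.seed(2)
  for (i in 1:15) {
    Phi <- matrix(rnorm(32 * 64), 32, 64)
    x0 <- rep(0, 64)
    supp <- sample(64, 3)
    x0[supp] <- sample(c(-1, 1), 3, TRUE) * runif(3, 1, 2)
    y <- drop(Phi %*% x0)
    opts <- solver_options(k_hint = 3)
    expect_lt(rel_err(smomp_solve(Phi, y, opts)$coefficients, x0), 1e-6)
    expect_lt(rel_err(stomp_solve(Phi, y, opts)$coefficients, x0), 1e-6)
  }
})

test_that("zero observation yields the zero solution immediately", {
  set.seed(12)
  Phi <- matrix(rnorm(60), 10, 6)
  for (solve_fn in list(smomp_solve, stomp_solve)) {
    sol <- solve_fn(Phi, rep(0, 10))
    expect_equal(sol$coefficients, rep(0, 6))
    expect_length(sol$support, 0)
    expect_length(sol$trace, 0)
  }
})

test_that("stagewise traces are finite with non-increasing residuals and growing support", {
  set.seed(13)
  for (i in 1:40) {
    m <- 40; n <- 60
    Phi <- matrix(rnorm(m * n), m, n)
    x0 <- rep(0, n); supp <- sample(n, 5)
    x0[supp] <- rnorm(5, 0, 2)
    y <- drop(Phi %*% x0) + rnorm(m, 0, 0.3)
    sol <- if (i %% 2) smomp_solve(Phi, y) else stomp_solve(Phi, y)
    rn <- vapply(sol$trace, `[[`, numeric(1), "residual_norm")
    if (length(rn) > 1) expect_true(all(diff(rn) <= 1e-10))
    for (st in sol$trace) {
      expect_true(is.finite(st$null_sigma) && is.finite(st$threshold) &&
                  is.finite(st$residual_norm))
      expect_true(st$tpr_beta > 0 && st$tpr_beta <= 1)
      expect_gte(st$candidate_set_size, length(st$kept_set))
      expect_gte(length(st$kept_set), 1L)
    }
    expect_lte(length(sol$support), m)
    # nonzeros of the coefficient vector are exactly the support entries
    expect_setequal(which(sol$coefficients != 0), sol$support)
  }
})

test_that("projection leaves the residual orthogonal to the selected columns", {
  set.seed(14)
  for (i in 1:10) {
    m <- 50; n <- 80
    Phi <- matrix(rnorm(m * n), m, n)
    x0 <- rep(0, n); x0[sample(n, 4)] <- rnorm(4, 0, 2)
    y <- drop(Phi %*% x0) + rnorm(m, 0, 0.2)
    sol <- smomp_solve(Phi, y)
    # reconstruct the solver's internal centered design
    Phic <- scale(Phi, center = TRUE, scale = FALSE)
    yc <- y - mean(y)
    r <- yc - drop(Phic %*% sol$coefficients)
    expect_lt(max(abs(crossprod(Phic[, sol$support, drop = FALSE], r))), 1e-8)
    expect_equal(sqrt(sum(r^2)),
                 sol$trace[[length(sol$trace)]]$residual_norm,
                 tolerance = 1e-8)
  }
})

test_that("zero columns are rejected before normalization", {
  Phi <- cbind(rnorm(10), rep(0, 10), rnorm(10))
  expect_error(smomp_solve(Phi, rnorm(10)), "zero")
})

test_that("total least squares solves consistent and noisy systems", {
  set.seed(15)
  # consistent limit: exact recovery
  Phi <- matrix(rnorm(50 * 5), 50, 5)
  x <- rnorm(5)
  expect_lt(rel_err(tls_solve(Phi, drop(Phi %*% x)), x), 1e-8)

  for (i in 1:10) {
    Phi <- matrix(rnorm(50 * 5), 50, 5) + 0.1 * matrix(rnorm(250), 50, 5)
    b <- drop(Phi %*% rnorm(5)) + rnorm(50, 0, 0.3)
    xt <- tls_solve(Phi, b)
    expect_equal(xt, oracle_tls(Phi, b), tolerance = 1e-10)
    # defining property: [x; -1] attains the smallest singular value of
    # the augmented matrix among all directions
    M <- cbind(Phi, b)
    w <- c(xt, -1)
    expect_equal(sqrt(sum((M %*% w)^2)) / sqrt(sum(w^2)),
                 min(svd(M)$d), tolerance = 1e-8)
  }
})

test_that("solver options validate their arguments", {
  expect_error(solver_options(max_stages = 0), "max_stages")
  expect_error(solver_options(residual_tol = -1), "tolerances")
  expect_error(solver_options(alpha0 = 1.5), "alpha0")
  expect_error(solver_options(min_keep = 0), "min_keep")
})
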