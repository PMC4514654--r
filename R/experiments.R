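#' Estimate the adjacency matrix of an artificial instance
#'
#' Recovers each column i of the causal adjacency from the noisy
#' measurement matrix A and observation column \code{B[, i]}, excluding
#' the structurally-zero self column, and assembles the estimates into an
#' n x n matrix with zero diagonal.
#'
#' @param instance an \code{\link{generate_artificial_instance}} result
#'   (or any list with matrices \code{A} and \code{B}).
#' @param solver one of \code{"smomp"}, \code{"stomp"}, \code{"tls"}.
#' @param opts \code{\link{solver_options}} for the stagewise solvers.
#' @return n x n estimated adjacency (column i = regulations onto gene i).
#' @export
estimate_instance_adjacency <- function(instance,
                                        solver = c("smomp", "stomp", "tls"),
                                        opts = solver_options()) {
  solver <- match.arg(solver)
  A <- instance$A; B <- instance$B
  n <- ncol(A)
  X <- matrix(0, n, n)
  for (i in seq_len(n)) {
    Phi <- A[, -i, drop = FALSE]
    y <- B[, i]
    # classical TLS runs on the raw columns: the noise on A and B shares
    # one standard deviation, so the equal-noise assumption holds in
    # original units and column scaling would break it
    coef <- switch(solver,
      smomp = smomp_solve(Phi, y, opts)$coefficients,
      stomp = stomp_solve(Phi, y, opts)$coefficients,
      tls = tls_solve(Phi, y))
    X[-i, i] <- coef
  }
  X
}

#' Benchmark solvers on the artificial linear network
#'
#' Runs repeated trials of the artificial benchmark: generate an
#' instance, recover the adjacency with each solver, and score the
#' off-diagonal magnitude ranking against the true support by AUROC and
#' AUPR.  The default configuration is the standard artificial-network
#' setting: 100 genes, A0 entries uniform on [1, 10], power-law column
#' sparsity (k_min 1, gamma 2.5), regulation magnitudes down to 1e-5,
#' and false-alarm parameter 0.3 for the stagewise solvers.
#'
#' @param n,m,sigma instance dimensions and noise level.
#' @param trials number of independent trials.
#' @param solvers character vector from \code{c("smomp","stomp","tls")}.
#' @param alpha0 false-alarm-control parameter for the stagewise solvers.
#' @param prior degree prior (default power law k_min 1, gamma 2.5).
#' @param rho_a smallest regulation magnitude.
#' @param entry_low,entry_high,two_interval passed to the generator.
#' @param opts base \code{\link{solver_options}}; \code{alpha0} overrides
#'   its false-alarm setting.
#' @param seed optional seed for the whole experiment.
#' @param keep_curves also return the per-trial \code{\link{roc_pr}}
#'   curve sets (for curve averaging).
#' @return list with \code{per_trial} (data.frame: trial, solver, auroc,
#'   aupr), \code{summary} (mean and sd per solver) and optionally
#'   \code{curves}.
#' @export
benchmark_artificial <- function(n = 100, m = 1000, sigma = 2.0,
                                 trials = 50,
                                 solvers = c("smomp", "tls"),
                                 alpha0 = 0.3,
                                 prior = power_law_prior(1, 2.5, n),
                                 rho_a = 1e-5,
                                 entry_low = 1, entry_high = 10,
                                 two_interval = FALSE,
                                 opts = solver_options(),
                                 seed = NULL, keep_curves = FALSE) {
  solvers <- match.arg(solvers, c("smomp", "stomp", "tls"),
                       several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  opts$alpha0 <- alpha0
  rows <- list()
  curves <- if (keep_curves)
    stats::setNames(vector("list", length(solvers)), solvers) else NULL

  for (tr in seq_len(trials)) {
    inst <- generate_artificial_instance(
      n = n, m = m, sigma = sigma, prior = prior, rho_a = rho_a,
      entry_low = entry_low, entry_high = entry_high,
      two_interval = two_interval)
    off <- row(inst$X0) != col(inst$X0)
    labels <- as.numeric(inst$X0[off] != 0)
    for (sv in solvers) {
      X_hat <- estimate_instance_adjacency(inst, solver = sv, opts = opts)
      cv <- roc_pr(abs(X_hat[off]), labels)
      rows[[length(rows) + 1L]] <- data.frame(
        trial = tr, solver = sv, auroc = cv$auroc, aupr = cv$aupr)
      if (keep_curves) curves[[sv]][[tr]] <- cv
    }
  }

  per_trial <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(per_trial, per_trial$solver),
    function(d) data.frame(
      solver = d$solver[1], trials = nrow(d),
      auroc_mean = mean(d$auroc), auroc_sd = stats::sd(d$auroc),
      aupr_mean = mean(d$aupr), aupr_sd = stats::sd(d$aupr))))
  rownames(summary) <- NULL
  out <- list(per_trial = per_trial, summary = summary,
              config = list(n = n, m = m, sigma = sigma, trials = trials,
                            alpha0 = alpha0, rho_a = rho_a,
                            entry_low = entry_low, entry_high = entry_high,
                            two_interval = two_interval, seed = seed))
  if (keep_curves) out$curves <- curves
  out
}

#' Empirical phase-transition experiment for sparse recovery
#'
#' Maps the success frequency of a stagewise solver over a grid of
#' undersampling ratios \eqn{\delta = m/n} and sparsity ratios
#' \eqn{\rho = k/m}.  For each cell, \code{trials} random noise-free
#' problems are generated (Gaussian measurement matrix with normalized
#' columns, k-sparse coefficient vector with signed magnitudes uniform on
#' [1, 2]) and a trial counts as a success when the relative L2
#' recovery error is below \code{success_tol}.
#'
#' @param n ambient dimension.
#' @param delta_grid undersampling ratios in (0, 1].
#' @param rho_grid sparsity ratios in (0, 1].
#' @param trials trials per grid cell.
#' @param solver \code{"smomp"} or \code{"stomp"}.
#' @param success_tol relative error defining success (default 1e-3;
#'   recovery is near-exact or grossly wrong, so the choice is not
#'   delicate).
#' @param opts \code{\link{solver_options}}.
#' @param seed optional seed.
#' @return matrix of success frequencies (rows = delta, cols = rho);
#'   cells where the rounded k falls outside [1, m) are NA.
#' @export
phase_experiment <- function(n = 200, delta_grid, rho_grid, trials = 50,
                             solver = c("smomp", "stomp"),
                             success_tol = 1e-3,
                             opts = solver_options(), seed = NULL) {
  solver <- match.arg(solver)
  if (any(delta_grid <= 0 | delta_grid > 1) ||
      any(rho_grid <= 0 | rho_grid > 1))
    stop("grids must lie in (0, 1]")
  if (trials < 1) stop("'trials' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  solve_fn <- if (solver == "smomp") smomp_solve else stomp_solve
  freq <- matrix(NA_real_, length(delta_grid), length(rho_grid),
                 dimnames = list(delta = sprintf("%.3f", delta_grid),
                                 rho = sprintf("%.3f", rho_grid)))
  for (di in seq_along(delta_grid)) {
    m <- round(delta_grid[di] * n)
    for (ri in seq_along(rho_grid)) {
      k <- round(rho_grid[ri] * m)
      if (k < 1 || k >= m) next  # infeasible cell, left NA
      cell_opts <- opts
      # FAC alpha0 from the known cell sparsity and the planning stage
      # count; SmOMP may then run up to k stages (its count is bounded by
      # the sparsity, not by the StOMP convention S)
      if (is.null(opts$alpha0) && is.null(opts$k_hint) && k < min(m, n))
        cell_opts$alpha0 <- (m - k) / (opts$max_stages * (n - k))
      if (solver == "smomp")
        cell_opts$max_stages <- max(opts$max_stages, k)
      succ <- 0L
      for (tr in seq_len(trials)) {
        Phi <- matrix(stats::rnorm(m * n), m, n)
        x0 <- rep(0, n)
        supp <- sample.int(n, k)
        x0[supp] <- sample(c(-1, 1), k, replace = TRUE) * stats::runif(k, 1, 2)
        y <- drop(Phi %*% x0)
        xh <- solve_fn(Phi, y, cell_opts)$coefficients
        if (sqrt(sum((xh - x0)^2)) / sqrt(sum(x0^2)) < success_tol)
          succ <- succ + 1L
      }
      freq[di, ri] <- succ / trials
    }
  }
  freq
}
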