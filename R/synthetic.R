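#' Generate an artificial linear network benchmark instance
#'
#' Builds the linear steady-state benchmark \eqn{A_0 X_0 = B_0}: a
#' measurement matrix \eqn{A_0} (m experiments by n genes) with entries
#' drawn uniformly from \code{[entry_low, entry_high]}, and a causal
#' adjacency matrix \eqn{X_0} whose column i holds the regulation strengths
#' onto gene i.  Each column of \eqn{X_0} is generated in three steps:
#' (i) its number of nonzeros k is drawn from the power-law degree prior,
#' (ii) the k locations are a uniform random subset of the n - 1 non-self
#' row indices (no self-regulation, so the diagonal is identically zero),
#' (iii) the nonzero values are uniform on
#' \eqn{[-2, -\rho_a] \cup [\rho_a, 2]}.  Finally Gaussian noise of
#' standard deviation \code{sigma} is added independently to both the
#' measurement matrix (\code{A = A0 + noise}) and the observations
#' (\code{B = A0 \%*\% X0 + noise}).
#'
#' The RNG is consumed in a fixed order -- degrees, locations, magnitudes,
#' measurement noise, observation noise -- so a given seed pins every
#' stage of the construction.
#'
#' @param n number of genes (>= 2).
#' @param m number of experiments (>= 1).
#' @param sigma noise level (>= 0) applied to both A and B.  By default
#'   this is a noise-to-signal ratio: the noise standard deviation is
#'   \code{sigma} times the empirical standard deviation of the A0
#'   entries (so \code{sigma = 0.1} on measurements with entry sd 2.6
#'   means absolute noise sd 0.26).  Set \code{relative_noise = FALSE}
#'   to use \code{sigma} as the absolute standard deviation.
#' @param prior degree prior; defaults to
#'   \code{power_law_prior(1, 2.5, n)}, the standard regulatory-network
#'   setting.
#' @param rho_a smallest admissible regulation magnitude (default 1e-5).
#' @param entry_low,entry_high range of the A0 entries (default [1, 10]).
#' @param two_interval if TRUE, A0 entries are drawn with random sign and
#'   magnitude uniform on \code{[entry_low, entry_high]}, i.e. from the
#'   two-interval set \eqn{[-h, -l] \cup [l, h]}.
#' @param relative_noise if TRUE (default) \code{sigma} scales the
#'   empirical standard deviation of the A0 entries; if FALSE it is the
#'   absolute noise standard deviation.
#' @param seed optional integer seed; identical seeds give bit-identical
#'   instances.
#' @return an object of class \code{"artificial_instance"} with fields
#'   \code{A0}, \code{X0}, \code{A}, \code{B}, \code{sigma}, \code{rho_a},
#'   \code{prior}, \code{seed}.
#' @examples
#' inst <- generate_artificial_instance(n = 10, m = 20, sigma = 0, seed = 1)
#' all(diag(inst$X0) == 0)
#' @export
generate_artificial_instance <- function(n, m, sigma,
                                         prior = power_law_prior(1, 2.5, n),
                                         rho_a = 1e-5,
                                         entry_low = 1, entry_high = 10,
                                         two_interval = FALSE,
                                         relative_noise = TRUE,
                                         seed = NULL) {
  if (length(n) != 1 || n < 2 || n != round(n))
    stop("'n' must be an integer >= 2")
  if (length(m) != 1 || m < 1 || m != round(m))
    stop("'m' must be an integer >= 1")
  if (sigma < 0) stop("'sigma' must be nonnegative")
  if (rho_a <= 0 || rho_a >= 2) stop("'rho_a' must lie in (0, 2)")
  stopifnot(inherits(prior, "power_law_prior"))
  if (prior$n_max > n) stop("degree prior support exceeds the gene count")
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n); m <- as.integer(m)

  # fixed RNG order: degrees, locations, magnitudes, noise on A, noise on B
  degrees <- sample_power_law_degree(prior, size = n)
  degrees <- pmin(degrees, n - 1L)  # at most n-1 non-self regulators
  X0 <- matrix(0, n, n)
  locations <- vector("list", n)
  for (i in seq_len(n)) {
    others <- seq_len(n)[-i]
    locations[[i]] <- others[sample.int(n - 1L, degrees[i])]
  }
  for (i in seq_len(n)) {
    k <- degrees[i]
    mag <- stats::runif(k, rho_a, 2)
    sgn <- ifelse(stats::runif(k) < 0.5, -1, 1)
    X0[locations[[i]], i] <- sgn * mag
  }

  if (two_interval) {
    magA <- stats::runif(m * n, entry_low, entry_high)
    sgnA <- ifelse(stats::runif(m * n) < 0.5, -1, 1)
    A0 <- matrix(sgnA * magA, m, n)
  } else {
    A0 <- matrix(stats::runif(m * n, entry_low, entry_high), m, n)
  }

  noise_sd <- if (relative_noise) sigma * stats::sd(as.vector(A0)) else sigma
  A <- A0 + matrix(stats::rnorm(m * n, 0, noise_sd), m, n)
  B <- A0 %*% X0 + matrix(stats::rnorm(m * n, 0, noise_sd), m, n)

  structure(
    list(A0 = A0, X0 = X0, A = A, B = B, sigma = sigma,
         noise_sd = noise_sd, rho_a = rho_a, prior = prior, seed = seed),
    class = "artificial_instance"
  )
}

#' @export
print.artificial_instance <- function(x, ...) {
  cat(sprintf(
    "Artificial linear network instance: %d genes, %d experiments, sigma = %g\n",
    ncol(x$A0), nrow(x$A0), x$sigma))
  cat(sprintf("  true edges: %d (mean in-degree %.2f), rho_a = %g\n",
              sum(x$X0 != 0), mean(colSums(x$X0 != 0)), x$rho_a))
  invisible(x)
}

#' Write an artificial instance to a directory of plain-text matrices
#'
#' Each matrix is written tab-separated, row-major, without headers, next
#' to a JSON sidecar (\code{meta.json}) recording the dimensions, noise
#' level, seed and degree-prior parameters.
#'
#' @param instance an \code{\link{generate_artificial_instance}} result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_instance <- function(instance, dir) {
  stopifnot(inherits(instance, "artificial_instance"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("A0", "X0", "A", "B")) {
    utils::write.table(instance[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  meta <- list(
    n = ncol(instance$A0), m = nrow(instance$A0),
    sigma = instance$sigma, noise_sd = instance$noise_sd,
    rho_a = instance$rho_a,
    seed = instance$seed,
    prior = list(k_min = instance$prior$k_min, gamma = instance$prior$gamma,
                 n_max = instance$prior$n_max)
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read an artificial instance written by \code{\link{write_instance}}
#'
#' @param dir directory containing the matrices and \code{meta.json}.
#' @return an \code{"artificial_instance"} object.
#' @export
read_instance <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  mats <- lapply(c("A0", "X0", "A", "B"), function(nm) {
    as.matrix(utils::read.table(file.path(dir, paste0(nm, ".tsv")),
                                sep = "\t", header = FALSE))
  })
  names(mats) <- c("A0", "X0", "A", "B")
  dimnames(mats$A0) <- dimnames(mats$X0) <- dimnames(mats$A) <- dimnames(mats$B) <- NULL
  structure(
    c(mats,
      list(sigma = meta$sigma, noise_sd = meta$noise_sd, rho_a = meta$rho_a,
           prior = power_law_prior(meta$prior$k_min, meta$prior$gamma,
                                   meta$prior$n_max),
           seed = meta$seed)),
    class = "artificial_instance"
  )
}
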