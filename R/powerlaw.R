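#' Power-law degree prior
#'
#' In-degree distribution used for the sparsity of each gene's incoming
#' regulation.  The probability mass over degrees \eqn{k \in \{1, \dots,
#' n_{max}\}} is flat at \eqn{\mu k_{min}^{-\gamma}} for \eqn{k \le k_{min}}
#' and decays as \eqn{\mu k^{-\gamma}} beyond, with \eqn{\mu} normalizing
#' the total mass to one.  With the default \code{k_min = 1} this is the
#' plain truncated power law commonly used for regulatory in-degrees.
#'
#' @param k_min minimum degree (positive integer, at most \code{n_max}).
#' @param gamma decay exponent (positive).
#' @param n_max maximum degree, usually the number of genes.
#' @return an object of class \code{"power_law_prior"} with the normalized
#'   probability mass function in \code{$pmf}.
#' @examples
#' pr <- power_law_prior(k_min = 1, gamma = 2.5, n_max = 100)
#' sum(pr$pmf)           # 1
#' power_law_mean(pr)    # close to 1.8 for these parameters
#' @export
power_law_prior <- function(k_min = 1, gamma = 2.5, n_max) {
  if (length(k_min) != 1 || k_min < 1 || k_min != round(k_min))
    stop("'k_min' must be a positive integer")
  if (length(gamma) != 1 || !is.finite(gamma) || gamma <= 0)
    stop("'gamma' must be a positive real")
  if (length(n_max) != 1 || n_max < k_min || n_max != round(n_max))
    stop("'n_max' must be an integer >= k_min")
  k <- seq_len(n_max)
  mass <- pmax(k, k_min)^(-gamma)
  mass[k < k_min] <- k_min^(-gamma)
  pmf <- mass / sum(mass)
  structure(
    list(k_min = as.integer(k_min), gamma = gamma, n_max = as.integer(n_max),
         pmf = pmf),
    class = "power_law_prior"
  )
}

#' @export
print.power_law_prior <- function(x, ...) {
  cat(sprintf("Power-law degree prior: k_min = %d, gamma = %g, support 1..%d\n",
              x$k_min, x$gamma, x$n_max))
  cat(sprintf("  mean degree %.4f, P{k = %d} = %.4f (modal)\n",
              power_law_mean(x), which.max(x$pmf), max(x$pmf)))
  invisible(x)
}

#' Analytic mean of a power-law degree prior
#'
#' @param prior a \code{\link{power_law_prior}}.
#' @return expected degree under the normalized mass function.
#' @export
power_law_mean <- function(prior) {
  stopifnot(inherits(prior, "power_law_prior"))
  sum(seq_len(prior$n_max) * prior$pmf)
}

#' Sample degrees from a power-law prior
#'
#' @param prior a \code{\link{power_law_prior}}.
#' @param size number of independent draws.
#' @return integer vector of degrees in \code{1..n_max}.
#' @export
sample_power_law_degree <- function(prior, size = 1) {
  stopifnot(inherits(prior, "power_law_prior"))
  if (prior$n_max == 1L) return(rep(1L, size))
  sample.int(prior$n_max, size = size, replace = TRUE, prob = prior$pmf)
}
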