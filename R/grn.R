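#' Steady-state perturbation dataset
#'
#' Container for one wild-type steady state plus the steady states reached
#' after m perturbations (e.g. single-gene knockouts).  Relative
#' expression changes computed from it drive the per-gene regression
#' problems.
#'
#' @param wildtype length-n vector of unperturbed steady-state levels;
#'   all entries must be strictly positive (relative changes divide by
#'   them).
#' @param perturbed m x n matrix of post-perturbation steady-state levels
#'   (row = experiment, column = gene).
#' @param gene_names optional n gene labels (default "G1".."Gn").
#' @param perturbation_labels optional m labels naming what each
#'   experiment perturbed; for knockout designs use the knocked-out
#'   gene's name so target rows can be excluded downstream.
#' @return an object of class \code{"perturbation_dataset"}.
#' @export
perturbation_dataset <- function(wildtype, perturbed, gene_names = NULL,
                                 perturbation_labels = NULL) {
  perturbed <- as.matrix(perturbed)
  n <- length(wildtype)
  if (ncol(perturbed) != n)
    stop("'perturbed' must have one column per wild-type gene")
  bad <- which(wildtype <= 0)
  if (length(bad) > 0) {
    nm <- if (!is.null(gene_names)) gene_names[bad[1]] else paste0("G", bad[1])
    stop(sprintf("wild-type level of gene %s is not strictly positive", nm))
  }
  if (is.null(gene_names)) gene_names <- paste0("G", seq_len(n))
  if (length(gene_names) != n) stop("'gene_names' must have length n")
  if (!is.null(perturbation_labels) &&
      length(perturbation_labels) != nrow(perturbed))
    stop("'perturbation_labels' must have one entry per perturbation row")
  structure(
    list(wildtype = as.numeric(wildtype), perturbed = perturbed,
         gene_names = gene_names, perturbation_labels = perturbation_labels),
    class = "perturbation_dataset"
  )
}

#' @export
print.perturbation_dataset <- function(x, ...) {
  cat(sprintf("Steady-state perturbation dataset: %d genes, %d perturbations\n",
              length(x$wildtype), nrow(x$perturbed)))
  invisible(x)
}

#' Relative steady-state changes
#'
#' For every experiment and gene, the fractional change of the perturbed
#' steady state against wild type:
#' \eqn{\phi_{\ell j} = (x_j^{pert,\ell} - x_j^{wt}) / x_j^{wt}}.
#' A knocked-out gene (perturbed level 0) yields \eqn{\phi = -1}.
#'
#' @param dataset a \code{\link{perturbation_dataset}}.
#' @return m x n matrix of relative changes.
#' @export
relative_changes <- function(dataset) {
  stopifnot(inherits(dataset, "perturbation_dataset"))
  sweep(sweep(dataset$perturbed, 2, dataset$wildtype, "-"),
        2, dataset$wildtype, "/")
}

#' Build the sparse regression problem for one target gene
#'
#' The incoming regulation of gene i satisfies \eqn{\Phi \alpha_i = b}
#' where \eqn{\Phi} collects the relative changes of the other n - 1
#' genes across the m experiments and b the relative changes of gene i.
#' With \code{normalize = TRUE} each column of \eqn{\Phi} is divided by
#' its Euclidean norm (scales recorded) to improve the conditioning of
#' the sparse recovery.
#'
#' @param phi m x n matrix of relative changes.
#' @param target index i of the target gene.
#' @param normalize divide each column by its L2 norm (default TRUE).
#' @param gene_names optional gene labels for error messages.
#' @return an object of class \code{"regression_problem"} with fields
#'   \code{target_index}, \code{Phi}, \code{b}, \code{column_scales},
#'   \code{column_gene_map}.
#' @export
build_gene_problem <- function(phi, target, normalize = TRUE,
                               gene_names = NULL) {
  phi <- as.matrix(phi)
  n <- ncol(phi)
  if (n < 2) stop("need at least two genes")
  if (target < 1 || target > n) stop("'target' out of range")
  keep <- seq_len(n)[-target]
  Phi <- phi[, keep, drop = FALSE]
  b <- phi[, target]
  scales <- rep(1, n - 1L)
  if (normalize) {
    scales <- sqrt(colSums(Phi^2))
    if (any(scales == 0)) {
      j <- keep[which(scales == 0)[1]]
      nm <- if (!is.null(gene_names)) gene_names[j] else paste0("G", j)
      stop(sprintf(
        "gene %s never responds in any experiment (zero column); cannot normalize",
        nm))
    }
    Phi <- sweep(Phi, 2, scales, "/")
  }
  structure(
    list(target_index = as.integer(target), Phi = Phi, b = b,
         column_scales = scales, column_gene_map = keep),
    class = "regression_problem"
  )
}

#' Infer a gene regulatory network from steady-state perturbation data
#'
#' For every gene i a sparse regression problem is built from the
#' relative-change matrix (all other genes' changes explaining gene i's
#' change) and solved with the chosen solver.  The estimated coefficient
#' vector is written into row i of the adjacency: entry (i, j) is the
#' estimated direct effect of gene j on gene i, positive for activation
#' and negative for inhibition.  The diagonal is structurally zero.
#' Edge-ranking scores are the absolute coefficients on the original
#' (unnormalized) column scale.
#'
#' For knockout designs, the row in which the target gene itself was
#' knocked out is an intervention on that gene rather than a response and
#' is excluded from its own regression (controlled by
#' \code{exclude_target_knockout}; requires perturbation labels matching
#' gene names).
#'
#' @param x a \code{\link{perturbation_dataset}} or an m x n matrix of
#'   relative changes.
#' @param solver one of \code{"smomp"}, \code{"stomp"}, \code{"tls"}.
#' @param opts \code{\link{solver_options}} for the stagewise solvers.
#' @param exclude_target_knockout drop the target gene's own knockout row
#'   from its regression (default TRUE; only applies when perturbation
#'   labels are available).
#' @param keep_traces retain per-gene solver traces (default FALSE).
#' @return an object of class \code{"network_estimate"}: signed
#'   \code{adjacency} (n x n, zero diagonal), nonnegative
#'   \code{ranking_scores}, \code{solver_name}, \code{gene_names} and
#'   optionally \code{per_gene_traces}.
#' @export
infer_network <- function(x, solver = c("smomp", "stomp", "tls"),
                          opts = solver_options(),
                          exclude_target_knockout = TRUE,
                          keep_traces = FALSE) {
  solver <- match.arg(solver)
  if (inherits(x, "perturbation_dataset")) {
    phi <- relative_changes(x)
    gene_names <- x$gene_names
    labels <- x$perturbation_labels
  } else {
    phi <- as.matrix(x)
    gene_names <- colnames(phi)
    if (is.null(gene_names)) gene_names <- paste0("G", seq_len(ncol(phi)))
    labels <- NULL
  }
  n <- ncol(phi)
  adjacency <- matrix(0, n, n, dimnames = list(gene_names, gene_names))
  traces <- if (keep_traces) vector("list", n) else NULL

  for (i in seq_len(n)) {
    rows <- seq_len(nrow(phi))
    if (exclude_target_knockout && !is.null(labels))
      rows <- rows[labels != gene_names[i]]
    phi_i <- phi[rows, , drop = FALSE]
    if (sum(phi_i[, i]^2) == 0) next  # gene i never responds: zero row
    coef <- tryCatch({
      if (solver == "tls") {
        # classical TLS assumes equal noise across [Phi b]; run it on the
        # raw columns rather than the normalized ones
        prob <- build_gene_problem(phi_i, i, normalize = FALSE,
                                   gene_names = gene_names)
        tls_solve(prob$Phi, prob$b)
      } else {
        prob <- build_gene_problem(phi_i, i, normalize = FALSE,
                                   gene_names = gene_names)
        sol <- if (solver == "smomp") smomp_solve(prob$Phi, prob$b, opts)
               else stomp_solve(prob$Phi, prob$b, opts)
        if (keep_traces) traces[[i]] <- sol$trace
        sol$coefficients
      }
    }, error = function(e) {
      stop(sprintf("gene %s: %s", gene_names[i], conditionMessage(e)),
           call. = FALSE)
    })
    adjacency[i, prob$column_gene_map] <- coef
  }

  structure(
    list(adjacency = adjacency, ranking_scores = abs(adjacency),
         solver_name = solver, gene_names = gene_names,
         per_gene_traces = traces),
    class = "network_estimate"
  )
}

#' @export
print.network_estimate <- function(x, ...) {
  n <- nrow(x$adjacency)
  cat(sprintf("Network estimate (%s): %d genes, %d predicted edges\n",
              x$solver_name, n, sum(x$adjacency != 0)))
  invisible(x)
}
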