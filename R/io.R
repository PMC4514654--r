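#' Read DREAM-style steady-state expression files
#'
#' The wild-type file holds a tab-separated header of gene names followed
#' by one row of unperturbed steady-state levels.  The knockout file
#' holds the same header followed by n rows of steady-state levels, row
#' l being the steady state reached after deleting gene l.
#'
#' @param wildtype_path path to the wild-type file.
#' @param knockout_path path to the knockout file.
#' @return a \code{\link{perturbation_dataset}} whose perturbation labels
#'   name the knocked-out gene of each row.
#' @export
read_dream_steady_state <- function(wildtype_path, knockout_path) {
  wt <- .read_dream_table(wildtype_path)
  ko <- .read_dream_table(knockout_path)
  if (!identical(wt$genes, ko$genes))
    stop("wild-type and knockout files list different genes")
  if (nrow(wt$values) != 1)
    stop(sprintf("wild-type file must contain exactly one data row, found %d",
                 nrow(wt$values)))
  perturbation_dataset(
    wildtype = drop(wt$values),
    perturbed = ko$values,
    gene_names = wt$genes,
    perturbation_labels = if (nrow(ko$values) == length(wt$genes))
      wt$genes else NULL
  )
}

.read_dream_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2)
    stop(sprintf("%s: expected a header row plus data rows", path))
  genes <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (any(grepl("^[-0-9.eE+]+$", genes)))
    stop(sprintf("%s: line 1 looks numeric; a gene-name header is required",
                 path))
  n <- length(genes)
  values <- matrix(NA_real_, length(lines) - 1L, n)
  for (r in seq_len(length(lines) - 1L)) {
    cells <- strsplit(lines[r + 1L], "\t", fixed = TRUE)[[1]]
    if (length(cells) != n)
      stop(sprintf("%s: line %d has %d columns, expected %d",
                   path, r + 1L, length(cells), n))
    vals <- suppressWarnings(as.numeric(cells))
    if (anyNA(vals)) {
      col <- which(is.na(vals))[1]
      stop(sprintf("%s: non-numeric value '%s' at line %d, column %d",
                   path, cells[col], r + 1L, col))
    }
    values[r, ] <- vals
  }
  list(genes = genes, values = values)
}

#' Write a ranked edge-prediction list
#'
#' Emits tab-separated lines \code{"G<regulator>\tG<target>\t<score>"} in
#' descending score order, with deterministic ties broken by (regulator,
#' target) index.  Edges with zero score are omitted unless needed to
#' fill \code{max_edges}.
#'
#' @param net a \code{\link{infer_network}} result.
#' @param path output file path.
#' @param max_edges optional cap on the number of lines.
#' @return \code{path}, invisibly.
#' @export
write_edge_predictions <- function(net, path, max_edges = NULL) {
  stopifnot(inherits(net, "network_estimate"))
  n <- nrow(net$ranking_scores)
  tgt <- rep(seq_len(n), times = n)     # row index: target
  reg <- rep(seq_len(n), each = n)      # col index: regulator
  keep <- tgt != reg
  tgt <- tgt[keep]; reg <- reg[keep]
  score <- net$ranking_scores[cbind(tgt, reg)]
  ord <- order(-score, reg, tgt)
  tgt <- tgt[ord]; reg <- reg[ord]; score <- score[ord]
  if (is.null(max_edges)) {
    nz <- score > 0
    tgt <- tgt[nz]; reg <- reg[nz]; score <- score[nz]
  } else {
    take <- seq_len(min(max_edges, length(score)))
    tgt <- tgt[take]; reg <- reg[take]; score <- score[take]
  }
  lines <- sprintf("%s\t%s\t%.10g",
                   net$gene_names[reg], net$gene_names[tgt], score)
  writeLines(lines, path)
  invisible(path)
}

#' Read a DREAM gold-standard edge list
#'
#' Lines are \code{"G<i>\tG<j>\t{0,1}"}, regulator then target.  Pairs
#' absent from the file are treated as non-edges.
#'
#' @param path path to the edge list.
#' @param gene_names gene labels defining the adjacency indexing.
#' @return n x n binary matrix; entry (i, j) = 1 when gene j regulates
#'   gene i (matching the \code{\link{infer_network}} orientation).
#' @export
read_gold_standard <- function(path, gene_names) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop(sprintf("%s: empty gold standard", path))
  n <- length(gene_names)
  gold <- matrix(0, n, n, dimnames = list(gene_names, gene_names))
  for (r in seq_along(lines)) {
    cells <- strsplit(lines[r], "\t", fixed = TRUE)[[1]]
    if (length(cells) != 3)
      stop(sprintf("%s: line %d has %d fields, expected 3",
                   path, r, length(cells)))
    reg <- match(cells[1], gene_names)
    tgt <- match(cells[2], gene_names)
    if (is.na(reg) || is.na(tgt))
      stop(sprintf("%s: line %d names an unknown gene", path, r))
    lab <- suppressWarnings(as.numeric(cells[3]))
    if (is.na(lab) || !(lab %in% c(0, 1)))
      stop(sprintf("%s: line %d label must be 0 or 1", path, r))
    gold[tgt, reg] <- lab
  }
  gold
}
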