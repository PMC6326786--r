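#' Construct an expression compendium
#'
#' Bundles a log-scale expression matrix (genes x samples) with per-sample
#' experiment metadata. Each sample belongs to an experiment; within an
#' experiment one sample is designated the unperturbed reference against
#' which the remaining case samples are contrasted.
#'
#' @param values numeric matrix of log-scale expression, rownames = gene
#'   ids, colnames = sample ids.
#' @param sample_meta data.frame with columns `sample_id`, `experiment_id`,
#'   `is_reference` (logical or 0/1), `is_perturbed` (logical or 0/1), one
#'   row per column of `values`.
#' @return An object of class `expression_compendium`.
#' @export
expression_compendium <- function(values, sample_meta) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  need <- c("sample_id", "experiment_id", "is_reference", "is_perturbed")
  if (!all(need %in% names(sample_meta)))
    stop("sample_meta must have columns ", paste(need, collapse = ", "))
  sample_meta$sample_id <- as.character(sample_meta$sample_id)
  sample_meta$experiment_id <- as.character(sample_meta$experiment_id)
  sample_meta$is_reference <- as.logical(as.integer(sample_meta$is_reference))
  sample_meta$is_perturbed <- as.logical(as.integer(sample_meta$is_perturbed))
  if (!setequal(sample_meta$sample_id, colnames(values)) ||
      nrow(sample_meta) != ncol(values))
    stop("sample_meta rows must match matrix columns one-to-one")
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), ,
                             drop = FALSE]
  rownames(sample_meta) <- NULL
  structure(list(values = values, sample_meta = sample_meta),
            class = "expression_compendium")
}

#' @export
print.expression_compendium <- function(x, ...) {
  cat(sprintf("Expression compendium: %d genes x %d samples, %d experiments\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$sample_meta$experiment_id))))
  invisible(x)
}

#' Read an expression compendium from TSV files
#'
#' The expression matrix has gene ids in the first column and one header
#' column per sample; the metadata file has columns `sample_id`,
#' `experiment_id`, `is_reference` (0/1), `is_perturbed` (0/1).
#'
#' @param expression_table path to the expression TSV.
#' @param sample_meta_table path to the sample metadata TSV.
#' @return An `expression_compendium`.
#' @export
read_compendium <- function(expression_table, sample_meta_table) {
  tab <- utils::read.delim(expression_table, check.names = FALSE,
                           comment.char = "#")
  values <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(values)) stop("non-numeric expression values")
  rownames(values) <- as.character(tab[[1]])
  meta <- utils::read.delim(sample_meta_table, comment.char = "#")
  expression_compendium(values, meta)
}

#' Write an expression compendium to TSV files
#' @param comp an `expression_compendium`.
#' @param expression_table,sample_meta_table output paths.
#' @return `expression_table`, invisibly.
#' @export
write_compendium <- function(comp, expression_table, sample_meta_table) {
  df <- data.frame(gene = rownames(comp$values), comp$values,
                   check.names = FALSE)
  write_tsv(df, expression_table)
  meta <- comp$sample_meta
  meta$is_reference <- as.integer(meta$is_reference)
  meta$is_perturbed <- as.integer(meta$is_perturbed)
  write_tsv(meta, sample_meta_table)
  invisible(expression_table)
}

#' Quantile-normalize an expression matrix
#'
#' Forces every column (sample) onto a common distribution: each value is
#' replaced by the mean, across columns, of the values at its rank, so
#' after the call all columns share an identical multiset of values. Ties
#' are resolved by average-rank assignment. This is the standard
#' between-array normalization applied to microarray compendia before
#' log-ratio analysis; delegated to \code{\link[limma]{normalizeQuantiles}}.
#'
#' @param values numeric matrix with at least one column.
#' @return Matrix of the same dimensions and dimnames.
#' @export
quantile_normalize <- function(values) {
  stopifnot(is.matrix(values))
  if (!is.numeric(values)) stop("non-numeric entries in expression matrix")
  if (ncol(values) < 1) stop("matrix must have at least one column")
  out <- limma::normalizeQuantiles(values, ties = TRUE)
  dimnames(out) <- dimnames(values)
  out
}

#' Aggregate gene-level expression to network vertices
#'
#' Genes in a transcription unit are transcribed together and expected to
#' co-vary, so a TU vertex is summarized as the per-sample arithmetic
#' \emph{mean} of its member genes. A TF complex requires all member
#' proteins, so its availability is limited by the scarcest member: a
#' complex vertex takes the per-sample \emph{minimum} of its member genes.
#' Single-gene vertices take their gene row unchanged.
#'
#' @param comp an `expression_compendium` (or a plain gene x sample matrix).
#' @param net a `signed_grn` whose member genes are all present in `comp`
#'   (apply \code{\link{filter_by_expression}} first).
#' @return Numeric matrix, rows = vertex ids (regulators then targets),
#'   columns = sample ids.
#' @export
vertex_expression <- function(comp, net) {
  values <- if (inherits(comp, "expression_compendium")) comp$values else comp
  agg_one <- function(id, genes, fun) {
    miss <- setdiff(genes, rownames(values))
    if (length(miss))
      stop(sprintf("vertex '%s' has unmeasured member gene(s): %s",
                   id, paste(miss, collapse = ", ")))
    rows <- values[genes, , drop = FALSE]
    if (length(genes) == 1L) rows[1L, ] else apply(rows, 2L, fun)
  }
  reg <- t(vapply(names(net$regulators), function(id)
    agg_one(id, net$regulators[[id]], min), numeric(ncol(values))))
  tgt <- t(vapply(names(net$targets), function(id)
    agg_one(id, net$targets[[id]], mean), numeric(ncol(values))))
  out <- rbind(reg, tgt)
  colnames(out) <- colnames(values)
  out
}

#' Compute per-experiment contrasts against reference samples
#'
#' For each experiment, every non-reference (case) sample is contrasted
#' against the experiment's designated unperturbed reference: the contrast
#' value is case minus reference log-expression, i.e. the log-ratio, with
#' positive values meaning higher expression in the case. Each contrast
#' inherits the case sample's perturbation flag. Experiments with no
#' designated reference are excluded with a warning (compendium metadata
#' is often incomplete); experiments with several references are an error.
#'
#' @param vertex_expr numeric matrix, rows = vertex (or gene) ids,
#'   columns = sample ids.
#' @param sample_meta data.frame as in \code{\link{expression_compendium}}.
#' @return An object of class `contrast_set`: list with `values` (matrix,
#'   rows = vertex ids, one column per contrast) and `contrast_meta`
#'   (columns `contrast_id`, `experiment_id`, `case_sample`,
#'   `reference_sample`, `is_perturbed`).
#' @export
compute_contrasts <- function(vertex_expr, sample_meta) {
  stopifnot(is.matrix(vertex_expr))
  sample_meta$is_reference <- as.logical(as.integer(sample_meta$is_reference))
  sample_meta$is_perturbed <- as.logical(as.integer(sample_meta$is_perturbed))
  if (!all(sample_meta$sample_id %in% colnames(vertex_expr)))
    stop("sample_meta lists samples absent from the expression matrix")

  n_ref <- tapply(sample_meta$is_reference, sample_meta$experiment_id, sum)
  multi <- names(n_ref)[n_ref > 1]
  if (length(multi))
    stop("experiment(s) with multiple reference samples: ",
         paste(multi, collapse = ", "))
  none <- names(n_ref)[n_ref == 0]
  if (length(none))
    warning("excluding experiment(s) with no reference sample: ",
            paste(none, collapse = ", "))
  sample_meta <- sample_meta[!(sample_meta$experiment_id %in% none), ,
                             drop = FALSE]

  ref <- sample_meta[sample_meta$is_reference, , drop = FALSE]
  cases <- sample_meta[!sample_meta$is_reference, , drop = FALSE]
  if (!nrow(cases))
    stop("no case samples available for contrasts")
  ref_of <- stats::setNames(ref$sample_id, ref$experiment_id)
  cases <- cases[order(match(cases$experiment_id, names(ref_of)),
                       cases$sample_id), , drop = FALSE]

  vals <- vertex_expr[, cases$sample_id, drop = FALSE] -
    vertex_expr[, ref_of[cases$experiment_id], drop = FALSE]
  meta <- data.frame(
    contrast_id = paste(cases$experiment_id, cases$sample_id, sep = "."),
    experiment_id = cases$experiment_id,
    case_sample = cases$sample_id,
    reference_sample = unname(ref_of[cases$experiment_id]),
    is_perturbed = cases$is_perturbed,
    stringsAsFactors = FALSE)
  colnames(vals) <- meta$contrast_id
  structure(list(values = vals, contrast_meta = meta), class = "contrast_set")
}

#' @export
print.contrast_set <- function(x, ...) {
  cat(sprintf("Contrast set: %d vertices x %d contrasts (%d perturbed)\n",
              nrow(x$values), ncol(x$values),
              sum(x$contrast_meta$is_perturbed)))
  invisible(x)
}
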