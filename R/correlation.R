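# Correlation of regulator and target expression profiles across samples.
# Under direct transcriptional control one expects activator-target pairs
# to correlate positively and repressor-target pairs negatively; comparing
# the known-interaction distribution with the all-pairs background shows
# how much of that signal is actually present in a compendium.

cor_pairs <- function(vertex_expr, regs, tgts, method) {
  # row-wise correlations for matched (regulator, target) id vectors;
  # zero-variance profiles yield NA (flagged by the caller)
  x <- vertex_expr[regs, , drop = FALSE]
  y <- vertex_expr[tgts, , drop = FALSE]
  suppressWarnings(
    vapply(seq_along(regs), function(k)
      stats::cor(x[k, ], y[k, ], method = method), numeric(1)))
}

stratum_summary <- function(records, name, keep) {
  r <- records$r[keep]
  data.frame(stratum = name, n = sum(keep),
             n_missing = sum(is.na(r)),
             mean_r = if (any(!is.na(r))) mean(r, na.rm = TRUE) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Correlate known regulator-target interactions
#'
#' Computes one correlation coefficient per interaction between the
#' regulator's and the target's expression profiles across all samples
#' (aggregated vertex profiles: TU mean, complex minimum). Summaries are
#' reported for all interactions, activations, repressions, and the
#' single-regulator subsets of each. Zero-variance profiles produce a
#' missing coefficient, excluded from stratum means with a warning.
#'
#' @param net a `signed_grn`.
#' @param vertex_expr vertex x sample matrix from
#'   \code{\link{vertex_expression}} (at least 3 samples).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return An object of class `correlation_report`: list with `records`
#'   (regulator, target, sign, single_regulator, r), `strata`
#'   (stratum, n, n_missing, mean_r) and `method`.
#' @export
interaction_correlations <- function(net, vertex_expr,
                                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.matrix(vertex_expr))
  if (ncol(vertex_expr) < 3)
    stop("need at least 3 samples to correlate profiles")
  inter <- net$interactions
  miss <- setdiff(unique(c(inter$regulator, inter$target)),
                  rownames(vertex_expr))
  if (length(miss))
    stop("expression matrix lacks rows for vertices: ",
         paste(utils::head(miss, 5), collapse = ", "))

  r <- cor_pairs(vertex_expr, inter$regulator, inter$target, method)
  if (anyNA(r))
    warning(sum(is.na(r)),
            " interaction(s) with a zero-variance profile; ",
            "correlation recorded as missing")
  single <- single_regulator_targets(net)
  records <- data.frame(
    regulator = inter$regulator, target = inter$target, sign = inter$sign,
    single_regulator = inter$target %in% single, r = r,
    stringsAsFactors = FALSE)

  act <- records$sign == "activation"
  strata <- rbind(
    stratum_summary(records, "all_known", rep(TRUE, nrow(records))),
    stratum_summary(records, "activation", act),
    stratum_summary(records, "repression", !act),
    stratum_summary(records, "single_regulator_activation",
                    act & records$single_regulator),
    stratum_summary(records, "single_regulator_repression",
                    !act & records$single_regulator))
  structure(list(records = records, strata = strata, method = method),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat(sprintf("Interaction correlations (%s), %d interactions\n",
              x$method, nrow(x$records)))
  print(x$strata, row.names = FALSE)
  invisible(x)
}

#' Background correlation over all regulator-target pairs
#'
#' Computes correlations over the full regulator x target cross product
#' (which includes the known pairs) or, when `max_pairs` is smaller than
#' the cross product, over a uniform random sample of pairs. The
#' background anchors the known-interaction distribution: a mean near
#' zero indicates no network-wide co-expression structure.
#'
#' @inheritParams interaction_correlations
#' @param max_pairs maximum number of pairs to evaluate (default `Inf`,
#'   i.e. exhaustive).
#' @param seed optional integer seed for pair sampling.
#' @param exclude_known drop known interacting pairs from the background
#'   (default FALSE: the background is all possible pairs).
#' @return list with `n_pairs`, `mean_r`, `sd_r`, `quantiles`
#'   (5%/25%/50%/75%/95%) and `method`.
#' @export
background_correlations <- function(net, vertex_expr,
                                    method = c("pearson", "spearman"),
                                    max_pairs = Inf, seed = NULL,
                                    exclude_known = FALSE) {
  method <- match.arg(method)
  regs <- names(net$regulators)
  tgts <- names(net$targets)
  n_total <- length(regs) * length(tgts)
  if (n_total == 0) stop("network has no regulator-target pairs")

  idx <- if (is.finite(max_pairs) && max_pairs < n_total) {
    with_seed(seed, sample.int(n_total, max_pairs))
  } else {
    seq_len(n_total)
  }
  # pair k maps to (regulator row, target column) of the cross product
  ri <- ((idx - 1L) %% length(regs)) + 1L
  ti <- ((idx - 1L) %/% length(regs)) + 1L
  pr <- regs[ri]; pt <- tgts[ti]
  if (exclude_known) {
    known <- paste(net$interactions$regulator, net$interactions$target,
                   sep = "\r")
    keep <- !(paste(pr, pt, sep = "\r") %in% known)
    pr <- pr[keep]; pt <- pt[keep]
  }
  r <- cor_pairs(vertex_expr, pr, pt, method)
  r <- r[!is.na(r)]
  list(n_pairs = length(r), mean_r = mean(r), sd_r = stats::sd(r),
       quantiles = stats::quantile(r, c(0.05, 0.25, 0.5, 0.75, 0.95)),
       method = method)
}
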