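#' Sign-consistency model configuration
#'
#' The ternary model labels each vertex, per contrast, as upregulated (+),
#' downregulated (-) or unchanged (0) using a log-ratio magnitude
#' threshold `t`; the binary variant drops the unchanged state and labels
#' strictly positive contrasts + and all others -, ignoring `t`.
#'
#' @param threshold non-negative log-ratio magnitude `t`.
#' @param variant `"ternary"` (default) or `"binary"`.
#' @return An object of class `sign_model_config`.
#' @export
sign_model_config <- function(threshold = 0,
                              variant = c("ternary", "binary")) {
  variant <- match.arg(variant)
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            is.finite(threshold), threshold >= 0)
  structure(list(threshold = threshold, variant = variant),
            class = "sign_model_config")
}

normalize_labels <- function(labels) {
  if (is.character(labels)) {
    out <- ifelse(labels == "+", 1L, ifelse(labels == "-", -1L,
                  ifelse(labels == "0", 0L, NA_integer_)))
  } else {
    out <- as.integer(labels)
    out[!(out %in% c(-1L, 0L, 1L))] <- NA_integer_
  }
  if (anyNA(out)) stop("labels must be in {+, -, 0} (or -1, 0, 1)")
  out
}

normalize_sign <- function(sign) {
  out <- ifelse(sign %in% c("activation", "+", "up"), "activation",
                ifelse(sign %in% c("repression", "-", "down"),
                       "repression", NA_character_))
  if (anyNA(out))
    stop("interaction sign must be 'activation' or 'repression'")
  out
}

#' Label vertices as up-, down- or unregulated per contrast
#'
#' Ternary variant: a vertex is downregulated (-1) in a contrast when its
#' log-ratio is strictly below `-t`, upregulated (+1) when strictly above
#' `t`, and unchanged (0) otherwise (so a value exactly at the threshold
#' is unchanged). Binary variant: +1 when strictly positive, -1 otherwise.
#'
#' @param contrasts a `contrast_set` (or plain vertex x contrast matrix).
#' @param config a \code{\link{sign_model_config}}.
#' @return Integer matrix over \{-1, 0, 1\} with the same dimnames as the
#'   contrast matrix.
#' @export
label_vertices <- function(contrasts, config = sign_model_config()) {
  vals <- if (inherits(contrasts, "contrast_set")) contrasts$values
          else contrasts
  stopifnot(is.matrix(vals), is.numeric(vals))
  if (config$variant == "binary") {
    lab <- ifelse(vals > 0, 1L, -1L)
  } else {
    t <- config$threshold
    lab <- matrix(0L, nrow(vals), ncol(vals))
    lab[vals > t] <- 1L
    lab[vals < -t] <- -1L
  }
  dimnames(lab) <- dimnames(vals)
  lab
}

#' Choose the labeling threshold from the contrast distribution
#'
#' Returns the threshold `t` such that approximately
#' `target_changed_fraction` of all pooled contrast values (across every
#' vertex and contrast) have magnitude strictly above `t`, i.e. the
#' `(1 - target_changed_fraction)` quantile of the pooled absolute
#' log-ratios. With the default 0.5, about half of all contrast values are
#' labeled up- or downregulated. One global threshold is computed from the
#' pooled values (a single `t` for the whole compendium).
#'
#' @param contrasts a `contrast_set` or numeric matrix.
#' @param target_changed_fraction desired fraction of changed (+/-) labels
#'   in (0, 1]. A fraction of 1 returns `t = 0`.
#' @return The threshold, a single non-negative number.
#' @export
select_threshold <- function(contrasts, target_changed_fraction = 0.5) {
  vals <- if (inherits(contrasts, "contrast_set")) contrasts$values
          else contrasts
  stopifnot(is.numeric(vals), length(vals) > 0,
            target_changed_fraction > 0, target_changed_fraction <= 1)
  a <- abs(as.vector(vals))
  a <- a[is.finite(a)]
  if (!length(a) || all(a == 0))
    stop("threshold undefined: all contrast values are zero")
  if (target_changed_fraction >= 1) return(0)
  stats::quantile(a, 1 - target_changed_fraction, names = FALSE)
}

#' Edge consistency rule of the ternary sign model
#'
#' Decides, for one (regulation sign, TF label, target label) combination
#' per element, whether the interaction is inconsistent (1) or consistent
#' (0). An activation is inconsistent when the TF is up but the target is
#' not up, or the TF is down but the target is up. A repression is
#' inconsistent when the TF is up but the target is not down, or both TF
#' and target are down. An unchanged TF (label 0) is always consistent:
#' with no change in regulator expression the model makes no prediction
#' about the target.
#'
#' @param sign `"activation"`/`"repression"` (or `"+"`/`"-"`), recycled.
#' @param tf_label,target_label labels in \{+, -, 0\} as characters or
#'   \{-1, 0, 1\} integers.
#' @return Integer vector of 0/1 inconsistency indicators.
#' @export
edge_inconsistency <- function(sign, tf_label, target_label) {
  sgn <- normalize_sign(sign)
  tf <- normalize_labels(tf_label)
  tg <- normalize_labels(target_label)
  act <- sgn == "activation"
  incon <- ifelse(act,
                  (tf == 1L & tg != 1L) | (tf == -1L & tg == 1L),
                  (tf == 1L & tg != -1L) | (tf == -1L & tg == -1L))
  as.integer(incon)
}

#' Edge consistency rule of the binary variant
#'
#' With only up/down labels the rule collapses to sign agreement: an
#' activation is inconsistent when TF and target labels differ, a
#' repression when they agree. Unchanged (0) labels are a variant
#' mismatch and raise an error.
#'
#' @inheritParams edge_inconsistency
#' @return Integer vector of 0/1 inconsistency indicators.
#' @export
edge_inconsistency_binary <- function(sign, tf_label, target_label) {
  sgn <- normalize_sign(sign)
  tf <- normalize_labels(tf_label)
  tg <- normalize_labels(target_label)
  if (any(tf == 0L) || any(tg == 0L))
    stop("binary variant received an unchanged (0) label")
  act <- sgn == "activation"
  as.integer(ifelse(act, tf != tg, tf == tg))
}

#' Evaluate network-wide sign consistency
#'
#' Computes the inconsistency vector I(e) of every edge (one 0/1 entry per
#' contrast, from the edge rule) and the inconsistency vector J(v) of
#' every target as the product of I(e) over its incoming edges: a target
#' is inconsistent in a contrast only when \emph{every} incoming
#' regulation is inconsistent there, i.e. one consistent regulator
#' suffices to explain the target (a conservative lower bound when
#' regulators of mixed type compete). The global inconsistency load is the
#' total number of (target, contrast) inconsistencies.
#'
#' Targets without incoming edges (possible in hand-built networks) are
#' excluded from the vertex summaries; the empty product would count them
#' as always inconsistent, contradicting the model's intent.
#'
#' @param net a `signed_grn`.
#' @param labels integer label matrix from \code{\link{label_vertices}};
#'   must contain a row for every network vertex.
#' @param config the \code{\link{sign_model_config}} used for labeling
#'   (determines the edge rule variant).
#' @return An object of class `inconsistency_result`: list with
#'   `edge_table` (regulator, target, sign, `n_inconsistent` = |I(e)|_1),
#'   `I` (edges x contrasts 0/1 matrix), `J` (targets x contrasts 0/1
#'   matrix), `vertex_table` (target, in_degree, `n_inconsistent` =
#'   |J(v)|_1), `global_load`, `per_contrast_load`,
#'   `per_contrast_changed` (number of +/- labeled vertices per contrast)
#'   and `n_contrasts`.
#' @export
evaluate_consistency <- function(net, labels, config = sign_model_config()) {
  inter <- net$interactions
  if (!nrow(inter)) stop("network has no interactions")
  vertices <- c(names(net$regulators), names(net$targets))
  miss <- setdiff(vertices, rownames(labels))
  if (length(miss))
    stop("label matrix lacks rows for vertices: ",
         paste(utils::head(miss, 5), collapse = ", "))

  tfL <- labels[inter$regulator, , drop = FALSE]
  tgL <- labels[inter$target, , drop = FALSE]
  if (config$variant == "binary" && any(tfL == 0L | tgL == 0L))
    stop("binary variant received an unchanged (0) label")

  act <- inter$sign == "activation"
  I <- matrix(0L, nrow(inter), ncol(labels))
  if (config$variant == "binary") {
    I[act, ] <- (tfL[act, , drop = FALSE] != tgL[act, , drop = FALSE]) * 1L
    I[!act, ] <- (tfL[!act, , drop = FALSE] == tgL[!act, , drop = FALSE]) * 1L
  } else {
    I[act, ] <- ((tfL[act, , drop = FALSE] == 1L &
                    tgL[act, , drop = FALSE] != 1L) |
                 (tfL[act, , drop = FALSE] == -1L &
                    tgL[act, , drop = FALSE] == 1L)) * 1L
    I[!act, ] <- ((tfL[!act, , drop = FALSE] == 1L &
                     tgL[!act, , drop = FALSE] != -1L) |
                  (tfL[!act, , drop = FALSE] == -1L &
                     tgL[!act, , drop = FALSE] == -1L)) * 1L
  }
  colnames(I) <- colnames(labels)

  # J_i(v) = prod over incoming edges of I_i(e): inconsistent iff no
  # incoming edge is consistent in contrast i
  cons_count <- rowsum((1L - I), group = inter$target, reorder = TRUE)
  J <- (cons_count == 0) * 1L

  edge_table <- data.frame(
    regulator = inter$regulator, target = inter$target, sign = inter$sign,
    n_inconsistent = as.integer(rowSums(I)), stringsAsFactors = FALSE)
  in_degree <- table(inter$target)
  vertex_table <- data.frame(
    target = rownames(J),
    in_degree = as.integer(in_degree[rownames(J)]),
    n_inconsistent = as.integer(rowSums(J)), stringsAsFactors = FALSE)

  structure(list(
    edge_table = edge_table,
    I = I,
    J = J,
    vertex_table = vertex_table,
    global_load = as.integer(sum(J)),
    per_contrast_load = stats::setNames(as.integer(colSums(J)),
                                        colnames(labels)),
    per_contrast_changed = stats::setNames(as.integer(colSums(labels != 0L)),
                                           colnames(labels)),
    n_contrasts = ncol(labels),
    config = config), class = "inconsistency_result")
}

#' @export
print.inconsistency_result <- function(x, ...) {
  cat(sprintf(paste0(
    "Sign-consistency evaluation (%s model): %d edges, %d targets, ",
    "%d contrasts\n  global inconsistency load: %d\n"),
    x$config$variant, nrow(x$edge_table), nrow(x$vertex_table),
    x$n_contrasts, x$global_load))
  invisible(x)
}

#' Summarize edge inconsistency by stratum
#'
#' Partitions edges by regulation sign, by sign restricted to
#' single-regulator targets, by evidence class (strong/weak) or by
#' individual evidence type, and reports the mean per-edge inconsistency
#' count |I(e)|_1 and the number of edges in each stratum. For
#' `by_evidence_type`, an edge supported by several evidence types counts
#' in each of them.
#'
#' @param result an `inconsistency_result`.
#' @param net the `signed_grn` the result was computed on.
#' @param strata one of `"by_sign"`, `"single_regulator_by_sign"`,
#'   `"by_evidence_class"`, `"by_evidence_type"`.
#' @return data.frame with columns `stratum`, `n_edges`,
#'   `mean_inconsistency`.
#' @export
stratify_edges <- function(result, net,
                           strata = c("by_sign", "single_regulator_by_sign",
                                      "by_evidence_class",
                                      "by_evidence_type")) {
  strata <- match.arg(strata)
  et <- result$edge_table
  inter <- net$interactions

  summarize <- function(groups, counts) {
    keep <- !is.na(groups)
    groups <- groups[keep]; counts <- counts[keep]
    if (!length(groups))
      return(data.frame(stratum = character(), n_edges = integer(),
                        mean_inconsistency = numeric()))
    m <- tapply(counts, groups, mean)
    n <- tapply(counts, groups, length)
    data.frame(stratum = names(m), n_edges = as.integer(n),
               mean_inconsistency = as.numeric(m), row.names = NULL)
  }

  if (strata == "by_sign") {
    summarize(et$sign, et$n_inconsistent)
  } else if (strata == "single_regulator_by_sign") {
    single <- single_regulator_targets(net)
    keep <- et$target %in% single
    summarize(et$sign[keep], et$n_inconsistent[keep])
  } else if (strata == "by_evidence_class") {
    if (all(is.na(inter$evidence_class)))
      stop("network carries no evidence-class annotations")
    cls <- inter$evidence_class[match(paste(et$regulator, et$target),
                                      paste(inter$regulator, inter$target))]
    summarize(cls, et$n_inconsistent)
  } else {
    if (all(is.na(inter$evidence_types)))
      stop("network carries no evidence-type annotations")
    types <- inter$evidence_types[match(paste(et$regulator, et$target),
                                        paste(inter$regulator, inter$target))]
    split_types <- strsplit(ifelse(is.na(types), "", types), ",", fixed = TRUE)
    idx <- rep(seq_along(split_types), lengths(split_types))
    summarize(trimws(unlist(split_types)), et$n_inconsistent[idx])
  }
}
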