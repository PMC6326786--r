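#' Randomly redistribute expression profiles among vertices
#'
#' Applies a uniformly random permutation (Fisher-Yates shuffle) to the
#' assignment of rows (whole expression or contrast profiles) to vertex
#' ids. Entire profiles are exchanged so that each profile stays
#' internally consistent; the multiset of rows, and hence every marginal
#' distribution, is unchanged — only which vertex owns which profile is
#' randomized. Topology is untouched, so all vertex degrees are preserved.
#'
#' @param values numeric matrix with rownames (vertex or gene ids).
#' @param seed optional integer for reproducibility.
#' @return A matrix of identical dimensions and rownames whose rows have
#'   been permuted.
#' @export
shuffle_profiles <- function(values, seed = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  perm <- with_seed(seed, sample.int(nrow(values)))
  out <- values[perm, , drop = FALSE]
  rownames(out) <- rownames(values)
  out
}

#' Degree-preserving edge rewiring
#'
#' Randomizes network topology by repeated double edge swaps: pick two
#' existing edges (p, q) and (r, s) and replace them with (p, s) and
#' (r, q). A proposal is aborted (the edge set is left unchanged for that
#' attempt) when either new edge already exists, when the two edges share
#' a regulator or a target, or when the two picks are the same edge.
#' `rounds_factor * |E|` attempts are performed (attempts, not successful
#' swaps, so the procedure terminates even on swap-saturated graphs such
#' as complete bipartite networks). Every vertex keeps its exact in- and
#' out-degree and the edge count is unchanged. The sign (and evidence) of
#' a rewired edge follows the regulator's outgoing stub: new edge (p, s)
#' carries the sign of old edge (p, q), so each regulator's
#' activator/repressor out-profile is preserved.
#'
#' @param net a `signed_grn` with at least 2 interactions.
#' @param rounds_factor number of swap attempts per edge (default 10).
#' @param seed optional integer for reproducibility.
#' @return A rewired `signed_grn` with attribute `n_swaps`, the number of
#'   successful swaps.
#' @export
rewire_edges <- function(net, rounds_factor = 10, seed = NULL) {
  inter <- net$interactions
  m <- nrow(inter)
  if (m < 2) stop("rewiring requires at least 2 interactions")
  reg <- inter$regulator
  tgt <- inter$target

  with_seed(seed, {
    attempts <- ceiling(rounds_factor * m)
    pick1 <- sample.int(m, attempts, replace = TRUE)
    pick2 <- sample.int(m, attempts, replace = TRUE)
    edge_set <- new.env(hash = TRUE, parent = emptyenv(), size = 2L * m)
    key <- paste(reg, tgt, sep = "\r")
    for (k in key) assign(k, TRUE, envir = edge_set)
    n_swaps <- 0L
    for (a in seq_len(attempts)) {
      i <- pick1[a]; j <- pick2[a]
      if (i == j) next
      p <- reg[i]; q <- tgt[i]; r <- reg[j]; s <- tgt[j]
      if (p == r || q == s) next
      new1 <- paste(p, s, sep = "\r")
      new2 <- paste(r, q, sep = "\r")
      if (exists(new1, envir = edge_set, inherits = FALSE) ||
          exists(new2, envir = edge_set, inherits = FALSE)) next
      rm(list = c(paste(p, q, sep = "\r"), paste(r, s, sep = "\r")),
         envir = edge_set)
      assign(new1, TRUE, envir = edge_set)
      assign(new2, TRUE, envir = edge_set)
      tgt[i] <- s
      tgt[j] <- q
      n_swaps <- n_swaps + 1L
    }
    inter$target <- tgt
    out <- signed_grn(net$regulators, net$targets, inter)
    attr(out, "n_swaps") <- n_swaps
    out
  })
}

#' Null distribution of the global inconsistency load
#'
#' Repeatedly perturbs either the expression side (profile shuffling) or
#' the topology side (degree-preserving rewiring) and re-evaluates the
#' global inconsistency load, yielding the null distribution against
#' which the observed load is compared. After a profile shuffle, labels
#' are recomputed with the same threshold (a row permutation leaves the
#' pooled contrast values, and hence the threshold, unchanged); after
#' rewiring, the original labels are reused with the new topology.
#'
#' @param net a `signed_grn`.
#' @param contrasts a `contrast_set` over the network's vertices.
#' @param config a \code{\link{sign_model_config}}.
#' @param method `"shuffle_profiles"` or `"rewire_edges"`.
#' @param repetitions number of perturbed replicates (default 200).
#' @param seed master seed; per-repetition seeds are derived from it.
#' @param rounds_factor swap attempts per edge for the rewiring method.
#' @return An object of class `null_model_report`: list with `method`,
#'   `repetitions`, `loads` (one global load per replicate),
#'   `observed_load`, `summary` (median/mean/min/max) and `empirical_p`,
#'   the proportion of null loads less than or equal to the observed load
#'   (one-sided: small values mean the observed network is *less*
#'   consistent-looking than random, i.e. null loads mostly exceed it).
#' @export
null_distribution <- function(net, contrasts, config = sign_model_config(),
                              method = c("shuffle_profiles", "rewire_edges"),
                              repetitions = 200, seed = NULL,
                              rounds_factor = 10) {
  method <- match.arg(method)
  stopifnot(repetitions >= 1)
  labels <- label_vertices(contrasts, config)
  observed <- evaluate_consistency(net, labels, config)$global_load
  seeds <- derive_seeds(seed %||% sample.int(.Machine$integer.max, 1),
                        repetitions)
  loads <- vapply(seq_len(repetitions), function(r) {
    if (method == "shuffle_profiles") {
      shuffled <- shuffle_profiles(contrasts$values, seed = seeds[r])
      lab <- label_vertices(shuffled, config)
      evaluate_consistency(net, lab, config)$global_load
    } else {
      perturbed <- rewire_edges(net, rounds_factor = rounds_factor,
                                seed = seeds[r])
      evaluate_consistency(perturbed, labels, config)$global_load
    }
  }, numeric(1))
  structure(list(
    method = method,
    repetitions = repetitions,
    loads = loads,
    observed_load = observed,
    summary = c(median = stats::median(loads), mean = mean(loads),
                min = min(loads), max = max(loads)),
    empirical_p = mean(loads <= observed)), class = "null_model_report")
}

#' @export
print.null_model_report <- function(x, ...) {
  cat(sprintf(paste0(
    "Null model (%s, %d repetitions)\n  observed load: %d\n",
    "  null loads: median %.1f, mean %.1f, range [%d, %d]\n",
    "  empirical p (null <= observed): %.4g\n"),
    x$method, x$repetitions, x$observed_load,
    x$summary["median"], x$summary["mean"],
    as.integer(x$summary["min"]), as.integer(x$summary["max"]),
    x$empirical_p))
  invisible(x)
}
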