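#' Configuration for the synthetic study generator
#'
#' Describes a synthetic signed regulatory network and a matching
#' expression compendium organized as experiments with one unperturbed
#' reference sample and several case samples. Three regimes control how
#' expression relates to the network:
#' \describe{
#'   \item{causal}{target genes respond linearly to the latent activities
#'     of their regulators with the sign and weight of each edge; TF genes
#'     report their own activity. The idealized situation in which the
#'     network explains the data.}
#'   \item{decoupled}{every gene is independent noise around its baseline;
#'     the network has no relation to expression. The situation where the
#'     network and the compendium carry no shared signal.}
#'   \item{confounded}{as decoupled, but every gene additionally receives
#'     a shared per-sample confounder, inducing positive co-expression
#'     between all pairs regardless of regulation sign (global factors
#'     such as growth rate or batch).}
#' }
#'
#' @param n_tf,n_targets,n_edges network dimensions.
#' @param frac_activating probability that an edge is an activation
#'   (default 0.55, matching the roughly balanced activator excess of
#'   curated bacterial networks).
#' @param out_degree_tail_exponent exponent of the truncated power law
#'   from which regulator out-degrees are drawn (default 2, a heavy tail
#'   with a few global regulators).
#' @param tu_fraction fraction of targets that are multi-gene
#'   transcription units (2-4 member genes).
#' @param complex_fraction fraction of regulators that are multi-gene TF
#'   complexes (2-3 member genes).
#' @param n_experiments,cases_per_experiment compendium layout: each
#'   experiment has one reference plus this many case samples.
#' @param perturbed_fraction fraction of experiments flagged as perturbed
#'   (their case samples receive strong activity shifts; a quarter of
#'   perturbed cases are TF knockouts in the causal regime).
#' @param effect_size linear response weight `w` of a target to one unit
#'   of regulator activity.
#' @param noise_sd residual expression noise standard deviation (log
#'   scale).
#' @param confounder_sd standard deviation of the shared per-sample
#'   confounder (confounded regime only).
#' @param regime `"causal"`, `"decoupled"` or `"confounded"`.
#' @param seed integer seed; the full study is deterministic given the
#'   configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_tf = 50, n_targets = 200, n_edges = 600,
                       frac_activating = 0.55,
                       out_degree_tail_exponent = 2,
                       tu_fraction = 0.2, complex_fraction = 0.1,
                       n_experiments = 25, cases_per_experiment = 4,
                       perturbed_fraction = 0.5,
                       effect_size = 1, noise_sd = 0.5,
                       confounder_sd = 1,
                       regime = c("causal", "decoupled", "confounded"),
                       seed = 1L) {
  regime <- match.arg(regime)
  cfg <- list(n_tf = n_tf, n_targets = n_targets, n_edges = n_edges,
              frac_activating = frac_activating,
              out_degree_tail_exponent = out_degree_tail_exponent,
              tu_fraction = tu_fraction, complex_fraction = complex_fraction,
              n_experiments = n_experiments,
              cases_per_experiment = cases_per_experiment,
              perturbed_fraction = perturbed_fraction,
              effect_size = effect_size, noise_sd = noise_sd,
              confounder_sd = confounder_sd, regime = regime,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_tf >= 1, n_targets >= 1, n_edges >= 1,
              frac_activating >= 0, frac_activating <= 1,
              out_degree_tail_exponent > 0,
              tu_fraction >= 0, tu_fraction <= 1,
              complex_fraction >= 0, complex_fraction <= 1,
              n_experiments >= 1, cases_per_experiment >= 1,
              perturbed_fraction >= 0, perturbed_fraction <= 1,
              effect_size > 0, noise_sd >= 0, confounder_sd >= 0)
  })
  if (cfg$n_edges > cfg$n_tf * cfg$n_targets)
    stop("infeasible edge count: n_edges exceeds n_tf * n_targets")
  structure(cfg, class = "sim_config")
}

# draw regulator out-degrees from a truncated power law and rescale them
# to sum exactly to n_edges, each degree in [1, n_targets]
draw_out_degrees <- function(n_tf, n_targets, n_edges, exponent) {
  if (n_edges < n_tf)
    stop("n_edges must be at least n_tf (every regulator needs one edge)")
  kmax <- min(n_targets, max(1L, ceiling(n_edges / 2)))
  support <- seq_len(kmax)
  raw <- sample(support, n_tf, replace = TRUE, prob = support^(-exponent))
  d <- pmin(pmax(round(raw * n_edges / sum(raw)), 1L), n_targets)
  while (sum(d) != n_edges) {
    gap <- n_edges - sum(d)
    if (gap > 0) {
      slack <- which(d < n_targets)
      i <- if (length(slack) > 1) sample(slack, 1) else slack
      d[i] <- d[i] + 1L
    } else {
      slack <- which(d > 1L)
      i <- if (length(slack) > 1) sample(slack, 1) else slack
      d[i] <- d[i] - 1L
    }
  }
  d
}

#' Generate a synthetic signed regulatory network
#'
#' Out-degrees are drawn from a truncated power law with the configured
#' tail exponent (rescaled to hit the requested edge count exactly);
#' each regulator's targets are attached uniformly at random without
#' duplicate edges; edge signs are i.i.d. Bernoulli draws. The requested
#' fractions of targets become 2-4-gene transcription units and of
#' regulators become 2-3-gene complexes.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with `network` (a `signed_grn`) and `truth` (ground truth:
#'   per-edge `weights` data.frame whose weight is `+effect_size` for
#'   activations and `-effect_size` for repressions).
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n_tu <- round(config$tu_fraction * config$n_targets)
    n_cx <- round(config$complex_fraction * config$n_tf)

    tf_ids <- sprintf("TF%03d", seq_len(config$n_tf))
    is_cx <- seq_len(config$n_tf) <= n_cx
    regulators <- lapply(seq_len(config$n_tf), function(i) {
      k <- if (is_cx[i]) sample(2:3, 1) else 1L
      paste0(tf_ids[i], "_g", seq_len(k))
    })
    names(regulators) <- tf_ids

    tgt_ids <- c(sprintf("TU%04d", seq_len(n_tu)),
                 sprintf("G%04d", seq_len(config$n_targets - n_tu)))
    targets <- lapply(seq_len(config$n_targets), function(i) {
      if (i <= n_tu) paste0(tgt_ids[i], "_g", seq_len(sample(2:4, 1)))
      else tgt_ids[i]
    })
    names(targets) <- tgt_ids

    d <- draw_out_degrees(config$n_tf, config$n_targets, config$n_edges,
                          config$out_degree_tail_exponent)
    edges <- do.call(rbind, lapply(seq_len(config$n_tf), function(i) {
      picked <- if (d[i] == config$n_targets) seq_len(config$n_targets)
                else sample.int(config$n_targets, d[i])
      data.frame(regulator = tf_ids[i], target = tgt_ids[picked],
                 stringsAsFactors = FALSE)
    }))
    act <- stats::rbinom(nrow(edges), 1, config$frac_activating) == 1
    edges$sign <- ifelse(act, "activation", "repression")

    net <- signed_grn(regulators, targets, edges)
    truth <- list(weights = data.frame(
      regulator = edges$regulator, target = edges$target,
      weight = ifelse(act, config$effect_size, -config$effect_size),
      stringsAsFactors = FALSE))
    list(network = net, truth = truth)
  })
}

# activity shift parameters: perturbed cases shift many TFs strongly,
# unperturbed cases few and weakly (held fixed; see the methods vignette)
SHIFT_PROB <- c(unperturbed = 0.1, perturbed = 0.4)
SHIFT_SD <- c(unperturbed = 0.5, perturbed = 2)
KNOCKOUT_PROB <- 0.25
TU_JITTER_SD <- 0.1

#' Generate a synthetic expression compendium for a network
#'
#' Lays out `n_experiments` experiments of one unperturbed reference plus
#' `cases_per_experiment` case samples. Latent TF activities are a
#' per-experiment baseline (standard normal, shared by reference and
#' cases) plus per-case shifts applied to a random subset of TFs;
#' perturbed experiments shift more TFs, more strongly. In the causal
#' regime a quarter of perturbed cases are knockouts: one shifted TF's
#' activity is forced to a strong negative value and its gene row is
#' clamped to baseline minus three noise standard deviations. Gene-level
#' log expression follows the configured regime (see
#' \code{\link{sim_config}}); transcription-unit member genes are the
#' TU-level value plus small i.i.d. jitter, so members co-vary without
#' being identical.
#'
#' @param net the `signed_grn` from \code{\link{generate_network}}.
#' @param truth its ground truth (per-edge weights).
#' @param config the same \code{\link{sim_config}}.
#' @return list with `compendium` (an `expression_compendium` over all
#'   member genes), `activities` (TF x sample latent activity matrix) and
#'   `confounders` (per-sample confounder values; zero outside the
#'   confounded regime).
#' @export
generate_compendium <- function(net, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    n_exp <- config$n_experiments
    n_case <- config$cases_per_experiment
    exp_ids <- sprintf("EXP%03d", seq_len(n_exp))
    perturbed_exp <- exp_ids[seq_len(n_exp) %in%
      sample.int(n_exp, round(config$perturbed_fraction * n_exp))]

    meta <- do.call(rbind, lapply(exp_ids, function(e) {
      data.frame(
        sample_id = paste0(e, ".", c("ref", paste0("c", seq_len(n_case)))),
        experiment_id = e,
        is_reference = c(TRUE, rep(FALSE, n_case)),
        is_perturbed = c(FALSE, rep(e %in% perturbed_exp, n_case)),
        stringsAsFactors = FALSE)
    }))
    n_samp <- nrow(meta)
    tf_ids <- names(net$regulators)

    # latent activities: per-experiment baseline + per-case shifts
    baseline <- matrix(stats::rnorm(length(tf_ids) * n_exp), length(tf_ids),
                       dimnames = list(tf_ids, exp_ids))
    activities <- baseline[, meta$experiment_id, drop = FALSE]
    colnames(activities) <- meta$sample_id
    knockout <- matrix(FALSE, length(tf_ids), n_samp,
                       dimnames = list(tf_ids, meta$sample_id))
    for (s in which(!meta$is_reference)) {
      kind <- if (meta$is_perturbed[s]) "perturbed" else "unperturbed"
      hit <- stats::runif(length(tf_ids)) < SHIFT_PROB[[kind]]
      activities[hit, s] <- activities[hit, s] +
        stats::rnorm(sum(hit), 0, SHIFT_SD[[kind]])
      if (config$regime == "causal" && meta$is_perturbed[s] &&
          any(hit) && stats::runif(1) < KNOCKOUT_PROB) {
        ko <- if (sum(hit) > 1) sample(which(hit), 1) else which(hit)
        activities[ko, s] <- -3
        knockout[ko, s] <- TRUE
      }
    }

    genes <- network_genes(net)
    alpha <- stats::setNames(stats::rnorm(length(genes), 7, 1), genes)
    conf <- if (config$regime == "confounded")
      stats::rnorm(n_samp, 0, config$confounder_sd) else numeric(n_samp)

    values <- matrix(NA_real_, length(genes), n_samp,
                     dimnames = list(genes, meta$sample_id))

    # regulator member genes
    for (f in tf_ids) {
      members <- net$regulators[[f]]
      signal <- if (config$regime == "causal") activities[f, ]
                else numeric(n_samp)
      for (g in members) {
        values[g, ] <- alpha[[g]] + signal + conf +
          stats::rnorm(n_samp, 0, config$noise_sd)
      }
      if (config$regime == "causal" && any(knockout[f, ])) {
        for (g in members)
          values[g, knockout[f, ]] <- alpha[[g]] - 3 * config$noise_sd
      }
    }

    # target vertices: linear response to incoming regulator activities
    w <- truth$weights
    w_by_target <- split(seq_len(nrow(w)), w$target)
    for (t in names(net$targets)) {
      members <- net$targets[[t]]
      idx <- w_by_target[[t]]
      z <- if (config$regime == "causal" && length(idx)) {
        as.vector(w$weight[idx] %*%
                    activities[w$regulator[idx], , drop = FALSE])
      } else numeric(n_samp)
      level <- alpha[[members[1]]] + z + conf +
        stats::rnorm(n_samp, 0, config$noise_sd)
      if (length(members) == 1L) {
        values[members, ] <- level
      } else {
        for (g in members)
          values[g, ] <- level + stats::rnorm(n_samp, 0, TU_JITTER_SD)
      }
    }

    list(compendium = expression_compendium(values, meta),
         activities = activities, confounders = conf)
  })
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper: network plus compendium from one configuration.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with `network`, `truth`, `compendium`, `activities`,
#'   `confounders`.
#' @export
simulate_study <- function(config = sim_config()) {
  gn <- generate_network(config)
  gc <- generate_compendium(gn$network, gn$truth, config)
  c(gn, gc)
}
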