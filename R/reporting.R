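# Per-contrast and per-evidence summaries, statistical comparisons, and
# the full-pipeline orchestration.

mwu_test <- function(x, y) {
  # two-sided Mann-Whitney U, normal approximation with tie correction
  stats::wilcox.test(x, y, alternative = "two.sided", exact = FALSE,
                     correct = TRUE)$p.value
}

#' Compare inconsistency load between perturbed and unperturbed contrasts
#'
#' Splits contrasts by the perturbation status of their case sample and
#' compares both the per-contrast inconsistency load and the number of
#' up-/down-labeled vertices between the groups (two-sided Mann-Whitney
#' U). Also reports the correlation between the changed-vertex count and
#' the load: perturbed conditions typically change more genes, which by
#' itself inflates the number of scoreable inconsistencies.
#'
#' @param result an `inconsistency_result`.
#' @param contrast_meta the `contrast_meta` data.frame of the evaluated
#'   `contrast_set` (carries `is_perturbed`).
#' @return list with `per_contrast` (contrast_id, is_perturbed, load,
#'   changed), `group_summary`, `load_p`, `changed_p` (NA when a group
#'   has fewer than 2 contrasts) and `load_changed_correlation`.
#' @export
contrast_analysis <- function(result, contrast_meta) {
  if (!"is_perturbed" %in% names(contrast_meta))
    stop("contrast_meta lacks an is_perturbed column")
  stopifnot(nrow(contrast_meta) == result$n_contrasts)
  per <- data.frame(
    contrast_id = contrast_meta$contrast_id,
    is_perturbed = contrast_meta$is_perturbed,
    load = as.integer(result$per_contrast_load),
    changed = as.integer(result$per_contrast_changed),
    stringsAsFactors = FALSE)

  grp <- split(per, per$is_perturbed)
  group_summary <- do.call(rbind, lapply(names(grp), function(g)
    data.frame(group = ifelse(g == "TRUE", "perturbed", "unperturbed"),
               n = nrow(grp[[g]]),
               mean_load = mean(grp[[g]]$load),
               median_load = stats::median(grp[[g]]$load),
               mean_changed = mean(grp[[g]]$changed))))

  load_p <- changed_p <- NA_real_
  if (length(grp) == 2 && all(vapply(grp, nrow, 0L) >= 2)) {
    load_p <- mwu_test(grp[["TRUE"]]$load, grp[["FALSE"]]$load)
    changed_p <- mwu_test(grp[["TRUE"]]$changed, grp[["FALSE"]]$changed)
  } else {
    warning("a perturbation group has fewer than 2 contrasts; ",
            "tests skipped, summaries reported")
  }
  lcc <- if (stats::sd(per$load) > 0 && stats::sd(per$changed) > 0)
    stats::cor(per$changed, per$load) else NA_real_
  list(per_contrast = per, group_summary = group_summary,
       load_p = load_p, changed_p = changed_p,
       load_changed_correlation = lcc)
}

#' Compare inconsistency across experimental-evidence annotations
#'
#' Compares per-edge inconsistency counts |I(e)|_1 between interactions
#' with strong and weak experimental evidence (two-sided Mann-Whitney U)
#' and summarizes mean inconsistency per individual evidence type,
#' excluding uncommon types supporting fewer than `min_count` edges.
#'
#' @param result an `inconsistency_result`.
#' @param net the annotated `signed_grn`.
#' @param min_count minimum number of edges for an evidence type to be
#'   reported (default 100).
#' @return list with `class_summary`, `class_p` (NA when either class has
#'   fewer than 2 edges) and `type_summary`.
#' @export
evidence_analysis <- function(result, net, min_count = 100) {
  inter <- net$interactions
  if (all(is.na(inter$evidence_class)) && all(is.na(inter$evidence_types)))
    stop("network carries no evidence annotations")

  class_summary <- stratify_edges(result, net, "by_evidence_class")
  class_p <- NA_real_
  cls <- inter$evidence_class[match(
    paste(result$edge_table$regulator, result$edge_table$target),
    paste(inter$regulator, inter$target))]
  strong <- result$edge_table$n_inconsistent[!is.na(cls) & cls == "strong"]
  weak <- result$edge_table$n_inconsistent[!is.na(cls) & cls == "weak"]
  if (length(strong) >= 2 && length(weak) >= 2) {
    class_p <- mwu_test(strong, weak)
  } else {
    warning("fewer than 2 edges in an evidence class; test skipped")
  }

  type_summary <- stratify_edges(result, net, "by_evidence_type")
  type_summary <- type_summary[type_summary$n_edges >= min_count, ,
                               drop = FALSE]
  rownames(type_summary) <- NULL
  list(class_summary = class_summary, class_p = class_p,
       type_summary = type_summary)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full consistency-analysis pipeline
#'
#' Orchestrates every stage: read (or simulate) the network and
#' compendium, filter the network to measured genes, aggregate expression
#' to vertices, compute contrasts, choose the labeling threshold, label,
#' evaluate sign consistency, run the null models, correlate interaction
#' profiles against the background, and compare perturbed vs unperturbed
#' contrasts (plus evidence strata when annotations are present). All
#' tables are written to `out_dir` together with a JSON summary and a run
#' manifest listing every output file. The run is deterministic given the
#' seed.
#'
#' @param out_dir output directory (created if needed).
#' @param simulate a \code{\link{sim_config}} to generate the study, or
#'   NULL to read inputs from files.
#' @param network_table,tu_annotations,complex_annotations,dialect network
#'   input files (when `simulate` is NULL); see \code{\link{read_network}}.
#' @param expression_table,sample_meta_table compendium input files (when
#'   `simulate` is NULL); see \code{\link{read_compendium}}.
#' @param variant sign-model variant, `"ternary"` or `"binary"`.
#' @param threshold fixed labeling threshold, or NULL to choose it from
#'   the contrast distribution via \code{\link{select_threshold}}.
#' @param target_changed_fraction changed fraction for automatic threshold
#'   selection (default 0.5).
#' @param null_methods null models to run (default both).
#' @param null_repetitions replicates per null model (default 200).
#' @param rounds_factor rewiring attempts per edge (default 10).
#' @param correlation_method `"pearson"` or `"spearman"`.
#' @param max_background_pairs cap on background correlation pairs.
#' @param seed master seed for all randomness.
#' @return Invisibly, a list with all in-memory results (`network`,
#'   `contrasts`, `threshold`, `result`, `nulls`, `correlations`,
#'   `background`, `contrast_groups`, `evidence`, `manifest`).
#' @export
run_pipeline <- function(out_dir,
                         simulate = NULL,
                         network_table = NULL, tu_annotations = NULL,
                         complex_annotations = NULL, dialect = "simple",
                         expression_table = NULL, sample_meta_table = NULL,
                         variant = c("ternary", "binary"),
                         threshold = NULL, target_changed_fraction = 0.5,
                         null_methods = c("shuffle_profiles", "rewire_edges"),
                         null_repetitions = 200, rounds_factor = 10,
                         correlation_method = c("pearson", "spearman"),
                         max_background_pairs = 200000,
                         seed = 1L) {
  variant <- match.arg(variant)
  correlation_method <- match.arg(correlation_method)
  null_methods <- match.arg(null_methods, several.ok = TRUE)
  t_start <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  emit <- function(name, writer) {
    path <- file.path(out_dir, name)
    writer(path)
    files <<- c(files, name)
  }
  stage <- "configure"
  res <- try({
    if (is.null(simulate)) {
      if (is.null(network_table) || is.null(expression_table) ||
          is.null(sample_meta_table))
        stop("provide either `simulate` or the network and expression files")
      stage <- "read_network"
      net <- read_network(network_table, tu_annotations,
                          complex_annotations, dialect)
      stage <- "read_compendium"
      comp <- read_compendium(expression_table, sample_meta_table)
    } else {
      stage <- "simulate"
      study <- simulate_study(simulate)
      net <- study$network
      comp <- study$compendium
      emit("network.tsv", function(p) write_network(net, p))
      emit("expression.tsv", function(p)
        write_compendium(comp, p, file.path(out_dir, "sample_meta.tsv")))
      files <- c(files, "sample_meta.tsv")
    }

    stage <- "filter_by_expression"
    net <- filter_by_expression(net, rownames(comp$values))
    if (!nrow(net$interactions))
      stop("no interactions remain after expression filtering")

    stage <- "vertex_expression"
    vexpr <- vertex_expression(comp, net)
    stage <- "compute_contrasts"
    contrasts <- compute_contrasts(vexpr, comp$sample_meta)

    stage <- "select_threshold"
    t_used <- threshold %||%
      select_threshold(contrasts, target_changed_fraction)
    config <- sign_model_config(t_used, variant)

    stage <- "evaluate"
    labels <- label_vertices(contrasts, config)
    result <- evaluate_consistency(net, labels, config)
    emit("edge_inconsistency.tsv", function(p)
      write_tsv(result$edge_table, p))
    emit("target_inconsistency.tsv", function(p)
      write_tsv(result$vertex_table, p))
    emit("per_contrast.tsv", function(p)
      write_tsv(data.frame(contrast_id = colnames(result$I),
                           changed = as.integer(result$per_contrast_changed),
                           load = as.integer(result$per_contrast_load)), p))

    stage <- "null_models"
    seeds <- derive_seeds(seed, length(null_methods) + 1L)
    nulls <- list()
    for (k in seq_along(null_methods)) {
      m <- null_methods[k]
      nulls[[m]] <- null_distribution(
        net, contrasts, config, method = m,
        repetitions = null_repetitions, seed = seeds[k],
        rounds_factor = rounds_factor)
      emit(paste0("null_", m, ".tsv"), function(p)
        write_tsv(data.frame(repetition = seq_len(null_repetitions),
                             load = nulls[[m]]$loads), p))
    }

    stage <- "correlations"
    correlations <- interaction_correlations(net, vexpr, correlation_method)
    background <- background_correlations(
      net, vexpr, correlation_method, max_pairs = max_background_pairs,
      seed = seeds[length(null_methods) + 1L])
    emit("interaction_correlations.tsv", function(p)
      write_tsv(correlations$records, p))

    stage <- "contrast_analysis"
    groups <- contrast_analysis(result, contrasts$contrast_meta)

    stage <- "evidence_analysis"
    evidence <- NULL
    if (!all(is.na(net$interactions$evidence_class)) ||
        !all(is.na(net$interactions$evidence_types)))
      evidence <- evidence_analysis(result, net)

    stage <- "summarize"
    summary <- list(
      threshold = t_used, variant = variant,
      n_regulators = length(net$regulators),
      n_targets = length(net$targets),
      n_interactions = nrow(net$interactions),
      n_contrasts = result$n_contrasts,
      changed_fraction = mean(labels != 0L),
      global_load = result$global_load,
      by_sign = stratify_edges(result, net, "by_sign"),
      single_regulator_by_sign =
        stratify_edges(result, net, "single_regulator_by_sign"),
      nulls = lapply(nulls, function(x)
        x[c("method", "repetitions", "observed_load", "summary",
            "empirical_p")]),
      correlation_strata = correlations$strata,
      background_mean_r = background$mean_r,
      contrast_groups = groups[c("group_summary", "load_p", "changed_p",
                                 "load_changed_correlation")],
      evidence = if (!is.null(evidence))
        evidence[c("class_summary", "class_p", "type_summary")])
    emit("summary.json", function(p) write_json_file(summary, p))

    manifest <- list(
      seed = seed,
      variant = variant,
      threshold = t_used,
      simulate = if (!is.null(simulate)) unclass(simulate),
      inputs = Filter(Negate(is.null),
                      list(network_table = network_table,
                           expression_table = expression_table,
                           sample_meta_table = sample_meta_table)),
      null_methods = null_methods,
      null_repetitions = null_repetitions,
      correlation_method = correlation_method,
      package_version = as.character(utils::packageVersion("signcon")),
      r_version = R.version.string,
      outputs = files,
      elapsed_seconds = as.numeric(difftime(Sys.time(), t_start,
                                            units = "secs")))
    write_json_file(manifest, file.path(out_dir, "manifest.json"))

    invisible(list(network = net, contrasts = contrasts,
                   threshold = t_used, result = result, nulls = nulls,
                   correlations = correlations, background = background,
                   contrast_groups = groups, evidence = evidence,
                   manifest = manifest))
  }, silent = TRUE)
  if (inherits(res, "try-error"))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 attr(res, "condition")$message), call. = FALSE)
  res
}
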