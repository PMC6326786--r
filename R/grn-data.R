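#' Construct a signed regulatory network
#'
#' A `signed_grn` is a directed bipartite graph: regulator vertices
#' (transcription factors or TF complexes) connected to target vertices
#' (genes or transcription units, TUs) by edges signed as activation or
#' repression. A vertex with more than one member gene marks a TF complex
#' (regulator side) or a TU (target side). Regulator and target vertex ids
#' must be disjoint because downstream expression and label matrices are
#' keyed by vertex id; the same *gene* may still appear both as a
#' regulator's member and as a target.
#'
#' @param regulators named list; each element a non-empty character vector
#'   of member gene ids, names are regulator vertex ids.
#' @param targets named list of member gene vectors, names are target
#'   vertex ids.
#' @param interactions data.frame with columns `regulator`, `target`,
#'   `sign` (`"activation"` or `"repression"`) and optionally
#'   `evidence_class` (`"strong"`/`"weak"`) and `evidence_types`
#'   (comma-separated codes such as `"BPP,SM"`).
#' @return An object of class `signed_grn`.
#' @export
signed_grn <- function(regulators, targets, interactions) {
  stopifnot(is.list(regulators), is.list(targets), is.data.frame(interactions))
  if (is.null(names(regulators)) && length(regulators) > 0)
    stop("regulators must be a named list")
  if (is.null(names(targets)) && length(targets) > 0)
    stop("targets must be a named list")
  if (anyDuplicated(names(regulators)))
    stop("duplicate regulator ids")
  if (anyDuplicated(names(targets)))
    stop("duplicate target ids")
  clash <- intersect(names(regulators), names(targets))
  if (length(clash))
    stop("vertex ids used on both sides of the bipartite graph: ",
         paste(utils::head(clash, 5), collapse = ", "))
  if (any(lengths(regulators) == 0) || any(lengths(targets) == 0))
    stop("every vertex must have at least one member gene")

  need <- c("regulator", "target", "sign")
  if (!all(need %in% names(interactions)))
    stop("interactions must have columns regulator, target, sign")
  if (is.null(interactions$evidence_class))
    interactions$evidence_class <- rep(NA_character_, nrow(interactions))
  if (is.null(interactions$evidence_types))
    interactions$evidence_types <- rep(NA_character_, nrow(interactions))
  interactions <- interactions[, c(need, "evidence_class", "evidence_types")]
  interactions$regulator <- as.character(interactions$regulator)
  interactions$target <- as.character(interactions$target)
  interactions$sign <- as.character(interactions$sign)

  bad_sign <- setdiff(unique(interactions$sign), c("activation", "repression"))
  if (length(bad_sign))
    stop("invalid interaction sign(s): ", paste(bad_sign, collapse = ", "))
  if (anyDuplicated(interactions[, c("regulator", "target")]))
    stop("duplicate (regulator, target) interactions")
  miss_r <- setdiff(interactions$regulator, names(regulators))
  if (length(miss_r))
    stop("interaction references undeclared regulator(s): ",
         paste(utils::head(miss_r, 5), collapse = ", "))
  miss_t <- setdiff(interactions$target, names(targets))
  if (length(miss_t))
    stop("interaction references undeclared target(s): ",
         paste(utils::head(miss_t, 5), collapse = ", "))

  rownames(interactions) <- NULL
  structure(
    list(regulators = regulators, targets = targets,
         interactions = interactions),
    class = "signed_grn")
}

#' @export
print.signed_grn <- function(x, ...) {
  n_cx <- sum(lengths(x$regulators) > 1)
  n_tu <- sum(lengths(x$targets) > 1)
  cat(sprintf(paste0(
    "Signed regulatory network: %d regulators (%d complexes), ",
    "%d targets (%d TUs), %d interactions\n"),
    length(x$regulators), n_cx, length(x$targets), n_tu,
    nrow(x$interactions)))
  if (nrow(x$interactions)) {
    sgn <- table(x$interactions$sign)
    cat(sprintf("  activation: %d, repression: %d\n",
                sgn["activation"] %||% 0L, sgn["repression"] %||% 0L))
  }
  invisible(x)
}

#' All member genes appearing in a network
#' @param net a `signed_grn`.
#' @return character vector of unique gene ids.
#' @export
network_genes <- function(net) {
  unique(c(unlist(net$regulators, use.names = FALSE),
           unlist(net$targets, use.names = FALSE)))
}

parse_annotation_file <- function(path) {
  if (is.null(path)) return(list())
  src <- read_tsv_lines(path)
  if (!length(src$lines)) return(list())
  out <- list()
  for (k in seq_along(src$lines)) {
    fields <- strsplit(src$lines[[k]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2)
      stop(sprintf("malformed annotation row at line %d of %s: expected 2 tab-separated fields",
                   src$numbers[[k]], path))
    genes <- trimws(strsplit(fields[[2]], ",", fixed = TRUE)[[1]])
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stop(sprintf("empty gene list at line %d of %s", src$numbers[[k]], path))
    out[[trimws(fields[[1]])]] <- genes
  }
  out
}

#' Read a signed regulatory network from interaction tables
#'
#' Two tab-separated dialects are supported. `"simple"`: header
#' `regulator target sign [evidence]` with sign in `{+, -}`. `"regulondb"`:
#' a RegulonDB-style export with header columns `regulator`, `target`,
#' `effect` (one of `+`, `-`, `+-`, `?`) and optional `evidence_types`
#' (comma-separated codes), `evidence_class` (`strong`/`weak`) and
#' `target_type` (`gene`/`tu`). Comment lines start with `#`.
#'
#' Interactions with dual (`+-`) or unknown (`?`) effect are dropped and
#' counted, as are pairs reported with conflicting signs across rows (a
#' conflict is dual evidence about the edge's sign). Duplicate
#' `(regulator, target, sign)` rows collapse to one interaction with merged
#' evidence. Drop counts are attached as `attr(net, "dropped")`.
#'
#' @param interaction_table path to the interaction TSV.
#' @param tu_annotations optional path to a TSV mapping TU id to a
#'   comma-separated member gene list.
#' @param complex_annotations optional path mapping TF-complex id to its
#'   member gene list.
#' @param dialect `"simple"` or `"regulondb"`.
#' @return A `signed_grn` with attribute `dropped`, a named integer vector
#'   counting rows dropped as `dual`, `unknown` and `conflicting`.
#' @export
read_network <- function(interaction_table, tu_annotations = NULL,
                         complex_annotations = NULL,
                         dialect = c("simple", "regulondb")) {
  dialect <- match.arg(dialect)
  tu_map <- parse_annotation_file(tu_annotations)
  cx_map <- parse_annotation_file(complex_annotations)

  src <- read_tsv_lines(interaction_table)
  dropped <- c(dual = 0L, unknown = 0L, conflicting = 0L)
  if (!length(src$lines)) {
    net <- signed_grn(cx_map, tu_map,
                      data.frame(regulator = character(), target = character(),
                                 sign = character()))
    attr(net, "dropped") <- dropped
    return(net)
  }

  header <- strsplit(src$lines[[1]], "\t", fixed = TRUE)[[1]]
  body <- src$lines[-1]
  body_no <- src$numbers[-1]
  eff_col <- if (dialect == "simple") "sign" else "effect"
  if (!all(c("regulator", "target", eff_col) %in% header))
    stop(sprintf("interaction table header must contain regulator, target, %s",
                 eff_col))

  rows <- lapply(seq_along(body), function(k) {
    fields <- strsplit(body[[k]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3 || length(fields) > length(header))
      stop(sprintf("malformed interaction row at line %d: expected %d tab-separated fields, found %d",
                   body_no[[k]], length(header), length(fields)))
    length(fields) <- length(header)
    stats::setNames(as.list(fields), header)
  })
  get_col <- function(col, default = NA_character_) {
    if (col %in% header)
      vapply(rows, function(r) r[[col]] %||% NA_character_, character(1))
    else rep(default, length(rows))
  }

  tab <- data.frame(
    regulator = trimws(get_col("regulator")),
    target = trimws(get_col("target")),
    effect = trimws(get_col(eff_col)),
    evidence_types = if (dialect == "simple") get_col("evidence")
                     else get_col("evidence_types"),
    evidence_class = get_col("evidence_class"),
    target_type = get_col("target_type"),
    line = body_no,
    stringsAsFactors = FALSE)

  ok_eff <- c("+", "-")
  bad <- !(tab$effect %in% c(ok_eff, "+-", "?"))
  if (any(bad))
    stop(sprintf("malformed interaction row at line %d: effect '%s' not one of +, -, +-, ?",
                 tab$line[bad][1], tab$effect[bad][1]))

  # declared-TU validation (regulondb exports flag TU targets explicitly)
  is_tu <- !is.na(tab$target_type) & tolower(tab$target_type) == "tu"
  undecl <- unique(tab$target[is_tu & !(tab$target %in% names(tu_map))])
  if (length(undecl))
    stop("interaction references undeclared TU(s): ",
         paste(utils::head(undecl, 5), collapse = ", "))

  dropped["dual"] <- sum(tab$effect == "+-")
  dropped["unknown"] <- sum(tab$effect == "?")
  tab <- tab[tab$effect %in% ok_eff, , drop = FALSE]

  # pairs reported with both signs carry dual evidence: drop the pair
  if (nrow(tab)) {
    key <- paste(tab$regulator, tab$target, sep = "\r")
    n_signs <- tapply(tab$effect, key, function(e) length(unique(e)))
    conflict <- names(n_signs)[n_signs > 1]
    hit <- key %in% conflict
    dropped["conflicting"] <- sum(hit)
    tab <- tab[!hit, , drop = FALSE]
    key <- key[!hit]
  }

  # collapse duplicate (regulator, target, sign) rows, merging evidence
  if (nrow(tab)) {
    merge_types <- function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) return(NA_character_)
      paste(sort(unique(trimws(unlist(strsplit(x, ",", fixed = TRUE))))),
            collapse = ",")
    }
    merge_class <- function(x) {
      x <- tolower(x[!is.na(x)])
      if (!length(x)) NA_character_
      else if (any(x == "strong")) "strong" else "weak"
    }
    key <- paste(tab$regulator, tab$target, sep = "\r")
    first <- !duplicated(key)
    inter <- data.frame(
      regulator = tab$regulator[first],
      target = tab$target[first],
      sign = ifelse(tab$effect[first] == "+", "activation", "repression"),
      evidence_class = as.character(
        tapply(tab$evidence_class, key, merge_class)[key[first]]),
      evidence_types = as.character(
        tapply(tab$evidence_types, key, merge_types)[key[first]]),
      stringsAsFactors = FALSE)
  } else {
    inter <- data.frame(regulator = character(), target = character(),
                        sign = character())
  }

  reg_ids <- unique(inter$regulator)
  tgt_ids <- unique(inter$target)
  regulators <- lapply(stats::setNames(reg_ids, reg_ids), function(id)
    cx_map[[id]] %||% id)
  targets <- lapply(stats::setNames(tgt_ids, tgt_ids), function(id)
    tu_map[[id]] %||% id)

  net <- signed_grn(regulators, targets, inter)
  attr(net, "dropped") <- dropped
  net
}

#' Write a network in the simple dialect
#'
#' Writes the interaction table (`regulator`, `target`, `sign` in
#' `{+, -}`, `evidence`) and, when paths are given, the TU and complex
#' annotation files for multi-gene vertices, so that
#' `read_network(..., dialect = "simple")` round-trips the network.
#' Evidence classes are not representable in this dialect.
#'
#' @param net a `signed_grn`.
#' @param interaction_table output path for the interaction TSV.
#' @param tu_annotations,complex_annotations optional output paths for the
#'   membership tables of multi-gene vertices.
#' @return `interaction_table`, invisibly.
#' @export
write_network <- function(net, interaction_table, tu_annotations = NULL,
                          complex_annotations = NULL) {
  inter <- net$interactions
  out <- data.frame(
    regulator = inter$regulator,
    target = inter$target,
    sign = ifelse(inter$sign == "activation", "+", "-"),
    evidence = ifelse(is.na(inter$evidence_types), "",
                      inter$evidence_types))
  write_tsv(out, interaction_table)
  write_members <- function(members, path) {
    if (is.null(path)) return(invisible())
    multi <- members[lengths(members) > 1]
    write_tsv(data.frame(id = names(multi),
                         genes = vapply(multi, paste, "", collapse = ",")),
              path)
  }
  write_members(net$targets, tu_annotations)
  write_members(net$regulators, complex_annotations)
  invisible(interaction_table)
}

#' Restrict a network to vertices with fully measured member genes
#'
#' Removes every regulator and target with one or more member genes absent
#' from `measured_genes`, together with all interactions touching a removed
#' vertex. Mirrors the standard preprocessing step where TFs and TUs
#' lacking an expression profile for any constituent gene are excluded.
#'
#' @param net a `signed_grn`.
#' @param measured_genes character vector of gene ids with expression
#'   profiles.
#' @return The filtered `signed_grn`, with attribute `removed`: fractions
#'   of regulators, targets and interactions removed.
#' @export
filter_by_expression <- function(net, measured_genes) {
  measured_genes <- as.character(measured_genes)
  keep_r <- vapply(net$regulators, function(g) all(g %in% measured_genes),
                   logical(1))
  keep_t <- vapply(net$targets, function(g) all(g %in% measured_genes),
                   logical(1))
  inter <- net$interactions
  keep_e <- inter$regulator %in% names(net$regulators)[keep_r] &
    inter$target %in% names(net$targets)[keep_t]
  out <- signed_grn(net$regulators[keep_r], net$targets[keep_t],
                    inter[keep_e, , drop = FALSE])
  frac <- function(kept, total) if (total == 0) 0 else 1 - kept / total
  attr(out, "removed") <- c(
    regulators = frac(sum(keep_r), length(keep_r)),
    targets = frac(sum(keep_t), length(keep_t)),
    interactions = frac(sum(keep_e), length(keep_e)))
  out
}

#' Targets regulated by exactly one regulator
#'
#' Single-regulator targets isolate pairwise TF-target relationships:
#' their expression is not shaped by competing regulators, so they are the
#' cleanest stratum for correlation and consistency summaries.
#'
#' @param net a `signed_grn`.
#' @return character vector of target vertex ids with in-degree 1.
#' @export
single_regulator_targets <- function(net) {
  deg <- table(net$interactions$target)
  names(deg)[deg == 1L]
}
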