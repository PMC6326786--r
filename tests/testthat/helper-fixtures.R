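# Shared fixtures and independent oracles for the test suite.

# Hand-transcribed edge rule table of the ternary model: one row per
# (regulation sign, TF label, target label) combination, `consistent`
# copied by eye from the model definition. Used as an oracle for
# edge_inconsistency(); kept as literal data, independent of any package
# code path.
ternary_rule_table <- function() {
  df <- rbind(
    c("activation", "+", "+", "yes"),
    c("activation", "+", "-", "no"),
    c("activation", "+", "0", "no"),
    c("activation", "-", "+", "no"),
    c("activation", "-", "-", "yes"),
    c("activation", "-", "0", "yes"),
    c("activation", "0", "+", "yes"),
    c("activation", "0", "-", "yes"),
    c("activation", "0", "0", "yes"),
    c("repression", "+", "+", "no"),
    c("repression", "+", "-", "yes"),
    c("repression", "+", "0", "no"),
    c("repression", "-", "+", "yes"),
    c("repression", "-", "-", "no"),
    c("repression", "-", "0", "yes"),
    c("repression", "0", "+", "yes"),
    c("repression", "0", "-", "yes"),
    c("repression", "0", "0", "yes"))
  data.frame(sign = df[, 1], tf = df[, 2], target = df[, 3],
             inconsistent = as.integer(df[, 4] == "no"),
             stringsAsFactors = FALSE)
}

# Independent brute-force evaluation: double loop over (target, contrast)
# re-deriving every edge verdict from the rule table and declaring a
# target inconsistent only when every incoming regulation is inconsistent.
# Deliberately naive; never calls the package's evaluation path.
brute_force_loads <- function(net, labels) {
  rules <- ternary_rule_table()
  # index the transcribed table as verdict[sign, tf+2, target+2]
  lab_idx <- c("-" = 1L, "0" = 2L, "+" = 3L)
  verdict <- array(NA_integer_, c(2, 3, 3),
                   dimnames = list(c("activation", "repression"), NULL, NULL))
  for (k in seq_len(nrow(rules)))
    verdict[rules$sign[k], lab_idx[[rules$tf[k]]],
            lab_idx[[rules$target[k]]]] <- rules$inconsistent[k]
  inter <- net$interactions
  tgts <- unique(inter$target)
  n <- ncol(labels)
  J <- matrix(0L, length(tgts), n, dimnames = list(tgts, colnames(labels)))
  for (v in tgts) {
    inc <- which(inter$target == v)
    for (i in seq_len(n)) {
      all_bad <- TRUE
      for (e in inc) {
        if (verdict[inter$sign[e], labels[inter$regulator[e], i] + 2L,
                    labels[v, i] + 2L] == 0L) {
          all_bad <- FALSE
          break
        }
      }
      J[v, i] <- as.integer(all_bad)
    }
  }
  list(J = J, global_load = sum(J), per_contrast = colSums(J))
}

# Random single-gene bipartite fixture: every target gets >= 1 regulator.
random_net <- function(n_tf, n_targets, n_edges, seed) {
  stopifnot(n_edges >= n_targets)
  set.seed(seed)
  tf <- sprintf("tf%02d", seq_len(n_tf))
  tg <- sprintf("g%03d", seq_len(n_targets))
  edges <- data.frame(regulator = sample(tf, n_targets, replace = TRUE),
                      target = tg, stringsAsFactors = FALSE)
  while (nrow(edges) < n_edges) {
    cand <- data.frame(regulator = sample(tf, 1), target = sample(tg, 1),
                       stringsAsFactors = FALSE)
    if (!any(edges$regulator == cand$regulator &
               edges$target == cand$target))
      edges <- rbind(edges, cand)
  }
  edges$sign <- sample(c("activation", "repression"), nrow(edges),
                       replace = TRUE)
  signed_grn(as.list(setNames(tf, tf)), as.list(setNames(tg, tg)), edges)
}

random_labels <- function(net, n_contrasts, seed) {
  set.seed(seed)
  ids <- c(names(net$regulators), names(net$targets))
  matrix(sample(c(-1L, 0L, 1L), length(ids) * n_contrasts, replace = TRUE),
         nrow = length(ids), dimnames = list(ids, NULL))
}

# Tiny 3-TF / 4-target network used across modules: tfC is a 2-gene
# complex, tu1 a 2-gene transcription unit; g2 has two regulators.
tiny_net <- function() {
  signed_grn(
    regulators = list(tfA = "tfA_g", tfB = "tfB_g", tfC = c("tfC_g1", "tfC_g2")),
    targets = list(g1 = "g1", g2 = "g2", g3 = "g3", tu1 = c("tu1_g1", "tu1_g2")),
    interactions = data.frame(
      regulator = c("tfA", "tfA", "tfB", "tfC", "tfC"),
      target = c("g1", "g2", "g2", "g3", "tu1"),
      sign = c("activation", "activation", "repression", "repression",
               "activation"),
      stringsAsFactors = FALSE))
}

# Compendium over the tiny network's genes: 2 experiments, deterministic
# values.
tiny_compendium <- function(seed = 1) {
  net <- tiny_net()
  genes <- network_genes(net)
  set.seed(seed)
  samples <- c("e1.ref", "e1.c1", "e1.c2", "e2.ref", "e2.c1")
  values <- matrix(rnorm(length(genes) * length(samples), 7, 1),
                   nrow = length(genes),
                   dimnames = list(genes, samples))
  meta <- data.frame(
    sample_id = samples,
    experiment_id = c("e1", "e1", "e1", "e2", "e2"),
    is_reference = c(1, 0, 0, 1, 0),
    is_perturbed = c(0, 1, 1, 0, 0))
  expression_compendium(values, meta)
}

write_lines_tmp <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
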