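test_that("ternary labeling uses strict inequalities at the threshold", {
  m <- matrix(c(-1.5, -1.0, -0.2, 0, 0.7, 1.0, 1.2), nrow = 1)
  cfg <- sign_model_config(threshold = 1)
  expect_equal(as.vector(label_vertices(m, cfg)),
               c(-1L, 0L, 0L, 0L, 0L, 0L, 1L))
  cfg0 <- sign_model_config(threshold = 0)
  expect_equal(as.vector(label_vertices(matrix(c(-0.2, 0, 0.7), 1), cfg0)),
               c(-1L, 0L, 1L))
})

test_that("binary labeling splits at zero with no unchanged state", {
  m <- matrix(c(-2, -0.01, 0, 0.01, 2), nrow = 1)
  lab <- label_vertices(m, sign_model_config(variant = "binary"))
  expect_equal(as.vector(lab), c(-1L, -1L, -1L, 1L, 1L))
})

test_that("threshold selection hits the requested changed fraction", {
  pooled <- matrix(seq(0.1, 1.0, by = 0.1), nrow = 2)
  t <- select_threshold(pooled, 0.5)
  expect_equal(t, median(seq(0.1, 1.0, by = 0.1)))
  frac <- mean(abs(pooled) > t)
  expect_gte(frac, 0.4)
  expect_lte(frac, 0.6)

  expect_equal(select_threshold(pooled, 1.0), 0)
  expect_error(select_threshold(matrix(0, 3, 3)), "all contrast values")

  set.seed(41)
  big <- matrix(rnorm(1e5), nrow = 100)
  tb <- select_threshold(big, 0.5)
  expect_equal(mean(abs(big) > tb), 0.5, tolerance = 0.02)
})

test_that("edge rule matches the transcribed ternary truth table", {
  rules <- ternary_rule_table()
  got <- edge_inconsistency(rules$sign, rules$tf, rules$target)
  expect_equal(got, rules$inconsistent)
  # spot checks straight from the rule definition
  expect_equal(edge_inconsistency("activation", "+", "+"), 0L)
  expect_equal(edge_inconsistency("activation", "+", "0"), 1L)
  expect_equal(edge_inconsistency("repression", "0", "-"), 0L)
})

test_that("binary edge rule is sign agreement, erroring on unchanged labels", {
  combos <- expand.grid(sign = c("activation", "repression"),
                        tf = c("+", "-"), target = c("+", "-"),
                        stringsAsFactors = FALSE)
  got <- edge_inconsistency_binary(combos$sign, combos$tf, combos$target)
  expected <- ifelse(combos$sign == "activation",
                     combos$tf != combos$target,
                     combos$tf == combos$target)
  expect_equal(got, as.integer(expected))
  expect_equal(sum(got), 4L)
  expect_error(edge_inconsistency_binary("activation", "0", "+"),
               "unchanged")
})

test_that("a target is inconsistent only when all incoming edges are", {
  net <- signed_grn(
    list(t1 = "t1g", t2 = "t2g"),
    list(g = "g"),
    data.frame(regulator = c("t1", "t2"), target = "g",
               sign = c("activation", "activation")))
  # contrast 1: both regulators up, target down -> both edges bad
  # contrast 2: t1 up/target down bad, but t2 unchanged -> consistent
  labels <- rbind(t1 = c(1L, 1L), t2 = c(1L, 0L), g = c(-1L, -1L))
  res <- evaluate_consistency(net, labels)
  expect_equal(unname(res$J["g", ]), c(1L, 0L))
  expect_equal(res$global_load, 1)

  single <- signed_grn(list(t1 = "t1g"), list(g = "g"),
                       data.frame(regulator = "t1", target = "g",
                                  sign = "activation"))
  lab1 <- rbind(t1 = c(1L, 0L, 1L), g = c(-1L, 1L, -1L))
  res1 <- evaluate_consistency(single, lab1)
  expect_equal(unname(res1$J["g", ]),
               unname(res1$I[1, ]))  # single-factor product
})

test_that("evaluation matches the brute-force oracle on random fixtures", {
  for (seed in 1:10) {
    net <- random_net(n_tf = 5, n_targets = 20, n_edges = 35, seed = seed)
    labels <- random_labels(net, n_contrasts = 15, seed = seed + 100)
    res <- evaluate_consistency(net, labels)
    oracle <- brute_force_loads(net, labels)
    expect_equal(res$global_load, oracle$global_load)
    expect_equal(res$J[rownames(oracle$J), ], oracle$J, ignore_attr = TRUE)
    # conservation across the three accounting routes
    expect_equal(res$global_load, sum(res$per_contrast_load))
    expect_equal(res$global_load, sum(res$vertex_table$n_inconsistent))
    # J never exceeds any incoming edge's I
    for (k in seq_len(nrow(net$interactions)))
      expect_true(all(res$J[net$interactions$target[k], ] <= res$I[k, ]))
  }
})

test_that("raising the threshold weakly reduces changed labels", {
  set.seed(9)
  m <- matrix(rnorm(500), 25)
  n_changed <- sapply(c(0, 0.2, 0.5, 1, 2), function(t)
    sum(label_vertices(m, sign_model_config(t)) != 0L))
  expect_true(all(diff(n_changed) <= 0))
})

test_that("adding an incoming edge cannot increase a target's inconsistency", {
  set.seed(5)
  for (rep in 1:5) {
    net <- random_net(4, 10, 15, seed = rep)
    labels <- random_labels(net, 10, seed = rep + 50)
    res <- evaluate_consistency(net, labels)
    # add one new edge to a random target
    inter <- net$interactions
    tgt <- sample(names(net$targets), 1)
    free <- setdiff(names(net$regulators),
                    inter$regulator[inter$target == tgt])
    if (!length(free)) next
    inter2 <- rbind(inter, data.frame(
      regulator = free[1], target = tgt, sign = "repression",
      evidence_class = NA, evidence_types = NA))
    net2 <- signed_grn(net$regulators, net$targets, inter2)
    res2 <- evaluate_consistency(net2, labels)
    expect_lte(sum(res2$J[tgt, ]), sum(res$J[tgt, ]))
  }
})

test_that("stratified summaries match hand computation", {
  net <- tiny_net()
  # labels chosen so every repression edge is inconsistent in both
  # contrasts and every activation edge is consistent
  labels <- rbind(tfA = c(0L, 0L), tfB = c(1L, 1L), tfC = c(1L, 1L),
                  g1 = c(1L, 0L), g2 = c(1L, 1L), g3 = c(0L, 0L),
                  tu1 = c(1L, 1L))
  res <- evaluate_consistency(net, labels)
  by_sign <- stratify_edges(res, net, "by_sign")
  expect_equal(by_sign$mean_inconsistency[by_sign$stratum == "repression"], 2)
  expect_equal(by_sign$mean_inconsistency[by_sign$stratum == "activation"], 0)
  expect_equal(by_sign$n_edges, c(3L, 2L))

  sr <- stratify_edges(res, net, "single_regulator_by_sign")
  # single-regulator targets: g1 (activation, 0), g3 (repression, 2),
  # tu1 (activation, 0)
  expect_equal(sr$mean_inconsistency[sr$stratum == "repression"], 2)
  expect_equal(sr$n_edges, c(2L, 1L))

  expect_error(stratify_edges(res, net, "by_evidence_class"),
               "no evidence-class")
})
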