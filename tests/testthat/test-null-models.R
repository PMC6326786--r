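test_that("profile shuffling permutes rows without changing their content", {
  set.seed(8)
  m <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("v", 1:8), NULL))
  sh <- shuffle_profiles(m, seed = 1)
  expect_equal(rownames(sh), rownames(m))
  expect_equal(dim(sh), dim(m))
  # row multiset unchanged: every original row appears exactly once
  key <- function(x) unname(apply(x, 1, paste, collapse = ","))
  expect_setequal(key(sh), key(m))
  expect_equal(sort(as.vector(sh)), sort(as.vector(m)))

  one <- matrix(1:4, 1, dimnames = list("v", NULL))
  expect_equal(shuffle_profiles(one, seed = 3), one)
})

test_that("profile shuffling is seed-deterministic and uniform over permutations", {
  m <- matrix(1:9, 3, dimnames = list(c("a", "b", "c"), NULL))
  expect_identical(shuffle_profiles(m, seed = 7), shuffle_profiles(m, seed = 7))

  draws <- vapply(1:6000, function(s)
    paste(shuffle_profiles(m, seed = s)[, 1], collapse = ""), character(1))
  counts <- table(draws)
  expect_equal(length(counts), 6L)  # all 3! permutations occur
  p <- suppressWarnings(chisq.test(counts)$p.value)
  expect_gt(p, 0.001)
})

test_that("a single successful swap exchanges exactly the two endpoints", {
  net <- signed_grn(
    list(p = "pg", r = "rg"), list(q = "q", s = "s"),
    data.frame(regulator = c("p", "r"), target = c("q", "s"),
               sign = c("activation", "repression")))
  rewired <- rewire_edges(net, rounds_factor = 10, seed = 4)
  key <- paste(rewired$interactions$regulator, rewired$interactions$target)
  if (attr(rewired, "n_swaps") %% 2 == 1) {
    expect_setequal(key, c("p s", "r q"))
    # signs travel with the regulator's outgoing stub
    expect_equal(
      rewired$interactions$sign[rewired$interactions$regulator == "p"],
      "activation")
  } else {
    expect_setequal(key, c("p q", "r s"))
  }
})

test_that("rewiring a complete bipartite graph aborts every proposal", {
  tf <- paste0("t", 1:3); tg <- paste0("g", 1:4)
  inter <- expand.grid(regulator = tf, target = tg,
                       stringsAsFactors = FALSE)
  inter$sign <- "activation"
  net <- signed_grn(as.list(setNames(paste0(tf, "_g"), tf)),
                    as.list(setNames(tg, tg)), inter)
  rewired <- rewire_edges(net, seed = 2)
  expect_equal(attr(rewired, "n_swaps"), 0L)
  expect_equal(rewired$interactions[order(rewired$interactions$regulator,
                                          rewired$interactions$target), ],
               net$interactions[order(net$interactions$regulator,
                                      net$interactions$target), ],
               ignore_attr = TRUE)
})

test_that("rewiring preserves degrees, edge count and the sign multiset", {
  net <- random_net(n_tf = 12, n_targets = 40, n_edges = 200, seed = 21)
  rewired <- rewire_edges(net, seed = 99)
  old <- net$interactions; new <- rewired$interactions
  expect_equal(nrow(new), nrow(old))
  expect_equal(table(new$regulator), table(old$regulator))
  expect_equal(table(new$target), table(old$target))
  expect_equal(table(new$sign), table(old$sign))
  expect_equal(anyDuplicated(new[, c("regulator", "target")]), 0L)
  # per-regulator sign out-profile preserved (signs follow the stub)
  expect_equal(table(new$regulator, new$sign), table(old$regulator, old$sign))
  # topology actually changed
  overlap <- mean(paste(new$regulator, new$target) %in%
                    paste(old$regulator, old$target))
  expect_lt(overlap, 1)
  expect_identical(rewire_edges(net, seed = 99)$interactions, new)
})

test_that("null distributions collect one load per repetition", {
  net <- tiny_net()
  comp <- tiny_compendium()
  vex <- vertex_expression(comp, net)
  cs <- compute_contrasts(vex, comp$sample_meta)
  cfg <- sign_model_config(select_threshold(cs))

  nd <- null_distribution(net, cs, cfg, "shuffle_profiles",
                          repetitions = 1, seed = 5)
  expect_length(nd$loads, 1)
  expect_equal(nd$summary[["median"]], nd$loads[1])

  # swap-saturated topology: every rewired replicate equals the observed
  tf <- paste0("t", 1:2); tg <- paste0("g", 1:3)
  inter <- expand.grid(regulator = tf, target = tg,
                       stringsAsFactors = FALSE)
  inter$sign <- "repression"
  complete <- signed_grn(as.list(setNames(paste0(tf, "_g"), tf)),
                         as.list(setNames(tg, tg)), inter)
  genes <- network_genes(complete)
  set.seed(12)
  vals <- matrix(rnorm(length(genes) * 4, 7), length(genes),
                 dimnames = list(genes, paste0("s", 1:4)))
  meta <- data.frame(sample_id = paste0("s", 1:4),
                     experiment_id = c("e1", "e1", "e2", "e2"),
                     is_reference = c(1, 0, 1, 0),
                     is_perturbed = c(0, 1, 0, 1))
  cvex <- vertex_expression(vals, complete)
  ccs <- compute_contrasts(cvex, meta)
  ccfg <- sign_model_config(select_threshold(ccs))
  ndr <- null_distribution(complete, ccs, ccfg, "rewire_edges",
                           repetitions = 5, seed = 6)
  expect_true(all(ndr$loads == ndr$observed_load))
  expect_equal(ndr$empirical_p, 1)
})
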