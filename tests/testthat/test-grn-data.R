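test_that("regulondb dialect keeps only signed effects and counts drops", {
  path <- write_lines_tmp(c(
    "# RegulonDB-style export",
    "regulator\ttarget\teffect\tevidence_types\tevidence_class",
    "ArcA\tsodA\t+\tBPP\tstrong",
    "ArcA\tfumC\t-\tGEA\tweak",
    "Fnr\tsodA\t+-\tGEA\tweak",
    "Crp\tlacZ\t?\t\t",
    "Crp\tsodA\t-\tSM\tstrong"))
  net <- read_network(path, dialect = "regulondb")
  expect_equal(nrow(net$interactions), 3)
  expect_equal(attr(net, "dropped"),
               c(dual = 1L, unknown = 1L, conflicting = 0L))
  expect_setequal(net$interactions$sign[net$interactions$regulator == "ArcA"],
                  c("activation", "repression"))
  expect_equal(
    net$interactions$evidence_class[net$interactions$regulator == "Crp"],
    "strong")
})

test_that("conflicting signs for a pair are dropped as dual evidence", {
  path <- write_lines_tmp(c(
    "regulator\ttarget\teffect",
    "ArcA\tsodA\t+",
    "ArcA\tsodA\t-",
    "Fnr\tsodA\t+"))
  net <- read_network(path, dialect = "regulondb")
  expect_equal(nrow(net$interactions), 1)
  expect_equal(attr(net, "dropped")[["conflicting"]], 2L)
})

test_that("duplicate rows collapse to one interaction with merged evidence", {
  path <- write_lines_tmp(c(
    "regulator\ttarget\tsign\tevidence",
    "tfA\tg1\t+\tBPP",
    "tfA\tg2\t+\t",
    "tfB\tg1\t-\tSM",
    "tfA\tg1\t+\tGEA",
    "tfB\tg3\t-\t"))
  net <- read_network(path, dialect = "simple")
  expect_equal(nrow(net$interactions), 4)
  merged <- net$interactions$evidence_types[
    net$interactions$regulator == "tfA" & net$interactions$target == "g1"]
  expect_equal(merged, "BPP,GEA")
})

test_that("empty interaction table yields an empty network without drops", {
  path <- write_lines_tmp(c("# only comments", ""))
  net <- read_network(path, dialect = "simple")
  expect_s3_class(net, "signed_grn")
  expect_equal(nrow(net$interactions), 0)
  expect_true(all(attr(net, "dropped") == 0))
})

test_that("parse errors name the offending line", {
  path <- write_lines_tmp(c(
    "regulator\ttarget\tsign",
    "tfA\tg1\t+",
    "tfB only-two-fields"))
  expect_error(read_network(path, dialect = "simple"), "line 3")
  path2 <- write_lines_tmp(c(
    "regulator\ttarget\teffect",
    "tfA\tg1\tmaybe"))
  expect_error(read_network(path2, dialect = "regulondb"), "line 2")
})

test_that("a target flagged as TU must be declared in the annotations", {
  tu <- write_lines_tmp(c("tu1\tga,gb"))
  path <- write_lines_tmp(c(
    "regulator\ttarget\teffect\ttarget_type",
    "tfA\ttu1\t+\ttu",
    "tfA\ttu9\t-\ttu"))
  expect_error(read_network(path, tu_annotations = tu,
                            dialect = "regulondb"),
               "undeclared TU.*tu9")
})

test_that("simple-dialect write/read round-trips the network", {
  path <- write_lines_tmp(c(
    "regulator\ttarget\tsign\tevidence",
    "tfA\tg1\t+\tBPP",
    "tfA\ttu1\t-\t",
    "cpxAB\tg2\t+\tSM,GEA"))
  tu <- write_lines_tmp("tu1\ttu1_g1,tu1_g2")
  cx <- write_lines_tmp("cpxAB\tcpxA,cpxB")
  net <- read_network(path, tu_annotations = tu, complex_annotations = cx,
                      dialect = "simple")
  out_i <- tempfile(); out_t <- tempfile(); out_c <- tempfile()
  write_network(net, out_i, out_t, out_c)
  back <- read_network(out_i, tu_annotations = out_t,
                       complex_annotations = out_c, dialect = "simple")
  expect_equal(back$regulators, net$regulators)
  expect_equal(back$targets, net$targets)
  expect_equal(
    back$interactions[order(back$interactions$regulator,
                            back$interactions$target), ],
    net$interactions[order(net$interactions$regulator,
                           net$interactions$target), ],
    ignore_attr = TRUE)
})

test_that("expression filtering removes vertices with unmeasured members", {
  net <- tiny_net()
  measured <- setdiff(network_genes(net), "tfC_g2")
  filtered <- filter_by_expression(net, measured)
  # the complex loses a member gene, so it and both its edges disappear
  expect_false("tfC" %in% names(filtered$regulators))
  expect_false(any(filtered$interactions$regulator == "tfC"))
  expect_equal(nrow(filtered$interactions), 3)
  expect_setequal(names(filtered$targets), c("g1", "g2", "g3", "tu1"))
  rem <- attr(filtered, "removed")
  expect_equal(rem[["regulators"]], 1 / 3)
  expect_equal(rem[["interactions"]], 2 / 5)
  # surviving members are all measured
  members <- c(unlist(filtered$regulators), unlist(filtered$targets))
  expect_true(all(members %in% measured))
})

test_that("filtering with all genes measured is the identity", {
  net <- tiny_net()
  filtered <- filter_by_expression(net, network_genes(net))
  expect_equal(filtered$interactions, net$interactions)
  expect_equal(names(filtered$targets), names(net$targets))
  expect_true(all(attr(filtered, "removed") == 0))
})

test_that("single-regulator targets are exactly those with in-degree 1", {
  star <- signed_grn(
    list(hub = "hub_g"),
    as.list(setNames(letters[1:5], letters[1:5])),
    data.frame(regulator = "hub", target = letters[1:5],
               sign = "activation"))
  expect_setequal(single_regulator_targets(star), letters[1:5])

  net <- tiny_net()  # g2 has two regulators
  expect_setequal(single_regulator_targets(net), c("g1", "g3", "tu1"))

  rnd <- random_net(8, 30, 60, seed = 11)
  # independent edge counting
  expected <- names(Filter(function(n) n == 1,
                           table(rnd$interactions$target)))
  expect_setequal(single_regulator_targets(rnd), expected)
})

test_that("vertex id collisions across the bipartition are rejected", {
  expect_error(
    signed_grn(list(x = "x"), list(x = "x"),
               data.frame(regulator = "x", target = "x",
                          sign = "activation")),
    "both sides")
})
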