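test_that("alteration subnetworks separate connected and isolated genes", {
  net <- fi_network(fi_table(c("A", "B", "X"), c("B", "C", "Y")))
  r <- induce_alteration_subnetwork(net, c("A", "B", "Q"))
  expect_setequal(igraph::V(r$subnetwork)$name, c("A", "B"))
  expect_equal(r$missing, "Q")
  r2 <- induce_alteration_subnetwork(net, c("A", "C"))  # no mutual FI
  expect_setequal(r2$isolated, c("A", "C"))
  expect_equal(igraph::vcount(r2$subnetwork), 0L)
  r3 <- induce_alteration_subnetwork(net, igraph::V(net)$name)
  expect_equal(igraph::ecount(r3$subnetwork), igraph::ecount(net))
})

test_that("edge-betweenness modules recover planted structure", {
  g <- two_clique_bridge(5)
  mp <- girvan_newman_modules(g)
  expect_equal(length(mp$modules), 2L)
  expect_setequal(mp$modules[["0"]], sprintf("A%02d", 1:5))
  expect_setequal(mp$modules[["1"]], sprintf("B%02d", 1:5))

  # disconnected input: the components are separate modules
  g2 <- igraph::graph_from_edgelist(rbind(c("A", "B"), c("B", "C"),
                                          c("X", "Y")), directed = FALSE)
  mp2 <- girvan_newman_modules(g2)
  expect_true(any(vapply(mp2$modules, setequal, TRUE, c("X", "Y"))))

  # edgeless input: one module per node
  g3 <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(g3)$name <- c("A", "B", "C")
  expect_equal(lengths(girvan_newman_modules(g3)$modules),
               c("0" = 1L, "1" = 1L, "2" = 1L))
})

test_that("module partitions are disjoint, covering and size-ordered", {
  set.seed(8)
  g <- igraph::sample_gnp(40, 0.12)
  igraph::V(g)$name <- sprintf("N%02d", 1:40)
  mp <- girvan_newman_modules(g)
  expect_setequal(unlist(mp$modules), igraph::V(g)$name)
  expect_equal(anyDuplicated(unlist(mp$modules)), 0L)
  expect_true(all(diff(lengths(mp$modules)) <= 0))
  expect_equal(names(mp$modules), as.character(seq_along(mp$modules) - 1L))
  # repeated runs are identical (deterministic tie rule)
  expect_identical(mp$membership, girvan_newman_modules(g)$membership)
})

test_that("the sample-module matrix marks per-module alterations", {
  part <- module_partition(list(c("A", "B", "C"), c("D", "E")))
  cohort <- list(s1 = c("A", "D"), s2 = c("B"), s3 = c("Z"))
  mat <- sample_module_matrix(cohort, part)
  expect_equal(mat, matrix(c(1L, 1L, 0L, 1L, 0L, 0L), nrow = 3,
                           dimnames = list(c("s1", "s2", "s3"), c("0", "1"))))
})

test_that("co-hit fractions and boundary p-values behave", {
  part <- module_partition(list(c("A", "B"), c("C", "D")))
  cohort <- list(s1 = c("A"), s2 = c("A", "C"))
  ch <- cohit_test(cohort, part, 0, 1, n_perm = 200, seed = 1)
  expect_equal(ch$fraction, 0.5)

  # every sample hits both modules: observed is maximal
  full <- list(s1 = c("A", "C"), s2 = c("B", "D"))
  ch2 <- cohit_test(full, part, 0, 1, n_perm = 200, seed = 1)
  expect_equal(ch2$fraction, 1.0)

  # a sample with a single in-universe gene can never co-hit: observed 0 is
  # below or equal to every permuted fraction
  low <- list(s1 = "A", s2 = "C")
  ch3 <- cohit_test(low, part, 0, 1, n_perm = 200, seed = 1)
  expect_equal(ch3$fraction, 0)
  expect_equal(ch3$p_value, 1.0)
})

test_that("binary sample distance matches the asymmetric-binary convention", {
  mat <- rbind(a = c(1, 1, 0), b = c(1, 0, 1), c = c(0, 0, 0),
               d = c(0, 0, 0), e = c(1, 1, 0))
  d <- as.matrix(binary_sample_dist(mat))
  expect_equal(d["a", "b"], 2 / 3)
  expect_equal(d["c", "d"], 0)         # all-zero pair convention
  expect_equal(d["a", "e"], 0)         # identical rows

  # against the standard implementation (defined except for all-zero pairs)
  set.seed(9)
  m2 <- matrix(rbinom(60, 1, 0.5), nrow = 6)
  m2[rowSums(m2) == 0, 1] <- 1
  expect_equal(as.matrix(binary_sample_dist(m2)),
               as.matrix(stats::dist(m2, method = "binary")),
               ignore_attr = TRUE)
})

test_that("sample clustering merges identical rows first", {
  mat <- rbind(s1 = c(1, 1, 0, 0), s2 = c(1, 1, 0, 0), s3 = c(0, 0, 1, 1),
               s4 = c(0, 0, 1, 0))
  cl <- cluster_samples(mat, k = 2)
  expect_equal(cl$assignment[["s1"]], cl$assignment[["s2"]])
  expect_false(cl$assignment[["s1"]] == cl$assignment[["s3"]])
  expect_error(cluster_samples(mat[1, , drop = FALSE]), "two samples")
})

test_that("contingency tests give exact one-sided enrichment p-values", {
  expect_equal(contingency_test(matrix(c(1, 0, 0, 1), 2), "hypergeometric"), 0.5)
  expect_equal(contingency_test(matrix(c(5, 0, 0, 5), 2), "hypergeometric"),
               1 / choose(10, 5))
  expect_gte(contingency_test(matrix(c(3, 3, 3, 3), 2), "fisher"), 0.5)
  # one-sided Fisher and the hypergeometric tail agree
  for (i in 1:5) {
    set.seed(i)
    tb <- matrix(rpois(4, 4), 2)
    if (sum(tb) == 0) next
    expect_equal(contingency_test(tb, "fisher"),
                 contingency_test(tb, "hypergeometric"), tolerance = 1e-12)
  }
  expect_error(contingency_test(matrix(0, 2, 2)), "all-zero")
})

test_that("enrichment handles boundary modules and unknown terms", {
  uni <- sprintf("G%02d", 1:20)
  ann <- list(t_half = uni[1:10], t_none = c("ZZ1", "ZZ2"))
  expect_warning(res <- enrich_annotations(uni[11:14], ann, uni, n_perm = 50,
                                           seed = 2),
                 "skipped")
  expect_equal(res$p_value[res$term == "t_half"], 1)  # k = 0 gives p = 1

  # module = universe: the hit count equals the annotated count, the p-value
  # is the exact tail at full annotation and the FDR stays well-defined
  res2 <- suppressWarnings(
    enrich_annotations(uni, ann, uni, n_perm = 50, seed = 2))
  expect_equal(res2$k[res2$term == "t_half"], 10L)
  expect_equal(res2$p_value[res2$term == "t_half"],
               sum(dbinom(10:20, 20, 0.5)), tolerance = 1e-12)
  expect_true(all(res2$fdr >= 0 & res2$fdr <= 1))
  expect_error(enrich_annotations(c("NOPE"), ann, uni), "subset")
})
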