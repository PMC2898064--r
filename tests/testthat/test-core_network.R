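test_that("average shortest path matches hand enumeration", {
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- sprintf("K%d", 1:5)
  expect_equal(as.numeric(average_shortest_path(k5, c("K1", "K4"))), 1.0)

  p4 <- path_graph(c("a", "b", "c", "d"))
  asp <- average_shortest_path(p4, c("a", "b", "c", "d"))
  expect_equal(as.numeric(asp), 10 / 6)
  expect_equal(attr(asp, "n_used"), 4L)

  # genes split across components cannot be averaged
  g <- igraph::graph_from_edgelist(rbind(c("a", "b"), c("a", "c"), c("x", "y")),
                                   directed = FALSE)
  expect_error(average_shortest_path(g, c("b", "y")), "largest connected")
  # ... but genes outside the largest component are excluded and counted
  asp2 <- average_shortest_path(g, c("b", "c", "y"))
  expect_equal(attr(asp2, "n_excluded"), 1L)
})

test_that("adding edges never increases pairwise distances", {
  set.seed(12)
  for (i in 1:5) {
    g <- random_connected_graph(25, 0.12)
    extra <- t(combn(igraph::V(g)$name, 2))
    extra <- extra[sample.int(nrow(extra), 10), ]
    g2 <- igraph::add_edges(g, t(extra))
    genes <- sample(igraph::V(g)$name, 8)
    d1 <- igraph::distances(g, genes, genes, weights = NA)
    d2 <- igraph::distances(g2, genes, genes, weights = NA)
    expect_true(all(d2 <= d1))
    expect_lte(as.numeric(average_shortest_path(g2, genes)),
               as.numeric(average_shortest_path(g, genes)))
  }
})

test_that("recurrence curves tabulate observed and null sharing", {
  # each gene in exactly one sample: nothing recurs
  c1 <- list(s1 = c("A", "B"), s2 = c("C"), s3 = c("D"))
  r1 <- recurrence_curve(c1, c("A", "B", "C", "D"), n_perm = 20, seed = 1)
  expect_equal(r1$frac_ge[r1$s == 2], 0)
  expect_equal(r1$frac_ge[r1$s == 1], 1)

  # identical samples: everything recurs at s = 2
  c2 <- list(s1 = c("A", "B"), s2 = c("A", "B"))
  r2 <- recurrence_curve(c2, c("A", "B", "C"), n_perm = 20, seed = 1)
  expect_equal(r2$frac_exact, c(0, 1))

  # three-sample toy cohort against exhaustive tabulation
  c3 <- list(s1 = c("A", "B", "C"), s2 = c("A", "B"), s3 = c("A", "X"))
  r3 <- recurrence_curve(c3, c("A", "B", "C", "X", "Y"), n_perm = 20, seed = 1)
  expect_equal(r3$n_genes, c(2L, 1L, 1L))      # C,X once; B twice; A thrice
  expect_equal(r3$frac_exact, c(2, 1, 1) / 4)
  expect_equal(r3$frac_ge, c(4, 2, 1) / 4)
  expect_error(recurrence_curve(c3, c("A", "B")), "universe")
})

test_that("recurrence null preserves per-sample counts", {
  set.seed(13)
  uni <- sprintf("G%02d", 1:40)
  cohort <- lapply(setNames(1:6, paste0("s", 1:6)),
                   function(i) sample(uni, 5))
  r <- recurrence_curve(cohort, uni, n_perm = 300, seed = 2)
  # observed cohort is itself a draw from the null: fractions sit inside the
  # null envelope at every level
  expect_true(all(r$frac_ge >= r$null_frac_ge_lo - 1e-9 &
                    r$frac_ge <= r$null_frac_ge_hi + 1e-9))
})

test_that("shortest-path gene clustering selects the dense planted cluster", {
  # an 8-clique and a 2-clique, far apart through a long path
  a <- sprintf("A%d", 1:8)
  b <- c("B1", "B2")
  edges <- rbind(t(combn(a, 2)), b,
                 c("A1", "L1"), c("L1", "L2"), c("L2", "L3"), c("L3", "B1"))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  cl <- cluster_genes_shortest_path(g, c(a, b), coverage = 0.7)
  expect_setequal(as.character(cl), a)          # 8 of 10 exceeds 70%

  # mutually adjacent genes: the first qualifying cluster is everything
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- sprintf("K%d", 1:5)
  expect_setequal(as.character(cluster_genes_shortest_path(k5, sprintf("K%d", 1:5))),
                  sprintf("K%d", 1:5))

  # coverage 1 can only be met by the root
  expect_warning(root <- cluster_genes_shortest_path(g, c(a, b), coverage = 1),
                 "root")
  expect_setequal(as.character(root), c(a, b))
  expect_gte(attr(cl, "coverage_achieved"), 0.7)
})

test_that("linker subnetworks connect candidates through shortest paths", {
  p3 <- path_graph(c("A", "B", "C"))
  core <- build_linker_subnetwork(p3, c("A", "C"))
  expect_equal(core$linkers, "B")
  expect_true(igraph::is_connected(core$subnetwork))

  # already-adjacent candidates need no linkers
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- sprintf("K%d", 1:4)
  expect_equal(length(build_linker_subnetwork(k4, c("K1", "K3"))$linkers), 0L)

  # roles distinguish shared candidates from linkers
  core2 <- build_linker_subnetwork(p3, c("A", "C"), shared = "A")
  expect_equal(core2$roles$role[core2$roles$gene == "A"], "shared_candidate")
  expect_equal(core2$roles$role[core2$roles$gene == "B"], "linker")
})

test_that("linker subnetworks stay connected and cover candidates on random graphs", {
  set.seed(14)
  for (i in 1:10) {
    g <- random_connected_graph(18, 0.14)
    genes <- sample(igraph::V(g)$name, sample(3:6, 1))
    core <- build_linker_subnetwork(g, genes)
    expect_true(igraph::is_connected(core$subnetwork))
    expect_true(all(genes %in% core$nodes))
    expect_equal(intersect(core$linkers, core$candidates), character(0))
  }
})

test_that("degree bins hold enough eligible nodes and match candidate counts", {
  set.seed(15)
  g <- igraph::sample_pa(120, m = 2, directed = FALSE)
  igraph::V(g)$name <- sprintf("H%03d", 1:120)
  deg <- igraph::degree(g)
  genes <- names(sort(deg, decreasing = TRUE))[1:12]   # hub-biased set
  bins <- finet:::.degree_bins(deg[genes], deg, min_bin_size = 5)
  expect_equal(sum(vapply(bins, `[[`, 0L, "count")), 12L)
  for (b in bins) {
    eligible <- sum(deg >= b$lo & deg <= b$hi)
    expect_gte(eligible, max(5, b$count))
  }
})
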