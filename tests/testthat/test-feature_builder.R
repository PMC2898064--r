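test_that("pair-list records expand by matrix expansion with the interactor cap", {
  f <- withr::local_tempfile(lines = c(
    "A\tB",
    "A\tB\tC",            # 3-interactor record: all three pairs
    "D\tE\tF\tG\tH",      # 5 interactors: dropped
    "Z\tZ"))              # self pair: contributes nothing
  pairs <- load_interactions(f)
  expect_setequal(pair_keys(pairs[, 1], pairs[, 2]),
                  c("A B", "A C", "B C"))
  # with a higher cap the 5-interactor record contributes its C(5,2) pairs
  pairs10 <- load_interactions(f, max_interactors = 10)
  expect_equal(nrow(pairs10), 3 + choose(5, 2))
  expect_error(load_interactions(withr::local_tempfile(lines = "lonely")),
               "line 1")
})

test_that("PSI-MI TAB subset parses prefixes and reassembles n-ary records", {
  mitab_line <- function(a, b, id) {
    paste(c(a, b, rep("-", 11), id, "-"), collapse = "\t")
  }
  f <- withr::local_tempfile(lines = c(
    mitab_line("uniprotkb:P10000", "uniprotkb:P20000", "intact:EBI-1"),
    # one co-IP record with 5 participants, spoke-expanded over one id
    mitab_line("uniprotkb:P30000", "uniprotkb:P40000", "intact:EBI-2"),
    mitab_line("uniprotkb:P30000", "uniprotkb:P50000", "intact:EBI-2"),
    mitab_line("uniprotkb:P30000", "uniprotkb:P60000", "intact:EBI-2"),
    mitab_line("uniprotkb:P30000", "uniprotkb:P70000", "intact:EBI-2"),
    mitab_line("uniprotkb:P80000-2", "uniprotkb:P90000", "-")))
  pairs <- load_interactions(f)
  keys <- pair_keys(pairs[, 1], pairs[, 2])
  expect_true("P10000 P20000" %in% keys)
  expect_true("P80000 P90000" %in% keys)        # isoform suffix stripped
  expect_false(any(grepl("P30000", keys)))      # 5-interactor record dropped
  # with a relaxed cap the co-IP record matrix-expands to C(5,2) pairs
  pairs10 <- load_interactions(f, max_interactors = 10)
  expect_equal(nrow(pairs10), 2 + choose(5, 2))
})

test_that("interolog projection expands ortholog images without self pairs", {
  map <- data.frame(from = c("x", "x", "y"), to = c("H1", "H2", "H2"))
  p <- project_interologs(cbind("x", "y"), map)
  expect_equal(pair_keys(p[, 1], p[, 2]), "H1 H2")  # (H2,H2) excluded
  map1 <- data.frame(from = c("x", "y"), to = c("H1", "H2"))
  p1 <- project_interologs(cbind("x", "y"), map1)
  expect_equal(pair_keys(p1[, 1], p1[, 2]), "H1 H2")
  expect_equal(nrow(project_interologs(cbind("x", "y"),
                                       data.frame(from = "z", to = "H9"))), 0L)
})

test_that("feature matrix is closed-world, symmetric and monotone", {
  cands <- rbind(c("A", "B"), c("C", "D"))
  m0 <- build_feature_matrix(cands)
  expect_true(all(m0[, FI_FEATURES] == FALSE))

  m1 <- build_feature_matrix(cands, sources = list(human_ppi = cbind("B", "A")))
  expect_equal(m1$human_ppi, c(TRUE, FALSE))     # pair order irrelevant
  expect_equal(m1, build_feature_matrix(cands[, 2:1],
                                        sources = list(human_ppi = cbind("A", "B"))))

  # enlarging a source never flips a feature to FALSE
  m2 <- build_feature_matrix(cands, sources = list(
    human_ppi = rbind(c("B", "A"), c("C", "D"), c("X", "Y"))))
  expect_true(all(m2$human_ppi >= m1$human_ppi))
  expect_error(build_feature_matrix(rbind(c("A", "A"))), "distinct")
})

test_that("domain evidence marks pairs with interacting domains", {
  domains <- list(
    protein_domains = data.frame(protein = c("A", "B", "C"),
                                 domain = c("d1", "d2", "d3")),
    domain_pairs = data.frame(a = "d1", b = "d2"))
  m <- build_feature_matrix(rbind(c("A", "B"), c("A", "C")), domains = domains)
  expect_equal(m$domain_interaction, c(TRUE, FALSE))
})

test_that("GO BP sharing respects the breadth filter and exclusions", {
  # ten annotated proteins; a specific term shared by A and B passes the
  # 25% breadth filter, a term annotating six of ten does not
  bg <- sprintf("Q%02d", 1:8)
  go <- rbind(
    data.frame(protein = c("A", "B"), term = "GOBP:SPEC", aspect = "P"),
    data.frame(protein = c("A", "B", bg[1:4]), term = "GOBP:BROAD", aspect = "P"),
    data.frame(protein = bg, term = paste0("GOBP:U", 1:8), aspect = "P"))
  m <- build_feature_matrix(rbind(c("A", "B"), c("A", bg[1])), go_bp = go)
  expect_equal(m$go_bp_shared, c(TRUE, FALSE))  # broad term never counts

  go_spec_only <- go[go$term != "GOBP:SPEC", ]
  m2 <- build_feature_matrix(rbind(c("A", "B")), go_bp = go_spec_only)
  expect_false(m2$go_bp_shared)

  # the explicit exclusion list (e.g. the BP root) also suppresses sharing
  m3 <- build_feature_matrix(rbind(c("A", "B")), go_bp = go,
                             go_bp_exclude = "GOBP:SPEC")
  expect_false(m3$go_bp_shared)
})

test_that("odds-ratio arithmetic and screening behave as expected", {
  expect_equal(finet:::.odds_ratio_2x2(20, 5, 5, 20), 16.0)
  expect_equal(finet:::.odds_ratio_2x2(10, 0, 5, 20),
               (10.5 * 20.5) / (0.5 * 5.5))  # continuity correction

  # independence: a random 'evidence' set over the reference universe gives
  # OR around 1
  set.seed(5)
  uni <- sprintf("P%03d", 1:200)
  ref_pairs <- t(combn(uni, 2))
  ref <- ref_pairs[sample.int(nrow(ref_pairs), 800), ]
  feat <- ref_pairs[sample.int(nrow(ref_pairs), 800), ]
  or_ind <- odds_ratio(feat, ref, n_perm = 20, seed = 9)
  expect_lt(abs(log(or_ind$odds_ratio)), log(2))

  # evidence nested inside a reference set sparse over its universe gives a
  # large OR (control pairs rarely touch the evidence set)
  or_sub <- odds_ratio(ref[1:100, ], ref, n_perm = 10, seed = 9)
  expect_gt(or_sub$odds_ratio, 5)
  expect_equal(or_sub$n_permutations, 10)
})

test_that("feature odds ratios rank by planted evidence contrast", {
  world <- default_world()
  fs <- default_sources()
  contrast <- fs$q_pos / fs$q_neg
  ors <- vapply(FI_FEATURES, function(f) {
    odds_ratio(fs$truth[[f]], world$reference_fis, n_perm = 20,
               seed = 101)$odds_ratio
  }, numeric(1))
  expect_equal(names(which.max(ors)), names(which.max(contrast)))
})
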