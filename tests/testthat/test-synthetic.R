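test_that("world generation is a pure function of its spec", {
  s <- world_spec(n_proteins = 80, n_pathways = 6, seed = 5)
  w1 <- gen_pathway_world(s)
  w2 <- gen_pathway_world(s)
  expect_identical(w1$reference_fis, w2$reference_fis)
  expect_identical(w1$compartments, w2$compartments)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_pathway_tsv(w1$pathways, f1)
  write_pathway_tsv(w2$pathways, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical on re-run

  expect_equal(nrow(gen_pathway_world(
    world_spec(n_proteins = 80, n_pathways = 0, seed = 5))$reference_fis), 0L)
})

test_that("the reference FI set round-trips through extraction", {
  w <- small_world()
  expect_equal(build_pathway_fi_set(w$pathways), w$reference_fis)
})

test_that("evidence generation realizes the planted per-feature rates", {
  w <- small_world()
  fs <- gen_feature_sources(w, seed = 6)
  planted <- pair_keys(w$reference_fis$protein_a, w$reference_fis$protein_b)
  n_bg <- choose(length(w$proteins), 2) - length(planted)
  for (f in c("human_ppi", "go_bp_shared", "worm_interolog")) {
    q <- fs$q_pos[[f]]
    hit <- mean(planted %in% fs$truth[[f]])
    expect_lt(abs(hit - q), 4 * sqrt(q * (1 - q) / length(planted)))
    qn <- fs$q_neg[[f]]
    n_flag_bg <- sum(!(fs$truth[[f]] %in% planted))
    expect_lt(abs(n_flag_bg / n_bg - qn), 4 * sqrt(qn * (1 - qn) / n_bg))
  }
})

test_that("interolog sources recover their planted human pairs by projection", {
  fs <- gen_feature_sources(small_world(), seed = 6)
  for (f in c("fly_interolog", "worm_interolog", "yeast_interolog")) {
    proj <- project_interologs(fs$species[[f]]$pairs,
                               fs$species[[f]]$ortholog_map)
    expect_setequal(pair_keys(proj[, 1], proj[, 2]), fs$truth[[f]])
  }
})

test_that("the feature matrix reproduces the generator's truth assignments", {
  w <- small_world()
  fs <- gen_feature_sources(w, seed = 6)
  set.seed(7)
  planted <- pair_keys(w$reference_fis$protein_a, w$reference_fis$protein_b)
  some_bg <- pair_keys(sample(w$proteins, 200, replace = TRUE),
                       sample(w$proteins, 200, replace = TRUE))
  some_bg <- setdiff(some_bg, planted)
  keys <- unique(c(planted, some_bg))
  keys <- keys[!grepl("^(\\S+) \\1$", keys)]
  cands <- finet:::split_pair_keys(keys)
  feats <- build_feature_matrix(cands, resolve_feature_sources(fs),
                                go_bp = fs$go_bp, domains = fs$domains)
  for (f in FI_FEATURES) {
    expect_identical(feats[[f]], keys %in% fs$truth[[f]])
  }
})

test_that("degenerate evidence rates drive the classifier to the extremes", {
  # one perfectly separating feature: downstream AUC reaches 1
  s <- world_spec(n_proteins = 80, n_pathways = 8,
                  q_pos = setNames(c(1, rep(0.2, 8)), FI_FEATURES),
                  q_neg = setNames(c(1e-9, rep(0.05, 8)), FI_FEATURES),
                  seed = 9)
  w <- gen_pathway_world(s)
  fs <- gen_feature_sources(w)
  planted <- pair_keys(w$reference_fis$protein_a, w$reference_fis$protein_b)
  pos <- build_feature_matrix(finet:::split_pair_keys(planted),
                              resolve_feature_sources(fs), go_bp = fs$go_bp,
                              domains = fs$domains)
  uni <- unique(c(w$reference_fis$protein_a, w$reference_fis$protein_b))
  neg_pairs <- sample_negative_pairs(uni, planted, 10 * length(planted),
                                     seed = 10)
  neg <- build_feature_matrix(neg_pairs, resolve_feature_sources(fs),
                              go_bp = fs$go_bp, domains = fs$domains)
  m <- train_nbc(pos, neg, prior = compute_prior(length(planted), length(uni)))
  expect_equal(evaluate_roc(m, pos, neg)$auc, 1.0)
})

test_that("cohorts realize planted hit probabilities and passenger load", {
  uni <- sprintf("G%03d", 1:200)
  mods <- list(uni[1:12], uni[13:24])

  # deterministic extremes
  all_hit <- gen_cohort(uni, cohort_spec(mods, hit_prob = 1,
                                         passenger_rate = 0, n_samples = 10,
                                         seed = 3))
  expect_true(all(vapply(all_hit, function(g)
    any(g %in% mods[[1]]) && any(g %in% mods[[2]]), TRUE)))
  expect_true(all(lengths(all_hit) > 0))

  # planted hit fraction within binomial error of the specification
  coh <- gen_cohort(uni, cohort_spec(mods, hit_prob = 0.6, passenger_rate = 0,
                                     n_samples = 400, seed = 4))
  hit0 <- mean(vapply(coh, function(g) any(g %in% mods[[1]]), TRUE))
  expect_lt(abs(hit0 - 0.6), 4 * sqrt(0.6 * 0.4 / 400))

  # determinism and the non-empty invariant under pure noise
  c1 <- gen_cohort(uni, cohort_spec(list(), passenger_rate = 2, n_samples = 30,
                                    seed = 5))
  c2 <- gen_cohort(uni, cohort_spec(list(), passenger_rate = 2, n_samples = 30,
                                    seed = 5))
  expect_identical(c1, c2)
  expect_true(all(lengths(c1) > 0))
  expect_error(gen_cohort(uni[1:5], cohort_spec(list(c("NOPE")))), "subsets")
})
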