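#' Default pipeline configuration
#'
#' A run configuration is a plain named list; [run_pipeline()] merges the
#' user's configuration over these defaults. File-name entries are relative
#' to `out_dir`.
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(out_dir = "finet_run",
       seed = 1,
       world = list(),                 # overrides for world_spec()
       max_interactors = 4,
       ratio = 10,                     # negatives per positive
       threshold = 0.5,
       holdout_fraction = 0.25,        # pathways held out for ROC evaluation
       go_bp_max_frac = 0.25,
       go_bp_exclude = character(0),
       n_perm = 1000,
       cohort = list(),                # overrides for cohort_spec()
       cluster_k = 5,
       coverage = 0.70,
       min_recurrence = 2)
}

#' Read a pipeline configuration file (YAML or JSON)
#'
#' @param path file path; format chosen by extension (`.json` vs
#'   `.yml`/`.yaml`).
#' @return named configuration list merged over [default_config()].
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  utils::modifyList(default_config(), cfg)
}

.path_in <- function(config, name) file.path(config$out_dir, name)

.need_file <- function(path, stage, produced_by) {
  if (!file.exists(path)) {
    stop("stage '", stage, "' needs ", path,
         " - run the '", produced_by, "' stage first")
  }
  path
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

# append stage record counts to the run manifest
.update_manifest <- function(config, stage, records) {
  mpath <- .path_in(config, "manifest.json")
  manifest <- if (file.exists(mpath)) {
    jsonlite::read_json(mpath, simplifyVector = TRUE)
  } else {
    list(package = "finet",
         version = as.character(utils::packageVersion("finet")),
         config = config[setdiff(names(config), "out_dir")],
         stages = list())
  }
  manifest$stages[[stage]] <- records
  .write_json(manifest, mpath)
}

#' Run the FI-network pipeline
#'
#' Chains the stages of the two workflows (network construction, then cancer
#' cohort analysis) over a run directory. Stages:
#'
#' * `simulate` - generate the synthetic world and write every input file
#'   (pathway TSV, per-feature evidence, annotation tables, cohort);
#' * `extract` - pathway FI extraction;
#' * `features` - candidate pairs and the nine-feature matrix;
#' * `train` - NBC training on a pathway split, ROC on the held-out part;
#' * `predict` - score candidates, keep those at or above the threshold;
#' * `merge` - merged network, statistics, CC-sharing check;
#' * `modules` - induced alteration subnetwork, edge-betweenness modules,
#'   sample-module matrix, co-hit test, sample clustering;
#' * `core` - recurrence curve, shortest-path gene cluster, ASP permutation
#'   tests, linker subnetwork.
#'
#' Every stage is a pure function of the run directory contents and the
#' configuration (all randomness is seeded from `config$seed`), so rerunning
#' a stage reproduces its outputs.
#'
#' @param config configuration list (merged over [default_config()]) or the
#'   path of a YAML/JSON configuration file.
#' @param stages character vector of stage names, in order.
#' @return the configuration, invisibly.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("simulate", "extract", "features",
                                    "train", "predict", "merge", "modules",
                                    "core")) {
  if (is.character(config)) config <- read_run_config(config)
  config <- utils::modifyList(default_config(), config)
  known <- c("simulate", "extract", "features", "train", "predict", "merge",
             "modules", "core")
  bad <- setdiff(stages, known)
  if (length(bad) > 0L) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (stage in stages) {
    switch(stage,
           simulate = .stage_simulate(config),
           extract = .stage_extract(config),
           features = .stage_features(config),
           train = .stage_train(config),
           predict = .stage_predict(config),
           merge = .stage_merge(config),
           modules = .stage_modules(config),
           core = .stage_core(config))
  }
  invisible(config)
}

.write_pairs_tsv <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.stage_simulate <- function(config) {
  spec <- do.call(world_spec, utils::modifyList(list(seed = config$seed),
                                                config$world))
  world <- gen_pathway_world(spec)
  fs <- gen_feature_sources(world)
  out <- config$out_dir
  write_pathway_tsv(world$pathways, file.path(out, "pathways.tsv"))
  for (f in names(fs$sources)) {
    .write_pairs_tsv(fs$sources[[f]], file.path(out, paste0(f, ".tsv")))
  }
  for (f in names(fs$species)) {
    .write_pairs_tsv(fs$species[[f]]$pairs, file.path(out, paste0(f, ".tsv")))
    .write_pairs_tsv(fs$species[[f]]$ortholog_map,
                     file.path(out, paste0(f, "_orthologs.tsv")))
  }
  utils::write.table(fs$go_bp, file.path(out, "go_bp.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(world$go_cc, file.path(out, "go_cc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(fs$domains$protein_domains,
                     file.path(out, "protein_domains.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  .write_pairs_tsv(fs$domains$domain_pairs,
                   file.path(out, "domain_pairs.tsv"))
  writeLines(world$proteins, file.path(out, "proteins.txt"))
  # cohort with the two largest complexes planted as driver modules
  ref_net <- fi_network(world$reference_fis)
  complexes <- unlist(lapply(world$pathways, `[[`, "complexes"),
                      recursive = FALSE)
  registry <- stats::setNames(complexes,
                              vapply(complexes, `[[`, "", "id"))
  flat <- lapply(complexes, function(cx) flatten_members(cx$components, registry))
  flat <- flat[order(-lengths(flat))]
  cspec <- do.call(cohort_spec, utils::modifyList(
    list(modules = flat[1:2], seed = config$seed + 2), config$cohort))
  cohort <- gen_cohort(igraph::V(ref_net)$name, cspec)
  write_cohort(cohort, file.path(out, "cohort.tsv"))
  .write_json(list(planted_module_0 = sort(cspec$modules[[1]]),
                   planted_module_1 = sort(cspec$modules[[2]])),
              file.path(out, "planted_modules.json"))
  .update_manifest(config, "simulate",
                   list(n_proteins = length(world$proteins),
                        n_pathways = length(world$pathways),
                        n_reference_fis = nrow(world$reference_fis),
                        n_samples = length(cohort)))
}

.stage_extract <- function(config) {
  pathways <- read_pathway_tsv(
    .need_file(.path_in(config, "pathways.tsv"), "extract", "simulate"))
  fis <- build_pathway_fi_set(pathways)
  write_fi_tsv(fis, .path_in(config, "pathway_fis.tsv"))
  .update_manifest(config, "extract", list(n_pathway_fis = nrow(fis)))
}

# evidence tables shared by the features stage and the merge-stage CC check
.load_evidence <- function(config) {
  p <- function(name) .need_file(.path_in(config, name), "features", "simulate")
  sources <- list(
    human_ppi = load_interactions(p("human_ppi.tsv"),
                                  max_interactors = config$max_interactors),
    coexpr_set1 = load_interactions(p("coexpr_set1.tsv"),
                                    max_interactors = config$max_interactors),
    coexpr_set2 = load_interactions(p("coexpr_set2.tsv"),
                                    max_interactors = config$max_interactors),
    textmined_ppi = load_interactions(p("textmined_ppi.tsv"),
                                      max_interactors = config$max_interactors))
  for (f in c("fly_interolog", "worm_interolog", "yeast_interolog")) {
    sources[[f]] <- project_interologs(
      load_interactions(p(paste0(f, ".tsv")),
                        max_interactors = config$max_interactors),
      read_ortholog_map(p(paste0(f, "_orthologs.tsv"))))
  }
  go_bp <- utils::read.delim(p("go_bp.tsv"), header = FALSE,
                             colClasses = "character")
  names(go_bp) <- c("protein", "term", "aspect")
  pd <- utils::read.delim(p("protein_domains.tsv"), header = FALSE,
                          colClasses = "character")
  names(pd) <- c("protein", "domain")
  dp <- utils::read.delim(p("domain_pairs.tsv"), header = FALSE,
                          colClasses = "character")
  names(dp) <- c("domain_a", "domain_b")
  list(sources = sources, go_bp = go_bp,
       domains = list(protein_domains = pd, domain_pairs = dp))
}

.stage_features <- function(config) {
  ev <- .load_evidence(config)
  keys <- unique(c(
    unlist(lapply(ev$sources, as_pair_keys), use.names = FALSE),
    .domain_pair_keys(ev$domains$protein_domains, ev$domains$domain_pairs),
    .shared_term_pair_keys(ev$go_bp[ev$go_bp$aspect == "P", ],
                           max_frac = config$go_bp_max_frac,
                           exclude = config$go_bp_exclude)))
  candidates <- split_pair_keys(sort(keys))
  feats <- build_feature_matrix(candidates, ev$sources, go_bp = ev$go_bp,
                                domains = ev$domains,
                                go_bp_max_frac = config$go_bp_max_frac,
                                go_bp_exclude = config$go_bp_exclude)
  utils::write.table(feats, .path_in(config, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  .update_manifest(config, "features",
                   list(n_candidates = nrow(feats),
                        n_true_per_feature = as.list(colSums(
                          feats[, FI_FEATURES, drop = FALSE]))))
}

.read_features <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (f in FI_FEATURES) df[[f]] <- as.logical(df[[f]])
  df
}

.stage_train <- function(config) {
  pathways <- read_pathway_tsv(
    .need_file(.path_in(config, "pathways.tsv"), "train", "simulate"))
  feats <- .read_features(
    .need_file(.path_in(config, "features.tsv"), "train", "features"))
  key_feats <- pair_keys(feats$protein_a, feats$protein_b)
  n_hold <- max(1L, round(config$holdout_fraction * length(pathways)))
  hold_idx <- seq_len(n_hold)       # deterministic split
  train_fis <- build_pathway_fi_set(pathways[-hold_idx])
  test_fis <- build_pathway_fi_set(pathways[hold_idx])
  lookup <- function(fis) {
    k <- pair_keys(fis$protein_a, fis$protein_b)
    m <- feats[match(k, key_feats), FI_FEATURES, drop = FALSE]
    m[is.na(m)] <- FALSE
    m
  }
  pos <- lookup(train_fis)
  keep <- rowSums(pos) >= 1
  pos <- pos[keep, , drop = FALSE]
  pos_pairs <- train_fis[keep, c("protein_a", "protein_b")]
  universe <- unique(c(pos_pairs$protein_a, pos_pairs$protein_b))
  prior <- compute_prior(nrow(pos), length(universe))
  neg_pairs <- sample_negative_pairs(
    universe, pair_keys(pos_pairs$protein_a, pos_pairs$protein_b),
    n = config$ratio * nrow(pos), seed = config$seed + 3)
  neg <- feats[match(pair_keys(neg_pairs[, 1], neg_pairs[, 2]), key_feats),
               FI_FEATURES, drop = FALSE]
  neg[is.na(neg)] <- FALSE
  model <- train_nbc(pos, neg, prior = prior, threshold = config$threshold)
  write_nbc_model(model, .path_in(config, "model.json"))
  # held-out evaluation: test-pathway FIs vs random pairs from their universe
  tk <- pair_keys(test_fis$protein_a, test_fis$protein_b)
  test_pos <- lookup(test_fis)
  tkeep <- rowSums(test_pos) >= 1 &
    !(tk %in% pair_keys(pos_pairs$protein_a, pos_pairs$protein_b))
  test_pos <- test_pos[tkeep, , drop = FALSE]
  test_uni <- unique(c(test_fis$protein_a, test_fis$protein_b))
  avail <- choose(length(test_uni), 2) - length(unique(tk))
  tneg_pairs <- sample_negative_pairs(test_uni, tk,
                                      n = min(config$ratio * max(1L, nrow(test_pos)),
                                              avail),
                                      seed = config$seed + 4)
  test_neg <- feats[match(pair_keys(tneg_pairs[, 1], tneg_pairs[, 2]),
                          key_feats), FI_FEATURES, drop = FALSE]
  test_neg[is.na(test_neg)] <- FALSE
  roc <- evaluate_roc(model, test_pos, test_neg)
  utils::write.table(roc$points, .path_in(config, "roc_points.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  .update_manifest(config, "train",
                   list(n_positives = nrow(pos),
                        n_negatives = nrow(neg),
                        prior = prior, auc = roc$auc,
                        sensitivity = roc$sensitivity,
                        specificity = roc$specificity))
}

.stage_predict <- function(config) {
  model <- read_nbc_model(
    .need_file(.path_in(config, "model.json"), "predict", "train"))
  feats <- .read_features(
    .need_file(.path_in(config, "features.tsv"), "predict", "features"))
  predicted <- predict_fis(model, feats)
  write_fi_tsv(predicted[, setdiff(names(predicted), "score")],
               .path_in(config, "predicted_fis.tsv"))
  .update_manifest(config, "predict",
                   list(n_predicted = nrow(predicted),
                        threshold = model$threshold))
}

.stage_merge <- function(config) {
  pathway_fis <- read_fi_tsv(
    .need_file(.path_in(config, "pathway_fis.tsv"), "merge", "extract"))
  predicted_fis <- read_fi_tsv(
    .need_file(.path_in(config, "predicted_fis.tsv"), "merge", "predict"))
  net <- merge_fi_network(pathway_fis, predicted_fis)
  fis <- as_fi_table(net)
  write_fi_tsv(fis, .path_in(config, "network_fis.tsv"))
  write_graphml(net, .path_in(config, "network.graphml"))
  stats <- network_stats(net)
  go_cc <- utils::read.delim(.path_in(config, "go_cc.tsv"), header = FALSE,
                             colClasses = "character")
  names(go_cc) <- c("protein", "term", "aspect")
  cc_pred <- cc_sharing_rate(predicted_fis, go_cc)
  raw_ppi <- load_interactions(.path_in(config, "human_ppi.tsv"),
                               max_interactors = config$max_interactors)
  cc_raw <- cc_sharing_rate(raw_ppi, go_cc)
  stats$cc_sharing_predicted <- cc_pred$rate
  stats$cc_sharing_raw_ppi <- cc_raw$rate
  .write_json(stats, .path_in(config, "network_stats.json"))
  .update_manifest(config, "merge", stats)
}

.read_network <- function(config, stage) {
  fi_network(read_fi_tsv(
    .need_file(.path_in(config, "network_fis.tsv"), stage, "merge")))
}

.stage_modules <- function(config) {
  net <- .read_network(config, "modules")
  cohort <- read_cohort(
    .need_file(.path_in(config, "cohort.tsv"), "modules", "simulate"))
  sub <- induce_alteration_subnetwork(net, toupper(unique(unlist(cohort))))
  partition <- girvan_newman_modules(sub$subnetwork)
  part_df <- data.frame(gene = names(partition$membership),
                        module = unname(partition$membership))
  utils::write.table(part_df[order(part_df$module, part_df$gene), ],
                     .path_in(config, "modules.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  mat <- sample_module_matrix(cohort, partition)
  utils::write.table(mat, .path_in(config, "sample_module_matrix.tsv"),
                     sep = "\t", quote = FALSE)
  records <- list(n_subnetwork_genes = igraph::vcount(sub$subnetwork),
                  n_isolated = length(sub$isolated),
                  n_missing = length(sub$missing),
                  n_modules = length(partition$modules),
                  modularity = partition$modularity)
  if (length(partition$modules) >= 2L) {
    ch <- cohit_test(cohort, partition, 0, 1, n_perm = config$n_perm,
                     seed = config$seed + 5)
    .write_json(list(fraction = ch$fraction, p_value = ch$p_value,
                     p_label = ch$p_label),
                .path_in(config, "cohit.json"))
    records$cohit_fraction <- ch$fraction
    records$cohit_p <- ch$p_label
  }
  cl <- cluster_samples(mat, k = min(config$cluster_k, nrow(mat)))
  utils::write.table(
    data.frame(sample = names(cl$assignment), cluster = unname(cl$assignment)),
    .path_in(config, "sample_clusters.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  .update_manifest(config, "modules", records)
}

.stage_core <- function(config) {
  net <- .read_network(config, "core")
  cohort <- read_cohort(
    .need_file(.path_in(config, "cohort.tsv"), "core", "simulate"))
  genes <- unlist(cohort, use.names = FALSE)
  universe <- unique(c(genes, igraph::V(net)$name))
  curve <- recurrence_curve(cohort, universe, net = net,
                            n_perm = config$n_perm, seed = config$seed + 6)
  utils::write.table(curve, .path_in(config, "recurrence_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- table(unlist(lapply(cohort, unique)))
  recurrent <- names(rec)[rec >= config$min_recurrence]
  cluster <- cluster_genes_shortest_path(net, recurrent,
                                         coverage = config$coverage)
  asp_u <- asp_permutation_test(net, cluster, mode = "uniform",
                                n_perm = config$n_perm,
                                seed = config$seed + 7)
  asp_d <- asp_permutation_test(net, cluster, mode = "degree_stratified",
                                n_perm = config$n_perm,
                                seed = config$seed + 8)
  core <- build_linker_subnetwork(net, cluster)
  write_core_subnetwork(core, .path_in(config, "core_subnetwork.tsv"))
  .write_json(list(
    n_recurrent = length(recurrent),
    n_cluster = length(cluster),
    cluster_coverage = attr(cluster, "coverage_achieved"),
    asp_observed = asp_u$observed,
    asp_null_uniform = asp_u$null_mean,
    asp_p_uniform = asp_u$p_label,
    asp_null_degree = asp_d$null_mean,
    asp_p_degree = asp_d$p_label,
    n_linkers = length(core$linkers)),
    .path_in(config, "core_summary.json"))
  .update_manifest(config, "core",
                   list(n_recurrent = length(recurrent),
                        n_cluster = length(cluster),
                        n_linkers = length(core$linkers)))
}
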