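#' Specification of a synthetic pathway world
#'
#' Bundles the parameters of the seeded synthetic world used to exercise the
#' whole pipeline without external databases: a protein universe, pathways
#' whose reactions and complexes yield a reference FI set, per-feature
#' evidence rates, and compartment assignments for the cellular-component
#' sharing check.
#'
#' Defaults describe a 500-protein, 40-pathway world. Pathway sizes are set
#' so that the planted FI density over the pathway protein universe is close
#' to the pair-density prior observed in real curated pathway data (a few
#' parts per thousand), which keeps negative sampling feasible even at a
#' 100:1 negative:positive training ratio. Evidence rates are chosen so that
#' a planted FI carries feature i with probability `q_pos[i]` and a
#' background pair with probability `q_neg[i]`; the spread of the resulting
#' per-feature odds ratios (roughly 4-40) mirrors the spread seen across
#' real evidence sources, and `q_neg` is kept well below `q_pos` for every
#' feature so that all nine are informative.
#'
#' @param n_proteins size of the protein universe.
#' @param n_pathways number of pathways.
#' @param n_compartments number of cellular compartments.
#' @param compartment_coherence probability that a pathway member is drawn
#'   from the pathway's home compartment (drives CC-sharing of planted FIs).
#' @param reaction_count,complex_count integer ranges (min, max) per pathway.
#' @param pathway_size range of distinct proteins per pathway.
#' @param q_pos,q_neg named per-feature evidence rates (names =
#'   [FI_FEATURES]).
#' @param seed integer seed; the seed fully determines the generated world.
#' @return list of class `"world_spec"`.
#' @export
world_spec <- function(n_proteins = 500, n_pathways = 40, n_compartments = 5,
                       compartment_coherence = 0.9,
                       reaction_count = c(2, 4), complex_count = c(1, 2),
                       pathway_size = c(10, 18),
                       q_pos = c(human_ppi = 0.60, fly_interolog = 0.15,
                                 worm_interolog = 0.10, yeast_interolog = 0.20,
                                 domain_interaction = 0.55, coexpr_set1 = 0.40,
                                 coexpr_set2 = 0.30, go_bp_shared = 0.80,
                                 textmined_ppi = 0.25),
                       q_neg = c(human_ppi = 0.015, fly_interolog = 0.030,
                                 worm_interolog = 0.025, yeast_interolog = 0.030,
                                 domain_interaction = 0.050, coexpr_set1 = 0.040,
                                 coexpr_set2 = 0.035, go_bp_shared = 0.050,
                                 textmined_ppi = 0.035),
                       seed = 1) {
  q_pos <- q_pos[FI_FEATURES]
  q_neg <- q_neg[FI_FEATURES]
  stopifnot(!anyNA(q_pos), !anyNA(q_neg), all(q_neg < q_pos),
            all(q_pos <= 1), all(q_neg >= 0), n_proteins >= 4,
            pathway_size[1] >= 4, pathway_size[2] <= n_proteins)
  structure(list(n_proteins = n_proteins, n_pathways = n_pathways,
                 n_compartments = n_compartments,
                 compartment_coherence = compartment_coherence,
                 reaction_count = reaction_count,
                 complex_count = complex_count,
                 pathway_size = pathway_size,
                 q_pos = q_pos, q_neg = q_neg, seed = seed),
            class = "world_spec")
}

#' Generate a synthetic pathway world
#'
#' Draws pathways (reactions, complexes and their member proteins) over a
#' protein universe, with each pathway anchored to a home compartment so that
#' pathway-derived FIs tend to connect co-localized proteins. The reference
#' FI set is obtained by running the package's own extraction over the
#' generated pathways, so extraction and generation are consistent by
#' construction. All output is a pure function of the spec (including its
#' seed).
#'
#' @param spec a [world_spec()].
#' @return list of class `"fi_world"`: `spec`, `proteins`, `pathways`
#'   (list of `pathway_record`s), `reference_fis` ([fi_table()]),
#'   `compartments` (named vector protein -> compartment term), `go_cc`
#'   (data.frame `protein`, `term`, `aspect`).
#' @export
gen_pathway_world <- function(spec = world_spec()) {
  with_seed(spec$seed, {
    proteins <- sprintf("P%04d", seq_len(spec$n_proteins))
    cpt_terms <- sprintf("GOCC:%04d", seq_len(spec$n_compartments))
    compartments <- stats::setNames(
      sample(cpt_terms, spec$n_proteins, replace = TRUE), proteins)
    pathways <- vector("list", spec$n_pathways)
    for (pw in seq_len(spec$n_pathways)) {
      home <- sample(cpt_terms, 1)
      home_pool <- proteins[compartments == home]
      size <- sample(spec$pathway_size[1]:spec$pathway_size[2], 1)
      n_home <- min(stats::rbinom(1, size, spec$compartment_coherence),
                    length(home_pool))
      members <- c(sample(home_pool, n_home),
                   sample(setdiff(proteins, home_pool), size - n_home))
      # rotate through the pathway members so that most members take part in
      # some reaction or complex: this spreads FIs thinly over the universe,
      # keeping the planted pair density in the regime of real pathway data
      queue <- sample(members)
      take <- function(k) {
        if (k <= 0) return(character(0))
        if (length(queue) < k) {
          queue <<- c(queue, sample(setdiff(members, queue)))
        }
        out <- queue[seq_len(k)]
        queue <<- queue[-seq_len(k)]
        out
      }
      reactions <- list()
      n_r <- sample(spec$reaction_count[1]:spec$reaction_count[2], 1)
      for (r in seq_len(n_r)) {
        inputs <- take(sample(1:2, 1))
        cat_n <- stats::rbinom(1, 1, 0.7)
        act_n <- stats::rbinom(1, 1, 0.15)
        inh_n <- stats::rbinom(1, 1, 0.15)
        picks <- setdiff(take(cat_n + act_n + inh_n), inputs)
        reactions[[r]] <- reaction_record(
          sprintf("pw%02d_r%02d", pw, r),
          inputs = inputs,
          catalysts = if (cat_n >= 1 && length(picks) >= 1) picks[1] else character(0),
          activators = if (act_n >= 1 && length(picks) >= cat_n + 1) picks[cat_n + 1] else character(0),
          inhibitors = if (inh_n >= 1 && length(picks) >= cat_n + act_n + 1) picks[cat_n + act_n + 1] else character(0),
          outputs = sample(members, sample(1:2, 1)))
      }
      complexes <- list()
      n_c <- sample(spec$complex_count[1]:spec$complex_count[2], 1)
      for (cc in seq_len(n_c)) {
        comps <- take(sample(2:3, 1))
        if (cc > 1L && stats::runif(1) < 0.1) {
          comps <- c(comps[-1], paste0("complex:",
                                       sprintf("pw%02d_c%02d", pw, cc - 1L)))
        }
        complexes[[cc]] <- complex_record(sprintf("pw%02d_c%02d", pw, cc),
                                          comps)
      }
      pathways[[pw]] <- pathway_record(
        sprintf("pathway%02d", pw),
        source = sprintf("pathdb%d", ((pw - 1) %% 5) + 1),
        reactions = reactions, complexes = complexes)
    }
    go_cc <- data.frame(protein = proteins,
                        term = unname(compartments),
                        aspect = "C", stringsAsFactors = FALSE)
    structure(list(spec = spec, proteins = proteins, pathways = pathways,
                   reference_fis = build_pathway_fi_set(pathways),
                   compartments = compartments, go_cc = go_cc),
              class = "fi_world")
  })
}

# all unordered pair keys over a universe (integer enumeration, canonical)
.all_universe_keys <- function(proteins) {
  proteins <- sort(proteins)
  idx <- utils::combn(length(proteins), 2L)
  pair_keys(proteins[idx[1, ]], proteins[idx[2, ]])
}

#' Generate per-feature evidence sources for a synthetic world
#'
#' Every planted (reference) FI pair enters evidence source i with
#' probability `q_pos[i]`; every other pair of the protein universe enters
#' with probability `q_neg[i]`. Interolog evidence is emitted in a non-human
#' namespace together with a complete one-to-one ortholog map, so recovering
#' the human pairs exercises interolog projection. Domain evidence assigns
#' each protein a private domain and lists the interacting domain pairs; GO
#' biological-process evidence annotates each flagged pair with a private
#' shared term (plus one broad term covering most of the universe, which the
#' breadth filter must remove).
#'
#' @param world an `"fi_world"` from [gen_pathway_world()].
#' @param seed integer seed (defaults to the world's seed + 1).
#' @return list of class `"feature_sources"`: `truth` (named list of flagged
#'   human pair keys per feature), `sources` (pair sets for the set-based
#'   features, human namespace), `species` (per interolog feature: `pairs` in
#'   species namespace and `ortholog_map`), `go_bp`, `domains`, `q_pos`,
#'   `q_neg`.
#' @export
gen_feature_sources <- function(world, seed = world$spec$seed + 1) {
  spec <- world$spec
  with_seed(seed, {
    planted <- pair_keys(world$reference_fis$protein_a,
                         world$reference_fis$protein_b)
    all_keys <- .all_universe_keys(world$proteins)
    bg <- setdiff(all_keys, planted)
    truth <- list()
    for (f in FI_FEATURES) {
      truth[[f]] <- sort(c(
        planted[stats::runif(length(planted)) < spec$q_pos[[f]]],
        bg[stats::runif(length(bg)) < spec$q_neg[[f]]]))
    }
    species_prefix <- c(fly_interolog = "FLY", worm_interolog = "WORM",
                        yeast_interolog = "YST")
    species <- lapply(names(species_prefix), function(f) {
      pre <- species_prefix[[f]]
      map <- data.frame(from = paste0(pre, "_", world$proteins),
                        to = world$proteins, stringsAsFactors = FALSE)
      hp <- split_pair_keys(truth[[f]])
      list(pairs = cbind(paste0(pre, "_", hp[, 1]), paste0(pre, "_", hp[, 2])),
           ortholog_map = map)
    })
    names(species) <- names(species_prefix)
    dom_pairs <- split_pair_keys(truth$domain_interaction)
    domains <- list(
      protein_domains = data.frame(protein = world$proteins,
                                   domain = paste0("D_", world$proteins),
                                   stringsAsFactors = FALSE),
      domain_pairs = data.frame(domain_a = paste0("D_", dom_pairs[, 1]),
                                domain_b = paste0("D_", dom_pairs[, 2]),
                                stringsAsFactors = FALSE))
    bp_pairs <- split_pair_keys(truth$go_bp_shared)
    bp_terms <- sprintf("GOBP:%06d", seq_len(nrow(bp_pairs)))
    broad_n <- floor(0.6 * length(world$proteins))
    go_bp <- data.frame(
      protein = c(bp_pairs[, 1], bp_pairs[, 2],
                  sort(sample(world$proteins, broad_n))),
      term = c(bp_terms, bp_terms, rep("GOBP:BROAD", broad_n)),
      aspect = "P", stringsAsFactors = FALSE)
    set_only <- c("human_ppi", "coexpr_set1", "coexpr_set2", "textmined_ppi")
    structure(list(truth = truth,
                   sources = lapply(stats::setNames(set_only, set_only),
                                    function(f) split_pair_keys(truth[[f]])),
                   species = species, go_bp = go_bp, domains = domains,
                   q_pos = spec$q_pos, q_neg = spec$q_neg),
              class = "feature_sources")
  })
}

#' Resolve feature sources into the nine per-feature human pair sets
#'
#' Projects the interolog evidence through its ortholog maps and returns the
#' named list of pair sets consumed by [build_feature_matrix()]'s `sources`
#' argument (set-based features only; GO BP and domain evidence stay in
#' their own tables).
#'
#' @param fs a `"feature_sources"` object.
#' @return named list of two-column pair matrices.
#' @export
resolve_feature_sources <- function(fs) {
  out <- fs$sources
  for (f in names(fs$species)) {
    out[[f]] <- project_interologs(fs$species[[f]]$pairs,
                                   fs$species[[f]]$ortholog_map)
  }
  out
}

#' Specification of a synthetic cancer cohort
#'
#' @param modules list of planted driver-module gene sets (may be empty).
#' @param hit_prob per-module probability that a sample carries an alteration
#'   in the module (scalar or per-module vector).
#' @param passenger_rate Poisson mean of passenger alterations per sample,
#'   drawn uniformly from the gene universe. The default of 5 scales the
#'   per-specimen alteration load of real resequencing cohorts down to a
#'   network a few hundred genes in size.
#' @param hit_extra_rate Poisson mean of additional altered genes within a
#'   hit module (a hit yields `1 + Pois(hit_extra_rate)` genes, capped at the
#'   module size).
#' @param n_samples cohort size (default 91).
#' @param seed integer seed.
#' @return list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(modules = list(), hit_prob = 0.85,
                        passenger_rate = 5, hit_extra_rate = 0.5,
                        n_samples = 91, seed = 1) {
  hit_prob <- rep_len(hit_prob, length(modules))
  structure(list(modules = modules, hit_prob = hit_prob,
                 passenger_rate = passenger_rate,
                 hit_extra_rate = hit_extra_rate,
                 n_samples = n_samples, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic cancer cohort
#'
#' For each sample and each planted module, an independent Bernoulli hit with
#' the module's probability contributes at least one uniformly chosen module
#' gene; passenger alterations are added as a Poisson-distributed number of
#' genes drawn uniformly from the gene universe. A sample that would end up
#' with no alteration receives one passenger, keeping alteration sets
#' non-empty.
#'
#' @param universe character vector of network genes (or an `igraph` graph,
#'   whose vertex names are used).
#' @param spec a [cohort_spec()]; its modules must be subsets of the
#'   universe.
#' @return named list sample id -> character vector of altered genes.
#' @export
gen_cohort <- function(universe, spec = cohort_spec()) {
  if (inherits(universe, "igraph")) universe <- igraph::V(universe)$name
  universe <- unique(universe)
  if (!all(unlist(spec$modules) %in% universe)) {
    stop("planted modules must be subsets of the gene universe")
  }
  with_seed(spec$seed, {
    samples <- sprintf("S%03d", seq_len(spec$n_samples))
    out <- lapply(samples, function(s) {
      genes <- character(0)
      for (m in seq_along(spec$modules)) {
        if (stats::runif(1) < spec$hit_prob[m]) {
          mod <- spec$modules[[m]]
          k <- min(1 + stats::rpois(1, spec$hit_extra_rate), length(mod))
          genes <- c(genes, mod[sample.int(length(mod), k)])
        }
      }
      n_pass <- stats::rpois(1, spec$passenger_rate)
      if (n_pass > 0) {
        genes <- c(genes,
                   universe[sample.int(length(universe),
                                       min(n_pass, length(universe)))])
      }
      if (length(genes) == 0L) {
        genes <- universe[sample.int(length(universe), 1)]
      }
      sort(unique(genes))
    })
    stats::setNames(out, samples)
  })
}
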