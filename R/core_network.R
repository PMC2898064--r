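# vertex names of the largest connected component (ties: the component
# containing the lexicographically smallest vertex name among the largest)
largest_component_nodes <- function(net) {
  comp <- igraph::components(net)
  big <- which(comp$csize == max(comp$csize))
  if (length(big) > 1L) {
    firsts <- vapply(big, function(b) {
      min(names(comp$membership)[comp$membership == b])
    }, "")
    big <- big[order(firsts)][1]
  }
  sort(names(comp$membership)[comp$membership == big])
}

# distance matrix over a node set (unweighted breadth-first shortest paths)
.dist_matrix <- function(net, nodes) {
  igraph::distances(net, v = nodes, to = nodes, weights = NA)
}

.mean_pair_dist <- function(dmat, nodes) {
  sub <- dmat[nodes, nodes, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Average shortest path of a gene set in the FI network
#'
#' Mean unweighted shortest-path length over all unordered pairs of the genes
#' that lie in the network's largest connected component. Genes outside the
#' component (or absent from the network) are excluded from the average;
#' their count is available as an attribute.
#'
#' @param net an `igraph` FI network.
#' @param genes character vector.
#' @return numeric scalar (>= 1) with attributes `n_used` and `n_excluded`.
#' @export
average_shortest_path <- function(net, genes) {
  comp <- largest_component_nodes(net)
  usable <- intersect(unique(genes), comp)
  if (length(usable) < 2L) {
    stop("need at least two genes inside the largest connected component")
  }
  d <- .dist_matrix(net, usable)
  structure(mean(d[upper.tri(d)]),
            n_used = length(usable),
            n_excluded = length(unique(genes)) - length(usable))
}

# greedy degree bins over the sorted candidate degrees; every bin's degree
# interval must contain at least `min_bin_size` eligible component nodes
.degree_bins <- function(cand_degrees, node_degrees, min_bin_size = 5) {
  cd <- sort(cand_degrees)
  bins <- list()
  i <- 1L
  while (i <= length(cd)) {
    lo <- cd[i]
    j <- i
    repeat {
      # a bin may only close at a degree boundary, so candidates sharing a
      # degree always land in the same bin
      while (j < length(cd) && cd[j + 1L] == cd[j]) j <- j + 1L
      hi <- cd[j]
      count <- j - i + 1L
      eligible <- sum(node_degrees >= lo & node_degrees <= hi)
      if ((eligible >= max(min_bin_size, count)) || j == length(cd)) break
      j <- j + 1L
    }
    bins[[length(bins) + 1L]] <- list(lo = lo, hi = cd[j], count = j - i + 1L)
    i <- j + 1L
  }
  # widen a terminal bin that cannot supply its draw by merging it backwards
  repeat {
    nb <- length(bins)
    last <- bins[[nb]]
    eligible <- sum(node_degrees >= last$lo & node_degrees <= last$hi)
    if (eligible >= max(min_bin_size, last$count) || nb == 1L) break
    prev <- bins[[nb - 1L]]
    bins[[nb - 1L]] <- list(lo = prev$lo, hi = last$hi,
                            count = prev$count + last$count)
    bins[[nb]] <- NULL
  }
  bins
}

#' Permutation significance of a gene set's average shortest path
#'
#' Compares the observed average shortest path (ASP) of a gene set against
#' null gene sets of the same size drawn from the largest connected
#' component. In `"uniform"` mode nodes are drawn uniformly. In
#' `"degree_stratified"` mode degree bins are generated dynamically from the
#' sorted candidate degrees (each bin wide enough to hold at least
#' `min_bin_size` component nodes) and every null set matches the candidate
#' count bin by bin, which controls for the tendency of high-degree hubs to
#' sit close to everything. The p-value is the fraction of permutations with
#' null ASP less than or equal to the observed ASP.
#'
#' @param net an `igraph` FI network.
#' @param genes character vector.
#' @param mode `"uniform"` or `"degree_stratified"`.
#' @param n_perm number of permutations (default 1000).
#' @param seed optional integer seed.
#' @param min_bin_size minimum eligible component nodes per degree bin.
#' @param keep_sets also return the drawn null gene sets (list column
#'   `null_sets`); off by default to save memory.
#' @return object of class `"asp_result"`: list with `observed`,
#'   `null_mean`, `null_sd`, `p_value`, `p_label`, `mode`, `n_used`,
#'   `n_excluded`, `null_values`, and for the stratified mode `bins`.
#' @export
asp_permutation_test <- function(net, genes,
                                 mode = c("uniform", "degree_stratified"),
                                 n_perm = 1000, seed = NULL,
                                 min_bin_size = 5, keep_sets = FALSE) {
  mode <- match.arg(mode)
  comp <- largest_component_nodes(net)
  usable <- intersect(unique(genes), comp)
  if (length(usable) < 2L) {
    stop("need at least two genes inside the largest connected component")
  }
  dmat <- .dist_matrix(net, comp)
  observed <- .mean_pair_dist(dmat, usable)
  bins <- NULL
  if (mode == "degree_stratified") {
    deg <- igraph::degree(net)[comp]
    bins <- .degree_bins(deg[usable], deg, min_bin_size)
    pools <- lapply(bins, function(b) {
      names(deg)[deg >= b$lo & deg <= b$hi]
    })
    draw <- function() {
      unlist(mapply(function(pool, b) pool[sample.int(length(pool), b$count)],
                    pools, bins, SIMPLIFY = FALSE), use.names = FALSE)
    }
  } else {
    draw <- function() comp[sample.int(length(comp), length(usable))]
  }
  sets <- with_seed(seed, lapply(seq_len(n_perm), function(p) draw()))
  nulls <- vapply(sets, function(s) .mean_pair_dist(dmat, s), numeric(1))
  r <- sum(nulls <= observed)
  structure(list(observed = observed, null_mean = mean(nulls),
                 null_sd = stats::sd(nulls),
                 p_value = r / n_perm,
                 p_label = if (r == 0) paste0("< ", format(1 / n_perm)) else
                   format(r / n_perm),
                 mode = mode, n_used = length(usable),
                 n_excluded = length(unique(genes)) - length(usable),
                 bins = bins, null_values = nulls,
                 null_sets = if (keep_sets) sets else NULL),
            class = "asp_result")
}

#' @export
print.asp_result <- function(x, ...) {
  cat(sprintf("ASP %.3f vs %s null %.3f +/- %.3f (p %s; %d genes used, %d excluded)\n",
              x$observed, x$mode, x$null_mean, x$null_sd, x$p_label,
              x$n_used, x$n_excluded))
  invisible(x)
}

#' Recurrence curve of altered genes across samples
#'
#' For each recurrence level s, the fraction of altered genes occurring in
#' exactly s and in at least s samples, compared against random assignment of
#' genes to samples (per-sample altered-gene counts preserved, genes redrawn
#' uniformly from the universe). Optionally also reports the average shortest
#' path of the genes altered in >= s samples, which for driver-rich
#' recurrence levels falls below the random expectation.
#'
#' @param cohort named list sample -> altered gene vector.
#' @param universe character vector containing every altered gene.
#' @param net optional `igraph` FI network for the ASP column.
#' @param n_perm permutations for the null (default 1000).
#' @param seed optional integer seed.
#' @return data.frame with columns `s`, `n_genes`, `frac_exact`, `frac_ge`,
#'   `null_frac_ge`, `null_frac_ge_lo`, `null_frac_ge_hi`, `asp_ge`.
#' @export
recurrence_curve <- function(cohort, universe, net = NULL, n_perm = 1000,
                             seed = NULL) {
  cohort <- lapply(cohort, unique)
  universe <- unique(universe)
  if (!all(unlist(cohort) %in% universe)) {
    stop("universe must contain every altered gene")
  }
  counts <- lengths(cohort)
  s_max <- length(cohort)
  rec_fracs <- function(sets) {
    rec <- table(factor(unlist(sets), levels = universe))
    rec <- rec[rec > 0]
    n <- length(rec)
    exact <- tabulate(rec, nbins = s_max) / n
    ge <- rev(cumsum(rev(exact)))
    list(exact = exact, ge = ge, rec = rec)
  }
  obs <- rec_fracs(cohort)
  nulls <- with_seed(seed, vapply(seq_len(n_perm), function(p) {
    sets <- lapply(counts, function(k) universe[sample.int(length(universe), k)])
    rec_fracs(sets)$ge
  }, numeric(s_max)))
  nulls <- matrix(nulls, nrow = s_max)
  asp_ge <- rep(NA_real_, s_max)
  if (!is.null(net)) {
    comp <- largest_component_nodes(net)
    dmat <- NULL
    for (s in seq_len(s_max)) {
      gs <- intersect(names(obs$rec)[obs$rec >= s], comp)
      if (length(gs) >= 2L) {
        if (is.null(dmat)) dmat <- .dist_matrix(net, comp)
        asp_ge[s] <- .mean_pair_dist(dmat, gs)
      }
    }
  }
  data.frame(s = seq_len(s_max),
             n_genes = tabulate(obs$rec, nbins = s_max),
             frac_exact = obs$exact,
             frac_ge = obs$ge,
             null_frac_ge = rowMeans(nulls),
             null_frac_ge_lo = apply(nulls, 1, stats::quantile, 0.025),
             null_frac_ge_hi = apply(nulls, 1, stats::quantile, 0.975),
             asp_ge = asp_ge)
}

#' Shortest-path hierarchical clustering of candidate genes
#'
#' Average-linkage agglomeration on the pairwise shortest-path matrix of the
#' candidate genes (restricted to the largest connected component). Scanning
#' the distinct merge heights from the bottom up, the tree is cut at each
#' height and the first (hence smallest) cluster whose membership exceeds
#' `coverage` of the usable genes is returned; if no cut below the root
#' yields a qualifying cluster, the root is returned with a warning.
#'
#' @param net an `igraph` FI network.
#' @param genes character vector of candidate genes.
#' @param coverage required fraction of usable genes (default 0.70).
#' @return character vector of clustered genes with attributes `height`,
#'   `n_usable`, `coverage_achieved`, `hclust`.
#' @export
cluster_genes_shortest_path <- function(net, genes, coverage = 0.70) {
  comp <- largest_component_nodes(net)
  usable <- intersect(unique(genes), comp)
  n <- length(usable)
  if (n < 2L) {
    stop("need at least two genes inside the largest connected component")
  }
  d <- .dist_matrix(net, usable)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  result <- NULL
  for (h in sort(unique(hc$height))) {
    cut <- stats::cutree(hc, h = h)
    groups <- split(names(cut), cut)
    qual <- groups[lengths(groups) > coverage * n]
    if (length(qual) > 0L) {
      qual <- qual[order(lengths(qual),
                         vapply(qual, function(g) min(g), ""))]
      result <- structure(sort(qual[[1]]), height = h)
      break
    }
  }
  if (is.null(result)) {
    warning("no cluster below the root reaches the coverage fraction; ",
            "returning the root cluster")
    result <- structure(sort(usable), height = max(hc$height))
  }
  attr(result, "n_usable") <- n
  attr(result, "coverage_achieved") <- length(result) / n
  attr(result, "hclust") <- hc
  result
}

# all shortest paths between two named vertices, as name sequences
.all_shortest_name_paths <- function(net, from, to) {
  res <- igraph::all_shortest_paths(net, from = from, to = to, weights = NA)
  paths <- res$res %||% res$vpaths
  lapply(paths, function(p) igraph::V(net)$name[as.integer(p)])
}

# TRUE if name sequence a is lexicographically smaller than b (equal lengths)
.seq_less <- function(a, b) {
  diff <- which(a != b)
  length(diff) > 0L && a[diff[1]] < b[diff[1]]
}

# canonical orientation of a path: the smaller of the sequence and its reverse
.canon_path <- function(p) {
  r <- rev(p)
  if (.seq_less(r, p)) r else p
}

#' Connect candidate genes into a core subnetwork with minimal linkers
#'
#' Greedy Steiner-style construction: every in-component candidate starts as
#' its own cluster; the two clusters with the smallest inter-cluster shortest
#' path are repeatedly connected via one such path, adding interior path
#' nodes as linker genes, until a single connected cluster remains. Among
#' equally short connecting paths, the lexicographically smallest node
#' sequence is chosen, making runs reproducible. Linker genes are the
#' non-candidate nodes needed to interconnect the candidates.
#'
#' @param net an `igraph` FI network.
#' @param genes character vector of candidate genes.
#' @param shared optional character vector of candidates to label
#'   `shared_candidate` (e.g. genes recurrent in two independent cohorts).
#' @return object of class `"core_subnetwork"`: list with `candidates`,
#'   `linkers`, `nodes`, `subnetwork` (igraph), `roles` (data.frame `gene`,
#'   `role`), `coverage` (fraction of input candidates included) and
#'   `excluded` (candidates outside the largest component).
#' @export
build_linker_subnetwork <- function(net, genes, shared = NULL) {
  comp <- largest_component_nodes(net)
  genes <- unique(genes)
  candidates <- intersect(genes, comp)
  if (length(candidates) < 2L) {
    stop("need at least two candidate genes inside the largest connected component")
  }
  dmat <- .dist_matrix(net, comp)
  clusters <- lapply(sort(candidates), function(g) g)
  while (length(clusters) > 1L) {
    nc <- length(clusters)
    dmin <- Inf
    min_pairs <- list()
    for (i in seq_len(nc - 1L)) {
      for (j in (i + 1L):nc) {
        d <- min(dmat[clusters[[i]], clusters[[j]], drop = FALSE])
        if (d < dmin - 1e-9) {
          dmin <- d
          min_pairs <- list(c(i, j))
        } else if (d <= dmin + 1e-9) {
          min_pairs[[length(min_pairs) + 1L]] <- c(i, j)
        }
      }
    }
    best_path <- NULL
    best_pair <- NULL
    for (pr in min_pairs) {
      sub <- dmat[clusters[[pr[1]]], clusters[[pr[2]]], drop = FALSE]
      hits <- which(sub <= dmin + 1e-9, arr.ind = TRUE)
      for (h in seq_len(nrow(hits))) {
        u <- rownames(sub)[hits[h, 1]]
        v <- colnames(sub)[hits[h, 2]]
        for (p in .all_shortest_name_paths(net, u, v)) {
          cp <- .canon_path(p)
          if (is.null(best_path) || .seq_less(cp, best_path)) {
            best_path <- cp
            best_pair <- pr
          }
        }
      }
    }
    merged <- unique(c(clusters[[best_pair[1]]], clusters[[best_pair[2]]],
                       best_path))
    clusters <- c(clusters[-best_pair], list(merged))
  }
  nodes <- sort(unique(unlist(clusters)))
  linkers <- setdiff(nodes, candidates)
  role <- ifelse(nodes %in% linkers, "linker",
                 ifelse(nodes %in% shared, "shared_candidate", "candidate"))
  sub <- igraph::induced_subgraph(net, nodes)
  structure(list(candidates = sort(candidates), linkers = sort(linkers),
                 nodes = nodes, subnetwork = sub,
                 roles = data.frame(gene = nodes, role = role,
                                    stringsAsFactors = FALSE),
                 coverage = length(candidates) / length(genes),
                 excluded = setdiff(genes, comp)),
            class = "core_subnetwork")
}

#' @export
print.core_subnetwork <- function(x, ...) {
  cat(sprintf("core subnetwork: %d candidates + %d linkers, %d edges (%.0f%% of candidates covered)\n",
              length(x$candidates), length(x$linkers),
              igraph::ecount(x$subnetwork), 100 * x$coverage))
  invisible(x)
}

#' Write a core subnetwork node table
#'
#' TSV with `gene` and `role` (`candidate`, `shared_candidate` or `linker`)
#' columns.
#'
#' @param core a `"core_subnetwork"`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_core_subnetwork <- function(core, path) {
  utils::write.table(core$roles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
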