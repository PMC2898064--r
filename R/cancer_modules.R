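#' Read a cancer cohort alteration table
#'
#' Two-column TSV `sample<TAB>gene`, one altered gene per line. Gene symbols
#' are uppercased.
#'
#' @param path file path.
#' @return named list: sample id -> character vector of altered genes.
#' @export
read_cohort <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "#")
  lapply(split(toupper(df[[2]]), df[[1]]), unique)
}

#' @rdname read_cohort
#' @param cohort named list sample -> gene vector.
#' @export
write_cohort <- function(cohort, path) {
  df <- data.frame(sample = rep(names(cohort), lengths(cohort)),
                   gene = unlist(cohort, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Induce the FI subnetwork of a gene set
#'
#' Subgraph of the network on the given genes. Genes absent from the network
#' or with no mutual FI among the gene set are reported as isolated (they
#' cannot take part in module detection).
#'
#' @param net an `igraph` FI network.
#' @param genes character vector.
#' @return list with `subnetwork` (igraph, isolated vertices removed),
#'   `isolated` (genes with no mutual FI), `missing` (genes not in the
#'   network).
#' @export
induce_alteration_subnetwork <- function(net, genes) {
  genes <- unique(genes)
  present <- intersect(genes, igraph::V(net)$name)
  sub <- igraph::induced_subgraph(net, present)
  deg <- igraph::degree(sub)
  isolated <- names(deg)[deg == 0]
  sub <- igraph::delete_vertices(sub, isolated)
  list(subnetwork = sub, isolated = isolated,
       missing = setdiff(genes, present))
}

# deterministic choice of the edge with maximal betweenness: among ties, the
# lexicographically smallest (sorted endpoint names) edge
.max_betweenness_edge <- function(g) {
  eb <- igraph::edge_betweenness(g, directed = FALSE)
  cand <- which(eb >= max(eb) - 1e-9)
  ends <- igraph::ends(g, cand, names = TRUE)
  a <- pmin(ends[, 1], ends[, 2])
  b <- pmax(ends[, 1], ends[, 2])
  cand[order(a, b)][1]
}

#' Girvan-Newman edge-betweenness module detection
#'
#' Iteratively removes the edge with the highest edge betweenness (number of
#' shortest paths running through it), tracking the component partition after
#' every removal, and returns the partition with maximal Newman-Girvan
#' modularity (computed on the original graph) over the whole removal
#' sequence. Betweenness ties are broken by the lexicographically smallest
#' edge so runs are reproducible. An edgeless input yields one module per
#' node.
#'
#' @param sub an undirected `igraph` graph (typically the induced alteration
#'   subnetwork).
#' @return object of class `"module_partition"`: list with `modules` (list of
#'   gene vectors, ordered by decreasing size; names `"0"`, `"1"`, ... as
#'   module indices), `membership` (named integer vector, 0-based module
#'   index per gene) and `modularity`.
#' @export
girvan_newman_modules <- function(sub) {
  g <- sub
  n <- igraph::vcount(g)
  if (n == 0L) {
    return(module_partition(list()))
  }
  best_mem <- igraph::components(g)$membership
  best_q <- if (igraph::ecount(g) > 0) {
    igraph::modularity(sub, best_mem)
  } else {
    -Inf
  }
  work <- g
  while (igraph::ecount(work) > 0L) {
    work <- igraph::delete_edges(work, .max_betweenness_edge(work))
    mem <- igraph::components(work)$membership
    q <- igraph::modularity(sub, mem[igraph::V(sub)$name])
    if (q > best_q + 1e-12) {
      best_q <- q
      best_mem <- mem
    }
  }
  groups <- split(names(best_mem), best_mem)
  groups <- lapply(groups, sort)
  ord <- order(-lengths(groups), vapply(groups, `[`, "", 1))
  mp <- module_partition(unname(groups[ord]))
  mp$modularity <- if (is.finite(best_q)) best_q else NA_real_
  mp
}

#' @rdname girvan_newman_modules
#' @param modules list of disjoint gene vectors (largest first after
#'   internal reordering).
#' @export
module_partition <- function(modules) {
  modules <- lapply(modules, sort)
  ord <- order(-lengths(modules),
               vapply(modules, function(m) if (length(m)) m[1] else "", ""))
  modules <- modules[ord]
  names(modules) <- as.character(seq_along(modules) - 1L)
  if (anyDuplicated(unlist(modules))) {
    stop("modules must be disjoint")
  }
  membership <- stats::setNames(
    rep.int(seq_along(modules) - 1L, lengths(modules)),
    unlist(modules))
  structure(list(modules = modules, membership = membership,
                 modularity = NA_real_),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(length(x$modules), "modules over", length(x$membership), "genes;",
      "sizes:", paste(utils::head(lengths(x$modules), 10), collapse = ", "),
      if (length(x$modules) > 10) "..." else "", "\n")
  invisible(x)
}

#' Sample x module incidence matrix
#'
#' Binary matrix with one row per sample and one column per module; an entry
#' is 1 iff the sample has at least one altered gene in the module.
#'
#' @param cohort named list sample -> altered gene vector.
#' @param partition a `"module_partition"`.
#' @return binary integer matrix, rownames samples, colnames module indices.
#' @export
sample_module_matrix <- function(cohort, partition) {
  mat <- vapply(partition$modules, function(m) {
    vapply(cohort, function(g) as.integer(any(g %in% m)), 0L)
  }, integer(length(cohort)))
  if (length(cohort) == 1L) mat <- matrix(mat, nrow = 1)
  dimnames(mat) <- list(names(cohort), names(partition$modules))
  mat
}

#' Permutation test of sample co-hits in two modules
#'
#' The observed statistic is the fraction of samples carrying at least one
#' altered gene in module `i` and at least one in module `j`. The null
#' preserves each sample's number of in-universe altered genes and redraws
#' that many genes uniformly (without replacement) from the clustered
#' subnetwork's gene universe, then recomputes the fraction; the p-value is
#' the fraction of permutations reaching the observed value. Because only
#' the per-module membership counts of a redrawn gene set matter, each
#' redraw is realized as the exact equivalent multivariate hypergeometric
#' count draw, which is fast and distributionally identical. A co-hit rate
#' far above this null indicates that the two modules are altered together
#' more often than gene-count chance allows.
#'
#' @param cohort named list sample -> altered gene vector.
#' @param partition a `"module_partition"` over the clustered subnetwork.
#' @param i,j module indices (0-based, as in the partition names).
#' @param n_perm number of permutations (default 10000).
#' @param seed optional integer seed.
#' @return list with `fraction`, `p_value` (`r / n_perm`), `p_label`
#'   (`"< 1/n_perm"` when no permutation reaches the observed value),
#'   `null_fractions`.
#' @export
cohit_test <- function(cohort, partition, i = 0, j = 1, n_perm = 10000,
                       seed = NULL) {
  mi <- partition$modules[[as.character(i)]]
  mj <- partition$modules[[as.character(j)]]
  if (is.null(mi) || is.null(mj)) stop("module index not in partition")
  universe <- names(partition$membership)
  cohit_frac <- function(sets) {
    mean(vapply(sets, function(g) any(g %in% mi) && any(g %in% mj), TRUE))
  }
  observed <- cohit_frac(cohort)
  counts <- vapply(cohort, function(g) sum(unique(g) %in% universe), 0L)
  nn <- length(universe)
  ni <- length(mi)
  nj <- length(mj)
  nulls <- with_seed(seed, {
    both <- matrix(FALSE, n_perm, length(counts))
    for (s in seq_along(counts)) {
      k <- counts[s]
      if (k == 0L) next
      xi <- stats::rhyper(n_perm, ni, nn - ni, k)
      xj <- stats::rhyper(n_perm, nj, nn - ni - nj, k - xi)
      both[, s] <- xi > 0L & xj > 0L
    }
    rowMeans(both)
  })
  r <- sum(nulls >= observed)
  list(fraction = observed,
       p_value = r / n_perm,
       p_label = if (r == 0) paste0("< ", format(1 / n_perm)) else
         format(r / n_perm),
       null_fractions = nulls)
}

#' Binary distance between sample incidence rows
#'
#' Asymmetric binary (Jaccard-type) distance: discordant positions divided by
#' positions where either row is 1; two all-zero rows are at distance 0.
#'
#' @param mat binary matrix (samples x modules).
#' @return a `dist` object.
#' @export
binary_sample_dist <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (s in seq_len(n)) {
    for (t in seq_len(s - 1L)) {
      active <- sum(mat[s, ] | mat[t, ])
      d[s, t] <- d[t, s] <-
        if (active == 0) 0 else sum(mat[s, ] != mat[t, ]) / active
    }
  }
  stats::as.dist(d)
}

#' Hierarchical clustering of samples on module incidence
#'
#' Complete-linkage agglomeration on the binary distance between sample
#' incidence rows; the tree is cut either at a height or into `k` clusters.
#'
#' @param mat binary sample x module matrix.
#' @param k desired number of clusters (used if `h` is `NULL`).
#' @param h cut height.
#' @return list with `clusters` (named list, cluster index -> sample ids,
#'   ordered by decreasing size), `assignment` (named integer vector) and
#'   `hclust` (the tree).
#' @export
cluster_samples <- function(mat, k = NULL, h = NULL) {
  if (nrow(mat) < 2L) stop("need at least two samples")
  hc <- stats::hclust(binary_sample_dist(mat), method = "complete")
  if (is.null(k) && is.null(h)) k <- 2L
  cut <- stats::cutree(hc, k = k, h = h)
  groups <- split(names(cut), cut)
  groups <- groups[order(-lengths(groups))]
  names(groups) <- as.character(seq_along(groups) - 1L)
  assignment <- stats::setNames(
    rep.int(seq_along(groups) - 1L, lengths(groups)), unlist(groups))
  list(clusters = groups, assignment = assignment, hclust = hc)
}

#' One-sided enrichment test on a 2x2 contingency table
#'
#' One-sided (enrichment) p-value for over-representation: the exact
#' hypergeometric upper tail P(X >= a), or the equivalent one-sided Fisher
#' exact test. `table[1, 1]` counts the doubly-positive cell.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param kind `"fisher"` or `"hypergeometric"`.
#' @return p-value.
#' @export
contingency_test <- function(table, kind = c("fisher", "hypergeometric")) {
  kind <- match.arg(kind)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) ||
      any(table != round(table))) {
    stop("need a 2x2 table of non-negative integer counts")
  }
  if (sum(table) == 0) stop("all-zero contingency table")
  if (kind == "fisher") {
    stats::fisher.test(table, alternative = "greater")$p.value
  } else {
    a <- table[1, 1]
    stats::phyper(a - 1, m = table[1, 1] + table[1, 2],
                  n = table[2, 1] + table[2, 2],
                  k = table[1, 1] + table[2, 1], lower.tail = FALSE)
  }
}

#' Read gene sets in GMT format
#'
#' `term<TAB>description<TAB>gene<TAB>gene...` per line.
#'
#' @param path file path.
#' @return named list term -> gene vector.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(f, function(x) unique(x[-(1:2)])),
                  vapply(f, `[`, "", 1))
}

#' Annotation enrichment of a module with permutation FDR
#'
#' For each term, the enrichment p-value is the binomial upper tail
#' P(X >= k) with X ~ Binomial(n = module size, p = fraction of the gene
#' universe annotated with the term). False-discovery rates come from
#' `n_perm` random same-size gene sets drawn from the universe: for a term
#' with observed p and ascending rank r, FDR = (mean count of null p-values
#' <= p per permutation) / r, clipped to \[0, 1\] and made monotone
#' non-decreasing in p (step-up).
#'
#' @param module character vector of genes (subset of `universe`).
#' @param annotations named list term -> gene vector (see [read_gmt()]).
#' @param universe character vector, the network gene universe.
#' @param n_perm permutations for the FDR (default 1000).
#' @param seed optional integer seed.
#' @return data.frame `term`, `k`, `n`, `p_bg`, `p_value`, `fdr`, sorted by
#'   `p_value`.
#' @export
enrich_annotations <- function(module, annotations, universe, n_perm = 1000,
                               seed = NULL) {
  module <- unique(module)
  universe <- unique(universe)
  if (!all(module %in% universe)) {
    stop("module must be a subset of the universe")
  }
  ann <- lapply(annotations, intersect, universe)
  empty <- lengths(ann) == 0L
  if (any(empty)) {
    warning(sum(empty), " term(s) with no gene in the universe skipped")
    ann <- ann[!empty]
  }
  if (length(ann) == 0L) {
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      p_bg = numeric(0), p_value = numeric(0),
                      fdr = numeric(0)))
  }
  n <- length(module)
  p_bg <- lengths(ann) / length(universe)
  k <- vapply(ann, function(g) sum(module %in% g), 0L)
  p <- stats::pbinom(k - 1, n, p_bg, lower.tail = FALSE)
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      rnd <- universe[sample.int(length(universe), n)]
      kb <- vapply(ann, function(g) sum(rnd %in% g), 0L)
      pb <- stats::pbinom(kb - 1, n, p_bg, lower.tail = FALSE)
      vapply(p, function(x) sum(pb <= x), 0L)
    }, integer(length(ann)))
  })
  null_counts <- matrix(null_counts, nrow = length(ann))
  mean_null <- rowMeans(null_counts)
  r <- rank(p, ties.method = "max")
  fdr <- pmin(1, pmax(0, mean_null / r))
  ord <- order(p, names(ann))
  fdr <- fdr[ord]
  fdr <- rev(cummin(rev(fdr)))   # step-up monotonization
  data.frame(term = names(ann)[ord], k = unname(k[ord]), n = n,
             p_bg = unname(p_bg[ord]), p_value = unname(p[ord]),
             fdr = unname(fdr), row.names = NULL)
}
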