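# Shared fixtures and independent oracles used across test files.

# --- graphs ----------------------------------------------------------------

# two k-cliques joined by a single bridge edge; vertices A*, B*
two_clique_bridge <- function(k = 5) {
  a <- sprintf("A%02d", seq_len(k))
  b <- sprintf("B%02d", seq_len(k))
  edges <- rbind(t(combn(a, 2)), t(combn(b, 2)), c(a[1], b[1]))
  igraph::graph_from_edgelist(edges, directed = FALSE)
}

# path graph with named vertices
path_graph <- function(nodes) {
  igraph::graph_from_edgelist(
    cbind(nodes[-length(nodes)], nodes[-1]), directed = FALSE)
}

# random connected G(n, p) graph with named vertices
random_connected_graph <- function(n, p) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  g
}

# --- independent oracles ---------------------------------------------------

# brute-force FI enumeration for a reaction: flatten roles by hand, then
# enumerate all unordered pairs over the non-output participants
oracle_reaction_pairs <- function(inputs, catalysts, activators, inhibitors) {
  parts <- sort(unique(c(inputs, catalysts, activators, inhibitors)))
  out <- character(0)
  n <- length(parts)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        out <- c(out, paste(parts[i], parts[j]))
      }
    }
  }
  out
}

# brute-force flattening of complex members against a registry of component
# lists (plain named list id -> members, members may be "complex:<id>")
oracle_flatten <- function(members, reg) {
  out <- character(0)
  for (m in members) {
    if (startsWith(m, "complex:")) {
      out <- c(out, oracle_flatten(reg[[sub("^complex:", "", m)]], reg))
    } else {
      out <- c(out, m)
    }
  }
  unique(out)
}

# exhaustive joint-table naive Bayes posterior, computed in plain probability
# space directly from training counts (no log transform, no model object)
oracle_nbc_posterior <- function(pos_mat, neg_mat, prior, v) {
  th1 <- (colSums(pos_mat) + 1) / (nrow(pos_mat) + 2)
  th0 <- (colSums(neg_mat) + 1) / (nrow(neg_mat) + 2)
  l1 <- prod(ifelse(v, th1, 1 - th1))
  l0 <- prod(ifelse(v, th0, 1 - th0))
  prior * l1 / (prior * l1 + (1 - prior) * l0)
}

# exact minimum number of linker nodes: smallest subset S of non-candidates
# such that the induced subgraph on candidates + S has all candidates in one
# connected component
oracle_min_linkers <- function(g, candidates) {
  others <- setdiff(igraph::V(g)$name, candidates)
  connected_with <- function(extra) {
    sub <- igraph::induced_subgraph(g, c(candidates, extra))
    comp <- igraph::components(sub)$membership
    length(unique(comp[candidates])) == 1L
  }
  for (k in 0:length(others)) {
    if (k == 0) {
      if (connected_with(character(0))) return(0L)
    } else {
      subsets <- combn(others, k, simplify = FALSE)
      for (s in subsets) {
        if (connected_with(s)) return(k)
      }
    }
  }
  stop("candidates cannot be connected")  # unreachable on connected graphs
}

# random logical feature matrix
random_feature_matrix <- function(n, p = 0.3) {
  matrix(runif(n * length(FI_FEATURES)) < p, nrow = n,
         dimnames = list(NULL, FI_FEATURES))
}

# small shared synthetic world, built once per test run
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- gen_pathway_world(world_spec(n_proteins = 120, n_pathways = 12,
                                             seed = 42))
    }
    cache
  }
})

# the default study-condition world (500 proteins, 40 pathways, seed 1) and
# its evidence sources, built once per test run
default_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- gen_pathway_world(world_spec())
    cache
  }
})

default_sources <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- gen_feature_sources(default_world())
    cache
  }
})
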