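#' Merge pathway-derived and predicted FIs into one annotated network
#'
#' The union of the two FI sets, deduplicated by unordered pair. When a pair
#' occurs in both, the pathway row wins: provenance stays `"pathway"` and its
#' direction tag is retained (predicted FIs are always undirected). Source
#' labels are unioned. The result is an undirected `igraph` graph whose edges
#' carry `provenance`, `direction`, `source_protein` and `sources`
#' attributes; directionality is an annotation, not an edge orientation,
#' because all network analyses here treat FIs as undirected adjacency.
#'
#' @param pathway_fis,predicted_fis [fi_table()]s (either may be empty).
#' @param nodes optional extra node names to include as isolated vertices.
#' @return an `igraph` graph.
#' @export
merge_fi_network <- function(pathway_fis = fi_table(),
                             predicted_fis = fi_table(), nodes = NULL) {
  keep <- c("protein_a", "protein_b", "provenance", "direction",
            "source_protein", "sources")
  fis <- dedup_fi_table(rbind(as.data.frame(pathway_fis)[, keep],
                              as.data.frame(predicted_fis)[, keep]))
  fi_network(fis, nodes = nodes)
}

#' Build an igraph network from an FI table
#'
#' @param fis an [fi_table()] (assumed deduplicated).
#' @param nodes optional extra vertex names.
#' @return an undirected `igraph` graph with FI edge attributes.
#' @export
fi_network <- function(fis, nodes = NULL) {
  vnames <- sort(unique(c(fis$protein_a, fis$protein_b, nodes)))
  g <- igraph::graph_from_data_frame(
    as.data.frame(fis)[, c("protein_a", "protein_b", "provenance",
                           "direction", "source_protein", "sources"),
                       drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = vnames, stringsAsFactors = FALSE))
  g
}

#' Recover the FI table of a network
#'
#' @param net an `igraph` graph built by [fi_network()] /
#'   [merge_fi_network()].
#' @return an [fi_table()].
#' @export
as_fi_table <- function(net) {
  if (igraph::ecount(net) == 0L) {
    return(fi_table())
  }
  el <- igraph::as_data_frame(net, what = "edges")
  out <- fi_table(el$from, el$to, provenance = el$provenance,
                  direction = el$direction, source_protein = el$source_protein,
                  sources = el$sources)
  dedup_fi_table(out)
}

#' Descriptive statistics of an FI network
#'
#' Node/edge counts, mean and maximum connection degree (number of
#' interaction partners per protein), and connected component sizes in
#' descending order.
#'
#' @param net an `igraph` graph.
#' @return list with `n_nodes`, `n_edges`, `mean_degree`, `max_degree`,
#'   `components` (integer vector, descending).
#' @export
network_stats <- function(net) {
  deg <- igraph::degree(net)
  comp <- igraph::components(net)
  list(n_nodes = igraph::vcount(net),
       n_edges = igraph::ecount(net),
       mean_degree = if (length(deg)) mean(deg) else 0,
       max_degree = if (length(deg)) max(deg) else 0,
       components = sort(as.integer(comp$csize), decreasing = TRUE))
}

#' GO cellular-component sharing rate of an edge set
#'
#' Fraction of edges whose endpoints share at least one cellular-component
#' annotation, among the evaluable edges (both endpoints annotated with at
#' least one CC term). Sharing of subcellular localization was not a
#' classifier feature, so it serves as an independent quality check of a
#' predicted FI set against, e.g., the raw physical-interaction input.
#'
#' @param edges an [fi_table()], two-column matrix/data.frame or key vector.
#' @param go_cc data.frame `protein`, `term` (optionally `aspect`, filtered
#'   to `"C"`).
#' @return list with `rate`, `n_evaluable`, `n_sharing`.
#' @export
cc_sharing_rate <- function(edges, go_cc) {
  if (inherits(edges, "fi_table")) {
    edges <- cbind(edges$protein_a, edges$protein_b)
  }
  p <- split_pair_keys(as_pair_keys(edges))
  if ("aspect" %in% names(go_cc)) {
    go_cc <- go_cc[is.na(go_cc$aspect) | go_cc$aspect == "C", , drop = FALSE]
  }
  terms <- split(go_cc$term, go_cc$protein)
  t1 <- terms[p[, 1]]
  t2 <- terms[p[, 2]]
  evaluable <- !vapply(t1, is.null, TRUE) & !vapply(t2, is.null, TRUE)
  if (!any(evaluable)) {
    stop("no evaluable edges: no edge has both endpoints CC-annotated")
  }
  sharing <- mapply(function(x, y) length(intersect(x, y)) > 0,
                    t1[evaluable], t2[evaluable])
  list(rate = mean(sharing), n_evaluable = sum(evaluable),
       n_sharing = sum(sharing))
}

#' Map an accession-level FI table to gene symbols
#'
#' Cancer cohort analysis works on gene symbols. Accessions are translated
#' via a two-column map, unmapped accessions are dropped (their count is
#' reported in a message) and the result re-deduplicated, since several
#' accessions can collapse onto one symbol.
#'
#' @param fis an [fi_table()].
#' @param symbol_map data.frame `accession`, `symbol`.
#' @return an [fi_table()] in symbol space.
#' @export
map_to_gene_symbols <- function(fis, symbol_map) {
  sym <- stats::setNames(toupper(symbol_map$symbol), symbol_map$accession)
  a <- unname(sym[fis$protein_a])
  b <- unname(sym[fis$protein_b])
  src <- unname(sym[fis$source_protein])
  drop <- is.na(a) | is.na(b) | a == b
  n_unmapped <- sum(is.na(a) | is.na(b))
  if (n_unmapped > 0L) {
    message(n_unmapped, " FI(s) dropped: unmapped accession(s)")
  }
  out <- fi_table(a[!drop], b[!drop], provenance = fis$provenance[!drop],
                  direction = fis$direction[!drop],
                  source_protein = src[!drop], sources = fis$sources[!drop])
  dedup_fi_table(out)
}

#' Export a network as GraphML
#'
#' @param net an `igraph` graph.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  ea <- igraph::edge_attr(net, "source_protein")
  if (!is.null(ea)) {
    igraph::E(net)$source_protein <- ifelse(is.na(ea), "", ea)
  }
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}
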