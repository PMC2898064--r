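#' The nine evidence features, in canonical order
#'
#' Feature order used everywhere a feature matrix or classifier parameter
#' vector appears: human physical PPIs; PPIs between fly, worm and yeast
#' orthologs (interologs); domain-domain interaction; two independent
#' co-expression sets; shared GO biological-process annotation; text-mined
#' PPIs.
#'
#' @export
FI_FEATURES <- c("human_ppi", "fly_interolog", "worm_interolog",
                 "yeast_interolog", "domain_interaction", "coexpr_set1",
                 "coexpr_set2", "go_bp_shared", "textmined_ppi")

# evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. A NULL seed uses (and advances) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# accept a pair set as canonical keys, a two-column matrix or a data.frame
as_pair_keys <- function(x) {
  if (is.character(x) && is.null(dim(x))) {
    return(unique(x))
  }
  if (is.data.frame(x)) x <- as.matrix(x[, 1:2])
  unique(pair_keys(x[, 1], x[, 2]))
}

#' Load an interaction evidence file as a set of unordered pairs
#'
#' Supports two dialects. A plain participant TSV has one interaction record
#' per line whose non-empty tab-separated fields are the participants (two or
#' more). A PSI-MI TAB 2.5 subset uses columns 1-2 as interactor identifiers
#' (database prefixes such as `uniprotkb:` are stripped); when an interaction
#' identifier column (column 14) is present, lines sharing an identifier are
#' reassembled into one n-ary record before filtering.
#'
#' Records with more than `max_interactors` distinct participants are dropped
#' (experiments such as co-immunoprecipitation pull-downs list whole
#' complexes; large records correlate poorly with true functional
#' interactions). Retained records are matrix-expanded to all unordered
#' pairs; self-pairs are removed and the result deduplicated.
#'
#' @param path file path.
#' @param max_interactors drop records with more distinct participants
#'   (default 4).
#' @param format `"auto"` (default; files with >= 11 columns are treated as
#'   PSI-MI TAB), `"pairs"` or `"mitab"`.
#' @return two-column character matrix of canonical unordered pairs.
#' @export
load_interactions <- function(path, max_interactors = 4,
                              format = c("auto", "pairs", "mitab")) {
  format <- match.arg(format)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    return(split_pair_keys(character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "auto") {
    format <- if (length(fields[[1]]) >= 11L) "mitab" else "pairs"
  }
  records <- list()
  if (format == "mitab") {
    ids_a <- vapply(fields, function(f) f[1], character(1))
    ids_b <- vapply(fields, function(f) if (length(f) >= 2L) f[2] else "",
                    character(1))
    bad <- !nzchar(ids_a) | !nzchar(ids_b)
    if (any(bad)) {
      stop("malformed PSI-MI TAB line ", lineno[which(bad)[1]],
           ": missing interactor column")
    }
    grp <- vapply(fields, function(f) {
      if (length(f) >= 14L && nzchar(f[14]) && f[14] != "-") f[14] else NA_character_
    }, character(1))
    grp[is.na(grp)] <- paste0(".line", seq_along(fields))[is.na(grp)]
    records <- lapply(split(c(rbind(ids_a, ids_b)), rep(grp, each = 2)),
                      function(v) unique(normalize_accession(v)))
  } else {
    for (i in seq_along(fields)) {
      f <- fields[[i]][nzchar(fields[[i]])]
      if (length(f) < 2L) {
        stop("malformed pair line ", lineno[i], ": fewer than two participants")
      }
      # a record may collapse to one distinct participant (a self-pair);
      # it then simply contributes no pairs
      records[[i]] <- unique(normalize_accession(f))
    }
  }
  records <- records[vapply(records, length, 0L) <= max_interactors]
  pairs <- lapply(records, all_unordered_pairs)
  keys <- unique(unlist(lapply(pairs, function(p) {
    if (nrow(p)) pair_keys(p[, 1], p[, 2]) else character(0)
  })))
  split_pair_keys(sort(keys))
}

#' Read an ortholog map (species protein -> human accessions)
#'
#' Two-column TSV `species_id<TAB>human_accession`; many-to-many mappings are
#' allowed (one row per mapping).
#'
#' @param path file path.
#' @return data.frame with columns `from`, `to`.
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", comment.char = "#")
  stats::setNames(df[, 1:2], c("from", "to"))
}

#' Project model-organism interactions onto human pairs (interologs)
#'
#' For a non-human pair (x, y), every human pair (hx, hy) with hx an ortholog
#' of x and hy an ortholog of y is emitted (self-pairs excluded). Proteins
#' without orthologs contribute nothing.
#'
#' @param pairs two-column matrix/data.frame of non-human pairs.
#' @param ortholog_map data.frame `from`, `to` as from [read_ortholog_map()].
#' @return two-column character matrix of canonical human pairs.
#' @export
project_interologs <- function(pairs, ortholog_map) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L) {
    return(split_pair_keys(character(0)))
  }
  names(pairs)[1:2] <- c("x", "y")
  pairs$.row <- seq_len(nrow(pairs))
  m1 <- merge(pairs, ortholog_map, by.x = "x", by.y = "from")
  names(m1)[names(m1) == "to"] <- "hx"
  m2 <- merge(m1, ortholog_map, by.x = "y", by.y = "from")
  names(m2)[names(m2) == "to"] <- "hy"
  m2 <- m2[m2$hx != m2$hy, , drop = FALSE]
  split_pair_keys(sort(unique(pair_keys(m2$hx, m2$hy))))
}

#' Read a GAF-like annotation table
#'
#' Three-column TSV `protein<TAB>go_id<TAB>aspect` (aspect one of `P`, `C`,
#' `F`). Lines starting with `!` or `#` are ignored.
#'
#' @param path file path.
#' @param aspect optional filter (`"P"`, `"C"` or `"F"`).
#' @return data.frame with columns `protein`, `term`, `aspect`.
#' @export
read_gaf <- function(path, aspect = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^[!#]", lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  df <- data.frame(protein = vapply(f, `[`, "", 1),
                   term = vapply(f, `[`, "", 2),
                   aspect = vapply(f, function(x) {
                     if (length(x) >= 3L) x[3] else NA_character_
                   }, ""),
                   stringsAsFactors = FALSE)
  if (!is.null(aspect)) df <- df[!is.na(df$aspect) & df$aspect == aspect, ]
  df
}

# pair keys implied by shared membership in annotation terms, after dropping
# excluded terms and terms annotating >= max_frac of all annotated proteins
.shared_term_pair_keys <- function(annotations, max_frac = 0.25,
                                   exclude = character(0)) {
  annotations <- unique(annotations[, c("protein", "term")])
  annotations <- annotations[!(annotations$term %in% exclude), , drop = FALSE]
  n_annotated <- length(unique(annotations$protein))
  if (n_annotated == 0L) {
    return(character(0))
  }
  sizes <- table(annotations$term)
  broad <- names(sizes)[as.vector(sizes) >= max_frac * n_annotated]
  annotations <- annotations[!(annotations$term %in% broad), , drop = FALSE]
  by_term <- split(annotations$protein, annotations$term)
  unique(unlist(lapply(by_term, function(p) {
    pr <- all_unordered_pairs(p)
    if (nrow(pr)) pair_keys(pr[, 1], pr[, 2]) else character(0)
  })))
}

# pair keys implied by a domain-domain interaction table
.domain_pair_keys <- function(protein_domains, domain_pairs) {
  by_domain <- split(unique(protein_domains)$protein,
                     unique(protein_domains)$domain)
  keys <- character(0)
  for (i in seq_len(nrow(domain_pairs))) {
    d1 <- as.character(domain_pairs[i, 1])
    d2 <- as.character(domain_pairs[i, 2])
    p1 <- by_domain[[d1]]
    p2 <- by_domain[[d2]]
    if (is.null(p1) || is.null(p2)) next
    if (d1 == d2) {
      pr <- all_unordered_pairs(p1)
      if (nrow(pr)) keys <- c(keys, pair_keys(pr[, 1], pr[, 2]))
    } else {
      g <- expand.grid(a = p1, b = p2, stringsAsFactors = FALSE)
      g <- g[g$a != g$b, , drop = FALSE]
      if (nrow(g)) keys <- c(keys, pair_keys(g$a, g$b))
    }
  }
  unique(keys)
}

#' Assemble the nine-feature evidence matrix for candidate pairs
#'
#' Features follow a closed-world assumption: a feature is `TRUE` iff the
#' corresponding evidence source contains the pair, and `FALSE` otherwise
#' (absence of evidence is evidence of absence for classifier purposes).
#'
#' * Set-based features (`human_ppi`, the three interologs, the two
#'   co-expression sets, `textmined_ppi`) are looked up directly in the
#'   supplied pair sets.
#' * `domain_interaction` is `TRUE` iff some domain of one protein interacts
#'   with some domain of the other per the domain-pair table.
#' * `go_bp_shared` is `TRUE` iff the two proteins share at least one GO
#'   biological-process term that is neither in `go_bp_exclude` (e.g. the BP
#'   root) nor annotates at least `go_bp_max_frac` of all annotated proteins
#'   (broad terms say little about shared participation in a specific
#'   reaction).
#'
#' @param candidates two-column matrix/data.frame of unordered candidate
#'   pairs.
#' @param sources named list of pair sets (keys, matrices or data.frames);
#'   names must be among the set-based features above.
#' @param go_bp data.frame `protein`, `term` (optionally `aspect`, filtered to
#'   `"P"`) or `NULL`.
#' @param domains list with `protein_domains` (data.frame `protein`,
#'   `domain`) and `domain_pairs` (two-column data.frame), or `NULL`.
#' @param go_bp_max_frac breadth filter threshold (default 0.25).
#' @param go_bp_exclude term ids never counted as shared.
#' @return data.frame: `protein_a`, `protein_b`, then the nine logical
#'   feature columns in [FI_FEATURES] order.
#' @export
build_feature_matrix <- function(candidates, sources = list(), go_bp = NULL,
                                 domains = NULL, go_bp_max_frac = 0.25,
                                 go_bp_exclude = character(0)) {
  if (is.data.frame(candidates)) candidates <- as.matrix(candidates[, 1:2])
  a <- pmin(candidates[, 1], candidates[, 2])
  b <- pmax(candidates[, 1], candidates[, 2])
  if (any(a == b)) stop("candidate pairs must have distinct members")
  keys <- pair_keys(a, b)
  set_features <- setdiff(FI_FEATURES, c("domain_interaction", "go_bp_shared"))
  unknown <- setdiff(names(sources), set_features)
  if (length(unknown) > 0L) {
    stop("unknown source feature(s): ", paste(unknown, collapse = ", "))
  }
  out <- data.frame(protein_a = a, protein_b = b, stringsAsFactors = FALSE)
  for (f in set_features) {
    src <- sources[[f]]
    out[[f]] <- if (is.null(src)) rep(FALSE, length(keys)) else
      keys %in% as_pair_keys(src)
  }
  if (!is.null(domains)) {
    dk <- .domain_pair_keys(domains$protein_domains, domains$domain_pairs)
    out$domain_interaction <- keys %in% dk
  } else {
    out$domain_interaction <- FALSE
  }
  if (!is.null(go_bp)) {
    if ("aspect" %in% names(go_bp)) {
      go_bp <- go_bp[is.na(go_bp$aspect) | go_bp$aspect == "P", , drop = FALSE]
    }
    gk <- .shared_term_pair_keys(go_bp, max_frac = go_bp_max_frac,
                                 exclude = go_bp_exclude)
    out$go_bp_shared <- keys %in% gk
  } else {
    out$go_bp_shared <- FALSE
  }
  out[, c("protein_a", "protein_b", FI_FEATURES)]
}

#' Odds-ratio screen of an evidence source against a reference FI set
#'
#' Measures how strongly membership in an evidence pair set correlates with
#' membership in a reference (pathway-derived) FI set, against random control
#' pairs drawn from the reference protein universe. For each permutation a
#' control set the same size as the (universe-restricted) evidence set is
#' drawn, and the odds ratio `(a d)/(b c)` is computed from the 2x2 table of
#' evidence-set membership against reference-vs-control. Zero cells receive
#' the Haldane-Anscombe +0.5 continuity correction. The mean and standard
#' deviation over permutations are returned.
#'
#' @param feature_pairs evidence pair set (keys, matrix or data.frame).
#' @param reference_fis reference FI pair set (keys, matrix, data.frame or
#'   [fi_table()]).
#' @param n_perm number of control permutations (default 10).
#' @param seed optional integer seed.
#' @return list with `odds_ratio` (mean), `sd`, `n_permutations` and
#'   `per_permutation`.
#' @export
# odds ratio (a d)/(b c) with Haldane-Anscombe +0.5 when any cell is zero
.odds_ratio_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells == 0)) cells <- cells + 0.5
  (cells[1] * cells[4]) / (cells[2] * cells[3])
}

odds_ratio <- function(feature_pairs, reference_fis, n_perm = 10, seed = NULL) {
  if (inherits(reference_fis, "fi_table")) {
    reference_fis <- pair_keys(reference_fis$protein_a, reference_fis$protein_b)
  }
  ref <- as_pair_keys(reference_fis)
  universe <- sort(unique(as.vector(split_pair_keys(ref))))
  feat <- as_pair_keys(feature_pairs)
  fp <- split_pair_keys(feat)
  feat <- feat[fp[, 1] %in% universe & fp[, 2] %in% universe]
  n_ctrl <- length(feat)
  if (n_ctrl == 0L) {
    stop("no evidence pairs fall inside the reference protein universe")
  }
  a <- sum(feat %in% ref)
  cc <- length(ref) - a
  ors <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    ctrl <- sample_pairs(universe, n_ctrl)
    bb <- sum(pair_keys(ctrl[, 1], ctrl[, 2]) %in% feat)
    .odds_ratio_2x2(a, bb, cc, n_ctrl - bb)
  }, numeric(1)))
  list(odds_ratio = mean(ors), sd = stats::sd(ors), n_permutations = n_perm,
       per_permutation = ors)
}
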