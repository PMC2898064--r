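#' Canonical unordered protein-pair keys
#'
#' Protein pairs throughout the package are unordered. A pair is stored in
#' canonical form with the lexicographically smaller identifier first, and is
#' addressed by a single string key (the two identifiers joined by a space).
#' Identifiers must not contain whitespace.
#'
#' @param a,b character vectors of identifiers (recycled to common length).
#' @return `pair_keys()`: a character vector of canonical keys.
#' @export
#' @examples
#' pair_keys(c("B", "C"), c("A", "A"))
pair_keys <- function(a, b) {
  paste(pmin(a, b), pmax(a, b))
}

#' @rdname pair_keys
#' @param keys character vector of canonical pair keys.
#' @return `split_pair_keys()`: a two-column character matrix
#'   (`protein_a`, `protein_b`).
#' @export
split_pair_keys <- function(keys) {
  if (length(keys) == 0L) {
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("protein_a", "protein_b"))))
  }
  parts <- strsplit(keys, " ", fixed = TRUE)
  m <- matrix(unlist(parts), ncol = 2, byrow = TRUE)
  colnames(m) <- c("protein_a", "protein_b")
  m
}

#' All unordered pairs over a set of identifiers
#'
#' Enumerates C(n, 2) unordered pairs in canonical order. Duplicated members
#' are collapsed first; self-pairs never occur.
#'
#' @param members character vector.
#' @return two-column character matrix (possibly 0 rows).
#' @keywords internal
all_unordered_pairs <- function(members) {
  members <- sort(unique(members))
  n <- length(members)
  if (n < 2L) {
    return(matrix(character(0), ncol = 2,
                  dimnames = list(NULL, c("protein_a", "protein_b"))))
  }
  m <- t(utils::combn(members, 2L))
  colnames(m) <- c("protein_a", "protein_b")
  m
}

#' Strip database prefixes and splice-isoform suffixes from accessions
#'
#' Pair-evidence files often carry namespaced identifiers such as
#' `uniprotkb:P12345` and splice isoforms such as `P12345-2`. Identity in the
#' FI network is by base accession, so both decorations are removed.
#'
#' @param x character vector of raw identifiers.
#' @return character vector of base accessions.
#' @export
#' @examples
#' normalize_accession(c("uniprotkb:P12345-2", "Q00001"))
normalize_accession <- function(x) {
  x <- sub("^[A-Za-z0-9_.]+:", "", x)
  sub("-[0-9]+$", "", x)
}

#' Sample distinct unordered pairs uniformly from a protein universe
#'
#' Draws `n` distinct unordered pairs from all C(|universe|, 2) pairs,
#' optionally excluding a set of known pairs. Sampling is by pair index, so it
#' is uniform over the eligible pairs and cheap even for large universes.
#'
#' @param universe character vector of identifiers (deduplicated internally).
#' @param n number of pairs to draw.
#' @param exclude character vector of canonical pair keys to exclude.
#' @return two-column character matrix of canonical pairs.
#' @keywords internal
sample_pairs <- function(universe, n, exclude = character(0)) {
  universe <- sort(unique(universe))
  nu <- length(universe)
  total <- choose(nu, 2)
  if (total - length(unique(exclude)) < n) {
    stop("not enough unordered pairs available to sample ", n,
         " pairs from a universe of ", nu, " proteins")
  }
  # linear pair index -> (i, j), i < j, over sorted universe
  idx_to_pair <- function(idx) {
    # index within the sequence of pairs (1,2), (1,3), ..., (1,nu), (2,3), ...
    i <- findInterval(idx - 1, cumsum(c(0, (nu - 1):1)), left.open = FALSE)
    off <- idx - c(0, cumsum((nu - 1):1))[i]
    cbind(universe[i], universe[i + off])
  }
  got <- character(0)
  excl <- unique(exclude)
  while (length(got) < n) {
    take <- min(total, ceiling((n - length(got)) * 1.2) + 10L)
    idx <- sample.int(total, take, replace = TRUE)
    p <- idx_to_pair(idx)
    k <- pair_keys(p[, 1], p[, 2])
    k <- setdiff(unique(k), c(excl, got))
    got <- c(got, k)
  }
  split_pair_keys(got[seq_len(n)])
}
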