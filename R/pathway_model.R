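#' Pathway records: reactions, complexes and regulation entries
#'
#' A pathway is represented as a plain list with fields `id`, `source` (a
#' dataset label used for FI provenance), `reactions`, `complexes` and
#' `regulations`. Reactions carry five role sets (`inputs`, `catalysts`,
#' `activators`, `inhibitors`, `outputs`); members are protein accessions or
#' references to complexes written as `complex:<id>`. Complexes carry a
#' `components` vector with the same member syntax, so nesting is allowed (the
#' nesting graph must be acyclic). Regulation entries describe
#' transcription-factor-to-target records (`factor`, `targets`).
#'
#' @param id record identifier.
#' @param inputs,catalysts,activators,inhibitors,outputs character vectors of
#'   members (accessions or `complex:<id>`); role sets may overlap.
#' @return a list of class `"reaction_record"`.
#' @export
reaction_record <- function(id, inputs = character(0), catalysts = character(0),
                            activators = character(0), inhibitors = character(0),
                            outputs = character(0)) {
  structure(list(id = as.character(id),
                 inputs = as.character(inputs),
                 catalysts = as.character(catalysts),
                 activators = as.character(activators),
                 inhibitors = as.character(inhibitors),
                 outputs = as.character(outputs)),
            class = "reaction_record")
}

#' @rdname reaction_record
#' @param components character vector of members (accessions or
#'   `complex:<id>`).
#' @export
complex_record <- function(id, components = character(0)) {
  structure(list(id = as.character(id), components = as.character(components)),
            class = "complex_record")
}

#' @rdname reaction_record
#' @param source dataset label attached to every FI extracted from the
#'   pathway.
#' @param reactions,complexes,regulations lists of the respective records.
#' @export
pathway_record <- function(id, source = id, reactions = list(),
                           complexes = list(), regulations = list()) {
  structure(list(id = as.character(id), source = as.character(source),
                 reactions = reactions, complexes = complexes,
                 regulations = regulations),
            class = "pathway_record")
}

is_complex_ref <- function(x) startsWith(x, "complex:")

#' Recursively flatten complex members to base protein accessions
#'
#' Resolves `complex:<id>` references against a registry of complex records
#' and strips splice-isoform suffixes. Cyclic nesting is a structural error.
#'
#' @param members character vector of members.
#' @param registry named list of `complex_record` objects, keyed by id.
#' @param .stack internal; ids currently being expanded (cycle detection).
#' @return character vector of distinct protein accessions.
#' @export
flatten_members <- function(members, registry = list(), .stack = character(0)) {
  out <- character(0)
  for (m in members) {
    if (is_complex_ref(m)) {
      cid <- sub("^complex:", "", m)
      if (cid %in% .stack) {
        stop("cyclic complex nesting detected at complex '", cid, "'")
      }
      cx <- registry[[cid]]
      if (is.null(cx)) {
        stop("reference to unknown complex '", cid, "'")
      }
      out <- c(out, flatten_members(cx$components, registry, c(.stack, cid)))
    } else {
      out <- c(out, normalize_accession(m))
    }
  }
  unique(out)
}

#' Construct a functional-interaction table
#'
#' The package-wide tabular representation of functional interactions: one row
#' per unordered protein pair with columns `protein_a`, `protein_b` (canonical
#' order), `provenance` (`"pathway"` or `"predicted"`), `direction`
#' (`"undirected"`, `"activates"`, `"inhibits"`, `"expression_regulates"`),
#' `source_protein` (the oriented source accession for directed FIs, `NA`
#' otherwise) and `sources` (`;`-joined sorted dataset labels).
#'
#' @param protein_a,protein_b character vectors (reordered canonically).
#' @param provenance,direction,source_protein,sources per-row annotations,
#'   recycled.
#' @return a `data.frame` of class `c("fi_table", "data.frame")`.
#' @export
fi_table <- function(protein_a = character(0), protein_b = character(0),
                     provenance = "pathway", direction = "undirected",
                     source_protein = NA_character_, sources = "") {
  a <- pmin(protein_a, protein_b)
  b <- pmax(protein_a, protein_b)
  df <- data.frame(protein_a = a, protein_b = b,
                   provenance = rep_len(as.character(provenance), length(a)),
                   direction = rep_len(as.character(direction), length(a)),
                   source_protein = rep_len(as.character(source_protein), length(a)),
                   sources = rep_len(as.character(sources), length(a)),
                   stringsAsFactors = FALSE)
  bad <- df$direction != "undirected" & df$provenance != "pathway"
  if (any(bad)) {
    stop("directed FIs must have provenance 'pathway'")
  }
  class(df) <- c("fi_table", "data.frame")
  df
}

# direction tag for one pair given flattened role sets; regulator->input pairs
# get a direction, everything else is undirected. The inhibitor role wins over
# catalyst/activator when a protein holds several roles.
.pair_direction <- function(x, y, inputs, cata, inhib) {
  dir_for <- function(src, tgt) {
    if (src %in% inhib && tgt %in% inputs) {
      c("inhibits", src)
    } else if (src %in% cata && tgt %in% inputs) {
      c("activates", src)
    } else {
      NULL
    }
  }
  d <- dir_for(x, y)
  if (is.null(d)) d <- dir_for(y, x)
  if (is.null(d)) d <- c("undirected", NA_character_)
  d
}

#' Extract functional interactions from one reaction
#'
#' Two proteins functionally interact when they take part in the same
#' biochemical reaction as an input, catalyst, activator or inhibitor.
#' Complexes appearing in roles are flattened to their protein components
#' first; outputs never contribute. Returns all unordered pairs over the
#' participating proteins. Catalyst/activator-to-input pairs are tagged
#' `activates` (oriented from the regulator), inhibitor-to-input pairs
#' `inhibits`; all other pairs are undirected.
#'
#' @param r a `reaction_record`.
#' @param registry named list of `complex_record`s for resolving
#'   `complex:<id>` members.
#' @param source dataset label recorded on each FI.
#' @return an [fi_table()].
#' @export
extract_fis_from_reaction <- function(r, registry = list(), source = r$id) {
  inputs <- flatten_members(r$inputs, registry)
  cata <- flatten_members(c(r$catalysts, r$activators), registry)
  inhib <- flatten_members(r$inhibitors, registry)
  participants <- unique(c(inputs, cata, inhib))
  pairs <- all_unordered_pairs(participants)
  if (nrow(pairs) == 0L) {
    return(fi_table())
  }
  dirs <- t(apply(pairs, 1, function(p) {
    .pair_direction(p[1], p[2], inputs, cata, inhib)
  }))
  fi_table(pairs[, 1], pairs[, 2], provenance = "pathway",
           direction = dirs[, 1], source_protein = dirs[, 2],
           sources = source)
}

#' Extract functional interactions from one complex
#'
#' Two members of the same protein complex functionally interact, since the
#' activity of the complex presumably depends on all of its subunits. Nested
#' complexes are flattened recursively. All pairs are undirected.
#'
#' @param cx a `complex_record`.
#' @inheritParams extract_fis_from_reaction
#' @return an [fi_table()].
#' @export
extract_fis_from_complex <- function(cx, registry = list(), source = cx$id) {
  prots <- flatten_members(cx$components, registry)
  if (length(prots) == 0L) {
    warning("complex '", cx$id, "' has no protein components")
    return(fi_table())
  }
  pairs <- all_unordered_pairs(prots)
  if (nrow(pairs) == 0L) {
    return(fi_table())
  }
  fi_table(pairs[, 1], pairs[, 2], provenance = "pathway",
           direction = "undirected", sources = source)
}

# direction precedence used when merging duplicate reports of the same pair
.DIRECTION_RANK <- c(undirected = 0, expression_regulates = 1,
                     activates = 2, inhibits = 3)

#' Deduplicate an FI table
#'
#' Collapses duplicate unordered pairs. Provenance `"pathway"` wins over
#' `"predicted"`; a directed report wins over an undirected one (so a reaction
#' pair and a complex pair merge into one FI that keeps the direction); among
#' distinct directed tags the precedence is inhibits > activates >
#' expression_regulates. Source labels are unioned.
#'
#' @param fis an [fi_table()] (or rbind of several).
#' @return a deduplicated [fi_table()], sorted by pair.
#' @export
dedup_fi_table <- function(fis) {
  if (nrow(fis) == 0L) {
    return(fi_table())
  }
  key <- pair_keys(fis$protein_a, fis$protein_b)
  ord <- order(key,
               fis$provenance != "pathway",            # pathway rows first
               -.DIRECTION_RANK[fis$direction])        # strongest direction first
  fis <- fis[ord, , drop = FALSE]
  key <- key[ord]
  first <- !duplicated(key)
  out <- fis[first, , drop = FALSE]
  src <- vapply(split(fis$sources, factor(key, levels = unique(key))),
                function(s) {
                  paste(sort(unique(unlist(strsplit(s, ";", fixed = TRUE)))),
                        collapse = ";")
                }, character(1))
  out$sources <- unname(src)
  rownames(out) <- NULL
  class(out) <- c("fi_table", "data.frame")
  out
}

#' Extract the pathway-derived FI set from a collection of pathways
#'
#' Runs reaction, complex and regulation extraction over every pathway and
#' returns the deduplicated union. Each FI records every contributing pathway
#' source label; a directed and an undirected report of the same pair merge
#' into one FI that keeps the direction. Transcription-factor-to-target
#' regulation records yield `expression_regulates` FIs oriented from the
#' factor.
#'
#' @param pathways list of `pathway_record`s (may be empty).
#' @return an [fi_table()] with provenance `"pathway"`.
#' @export
build_pathway_fi_set <- function(pathways) {
  parts <- list(fi_table())
  for (pw in pathways) {
    registry <- stats::setNames(pw$complexes,
                                vapply(pw$complexes, `[[`, "", "id"))
    for (r in pw$reactions) {
      parts[[length(parts) + 1L]] <-
        extract_fis_from_reaction(r, registry, source = pw$source)
    }
    for (cx in pw$complexes) {
      parts[[length(parts) + 1L]] <-
        extract_fis_from_complex(cx, registry, source = pw$source)
    }
    for (rg in pw$regulations) {
      f <- normalize_accession(rg$factor)
      tg <- setdiff(normalize_accession(rg$targets), f)
      if (length(tg) > 0L) {
        parts[[length(parts) + 1L]] <-
          fi_table(rep(f, length(tg)), tg, provenance = "pathway",
                   direction = "expression_regulates", source_protein = f,
                   sources = pw$source)
      }
    }
  }
  dedup_fi_table(do.call(rbind, parts))
}
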