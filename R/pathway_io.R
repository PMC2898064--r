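#' Read and write the line-oriented pathway TSV dialect
#'
#' A deliberately small text format carrying exactly the pathway content the
#' FI definition needs. One record per line, tab-separated:
#'
#' * `PATHWAY<TAB>id<TAB>source_label` starts a pathway block (the label is
#'   recorded as FI provenance source);
#' * `REACTION<TAB>id<TAB>role=member;member<TAB>...` with roles among
#'   `input`, `catalyst`, `activator`, `inhibitor`, `output`;
#' * `COMPLEX<TAB>id<TAB>member;member;...`;
#' * `REGULATION<TAB>id<TAB>factor=X<TAB>targets=A;B` for
#'   transcription-factor-to-target records.
#'
#' Members are protein accessions or `complex:<id>` references. Lines starting
#' with `#` and blank lines are ignored. Records appearing before any
#' `PATHWAY` line are collected into an implicit pathway named `"pathway1"`.
#'
#' @param path file path.
#' @return `read_pathway_tsv()`: a list of `pathway_record`s.
#' @export
read_pathway_tsv <- function(path) {
  lines <- readLines(path)
  pathways <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur)) pathways[[length(pathways) + 1L]] <<- cur
  }
  split_members <- function(x) {
    m <- strsplit(x, ";", fixed = TRUE)[[1]]
    m[nzchar(m)]
  }
  parse_roles <- function(fields, lineno) {
    roles <- list()
    for (f in fields) {
      kv <- strsplit(f, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2L) {
        stop("malformed role field '", f, "' at line ", lineno)
      }
      roles[[kv[1]]] <- c(roles[[kv[1]]], split_members(kv[2]))
    }
    roles
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i], which = "right")
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L) stop("malformed record at line ", i)
    kind <- f[1]
    if (kind == "PATHWAY") {
      flush()
      cur <- pathway_record(f[2], source = if (length(f) >= 3L) f[3] else f[2])
    } else {
      if (is.null(cur)) cur <- pathway_record("pathway1")
      if (kind == "REACTION") {
        roles <- parse_roles(f[-(1:2)], i)
        known <- c("input", "catalyst", "activator", "inhibitor", "output")
        extra <- setdiff(names(roles), known)
        if (length(extra) > 0L) {
          stop("unknown reaction role(s) ", paste(extra, collapse = ", "),
               " at line ", i)
        }
        cur$reactions[[length(cur$reactions) + 1L]] <- reaction_record(
          f[2],
          inputs = roles[["input"]] %||% character(0),
          catalysts = roles[["catalyst"]] %||% character(0),
          activators = roles[["activator"]] %||% character(0),
          inhibitors = roles[["inhibitor"]] %||% character(0),
          outputs = roles[["output"]] %||% character(0))
      } else if (kind == "COMPLEX") {
        if (length(f) < 3L) stop("COMPLEX record without members at line ", i)
        cur$complexes[[length(cur$complexes) + 1L]] <-
          complex_record(f[2], split_members(f[3]))
      } else if (kind == "REGULATION") {
        roles <- parse_roles(f[-(1:2)], i)
        if (is.null(roles[["factor"]]) || is.null(roles[["targets"]])) {
          stop("REGULATION record needs factor= and targets= at line ", i)
        }
        cur$regulations[[length(cur$regulations) + 1L]] <-
          list(id = f[2], factor = roles[["factor"]][1],
               targets = roles[["targets"]])
      } else {
        stop("unknown record type '", kind, "' at line ", i)
      }
    }
  }
  flush()
  pathways
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_pathway_tsv
#' @param pathways list of `pathway_record`s.
#' @return `write_pathway_tsv()`: `path`, invisibly.
#' @export
write_pathway_tsv <- function(pathways, path) {
  out <- character(0)
  for (pw in pathways) {
    out <- c(out, paste("PATHWAY", pw$id, pw$source, sep = "\t"))
    for (r in pw$reactions) {
      fields <- c(
        if (length(r$inputs)) paste0("input=", paste(r$inputs, collapse = ";")),
        if (length(r$catalysts)) paste0("catalyst=", paste(r$catalysts, collapse = ";")),
        if (length(r$activators)) paste0("activator=", paste(r$activators, collapse = ";")),
        if (length(r$inhibitors)) paste0("inhibitor=", paste(r$inhibitors, collapse = ";")),
        if (length(r$outputs)) paste0("output=", paste(r$outputs, collapse = ";")))
      out <- c(out, paste(c("REACTION", r$id, fields), collapse = "\t"))
    }
    for (cx in pw$complexes) {
      out <- c(out, paste("COMPLEX", cx$id,
                          paste(cx$components, collapse = ";"), sep = "\t"))
    }
    for (rg in pw$regulations) {
      out <- c(out, paste("REGULATION", rg$id,
                          paste0("factor=", rg$factor),
                          paste0("targets=", paste(rg$targets, collapse = ";")),
                          sep = "\t"))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Write / read an FI table as TSV
#'
#' Column layout: `protein_a`, `protein_b`, `provenance`, `direction`,
#' `source_protein`, `sources` with a header line.
#'
#' @param fis an [fi_table()].
#' @param path file path.
#' @return `write_fi_tsv()`: `path` invisibly; `read_fi_tsv()`: an
#'   [fi_table()].
#' @export
write_fi_tsv <- function(fis, path) {
  utils::write.table(fis, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_fi_tsv
#' @export
read_fi_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  df$source_protein[df$source_protein == ""] <- NA_character_
  fi_table(df$protein_a, df$protein_b, provenance = df$provenance,
           direction = df$direction, source_protein = df$source_protein,
           sources = df$sources)
}
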