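#' Canonicalize compound identifiers
#'
#' Identifiers are treated as opaque strings: canonicalization only trims
#' surrounding whitespace, strips a trailing compartment tag in square
#' brackets (e.g. \code{"C00031[c]"} -> \code{"C00031"}) and uppercases.
#'
#' @param x character vector of raw compound identifiers.
#' @return canonical character vector of the same length.
#' @export
canonicalize_compound <- function(x) {
  x <- trimws(x)
  x <- sub("\\[[^]]*\\]$", "", x)
  toupper(x)
}

#' Create a reaction record
#'
#' A reaction record keeps only the topology of a reaction: which compounds
#' are substrates, which are products, and whether the reaction is
#' reversible. Stoichiometric coefficients are not represented. A record in
#' which the same compound appears on both sides after canonicalization is
#' kept but flagged (\code{flagged(rec)} is \code{TRUE}); network
#' reconstruction refuses flagged records.
#'
#' @param reaction_id opaque reaction identifier (e.g. a KEGG R-number).
#' @param substrates,products character vectors of compound identifiers;
#'   each must be non-empty after canonicalization.
#' @param reversible logical flag; \code{NA} means the source format carried
#'   no direction, to be resolved at reconstruction time.
#' @return an object of class \code{reaction_record}.
#' @export
reaction_record <- function(reaction_id, substrates, products, reversible = NA) {
  reaction_id <- as.character(reaction_id)[1]
  substrates <- unique(canonicalize_compound(as.character(substrates)))
  products <- unique(canonicalize_compound(as.character(products)))
  if (length(substrates) == 0L || any(!nzchar(substrates))) {
    stop("reaction ", reaction_id, ": substrates must be non-empty identifiers",
         call. = FALSE)
  }
  if (length(products) == 0L || any(!nzchar(products))) {
    stop("reaction ", reaction_id, ": products must be non-empty identifiers",
         call. = FALSE)
  }
  rec <- structure(
    list(reaction_id = reaction_id,
         substrates = sort(substrates),
         products = sort(products),
         reversible = as.logical(reversible)[1],
         flagged = length(intersect(substrates, products)) > 0L),
    class = "reaction_record")
  rec
}

#' @export
print.reaction_record <- function(x, ...) {
  arrow <- if (isTRUE(x$reversible)) "<=>" else if (is.na(x$reversible)) "<?>" else "=>"
  cat(sprintf("<reaction %s> %s %s %s%s\n", x$reaction_id,
              paste(x$substrates, collapse = " + "), arrow,
              paste(x$products, collapse = " + "),
              if (x$flagged) "  [flagged: compound on both sides]" else ""))
  invisible(x)
}

#' Is a reaction record flagged?
#'
#' @param rec a \code{reaction_record}.
#' @return \code{TRUE} if a compound appears as both substrate and product.
#' @export
flagged <- function(rec) isTRUE(rec$flagged)

# Split one side of a reaction equation into canonical compound identifiers,
# dropping stoichiometric coefficients ("2 C00031", "(n+1) C00001", "3n G10599").
parse_equation_side <- function(side, where) {
  terms <- strsplit(side, "\\s*\\+\\s+")[[1]]
  terms <- trimws(terms)
  terms <- terms[nzchar(terms)]
  if (length(terms) == 0L) {
    stop("empty ", where, " side in equation", call. = FALSE)
  }
  ids <- vapply(terms, function(term) {
    toks <- strsplit(term, "\\s+")[[1]]
    # leading tokens that are pure coefficients: integers, decimals, or
    # parenthesized/symbolic multipliers like (n), n, 2n, (n+1)
    is_coef <- grepl("^\\(?[0-9n+*-]*\\)?$", toks) & toks != ""
    keep <- toks[!is_coef]
    if (length(keep) == 0L) keep <- toks[length(toks)]
    keep[length(keep)]
  }, character(1), USE.NAMES = FALSE)
  unique(canonicalize_compound(ids))
}

#' Parse KEGG-style reaction flat files
#'
#' Reads entries of the KEGG reaction flat-file dialect: records separated by
#' \code{///}, with an \code{ENTRY} field giving the reaction identifier and
#' an \code{EQUATION} field (possibly continued over indented lines) giving
#' substrates and products. The arrow \code{<=>} maps to a reversible record;
#' \code{=>} and \code{->} map to irreversible. Stoichiometric coefficients
#' and compartment tags are stripped: only topology is kept.
#'
#' @param con a file path, a connection, or (with \code{text}) \code{NULL}.
#' @param text optional character vector of lines, used instead of \code{con}.
#' @return a list of \code{\link{reaction_record}} objects (possibly empty).
#' @export
parse_reaction_flatfile <- function(con = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(con, warn = FALSE)
  if (length(lines) == 0L) return(list())
  records <- list()
  entry_id <- NULL
  equation <- NULL
  in_equation <- FALSE
  entry_line <- 0L

  flush_entry <- function(last_line) {
    if (is.null(entry_id) && is.null(equation)) return(NULL)
    if (is.null(entry_id)) {
      stop("malformed entry ending at line ", last_line, ": missing ENTRY field",
           call. = FALSE)
    }
    if (is.null(equation)) {
      stop("malformed entry '", entry_id, "' at line ", entry_line,
           ": missing EQUATION field", call. = FALSE)
    }
    eq <- trimws(equation)
    arrow <- regmatches(eq, regexpr("<=>|=>|->", eq))
    if (length(arrow) == 0L) {
      stop("malformed entry '", entry_id, "' at line ", entry_line,
           ": equation has no reaction arrow: ", eq, call. = FALSE)
    }
    sides <- strsplit(eq, "<=>|=>|->")[[1]]
    if (length(sides) != 2L) {
      stop("malformed entry '", entry_id, "' at line ", entry_line,
           ": equation must have exactly one arrow: ", eq, call. = FALSE)
    }
    reaction_record(entry_id,
                    parse_equation_side(sides[1], "substrate"),
                    parse_equation_side(sides[2], "product"),
                    reversible = (arrow == "<=>"))
  }

  for (i in seq_along(lines)) {
    line <- lines[i]
    if (grepl("^///", line)) {
      rec <- flush_entry(i)
      if (!is.null(rec)) records[[length(records) + 1L]] <- rec
      entry_id <- NULL; equation <- NULL; in_equation <- FALSE
      next
    }
    if (grepl("^ENTRY", line)) {
      toks <- strsplit(trimws(sub("^ENTRY", "", line)), "\\s+")[[1]]
      if (length(toks) == 0L || !nzchar(toks[1])) {
        stop("malformed ENTRY field at line ", i, call. = FALSE)
      }
      entry_id <- toks[1]
      entry_line <- i
      in_equation <- FALSE
      next
    }
    if (grepl("^EQUATION", line)) {
      equation <- trimws(sub("^EQUATION", "", line))
      in_equation <- TRUE
      next
    }
    if (in_equation && grepl("^\\s", line)) {
      equation <- paste(equation, trimws(line))
      next
    }
    in_equation <- FALSE
  }
  rec <- flush_entry(length(lines))
  if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  records
}

#' Write reaction records to the flat format
#'
#' Produces entries that \code{\link{parse_reaction_flatfile}} reads back,
#' so generated fixtures and the on-disk cache share one format.
#'
#' @param records list of \code{reaction_record} objects.
#' @param path output file path; if \code{NULL} the lines are returned.
#' @return invisibly, the character vector of lines written.
#' @export
write_reaction_flatfile <- function(records, path = NULL) {
  lines <- unlist(lapply(records, function(r) {
    arrow <- if (is.na(r$reversible) || isTRUE(r$reversible)) "<=>" else "=>"
    c(sprintf("ENTRY       %s  Reaction", r$reaction_id),
      sprintf("EQUATION    %s %s %s",
              paste(r$substrates, collapse = " + "), arrow,
              paste(r$products, collapse = " + ")),
      "///")
  }), use.names = FALSE)
  if (length(lines) == 0L) lines <- character(0)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Parse a tab-delimited KO annotation profile
#'
#' Expects an IMG-export style table with a header naming a gene-identifier
#' column and a KO-identifier column (\code{gene_id}, \code{ko_id} by
#' default; \code{ko_id} may also be named \code{ko} or \code{ko_term}).
#' Duplicate KO terms are collapsed.
#'
#' @param con file path or connection; or use \code{text}.
#' @param organism_id identifier attached to the profile.
#' @param text optional character vector of lines.
#' @return a list with class \code{annotation_profile}: \code{organism_id},
#'   \code{ko_terms} (sorted unique character vector) and \code{gene_count}.
#' @export
parse_annotation_profile <- function(con = NULL, organism_id = "organism",
                                     text = NULL) {
  df <- utils::read.delim(if (!is.null(text)) textConnection(text) else con,
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  ko_col <- intersect(c("ko_id", "ko", "ko_term", "KO"), names(df))
  if (length(ko_col) == 0L) {
    stop("annotation profile lacks a KO column (expected one of ko_id/ko/ko_term)",
         call. = FALSE)
  }
  ko <- trimws(df[[ko_col[1]]])
  ko <- unique(ko[nzchar(ko)])
  gene_col <- intersect(c("gene_id", "gene", "locus_tag"), names(df))
  gene_count <- if (length(gene_col) > 0L) {
    length(unique(df[[gene_col[1]]][nzchar(df[[gene_col[1]]])]))
  } else {
    nrow(df)
  }
  structure(list(organism_id = organism_id,
                 ko_terms = sort(ko),
                 gene_count = as.integer(gene_count)),
            class = "annotation_profile")
}

#' Parse a KO-to-reaction mapping table
#'
#' Two tab-delimited columns, \code{ko_id} and \code{reaction_id}, mapping
#' KEGG Orthology terms to the reactions their gene products catalyse. Used
#' to select, from a packaged reaction catalogue, the reactions supported by
#' an organism's annotation profile, so reconstruction works offline.
#'
#' @param con file path or connection; or use \code{text}.
#' @param text optional character vector of lines.
#' @return a data frame with columns \code{ko_id}, \code{reaction_id}.
#' @export
parse_ko_reaction_map <- function(con = NULL, text = NULL) {
  df <- utils::read.delim(if (!is.null(text)) textConnection(text) else con,
                          header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("ko_id", "reaction_id") %in% names(df))) {
    stop("KO-reaction map needs columns ko_id and reaction_id", call. = FALSE)
  }
  unique(df[, c("ko_id", "reaction_id")])
}

#' Select the reactions supported by an annotation profile
#'
#' @param records list of \code{reaction_record} (the reaction catalogue).
#' @param profile an \code{annotation_profile}.
#' @param ko_map data frame from \code{\link{parse_ko_reaction_map}}.
#' @return the subset of \code{records} whose id is mapped from any of the
#'   profile's KO terms.
#' @export
reactions_for_profile <- function(records, profile, ko_map) {
  if (length(profile$ko_terms) == 0L) {
    stop("annotation profile of '", profile$organism_id,
         "' has no KO terms; refusing reconstruction", call. = FALSE)
  }
  wanted <- unique(ko_map$reaction_id[ko_map$ko_id %in% profile$ko_terms])
  Filter(function(r) r$reaction_id %in% wanted, records)
}
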