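#' Reconstruct a directed compound graph from reaction records
#'
#' Nodes are the compounds appearing in admitted reactions; there is an edge
#' A -> B whenever A is a substrate of some reaction producing B. Reversible
#' reactions contribute edges in both directions. Self-pairs (a compound on
#' both sides would give A -> A) never occur because such records are flagged
#' and refused. Stoichiometry plays no role: the graph is purely topological.
#'
#' @param reactions list of \code{\link{reaction_record}}.
#' @param organism_id identifier stored on the network.
#' @param exclude compound identifiers (e.g. currency metabolites such as
#'   water or ATP) removed before edge construction. Default empty.
#' @param default_reversible how to resolve records whose source format
#'   carried no direction flag (\code{reversible = NA}). Default \code{TRUE}.
#' @param drop_flagged if \code{TRUE} (default) records with a compound on
#'   both sides are dropped with a warning rather than aborting.
#' @return object of class \code{metabolic_network}: a list with
#'   \code{organism_id} and \code{graph} (a directed \pkg{igraph} graph whose
#'   vertex names are compound identifiers).
#' @export
reconstruct_network <- function(reactions, organism_id,
                                exclude = character(),
                                default_reversible = TRUE,
                                drop_flagged = TRUE) {
  exclude <- canonicalize_compound(exclude)
  bad <- vapply(reactions, flagged, logical(1))
  if (any(bad)) {
    ids <- vapply(reactions[bad], `[[`, "", "reaction_id")
    if (!drop_flagged) {
      stop("flagged reactions (compound on both sides): ",
           paste(ids, collapse = ", "), call. = FALSE)
    }
    warning("dropping ", sum(bad), " flagged reaction(s): ",
            paste(ids, collapse = ", "), call. = FALSE)
    reactions <- reactions[!bad]
  }

  froms <- character(0); tos <- character(0)
  nodes <- character(0)
  for (r in reactions) {
    subs <- setdiff(r$substrates, exclude)
    prods <- setdiff(r$products, exclude)
    if (length(subs) == 0L || length(prods) == 0L) next
    nodes <- c(nodes, subs, prods)
    pairs <- expand.grid(from = subs, to = prods,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    froms <- c(froms, pairs$from)
    tos <- c(tos, pairs$to)
    rev <- if (is.na(r$reversible)) default_reversible else r$reversible
    if (rev) {
      froms <- c(froms, pairs$to)
      tos <- c(tos, pairs$from)
    }
  }
  if (length(nodes) == 0L) {
    stop("no admitted reactions for '", organism_id,
         "': cannot reconstruct an empty network", call. = FALSE)
  }
  keep <- froms != tos
  edges <- unique(data.frame(from = froms[keep], to = tos[keep],
                             stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = sort(unique(nodes)))
  structure(list(organism_id = as.character(organism_id)[1], graph = g),
            class = "metabolic_network")
}

#' Build a metabolic network directly from node and edge lists
#'
#' Low-level constructor used by importers and the synthetic generators.
#' Validates the network invariants: edge endpoints must be nodes, no
#' self-loops, parallel edges collapsed.
#'
#' @param organism_id identifier.
#' @param nodes character vector of compound identifiers.
#' @param edges two-column data frame (\code{from}, \code{to}) or a
#'   2-column character matrix; may have zero rows.
#' @return a \code{metabolic_network}.
#' @export
metabolic_network <- function(organism_id, nodes, edges) {
  nodes <- sort(unique(as.character(nodes)))
  if (length(nodes) == 0L) stop("network must have at least one node", call. = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0L) {
    names(edges)[1:2] <- c("from", "to")
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    if (!all(c(edges$from, edges$to) %in% nodes)) {
      stop("edge endpoints must all be nodes", call. = FALSE)
    }
    if (any(edges$from == edges$to)) stop("self-loop edges are not allowed", call. = FALSE)
    edges <- unique(edges[, c("from", "to")])
  } else {
    edges <- data.frame(from = character(0), to = character(0))
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
  structure(list(organism_id = as.character(organism_id)[1], graph = g),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("<metabolic network '%s'> %d compounds, %d directed edges\n",
              x$organism_id, igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Compounds of a metabolic network
#' @param network a \code{metabolic_network}.
#' @return sorted character vector of compound identifiers.
#' @export
network_nodes <- function(network) {
  sort(igraph::V(network$graph)$name)
}

#' Directed edges of a metabolic network
#' @param network a \code{metabolic_network}.
#' @return data frame with columns \code{from}, \code{to}, sorted.
#' @export
network_edges <- function(network) {
  el <- igraph::as_edgelist(network$graph, names = TRUE)
  df <- data.frame(from = el[, 1], to = el[, 2], stringsAsFactors = FALSE)
  df <- df[order(df$from, df$to), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Export a network as edge-list TSV plus node list
#'
#' Writes \code{<path>} with columns \code{source}, \code{target} and a
#' companion \code{<path>.nodes} file listing every compound (so isolated
#' nodes survive the round trip).
#'
#' @param network a \code{metabolic_network}.
#' @param path output TSV path.
#' @export
write_network_tsv <- function(network, path) {
  ed <- network_edges(network)
  utils::write.table(data.frame(source = ed$from, target = ed$to),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(network_nodes(network), paste0(path, ".nodes"))
  invisible(path)
}

#' Read a network written by \code{\link{write_network_tsv}}
#' @param path TSV path (a \code{<path>.nodes} companion file is read too).
#' @param organism_id identifier for the re-imported network.
#' @return a \code{metabolic_network}.
#' @export
read_network_tsv <- function(path, organism_id = "organism") {
  ed <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  nodes_file <- paste0(path, ".nodes")
  nodes <- if (file.exists(nodes_file)) readLines(nodes_file)
           else unique(c(ed$source, ed$target))
  metabolic_network(organism_id, nodes,
                    data.frame(from = ed$source, to = ed$target))
}

#' Export a network as JSON
#' @param network a \code{metabolic_network}.
#' @param path output path.
#' @export
write_network_json <- function(network, path) {
  ed <- network_edges(network)
  jsonlite::write_json(
    list(organism_id = network$organism_id,
         nodes = network_nodes(network),
         edges = unname(Map(function(f, t) c(f, t), ed$from, ed$to))),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a network from JSON written by \code{\link{write_network_json}}
#' @param path JSON path.
#' @return a \code{metabolic_network}.
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  edges <- if (length(obj$edges) == 0L) {
    data.frame(from = character(0), to = character(0))
  } else if (is.matrix(obj$edges)) {
    data.frame(from = obj$edges[, 1], to = obj$edges[, 2])
  } else {
    data.frame(from = vapply(obj$edges, `[`, "", 1),
               to = vapply(obj$edges, `[`, "", 2))
  }
  metabolic_network(obj$organism_id, obj$nodes, edges)
}
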