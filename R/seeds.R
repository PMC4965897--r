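#' Identify the seed set of a metabolic network
#'
#' The seed set is the minimal set of compounds an organism must acquire from
#' its environment: every other compound in the network can be synthesized
#' once the seeds are available. Topologically, the candidate seed compounds
#' are the members of the source components of the SCC condensation — the
#' components with no incoming edge from another component and at least one
#' outgoing edge to another component. Because producing any one compound of
#' an SCC suffices to produce them all, each member of a seed component is an
#' equally plausible seed and receives a confidence score of 1/|SCC|; the
#' confidences of a seed component therefore sum to one.
#'
#' The out-degree requirement is applied at the condensation level: a
#' component whose only edges are internal supplies nothing to the rest of
#' the network and is not a seed. A network whose condensation has no
#' qualifying component (e.g. one giant SCC) yields an empty seed set, which
#' is representable but refused by the interaction indices.
#'
#' @param network a \code{metabolic_network}.
#' @return object of class \code{seed_set}: list with \code{organism_id},
#'   \code{seed_components} (list of sorted compound vectors),
#'   \code{confidence} (named numeric, one entry per candidate seed
#'   compound, value 1/|its component|), \code{partition} (the full
#'   \code{scc_partition}, kept for permutation nulls) and
#'   \code{seed_component_idx} (indices of the seed components within the
#'   partition).
#' @export
identify_seed_set <- function(network) {
  partition <- strongly_connected_components(network)
  edges <- network_edges(network)
  deg <- condensation_degrees(partition, edges)
  idx <- which(deg$indeg == 0L & deg$outdeg >= 1L)
  seed_components <- partition$components[idx]
  confidence <- numeric(0)
  if (length(seed_components) > 0L) {
    confidence <- unlist(lapply(seed_components,
                                function(cmp) stats::setNames(rep(1 / length(cmp),
                                                                  length(cmp)), cmp)))
    confidence <- confidence[order(names(confidence))]
  }
  structure(list(organism_id = network$organism_id,
                 seed_components = seed_components,
                 confidence = confidence,
                 partition = partition,
                 seed_component_idx = idx),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  if (is_empty_seed_set(x)) {
    cat(sprintf("<seed set '%s'> EMPTY (no source component qualifies)\n",
                x$organism_id))
  } else {
    cat(sprintf("<seed set '%s'> %d seed components, %d candidate compounds\n",
                x$organism_id, length(x$seed_components),
                length(x$confidence)))
  }
  invisible(x)
}

#' Is a seed set empty?
#' @param seeds a \code{seed_set}.
#' @return \code{TRUE} if no component qualified as a source.
#' @export
is_empty_seed_set <- function(seeds) length(seeds$seed_components) == 0L

#' Candidate seed compounds of a seed set
#' @param seeds a \code{seed_set}.
#' @return sorted character vector of all members of all seed components.
#' @export
seed_compounds <- function(seeds) sort(names(seeds$confidence))

#' Export a seed set as TSV
#'
#' Columns: \code{compound_id}, \code{component_index} (index of the seed
#' component, 1-based in deterministic component order), \code{confidence}.
#'
#' @param seeds a \code{seed_set}.
#' @param path output path.
#' @export
write_seed_tsv <- function(seeds, path) {
  rows <- do.call(rbind, lapply(seq_along(seeds$seed_components), function(i) {
    cmp <- seeds$seed_components[[i]]
    data.frame(compound_id = cmp, component_index = i,
               confidence = 1 / length(cmp), stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(compound_id = character(0), component_index = integer(0),
                       confidence = numeric(0))
  }
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a seed set as JSON
#' @param seeds a \code{seed_set}.
#' @param path output path.
#' @export
write_seed_json <- function(seeds, path) {
  jsonlite::write_json(
    list(organism_id = seeds$organism_id,
         seed_components = lapply(seeds$seed_components, as.list),
         confidence = as.list(seeds$confidence),
         empty = is_empty_seed_set(seeds)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
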