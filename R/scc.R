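# Kosaraju's strongly connected components algorithm, iterative so that
# genome-scale graphs (thousands of compounds) never hit R's recursion limit.
#
# Works on integer adjacency lists; the exported wrapper handles compound
# names and deterministic ordering.

kosaraju_components <- function(n, adj, radj) {
  # pass 1: DFS finish order on the forward graph
  visited <- logical(n)
  finish <- integer(n)
  fi <- 0L
  stack_v <- integer(n)
  stack_i <- integer(n)
  for (s in seq_len(n)) {
    if (visited[s]) next
    top <- 1L
    stack_v[1L] <- s
    stack_i[1L] <- 1L
    visited[s] <- TRUE
    while (top > 0L) {
      v <- stack_v[top]
      i <- stack_i[top]
      nb <- adj[[v]]
      if (i <= length(nb)) {
        stack_i[top] <- i + 1L
        w <- nb[i]
        if (!visited[w]) {
          visited[w] <- TRUE
          top <- top + 1L
          stack_v[top] <- w
          stack_i[top] <- 1L
        }
      } else {
        fi <- fi + 1L
        finish[fi] <- v
        top <- top - 1L
      }
    }
  }
  # pass 2: DFS on the transpose graph in reverse finish order
  comp <- integer(n)
  ncomp <- 0L
  for (k in rev(seq_len(n))) {
    s <- finish[k]
    if (comp[s] != 0L) next
    ncomp <- ncomp + 1L
    top <- 1L
    stack_v[1L] <- s
    comp[s] <- ncomp
    while (top > 0L) {
      v <- stack_v[top]
      top <- top - 1L
      for (w in radj[[v]]) {
        if (comp[w] == 0L) {
          comp[w] <- ncomp
          top <- top + 1L
          stack_v[top] <- w
        }
      }
    }
  }
  comp
}

# adjacency lists (indices into `nodes`) from an edge data frame
adjacency_lists <- function(nodes, edges) {
  n <- length(nodes)
  adj <- rep(list(integer(0)), n)
  radj <- rep(list(integer(0)), n)
  if (nrow(edges) > 0L) {
    fi <- match(edges$from, nodes)
    ti <- match(edges$to, nodes)
    fwd <- split(ti, fi)
    for (k in names(fwd)) adj[[as.integer(k)]] <- fwd[[k]]
    bwd <- split(fi, ti)
    for (k in names(bwd)) radj[[as.integer(k)]] <- bwd[[k]]
  }
  list(adj = adj, radj = radj)
}

#' Strongly connected components of a metabolic network
#'
#' Decomposes the directed compound graph into maximal strongly connected
#' components (SCCs) with Kosaraju's two-pass algorithm. Components are
#' ordered deterministically by their lexicographically smallest member, and
#' members within a component are sorted, so output is reproducible
#' byte-for-byte.
#'
#' @param network a \code{metabolic_network}.
#' @return object of class \code{scc_partition}: list with
#'   \code{components} (list of sorted character vectors partitioning the
#'   node set) and \code{component_of} (named integer vector mapping each
#'   compound to its component index).
#' @export
strongly_connected_components <- function(network) {
  nodes <- network_nodes(network)
  if (length(nodes) == 0L) stop("network is empty", call. = FALSE)
  edges <- network_edges(network)
  al <- adjacency_lists(nodes, edges)
  comp <- kosaraju_components(length(nodes), al$adj, al$radj)
  groups <- split(nodes, comp)
  groups <- lapply(groups, sort)
  # deterministic: order components by smallest member
  groups <- groups[order(vapply(groups, `[`, "", 1))]
  names(groups) <- NULL
  component_of <- integer(length(nodes))
  names(component_of) <- nodes
  for (i in seq_along(groups)) component_of[groups[[i]]] <- i
  structure(list(components = groups, component_of = component_of),
            class = "scc_partition")
}

#' @export
print.scc_partition <- function(x, ...) {
  sizes <- lengths(x$components)
  cat(sprintf("<SCC partition> %d components over %d compounds (largest: %d)\n",
              length(sizes), sum(sizes), max(sizes)))
  invisible(x)
}

# condensation in/out degree per component: edges whose endpoints lie in
# different components
condensation_degrees <- function(partition, edges) {
  k <- length(partition$components)
  indeg <- integer(k); outdeg <- integer(k)
  if (nrow(edges) > 0L) {
    cf <- partition$component_of[edges$from]
    ct <- partition$component_of[edges$to]
    cross <- cf != ct
    if (any(cross)) {
      ot <- table(factor(cf[cross], levels = seq_len(k)))
      it <- table(factor(ct[cross], levels = seq_len(k)))
      outdeg <- as.integer(ot)
      indeg <- as.integer(it)
    }
  }
  list(indeg = indeg, outdeg = outdeg)
}
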