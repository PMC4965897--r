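# Independent oracles and small builders shared across the test files.
# Everything here is deliberately brute force, so it cannot share defects
# with the package's algorithmic implementations.

# reachability closure by boolean Floyd-Warshall
oracle_reachability <- function(nodes, edges) {
  n <- length(nodes)
  R <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  diag(R) <- TRUE
  if (nrow(edges) > 0L) R[cbind(edges$from, edges$to)] <- TRUE
  for (k in seq_len(n)) {
    R <- R | (outer(R[, k], R[k, ], `&`))
  }
  R
}

# SCC partition from pairwise mutual reachability
oracle_scc <- function(nodes, edges) {
  R <- oracle_reachability(nodes, edges)
  mutual <- R & t(R)
  seen <- logical(length(nodes))
  comps <- list()
  for (i in seq_along(nodes)) {
    if (seen[i]) next
    members <- which(mutual[i, ])
    seen[members] <- TRUE
    comps[[length(comps) + 1L]] <- sort(nodes[members])
  }
  comps[order(vapply(comps, `[`, "", 1))]
}

# source components of the condensation (in-degree 0), split by whether they
# also have an outgoing cross-component edge
oracle_sources <- function(nodes, edges) {
  comps <- oracle_scc(nodes, edges)
  comp_of <- integer(length(nodes)); names(comp_of) <- nodes
  for (i in seq_along(comps)) comp_of[comps[[i]]] <- i
  indeg <- integer(length(comps)); outdeg <- integer(length(comps))
  if (nrow(edges) > 0L) {
    cf <- comp_of[edges$from]; ct <- comp_of[edges$to]
    for (k in which(cf != ct)) {
      outdeg[cf[k]] <- outdeg[cf[k]] + 1L
      indeg[ct[k]] <- indeg[ct[k]] + 1L
    }
  }
  list(components = comps,
       source_idx = which(indeg == 0L),
       seed_idx = which(indeg == 0L & outdeg >= 1L))
}

# random digraph as a metabolic_network (no self-loops, unique edges)
random_digraph <- function(n, p = 0.1, seed = 1L) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  pairs <- pairs[runif(nrow(pairs)) < p, ]
  metabolic_network("rand", nodes, pairs)
}

# network straight from an edge string like "A->B B->C", optional isolates
net_from_edges <- function(edge_str, isolates = character(0),
                           organism_id = "toy") {
  if (nzchar(edge_str)) {
    parts <- strsplit(strsplit(edge_str, "\\s+")[[1]], "->")
    edges <- data.frame(from = vapply(parts, `[`, "", 1),
                        to = vapply(parts, `[`, "", 2))
  } else {
    edges <- data.frame(from = character(0), to = character(0))
  }
  metabolic_network(organism_id, unique(c(edges$from, edges$to, isolates)),
                    edges)
}

# the hand-built three-species toy community used by the closed-form index
# checks; every expected index value below was computed by hand from the
# definitions before the implementation existed (see test-acceptance.R)
toy_community <- function() {
  s1 <- reconstruct_network(list(
    reaction_record("R11", "A", "C", FALSE),
    reaction_record("R12", "B", "C", FALSE),
    reaction_record("R13", "C", "D", FALSE)), "S1")
  s2 <- reconstruct_network(list(
    reaction_record("R21", "A", "C", FALSE),
    reaction_record("R22", "F", "G", TRUE),
    reaction_record("R23", "G", "C", FALSE),
    reaction_record("R24", "D", "C", FALSE)), "S2")
  s3 <- reconstruct_network(list(
    reaction_record("R31", "C", "B", FALSE),
    reaction_record("R32", "B", "H", FALSE)), "S3")
  lapply(list(s1, s2, s3),
         function(n) list(network = n, seeds = identify_seed_set(n)))
}

# hand-computed expected matrices for toy_community(), rows = focal species
toy_expected <- function() {
  ids <- c("S1", "S2", "S3")
  comp <- matrix(c(1, 1/2, 0,
                   1/3, 1, 0,
                   0, 0, 1), 3, 3, byrow = TRUE,
                 dimnames = list(ids, ids))
  compl <- matrix(c(0, 0, 1/2,
                    1/3, 0, 0,
                    1, 1, 0), 3, 3, byrow = TRUE,
                  dimnames = list(ids, ids))
  list(competition = comp, complementarity = compl)
}
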