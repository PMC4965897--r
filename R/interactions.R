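assert_nonempty_seeds <- function(seeds, what = "seed set") {
  if (is_empty_seed_set(seeds)) {
    stop(what, " of '", seeds$organism_id,
         "' is empty: interaction indices are undefined", call. = FALSE)
  }
  invisible(seeds)
}

#' Competition index between two species
#'
#' The confidence-weighted fraction of species A's candidate seed compounds
#' that are also candidate seed compounds of species B: the two species then
#' demand the same exogenous resources. Each seed compound of A contributes
#' its confidence (1/|its SCC|); the sum is normalized by A's total seed
#' confidence, which equals A's number of seed components, so the index lies
#' in [0, 1] and self-competition is exactly 1.
#'
#' The index is directional: it measures competition experienced by A
#' relative to B and generally differs from the B-vs-A value.
#'
#' @param seed_a,seed_b \code{seed_set} objects; both must be non-empty.
#' @return a score in [0, 1].
#' @export
competition_index <- function(seed_a, seed_b) {
  assert_nonempty_seeds(seed_a, "seed set")
  assert_nonempty_seeds(seed_b, "seed set")
  conf <- seed_a$confidence
  shared <- names(conf) %in% names(seed_b$confidence)
  sum(conf[shared]) / sum(conf)
}

#' Complementarity index between two species
#'
#' The confidence-weighted fraction of species A's candidate seed compounds
#' that appear in species B's metabolic network but are not candidate seed
#' compounds of B: compounds B can synthesize and potentially supply to A.
#' Normalized like \code{\link{competition_index}}, so the index lies in
#' [0, 1] and self-complementarity is 0.
#'
#' @param seed_a seed set of the focal species A (non-empty).
#' @param network_b metabolic network of the potential donor B.
#' @param seed_b seed set of B (used for the exclusion; may be empty).
#' @return a score in [0, 1].
#' @export
complementarity_index <- function(seed_a, network_b, seed_b) {
  assert_nonempty_seeds(seed_a, "seed set")
  conf <- seed_a$confidence
  in_b <- names(conf) %in% network_nodes(network_b) &
    !(names(conf) %in% names(seed_b$confidence))
  sum(conf[in_b]) / sum(conf)
}

validate_community <- function(community) {
  if (length(community) < 2L) {
    stop("a community needs at least 2 species", call. = FALSE)
  }
  ids <- vapply(community, function(m) m$seeds$organism_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate organism_ids in community: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  empty <- vapply(community, function(m) is_empty_seed_set(m$seeds), logical(1))
  if (any(empty)) {
    stop("empty seed set for species: ", paste(ids[empty], collapse = ", "),
         call. = FALSE)
  }
  ids
}

#' Pairwise interaction matrices for a community
#'
#' Applies \code{\link{competition_index}} and
#' \code{\link{complementarity_index}} to every ordered species pair. Rows
#' play the role of the focal species A, columns the counterpart B, so the
#' matrices are generally asymmetric and are never symmetrized.
#'
#' @param community list of members, each a list with elements
#'   \code{network} (\code{metabolic_network}) and \code{seeds}
#'   (\code{seed_set}); at least two members, unique organism ids, no empty
#'   seed set.
#' @return list with elements \code{competition} and \code{complementarity},
#'   square numeric matrices with species ids as dimnames. The competition
#'   diagonal is 1 and the complementarity diagonal 0.
#' @export
interaction_matrices <- function(community) {
  ids <- validate_community(community)
  n <- length(community)
  comp <- matrix(0, n, n, dimnames = list(ids, ids))
  compl <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      comp[i, j] <- competition_index(community[[i]]$seeds,
                                      community[[j]]$seeds)
      compl[i, j] <- complementarity_index(community[[i]]$seeds,
                                           community[[j]]$network,
                                           community[[j]]$seeds)
    }
  }
  list(competition = comp, complementarity = compl)
}

# evaluate one index for A's confidences against a null seed-compound set of B
index_against_membership <- function(conf_a, member_set, index_kind,
                                     nodes_b = NULL) {
  if (index_kind == "competition") {
    sum(conf_a[names(conf_a) %in% member_set]) / sum(conf_a)
  } else {
    sel <- names(conf_a) %in% nodes_b & !(names(conf_a) %in% member_set)
    sum(conf_a[sel]) / sum(conf_a)
  }
}

#' Permutation p-values for interaction indices
#'
#' For each ordered pair (A, B) the null hypothesis is that B's seed
#' components sit at random positions within B's own SCC partition: each
#' null replicate draws |seed components of B| components uniformly without
#' replacement from B's partition (preserving the component-size spectrum and
#' hence the confidence weights) and recomputes the index of A against that
#' fake seed set. The p-value uses the add-one estimator
#' p = (1 + #\{null >= observed\}) / (1 + n_perm), so p is never zero.
#'
#' @param community as in \code{\link{interaction_matrices}}.
#' @param index_kind \code{"competition"} or \code{"complementarity"}.
#' @param n_perm number of permutations, at least 99.
#' @param rng_seed integer seed; results are reproducible given the seed.
#' @return square matrix of p-values in (0, 1] with species-id dimnames;
#'   diagonal included (self-indices are tested like any pair).
#' @export
permutation_pvalues <- function(community, index_kind = c("competition",
                                                          "complementarity"),
                                n_perm = 999, rng_seed = 1L) {
  index_kind <- match.arg(index_kind)
  ids <- validate_community(community)
  if (n_perm < 99L) {
    stop("n_perm must be at least 99 (p-value resolution too coarse)",
         call. = FALSE)
  }
  n <- length(community)
  obs <- interaction_matrices(community)[[index_kind]]
  pmat <- matrix(1, n, n, dimnames = list(ids, ids))
  with_seed(rng_seed, {
    for (j in seq_len(n)) {
      b <- community[[j]]
      comps_b <- b$seeds$partition$components
      k <- length(b$seeds$seed_component_idx)
      nodes_b <- network_nodes(b$network)
      # one set of null seed placements per target species B, reused for
      # every focal species A
      null_members <- lapply(seq_len(n_perm), function(r) {
        pick <- sample.int(length(comps_b), k)
        unlist(comps_b[pick], use.names = FALSE)
      })
      for (i in seq_len(n)) {
        conf_a <- community[[i]]$seeds$confidence
        null_vals <- vapply(null_members, function(m) {
          index_against_membership(conf_a, m, index_kind, nodes_b)
        }, numeric(1))
        pmat[i, j] <- (1 + sum(null_vals >= obs[i, j] - 1e-12)) / (1 + n_perm)
      }
    }
  })
  pmat
}

#' Write a square matrix as TSV with species ids as headers
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(species_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by \code{\link{write_matrix_tsv}}
#' @param path TSV path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write interaction values in long format
#'
#' One row per ordered species pair: \code{species_a}, \code{species_b},
#' \code{index_kind}, \code{value} and, if supplied, \code{p}.
#'
#' @param m interaction matrix (rows = focal species A).
#' @param index_kind label written in the \code{index_kind} column.
#' @param path output path.
#' @param pvalues optional matching p-value matrix.
#' @export
write_interactions_long <- function(m, index_kind, path, pvalues = NULL) {
  ids <- rownames(m)
  grid <- expand.grid(species_a = ids, species_b = ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[grid$species_a != grid$species_b, ]
  grid$index_kind <- index_kind
  grid$value <- m[cbind(grid$species_a, grid$species_b)]
  if (!is.null(pvalues)) {
    grid$p <- pvalues[cbind(grid$species_a, grid$species_b)]
  }
  utils::write.table(grid, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# run code with a temporarily fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
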