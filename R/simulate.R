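#' Generate a random reaction set
#'
#' Draws reactions over a compound universe \code{C00001..C<n>}: each
#' reaction takes 1-3 substrates and 1-3 products, sampled without overlap
#' between the two sides, and is reversible with probability
#' \code{reversible_prob}. Deterministic given \code{rng_seed}.
#'
#' @param n_compounds size of the compound universe (>= 2).
#' @param n_reactions number of reactions (>= 1).
#' @param reversible_prob probability a reaction is reversible.
#' @param rng_seed integer seed.
#' @return list of \code{\link{reaction_record}}.
#' @export
random_reaction_set <- function(n_compounds, n_reactions,
                                reversible_prob = 0.3, rng_seed = 1L) {
  if (n_compounds < 2L) stop("need at least 2 compounds", call. = FALSE)
  if (n_reactions < 1L) stop("need at least 1 reaction", call. = FALSE)
  universe <- sprintf("C%05d", seq_len(n_compounds))
  with_seed(rng_seed, {
    lapply(seq_len(n_reactions), function(i) {
      ns <- sample.int(min(3L, n_compounds - 1L), 1L)
      np <- sample.int(min(3L, n_compounds - ns), 1L)
      picked <- sample(universe, ns + np)
      reaction_record(sprintf("R%05d", i),
                      substrates = picked[seq_len(ns)],
                      products = picked[ns + seq_len(np)],
                      reversible = stats::runif(1) < reversible_prob)
    })
  })
}

#' Specify a synthetic community with planted interaction structure
#'
#' @param n_species number of species (>= 2).
#' @param compound_universe_size number of distinct compound identifiers
#'   available to the generator.
#' @param n_reactions_per_species reactions per species.
#' @param seed_overlap fraction of seed compounds shared by each planted
#'   competitor pair, in [0, 1].
#' @param n_seeds seed compounds per species.
#' @param rng_seed integer seed.
#' @return a validated list of class \code{community_spec}.
#' @export
community_spec <- function(n_species = 6L, compound_universe_size = 400L,
                           n_reactions_per_species = 30L, seed_overlap = 0.5,
                           n_seeds = 8L, rng_seed = 1L) {
  stopifnot(n_species >= 2L, compound_universe_size >= 2L,
            n_reactions_per_species >= 1L, n_seeds >= 1L,
            seed_overlap >= 0, seed_overlap <= 1)
  structure(list(n_species = as.integer(n_species),
                 compound_universe_size = as.integer(compound_universe_size),
                 n_reactions_per_species = as.integer(n_reactions_per_species),
                 seed_overlap = seed_overlap,
                 n_seeds = as.integer(n_seeds),
                 rng_seed = as.integer(rng_seed)),
            class = "community_spec")
}

# build one species bottom-up: seeds are never produced, every internal
# compound is produced from an earlier compound, every seed feeds a reaction.
build_species <- function(organism_id, seed_ids, internal_ids, n_reactions) {
  stopifnot(length(internal_ids) >= 1L)
  reactions <- list()
  pool <- character(0) # compounds available as substrates so far
  # chain construction: internal k is produced by a compound drawn from
  # seeds + earlier internals; cycle through seeds first so each seed is used
  producers <- c(seed_ids, internal_ids[-length(internal_ids)])
  for (k in seq_along(internal_ids)) {
    sub <- if (k <= length(seed_ids)) seed_ids[k]
           else sample(c(seed_ids, internal_ids[seq_len(k - 1L)]), 1L)
    reactions[[length(reactions) + 1L]] <-
      reaction_record(sprintf("%s_R%03d", organism_id, length(reactions) + 1L),
                      substrates = sub, products = internal_ids[k],
                      reversible = FALSE)
  }
  # ensure every seed has an outgoing reaction even if n_seeds > n_internal
  used <- unique(unlist(lapply(reactions, `[[`, "substrates")))
  for (s in setdiff(seed_ids, used)) {
    reactions[[length(reactions) + 1L]] <-
      reaction_record(sprintf("%s_R%03d", organism_id, length(reactions) + 1L),
                      substrates = s, products = sample(internal_ids, 1L),
                      reversible = FALSE)
  }
  # pad with internal-to-internal reactions (cycles among internals are fine:
  # every internal keeps an incoming edge from an earlier compound)
  while (length(reactions) < n_reactions && length(internal_ids) >= 2L) {
    ends <- sample(internal_ids, 2L)
    reactions[[length(reactions) + 1L]] <-
      reaction_record(sprintf("%s_R%03d", organism_id, length(reactions) + 1L),
                      substrates = ends[1], products = ends[2],
                      reversible = FALSE)
  }
  reconstruct_network(reactions, organism_id)
}

#' Generate a community with planted competition and complementarity
#'
#' Builds species bottom-up from designated seed compounds outward, so the
#' ground truth is exact by construction, then verifies each species with
#' \code{\link{identify_seed_set}} rather than trusting the construction.
#'
#' Species 1 and 2 form the planted competitor pair: they share
#' \code{round(seed_overlap * n_seeds)} seed compounds, all other compounds
#' disjoint. Species 3 and 4 (when present) form the planted complementary
#' pair: species 3's seed compounds are embedded as internal (non-seed)
#' nodes of species 4's network. Remaining species draw from disjoint
#' compound pools and are unrelated. Pair roles are recorded in the
#' \code{ground_truth} attribute.
#'
#' @param spec a \code{\link{community_spec}}.
#' @return list of members (each \code{list(network, seeds)}) with attribute
#'   \code{ground_truth}: data frame of (species_a, species_b, role).
#' @export
planted_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  k <- spec$n_seeds
  n_internal <- max(2L, spec$n_reactions_per_species - k)
  n_shared <- round(spec$seed_overlap * k)
  # compound demand: per species k seeds + n_internal internals, minus the
  # shared seeds counted once, plus species 3's seeds reused inside species 4
  demand <- spec$n_species * (k + n_internal) - n_shared
  if (demand > spec$compound_universe_size) {
    stop("infeasible community spec: ", demand, " compounds needed but ",
         "universe has only ", spec$compound_universe_size, call. = FALSE)
  }
  universe <- sprintf("C%05d", seq_len(spec$compound_universe_size))
  with_seed(spec$rng_seed, {
    ids <- sprintf("sp%02d", seq_len(spec$n_species))
    cursor <- 0L
    take <- function(n) {
      out <- universe[cursor + seq_len(n)]
      cursor <<- cursor + n
      out
    }
    shared <- take(n_shared)
    members <- vector("list", spec$n_species)
    seeds_of <- vector("list", spec$n_species)
    for (i in seq_len(spec$n_species)) {
      own <- take(k - if (i <= 2L) n_shared else 0L)
      seed_ids <- if (i <= 2L) c(shared, own) else own
      internal_ids <- take(n_internal)
      if (i == 4L && spec$n_species >= 4L) {
        # embed species 3's seeds as internal nodes of species 4
        internal_ids <- c(seeds_of[[3L]],
                          internal_ids[seq_len(max(1L, n_internal -
                                                     length(seeds_of[[3L]])))])
      }
      seeds_of[[i]] <- seed_ids
      net <- build_species(ids[i], seed_ids, internal_ids,
                           spec$n_reactions_per_species)
      det <- identify_seed_set(net)
      if (!setequal(seed_compounds(det), seed_ids)) {
        stop("generator-detector inconsistency for ", ids[i], call. = FALSE)
      }
      members[[i]] <- list(network = net, seeds = det)
    }
    gt <- data.frame(species_a = character(0), species_b = character(0),
                     role = character(0), stringsAsFactors = FALSE)
    gt <- rbind(gt, data.frame(species_a = ids[1], species_b = ids[2],
                               role = "competitor"))
    if (spec$n_species >= 4L) {
      gt <- rbind(gt, data.frame(species_a = ids[3], species_b = ids[4],
                                 role = "complementary"))
    }
    attr(members, "ground_truth") <- gt
    names(members) <- ids
    members
  })
}

#' Generate a null abundance table
#'
#' Independent presence/absence with log-normal abundances where present:
#' no built-in association between species, suitable for calibration studies.
#'
#' @param species_ids character vector of species.
#' @param n_samples number of samples.
#' @param presence_prob probability a species is present in a sample.
#' @param rng_seed integer seed.
#' @return an \code{\link{abundance_table}}.
#' @export
null_abundance_table <- function(species_ids, n_samples = 124,
                                 presence_prob = 0.5, rng_seed = 1L) {
  with_seed(rng_seed, {
    n <- length(species_ids)
    present <- matrix(stats::runif(n * n_samples) < presence_prob, n, n_samples)
    ab <- matrix(0, n, n_samples,
                 dimnames = list(species_ids,
                                 sprintf("sample%03d", seq_len(n_samples))))
    ab[present] <- stats::rlnorm(sum(present))
    abundance_table(ab)
  })
}

#' Assemble a community from random reaction sets
#'
#' Convenience wrapper used in property tests: draws an independent random
#' reaction set per species over a shared compound universe, reconstructs
#' each network and detects its seed set. Species whose seed set comes out
#' empty are dropped (with a message) since the interaction indices refuse
#' them.
#'
#' @param n_species number of species to draw.
#' @param n_compounds universe size per species.
#' @param n_reactions reactions per species.
#' @param rng_seed integer seed.
#' @return community list as accepted by \code{\link{interaction_matrices}}.
#' @export
random_community <- function(n_species = 4L, n_compounds = 40L,
                             n_reactions = 15L, rng_seed = 1L) {
  members <- list()
  for (i in seq_len(n_species)) {
    recs <- random_reaction_set(n_compounds, n_reactions,
                                reversible_prob = 0.3,
                                rng_seed = rng_seed * 1000L + i)
    recs <- Filter(Negate(flagged), recs)
    if (length(recs) == 0L) next
    net <- reconstruct_network(recs, sprintf("rsp%02d", i))
    det <- identify_seed_set(net)
    if (is_empty_seed_set(det)) {
      message("dropping species with empty seed set: ", net$organism_id)
      next
    }
    members[[length(members) + 1L]] <- list(network = net, seeds = det)
  }
  members
}
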