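# small builder: a seed_set-like object with prescribed confidences, produced
# through real networks so it satisfies every invariant
seedset_of <- function(net) identify_seed_set(net)

test_that("competition follows the weighted-sum formula on hand-built cases", {
  # A's seeds: x (singleton, conf 1), y+z (2-cycle, conf 0.5 each)
  a <- net_from_edges("X->Q Y->Z Z->Y Y->Q")
  sa <- seedset_of(a)
  expect_equal(unname(sa$confidence[c("X", "Y", "Z")]), c(1, 0.5, 0.5))

  # B's seeds include x and y but not z
  b <- net_from_edges("X->W Y->W Z->W W->V")  # z is a seed of B here too
  b2 <- net_from_edges("X->W Y->W W->Z")      # z internal to B
  expect_equal(competition_index(sa, seedset_of(b2)), (1 + 0.5) / 2)
  expect_equal(competition_index(sa, seedset_of(b)), (1 + 0.5 + 0.5) / 2)

  # self-competition and disjoint seed sets
  expect_equal(competition_index(sa, sa), 1)
  disj <- seedset_of(net_from_edges("P->Q"))
  expect_equal(competition_index(sa, disj), 0)
})

test_that("complementarity follows the formula on hand-built cases", {
  a <- net_from_edges("X->Q Y->Q")        # seeds {X:1, Y:1}
  sa <- seedset_of(a)
  # B contains X as an internal node, lacks Y entirely
  b <- net_from_edges("P->X X->W")
  expect_equal(complementarity_index(sa, b, seedset_of(b)), 1 / 2)
  # against itself every seed of A is a seed of A
  expect_equal(complementarity_index(sa, a, sa), 0)
  # disjoint metabolisms
  c_ <- net_from_edges("M->N")
  expect_equal(complementarity_index(sa, c_, seedset_of(c_)), 0)
})

test_that("toy community matrices equal the hand-computed values exactly", {
  mats <- interaction_matrices(toy_community())
  want <- toy_expected()
  expect_equal(mats$competition, want$competition, tolerance = 1e-12)
  expect_equal(mats$complementarity, want$complementarity, tolerance = 1e-12)
  # asymmetry is preserved, never symmetrized
  expect_false(isSymmetric(mats$competition))
  expect_false(isSymmetric(mats$complementarity))
})

test_that("matrices equal an element-wise pairwise loop and clones behave", {
  comm <- toy_community()
  mats <- interaction_matrices(comm)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(mats$competition[i, j],
                 competition_index(comm[[i]]$seeds, comm[[j]]$seeds))
    expect_equal(mats$complementarity[i, j],
                 complementarity_index(comm[[i]]$seeds, comm[[j]]$network,
                                       comm[[j]]$seeds))
  }

  # two identical species: competition all 1, complementarity all 0
  n1 <- net_from_edges("A->B B->C", organism_id = "c1")
  n2 <- net_from_edges("A->B B->C", organism_id = "c2")
  clones <- lapply(list(n1, n2),
                   function(n) list(network = n, seeds = identify_seed_set(n)))
  m <- interaction_matrices(clones)
  expect_true(all(m$competition == 1))
  expect_true(all(m$complementarity == 0))
})

test_that("community preconditions are enforced", {
  comm <- toy_community()
  expect_error(interaction_matrices(comm[1]), "at least 2")
  dup <- comm
  dup[[2]]$seeds$organism_id <- "S1"
  expect_error(interaction_matrices(dup), "duplicate")
  cyc <- net_from_edges("A->B B->C C->A", organism_id = "allcycle")
  bad <- c(comm[1], list(list(network = cyc, seeds = identify_seed_set(cyc))))
  expect_error(interaction_matrices(bad), "allcycle")
})

test_that("competition + complementarity <= 1 over random communities", {
  for (seed in 1:20) {
    comm <- random_community(4, 40, 15, rng_seed = seed)
    if (length(comm) < 2) next
    mats <- interaction_matrices(comm)
    expect_true(all(mats$competition + mats$complementarity <= 1 + 1e-12),
                info = paste("seed", seed))
    expect_true(all(mats$competition >= 0 & mats$competition <= 1 + 1e-12))
    expect_true(all(mats$complementarity >= 0 &
                      mats$complementarity <= 1 + 1e-12))
  }
})

test_that("indices are invariant under consistent compound relabeling", {
  relabel <- function(net, map) {
    ed <- network_edges(net)
    metabolic_network(net$organism_id,
                      unname(map[network_nodes(net)]),
                      data.frame(from = unname(map[ed$from]),
                                 to = unname(map[ed$to])))
  }
  comm <- toy_community()
  nodes <- sort(unique(unlist(lapply(comm, function(m) network_nodes(m$network)))))
  set.seed(11)
  map <- setNames(sprintf("Z%03d", sample(999, length(nodes))), nodes)
  comm2 <- lapply(comm, function(m) {
    n2 <- relabel(m$network, map)
    list(network = n2, seeds = identify_seed_set(n2))
  })
  m1 <- interaction_matrices(comm)
  m2 <- interaction_matrices(comm2)
  expect_equal(unname(m1$competition), unname(m2$competition))
  expect_equal(unname(m1$complementarity), unname(m2$complementarity))
})

test_that("permutation p-values are deterministic and respect edge cases", {
  comm <- toy_community()
  p1 <- permutation_pvalues(comm, "competition", n_perm = 99, rng_seed = 5)
  p2 <- permutation_pvalues(comm, "competition", n_perm = 99, rng_seed = 5)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 <= 1))
  # observed index 0 must give p = 1 (every null value is >= 0)
  obs <- interaction_matrices(comm)$competition
  expect_true(all(p1[obs == 0] == 1))
  expect_error(permutation_pvalues(comm, "competition", n_perm = 50), "99")
})

test_that("a planted full-overlap pair is detected as significant", {
  # B is a long chain: many SCCs, few of them sources; A's seeds equal B's,
  # so the observed competition is 1 and random seed placement rarely ties it
  set.seed(21)
  hits <- 0L
  n_draws <- 20
  for (d in seq_len(n_draws)) {
    chain <- paste(sprintf("V%02d->V%02d", 1:39, 2:40), collapse = " ")
    b <- net_from_edges(chain, organism_id = "B")   # 40 singleton SCCs, 1 source
    a <- net_from_edges("V01->X01", organism_id = "A")
    comm <- list(list(network = a, seeds = identify_seed_set(a)),
                 list(network = b, seeds = identify_seed_set(b)))
    p <- permutation_pvalues(comm, "competition", n_perm = 999,
                             rng_seed = 7000 + d)
    if (p["A", "B"] <= 0.05) hits <- hits + 1L
  }
  # null probability of drawing the one matching source among 40 SCCs is 1/40
  expect_gte(hits, ceiling(0.95 * n_draws))
})

test_that("matrix TSV and long-format exports round trip", {
  comm <- toy_community()
  mats <- interaction_matrices(comm)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(mats$competition, f)
  expect_equal(read_matrix_tsv(f), mats$competition)

  p <- permutation_pvalues(comm, "competition", n_perm = 99, rng_seed = 1)
  lf <- withr::local_tempfile(fileext = ".tsv")
  write_interactions_long(mats$competition, "competition", lf, pvalues = p)
  long <- read.delim(lf)
  expect_identical(nrow(long), 6L)
  expect_equal(long$value[long$species_a == "S1" & long$species_b == "S2"],
               mats$competition["S1", "S2"])
})
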