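# ecoseed

Reverse ecology of microbial communities from metabolic network topology.

Most microbes cannot be cultured, so their ecology — what they consume, whom
they compete with, whom they can feed — must be inferred from their genomes.
`ecoseed` implements the reverse-ecology workflow for doing that at community
scale: it reconstructs each organism's metabolic network from reaction
annotations, predicts the compounds the organism must acquire from its
environment (its *seed set*), and scores every ordered species pair for
resource **competition** and metabolic **complementarity**. Predicted
interactions can then be compared with observed co-occurrence across samples
via Jaccard similarity and a Mantel permutation test.

## The model

**Network.** For each organism, a directed compound graph: nodes are
compounds, with an edge A → B whenever A is a substrate of some reaction that
produces B (reversible reactions contribute both directions; stoichiometry is
ignored).

**Seed set.** The network is decomposed into strongly connected components
(SCCs) with Kosaraju's algorithm. The seed components are the sources of the
condensation — SCCs with no incoming edge from another component and at least
one outgoing edge. Producing any one compound of an SCC yields them all, so
each member of a seed component is an equally plausible exogenously acquired
compound and carries a confidence score of 1/|SCC|; confidences within a seed
component sum to 1.

**Interaction indices.** With S(A) the candidate seed compounds of A and
w_A(c) = 1/|SCC of c| their confidences, for an ordered pair (A, B):

- competition(A, B) = Σ_{c ∈ S(A) ∩ S(B)} w_A(c) / Σ_{c ∈ S(A)} w_A(c)
- complementarity(A, B) = Σ_{c ∈ S(A) ∩ (V(B) ∖ S(B))} w_A(c) / Σ_{c ∈ S(A)} w_A(c)

Both lie in [0, 1]; self-competition is 1 and self-complementarity 0; the
matrices are directional and never symmetrized. Permutation p-values resample
which of B's SCCs act as sources (preserving B's component-size spectrum) with
an add-one estimator p = (1 + #{null ≥ observed}) / (1 + n_perm).

**Co-occurrence.** Presence/absence Jaccard similarity across samples, and a
Mantel test whose statistic is the Pearson correlation over all n(n−1)
off-diagonal cells, with joint row/column permutation of the second matrix.

## Worked example

```r
library(ecoseed)

path  <- system.file("extdata", "toy_reactions.txt", package = "ecoseed")
net   <- reconstruct_network(parse_reaction_flatfile(path), "toy")
net
#> <metabolic network 'toy'> 19 compounds, 32 directed edges
seeds <- identify_seed_set(net)
seeds
#> <seed set 'toy'> 5 seed components, 5 candidate compounds
head(data.frame(compound = names(seeds$confidence),
                confidence = unname(seeds$confidence)))
#>   compound confidence
#> 1   C00002          1
#> 2   C00031          1
#> ...
```

Each listed compound heads a source SCC of the toy network: the organism
cannot synthesize it from anything else it metabolizes, so it must take it up
from the environment; confidence 1 means the component is a singleton.

```r
comm <- planted_community(community_spec(n_species = 4, rng_seed = 1))
mats <- interaction_matrices(comm)
round(mats$competition, 3)
#>      sp01 sp02 sp03 sp04
#> sp01  1.0  0.5    0    0
#> sp02  0.5  1.0    0    0
#> sp03  0.0  0.0    1    0
#> sp04  0.0  0.0    0    1
round(mats$complementarity, 3)
#>      sp01 sp02 sp03 sp04
#> sp01    0    0    0    0
#> sp02    0    0    0    0
#> sp03    0    0    0    1
#> sp04    0    0    0    0
```

The generator planted sp01/sp02 as competitors sharing half their seed
compounds (competition 0.5 both ways) and embedded all of sp03's seeds as
internal nodes of sp04's network (complementarity(sp03, sp04) = 1: sp04 can
synthesize everything sp03 needs).

A command-line front end covering the same operations ships as
`inst/cli/ecoseed.R` (subcommands `reconstruct`, `seeds`, `interact`,
`cooccur`, `mantel`, `simulate`).

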