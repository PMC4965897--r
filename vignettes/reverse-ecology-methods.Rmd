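---
title: "Seed sets, interaction indices and their validation"
author: "ecoseed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed sets, interaction indices and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoseed)
```

## The procedure

`ecoseed` predicts microbe–microbe interactions from genome-derived metabolic
topology alone. The pipeline has four stages.

**1. Network reconstruction.** Reaction annotations (KEGG-style flat files, or
KO annotation profiles joined to a reaction catalogue through a packaged
KO-to-reaction map) become a directed compound graph per organism: an edge
A → B whenever compound A is a substrate of a reaction producing B.
Stoichiometric coefficients and compartment tags are stripped during
canonicalization — the analysis is purely topological, and identifiers are
otherwise treated as opaque strings (only whitespace trimming and
uppercasing). Reversible reactions (equation arrow `<=>`) yield edges in both
directions; `=>` and `->` only as written. When a record carries no direction
flag at all, `reconstruct_network(default_reversible = TRUE)` treats it as
reversible — the conservative reading, since assuming irreversibility can
fabricate spurious sources — and the switch is exposed for users who prefer
the stricter reading. Records with the same compound on both sides are
flagged and excluded from reconstruction rather than silently creating
self-loops. An optional `exclude` list removes currency metabolites (water,
ATP, H+ and the like) before edge construction; it defaults to empty because
seed prediction should not silently depend on a curated hub list, but the
knob matters: hub compounds can glue otherwise independent SCCs together.

**2. Seed detection.** The graph is decomposed into strongly connected
components with a hand-written iterative Kosaraju implementation (explicit
stacks; genome-scale graphs would overflow R's recursion limit). The seed
components are the sources of the condensation: in-degree 0 *and* out-degree
≥ 1, both measured on cross-component edges only, so a component whose only
edges are internal is not a seed — it supplies nothing to the rest of the
network. Every member of a seed component is an equally plausible exogenously
acquired compound (producing one member of an SCC produces them all), so each
carries confidence 1/|SCC| and confidences per component sum to one. A
network that is one giant SCC has an empty seed set; the object represents
that state explicitly and the interaction indices refuse it, rather than
emitting misleading zeros.

**3. Interaction indices.** For an ordered pair (A, B), competition is the
confidence-weighted fraction of A's candidate seed compounds that are also
candidate seed compounds of B; complementarity is the weighted fraction of
A's candidates that occur in B's network as non-seed nodes. The denominator
is A's total seed confidence (equal to its number of seed components), which
makes self-competition exactly 1, bounds both indices in [0, 1], and
guarantees competition + complementarity ≤ 1 for every ordered pair (the two
conditions partition a subset of A's seeds under shared weights). Membership
is tested at the compound-identifier level against all of B's candidate seed
compounds, not against any one-per-SCC selection: the weighted sum already
averages over selections, which is why the package exports all candidates
with confidences and leaves discrete seed selection to consumers.

**4. Significance and co-occurrence.** No analytical null is available for
the indices, so significance is assessed by permutation: for a target species
B, each null replicate redraws which of B's SCCs are sources — sampling
|seed components of B| components uniformly without replacement from B's full
partition — and recomputes the index. This conditions on B's network
modularity (the SCC size spectrum, and hence the confidence weights, are
preserved) and randomizes only where the sources sit. The add-one estimator
p = (1 + #{null ≥ observed})/(1 + n_perm) keeps p strictly positive;
n_perm < 99 is refused as too coarse. Co-occurrence is presence/absence
Jaccard similarity across samples; the Mantel statistic is the Pearson
correlation over all n(n−1) off-diagonal cells (both triangles, because the
interaction matrices are directional), with the null generated by jointly
permuting rows and columns of the second matrix only — permuting either
matrix is statistically equivalent, one is fixed for reproducibility. The
default p-value is two-sided, since both positive (competition) and negative
(complementarity) associations with co-occurrence are of interest; one-sided
alternatives are available, and for n ≤ 8 an exact mode enumerates all n!
permutations.

## Tunable parameters

| Parameter | Default | Units / range | Why this default |
|---|---|---|---|
| `default_reversible` | `TRUE` | logical | direction-less records treated as reversible (conservative) |
| `exclude` | empty | compound ids | no silent currency-metabolite filtering |
| `presence_threshold` | 0 | abundance | any strictly positive abundance counts as presence; coverage-style cutoffs (e.g. 1 %) belong to species selection, not presence calls, so they are settable but not default |
| `n_perm` | 999 | count ≥ 99 | p resolution 0.001 with the add-one estimator |
| `alternative` | two-sided | — | both signs of association are hypotheses of interest |

## The synthetic generators

Offline validation rests on two generators. `random_reaction_set()` draws
reactions with 1–3 substrates and 1–3 products (disjoint sides) over a
compound universe — the appropriate null for property tests because it embeds
no interaction structure at all. `planted_community()` builds species
bottom-up from designated seed compounds outward: seeds are never produced by
any reaction, every internal compound is produced from a strictly earlier
compound, and every seed feeds at least one reaction. That construction makes
the ground truth exact — the intended seeds are necessarily the condensation
sources — and the generator still verifies each species with
`identify_seed_set()` instead of trusting the construction. Planted structure:
species 1 and 2 share a `seed_overlap` fraction of their seed compounds
(default 0.5, with 8 single-compound seeds per species — mid-scale overlap, so
recovery is informative rather than trivial at either extreme); species 3's
seeds are embedded as internal nodes of species 4; all remaining species draw
from disjoint compound pools. Defaults of 30 reactions over a universe of 400
compounds give sparse networks of roughly bacterial-pathway edge density at
toy scale.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: scale-free degree distributions and hub currency
metabolites, annotation noise and incomplete genomes, reversibility
mis-annotation, and compounds shared by hundreds of reactions. Recovery of
planted structure demonstrates correctness of the machinery, not field
performance on IMG/KEGG annotations.

## Numerical choices

- Confidence sums are checked to 1e-9; index equality in tests to 1e-12
  (pure rational arithmetic on small denominators, so exactness is expected).
- Permutation exceedance counts use a 1e-12 slack so that exact ties (common
  with rational index values) count as exceedances rather than being lost to
  floating-point noise.
- Components and their members are ordered lexicographically by smallest
  member, making every export byte-reproducible.
- Degenerate inputs fail loudly: empty reaction lists, empty seed sets,
  constant off-diagonal matrices in the Mantel test, n < 4 objects,
  duplicate organism ids.

## Validation problem sizes

The shipped test suite checks the SCC/seed machinery against a brute-force
transitive-closure oracle on 200 random digraphs of up to 30 nodes (plus an
igraph cross-check), the index formulas against a hand-computed three-species
community, Mantel type-I error with 1000 replicates of independent 10×10
matrices at 999 permutations (expected rejection 0.05, accepted within
[0.03, 0.07]), exactness against full 4! enumeration, and planted-structure
recovery over 100 generated communities. These sizes were chosen so the whole
suite stays interactive while estimator variance remains small enough for the
calibration bands to be meaningful.

## Known limitations

- Seed prediction is topological: it knows nothing of flux, regulation,
  transport, or growth media, and inherits every gap in the annotation.
- The complementarity normalization follows the same total-confidence
  denominator as competition, which bounds both indices and makes them
  directly comparable; other formulations of "support capability" normalize
  differently, so absolute values are comparable within this package, not
  necessarily across tools.
- The permutation null conditions on the SCC partition of the target species;
  it does not model uncertainty in the network reconstruction itself.
- Fetching live KEGG data requires network access; everything else is
  offline by design.
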