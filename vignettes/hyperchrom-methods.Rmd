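---
title: "Genomic hypergraphs from multi-way chromatin contacts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic hypergraphs from multi-way chromatin contacts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperchrom)
```

## The model

Concatemer long-read protocols (Pore-C and relatives) capture sets of
genomic restriction fragments that were proximity-ligated together. Each
read therefore witnesses a *multi-way* contact among two or more loci.
Decomposing such reads into pairwise contacts — the Hi-C view — discards
the information that the loci co-occurred simultaneously on one molecule.

hyperchrom keeps that information in a hypergraph `G = (V, E)`: nodes are
genomic bins at a chosen resolution and every read is a hyperedge joining
the bins its aligned monomers fall into. The central data structure is the
`n × m` incidence matrix `H` (rows = bins, columns = hyperedges, entries
0/1): a column sum is the order of a contact, a row sum the degree of a
locus.

### Binning

Each monomer is assigned to the bin containing its midpoint
(`floor(midpoint / resolution)`). The midpoint rule is a deliberate
choice: a fragment spanning a bin boundary is assigned to exactly one bin,
and binning is consistent across nested resolutions (binning at 100 kb and
coarsening to 1 Mb equals binning at 1 Mb directly, because
`floor(floor(x/r)/k) = floor(x/(rk))`). Bins repeated within a read
collapse, so hyperedge order can shrink below the monomer count; reads
collapsing to a single bin are retained as order-1 self-contacts (they
appear on the diagonal of decomposed contact matrices and are excluded
from pair statistics).

When a chromosome-sizes table is supplied, the node universe is *every*
bin of every listed chromosome, in table order. This guarantees that
hypergraphs from different samples share a row order, which the distance
measures require.

### Weighting

Distinct hyperedges are always stored merged with a multiplicity weight.
Whether multiplicities expand into repeated incidence columns is decided
at `build_incidence()` time: by default coarse resolutions (≥ 1 Mb) use
one column per distinct contact with weights carried separately, while
read-level and fine resolutions use one column per read occurrence —
repeated higher-order contacts are rare at fine scales, common at coarse
ones. All spectral computations expand weights into repeated columns so
that node degrees and hyperedge orders keep their counting semantics and
the handshake identity (sum of row sums = sum of column sums) holds.

## Filtering

Spurious ligation products are pruned through their pairwise support.
The hypergraph is decomposed into distinct locus-pair counts; the support
threshold `t` is the nearest-rank `percentile` (default 85) of that count
distribution, i.e. the smallest count with at least 85% of pairs at or
below it; a pair is supported iff its count ≥ `t`. Within each hyperedge
the node incident to the most unsupported internal pairs is removed, ties
going to the lower node index, until all internal pairs are supported;
hyperedges reduced below two nodes are dropped.

What happens to a hyperedge containing an unsupported pair is genuinely
underdetermined — removing the whole hyperedge, one node, or only the
pair from downstream statistics are all defensible. We chose iterative
worst-node trimming because it retains the maximal well-supported core of
each contact and is deterministic. Because trimming changes the
pair-count distribution (and with it the nearest-rank threshold), a
single pass is not idempotent; `filter_hypergraph()` therefore iterates
the pass to a fixed point. Each pass strictly removes incidence mass, so
the iteration terminates, and idempotence holds by construction.

## Spectral quantities

The hypergraph Laplacian is

$$L = D - H E^{-1} H^\top,$$

with `D` the diagonal matrix of node degrees and `E` the diagonal matrix
of hyperedge orders. Scaling each hyperedge's contribution by its order
distinguishes `L` from the clique-expansion graph Laplacian: for the
textbook hypergraph `{v1,v2,v3}, {v3,v4}` the shared node's diagonal
entry is `2 − (1/3 + 1/2) = 7/6`, not the clique-expansion degree 3.
Zero row sums and positive semidefiniteness are asserted in the test
suite on random instances. Note that any matrix printed as this example's
Laplacian must have vanishing row sums; a value other than 7/6 at (3,3)
is arithmetically inconsistent with the defining equation, which is why
the implementation derives every entry from the equation and cross-checks
against an independent dense-arithmetic oracle rather than hard-coding
tabulated values.

The hypergraph entropy is the Shannon entropy of the trace-normalized
spectrum,

$$S = -\sum_i \bar\lambda_i \ln \bar\lambda_i, \qquad
  \bar\lambda_i = \lambda_i / \textstyle\sum_j \lambda_j,$$

with `0 ln 0 = 0` and eigenvalues clipped at zero before normalization
(symmetric eigensolvers can return tiny negative values). A single
hyperedge spanning all `n` nodes has `L = I − J/n` with spectrum
`{0, 1 × (n−1)}`, hence entropy `ln(n−1)` — the closed form the test
suite checks to 1e-12. Entropy is undefined (an error) when the spectrum
is identically zero, which happens exactly when the hypergraph carries
no structure beyond isolated self-contacts. Entropy is not normalized
for hypergraph size; comparisons are only meaningful at fixed `n`.

## Distance measures

Comparison operates on matrices over the shared node universe:
adjacency `A = H E⁻¹ Hᵀ` (diagonal included), normalized Laplacian
`L̃ = I − D^{-1/2} A D^{-1/2}`, and the fast-belief-propagation affinity
`S = (I + ε² Dᵃ − ε A)⁻¹` with `Dᵃ = diag(rowSums(A))`. Zero-degree
nodes (bins untouched in a sample) get zero rows in `L̃` rather than
being dropped, so samples of different sparsity remain comparable.

- **Hamming**: `D_H = (1/n²) Σ |A₁ − A₂|` — local differences.
- **Spectral**: `D_λ = (1/n) (Σ |λ₁ⱼ − λ₂ⱼ|ᵖ)^{1/p}` on the ascending
  eigenvalues of the two normalized Laplacians (`p = 2` by default).
  We use `L̃` rather than `L` so that the spectra live on a common
  `[0, 2]` scale. The distance is invariant under node relabelling.
- **DeltaCon**: `D_Δ = (1/n²) (Σ (√S₁ − √S₂)²)^{1/2}`, the Matusita
  difference of affinities, with `ε = 1e-3` by default.

On the choice of `ε`: off-diagonal affinities are `≈ εA`, so after the
elementwise square root the raw Matusita value scales as `√ε`. The raw
number is therefore *not* stable across `ε`; what is stable — and what
the test suite asserts to within 10% across `ε ∈ {1e-2, 1e-3, 1e-4}` —
are comparative results such as ratios of distances between pairs of
hypergraphs. Any `ε` in that range yields the same orderings; large `ε`
can make `S` develop negative entries, which raises an error advising a
smaller value.

## Permutation significance

The significance of an observed distance `d(G₁, G₂)` is assessed against
`N` (default 1000) random hypergraphs "similar" to `G₁`: each draw keeps
the node universe, the hyperedge order multiset and the weights, and
re-draws every hyperedge's members without replacement with probability
proportional to the template's weighted node degrees — a bipartite
configuration-style null that approximately preserves the degree profile.
Exact degree-sequence preservation (edge-swap MCMC) was considered and
rejected: it is slower, and the additional rigidity is not needed for a
null that only has to look "like" the template. The p-value is the
proportion of null distances **greater than or equal to** the observed
one; ties count toward the null, the conservative direction, and a
reported 0 means no null draw reached the observed distance.

A test-design note: when the null distance distribution is effectively
continuous, the observed distance is exchangeable with the `N` background
draws, so `P(α ≥ 0.05) = (0.95·N + 1)/(N + 1)` exactly — there is no
margin for a finite-sample check of "≥ 95%". The calibration test
therefore uses a small discrete template (three active nodes, six
hyperedges over a 16-node universe) whose null distances carry
substantial tie mass; the ≥-convention then keeps α away from small
values under the null with real margin, and a planted relocation of half
the hyperedges onto untouched nodes is flagged at α ≤ 0.05.

The same machinery supports transcription-cluster significance: contacts
are partitioned by order (3, 4, 5, 6-or-more, plus a pooled class), and
in each trial as many random contacts as there are candidates are scored
against the downstream criteria (≥1 expressed gene, ≥2 expressed genes,
common TFs, common master regulators).

## Transcription clusters

The pipeline works on read-level contacts (binned operation is available
through the hypergraph layer for matrix exports). Parameters, defaults
and rationale:

| parameter | default | meaning |
|---|---|---|
| `flank` | 5000 bp | loci are extended ±5 kb before any overlap query |
| `expr_threshold` | 1 | a gene is expressed when its value (TPM scale) is ≥ 1 |
| `min_sites` | 3 | a TF "binds" a gene at ≥ 3 motif occurrences near its TSS |

The expression threshold is the one genuinely free parameter: expression
units are whatever the supplied table uses, and 1 on a TPM scale is the
conventional detection floor; it is exposed as an argument everywhere.
Gene proximity uses gene-body overlap with the flanked locus; TSS-only
matching was rejected as stricter than "nearby gene" warrants.

Classification tiers, each a subset of the previous:

1. **potential**: every flanked locus overlaps an accessibility peak and
   at least one overlaps an RNA Pol II peak; order ≥ 2.
2. **cluster**: ≥ 2 expressed genes sharing a common TF — with exactly
   two genes the TF must bind both; with three or more, a strict
   majority.
3. **specialized**: some common TF is a master regulator (MR), meaning
   its motif occurs ≥ `min_sites` times at its own encoding gene. TFs
   with no mapped encoding gene cannot be MRs.

Orthogonally, a cluster is **self-sustaining** when it contains an
expressed TF-encoding gene whose TF binds at least one gene of the same
cluster ("binding at the cluster" is operationalized through the motif
table, i.e. promoter-proximal sites of cluster genes; binding inside the
flanked loci directly would be an alternative reading), and **core**
when such a TF is additionally an MR. TF-encoding genes expressed in one
cluster whose TF binds only other clusters are reported separately, as
are expressed TF genes appearing in no cluster.

Peak-set enrichment (CTCF, cohesin subunits, enhancers) compares the
fraction of clusters with a peak-overlapping flanked locus against
size-matched random contact samples, one-sided.

## Synthetic data

The generator produces all six input types with planted structure. Its
defaults define the study conditions used throughout the tests: a
three-chromosome 2-Mb-each genome, 1,000 background reads with a contact
order distribution decaying from pairwise to 6-way
(0.45/0.25/0.15/0.10/0.05 — qualitatively the shape observed in real
multi-way contact data, where frequency falls monotonically with order),
70% intra-chromosomal contacts, 1-kb monomers, and eight planted clusters
of orders 3–5 emitting three reads each. Planted clusters are constructed
to satisfy exactly the criteria of an assigned tier: accessibility peaks
at every planted locus, Pol II at the first, expressed genes (TPM 10) on
the loci, a shared TF with four motif sites at each relevant gene,
self-binding sites for specialized/core tiers, and in-cluster placement
of the TF-encoding gene for self-sustaining/core tiers.

Background annotation noise (peak density per Mb, gene density,
expressed fraction, motif rate) is configurable and zero by default:
background monomers are rejection-sampled away from the ±5 kb flanked
neighbourhoods of planted loci, and distant TF-encoding genes live in a
reserved region near chromosome starts, so at zero noise no background
contact can satisfy any criterion — planted recovery is then exact by
construction, which is what the recovery tests assert
(precision = recall = 1 at every tier on a 5,000-read simulation).

What the generator does **not** emulate: polymer-physics contact decay
with genomic distance, restriction-site structure, mappability artifacts,
copy-number variation, or realistic motif count distributions. Passing
tests therefore demonstrate correctness of the algorithms under their
stated definitions, not robustness to the full messiness of real
Pore-C data.

`perturb_hypergraph()` provides calibrated alternatives for the distance
tests: `"relocate"` moves a fraction of hyperedges onto a disjoint node
block (shift by `n/2` modulo `n`), `"rewire"` resamples individual
memberships; strength 0 is the identity in both modes and distances grow
with strength on average.

## Numerical conventions and problem sizes

- Eigenvalues come from symmetric eigensolvers, are clipped at zero and
  sorted ascending; Laplacians are symmetrized (`(L + Lᵀ)/2`) before
  decomposition to remove floating-point asymmetry.
- Nearest-rank percentile: `sorted(x)[ceiling(p/100 · length(x))]`.
- All deterministic tie-breaks are by lower node index or lexicographic
  node order (filtering, top-contact selection, TF ranking by name).
- Stochastic functions take an explicit `seed` and restore the caller's
  RNG state, so library use never clobbers a session's stream.
- The test suite and the acceptance script use desk-scale problem sizes
  chosen to exercise every code path with comfortable statistical margin:
  toys of 10–20 nodes for spectral and distance properties, 100 random
  pairs for the distance axioms, N = 200 permutations with 50 repeats for
  calibration, and a 5,000-read simulation with 10 planted clusters for
  the pipeline; the whole suite completes in about a minute.

## Known limitations

- Entropy is not normalized for hypergraph size; cross-chromosome
  comparisons conflate size with disorder.
- The similar-hypergraph null preserves degrees in expectation, not
  exactly; hypergraphs with extreme degree skew may need the larger `N`.
- The filtering trimming rule is one of several defensible readings of
  pairwise support (see Filtering above) and is kept behind its own
  function boundary.
- Read-level node universes are sample-specific; distance computations
  require binned hypergraphs built against a shared chromosome-sizes
  table.
- The motif table is consumed, never computed: motif scanning, enhancer
  target assignment, and TAD calling are out of scope (the decomposed
  contact matrices are exported in a form TAD callers accept).
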