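---
title: "Auditing a DNA barcode reference library: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing a DNA barcode reference library: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# What this package computes

A DNA barcode reference library is a set of aligned mitochondrial COI
fragments (typically 658 bp), each attached to a specimen with an expert
species identification. `barcodeaudit` answers the operational question such
libraries exist for: *which species can be reliably identified from a barcode
alone, which cannot, and does adding morphology rescue the failures?*

The pipeline is: distance computation → tree building → per-species
classification → integrative accounting, with a ground-truth simulator for
end-to-end testing.

# The distance model

Pairwise distances use the Kimura 2-parameter model. For one pair of
sequences, comparable sites are the alignment columns where *both* sequences
carry an unambiguous base (pairwise deletion); over those sites, `P` is the
proportion of transitions (A↔G, C↔T) and `Q` the proportion of transversions,
and

$$d = -\tfrac12 \ln\!\left[(1 - 2P - Q)\sqrt{1 - 2Q}\right].$$

Numerical choices, all deliberate:

* **Pairwise deletion, not complete deletion.** An `N` in one specimen should
  not discard a column for every other pair. This also means two sequences
  that differ only at sites masked by `N` have $d = 0$ and legitimately
  "share a barcode" — identity is defined on the comparable sites.
* **Saturation gives `NA`, never a clamp.** If $1-2P-Q \le 0$ or
  $1-2Q \le 0$ the distance is undefined. Clamping to some large value would
  silently corrupt nearest-neighbor minima, which drive every downstream
  classification.
* **Minimum overlap 100 sites** (configurable). The threshold below which a
  pair's distance is considered unreliable; 100 of 658 is conservative. Low
  overlap is reported (fatal only in strict mode) rather than `NA`, since the
  distance is still defined, just noisy.
* All ambiguity codes other than `N` are mapped to `N` on input: under
  pairwise deletion every non-ACGT symbol behaves identically, so keeping
  the finer IUPAC distinctions would only complicate the identity rule.

Distances are stored in substitutions/site and reported in percent; every
user-facing table says which.

# Tree building

Neighbor-joining (Saitou–Nei Q-criterion) is implemented in the package
rather than delegated, because the audit needs determinism guarantees a
generic implementation does not give:

* **Tie-breaking.** Among equal-Q pairs the lexicographically smallest pair
  of cluster representative labels is joined, making the topology independent
  of input row order (important for degenerate all-zero or highly symmetric
  matrices).
* **Negative branch lengths are clamped to 0** without redistribution; these
  arise only on near-zero edges where no defensible length exists anyway.
* Undefined (saturated) distances are a hard error at this stage: the caller
  must drop or impute, never the tree builder.

On additive matrices NJ is consistent; the test suite verifies exact
topology recovery and path-metric reproduction to 1e-9 on random additive
inputs of up to 8 taxa, and agreement with `ape::nj` as an independent
oracle.

**Bootstrap.** Nonparametric bootstrap resamples alignment columns with
replacement (same length), recomputes the K2P matrix and NJ tree, and counts
how often each internal bipartition of the *original* tree recurs. Support
annotates the original tree, not a consensus — this matches how support
values decorate published NJ trees. A single integer seed drives one RNG
stream; identical seeds give identical supports. Replicates producing
undefined distances are discarded and counted; more than 50% discarded is an
error. The default of 100 replicates is a desk-scale choice.

**Midpoint rooting** places the root halfway along the longest leaf-to-leaf
path (ties: lexicographically smallest leaf pair; all-zero trees root at the
first leaf with a warning). It is the only label-free rooting available when
no outgroup is designated, and it never changes the unrooted bipartition
set — supports are re-attached by bipartition, not by node index.

# Per-species classification

For each species: maximum and mean intraspecific divergence (singletons:
undefined, and excluded from the library-level mean of maxima), the nearest
non-conspecific record and its species, and the set of heterospecific
species at distance exactly 0 ("shared barcodes").

**Monophyly.** On an unrooted NJ tree a species is monophyletic iff some
edge splits exactly its specimens from everything else. Non-monophyletic
species are refined on the midpoint-rooted tree: *paraphyletic* if the
foreign specimens inside the smallest clade containing the species form
exactly one clade (pruning that one clade would restore monophyly),
*polyphyletic* otherwise. A genuinely rooted input tree is judged on its own
clades with its own rooting. Note the rooted/unrooted distinction matters:
a caterpillar `((((b1,b2),a1),a2),a3)` makes species *a* paraphyletic when
rooted, yet monophyletic as an unrooted tree, because the edge below
`(b1,b2)` already separates the two species.

**Diagnosability** is computed under two published criteria:

* *Barcode-cluster criterion* (`cluster_diagnostic`): the species is
  monophyletic and shares no barcode — or is a singleton whose nearest
  neighbor is at positive distance (a singleton cannot be "monophyletic",
  but a unique haplotype still identifies it).
* *Species-specific-haplotype criterion* (`haplotype_diagnostic`): no shared
  barcode, regardless of monophyly. A paraphyletic species whose haplotypes
  are all species-specific still identifies every query that matches one of
  them.

By construction the cluster criterion implies the haplotype criterion; the
test suite asserts this set inclusion on every input.

**Cryptic-diversity flags** mark species whose maximum intraspecific
divergence strictly exceeds 2% and 3% (strict because the working definition
is "over 2%"; a species at exactly 2.0% is not flagged). The thresholds are
screening conventions from the barcoding literature, not species-delimitation
rules, and are configurable.

**Query identification** returns the species of the nearest record if it
lies within the acceptance threshold (default 2%) and no second species ties
(default tie margin 0: exact ties only, which is how identical-haplotype
ambiguities manifest; a best-close-match margin is available but off by
default).

# Integrative accounting

Morphological difficulty is expert knowledge, not something computable from
sequences, so it enters as an annotation table: groups of species that are
difficult to separate, per sex. The packaged table
(`inst/extdata/swiss_confusable_groups.tsv`) transcribes the published
Swiss assessment — ten barcode-problematic groups (eight pairs, two trios;
four of the pairs para/polyphyletic *without* sharing barcodes), eight
male-morphology pairs and eight female-morphology groups — and is meant to
be copied and edited for other faunas.

Each channel becomes a *confusability graph*: species are nodes, each group
a clique. The integrated (barcode + morphology) channel is the edge-wise
intersection — a pair stays confusable only if both channels fail on it. A
species is "difficult" if any edge touches it, and the identification rate
is $100\,(n - n_\text{difficult})/n$.

Two accounting choices are worth making explicit:

* **The denominator is the number of sequenced resident species (217).**
  Reverse-engineering the published percentages (16/217 = 7.4%,
  4/217 = 1.8%) confirms this is the denominator actually used, though it is
  nowhere stated.
* **Entanglement edges from an audit are mutual.** When building the barcode
  graph from audit output rather than from the fixture, an edge joins two
  species only if each appears inside the other's spanning clade (or they
  share a barcode). A monophyletic species that merely sits inside the
  spanning clade of a polyphyletic neighbor is not itself compromised.

Percentages are exact internally and rounded half-up to one decimal only at
serialization; the published improvement deltas (e.g. integrated-male minus
barcode) are differences of the *rounded* rates, so the package reports them
the same way.

# The simulator: a stated world

`simulate_library()` generates libraries with known truth. Its defaults are
the regime a regional COI library actually shows: expected within-species
pairwise distance 0.6%, expected between-species distance 5%,
transition/transversion rate ratio 4, 658 bp, four specimens per species.

* The **species tree** has a random coalescent topology with equal tip
  depths. Raw coalescent node heights would place some speciations
  arbitrarily close to the present, letting intraspecific variation swamp
  the shallowest species pair — real barcode libraries instead show a floor
  on nearest-neighbor distances (roughly 1% against a 4.5% mean in the Swiss
  data). Internal node heights are therefore compressed into the upper half
  of the tree depth before rescaling, which bounds the minimum
  between-species distance at about half the mean. This is the one place the
  generator deliberately departs from the neutral coalescent, and it is what
  makes "clean separation ⇒ monophyly" tests sharp rather than flaky.
* **Substitutions follow the exact K2P process** (per-branch transition
  probabilities from the rate-matrix exponential), so realized distances are
  consistent with the estimator's model and parameter-recovery regressions
  have slope ≈ 1 with no correction factors.
* Each specimen evolves from its species ancestor along a branch of half the
  intraspecific target, so the expected distance between two conspecifics
  equals the target.
* **Introgression** (mitochondrial capture) copies a donor haplotype over a
  recipient specimen's sequence, keeping the recipient's species label —
  exactly the phenomenon behind shared barcodes between good species. By
  default the copy is exact, guaranteeing a zero distance; optional
  post-copy mutation relaxes this for stress tests.

What the simulator does *not* emulate: indels and alignment error,
sequencing error and chimeras, geographic population structure within
species, rate variation among lineages or sites, and nuclear
mitochondrial pseudogenes. A green test on simulated data therefore
establishes correctness of the audit logic under the stated model — not
robustness of barcoding itself against those real-world complications.

# Known limitations

* Monophyly refinement depends on midpoint rooting; on trees whose diameter
  path is ambiguous at near-zero lengths, the paraphyletic/polyphyletic
  distinction (never the monophyletic/non-monophyletic one) can be
  convention-dependent.
* Distances replicate the standard K2P/pairwise-deletion convention, but
  third-party platforms' unpublished ambiguity handling can differ in the
  last decimals; audits are defined relative to the supplied alignment.
* Maximum-likelihood trees, consensus trees, BIN-style clustering and
  automatic species delimitation are out of scope; NJ with bootstrap is the
  implemented pathway.
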