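---
title: "Covariation analysis of RNA alignments: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariation analysis of RNA alignments: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnacov)
```

## The problem

Positions in an RNA alignment that form a base pair are constrained to
change together: when one partner of a G:C pair mutates, compensatory
selection usually restores pairing (G:C → A:U, U:A, C:G, sometimes through
the G:U wobble). Covariation analysis looks for column pairs with such
coordinated patterns of variation; strong, exclusive covariation almost
always marks a secondary-structure base pair, while weaker shared
covariation often marks nucleotides that are merely close in the folded
molecule ("neighbor effects"). `rnacov` implements both a
phylogeny-aware event-counting statistic and the classical
frequency-based statistics, plus the selection, extension and annotation
machinery around them.

## Phylogenetic event counting (PEC)

For a column pair, every informative leaf (unambiguous nucleotide at both
columns) carries an ordered pair type such as `A:U`. Internal nodes of the
— possibly multifurcating — phylogeny are assigned the pair type occurring
most frequently among the leaves of their subtree, a majority variant of
Fitch parsimony suited to taxonomy trees whose nodes can have many
children. At each internal node the *distinct* child pair types that
differ from the node's own type are collected; each distinct type counts
exactly once, regardless of how many children carry it. This
de-duplication is the method's guard against repeat sampling: a clade of
fifty identical descendants is one observation of one change, not fifty.
A counted change is a **positive event** when both positions changed, a
**negative event** when only one did, and

$$\mathrm{CPE} = \frac{\text{positive events}}
{\text{positive} + \text{negative events}}.$$

CPE near 1 means every observed change was compensatory. Pairs with fewer
than 10 total events are flagged and set aside by default
(`min_total_events`): with almost no observed changes the ratio is noise.

Numerical choices worth knowing:

* **Tie-break.** Majorities are tied occasionally; ties resolve
  lexicographically on the ordered pair string (`A < C < G < U`). This is
  deterministic and documented, but it is *orientation-dependent*: a tie
  such as {`A:U` ×2, `U:A` ×2} resolves to `A:U` whichever column is
  listed first, so swapping the two columns can change counts for tied
  reconstructions. On tie-free reconstructions the counts are exactly
  symmetric, and the test suite asserts this.
* **Gaps and ambiguity codes** remove a leaf from both the majority
  computation and event counting for that pair; no gap-involving events
  are ever counted.
* **Unary chains** (ubiquitous after pruning a public taxonomy to the
  sequenced taxa) are collapsed at tree-ingestion time; no state change
  can occur across a single-child edge under the majority rule, so counts
  are unaffected.

## Frequency-based statistics

* **Conservation entropy** (per column):
  $H = -\sum_{i \in \{A,C,G,U\}} P_i \log_2 P_i - P_\Delta \log_2 P_\Delta$,
  with $P_\Delta$ the gap frequency. Ambiguity codes are excluded from the
  frequencies and the denominator. Low = conserved. Base 2 throughout;
  the base only rescales ranks and ratio scores, but the
  entropy-difference filter threshold (0.2) is defined on this bits scale.
* **MIxy**: mutual information of the joint nucleotide distribution,
  $\sum \Pr(M,N)\log_2 \frac{\Pr(M,N)}{\Pr(M)\Pr(N)}$, computed over
  sequences with nucleotides at both columns (gaps excluded as states —
  base-pair covariation is defined on nucleotides, whereas the
  conservation score explicitly includes gaps).
* **MIp**: MIxy minus the average-product correction
  $\mathrm{APC}(a,b) = \bar{MI}(a,\cdot)\,\bar{MI}(\cdot,b)/\bar{MI}$,
  which removes the background MI shared by high-entropy columns. The
  means are taken over the candidate set actually scored (the data flow
  of the pipeline); a full-matrix run reproduces the textbook form. The
  Z-standardised `MIp_Z` is exposed with a configurable cutoff
  (default 4) for users wanting a Dunn-style threshold.
* **OMES**: $\sum (N_0 - N_e)^2 / N_t$ summed over all 16 dinucleotide
  cells, observed or not, with $N_e$ the independence expectation from
  the marginal counts.

## Candidate filtering and calling

Scoring every pair of a 3000-column alignment with PEC is prohibitive
(a 3236-column alignment alone implies 5,234,230 pairwise comparisons),
and columns with very different conservation cannot covary strongly. The
**coarse filter** keeps pairs whose entropies differ by at most 0.2 bits
*and* whose MIxy ranks in the top 100 partners of both columns.

The **Joint N-Best** caller works on ratios: for column $X$,
`nbest(X)` = second-highest / highest score among $X$'s partners. A pair
(X, Y) is called when X and Y are each other's best partners and both
ratios are ≤ 0.5 — the covariation must be mutual and unambiguous. A
column with a single scored partner gets ratio 0 (no competitor exists)
but is flagged so users can exclude it; best-partner ties resolve to the
lower column index. PEC calls and the union of MIxy/MIp calls are merged
with provenance tags, since the two families of methods demonstrably find
overlapping but non-identical pair sets.

## Helix extension, purity, neighbor effects

**Helix extension** grows helices from called ("nucleation") pairs: the
adjacent antiparallel pairs (i−1, j+1) and (i+1, j−1) are added while at
least 85% of the (ungapped, unambiguous) sequences form a canonical
G:C/A:U/G:U pair there, stopping at the first failure. This recovers
conserved base pairs that cannot covary because they barely vary. The
denominator convention (gapped rows excluded) is a package decision and
is switchable via the reported fractions. Extensions that would reuse a
nucleation column are dropped; column conflicts between extensions
resolve to the higher canonical fraction.

**Purity** measures how exclusive a pair's covariation is: pair types are
ranked by frequency (ties lexicographic), the top type is accepted, and
each further type is accepted only when both its 5′ and 3′ nucleotides
are unused by every accepted type — i.e. it covaries with all of them.
Purity is the accepted types' summed frequency. The GU-plus variant lets
G:U/U:G sit alongside canonical partners without blocking, crediting the
wobble pair's presence inside regular helices. GU-plus purity is never
smaller than plain purity (property-tested on randomized tables).

**Neighbor effects** are pairs whose covariation is significant but not
exclusive: one-directional N-Best ratio ≥ 0.85 (the signal is shared with
competitors), CPE ≥ 0.25, at least 10 total events, and not already
called as a base pair. The ratio definition names one column without
saying which; the package flags a pair when *either* column's ratio
reaches the threshold and reports the larger of the two — the criterion
is about the covariation being non-exclusive, which either column can
reveal. The CPE boundary is taken as ≥ 0.25 for consistency with the
other two inclusive thresholds. When a PDB structure is supplied, each
flagged pair is annotated with the Euclidean distance between the bases'
hydrogen-bond-edge atom centers (defaults: purines N1/C2-amine/O6-or-N6,
pyrimidines N3/O2/O4-or-N4; the atom sets are arguments, since the
underlying definition — "the atoms that usually form the hydrogen
bonds" — leaves the exact list open) and with its annotation class in
the reference structure.

## The synthetic generator

`synth_spec()` / `synth_simulate()` produce the test bed: a rooted
multifurcating tree (random out-degree 2–4), and an alignment whose
columns play defined roles — planted compensatory pairs that substitute
jointly between canonical partners, helix blocks whose centre pair varies
while the flanking pairs are invariant canonical, independently mutating
unpaired columns, frozen conserved columns, and all-gap columns.
Substitutions are per-edge Bernoulli events rather than a continuous-time
model: the event counter tallies discrete changes, so a discrete
generator keeps truth comparisons exact. Root states are drawn uniformly
per column; everything is reproducible to the byte under a fixed seed.

Reference conditions (the defaults): 200 leaves, 120 columns, 20 planted
pairs (3 of them centres of 5-pair helices), compensatory rate 0.10 per
edge, unpaired rate 0.04, conserved fraction 0.15, gap fraction 0.05 —
sizes chosen so the full pipeline runs in seconds while the tree still
contains enough events per pair (typically ≥ 15) to clear the
total-event threshold. What the generator does *not* emulate matters for
interpreting green tests: real rRNA alignments have indel evolution, rate
heterogeneity across sites and lineages, non-canonical and tertiary
pairs, alignment error, and taxonomically biased sampling. Passing the
planted-recovery tests shows the statistics and the calling logic are
implemented correctly, not that the same precision/recall transfers to
curated biological alignments.

## Evaluation

Against a reference structure (BPSEQ/CT plus optional tertiary pairs in
ungapped reference coordinates), each call maps through the
column-to-position map; calls on reference-gapped columns are reported
unmappable and excluded. Mapped calls are true positives when annotated
(secondary or tertiary), and the precision-of-top-N curve summarises the
ranked call list. On simulated data the emitted truth table supplies
exact precision and recall per method.

## Known limitations

* The event counter's worked examples and all counts treat a child type
  differing from its parent in both symbols as positive even when the
  substitution path is biologically implausible; the method counts
  patterns, not mechanisms.
* Neighbor-effect base triples are not detected, only carried through
  when the reference annotation provides them.
* The coarse filter can, by construction, discard a weakly covarying true
  pair; on simulated data at defaults the property tests check that no
  Joint-N-Best-callable pair is lost.
* McBASC, ELSC and model-based ancestral reconstruction are out of scope;
  MIp serves as the strongest frequency-based comparator.

## Problem sizes used by the automated checks

The test suite and the acceptance script run entirely on simulated or
constructed data: the exhaustive event-counter verification covers every
rooted multifurcating topology with 2–6 leaves (1 + 4 + 26 + 236 + 2752
trees) against an independent brute-force implementation — with all
4^n two-letter leaf assignments for up to 4 leaves and seeded random
assignments beyond — and the planted-recovery checks run the full
pipeline at the reference generator conditions above.
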