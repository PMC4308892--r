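---
title: "Methods: transposon-interaction triplet features for piRNA classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: transposon-interaction triplet features for piRNA classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripiR)
```

## The problem and the model

PIWI-interacting RNAs (piRNAs) are 24–31 nt germline small RNAs that silence
transposons. They carry no conserved sequence motif and no conserved
secondary structure, so neither homology search nor motif scanning separates
them from other small RNA fragments. What piRNAs *do* share is their
function: they base-pair with transposon transcripts. tripiR classifies
candidate small RNAs by that interaction.

The procedure, end to end:

1. **Alignment.** Each candidate is aligned to a transposon library allowing
   at most three substitutions (no indels), on both strands. Candidates with
   no placement are reported as not transposon-associated and never scored.
2. **Duplex prediction.** For the selected best hit the package predicts the
   intermolecular RNA–RNA duplex between the candidate and the
   transcript-sense sequence of its matched region, writing the result in
   dot-bracket notation: `(` for a paired candidate base, `)` for its
   partner, `.` for unpaired positions.
3. **Feature extraction.** A width-3 window slides along the candidate. Each
   window has one of $2^3 = 8$ pairing patterns (`(((`, `((.`, `(..`, `(.(`,
   `.((`, `.(.`, `..(`, `...`); combined with the middle nucleotide
   (A/C/G/U) this gives $4 \times 8 = 32$ *structure–sequence triplet
   elements*. A length-$L$ candidate yields $L-2$ windows; the normalized
   counts form a 32-dimensional frequency vector summing to 1.
4. **Classification.** A soft-margin SVM with RBF kernel
   $K(x, x') = \exp(-\gamma \lVert x - x' \rVert^2)$ separates real piRNAs
   ($y = +1$) from pseudo piRNAs ($y = -1$) with decision function
   $f(x) = \mathrm{sgn}\left(\sum_i \alpha_i y_i K(x, x_i) + b\right)$.

Training requires a negative class. Pseudo piRNAs are built by double
randomization: pick a random sequence from an unrelated ncRNA pool (with all
real piRNAs removed), cut a random 20–30 nt fragment, keep it only if it
still maps to the transposons within three mismatches, deduplicate, and
subsample the survivors so their length distribution matches the real
piRNAs. The mappability filter is essential: it makes the negative class
hard, since pseudo piRNAs are *also* antisense to transposons, and forces
the classifier to use the fine structure of the interaction rather than mere
mappability.

## Components and their parameters

### Mismatch-limited alignment

A seed-and-verify search (hash index of `seed_length`-mers, default 8 nt)
with the pigeonhole guarantee: a query split into $k+1$ disjoint segments
must contain one exact segment in any placement with $\le k$ substitutions.
Queries too short to carry $k+1$ seeds fall back to a full scan, so the
search is exact at every length; the suite checks exact equivalence with a
brute-force Hamming scan. Coordinates are 0-based half-open on the target
forward strand; ties are reported in `(target_id, offset, strand)` order so
every downstream selection is reproducible.

Both strands are searched by default. The mapping protocol this package
follows does not state strandedness; since piRNAs are predominantly
antisense to transposons, reverse-strand placements must at least be
representable, and searching both is the conservative default.

### The duplex engine

The reference method used an external thermodynamic tool for the
piRNA–transposon duplex. tripiR instead ships a self-contained
dynamic-programming engine so that results are deterministic and the whole
artifact is testable offline, with the same output contract (dot-bracket
strings plus an energy-like score):

* pair scores GC = 3, AU = 2, G·U wobble = 1 (wobble can be disabled);
* +1 stacking bonus for each pair stacked directly on the previous one;
* antiparallel, non-crossing pairs only; no intramolecular structure;
* `energy` is the negative of the optimal score — only its ordering is used
  downstream (choosing among equally-mismatched hits).

The DP is verified against exhaustive enumeration of all non-crossing
matchings on random 8-mer pairs. Traceback preference (pair > advance query
> advance window; stacked before unstacked) is fixed, so structures are
deterministic even when several matchings tie.

Which sequence the duplex predictor should see is genuinely open; tripiR
feeds it the reverse complement of the matched span in query orientation
(the transcript the piRNA would silence), with a configurable flank
(default 0, clipped at target ends). For a 0-mismatch hit this yields a
near-perfect duplex, which is the sanity anchor the tests assert (≥ 90% of
positions paired).

### Feature extraction and F-values

The first and last nucleotides are never window centers, giving exactly
$L-2$ windows and exact normalization. Only the query-side structure enters
the features. Discriminative power per element is summarized by
$F_j = |\mu_j^+ - \mu_j^-|\,/\,(\sigma_j^+ + \sigma_j^-)$. The standard
deviations are population ($n$ in the denominator) by default — the source
formula does not specify, and the choice is exposed as an argument. A zero
denominator yields $F = 0$ when the means agree and an `Inf` sentinel
(ranked first) when they differ.

### SVM and model selection

No SVM solver ships with the supported R stack, so the package implements
sequential minimal optimization with first-order (maximal violating pair)
working-set selection and a precomputed kernel matrix — adequate to a few
thousand training points, deterministic for fixed data order. Stopping
tolerance is $10^{-3}$ on the KKT violation gap; $b$ is the midpoint of the
violation bounds at convergence.

Model selection follows the 7/2/1 scheme: the data are split into ten
stratified partitions (each preserving the class ratio within one sample);
in each of ten rotations seven partitions train, two validate the
$(C, \gamma)$ grid search (ties resolved toward the smallest $C$, then
$\gamma$), and the held-out partition is scored. Reported metrics are
$Se = TP/(TP+FN)$, $Sp = TN/(TN+FP)$, $Pre = TP/(TP+FP)$ and
$ACC = (TP+TN)/N$, all in percent, aggregated as mean ± sd over the ten
rotations. The conventional exponential grid
($C \in 2^{-5..15}$, $\gamma \in 2^{-15..3}$, step $2^2$) is the default;
the test suite and the acceptance script use a reduced 2×3 grid because the
full grid costs roughly an hour at $n = 2{,}000$ — the accuracy criterion,
not the grid, is what is being tested.

## The synthetic world

All tests run without downloads, on generated data:

* `make_transposons()` — uniform-composition random sequences with
  SINE/LINE/LTR/DNA class labels assigned round-robin.
* `plant_positive_reads()` — 24–30 nt substrings of the transposons (peak at
  26 nt, the fly-like mode; half reverse-complemented) with
  Binomial(3, 0.15) planted substitutions, so every read is mappable at
  three mismatches by construction. An optional 5′-U bias is available but
  off by default, since the classifier must not rely on it.
* the ncRNA pool for the negative generator — transposon fragments diverged
  by ~12% substitution, embedded in random padding. This is the one place
  the generator deliberately shapes the world: with *exact* transposon
  copies in the pool, pseudo fragments would map at 0 mismatches and their
  duplexes would be indistinguishable from the planted positives — the
  fixture classes would coincide and nothing could be learned. Divergence
  makes pseudo reads map with more substitutions than positives, which is
  the qualitative situation with real ncRNA fragments, while the ~12% level
  keeps enough fragments mappable within three mismatches for the generator
  to fill its quotas.
* `make_labeled_features()` — Dirichlet-distributed 32-dimensional frequency
  vectors (total concentration 60) whose class means differ along fixed
  element subsets: fully paired triplets (`(((A`…`(((U`) raised in the
  positive class, two-paired/one-unpaired patterns raised in the negative
  class — the qualitative class difference reported for real data. The
  `separation` knob scales the difference; 0 makes the classes
  exchangeable. The default (1) is calibrated by the classifier-recovery
  experiment: 10-fold CV must reach ≥ 90% mean accuracy, and at separation
  0 it must sit at 50 ± 5%.

What a green suite establishes: the alignment, duplex, feature, fold and
metric machinery is exact against independent oracles, the pipeline is
deterministic, and the classifier recovers planted class structure. What it
does not establish: accuracy on real piRNA data. The synthetic generators do
not model sequencing error, read-abundance distributions, transposon family
structure, genomic piRNA clusters or species-specific composition biases, so
the headline cross-validation numbers reported for real fly data are out of
reach of this artifact's fixtures by design.

## Numerical and boundary conventions

* Internal canonical alphabet is DNA (`T`); RNA (`U`) appears at the duplex
  and feature boundary. `T`/`U` are interconvertible everywhere.
* Redundancy removal defaults to exact-duplicate removal (first occurrence
  wins, multiplicities retained); an optional near-duplicate mode (equal
  length, Hamming ≤ 2) exists because the source protocol's threshold is
  unstated.
* Records containing `N` are kept in libraries but yield no alignments and
  no features; the pipeline labels them not transposon-associated.
* Multi-mapping reads take the hit with fewest mismatches, then lowest
  duplex energy, then lexicographic hit order.
* Pseudo-piRNA length matching uses bin-exact quotas (largest-remainder
  apportionment); underfillable bins shorten the output with a warning
  rather than distorting the distribution.
* All randomness flows from explicit integer seeds through `withr`;
  identical seeds give byte-identical libraries, models and predictions.

## Known limitations

* The duplex engine is a scoring heuristic, not a thermodynamic model;
  energies are in arbitrary units and only comparable within one query.
* The SMO solver precomputes the full kernel matrix ($O(n^2)$ memory), so
  training beyond ~10⁴ points would need chunked kernels.
* Transposon class assignment trusts `class=` header tokens or a sidecar
  table; no annotation lookup is performed.
* The alignment index is an in-memory hash over all target k-mers —
  appropriate for transposon libraries, not for whole genomes.
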