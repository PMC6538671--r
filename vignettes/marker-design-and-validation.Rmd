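---
title: "Designing and validating short metabarcoding markers with ampliscan"
author: "ampliscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and validating short metabarcoding markers with ampliscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliscan)
```

## The problem

Environmental-DNA (eDNA) metabarcoding identifies the taxa present in a
water (or soil) sample by PCR-amplifying a short, taxonomically informative
fragment from the trace DNA the organisms shed, sequencing the amplicons in
bulk, and assigning reads to reference sequences.  A usable marker for a
focal genus must satisfy three constraints simultaneously:

1. the amplicon must be **short** (here, a variable core under 200 bp),
   because eDNA is degraded;
2. the amplified region must carry **enough interspecific differences** to
   separate all target species; and
3. the core must be bracketed by **conserved, primer-sized windows**
   (20–30 bp) shared by every target species, so one primer pair amplifies
   them all.

`ampliscan` implements this design procedure as a scan over an aligned
reference panel, evaluates the resulting primer pair thermodynamically and
against each template, quantifies the taxonomic resolution of the amplified
region, and re-implements the downstream read-processing and assignment
pipeline.  The motivating use case is a freshwater-eel (genus *Anguilla*)
marker in the mitochondrial ATP6 gene: 19 species and subspecies whose
whole mitogenomes admit exactly this architecture — a 167 bp variable core
between a 22 nt forward primer (1 tolerated template mismatch in 12 of 19
species: 10 T·G wobbles, 2 A·C) and a perfectly conserved 26 nt reverse
primer.  That pair, with its printed melting temperatures (55.7/55.9 °C)
and G/C contents (50%/38%), serves as the package's benchmark throughout.

## Marker discovery

`conservationProfile()` tallies A/C/G/T/gap per alignment column (the
WebLogo-style view).  `findConservedWindows()` reports every maximal,
gap-free window of width 20–30 whose majority consensus differs from
*each* template by at most `maxMmPerTemplate` positions (default 1 — a
single primer–template mismatch away from the 3′ end rarely kills
amplification, and the benchmark forward primer tolerates exactly one).
Consensus ties are broken alphabetically, which is equivalent to
minimising total mismatches and keeps output deterministic.  Degenerate
template bases count as mismatches unless the consensus base is inside
their IUPAC set — a deliberately conservative conservation call.  Windows
containing any gap column are excluded outright: primers cannot span
indels.

`enumerateCandidates()` pairs windows whose inter-window core is shorter
than `maxCoreLen` (200 bp, ungapped, in every template) and whose minimum
pairwise core difference count reaches `minCoreDiffs`.  The spec of
"sufficient interspecific differences" is deliberately a tunable floor;
the default of 5 reflects the smallest interspecies difference observed in
the benchmark marker.  Note that for panels containing subspecies pairs
(1–3 differences) the floor must be lowered accordingly.

A subtlety worth documenting: a conserved window adjacent to further
conserved columns (a perfectly matched primer region next to an invariant
core boundary, say) legitimately *extends* under the mismatch-budget rule,
so the maximal window reported may be a column or two wider than the
primer actually designed.  The planted-marker recovery criterion used by
the test-suite therefore asks that a candidate's windows **contain** the
planted flanks and that the planted primer pair recovers the exact planted
core via `extractAmplicons()` — not that window coordinates match
byte-for-byte.  The synthetic generator keeps the outermost core columns
mutation-free so such extension never erodes planted differences.

## Primer evaluation

`gcContent()` uses fractional IUPAC weights; `nnTm()` is a
nearest-neighbor melting temperature

$$T_m = \frac{\Delta H}{\Delta S + R\,\ln(C/4)} - 273.15
        + 16.6\,\log_{10}[\mathrm{Na^+}]$$

with stacking terms summed over dinucleotide steps plus a helix-initiation
term.  Three published parameter tables are available
(`sugimoto1996`, `santalucia1998`, `breslauer1986`).  The default
`ThermoParams` were calibrated once against the benchmark primer pair's
nearest-neighbor values of 55.7 and 55.9 °C and then frozen: the
Sugimoto 1996 table with the classic salt correction solves both
simultaneously at 267 nM total oligo and 53.9 mM Na⁺ — within the normal
PCR range and close to the conventional 250 nM / 50 mM.  The
Breslauer table cannot reproduce the benchmark pair under any
concentration choice (it separates the two primers by almost 5 °C where
the benchmark gap is 0.2 °C), which is why it is not the default despite
being the table many older web calculators cite.  The nearest-neighbor
tables are reverse-complement symmetric, so `nnTm(s) == nnTm(revcomp(s))`
— a duplex has one melting temperature.

`findBindingSites()` scans the degapped plus strand for a primer in either
annealing sense (internally via `Biostrings::matchPattern`), and
classifies each mismatch by the base pair actually formed in the annealed
duplex: a forward primer pairs each base with the *complement* of the
plus-strand base, a reverse primer pairs with the plus-strand base
directly.  Classes are T·G (a thermodynamically tolerated wobble), A·C, or
other — the two non-canonical pairings that dominate tolerated
primer-template mismatches in practice.

## Taxonomic resolution

`distanceMatrix()` computes difference counts, uncorrected p-distances or
Kimura two-parameter distances, under complete deletion (columns gapped or
ambiguous in *any* sequence dropped panel-wide — the convention used for
published NJ trees of this kind) or pairwise deletion.  K2P saturation is
an error, never a silent clamp.  `njTree()` is a classical Saitou–Nei
agglomeration made fully deterministic: criterion ties are broken toward
the lexicographically smallest label pair, and negative branch lengths are
clamped to zero with the deficit moved to the sibling branch, preserving
the joined pair's path length (the behaviour of mainstream tree software).
`bootstrapSupports()` resamples alignment columns with replacement
(seed-controlled, 300 replicates by default) and scores each internal edge
by the percentage of replicate trees containing the same bipartition,
ignoring branch lengths.

`resolutionReport()` turns a difference-count matrix into the practical
question: *which taxon pairs can an identity-threshold assignment not
separate?*  With a 98.5% identity threshold over a 167 bp core, two
nucleotide differences are tolerated, so pairs at ≤ 2 differences are
flagged ambiguous by default.  On the benchmark-like panel this flags
exactly the closest subspecies pair (1 difference); at tolerance 3 all
three subspecies pairs (1/3/3 differences) are flagged — sequencing error
of that magnitude makes subspecies assignment unreliable even after
denoising, which is a real limitation of short-core markers.

## The read pipeline

`runPipeline()` chains six stages per sample, with every stage's
read count logged:

1. **tail truncation + merging** — each mate is truncated at its first
   base below Phred 20; the pair is merged over the best-matching proper
   ungapped overlap (every offset scored, ties to the longer overlap) and
   rejected if the best overlap is under 16 bp or carries more than 5
   conflicting positions.  Agreeing positions take `max(Q1, Q2)`;
   conflicts take the higher-quality base with quality `|Q1 − Q2|`.
2. **primer stripping** — the forward primer must sit at the 5′ end and
   the reverse complement of the reverse primer at the 3′ end, each within
   2 mismatches (sequencing errors in a primer region should not discard a
   read); the inter-primer core is kept.
3. **expected-error filtering** — a core is kept iff
   `sum(10^(-Q/10)) / length ≤ 1%` *and* length ≥ 120 bp.  The filter is a
   *rate*, not an absolute expected-error cap, and the boundary is
   inclusive: 150 bases at exactly Q20 (EE rate exactly 1%) pass.
4. **dereplication** — exact grouping, descending abundance, ties
   lexicographic; uniques seen fewer than 4 times (singletons through
   tripletons) are removed, as error reads dominate that abundance range.
5. **denoising** — greedy abundance-skew clustering: a unique merges into
   a centroid when `abund_u / abund_c ≤ 1 / 2^(alpha·d + 1)` with
   `alpha = 2` and `d` the Hamming/edit distance; otherwise it founds a
   new centroid.  Chimera detection is intentionally out of scope (a
   separate concern with its own literature).
6. **assignment** — each centroid is compared with every reference
   amplicon; equal-length pairs are compared ungapped, unequal lengths via
   end-gap-free global alignment with internal gaps counted in the
   denominator.  This reproduces the "2 differences over 167 bp ⇒ 98.80%
   ≥ 98.5%, 3 ⇒ 98.20% < 98.5%" arithmetic exactly for substitution-only
   error while still penalising indels.  Ties at the top identity are
   assigned only when every tied reference shares one taxon label;
   otherwise the centroid is counted unassigned-ambiguous rather than
   arbitrarily split — the subspecies-ambiguity situation above.

Any read surviving to the count table in a declared blank (no-template
control) marks the whole run as contaminated (`isContaminated()`, CLI exit
code 2): the acceptance convention for such experiments is that results
count only when all blanks are clean.

All thresholds live in one `pipelineConfig()` block; the defaults are the
values above.

## The simulators

`plantMarkerAlignment()` builds an aligned panel with the exact
architecture the scanner looks for: divergent background (default 20%
per-base divergence from a background consensus — enough that no spurious
conserved window survives 19 templates), conserved flanks (optionally a
given primer pair), and a core whose minimum pairwise difference count is
*exact*: template 1 carries the core consensus and every other template
receives its differences at globally disjoint positions, so the minimum is
attained by construction rather than by chance.  Designated "subspecies"
pairs replace this with a fixed small difference count, and chosen
templates can carry a single forward-window mismatch of a requested duplex
class.  Generators are pure functions of their arguments and the seed.

`simulateMockReads()` draws paired 150 bp reads (the common 2 × 150
benchtop format) from each template's amplification fragment
(forward primer + core + reverse-complemented reverse primer, 215 bp for
the benchmark marker, giving a ~85 bp overlap).  Qualities come from a
clipped normal (mean Q35, sd 3, clipped to [2, 40] — a typical current
benchtop profile) and each base is substituted with its Phred-implied
probability.  The error model is substitution-only: the downstream
identity arithmetic and the denoiser are substitution-centric, and indel
simulation would mostly exercise the alignment fallback.  PCR bias from
primer–template mismatches is a single per-mismatch efficiency multiplier
applied to the requested read count — a deliberate simplification of
cycle-resolved amplification, matching how such dropout is observed
(qualitatively, as under-representation of mismatched templates).
Optional contamination injects labelled stray reads, e.g. a 7-read spike
into a blank.

What the simulations do **not** emulate: real platform error profiles
(position- and motif-dependent), index hopping, amplification
stochasticity beyond the bias multiplier, chimeras, or reference databases
with missing/misidentified taxa.  Passing tests therefore demonstrate the
*algorithmic* correctness of the chain under its stated model, not field
performance.

## Numerical and design choices

* Coordinates are 1-based closed throughout, the R/Bioconductor
  convention.
* The gap character is `-` only; `.` is rejected, so one alignment dialect
  exists in the package.
* FASTQ is Phred+33 only; quality characters implying scores outside
  [0, 60] are rejected loudly rather than reinterpreted.
* Merging considers proper overlaps only (fragment at least as long as
  each read); read-through of short fragments into adapters is out of
  scope.
* The identity denominator excludes terminal end-gaps but includes
  internal gaps; equal-length comparisons bypass alignment entirely, which
  keeps the threshold boundary exact for substitution-only variants
  regardless of where the substitutions fall.
* One seed drives every stochastic step; stage-specific sub-seeds are
  derived deterministically, and generators restore the caller's RNG
  state.
* Problem sizes used by the test-suite and the acceptance script —
  19-template panels, 20-seed property sweeps, 300 oracle-checked merges,
  300 bootstrap replicates, mock samples of a few hundred reads — were
  chosen as the smallest sizes at which each property is meaningfully
  exercised.

## Known limitations

* Multiple sequence alignment construction is upstream: the scanner
  assumes a trustworthy alignment.
* No primer-dimer/hairpin screening, degenerate-primer optimisation, or
  multiplex-compatibility scoring; co-amplifying additional primer sets is
  configuration, not computation.
* Subspecies separated by ≤ 2 core differences cannot be reliably
  distinguished at a 98.5% identity threshold — `resolutionReport()`
  exists precisely to surface such pairs before a marker is adopted.
* The accession-derived distance statistics of a real reference panel can
  only be recomputed with the accessions themselves; the package's
  validation workflow is exercised on synthetic panels with planted,
  known-true architecture.
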