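---
title: "Models and methods behind ltrfate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ltrfate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltrfate)
```

# The scientific problem

LTR retrotransposons dominate the intergenic space of plant genomes. Each
element inserts with two identical long terminal repeats (LTRs) and a
5-bp-scale target-site duplication (TSD) of host sequence on both flanks.
From the moment of insertion the element starts to decay: unequal
homologous recombination (UR) between the two LTRs of one element, or
between elements, collapses it to a solo LTR; illegitimate recombination
(IR) nibbles away LTRs and internal sequence. The structural remnant an
element leaves behind therefore records both *when* it arrived (LTR-LTR
divergence) and *how* it was being removed (which parts survive, and
whether the TSD does). Around the elements, double-strand-break (DSB)
repair occasionally captures gene-bearing fragments, moving genes to new
loci and leaving characteristic sequence footprints.

`ltrfate` implements this quantitative machinery as a tested pipeline:

* a synthetic-region simulator with planted ground truth (`sim_config()`,
  `simulate_region()`, `emit_truth()`),
* a structural annotator (`find_ltr_pairs()`, `match_library()`,
  `detect_tsd()`, `assemble_elements()`),
* a nine-category fate classifier with mechanism inference
  (`classify_fates()`, `mechanism_of()`, `region_tendency()`),
* Kimura two-parameter insertion dating (`k2p_distance()`,
  `insertion_time()`),
* region profiling (`composition_table()`, `gene_density()`,
  `chromatin_indicator()`),
* DSB-repair footprint scanners (`scan_tsd_capture()`,
  `scan_shared_border()`, `scan_helitron_capture()`,
  `scan_tandem_flank()`, `flag_retrocopy()`),
* and a one-call pipeline (`run_pipeline()`).

# The mutation model and insertion dating

Sequences evolve under the Kimura two-parameter (K2P) process,
parameterised by the overall substitution rate `r` (substitutions per site
per year; transitions at rate $\alpha$, each transversion at rate $\beta$,
$r = \alpha + 2\beta$) and the transition/transversion rate ratio
$\kappa = \alpha/\beta$. Defaults are `r = 1.3e-8`, the accepted rate for
grass repeat DNA, and `kappa = 2`.

Dating inverts the model. For an intact element the two LTRs are aligned
(`align_ltr_pair()`, global alignment, match +1, mismatch −1, gap opening
−5, gap extension −1 per position) and, over ungapped unambiguous columns,
the transition proportion $P$ and transversion proportion $Q$ give

$$K = -\tfrac12 \log(1 - 2P - Q) - \tfrac14 \log(1 - 2Q), \qquad
T = \frac{K}{2r}.$$

The closed form is used instead of a numerical maximum-likelihood fit: it
is exact for the model it names, dependency-free, and on indel-free LTR
pairs the two approaches differ by far less than the stochastic noise of a
1-kb LTR. The estimator is undefined (saturation error) when
$1-2P-Q \le 0$ or $1-2Q \le 0$. Gap and ambiguous-base columns are
excluded column-wise; `sites_used` is always reported. Solo and truncated
elements are not dated — they have only one LTR.

# The simulator: what it emulates, and what it does not

`simulate_region()` builds a random background (length and G+C
configurable; defaults 100 kb, 0.43, matching a gene-poor grass region)
and splices in feature blocks. An element of age $a$ is constructed as:
family consensus, mutated for time $a$ (the element lineage's drift since
the family consensus), then each LTR copy and the internal region mutated
*independently* for a further $a$, so the expected pairwise LTR-LTR
divergence is the K2P expectation at path length $2a$
(`expected_ltr_divergence()`). TSDs default to 5 bp — the canonical value
for LTR retrotransposons; footprint TSDs are configurable.

Each of the nine fates applies a structural transformation to the intact
template: solos keep one LTR (with both TSD copies, or with one copy
randomised); the truncated solo keeps a configurable LTR fraction (default
0.4); the 3'/5'-LTR-deleted fates drop the named LTR; the partially
deleted fate removes the central 70% of the internal region, leaving a
2–10 bp microhomology at the junction; the recombination complex splices
the 5' half of one family onto the 3' half of another.

Design choices worth knowing:

* **No indels inside repeats.** The substitution-only model keeps the
  dating oracle exact and lets both annotation alignment stages be
  ungapped. This is a documented contract: on real, indel-rich data the
  annotator's ungapped extension will fragment old elements.
* **Coordinates are 1-based inclusive** throughout, the R/Bioconductor
  and GFF3 convention.
* **Seeding.** One master seed; every feature draws from its own derived
  stream, so adding a feature never perturbs the sequence of an earlier
  one, and identical configurations are byte-identical.
* **Nesting** inserts a guest element at a uniformly chosen position
  inside its host's internal region and records host/guest in the truth
  table, so masking precedence is testable.
* **Genes** are annotated over background intervals with a fixed
  3-exon/2-intron structure; the simulator makes no attempt at realistic
  gene grammar (no promoters, no splice signals). Retrocopies are built
  by concatenating a planted gene's exon sequences.

Passing the planted-truth suites therefore demonstrates correctness of
the *algorithms* under the stated model — substitution-only divergence,
exact repeat boundaries, co-oriented LTRs — not performance on real BAC
sequence, where indels, segmental duplications and low-complexity DNA add
failure modes this simulator deliberately excludes.

# Structural annotation

`find_ltr_pairs()` seeds the sequence against itself with exact k-mers
(default `seed_k = 20`), chains co-diagonal seeds, and extends each chain
without gaps under an X-drop rule, reporting the maximum-scoring
endpoints. Bounds default to `min_ltr = 100`, `max_ltr = 3000`,
`min_span = 1000`, `max_span = 18000`, `min_identity = 0.8` —
literature-typical LTR geometry. The search is forward-strand only: the
two LTRs of one element are always co-oriented. `match_library()` runs
the same engine between each library consensus and both strands of the
sequence, reporting identity and consensus coverage per hit.

A subtlety discovered during development drives the conflict-resolution
design in `assemble_elements()`. In element-dense regions the
self-comparison also pairs LTRs of *different* same-family elements
(expected divergence $4ra$ instead of $2ra$), and two same-family solo
LTRs form a perfectly valid structural pair. Resolving overlaps by outer
span alone merges neighbours. The assembler therefore resolves jointly
with the homology evidence:

1. a pair must have internal-consensus coverage *of its own LTR family*
   over at least 20% of its inter-LTR interval (two solos enclosing an
   unrelated element fail this);
2. a pair spanning more than 1.3× its family's reconstructed full length
   is rejected unless a complete candidate pair nests fully inside (true
   hosts keep their guests, cross-element pairs are dropped);
3. a pair whose inter-LTR interval encloses an unexplained lone LTR copy
   is rejected;
4. remaining conflicts rank by descending identity (the true pair is
   always the closest), with exact ties — identical young copies — going
   to the shortest span.

Boundaries of accepted pairs are snapped to near-full-length LTR
consensus hits where available: extension against the library is bounded
by the consensus ends and is therefore base-exact, while self-comparison
extension can wander a few bases into the flanks. Library hits not
claimed by a pair are clustered by proximity (default gap 500 bp) into
solo/truncated/partial candidates.

`detect_tsd()` finds the longest exact duplicated motif with one copy
ending within `window` bp of the element's left boundary and the other
starting within `window` bp of its right boundary (default window 2,
lengths 4–20). The window is symmetric about each boundary so that a
1–2 bp annotation error does not mask a real TSD; ties break by boundary
proximity, then leftmost. The implementation is checked against a
brute-force all-substring-pairs oracle in the tests.

# Fate classification and mechanisms

`classify_element()` runs a decision cascade over an element's
sub-features: two full-length LTRs (coverage ≥ 0.8 of the consensus) with
internal coverage ≥ 0.5 give an intact element, discriminated into
with/without TSD; internal coverage below 0.5 with both termini gives
partially deleted; a lone full-length LTR gives a solo (by TSD); a lone
partial LTR a truncated solo; one LTR plus internal gives 3'- or
5'-LTR-deleted by position and strand; internal evidence from two
families gives a recombination complex. The 0.8/0.5/500 bp thresholds are
this package's own calibration, exposed in `fate_params()`.

Two TSD-evidence choices were calibrated on null sequence (random flanks,
400 trials): a 4-mer motif recurs by chance in 8.2% of flank pairs at
window 2 — far too often to count as evidence — while a ≥5-mer at window
2 false-alarms at 1.5% and a ≥4-mer at window 0 at 0.25%. The classifier
therefore demands TSDs of ≥ 5 bp (`fate_params(tsd_min = 5)`) and
tightens the window to 0 whenever all the element's LTR evidence is at
100% identity, where boundaries are exact. The residual With/WithoutTSD
confusion is about 1–2% of without-TSD elements; this is an inherent
limit of exact-motif TSD evidence, not an implementation artefact.

`mechanism_of()` is a fixed total mapping from category to removal
mechanism: solo with TSD → UR (intra-element); solo without TSD and
recombination complex → UR (inter-element); intact without TSD → UR
(intra); truncated solo → UR (inter) or UR (intra) combined with IR; the
three deletion categories → IR; intact → none.

`region_tendency()` reports a base-pair balance: `bp_inserted` is the
LTR-derived sequence present; `bp_removed_inferred` reconstructs, for
every element, the family's full length minus the observed length
(floored at zero). The region is expanding (E) when insertion outweighs
inferred removal, contracting (C) otherwise. No count-based rule is
offered: published per-region tendency calls do not follow any
recoverable function of the category counts, so the package states its
bp-balance definition explicitly and reports both totals so users may
apply their own rule.

# Composition tables and the chromatin indicator

`composition_table()` attributes every masked base to the innermost
(shortest enclosing, i.e. most recently inserted) element, so nested
insertions never double-count and class totals are conserved exactly at
the bp level. Intact-element rows are informational subsets and are never
added into the class totals; percent values are rounded to two decimals
only at the report layer. Class I totals include an explicit
unclassified-RNA residue rather than hiding mass that belongs to no named
subfamily. The package ships the published per-family percentages of the
Ghd7 orthologous regions (`ghd7_reference_composition()`); summing the
component rows reproduces the published class totals exactly, which the
acceptance suite checks.

`chromatin_indicator()` is purely descriptive: gene-poor (default ≥ 20
kb/gene) plus Gypsy-dominated (Gypsy:Copia percent ratio ≥ 2) is labelled
heterochromatin-like; the reversed pattern euchromatin-like; anything
else indeterminate. Gypsy elements preferentially insert into
heterochromatin and Copia into euchromatin, which is what makes the ratio
informative — but the label makes no cytological claim.

# Footprint scanners

All motif evidence is exact-match — a conservative reading of "identical"
sequence signatures; mismatch-tolerant modes are out of scope. Evidence
strings always occur verbatim at their reported coordinates (a tested
invariant). Defaults: pattern A demands a TSD of ≥ 8 bp embracing the
TE-plus-gene block (ordinary 4–6 bp element TSDs must not trigger it)
within a TE-gene gap of ≤ 2 kb; pattern B a shared border of ≥ 6 bp
anchored at the gene boundary on the same side of donor and acceptor;
pattern D tandem arrays within 500 bp on both sides, with 1–2 bp boundary
slop tolerated because detected array edges can drift by chance
agreement; pattern E flags a 1-exon gene whose length is within 10% of a
multi-exon paralog's summed exon length. Pattern B takes user-supplied
donor candidates: genome-wide donor discovery is not re-implemented.
`find_tandem_arrays()` detects arrays by period-k self-shift agreement
and reduces overlapping detections to the best period per locus (longest
array, ties to the smallest period); it is validated against a naive
per-position oracle.

# Problem sizes and numerical choices

The test and acceptance suites run entirely on simulated data sized for a
single CPU: nine-fate recovery uses seven 27-element regions (~21
elements per fate, ages 0.5–2 My, LTR-LTR divergence up to ~5%) plus two
zero-divergence regions; dating uses 50 elements per age in {0.5, 1, 2}
My with 1 kb LTRs; footprint sensitivity uses 50 planted footprints per
pattern; null scans use ~100 kb backgrounds. Measured behaviour at these
conditions: 99.5% fate recovery at ≤ 5% divergence, 100% at zero
divergence, mean dating error well within 10%, and zero false LTR pairs
on null background.

Numerical details: interval arithmetic is integer; identity is exact
match count over extended length; X-drop extension reports the
argmax-scoring endpoint (ties to the shorter extension); alignment
gap costs follow the convention that a gap of length $L$ costs
$\text{opening} + L \cdot \text{extension}$; degenerate inputs (empty
sequences, zero-length backgrounds, elements without LTR evidence,
saturated distances) raise errors rather than returning silent defaults.

# Known limitations

* Ungapped annotation alignment: old, indel-rich elements on real data
  will fragment; the simulator does not model indels, so the suites do
  not measure this.
* No PBS/PPT or terminal-motif (TG…CA) detection; no profile/HMM search.
* TSD evidence is exact-match; a mismatch-tolerant TSD mode is deferred.
* The tendency rule is a bp balance, not a reproduction of published
  per-region tendency calls.
* Pattern B footprints require donor candidates from the user.
* The chromatin indicator is descriptive only.
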