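---
title: "Methods: recurrent PPARγ mutation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recurrent PPARγ mutation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the methods it
implements: the models and conventions, the tunable parameters and
their defaults, what the synthetic-data generators do and do not
emulate, and the numerical choices made where a convention had to be
fixed.

## Coordinates, isoforms and recurrence

All positions are 1-based inclusive protein residue indices, matching
the conventional mutation notation (`T475M` = threonine 475 to
methionine). PPARγ has two isoforms: γ2 carries 28 extra N-terminal
residues relative to the ubiquitous γ1, and mutations are analyzed in
the γ2 frame because two observed changes (E3K, D7N) exist only there.
`harmonizeIsoform()` applies a signed offset between frames; positions
that would fall below the target frame's first residue are returned as
explicit `isoform_specific` unmappable markers. They are never clamped
or dropped — silently renumbering a γ2-only mutation into the γ1 frame
would fabricate a nonexistent residue.

A protein change is *recurrent* when the same (gene, change) is
observed at least `min_count` times. The default `min_count = 2`
follows the field's usual reading of "recurrent" (seen in at least two
samples); whether the observations must come from distinct cohorts is
not standardized, so the package counts observations and leaves the
threshold configurable. Cohort observations are deduplicated per
(sample, gene, change); external-database occurrences are counted per
reported entry because database records carry no stable sample
identity. With `pool_external = TRUE`, cohort and database occurrences
are pooled before thresholding — this is the step that promotes cohort
singletons with independent database support (E3K, M280I) to recurrent
status, and `recurrence_basis` records whether a call needed pooling.

Domain annotation uses configurable spans. The ligand-binding domain
span (231–505, γ2 numbering) matches the standard LBD construct
boundaries; the A/B (1–135) and DNA-binding domain (136–206) bounds
follow standard nuclear-receptor annotation and can be overridden via
`readDomainConfig()` — they are deliberately config, not constants,
because only the LBD span has a hard anchor.

## Exact association tests

`fisherExact2x2()` is a self-contained two-sided Fisher exact test.
With all margins fixed, the admissible 2×2 tables form a
one-parameter family indexed by the top-left count; each has the
hypergeometric point probability

$$P(k) = \frac{\binom{m}{k}\binom{n_2}{K-k}}{\binom{N}{K}}.$$

The two-sided p-value is the sum of $P(k)$ over all tables no more
probable than the observed one (the point-probability method, the
convention of standard implementations). Probabilities are compared
with a relative tolerance of $10^{-7}$ so floating-point noise cannot
split exact ties. Degenerate margins (an all-zero row or column) are
defined as p = 1 with a flag. The odds ratio is the raw cross-product
$ad/bc$; zero cells yield 0 or `Inf` with a `zero_cell` flag rather
than a Haldane continuity correction, because the analyses this
supports report raw Fisher results. The test suite checks the
implementation against an independent factorial-ratio enumeration
oracle on *every* 2×2 table with total $n \le 40$, against
`stats::fisher.test` on random tables, and for transposition symmetry.

A deliberate calibration point: the exact conditional test is
*conservative* when margins are small. At the frequencies typical of
this analysis (≈14 altered of 359), the attained size at nominal
α = 0.05 is about 0.026, purely from the discreteness of the
hypergeometric support. The type-I-error calibration experiment in the
tests and acceptance script therefore uses null cohorts with larger
margins (n = 500, subgroup fraction 0.45, alteration rate 0.3;
analytic attained size 0.0496), where discreteness is negligible and
the empirical rejection rate genuinely measures calibration rather
than discreteness.

Percentages are rounded half-up to one decimal, computed on the exact
integer rational $1000a/n$ so no binary-representation artifact can
flip a digit. Published frequency summaries round inconsistently in a
few places (e.g. 6/338 printed as 1.7%); the package documents and
applies one fixed rule instead of reproducing inconsistencies.

## Activation score

The PPARγ activation score of a sample is the mean of the centered
log expression of the signature genes. Centering is per gene across
samples; the default is the gene mean (making scores sum to exactly
zero over samples, a property the tests assert to $10^{-9}$ relative),
with the gene median as a recorded alternative. The score is invariant
to adding any per-gene constant, so platform-wide gene offsets cancel.
Expression is assumed already log-scale; no normalization is applied.

Signature refinement contrasts the top and bottom
$\lceil q \cdot n \rceil$ samples ranked by the anchor gene's
expression (*PPARG*; ties broken by sample id, stable), with
$q = 0.25$ by default. Each seed gene is tested one-sided for higher
expression in the anchor-high bin. The published description says
"significantly more expressed" without naming a test, so the default
is the distribution-robust Wilcoxon rank-sum with Benjamini–Hochberg
FDR at α = 0.05, with Welch's t selectable for sensitivity analysis;
both the choice and the parameters are recorded in the returned
`SignatureDefinition`. The activation-high threshold is likewise
unspecified upstream, so the default rule is score > 0, with
top-quartile and fixed-cutoff rules available, and the rule is recorded
on the classification.

The literal 77-gene signature of the original analysis is not
reproducible here: it requires the TCGA expression matrix and the prior
148-gene seed list, neither of which the package can ship. What the
package guarantees instead, by simulation, is that the refinement
pipeline recovers planted signatures (≥95% sensitivity, ≤5% FDR at a
2-SD effect with n = 200, averaged over 20 seeds) and degrades
monotonically as the effect vanishes.

## Structure mapping

`StructureModel` stores heavy atoms only; hydrogens and waters are
removed at parse time, alternate locations resolve to the
highest-occupancy conformer (ties to altloc A), and HETATM ligand atoms
are retained behind a `het` flag, excluded from residue distance
queries. Interface membership uses a 5.0 Å minimum heavy-atom distance
cutoff and intra-chain contacts 4.5 Å with sequence separation ≥ 3 —
standard structural-biology conventions, made explicit as parameters
because the qualitative claims they support ("co-localized at the
dimer interface", "interacts with Y505") do not state a criterion.
All distance code is checked against brute-force all-pairs oracles,
for rigid-body invariance (random seeded rotations/translations,
$10^{-6}$ Å), and for monotonicity of interface sets in the cutoff.
Deposited crystal structures are optional integration inputs; the
shipped tests run entirely on generated toy structures.

## Synthetic-data generators

`simulateCohort()` emulates a tumor series: stages assigned by exact
fractions, a subgroup (luminal-like) of fixed fraction, hotspot changes
planted at exactly their target counts plus binomial background
singletons, and the alteration–subgroup association induced by drawing
the number of altered samples inside the subgroup from **Fisher's
noncentral hypergeometric distribution** at the requested odds ratio —
the exact conditional model of the 2×2 test, so odds ratio 1 gives
log-odds centered at zero by construction. The equivalent two-rate
Bernoulli parameterization (rates solved in closed form from overall
rate, subgroup fraction and odds ratio via the quadratic in the rest
rate) is exposed and property-tested. Defaults mirror the study's
magnitudes: 359 tumors, 55/45 NMIBC/MIBC, ~4% mutation rate, 7%
amplification, 45% subgroup, odds ratio 8.

`simulateExpression()` draws i.i.d. Gaussian log expression
(noise SD 1), adds `effect_size`·SD (default 2) to signature genes in
activation-high samples (default 25% of samples), and couples an
anchor gene to the high state at +3 SD — strong coupling chosen
because receptor expression is the defining feature of the
activation-high phenotype being emulated. What these generators do
*not* emulate: mutational signatures, copy-number segment structure,
count-based RNA-seq noise, gene–gene correlation, batch effects.
Passing tests therefore demonstrate the correctness and calibration of
the *methods*, not performance on real tumor data.

`bladderCohortFixture()` is a fully synthetic, deterministic dataset
whose summary structure matches the published landscape (14/359 and
14/455 mutated samples, 21 unique changes, 6 cohort-recurrent, 8 after
pooling, stage coverage of the recurrent changes); individual sample
assignments and the 13 singleton labels beyond D7N are invented.

## Determinism and problem sizes

Every generator takes an explicit seed; the pipeline derives all
randomness from one master seed and stamps every output with a hash of
the resolved configuration (output location excluded), so identical
configs give byte-identical outputs anywhere. The shipped test and
acceptance workloads use deliberately desk-scale sizes — 1000 null
replicates for test calibration, 20 seeds for signature recovery,
toy structures of ≤ a few hundred atoms, the exhaustive exact-test
sweep capped at table totals of 40 — sizes at which the checked
properties are already sharp while the whole suite runs in minutes.

## Known limitations

- Protein-level only: no DNA variant calling, VCF ingestion or HGVS
  cDNA parsing; the unit of analysis is the protein change.
- External occurrences arrive as user-supplied tables; there is no
  live COSMIC/cBioPortal querying.
- The RXRα hotspot appears in the literature under two numbering
  frames (S242F/Y vs S427F/Y); the package carries both labels only if
  the user supplies an explicit `IsoformMap` — no silent
  reconciliation.
- No multiple-testing correction across the handful of association
  tests (raw exact p-values are reported), and no logistic modeling of
  enrichment.
- Structure queries are geometric; no dynamics, energetics or
  homology modeling.
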