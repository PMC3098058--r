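---
title: "The exon-definition splicing model in splicedef"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The exon-definition splicing model in splicedef}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicedef)
```

## The problem

Human introns are littered with decoy splice signals: intervals flanked by
acceptor-like (AG) and donor-like (GT, rarely GC) sequence that the
spliceosome never uses, and that outnumber authentic internal exons by an
order of magnitude. Predicting which candidate exons are real — and how a
mutation or SNP shifts that choice toward a cryptic site or a cryptic exon —
requires evidence beyond the splice sites themselves: the cis-acting
enhancers and silencers around each site, the compatibility of the two sites
across the exon, and the exon's length. `splicedef` implements an
exon-definition model that combines these evidence sources into a single
additive log-odds (LOD) score per candidate exon, and a variant engine that
re-scores a sequence after an edit and classifies every change.

## Bayesian oligonucleotide splice-site sensors

Each sensor reads a fixed window across the intron boundary — 3 exonic + 6
intronic nt for donors (9-mers), 18 intronic + 3 exonic nt for acceptors
(21-mers, covering the polypyrimidine tract) — and keeps two count tables:
how often each oligo was seen at true sites and at decoy splice-like
signals. With the prior $P(SS)$ and the likelihoods $P(oligo \mid SS)$,
$P(oligo \mid \neg SS)$ all estimated from the pooled counts, Bayes' rule
collapses to

$$P(SS \mid oligo) = \frac{t}{t + d},$$

where $t$ and $d$ are the oligo's true and decoy counts. The same
architecture serves all three sensors — canonical GT donors, canonical
acceptors, and the non-canonical 5'GC donor, which is handled by its own
sensor because its training material is scarce (GC donors flank under 1% of
human exons). The package ships the GC sensor's 40-oligo count table
(`gc_donor_count_table()`): the decoy counts there were amplified by the
ratio of corpus-confirmed GC donors to annotated ones (19059/1320
≈ 14.44) to compensate for decoys having been collected only from the
well-annotated genomes; `train_oligo_model()` exposes the same
`amplification_factor` for user-trained sensors, rounding scaled counts
half-up with a floor of one.

Three choices matter downstream:

* **Unseen oligos** default to posterior 0 (an optional additive
  pseudocount regularizes both counts). Raw counts are the honest choice
  for reproducing the shipped table; a pseudocount of ~0.5 is useful when
  a sensor must score decoy-like signals, e.g. for pseudoexon extraction.
* **Normalization.** Raw posteriors are not comparable across sensors, so
  each sensor carries a monotone piecewise-linear calibration mapping
  posterior to a 0–1 normalized score. The GC sensor's calibration
  interpolates the shipped (posterior, normalized) anchor pairs — using the
  exact recomputed posteriors as x-values, since the printed 3-decimal ones
  tie — and therefore reproduces the published normalized scores exactly at
  the anchors. Trained sensors self-calibrate with the percentile of each
  posterior among their own true sites.
* **Discrete strength.** Scores are binned into classes 1..5 by
  equal-probability quantiles of the true-site normalized-score
  distribution (`strength_breaks()`). The bin count is a parameter: the
  length model conditions on five classes, but nothing in the architecture
  fixes that number, so profile conditioning may use three bins where data
  are thin.

`scan_splice_sites()` applies the sensors along the forward strand (input is
the pre-mRNA sense sequence; reverse-complement upstream if needed), firing
only where the anchor dinucleotide sits at the intron boundary. Positions
are 0-based internally — a donor call marks the first intronic nucleotide,
an acceptor call the first exonic nucleotide after the intron — and 1-based
inclusive in reports.

## Positional LOD profiles for cis-acting elements

For each enhancer/silencer motif, `build_lod_profile()` compares the
frequency of exact motif starts at every offset $i$ relative to a splice
signal in true-site flank contexts against decoy-site contexts:

$$LOD(i) = \log_2 \frac{(c_t(i) + pc)/N_t}{(c_d(i) + pc)/N_d},$$

pseudocount-smoothed (default 0.5) and averaged over a centered window
(default 11 nt; the profile should vary on the scale of element spacing,
not single positions). Offsets with no defined ratio when the pseudocount
is 0 are dropped rather than fabricated. The motif catalog is deliberately
configurable — the algorithm, not any fixed catalog, is what the package
provides — and a small built-in set (`demo_element_motifs()`) covers the
poly-G family of intronic splicing enhancers (GGGGTGGG, CGGGGGCG) plus
AAGGTAA, the exonic core of a strong canonical donor, which behaves as a
*depleted* competitor signal near true boundaries.

Overlapping element hits are resolved per sign class
(`resolve_overlaps()`): enhancers compete with enhancers and silencers with
silencers, greedily keeping the largest |LOD| (ties: leftmost start, then
motif) and discarding whatever overlaps a kept hit, so an enhancer and a
silencer that overlap each other — antipodal annotations of the same
sequence — both survive. The rule also arbitrates between shorter and
longer variants of a motif sharing a prefix without special-casing. The
test suite checks the greedy result against an exhaustive-subset oracle on
randomized instances.

## The exon-length model

Steric constraints couple splice-site strength and exon length: stronger
sites tolerate tighter packing of the splicing machinery, so exons between
strong sites run shorter. `fit_length_model()` captures this with one Beta
mixture per (acceptor strength, donor strength) cell, fit by EM on lengths
scaled by `max_len` (default 400 nt, beyond which internal exons are rare).
The length evidence for a candidate exon is

$$LOD_{len} = \log_2 \frac{PDF_{mix}(size/max\_len)}{PDF_{uniform}},$$

with the uniform density (the pseudoexon null) equal to 1 on the scaled
support.

Numerical choices: initialization is method-of-moments on k quantile
slices; the M-step maximizes each component's weighted Beta log-likelihood
numerically (L-BFGS-B on log-parameters) and keeps the previous parameters
whenever the optimizer fails to improve its objective, which preserves the
monotone-likelihood guarantee of EM (asserted by the tests); convergence is
a relative improvement below 1e-6, capped at 500 iterations; components
whose weight collapses below 1e-6 are pruned with a warning; identical-data
input is an error, not a silent fit. Grid cells with fewer than 50
observations borrow the Manhattan-nearest populated cell's fit — 5×5 grids
are inevitably sparse at desk scale — and a corpus too small for any cell
falls back to a pooled fit, then to the uniform law, with a warning.

## The combined exon score

`score_exon()` adds five terms, and nothing else:

$$LOD_{exon} = LOD_{3'SS} + LOD_{5'SS} + LOD_{len} + LOD_{elements} + LOD_{competitors}$$

The two sensor terms are $\log_2(p/(1-p))$ of the site posteriors (clamped
at ±30 bits for degenerate posteriors). The element term is the sum over
the overlap-resolved hits. The competitor term penalizes strong same-side
signals near or inside the exon — the observation motivating exon-level
scoring is that a site flanked by strong competitors is unlikely to commit
with any one of them. No published formula exists for this term, so the
package uses a documented surrogate: every site with posterior above 0.5
within the exon or within 50 nt of either boundary contributes minus 0.5
times its own positive LOD. All three knobs (`competitor_min_posterior`,
`competitor_vicinity`, `competitor_scale`) are exposed and should be treated
as calibration parameters, not as settled constants.

Additivity is exact (tested at 1e-9): removing one element hit changes the
total by exactly that hit's LOD. The normalized exon score is the total
LOD's percentile under the empirical distribution of true-exon totals from
training, with a separate reference distribution for GC-donor exons (their
sensor scale differs); without a calibration the package falls back to a
base-2 logistic squash.

`scan_sequence()` composes the pipeline: sensors → all (acceptor, donor)
pairs between 6 and 399 nt apart, boundary to boundary → element and
competitor attachment → scoring. Every candidate is retained
programmatically; the `report_threshold` (default 0.5 on the normalized
score) only controls reporting, because the useful operating point traces a
sensitivity/specificity curve rather than a single cutoff
(`threshold_sweep()`). Overlapping predictions are all reported — the
method scores isoforms and deliberately has no non-overlap selection pass,
and no reading-frame logic: it is built to work where protein-coding
signal is absent or misleading.

For training-time decoy collection, `extract_pseudoexons()` implements the
standard filters: sites only in the intron interior (first and last 150 nt
excluded, to avoid exon-proximal element bias), acceptor+donor posterior
sum above 0.05, length in (5, 400), 205-nt flanks available on both sides,
and exact-duplicate contexts discarded.

## Variant effects and the event taxonomy

`apply_variant()` validates the stated reference allele, applies SNVs,
deletions, insertions and duplications, and returns a monotone partial
bijection between reference and alternate coordinates (undefined inside
deleted or inserted spans). Intron-relative notation (IVS2+2delC,
IVS27+3_6dup(GGGT), IVS9+1G>A) is resolved against an exon annotation by
`parse_ivs_variant()`; without an annotation only absolute positions are
accepted.

`classify_events()` aligns the reference and alternate scans through the
coordinate map — an exon persists when both mapped boundaries match; a
boundary inside a deleted span is gone by definition — and assigns each
difference exactly one of seven classes, with precedence annotated exon
(both boundaries equal an annotated exon) over shared splice site (exactly
one boundary annotated) over generic:

1. annotated exon disappears
2. annotated exon changes score
3. exon sharing a SS with an annotated exon changes score
4. exon sharing a SS with an annotated exon disappears
5. new cryptic exon created sharing a SS with an annotated exon
6. exon disappears
7. new cryptic exon created

Score change is the *relative* change of the normalized exon score and must
exceed 2% — the scale of change reported to shift inclusion of an exon —
with both the measure and the threshold exposed
(`score_change_threshold`). Two taxonomy decisions were genuinely open and
are resolved as follows: a score change on an exon with no annotated
boundary has no class and is dropped (the taxonomy has no row for it), and
an alternate-only exon matching both annotated boundaries is classed with
row 5 (there is no "annotated exon is created" row). The loss/creation
classes are symmetric under swapping reference and alternate.

For benchmark-style evaluation, a predicted variant effect is *correct*
(`score_aberrant_case()`) when an activation event (a created exon, or a
persisting exon whose score rises) carries exactly the annotated aberrant
boundaries — both of them, for cryptic-exon cases — and, for cryptic-site
cases, a loss or weakening event carries the original annotated exon.
Boundary matching is exact to the nucleotide; a slack parameter exists on
`compute_sn_sp()` for exploratory use only. Sensitivity and specificity
over exon boundaries follow $Sn = TE/AE$, $Sp = TE/PE$, with 0/0 reported
as undefined rather than 0.

## The synthetic corpus: what it emulates, and what it does not

`generate_corpus()` provides ground truth with no external downloads. It
emulates the *structure* of a splicing training corpus: genes as
alternating introns (800–1200 nt, long enough to carry 205-nt pseudoexon
flanks inside the 150-nt-trimmed interior) and internal exons; splice sites
emitted from consensus tables whose per-base consensus probability rises
with the intended strength class (0.6 to 1.0 across classes 1..5, so class
5 is the exact consensus); exon lengths from a Beta law whose second shape
parameter grows with the summed flanking strengths, making strong-strong
exons shorter; GC donors at 1% of true donors by default; a poly-G
enhancer planted 15–60 nt into the intron downstream of 10% of true donors
versus 1% of planted decoy donors; and two decoy signals per intron
emitted from the weakest consensus class. Generation is a pure function of
(spec, seed), tested byte-for-byte.

Default problem sizes — 200 genes × 2 exons for the end-to-end recall
study, 500 genes × 4 exons for the binomial check of the GC fraction, 5000
contexts for the label-shuffle null of the profiles, 12 paired cases for
the variant-pipeline null — were chosen as the smallest sizes at which the
checked statistics are stable, and are stated in the tests that use them.

What the generator does **not** emulate bounds what green tests can show.
Real splice sites vary along a low-dimensional consensus gradient here,
against a uniform background with no dinucleotide composition, no branch
point, no 3-periodic coding bias, and no phylogenetic structure. Because
the sensors are oligo count tables, a weak synthetic site whose oligo is
unique in the corpus still scores posterior 1 — on synthetic data most true
sites saturate the top strength class, so the strength axis of the length
model is exercised mainly through generator truth, not through
sensor-assigned classes. Variant test cases therefore use deterministic
consensus sites (strength class 5), where sensor scores are graded by
true/decoy collisions as intended. Passing tests demonstrate the
correctness of the machinery — count arithmetic, score composition, event
classification, coordinate mapping — not field accuracy on genomic
sequence, which depends on training corpora this package does not ship.

## Known limitations

* The oligo-table sensor does not generalize across unseen oligos; real
  deployments need either large training corpora or a pseudocount, and the
  shipped GC table covers only the 40 top-scoring 9-mers.
* The competitor term is a surrogate with tunable scale; it is the least
  constrained part of the score.
* Forward strand only; terminal (first/last) exons are out of scope, as is
  isoform chaining across exons.
* IVS resolution requires a well-ordered exon annotation; overlapping or
  unsorted annotations are the caller's responsibility.
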