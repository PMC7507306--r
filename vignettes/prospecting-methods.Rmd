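---
title: "Methods: from rubisco sequences to carboxylation kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from rubisco sequences to carboxylation kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rubiprospect)
```

`rubiprospect` chains two rather different kinds of computation: a
deterministic sequence-processing pipeline (curation, clustering, form
assignment, codon design) and statistical estimation of enzyme kinetic
parameters from two assay formats. This vignette documents the models
and assumptions behind each stage, the parameters a user may want to
touch, the numerical choices we made where the design was open, and
what the synthetic-data generators do and do not emulate.

## Sequence curation

Candidate protein records pass a funnel of four filters applied in a
fixed order — length, ambiguity, reference coverage, deduplication — so
that each removed record is attributed to exactly one stage. The order
is a design choice made purely for deterministic bookkeeping: the
retained set is identical under any order, and a property test asserts
both idempotence and order-independence.

* **Length** keeps sequences strictly inside the open interval
  (300, 700) residues. The bounds are exclusive: a 300- or 700-residue
  sequence is removed. This targets truncated fragments on one side
  and fusions/concatenations on the other.
* **Ambiguity** removes any sequence containing a character outside
  the 20 canonical amino acids. We take the strictest reading — B, J,
  Z, X, U, O, `*` and `-` all disqualify — because downstream scoring
  matrices and codon design assume canonical residues. The alphabet is
  configurable in `curation_config()`.
* **Coverage** aligns each candidate locally against a single bait
  sequence (Smith–Waterman semantics, BLOSUM62, affine gap cost
  11 + L; protein-BLAST-like defaults) and requires the aligned span
  to cover at least 50 % of the *bait*. The denominator is a genuine
  open choice — coverage of the query would be the other reading — and
  we chose the bait because the filter's purpose is "does this
  candidate span the reference enzyme", not "is this candidate mostly
  alignable". Alignment is delegated to `Biostrings::pairwiseAlignment`;
  a brute-force dynamic-programming oracle in the test suite pins the
  expected scores on short strings.
* **Deduplication** collapses records with byte-identical sequences
  (after uppercase normalization), keeping the first-seen id and
  recording the rest as synonyms. Near-duplicate collapse at a
  threshold is deliberately *not* done here — that is the clustering
  stage's job.

## Identity clustering and representatives

`greedy_cluster()` is a UCLUST-style greedy pass: records are visited
in length-descending order (ties broken by id in the C locale, so the
ordering is platform-independent), each record joins the first existing
centroid whose global identity meets the threshold, otherwise it founds
a new cluster. Two invariants follow by construction and are asserted
post hoc in tests: members are ≥ T to their centroid, and centroids are
mutually < T in creation order.

Percent identity is matching columns over alignment columns of the
optimal global alignment (BLOSUM62, gap open 10 / extend 0.5), with
terminal gap columns excluded from the denominator. No published
definition is canonical here — tools differ in whether internal gaps
and end gaps count — so the definition is centralized in
`global_identity()` and a matches-over-shorter-length alternative is
available via its `denominator` argument. For the regimes the pipeline
uses (70 % and 90 %) the two definitions rarely disagree on cluster
membership of intact sequences.

All pairs are aligned exactly; there is no k-mer prefilter. This is a
desk-scale decision: the package targets panels of at most a few
thousand sequences, where exactness and determinism are worth more than
speed.

## Form assignment

Cluster centroids are aligned by center-star progressive alignment: the
center is the record with maximal summed pairwise identity, every other
sequence is aligned to it globally, and gaps are merged under "once a
gap, always a gap". Center-star is a deliberately simple, fully
deterministic aligner; anything producible by an external aligner can
be supplied instead via `as_msa()` on an aligned FASTA.

The alignment is trimmed to columns whose non-gap occupancy strictly
exceeds 0.95 — a column absent in exactly 5 % of rows is removed. From
the trimmed alignment, uncorrected p-distances (pairwise deletion) feed
a neighbor-joining tree (`ape::nj`); NJ is exact on additive distances,
which the test suite verifies against random additive metrics up to
eight taxa. Negative branch lengths, which NJ can produce on noisy
distances, are clamped to zero with a warning.

Curated form labels propagate over the unrooted tree: a clade is either
side of an edge's bipartition, and each uncurated leaf takes the
unanimous label of the smallest clade containing it and at least one
curated leaf. Conflicts — within that clade, or between equally small
clades — yield `unknown`, and ties are deliberately broken *toward*
`unknown` rather than by any arbitrary preference. Labels assigned to a
centroid are inherited by its whole cluster. Form-IV sequences
(rubisco-like proteins without carboxylase activity) are then removed;
`unknown` is retained, since the cost of carrying a non-carboxylase
into expression is lower than the cost of discarding a novel clade.

## Codon design

Reverse translation starts from the CAI-optimal gene — every position
at its family's maximal-w codon, where w is Sharp–Li relative
adaptiveness (frequency over family maximum; zero-count codons get a
pseudo-weight of 0.01) — and repairs GC downward: while GC exceeds the
cap, apply the synonymous swap with the smallest CAI loss among all
GC-reducing swaps, ties broken by codon then position lexicographically.
The loop terminates because GC strictly decreases; if it stalls above
the cap, or the CAI floor is violated at termination, the error reports
the achieved (GC, CAI) frontier point — poly-glycine, whose codons are
all ≥ 2/3 GC, is the canonical infeasible case. CAI follows Sharp & Li
(1987): geometric mean of w excluding the single-codon families (ATG,
TGG) and stops. The defaults GC ≤ 0.60 and CAI ≥ 0.60 suit standard
synthesis and E. coli expression constraints. No real organism's usage
table is bundled — `toy_usage_table()` is a synthetic, deterministic
table for examples and tests — because a measured host table is an
experimental input, not a package constant.

## Plate kinetics

The model behind `analyze_plate()` has three layers:

1. **Slope.** A340 declines linearly while substrates are saturating;
   we fit ordinary least squares over a window that skips the first
   30 s (mixing dead time) and uses the next 300 s. The window is
   configurable (`fit_window_s`); an initial-rate window is preferred
   over the full trace because NADH depletion eventually bends the
   trace. Points with residuals beyond 5σ are reported but not removed.
2. **Rate.** `rate = (−slope / ε_eff) / 2`, in nM/s. The effective
   extinction coefficient ε_eff (absorbance per molar NADH) is a
   *required* parameter of `assay_config()` with no default: plate
   wells do not have a 1 cm path, so ε_eff is an empirical property of
   the instrument. The divisor 2 is stoichiometric — one carboxylation
   produces two 3PG, each oxidizing one NADH downstream. Slightly
   positive slopes within noise are clamped to rate 0.
3. **Titration.** CABP binds active sites essentially irreversibly, so
   rate falls linearly in [CABP] until all sites are blocked. The
   x-intercept of the fitted line is [E], the y-intercept Vmax, and
   kcat = Vmax/[E]. Because the protocol includes a CABP level above
   the enzyme concentration (90 nM vs 50 nM), the saturated point
   lies off the line and would bias a naive fit; after a first pass,
   points with CABP above the estimated [E] and rate below 5 % of the
   uninhibited rate are excluded and the line refit once. Duplicate
   zero-CABP wells are averaged before fitting. Fits with
   non-negative slope or [E] outside (0, 2·max CABP] are flagged
   not-quantifiable rather than reported.

Activity calls use kcat ≥ 0.5 s⁻¹, boundary-inclusive, per active site
(the alternative — per nominal enzyme — would conflate expression yield
with catalysis). `batch_reference_check()` supports the practice of
carrying a reference enzyme in every batch, flagging batches whose
reference deviates by more than 25 % from its expected turnover.

## Radiometric kinetics and specificity

Dissolved CO₂ is computed from bicarbonate via Henderson–Hasselbalch
with an apparent pKa of 6.10; this value makes the conventional
mM-bicarbonate to µM-CO₂ correspondences of pH 8.0 assay buffers come
out right, and it is configurable since it varies with temperature and
ionic strength. Counts convert to rates through a specific-activity
calibration (total CPM of an exhausted known-RuBP reaction divided by
the RuBP amount) and per-site normalization by ¹⁴C-CABP-quantified
active sites.

`fit_michaelis_menten()` uses unweighted nonlinear least squares
(Levenberg–Marquardt via `minpack.lm::nlsLM`) of v = kcat·S/(KM+S),
initialized from a Hanes–Woolf linearization (S/v on S); the
linearization is used only for starting values, never for the reported
estimates. Replicates enter individually. Standard errors come from the
local covariance.

Specificity uses the standard label bookkeeping for 1-labeled RuBP: one
labeled glycerate per carboxylation, one labeled glycolate per
oxygenation, so vc/vo is the glycerate:glycolate count ratio and
S_C/O = (vc/vo)·[O₂]/[CO₂]. This 1:1 partition assumption is isolated
in `specificity_from_peaks()` so an alternative stoichiometric
correction can be substituted in one place. Dissolved gas
concentrations come from Henry's law with default coefficients 0.0334
(CO₂) and 0.00126 (O₂) M/atm at 25 °C. Scintillation quench and
counting-efficiency corrections are out of scope; CPM are taken
proportional to disintegrations.

## Cross-variant statistics

Q10 adjustment is the textbook exponential `k·q10^(ΔT/10)` with
q10 = 2.2 by default. Catalytic efficiency is kcat/KM in s⁻¹·mM⁻¹. The
crossover of two Michaelis–Menten curves is the closed form
C* = (kcat_a·KM_b − kcat_b·KM_a)/(kcat_b − kcat_a), reported only when
positive and finite; otherwise a dominance verdict names the
everywhere-faster enzyme. Kinetic similarity is the larger-over-smaller
turnover ratio over all unordered pairs; the binned summary compares
the arithmetic mean of ratios among pairs with identity > 0.80 against
the mean over all pairs (a geometric-mean option exists, since ratios
are multiplicative by nature). Quantiles are type-7 (linear
interpolation), stated here because quantile conventions differ across
software.

## Synthetic data: what it emulates, what it does not

Each generator is the inverse model of its analysis stage and emits a
truth manifest:

* `gen_sequence_family()` mutates a random root into family ancestors
  and members by substitutions only (no indels), with substitution
  counts calibrated by a collision-corrected quadratic so realized
  pairwise identities land within ±0.05 of the requested within/between
  targets. It does *not* model rate heterogeneity across sites,
  indels, or selection — so passing clustering tests show correctness
  of the clustering logic, not robustness to gappy alignments.
* `gen_plate_traces()` simulates the tight-binding titration rate law
  rate(c) = kcat·max([E]−c, 0) with linear NADH decay and
  homoscedastic Gaussian absorbance noise (default σ = 0.002, 2-s
  cadence, 15-min traces). Real traces also show drift, lamp flicker
  and mixing transients; only the dead-time window handles those.
  Defaults ε_eff = 5000 A/M and NADH₀ = 800 µM are plate-scale values
  chosen so a 15-minute trace at the fastest simulated turnover stays
  far from NADH exhaustion (the generator errors if not).
* `gen_radio_points()` draws Poisson counts around Michaelis–Menten
  expectations at the six-concentration duplicate design; counting
  noise is the only noise source, so real-world pipetting variance is
  not represented.
* `gen_specificity_counts()` partitions turnovers binomially with
  carboxylation probability S_C/O·[CO₂]/(S_C/O·[CO₂]+[O₂]).

All generators use R's Mersenne–Twister with inversion sampling under
an explicit seed, and restore the caller's RNG state, so identical
seeds give identical outputs across platforms.

Test problem sizes — tens of sequences of 100–350 residues, 50
simulation replicates for recovery checks — were chosen as the smallest
sizes at which the statistical assertions are stable; they are the
package's own test design, and the same designs back
`scripts/acceptance.R`.

## Known limitations

* Center-star alignment and NJ are deliberate simplifications of
  profile-based alignment and maximum-likelihood inference; both
  stages accept externally produced alignments and trees for users who
  need them.
* Exact all-pairs alignment makes clustering quadratic; panels beyond
  a few thousand sequences need an external clusterer.
* The titration model assumes strictly stoichiometric, irreversible
  CABP binding; partially reversible binding would bias [E] upward.
* The MM fitter assumes homoscedastic errors; strongly
  heteroscedastic data would justify weighting that the package does
  not currently expose.
* Oxygenation side-flux in the plate assay is assumed suppressed by
  the low-O₂ atmosphere and is not modeled.
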