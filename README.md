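# rubiprospect

Rubisco — ribulose-1,5-bisphosphate carboxylase/oxygenase — fixes
essentially all biological carbon, yet it is slow: most plant enzymes
carboxylate a few times per second. Natural sequence diversity is a
largely unexplored reservoir of faster variants. `rubiprospect`
implements a desk-scale prospecting pipeline for finding them: it takes
a set of candidate rubisco large-subunit protein sequences from
sequence to synthesizable gene, and analyses the two kinetic assays
used to characterize the expressed enzymes. It is written for protein
biochemists and computational biologists who screen enzyme panels and
need the whole chain — curation, clustering, form assignment, codon
design, kinetics — reproducible in one place.

## What it computes

**Sequence side.** Candidates are curated by a fixed funnel — strict
length bounds `300 < l < 700`, removal of ambiguous residue calls,
a BLOSUM62 local-alignment coverage filter against a bait sequence
(≥ 50 % of the bait), exact-identity deduplication — then clustered by
greedy centroid selection on global percent identity (70 % for form
assignment, 90 % for representative selection). Cluster centroids are
aligned (center-star), trimmed to columns with > 95 % occupancy, and
placed on a neighbor-joining tree; curated form labels propagate to the
smallest informative clade, non-carboxylating form-IV homologs are
dropped, and representatives are reverse-translated under GC ≤ 60 % and
CAI ≥ 60 % constraints for synthesis.

**Kinetics side.** The spectrophotometric screen couples carboxylation
to NADH oxidation at 340 nm. For each well the initial A340 slope is
converted to a carboxylation rate via an empirical extinction
coefficient and the 2:1 NADH:carboxylation stoichiometry; a titration
with the tight-binding inhibitor CABP gives the line
`rate = Vmax − (Vmax/[E])·[CABP]`, whose x-intercept is the active-site
concentration [E] and whose y-intercept is Vmax, so

```
kcat = Vmax / [E]        (per active site, s⁻¹; active if kcat ≥ 0.5 s⁻¹)
```

Radiometric ¹⁴C fixation assays give Michaelis–Menten data: counts are
calibrated to nanomoles through a specific-activity standard, converted
to per-site rates, and fit by nonlinear least squares to
`v = kcat·S/(KM + S)`. CO₂:O₂ specificity is computed from labeled
glycerate/glycolate product peaks as
`S_C/O = (glycerate/glycolate) · [O₂]/[CO₂]`. Cross-variant statistics
include Q10 temperature adjustment, catalytic efficiency kcat/KM,
Michaelis–Menten crossover analysis, and kinetic-similarity-versus-
identity summaries.

Every stage has a matching synthetic-data generator
(`gen_sequence_family()`, `gen_plate_traces()`, `gen_radio_points()`,
`gen_specificity_counts()`) that emits a ground-truth manifest, so the
full pipeline is testable end to end without any external data.

## Worked example

```r
library(rubiprospect)

# sequence side: three synthetic families, curated and prospected
fam <- gen_sequence_family(3, 5, length = 350, seed = 20)
out <- run_pipeline(pipeline_config(
  fam$records, fam$records[1, ],
  curated_labels = fam$curated_labels,
  usage = toy_usage_table()
))
str(out$summary)
#> $ input                  : int 15
#> $ curated                : int 15
#> $ form_clusters          : int 3
#> $ form_counts            : List of 3 (Ia: 5, Id: 5, IIIc: 5)
#> $ carboxylating          : int 15
#> $ representative_clusters: int 3
#> $ genes_designed         : int 3

# plate screen: CABP titration of a 6.6 s⁻¹ reference-like variant
sim <- gen_plate_traces(true_kcat = 6.6, seed = 20)
analyze_plate(sim$traces, assay_config(epsilon_eff = 5000))
#>   variant   kcat_per_s active_sites_nM vmax_nM_s r_squared active
#> 1 synthetic      6.595           50.03       330         1   TRUE

# radiometric side: Michaelis-Menten fit of Poisson-count data
rad <- gen_radio_points(22.2, 276, seed = 20)
fit <- fit_michaelis_menten(cpm_to_rate(rad$points))
fit
#> Michaelis-Menten fit: kcat = 22.1 +/- 0.21 /s, KM = 275 +/- 6.3 uM (n = 12)
carbox_efficiency(fit$kcat_per_s, fit$km_uM)
#> [1] 80.5
```

The pipeline recovers the planted three-family structure (3 clusters, 3
designed genes), the plate analysis returns the simulated variant's
turnover (6.595 vs 6.6 s⁻¹ truth) and site concentration (50.03 vs
50 nM), and the Michaelis–Menten fit recovers kcat and KM within their
standard errors; kcat/KM is reported in s⁻¹·mM⁻¹. Fitted objects
support `tidy()`, `glance()` and `autoplot()`.

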