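---
title: "Methods: building and validating RIL linkage maps with rilmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and validating RIL linkage maps with rilmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rilmap)
```

## The problem

A recombinant inbred line (RIL) population is produced by crossing two
inbred parents and selfing the progeny for several generations by
single-seed descent. Each line ends up (nearly) homozygous, a mosaic of
parental genome blocks whose breakpoints record historical crossovers.
Genotyping the population at many loci — here with the mixed
genotyping-by-sequencing (RAD-seq) and array regime typical of crop
genomics, where sequencing-derived calls can be up to two-thirds missing —
lets us order the markers, measure genetic distances between them, and then
hold the resulting genetic map up against a draft genome assembly: checking
scaffold order and orientation, anchoring unplaced scaffolds, and measuring
how recombination rate varies along each chromosome.

`rilmap` implements that workflow end to end, together with a
meiosis-level population simulator that provides ground truth for every
step. All user-facing functions take a data frame first and return tibbles;
fitted maps support `tidy()`, `glance()` and `autoplot()`.

## The model

**Genotype calls.** Every call is one of `A` (parent-1 homozygote), `B`
(parent-2 homozygote), `H` (heterozygote) or `U` (missing). Heterozygotes
are transient in a RIL — the expectation after reaching generation $g$ is
$(1/2)^{g-1}$ per line, 1.5625% for an F7 — and carry no phase information,
so they are treated as missing wherever recombination is counted.

**Recombination fractions.** For a marker pair the observed recombinant
fraction is

$$\hat R = \frac{\#\{\text{lines with opposite homozygous calls}\}}
               {\#\{\text{lines homozygous and non-missing at both}\}} .$$

In a selfed RIL recombination accumulates over the generations of inbreeding:
at fixation $R = 2r/(1+2r)$ (Haldane–Waddington), where $r$ is the
per-meiosis recombination fraction. The inverse, $r = R/(2-2R)$, is exposed
as `ril_rf_correction()` and as the `ril_correction` argument of
`pairwise_rf()` and `build_map()`. The correction is **off by default** —
the classical workflow this package follows feeds raw fractions to the
grouping and ordering steps, and ordering is unaffected because the
transformation is monotone — but it must be **on** whenever absolute cM
lengths are compared against an external truth (all simulation-recovery
experiments in the test suite do this); without it an F7 map is roughly
twice its true cM length, since $R \approx 2r$ for small $r$.

**Map distances.** Adjacent fractions are converted to centimorgans with
the Kosambi map function, which accounts for moderate crossover
interference:

$$d = \tfrac{100}{4}\,\ln\!\frac{1+2r}{1-2r} \quad\text{(cM)},\qquad
  r = \tfrac12\tanh\!\frac{2d}{100}.$$

**The COUNT objective.** A marker order is scored by the total number of
apparent recombination events: for each line, the number of A↔B transitions
between consecutive non-missing homozygous calls along the order, summed
over lines (`count_recombinations()`). The true order minimises this in
expectation; ordering is therefore a combinatorial minimisation of COUNT.

## Pipeline stages and their parameters

| stage | function | defaults | notes |
|---|---|---|---|
| marker QC | `filter_markers()` | profile `"rad"`: ≤ 66% missing, ≤ 10% het, allele frequency in [0.2, 0.8]; profile `"map"`: ≤ 30% missing, same het/AF | “more than” thresholds are strict; the AF band is inclusive; AF is computed over homozygous calls only |
| line QC | `filter_lines()` | > 10% het removed; optional > 25% missing | the per-RIL missing criterion belongs to the pre-mapping profile |
| imputation | `impute_flanking()` | — | fills missing runs whose nearest non-missing neighbours agree, never across a scaffold boundary; assumes no recombination inside the run |
| binning | `bin_identical()` | genome-wide scope | patterns must be exactly identical, missing positions included; representative = fewest missing calls, ties by lowest bp then id |
| grouping | `group_markers()` | cutoff 0.2, ≥ 20 informative lines per pair | single-linkage transitive closure; the informative-pair floor replaces tool-internal quality scores |
| ordering | `order_record()` | 30 random starts | greedy insertion minimising COUNT, ties keep the earlier candidate; orientation canonicalised lexicographically |
| refinement | `ripple()` | window 5 | all window permutations, accepted only on strict COUNT improvement, sweeps to a fixed point |
| error correction | `correct_singletons()` | — | a call contradicting two agreeing flanks is an apparent double crossover in a one-marker interval, i.e. almost always a genotyping error; detected in one simultaneous pass, boundaries never touched |
| distortion | `distortion_scan()` | α = 0.05, band 0.4/0.6 | χ² against 1:1 on homozygotes (df = 1); distorted requires *both* p < α and AF outside (0.4, 0.6); no multiplicity correction by default (a Bonferroni option exists) |
| SDRs | `detect_sdr()` | gap 0 | ≥ 2 consecutive same-direction distorted markers; tolerated interruptions are a parameter |
| landscape | `interval_rates()` | hot > 20 cM/Mb, cold = 0, moderate 10–20 | boundaries: hot is strict, cold is exact zero |

`build_map()` runs two rounds: round 1 = group → order → ripple; then
singleton correction and flank re-imputation along the map order; round 2 =
re-order and re-ripple. Per group the candidate order with the shortest
total Kosambi length wins (ties keep round 1).

### Why distances ignore the re-imputed calls

The round-2 re-imputation fills a missing run only when its flanks agree —
that is, precisely when the line is (almost surely) non-recombinant there.
Recombinant lines keep their missing calls. Using the imputed matrix for
distance estimation therefore inflates the concordant denominator without
adding recombinant events and shrinks the map by roughly the missing rate
(about a third at 20% missing, in our simulations). `build_map()` hence
uses the imputed matrix **only to order markers** (where the extra calls
stabilise COUNT) and estimates every adjacent recombination fraction from
the singleton-corrected, non-imputed calls.

## The simulator

`simulate_ril_population()` emulates the statistical structure the pipeline
assumes, not the sequencing process that produces it:

* one F1, fully heterozygous, selfed $g-1$ times by single-seed descent
  (one offspring per line per generation, no outcrossing);
* each gamete recombines the plant's two haplotypes with an independent
  Bernoulli($r$) crossover per adjacent marker interval, $r$ =
  `inverse_kosambi()` of the interval's true cM span — a Markovian meiosis
  whose only interference is the one implied by the map function, chosen so
  that distance-recovery tests are self-consistent;
* transmission distortion is modelled as gametic viability: gametes
  carrying the disfavored allele at a distortion locus are accepted with
  probability $w \in (0,1]$ each generation (the field reports distortion
  direction and extent, not mechanism; viability weighting is the simplest
  generative account);
* observation noise is applied last: each call is set missing with
  `missing_rate`, then surviving homozygous calls are flipped A↔B with
  `error_rate`.

The defaults mirror the CPR-01 chickpea study design: 92 lines, F7,
eight chromosomes with the published per-group cM lengths, physical spans
and marker counts (`sim_config_cpr01()`). Marker grids are evenly spaced in
cM with physical positions collinear by construction.

What the simulator does **not** emulate: read-depth–dependent missingness
(missingness is i.i.d., whereas RAD-seq missingness clusters by restriction
site and line), reference bias, genotyping-error structure correlated with
heterozygosity, residual outcrossing, and real assemblies' misjoins (the
genome-comparison tests construct inversions explicitly instead). Passing
the recovery tests therefore shows the algorithms are correct under the
declared model, not that real data meet the model.

## Numerical and design choices

* **Tie-breaks.** Greedy insertion and ripple accept only strict
  improvements and keep the earliest candidate at equal COUNT, making every
  run deterministic under its seed. Orientation of a returned order is
  canonical (first marker id lexicographically before the last).
* **Degenerate inputs.** All-missing marker columns have undefined allele
  frequency and are flagged (and removed by the AF filter reason); groups
  of one marker are emitted as unplaced; adjacent pairs with no informative
  lines contribute 0 cM; fractions at or above 0.5 are clamped just below
  before the Kosambi transform (its pole).
* **Grouping cutoff semantics.** The 0.2 cutoff applies to raw observed
  fractions (the accumulated-recombination scale on which it was defined),
  regardless of `ril_correction`.
* **Coverage.** Chakravarti method 4 inflates each group by
  $(m+1)/(m-1)$; the Sekino–Hara coverage is observed/estimated. Because
  published work is ambiguous about whether the factor is applied per group
  or once globally, both modes are implemented (`mode = "per_group"` is
  the default, `"global"` applies the factor once with $m$ = total
  markers); on the bundled reference summary they give ≈ 98.3% and
  ≈ 99.9% coverage respectively.
* **Orientation of linkage groups** is arbitrary, so the genome comparison
  normalises each group against physical order (groups with negative
  Spearman ρ are reversed) before local-inversion scanning and interval
  rates; SDR detection is orientation-invariant by construction.
* **Gene counting** uses the midpoint rule (a gene belongs to the interval
  containing its midpoint) so adjacent intervals never double-count.
* **Coordinates** follow the conventions of their formats on input
  (GFF3 1-based closed, BED 0-based half-open, handled by `rtracklayer`);
  everything user-facing is 1-based closed.
* **Ambiguous published thresholds.** The pre-mapping "missing in more
  than 25% RILs and 30% per marker" rule is read as 25% on lines and 30%
  on markers, both exposed as options. Dominant-pattern markers are out of
  scope: the pipeline accepts codominant A/B/H/U calls only.

## Validation scale

The test-suite experiments are sized to run on a laptop in minutes while
keeping sampling error well inside the asserted tolerances: exhaustive
ordering oracles up to 8 markers (8! orders); parameter recovery at
92 lines × 200 markers on two chromosomes with 20% missing calls and 0.5%
genotyping error (group recovery exact, per-group Kendall τ ≥ 0.95 against
the true order, total length within 20% of truth); simulator calibration at
2,000 lines; null calibration of the distortion test over 300 unlinked
markers. At 92 lines the standard error of a single interval distance is
large (≈ 1 cM at 1–2 cM spacing); totals over ~100 intervals have relative
errors of a few percent, which is why length tolerances are 10–20% and not
tighter.

## Known limitations

* COUNT-optimal orders can be locally ambiguous between markers separated
  by no observed recombinant, and the shortest-map selection rule slightly
  favours orders that hide recombination events when markers are sparse;
  with dense markers (≲ 1 cM spacing) the effect is negligible.
* The χ² distortion test uses the asymptotic distribution; with ≈ 90
  informative lines its size is close to nominal, but very high missingness
  at a marker reduces the effective sample.
* Interval recombination rates inherit the assembly's physical coordinates:
  inside a true inversion the per-interval rates are meaningless until the
  assembly is corrected (such intervals surface as skipped, negative-span
  records).
* The RIL correction assumes complete selfing to fixation; at F7 the
  residual \~1.6% heterozygosity makes estimated distances ≈ 1.5% short,
  well inside sampling error at this population size.
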