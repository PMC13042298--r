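---
title: "Recombination landscapes in inversion-rich genomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recombination landscapes in inversion-rich genomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recombinv)
```

## The problem

Polymorphic chromosomal inversions are strong recombination modifiers: an
individual carrying one standard and one inverted arrangement (a
*heterokaryotype*) produces almost no viable crossover products inside the
inverted interval, while arrangement homozygotes recombine normally there.
In species whose genomes segregate many inversions — the spruce bark beetle
*Ips typographus*, with its 15 autosomes plus X and more than two dozen
described polymorphic inversions, is the motivating example — this turns the
recombination landscape into a mosaic that depends on each parent's
karyotype. `recombinv` implements a desk-scale, fully testable version of
the analysis chain used to characterize such landscapes:

1. classify markers by parental informativeness and filter them
   (`call_informative()`, `filter_markers()`);
2. assign markers to linkage groups by pairwise LOD and order them
   (`lod_matrix()`, `assign_linkage_groups()`, `order_markers()`);
3. build Marey maps, estimate windowed recombination rates, and flag
   candidate misassemblies (`build_marey()`, `sliding_rate()`,
   `detect_breaks()`, `map_summary()`);
4. count crossovers as switches in phased parental transmissions and test
   heterokaryotype suppression (`find_crossovers()`,
   `het_suppression_test()`);
5. compare collinear and inversion region rates and test TE/gene
   enrichment by permutation (`label_permutation_test()`,
   `enrichment_permutation()`);
6. genotype inversions in a population panel and call their boundaries
   (`ld_screen()`, `pca_genotype()`, `windowed_fst()`,
   `call_boundaries()`).

A seeded synthetic-data generator (`simulate_genome()`,
`simulate_family()`, `simulate_population()`) provides truth-known inputs
for every stage, so the pipeline's statistical behaviour — power,
calibration, recovery error — is itself under test.

## Models and statistics

### Two-point linkage and mapping functions

For two markers with phase-known transmission vectors over $n$ jointly
scored meioses, of which $k$ are recombinant,
$\hat r = \min(k/n,\, 1/2)$ and

$$\mathrm{LOD} = k \log_{10}\frac{\hat r}{0.5}
  + (n-k)\log_{10}\frac{1-\hat r}{0.5},$$

with the phase (which labeling counts as recombinant) chosen to maximize
the LOD and $0\log 0 \equiv 0$. Linkage groups are the connected
components of the graph joining pairs with LOD above `lod_limit`
(single-linkage / transitive closure); the default threshold of 19 is the
value at which the motivating map resolved its 16 linkage groups, and the
package exposes the same threshold sweep used to find that plateau.
Ordering within a group is a greedy nearest-neighbour path on $\hat r$
refined by 2-opt moves that minimize the sum of adjacent fractions —
a deliberate simplification of likelihood-annealing orderers, accepted on
order-recovery against simulation truth rather than parity with any
external tool. Adjacent fractions convert to distances by Kosambi
($d = 25\ln\frac{1+2r}{1-2r}$, the pipeline default, correcting for
interference) or Haldane ($d = -50\ln(1-2r)$, matching the simulator's
interference-free default so recovery is exact in expectation).

A practical identifiability note: with $n$ meioses, marker pairs closer
than roughly $1/n$ Morgans usually show zero recombinants, so their local
order carries no signal. Order-recovery checks therefore use map lengths
(about 0.4 cM marker spacing at 147 meioses) at which adjacent intervals
are resolvable; denser maps are still *grouped* correctly but their
within-blob order is arbitrary, which inflates neither map length much nor
the group assignment at all.

### Crossover counting and the suppression test

Crossovers are counted as switches between consecutive non-missing
haplotype labels along each offspring × parent × LG transmission vector;
an event is localized to the interval between its two flanking informative
markers and assigned to a region if the interval midpoint falls inside
(half-open). Counts are weighted by 1/65 or 1/82 — the reciprocal of each
family's offspring number — before testing. The suppression test pools
weighted counts per inversion × parent into heterokaryotypes (karyotype 1)
versus homokaryotypes (0 and 2 treated as one group) and applies a
one-sided Wilcoxon rank-sum test. Because weighted counts tie frequently
(many zeros in heterokaryotypes), the small-sample path enumerates the
permutation null on midranks exactly — which remains exact under ties —
instead of delegating to the tie-intolerant exact path of
`stats::wilcox.test`; the large-sample path uses the normal approximation
with tie correction.

Switch counting sees crossovers only up to parity within marker
intervals: two crossovers between adjacent informative markers cancel.
The truth channel therefore records raw crossover positions, and
`resolved_crossovers()` computes the parity-visible count on a given
marker grid — the exact expectation for error-free transmissions, against
which the test suite checks equality seed by seed.

### Permutation tests

Region rates (cM/Mb, boundaries linearly interpolated on the Marey map)
are compared between collinear regions and heterokaryotype inversions by
reshuffling region labels (1,000 permutations by default, matching the
original analysis; the statistic is the difference of group means, tested
one-sided because suppression has a stated direction). Feature
(TE/gene) enrichment relocates each inversion-sized segment to a uniform
random start on a uniform random LG that can hold it, with rejection on
overlap; random relocation was chosen over circular rotation because the
inversions sit on multiple LGs of different lengths. Enrichment is
reported two-sided with a direction label. All empirical p-values use the
add-one rule $p = (1 + \#\{\text{null at least as extreme}\})/(n_{\rm
perm}+1)$, so $p \in (0, 1]$, and every result records its seed.

### Population inversion scan

Genotype masking mirrors standard short-read hygiene: genotypes with
DP < 8 or GQ < 20 are set missing; sites that are not biallelic, have
minor allele frequency below 0.01, exceed the panel mean + 1 SD in mean
depth, or show heterozygote excess beyond 54.69 (phred) are dropped. The
heterozygote-excess statistic is $-10\log_{10}p$ from a one-sided exact
test on the Levene–Haldane conditional distribution of the heterozygote
count — a documented substitute for the GATK annotation of the same name
and threshold, which is computed from genotype likelihoods rather than
hard calls.

Candidate regions are genotyped by PCA: sites with more than 20% missing
genotypes are dropped, the rest mean-imputed and centered, and individuals
clustered by 1-D k-means (k = 3) on PC1. A call is *ambiguous* unless all
three clusters are occupied, the middle (heterozygote) cluster center lies
within the middle third of the homozygote-center interval, and the
between-cluster fraction of PC1 variance reaches 0.95. The last criterion
is the package's own: genuine arrangement clusters are near-discrete
(fraction ≈ 0.99) whereas the best 3-way split of a continuous unimodal
PC1 captures only ≈ 0.81, so 0.95 cleanly separates inversion-like
structure from a gradient. Cluster orientation (which homozygote class is
"derived") is not identifiable without external information; accuracy
against truth is therefore assessed up to the 0 ↔ 2 relabeling.

Differentiation between the two arrangement-homozygote groups is measured
by the Weir–Cockerham (1984) weighted estimator,
$\sum_s a_s / \sum_s (a_s + b_s + c_s)$ over SNPs in 100-kb windows
stepped every 20 kb, with per-site sample sizes reflecting missingness and
monomorphic sites skipped. Boundaries are the region where Fst exceeds
0.15 over at least 3 consecutive windows ("multiple consecutive" made
concrete and configurable), merging qualifying runs across sub-threshold
gaps shorter than 3 windows. Windows with no usable SNP carry no evidence
and are excluded before run detection: only an *observed* Fst below
threshold ends a region, so sparse coverage cannot split a call. Reported
intervals describe the differentiated region, not inversion breakpoints.

The LD screen keeps the first SNP with MAF > 0.2 in every 10-kb bin
(deterministic thinning) and reports blocks of ≥ 5 consecutive kept SNPs
whose sliding median pairwise genotype $r^2$ exceeds 0.5.

## The synthetic generator: what it emulates and what it does not

`simulate_genome()` defaults to the 16-LG genome geometry of the
motivating map (physical sizes 7–31 Mb, sex-averaged lengths 45–107 cM)
with a piecewise-linear monotone truth function per LG (uniform by
default). Inversions carry a derived-arrangement frequency; TE and gene
tracks are sampled as fixed-size chunks with configurable density
multipliers inside inversions (defaults 0.5 for TEs — depleted — and 1.5
for genes). `simulate_family()` defaults to the two-family design, 65 and
82 offspring; crossovers per meiosis and LG are Poisson with mean equal to
the map length in Morgans, placed uniformly on the genetic scale, and — in
heterokaryotypes — deleted inside the inversion without relocation,
because the motivating observations show suppression, not compensatory
gain (an optional flank behaviour is deliberately *not* provided; removal
is the model). Marker densities default to a few hundred per LG, inside
the $10^2$–$10^4$ band that keeps desk-scale runs tractable; genotyping
error is a symmetric uniform mis-call at rate 0.001 and missingness 0.02,
modest values typical of well-filtered short-read family data.

Deliberate simplifications, and what they imply for interpreting passing
tests: there is no obligate chiasma (Poisson admits zero-crossover
meioses, unlike real beetle bivalents), no crossover interference by
default (a gamma-renewal mode with shape ν = 5 is available; the species'
true interference strength is unpublished, so ν is a modeling choice), no
sequence-level simulation, no selection, no allele-biased genotyping
error, and population panels are panmictic outside inversions with
arrangement-specific allele frequencies $m \pm d/2$ inside (midpoint $m$
uniform such that both stay in [0, 1]; divergence $d = 1$ yields fixed
differences). Passing recovery tests therefore demonstrate correctness of
the inference chain under this model, not robustness to population
structure, reference bias, or complex rearrangements.

One consequence of the divergence model deserves emphasis: the pairwise
genotype correlation between two SNPs inside an inversion is
$r = d^2\,\mathrm{Var}(g) / (d^2\,\mathrm{Var}(g) + \mathbb{E}\,
\mathrm{Var}(x\mid g))$ with $g$ the arrangement dosage
($\mathrm{Var}(g) = 2f(1-f)$), so at the default divergence 0.5 and
frequency 0.4 the median pairwise $r^2$ inside an inversion is only about
0.06–0.09. The LD screen's median-$r^2 > 0.5$ block rule therefore fires
only for near-fixed arrangement differences ($d \gtrsim 0.85$); at
moderate divergence the PCA and Fst routes carry the detection, which is
why the end-to-end scan treats the LD screen as one source of candidates
rather than a gatekeeper.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; VCF positions (1-based)
  and BED intervals convert at the I/O boundary only.
* `map_distance()` rejects $r \ge 0.5$ and caps distances at 1,000 cM
  with a warning; inverses are closed-form and exact.
* Negative OLS slopes in `sliding_rate()` clamp to 0 (rates are physical);
  the raw slope is kept in a diagnostic column. The per-LG window defaults
  to span/20 because the original "automatically calculated window size"
  is unpublished; the parameter is exposed.
* Ties in 2-opt break toward the earlier move; thinning keeps the first
  qualifying SNP per bin; grouping labels order by component size then
  index — all outputs are deterministic given a seed.
* Markers sharing a physical position collapse to their mean cM;
  monotonicity violations are retained but counted.
* `filter_markers()` is a pure conjunction (MAF ≥ 0.1, per-family
  segregation chi-square p ≥ 0.01 against the Mendelian ratio of the
  cross type, worst-family missingness ≤ 0.1, informative in ≥ 2
  families), hence idempotent and order-free. The segregation test is an
  explicit Pearson chi-square — the upstream tool buries an equivalent
  tolerance inside its likelihood machinery, and the printed value is
  adopted as a plain p-value threshold.
* MAF is computed across offspring of all families pooled; missingness is
  per family with the worst family binding.
* Single global seeds expand into per-stage child seeds
  (`seed + stage × 10007`), all below $2^{31}$.

## Problem sizes used by the test and acceptance suites

Replicated suites run at scales chosen to keep the whole battery
comfortably reproducible on a single CPU: the suppression and
rate-comparison suites use 5 LGs × 8 Mb with 6 inversions and 100 markers
per LG over 100 power seeds and 200 null-calibration seeds; linkage
recovery uses 500 markers on two ~100-cM LGs at 147 meioses; the
population scan uses 50 panels of 240 individuals; enrichment uses 100
power and 200 null seeds at 2 LGs × 6 Mb. Replicated permutation runs use
199 or 999 permutations per replicate (resolution well beyond the 0.05 and
0.005 decision points); one-shot analyses keep the 1,000-permutation
default of the original study.

## Known limitations

* The ordering heuristic is local-search; pathological LOD landscapes
  (e.g. dense maps far beyond the meiosis resolution limit) yield
  arbitrary within-blob order, flagged only indirectly via map-length
  inflation.
* `het_suppression_test()` assumes observations are exchangeable across
  inversions × parents under the null; shared meioses across inversions on
  one LG mildly violate independence, which the null-calibration suite
  shows is negligible at study scale.
* The exact heterozygote-excess test substitutes for a likelihood-based
  annotation; sites near the threshold may be classified differently than
  by the original caller.
* Overlapping inversions are representable (`allow_overlap = TRUE`) but
  the scan makes no attempt to deconvolve them, mirroring the unresolved
  overlapping signals in the motivating data.
* X-chromosome dosage is not modeled in families; sex linkage is handled
  only through the coverage-ratio classifier (`sex_linkage_scan()`).

## A worked micro-example

```{r example}
inv <- region_set("LG1", 2e6, 5e6, derived_freq = 0.4, id = "inv1")
layout <- simulate_genome(c(LG1 = 8e6, LG2 = 8e6), c(LG1 = 55, LG2 = 55),
                          inversions = inv, markers_per_lg = 100, seed = 11)
cfg <- sim_config(offspring = c(65L, 82L), seed = 11)
fams <- lapply(1:2, function(f) simulate_family(layout, cfg, f))
events <- find_crossovers(do.call(rbind, lapply(fams, `[[`, "transmissions")),
                          c(F1 = 65, F2 = 82))
kary <- setNames(lapply(fams, `[[`, "karyotypes"), c("F1", "F2"))
tab <- inversion_event_table(events, layout$inversions, kary,
                             c(F1 = 65, F2 = 82))
het_suppression_test(tab)[c("p_value", "method", "n_het", "n_hom")]
```
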