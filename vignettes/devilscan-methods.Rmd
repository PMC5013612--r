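---
title: "Methods: temporal selection scans in replicated populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporal selection scans in replicated populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

devilscan detects genomic regions under parallel selection from temporally
sampled SNP genotypes in replicate wild populations. The motivating system
is the Tasmanian devil and its transmissible facial tumour: several small
populations (effective sizes in the 20s and 30s) were sampled before and a
handful of generations after an epidemic arrived, and the question is which
genomic regions changed more than drift and sampling noise can explain —
concordantly across populations. This vignette documents the statistical
machinery, the tunable parameters, the synthetic-data generator used for
calibration, and the numerical choices a user may want to audit.

## Data model and coordinates

All coordinates are 0-based half-open internally. VCF input (1-based) is
converted on read; BED output is written natively. A `genotype_table`
couples a samples-by-SNPs matrix of alt-allele dosages (0/1/2/NA) with SNP
metadata (scaffold, position, alleles, RAD-locus id, chromosome assignment
from a scaffold-ordering table) and sample metadata (population, collection
year). Raw GT strings are retained so phased haplotypes can be extracted
without re-reading the file. Phasing itself is taken as given: real data
are phased upstream, and the simulator emits truth phase. Windows never
span scaffold boundaries.

## Filtering

Four composable, order-explicit filters reproduce a standard RAD-seq QC
chain, applied in the order X-scaffolds, paralogues, call rate, MAF:

* `filter_x_scaffolds`: drop SNPs on scaffolds assigned to the X
  chromosome (temporal contrasts in mixed-sex samples are confounded
  there).
* `filter_paralog_loci`: observed heterozygosity above 0.5 at any SNP of a
  RAD locus flags the whole locus as a collapsed paralogue. The
  denominator uses called genotypes only. The inequality is strict: a SNP
  at exactly 0.5 survives.
* `filter_call_rate`: SNPs called in strictly less than a minimum fraction
  of the targeted samples (all samples, one population, or one time
  stratum) are dropped; the fraction is compared exactly, without
  rounding sample counts.
* `filter_maf`: minor allele frequency over pooled called alleles strictly
  below the threshold (default 0.01) drops the SNP; MAF exactly at the
  threshold survives.

Each step returns a report (step name, SNP counts, thresholds); reports
chain, so pipelines can assert that `n_after` of one step equals
`n_before` of the next.

## Allele-frequency-change scan

Per population, alt-allele frequencies are computed in a pre-epidemic and
a post-epidemic stratum (calendar-year groupings are configuration; time
points may be combined to raise stratum sample sizes). SNPs are first
LD-pruned: scanning left to right within each scaffold, whenever a
retained SNP and a later SNP within 20 SNPs and 50 kb have genotypic
r-squared above 0.99, the later SNP is removed. Genotypic r-squared is the
squared Pearson correlation of dosage vectors over jointly called samples,
the standard unphased LD measure.

SNPs are then ranked by absolute frequency change. Empirical quantiles use
the mid-rank convention rank/(N+1) with ties averaged, keeping every
quantile strictly inside (0,1) so that downstream log transforms are
finite; ranking is applied to values rounded to 12 significant digits so
that genuine ties (for example the same change computed from relabeled
alleles) rank identically. SNPs above the 1 − 0.025 quantile receive a
window of 100 kb on either side, clipped to scaffold bounds; windows are
merged per population, and candidate regions are the per-scaffold
intersection of all populations' merged windows. The signed change is kept
alongside for directionality displays. A 200-kb/50-kb-step sliding-window
mean |change| is available as a complementary view.

`expected_false_overlap` gives the analytic null for candidate regions:
conditional on each population's marker panel, the probability that a
genome position is covered by a population's windows is
1 − (1 − f)^k(x), with f the selected fraction and k(x) its panel SNPs
within one flank; the product over populations, integrated along the
genome, is the expected falsely-overlapped length when populations evolve
independently. Conditioning on the shared panel matters: a naive product
of genome-wide coverage fractions underestimates the overlap because all
populations can only place windows where markers exist.

## Haplotype homozygosity: EHHS, iES, Rsb

For each focal SNP, the site-level extended haplotype homozygosity at
distance x is the probability that two random haplotypes from the stratum
are identical at every SNP from the focal site out to x, normalized to 1
at the focal site. Homozygosity over a SNP interval uses the unbiased
estimator sum n_h(n_h−1)/(n(n−1)) over distinct multi-site haplotypes —
with 20–50 haplotypes per stratum the biased n² version is noticeably
off. The curve is computed outward one SNP at a time and truncated when it
drops below 0.05 (values below the threshold are discarded); integration
stops at scaffold ends. iES is the trapezoidal integral of the truncated
curve over both flanks, in bp.

Missing calls are conservative: a missing site breaks identity for every
pair involving that haplotype (implemented by giving each missing call a
private allele). This biases EHH downward symmetrically in both strata, so
the temporal contrast is not directionally distorted. Haplotype rows with
under 30% of sites called are dropped before any computation.

The temporal contrast is `rsb_raw = ln(iES_pre / iES_post)` per SNP with
MAF at least 0.05 in both strata, standardized genome-wide by subtracting
the median and dividing by the standard deviation (one pooled
standardization; no frequency-bin stratification). Under this formula a
sweep after the epidemic — homozygosity increased post — makes iES_post
large and drives the score into the lower tail. The source literature for
this statistic states the formula and a prose sign convention that
contradict one another; devilscan follows the formula and documents the
direction here. Because the composite statistic ranks evidence of
post-epidemic sweeps, the pipeline feeds it the negated standardized
score. Site-level (not allele-partitioned) EHH is used because the
contrast compares the same site across time strata rather than alleles
within a stratum, and one iES per SNP per stratum is required.

## Composite window statistic

The genome is tiled with non-overlapping 100-kb windows anchored at
position 0 of each scaffold. For each (population, statistic) combination
— absolute frequency change and the Rsb contrast per population —
quantiles are computed genome-wide, and within each window the maximum
quantile q and the count s of SNPs with non-missing values are taken. The
window-adjusted P value is 1 − q^s, the probability that the maximum of s
independent uniforms falls below q; with correlated SNPs this is
conservative. Combinations with s = 0 are skipped. Available adjusted P
values are combined with Fisher's method, −2 Σ ln p, referred to a
chi-squared distribution with twice the number of contributing
combinations as degrees of freedom. Candidate regions inherit the minimum
combined P over the grid windows they overlap (regions are window
overlaps, not grid cells, so some mapping is needed; the minimum is the
natural choice for a detection statistic and is flagged as an
interpretation).

Calibration: feeding the machinery independent uniform quantiles with
Poisson SNP counts per window yields combined P values that pass a
Kolmogorov–Smirnov uniformity test at alpha 0.01 in ~99 of 100
repetitions of 2,000 windows (computed by the test suite and the
acceptance script). The calibration uses independent SNPs deliberately,
since the adjustment is conservative under correlation.

## Temporal Ne: Jorde–Ryman two-sample estimator

For two samples t generations apart, the standardized temporal variance
pools loci: Fs = Σ(x−y)² / Σ z(1−z) with z = (x+y)/2. The sample-size
correction

Fs' = (Fs (1 − 1/(4ñ)) − 1/ñ) / (1 + Fs/4)

uses ñ, the harmonic mean sample size in diploid individuals across loci
and samples. Fs' estimates the accumulated drift F = 1 − (1 − 1/(2Ne))^t;
devilscan inverts this relation exactly rather than using the first-order
Ne = t/(2 Fs'), which at t = 4, Ne = 35 already biases the estimate
upward by about 2% and costs jackknife coverage. No census-size factor is
applied (sampling is treated as destructive/plan II with unknown census).
Confidence limits come from a delete-one-locus jackknife on Fs',
transformed to the Ne scale; a non-positive Fs' yields an unbounded
estimate with a warning, as the data then show no drift signal beyond
sampling noise. At the calibration design (5,000 unlinked loci, true
Ne 35, t 4, 25 diploids per sample) the median estimate is within a few
percent of truth and the 95% interval covers truth in roughly 90 of 100
replicates.

## Per-SNP selection coefficients: exact Wright–Fisher HMM

The allele-frequency time series of one SNP is modeled as a hidden Markov
chain on the population alt-allele count k in 0..2Ne. One generation
applies the deterministic genic-selection map p' = p(1+s)/(1+ps) followed
by binomial resampling of 2Ne alleles; k = 0 and 2Ne are absorbing.
Observed counts are binomial draws of the sampled alleles from the
population frequency; the initial state is uniform (anchoring on a noisy
first sample would bias s). The likelihood is computed by the scaled
forward algorithm with exact transition matrices — feasible because the
study-scale Ne is tiny (26–37); no diffusion approximation is used, and
Ne above 500 is out of scope. Genic (multiplicative) selection is the
minimal one-parameter model for a per-allele "selective advantage".

`estimate_s` profiles the likelihood on a grid (default −0.5 to 2.5 in
steps of 0.1, wide enough for estimates above 100%), refines the maximum
by golden-section search, and reports the profile-likelihood interval at
1.92 log-units. A maximum on the grid boundary is flagged and the
interval censored. Per-SNP fits always describe the *increasing* allele:
SNPs whose alt allele fell are label-flipped first, so s_hat is the
fitness advantage of the rising allele and is invariant to allele
labeling. Region summaries report the mean with per-SNP min/max; both the
per-SNP spread and the profile intervals are reported because published
"point estimate ranges" do not disambiguate the two.

Calibration at the study design (Ne 30, three time points over six
generations, 40 alleles per time point, 200 replicates): the median
estimate at s = 0 is within 0.05 of zero, at s = 0.3 it falls near 0.35,
and medians are strictly ordered across true s in {0, 0.1, 0.3, 0.5}.

## Annotation randomization test

To ask whether candidate regions are unusually rich in target functional
annotations, `randomization_test` samples pairs of distinct SNPs without
replacement, centers a 200-kb window on each (clipped at scaffold ends),
and scores the pair. The default criterion is lax — any overlapped gene
carrying any target term — because the observed unit in the motivating
analysis is a pair of regions jointly carrying relevant annotations; a
strict criterion requiring two distinct target terms across the pair is
available. Gene membership is any overlap with the window, not full
containment. Term matching is literal label matching; no GO-graph
propagation is attempted. Seeded runs are bit-reproducible and restore
the caller's RNG state.

## The synthetic-data generator

`simulate_dataset` produces datasets with known truth that emulate the
study's structure; its defaults are the study conditions, and the test
suite and acceptance script run against them.

* Three populations, Ne 34/37/26, generation time 2 years.
* A shared ancestral pool of 50 diploids evolves neutrally for 25
  generations from a linkage-equilibrium start whose minor-allele
  frequencies follow a neutral-like 1/p spectrum. The small pool and
  burn-in reproduce two features of the real system: very low diversity
  and LD persisting beyond 100 kb. The burn-in length balances LD
  build-up against drift flattening the frequency spectrum; a uniform
  spectrum would make the neutral |Δfreq| tail unrealistically heavy.
* Markers are laid down at three times the target density and, after
  burn-in, thinned back to one per 33 kb among sites still segregating,
  so the emitted panel has the intended usable-marker density. The
  scaled-down genome is 30 scaffolds of 1.5 Mb: many scaffolds keep the
  empirical top-2.5% cutoff stable across replicates.
* Each population is founded from the pool at its epidemic year, so the
  selected standing variant (pool frequency within 0.05 of 0.2) enters
  every sweep at its standing frequency. Selection is multiplicative with
  fitness (1+s) per copy of the favored allele (s = 0.5 by default),
  which reproduces the genic recursion exactly in expectation.
* Reproduction is discrete Wright–Fisher with crossover recombination
  between adjacent markers at probability min(0.5, 1e-8 per bp times the
  distance) and free recombination across scaffolds. No new mutations
  arise during the epidemic phase: over 4–6 generations selection acts on
  standing variation only.
* Sampling mirrors the study: a pre sample of up to 25 diploids at
  epidemic onset and a post stratum combining two collection years
  (6–7 generations after onset for the first population, 4–5 for the
  other two), sampled without replacement. Genotypes are masked i.i.d.
  with per-population missingness 0.31/0.44/0.36, matching per-individual
  call rates of roughly 69/56/64%.
* The gene annotation tiles 20-kb genes every 150 kb; 9.5% of genes carry
  a target GO term, which makes about a quarter of random 200-kb region
  pairs contain one — matching the observed-scale null — and target-term
  genes are placed inside the selected region.

What the generator does not emulate: locus-structured (non-i.i.d.)
missingness, genotyping error, new mutations, spatial structure within
populations, overlapping generations, and the real genome's length and
gene density. Passing calibration on these simulations shows the
statistics behave as designed under the study's sampling regime, not that
real RAD-seq artifacts are handled.

### Power of the three-population intersection

Under the default design, the scan recovers the true swept region in each
6-generation population in well over 90% of replicates, but in the
4-generation populations in roughly 75–85%, so the three-way intersection
succeeds in about half to two-thirds of runs (the acceptance script
recomputes this rate). The limit is the sweep itself, not the scan: with
Ne near 30 and four generations of s = 0.5 from a standing frequency of
0.2, the *true* allele-frequency change at the selected site exceeds a
typical neutral top-2.5% cutoff in only about two-thirds of replicates,
so even an oracle reading population frequencies directly would miss the
rest. Linked markers claw back some power, which is why per-population
hit rates sit above the single-site bound. Requiring concordance across
all replicate populations is what makes the detected regions trustworthy;
the cost is exactly this kind of power loss in the populations observed
fewest generations after epidemic arrival.

## Numerical choices and degenerate inputs

* Quantiles: mid-rank/(N+1), ties averaged after rounding to 12
  significant digits.
* EHHS truncation threshold 0.05; curves stop at scaffold ends; SNPs with
  zero iES in either stratum are excluded from Rsb and logged.
* LD pruning keeps the leftmost SNP of a violating pair (the rule only
  says one of the two goes; leftmost is deterministic).
* The scan refuses to rank fewer than 40 SNPs; quantiles of a handful of
  values are meaningless.
* Fisher combination rejects P values at or below 0, which the quantile
  convention prevents from arising.
* `adjusted_p` with s = 0 is NA and the combination is skipped, never
  treated as P = 1.
* Monomorphic SNPs or fewer than two jointly called samples make
  genotypic r-squared NA; NA pairs never trigger pruning.
* All simulation and randomization entry points take explicit seeds; the
  same configuration and seed reproduce byte-identical output files.

## Problem sizes used in the shipped checks

The test suite and acceptance script use scaled-down but structurally
faithful designs: oracle comparisons up to 32 haplotypes by 64 SNPs and
Ne 2 with three observation times; composite calibration on 100
repetitions of 2,000 windows; selection recovery on 200 replicates per
true s; Ne recovery on 100 replicates of 5,000 loci; sweep detection on
50 simulated datasets of a 45-Mb, ~1,350-marker genome; neutral false
overlap on 30–40 datasets. These sizes make the whole battery run in a
few minutes while keeping every Monte-Carlo margin well away from its
decision boundary, except where the vignette notes otherwise.

## Known limitations

* Cross-scaffold phasing effects on Rsb are not modeled; haplotype sets
  are per-scaffold.
* Rsb standardization is pooled, not frequency-binned; in panels with
  extreme frequency composition this can leave residual frequency
  dependence in the standardized scores.
* The composite statistic treats population/statistic combinations as
  independent in Fisher's combination; frequency change and Rsb at the
  same locus are not fully independent, so combined P values are
  approximate detection statistics rather than exact error rates (the
  motivating analysis reports them the same way).
* The Wright–Fisher fit conditions on a fixed, externally supplied Ne per
  population; s and Ne are not co-estimated.
* The annotation test matches labels literally and ignores the GO graph.
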