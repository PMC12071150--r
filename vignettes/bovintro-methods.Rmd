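---
title: "Methods: population-genomic scans for admixed cattle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-genomic scans for admixed cattle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

bovintro implements the statistical core of a whole-genome population study
of admixed cattle: windowed diversity and differentiation statistics, runs
of homozygosity (ROH) with automatic Gaussian-mixture length classification
and the FROH inbreeding coefficient, EHH/iHS selection scans with a
normal-tail nucleotide-diversity cutoff, and a wild-species introgression
toolkit (Patterson's D with block-jackknife Z, the U-statistic window scan,
and an incomplete-lineage-sorting length filter).  Because the real cohorts
behind such studies are hundreds of genomes, every method here is validated
on synthetic panels with planted, known truth.  This vignette explains the
models, the tunable parameters, and the design decisions.

## The synthetic cohort

`simulate_panel()` builds phased multi-population panels by a three-level
scheme:

1. **Ancestral frequencies.** Derived-allele frequencies are drawn from a
   density proportional to $1/x$ on $(p_{\min}, 1)$ (log-uniform
   inverse-CDF; `p_min = 5e-4`), the infinite-sites neutral expectation.  A
   symmetric Beta is available via `spectrum = "beta"` but produces an
   excess of intermediate-frequency variants, which biases windowed
   Tajima's D strongly positive.
2. **Population divergence.** Each population's frequencies drift from the
   ancestral values under the Balding–Nichols model with that population's
   $F$.  Deeply diverged lineages (a banteng/gaur-like donor, a
   buffalo-like outgroup) additionally receive a fraction `fixed_diff` of
   sites fixed for a private derived allele, emulating substitutions on
   the stem branch.  Pure drift from shared standing variation produces
   almost no donor-fixed/recipient-absent sites, and those sites are the
   entire signal of the U statistic.
3. **Haplotypes.** Per population, `n_founders` founder haplotypes are
   drawn site-wise from the population frequencies; each sampled haplotype
   is a founder mosaic with per-bp switch probability `switch_rate`
   (default `1e-5`, i.e. ~100 kb segments).  The finite founder pool and
   the mosaic copying generate linkage disequilibrium and EHH decay at
   trivial computational cost; no genealogies are simulated.

**What the generator does not emulate.** There is no recombination-map or
mutation-rate heterogeneity, no demographic history (bottlenecks,
expansions), and the founder pool leaves two realistic but un-tuned
signatures: windowed Tajima's D averages about +0.3 rather than 0 (founder
resampling slightly depletes rare variants), and with long mosaic segments
haplotype pairs occasionally copy the same founder over 100+ kb, creating
genuine background autozygosity.  Tests passing on these panels show the
statistics and detectors are correct and calibrated on LD-structured data;
they do not certify power on any particular real demography.

Planting functions modify panels only inside recorded truth intervals:
`plant_introgression()` copies one donor haplotype into a chosen fraction
of recipient haplotypes per tract; `plant_autozygosity()` sets one sample's
second haplotype equal to its first over an interval (perfect
autozygosity); `plant_sweep()` overwrites a fraction `carrier_freq` of
haplotypes with one core haplotype.  All operations take explicit seeds and
are reproducible to the byte.

## Windowed statistics

Windows are `[start, start + size)` in 0-based half-open coordinates,
advancing by `step` from position 0 (defaults 50 kb / 20 kb).  Empty or
data-poor windows are *flagged undefined*, never silently reported as zero.

* **θπ** per window is $\sum_s 2 p_s q_s \frac{n_s}{n_s-1}$ divided by the
  window size in bp, with $n_s$ the per-site called-haplotype count.  The
  denominator is the full window length (the VCFtools convention), not the
  callable-site count.
* **Tajima's D** uses the standard $a_1,a_2,b_1,b_2,c_1,c_2,e_1,e_2$
  constants; windows with fewer than 3 segregating sites are undefined —
  a zero would be indistinguishable from neutrality in sparse windows.
* **FST** is Hudson's ratio-of-averages estimator,
  $\sum_s [(p_1-p_2)^2 - \frac{p_1 q_1}{n_1 - 1} - \frac{p_2 q_2}{n_2-1}]
  \big/ \sum_s [p_1 q_2 + p_2 q_1]$, chosen because it is the standard
  unbiased two-population estimator; sites monomorphic for the same allele
  in both groups are excluded.  Note the finite-sample correction makes the
  estimator slightly negative when sample frequencies coincide exactly.
* **LD decay** averages haplotypic $r^2$ (direct gamete frequencies from
  phased data) in physical-distance bins.

## Runs of homozygosity

`detect_roh()` re-implements the PLINK `--homozyg` scanning-window
algorithm with the cattle-study defaults (gap 1000 kb, min length 100 kb,
min 200 SNPs, ≤1 het per 100-SNP window, hit-rate threshold 0.05):
a SNP is ROH-eligible when at least 5% of the scanning windows containing
it are homozygous; maximal eligible runs are split at gaps > 1 Mb and
filtered on SNP count and span.  Missing genotypes count as neither het nor
hom, matching PLINK.  Whether window-level het allowances also cap hets in
the final segment is left at PLINK's behaviour (they do not).

ROH detection should run on ascertained variant sites (as in a real
multi-sample VCF).  On panels that include globally monomorphic sites the
background "homozygosity" is inflated and boundaries smear outward; the
recovery study therefore subsets to polymorphic sites first.

`fit_length_mixture()` is a hand-written EM for a 3-component univariate
Gaussian mixture on log10(length) — lengths are strongly right-skewed, and
the scale is configurable (`scale = "linear"`).  Initialization is
k-means++-style center seeding; 10 restarts by default, best log-likelihood
wins, ties to the lowest restart index; variances are floored at 1e-8
(sd 1e-4) to avoid collapse.  The short/medium and medium/long boundaries
are the unique weighted-density crossings between adjacent component means
— for the between-means region this coincides with the posterior-argmax
rule that Mclust-style classifiers use, but it yields the single length
thresholds the downstream summaries need.  Classification is left-closed:
a length exactly at a boundary takes the longer class.  mclust itself is
used only as an independent cross-check in the tests.

`froh()` merges overlapping segments and divides by the autosome length;
`class_summaries()` gives per-group cumulative lengths/counts per class and
Pearson correlations of per-sample short-vs-medium and short-vs-long
cumulative lengths (undefined below 3 samples or at zero variance).

## Selection scans

**EHH** around a core allele is the probability that two random carrier
haplotypes are identical from the core out to a flanking site, computed by
exact haplotype-class counting ($\sum_h \binom{n_h}{2} / \binom{n}{2}$) in
compiled code.  Curves stop below `truncation` (default 0.05, the selscan
convention) or beyond `max_extent` (default 1 Mb).

**iHS**: iHH is the trapezoidal integral of EHH over physical distance,
both flanks, each inter-SNP gap capped at 200 kb; the unstandardized score
is $\ln(\mathrm{iHH}_A/\mathrm{iHH}_D)$.  Sites whose EHH fails to decay
below the truncation level within `max_extent` (or before the chromosome
ends) are flagged and excluded rather than integrated partially — a
truncation of 0 switches to full-extent integration with no flagging.
Ancestral alleles are known in simulation (allele 0); for real data the
orientation must come from an outgroup, or REF-as-ancestral as a documented
approximation.  Standardization subtracts the mean and divides by the SD
within derived-frequency bins (50 by default; bins under 20 sites merge
into their nearest neighbour; zero-variance bins are dropped with a
warning).

The windowed scan reports the per-window proportion of scored SNPs with
|iHS| ≥ 2; windows with fewer than 10 scored SNPs are undefined.  Candidate
windows are the top 5% by proportion, with ties broken *toward fewer*
candidates (strictly-greater-than rule), so an all-zero scan yields no
candidates.  The θπ cutoff fits a normal distribution to the window values
and takes the 1% tail quantile — the lower tail by default, because sweeps
deplete diversity; the direction is a flag.  The published wording "top 1%"
is ambiguous, and "nonoverlapping 50 kb windows with 20 kb steps" is
self-contradictory; sliding 50/20 windows are used throughout, matching the
diversity and introgression scans.  Candidate sets from the two methods are
intersected as half-open intervals; when a gene BED is supplied, genes
overlapping candidates of *both* methods are reported.  The further manual
curation step from overlap genes to a shortlist in such studies has no
stated criterion and is not implemented.

Calibration note: the per-bin |iHS| ≥ 2 fraction is checked on 10 merged
frequency bins (~800 sites each).  At ~100 sites per bin the binomial
standard error (≈0.021) exceeds the width of any meaningful band around
the normal tail expectation of 0.046, so raw 50-bin checks are noise.

## Introgression

**Patterson's D** uses the population-frequency form
$\mathrm{ABBA} = \sum (1-p_1) p_2 p_3 (1-p_O)$,
$\mathrm{BABA} = \sum p_1 (1-p_2) p_3 (1-p_O)$,
$D = (\mathrm{ABBA}-\mathrm{BABA})/(\mathrm{ABBA}+\mathrm{BABA})$, because
the study design compares populations, not single genomes.  The outgroup
polarizes: sites where the outgroup is fixed derived are flipped, sites
where it is polymorphic beyond 1% are dropped.  Standard errors come from a
delete-one block jackknife weighted by per-block informative-site counts
(Busing's weighted-jackknife variance); `Z = D/SE`.  The default block is
5 Mb and at least 20 informative blocks are required; blocks must be much
longer than the LD scale or Z inflates — with ~100 kb mosaic segments,
1 Mb blocks on a 40 Mb chromosome give a null Z SD of ≈1.0 in the
calibration study.  Identical per-block estimates leave only rounding dust
in the variance, reported as SE 0 with an infinite-Z flag.

**U scan**: a site counts toward $U_{A,B,C}(w,x,y)$ when, for the same
allele, the donor C has frequency ≥ y (default 1.0, tolerant of missing
data via called-haplotype frequencies), the control A < w (1%), and the
target B > x (20%).  Both allele orientations are checked.  Windows with
U ≥ 1 (configurable) are flagged; adjacent flagged windows merge into
candidate tracts.

**ILS filter**: under incomplete lineage sorting the expected shared-tract
length is $L = 1/(rt)$; the survival probability of a tract of length $m$
is the shape-2 gamma tail $1 - \Gamma_{\mathrm{CDF}}(m; 2, 1/L) =
(1+m/L)e^{-m/L}$.  The published cattle/banteng–gaur constant $L = 206.52$
bp is the default; $r$ and $t$ are accepted as an alternative
parameterization but have no published values of their own.  Tracts with
survival probability ≥ 0.05 are discarded; the implied minimum retained
length solves $(1+m/L)e^{-m/L} = \alpha$ by monotone root-finding
(≈ 979.7 bp at the defaults, scaling linearly in L).  The filter applies
equally to U-scan tracts or to externally supplied BED tracts; no local
ancestry inference is re-implemented.

## Pipeline and reproducibility

`run_pipeline()` executes simulate → filter → diversity → roh → selection
→ introgression from one configuration (R list or YAML), writing
per-stage TSV/BED/JSON artifacts plus a manifest with an MD5 checksum per
file and the full config snapshot; a stage failure halts the run, naming
the stage, and keeps partial outputs.  One global seed fans out to
per-stage seeds by a stable hash of the stage name, so stages can be
toggled without shifting each other's random streams, and two runs with
the same config produce byte-identical artifacts.  The site filter keeps
sites with depth within [mean/3, 3×mean] and dominance ratio (DR) > 0.9;
DR has no standard VCF encoding and travels as an opaque per-site scalar
in a TSV sidecar (the simulator writes DR = 1).

## Validation study sizes

The packaged studies (also used by `scripts/acceptance.R` and the
`analysis/` drivers) run on one CPU in minutes: ROH recovery on a 5 Mb
chromosome with 900 samples and one planted segment each (classes centred
at 0.2 / 1 / ~3.9 Mb); neutral iHS on 10 Mb × 50 diploids (~8,000 scored
SNPs, MAF 0.05); sweep recovery on 6 Mb × 50 diploids with a 200 kb,
carrier-0.9 sweep, 5 replicates; D-statistic calibration on 40 Mb × 24,000
sites with 200 null and 20 power replicates (16 × 250 kb tracts = 10%
donor ancestry); U-scan recovery on 10 Mb with five 200 kb tracts at
recipient frequency 0.3.  The demo pipeline configuration is 4 populations
× 50 diploids × 100,000 sites on 50 Mb.

## Known limitations

* The simulator's LD comes from a founder mosaic, not a coalescent;
  quantities that depend on the deep genealogy (e.g. the exact null
  distribution of Tajima's D) are only approximately neutral.
* Real-data ancestral-allele orientation for iHS, and the choice of
  jackknife block size, remain the user's responsibility; defaults are
  documented, not universal.
* FST values from the source study's smartpca runs are estimator-dependent
  and not comparable digit-for-digit with Hudson's estimator.
* Multi-chromosome inputs are handled one chromosome at a time
  (`read_vcf(region = ...)`).
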