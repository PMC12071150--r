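# bovintro

Population-genomic scans for diversity, inbreeding, selection and
wild-species introgression in admixed cattle — with a synthetic-data
generator that plants known truth so every scan is verifiable.

Whole-genome studies of indigenous cattle ask four recurring questions:
how much diversity and differentiation do the populations carry (windowed
θπ, Tajima's D, Hudson's F<sub>ST</sub>, LD decay); how inbred are they
(runs of homozygosity detected with the PLINK `--homozyg` algorithm,
length-classified by an unsupervised three-component Gaussian mixture, and
summarized as F<sub>ROH</sub> = L(ROH)/L(autosomes)); where has recent
selection acted (EHH/iHS scans with |iHS| ≥ 2 window proportions, θπ
cutoffs from the normal inverse survival function, and the intersection of
the two candidate sets); and which genomic tracts entered from wild
relatives such as banteng and gaur (Patterson's D with block-jackknife
Z scores, the U<sub>A,B,C</sub>(w,x,y) adaptive-introgression window scan
at (1%, 20%, 100%), and an incomplete-lineage-sorting filter that discards
tracts shorter than the length where (1 + m/L)e<sup>−m/L</sup> ≥ 0.05,
with L = 206.52 bp).

The real cohorts behind such studies are hundreds of genomes and cannot be
re-analysed at desk scale, so the package ships a founder-mosaic simulator
(`simulate_panel()`) producing phased multi-population panels with
realistic LD, plus planting functions for introgression tracts, autozygous
segments and selective sweeps — each emitting ground-truth tables that the
scans are scored against.

## Worked example

```r
library(bovintro)

pops <- data.frame(name = c("IND", "HN", "WILD", "OUT"),
                   n = c(20, 20, 15, 15),
                   f = c(0.025, 0.025, 0.5, 0.7),
                   fixed_diff = c(0, 0, 0.05, 0.10))
sim <- simulate_panel(sim_config(4e7, 24000, pops, seed = 1))

# plant 10% wild ancestry into the target population
pl <- plant_introgression(sim$panels$HN, sim$panels$WILD, n_tracts = 16,
                          tract_length = 2.5e5, recipient_freq = 1.0,
                          seed = 5001, donor_name = "WILD")
sim$panels$HN <- pl$panel
m <- merge_panels(sim$panels)

fr <- site_frequencies(m$panel, m$popmap, c("IND", "HN", "WILD", "OUT"))
block_jackknife(fr$freq[, 1], fr$freq[, 2], fr$freq[, 3], fr$freq[, 4],
                fr$pos, block_size = 1e6)
#> D = 0.1623 (ABBA 470.05, BABA 338.81, 20926 sites), SE 0.0356, Z 4.56 [40 blocks]
```

D > 0 with Z = 4.6 (> 3) says the target shares significantly more derived
alleles with the wild donor than its indicine sister does — exactly the
planted gene flow.  Without the planting step the same pipeline gives
Z ≈ 0 (|Z| > 3 occurred in 0 of 200 null replicates in the calibration
study).

The numbered drivers under `analysis/` run the full study on synthetic
cohorts and narrate what they find; for example `analysis/03_roh.R`:

```
Detected 900 ROH segments (900 matched to planted truth)
Max boundary error: 21253 bp (scanning window ~37400 bp)
Mixture means (log10 bp): 5.313, 5.995, 6.591
Class boundaries: 462670 bp (short/medium), 2157603 bp (medium/long)
Class accuracy vs planted labels: 100.0%
Max per-sample |FROH - planted fraction|: 0.0046
```

i.e. the three planted length classes (0.2 / 1 / ~3.9 Mb) are recovered
with boundaries inside one scanning window, classified perfectly, and
per-sample F<sub>ROH</sub> matches the planted autozygous fraction to
< 0.005.

See `vignettes/bovintro-methods.Rmd` for the models, parameter meanings
and design decisions.

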