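---
title: "Methods: analysing a three-sex-chromosome system with trisexscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing a three-sex-chromosome system with trisexscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trisexscan)
```

# The segregation model

`trisexscan` analyses species in which three sex chromosome types — W, Z and
Y — co-segregate in one population, as in the Western clawed frog. Sex is
determined by dominance: any Y makes a male; otherwise any W makes a female;
ZZ individuals are male. Two female genotypes (WW, WZ) and three male
genotypes (WY, ZY, ZZ) give six parental combinations
(`enumerate_crosses()`), and `cross_expectation()` derives each cross's
offspring distribution from equal-probability gamete union. Three crosses
(WZ×WY, WW×ZY, WW×WY) transmit the paternal Y to every son and no daughter,
so paternal variation distinguishing the father's two sex-chromosome
haplotypes is completely male-linked; two crosses (WW×ZZ, WZ×ZZ) are
completely female-linked in the same sense; and WZ×ZY is the unique
two-sex cross with a skewed (1:3 female:male) offspring ratio. YY individuals
are classified male by the same dominance rule but are never produced by
valid crosses (a YY offspring would need a sex-reversed parent, which we take
to be rare); the simulator refuses YY parents.

Gametes are drawn with equal probability. Transmission distortion is not
modelled: the segregation analysis throughout assumes Mendelian ratios, and
a distorted locus would surface in the sex-linkage scan rather than be
corrected for.

# What the simulators emulate

`sim_config()` holds every generator knob; the defaults are the study
conditions under which the package's properties are tested.

**Genome and markers.** Two chromosomes stand in for a frog-scale genome: a
133 Mb sex chromosome whose first 10.3 Mb are the sex-linked (SL) region with
the sex-determining locus at 9.94 Mb, and a 217 Mb autosome. RADtags are
placed uniformly at 1.5 tags/Mb, carrying 0–2 SNPs (probabilities
0.3/0.5/0.2); that yields roughly the post-filter marker density of a
reduced-representation study that retains one to two thousand SNPs per family
over a ~1.4 Gb genome. Restriction-site sequence composition is not modelled.

**Gametolog divergence.** Within the SL region, a fraction (0.7) of SNPs are
fixed differences diagnostic for one chromosome type. Which type differs is
drawn from per-site pattern probabilities solved from the three pairwise
divergences, `pW = (d_WZ + d_WY − d_ZY)/2` and cyclically, so all three
pairwise per-bp heterozygosities are matched exactly. Defaults `d_WZ = d_WY =
0.010`, `d_ZY = 0.002` and within-type polymorphism `5e-4` encode a Y
recently derived from a Z: Z–Y divergence is far below the divergence of
either from the W. The remaining SL SNPs, and all non-SL SNPs, are ordinary
biallelic polymorphisms with uniform(0.2, 0.8) frequencies drawn once per
site and shared by founders.

**Meiosis.** Crossover counts are Poisson with mean equal to the map length
in Morgans (no interference; the Kosambi function used downstream partially
assumes interference, a documented mismatch that is negligible at the small
per-interval fractions involved). Female crossover positions are uniform;
male positions follow a symmetric Beta(α, α) mapped to the chromosome with
α = 0.4, concentrating events near the tips — the functional form is our
choice, as only the qualitative shape is established. Defaults of 90 cM
(female) and 36 cM (male) per chromosome encode the ~2.5-fold female:male map
ratio. A parent carrying a W receives no crossovers inside the SL region
(suppression); Z–Y recombination is allowed, which is why a ZY father's SL
markers below the boundary can recombine away from the sex locus.

**Observation layer.** Depth is negative binomial (offspring mean 30,
parents four-fold higher, size 8); genotype quality is a deterministic
function of depth plus noise (GQ ≈ 4·DP, capped at 99), so the DP-15/GQ-20
filters bite together realistically. Heterozygous genotypes are miscalled as
a random homozygote with probability 0.02 (the allelic-dropout signature that
the double-recombinant masking targets), then genotypes go missing with
probability 0.03. Error injection happens after the genotype truth and
before missingness, and both masks are kept in the truth block.

**Expression.** `simulate_expression()` assigns sex effects at the gene
level (genes of 1–3 transcripts): 6% of SL genes are male-biased, 60% of
those male-specific (zero female expression), |log2FC| uniform on (2.5, 8);
1% of background genes are biased with random direction, giving the
rest-of-genome counts against which region enrichment is tested. Counts are
negative binomial (size 5) around lognormal baseline means split
symmetrically by half the logFC per sex. Per-individual heterozygosity in a
transcript is binomial over ~Poisson(50) callable bp at the divergence of
that individual's true SL genotype pair (or the within-type rate off the SL
region), matching the observed scale of ~780 SL transcripts × ~50 callable bp
per individual. Expression level and heterozygosity are simulated
independently; allele-specific expression is not modelled.

**What passing tests do not show.** The generators omit reference bias
(mapping to a W-derived reference of unknown genotype), linked selection,
shared population history between founders, crossover interference,
restriction-site dropout, and any correlation between expression level and
callable sites. Recovery of truth under these simulations demonstrates the
pipeline's statistical machinery, not robustness to those artefacts.

# Genotype quality control

`apply_qc()` applies, in a fixed, logged order: (1) mask genotypes with depth
below 15 (inclusive minimum) or genotype quality below 20; (2) drop sites
where more than 20% of offspring are missing (strict); (3) drop sites whose
offspring genotype counts fail an exact Hardy–Weinberg test at α = 0.01; (4)
drop sites where more than 10% of non-missing offspring genotypes are
impossible given both parents (strict; skipped when a parent is missing —
such sites are characteristically heterozygotes miscalled as homozygotes);
(5) thin to one seeded-random SNP per RADtag; (6) drop offspring (never
parents) with more than 20% missing genotypes, a filter that can be disabled
for small families. The cascade is idempotent under re-application.

Field practice fixes the cutoffs but not the HWE test or its level; we use
an exact test (enumeration via a numerically stable recurrence) with a
configurable α defaulting to 0.01, and note that applying HWE to F1 offspring
is conservative by design: a heterozygous-by-homozygous cross is out of HWE
in expectation, so tight α avoids discarding genuine segregation patterns.

# The sex-linkage scan

For a focal parent, informative sites are those where that parent is
heterozygous and the other homozygous; offspring genotypes are recoded to the
inherited focal-parent allele. Adjacent-marker phase is chosen to minimise
implied recombinants (ties keep the current coding). Putative genotyping
errors are then masked: within each offspring, any maximal run of identical
state flanked on both sides by the opposite state, with flank-to-flank span
at most 10 Mb, implies a double recombination in a short window and is set to
missing, iterating to a fixed point; runs touching chromosome ends are never
masked, and the window is configurable.

The association statistic is a conditional exact test on the 2×2 table of
inheritance state by phenotypic sex, two-sided by doubling the smaller
hypergeometric tail (capped at one). The doubling convention makes a
perfectly sex-linked table of five sons and seven daughters score exactly
2/C(12,5) ≈ 0.00253. A chi-squared variant is available. Benjamini–Hochberg
FDR is applied across sites within one family-by-parent scan and can be
switched off for small families.

Because fully sex-linked markers differ in p-value only through missingness,
the scan's location estimate is the *support set* of fully linked significant
markers (the span such a study reports), not the single minimum-p marker; on
simulated WW×WY families this support overlaps the true SL region in ≥95% of
replicates. Genuine linkage extends beyond the SL boundary wherever male
recombination adjacent to it is rare — that is biology, not error.

# Between-sex FST

Per-site differentiation between phenotypic females and males uses the Weir
and Cockerham (1984) two-population θ from the a/b/c variance components
(negative estimates are retained, not truncated); a Hudson-style estimator is
an option. The scan is a moving average over 50 consecutive SNPs, stepping by
one SNP, never spanning chromosomes, indexed by the median SNP position. The
reference band comes from autosomal windows in one of two modes: a bootstrap
confidence interval of the mean (B resamples, 2.5/97.5 percentiles of
resampled means) or a percentile envelope of the window values themselves —
wide genome-wide reference intervals in this kind of scan usually reflect an
envelope, so both are provided and the choice is logged. `find_peak()` returns the maximal
window, ties broken toward the smallest coordinate.

# Expression bias and region enrichment

Transcripts with a mean below one raw read per sample are discarded. TPM
normalisation divides counts by transcript length in kb and rescales each
individual to one million. The log2 male/female ratio adds a prior count of
0.125 to both means. The canonical differential-expression path consumes an
external table (transcript, logFC, FDR) from a dedicated DE engine; the
built-in fallback is a two-sided Welch t-test on log2(TPM + prior) with BH
FDR, a documented approximation; mainstream DE engines agree closely on data
of this shape, so the interface matters more than the engine.
A transcript is significantly biased when FDR < 0.05 *and* |logFC| > 2
(strict); a significant transcript is "specific" when every individual of the
minor sex has zero raw counts. Region statistics assign transcripts by start
coordinate: density is significant transcripts of the requested classes per
Mb (full precision internally, one decimal in reports), and enrichment is the
exact upper-tail binomial probability of the region's male:female split given
the rest-of-genome proportion. An enrichment ratio (region density over
rest-of-genome density) is reported without pinning it to any particular
headline multiple, since the combination behind such multiples is ambiguous.
Genotype-class subset contrasts (e.g. WW females vs WY males) run through the
identical code path.

# Nucleotide-diversity genotype inference

For a diploid, within-individual pairwise nucleotide diversity is per-site
heterozygosity: after removing genotypes with depth < 4, genotype quality
< 20 or map quality < 20, π per transcript is het/callable, and the
individual summary is site-weighted (Σhet/Σcallable) over the region's
transcripts — the transcript-averaged mean is reported alongside, since
either pooling is defensible.

Two diversity levels within a sex are detected by a largest-gap rule: the
split is accepted when the largest gap in sorted π values exceeds three times
the spread of background (non-SL) π across individuals. A cross is consistent
with the observations when it offers at least as many offspring genotypes per
sex as levels observed and the sample's sex ratio survives an exact binomial
check against the cross's expected female fraction; labels follow divergence
ordering (WZ over WW in daughters, WY over ZY in sons). When one sex shows a
single level but two genotypes are possible, the level is anchored against
the midpoint of the other sex's two level means — valid because both
W-containing pairs share the high divergence scale while Z–Y divergence sits
near the background end. If no cross, or more than one, remains consistent,
all calls abstain; inferred genotypes are hard-checked against phenotypic
sex. The Y is called Z-derived when pooled π of ZY individuals is below both
W-containing classes with bootstrap support ≥ 0.95 over 1,000 transcript
resamples (resampling transcripts, not sites, respects the within-transcript
correlation of divergence).

# Sex-specific linkage maps

Maps are built per parent from the phased, masked inheritance states in
physical marker order (marker ordering from an assembly is taken as given;
de novo grouping and ordering are out of scope). Recombination fractions are
recombinant/informative offspring per adjacent marker pair; pairs with fewer
than five informative offspring merge into the next interval. The Kosambi
function (25·ln((1+2r)/(1−2r)) cM) is the default conversion with Haldane as
an option — a convention choice, matching what mapping software typically
defaults to. Crossovers are localised to the interval between consecutive
non-missing states that flip, with the midpoint as point estimate; note that
events beyond the terminal markers of a chromosome are invisible, which
truncates observed tip densities relative to the simulated truth. Quartile
densities pool events into four equal physical bins per chromosome with tip
bias (Q1+Q4)/total. The map-length model `maplength ~ sex*family +
sex:family:bpcovered` is ordinary least squares with a separate slope of map
length on covered base pairs in every sex-by-family cell, t-based confidence
intervals, and a Shapiro–Wilk residual diagnostic.

# Numerical and testing choices

Problem sizes in the test suite are chosen for a laptop-scale run: families
of 40 offspring over two chromosomes (~450 post-thinning SNPs), population
panels of 12 females and 26 males at 8 SNPs/Mb, expression sets of 780 SL +
2,000 background transcripts across 14 individuals (nine daughters, five
sons), and batteries of 100 seeded replicates per property. Y-origin
replicates fix the family composition at 5 WZ + 4 WW daughters and 3 WY +
2 ZY sons, mirroring a family in which all four classes are observed;
with binomial genotype sampling, ~6% of such families lack a class entirely
and the method correctly abstains. All randomness flows through explicit
seeds (`withr::with_seed`), so every simulated dataset, bootstrap band and
pipeline run is byte-reproducible; coordinates are 1-based inclusive
internally (VCF convention) with BED conversion at the boundary.

# A short tour

```{r tour, eval = FALSE}
cfg <- sim_config()
fd <- simulate_family(cfg, seed = 1)
qc <- apply_qc(fd)
scan <- sex_linkage_scan(qc$dataset, "father")
head(scan[order(scan$p), ])

pop <- simulate_population(cfg, seed = 1)
fst_scan(pop$geno, pop$sites, pop$samples$sex, sex_chrom = "chr7", seed = 1)

report <- run_pipeline(run_config(seed = 1, outdir = "trisexscan_run"))
```
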