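---
title: "Mapping and dating an introgressed wing-pattern haplotype"
author: "wingscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping and dating an introgressed wing-pattern haplotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages({
  library(wingscan)
  library(GenomicRanges)
  library(S4Vectors)
})
```

# The scientific problem

Derived checker and T-check wing-shield patterns in the rock pigeon
(*Columba livia*) map to a single ~103 kb haplotype on Scaffold 68
(positions 1,702,691–1,805,600) containing a copy-number-variable
segment upstream of *NDP*. Three independent lines of evidence indicate
that this haplotype did not arise within *C. livia* but introgressed
from the speckled pigeon (*C. guinea*), a species with a checker-like
wing that diverged several million years ago yet still produces fertile
hybrids with *C. livia*:

1. **Site-pattern asymmetry.** In a four-taxon arrangement
   (P1 = bar *C. livia*, P2 = checker *C. livia*, P3 = *C. guinea*,
   O = *C. palumbus*), ABBA patterns (checker shares the derived allele
   with the donor) vastly outnumber BABA patterns inside the candidate
   region, while the genome-wide D-statistic stays near zero.
2. **Too few differences.** Checker haplotypes differ from *C. guinea*
   by far fewer nucleotide substitutions than the number expected to
   accumulate over a 4–5 MY species divergence.
3. **A young haplotype.** Extended haplotype homozygosity around the
   focal SNP decays at a rate consistent with an origin centuries, not
   megayears, ago.

`wingscan` implements the full computational chain behind these
arguments — differentiation scanning, haplotype delineation, D
statistics with moving-blocks bootstrap, triplet similarity scanning,
coalescent SNP-count dating, EHH/LD-decay age estimation, read-depth
CNV genotyping, and expression-ratio analyses — together with a
synthetic-data generator so that every stage is testable without
sequencing data.

# Data model

Phased biallelic SNPs live in a `HaplotypeMatrix` (sites × haplotypes,
codes 0/1/NA, site table as a `GRanges`); group membership and quartet
roles live in a `PopulationPanel`; read depth in a `DepthTrack`. All
coordinates are 1-based inclusive (the VCF convention, matching the
published positions); BED export converts to 0-based half-open. Indels
and multiallelic records are dropped on VCF import — every analysis
here is defined on SNP differences.

One deliberate wrinkle: inclusive arithmetic gives the minimal checker
haplotype a length of 102,910 bp, while the published analyses use the
constant 102,909. Every dating operation therefore takes the region
length `L` as an explicit argument rather than deriving it from the
region object, so the published constant can be supplied verbatim.

# Differentiation scan

The per-site test is a 1-df likelihood-ratio test on allele counts
under binomial likelihoods,

$$\Lambda = 2\left[\ell(k_1; n_1, \hat p_1) + \ell(k_2; n_2, \hat p_2)
  - \ell(k_1; n_1, \hat p) - \ell(k_2; n_2, \hat p)\right],$$

with $p$-values from $\chi^2_1$. Probabilistic scans of this family
(pFst and relatives) differ in how they handle genotype uncertainty;
with hard genotype calls, the allele-count LRT is the natural
reduction, and we make no claim of reproducing any particular tool's
per-SNP $p$-values. The genome-wide threshold is Bonferroni,
$\alpha / \#\text{sites tested}$ — consistent with a published
threshold of 9.72e-10 at $\alpha = 0.05$ over ~5.1e7 tested sites.
Significant sites closer than `mergeGap` (default 10 kb, our choice;
unspecified in the original analysis) fuse into candidate regions.

`minimalSharedHaplotype()` finds the maximal interval around a focal
position over which all carrier haplotypes are mutually identical.
Missing alleles are wildcards: only an observed 0 *and* 1 among
carriers breaks the haplotype. Bounds are exclusive of the nearest
discordant site on each side, so the resolution is limited by the local
informative-site spacing.

# D-statistics

Pattern weights use the frequency formulation
$\mathrm{ABBA} = (1-p_1)\,p_2\,p_3\,(1-p_O)$,
$\mathrm{BABA} = p_1\,(1-p_2)\,p_3\,(1-p_O)$ on derived-allele
frequencies after outgroup polarization; sites where the outgroup
carries some derived alleles keep weight $1-p_O$ rather than being
discarded. $D = (\sum \mathrm{ABBA} - \sum \mathrm{BABA}) /
(\sum \mathrm{ABBA} + \sum \mathrm{BABA})$. Windows with zero pattern
weight are flagged missing, never coerced to 0 — and the global D is
always the ratio of the summed weights, not the mean of window Ds (both
are reported, they differ). `comboMeanD()` mirrors the published
many-combination design (10 × 10 bar × checker individuals, one pair
per combination, windows averaged within combination, combinations
averaged into a grand mean). For single individuals the diploid
frequencies {0, ½, 1} are used by default; a one-haplotype-per-role
mode is available (`hapMode = "haplotype"`) since the original tool's
convention is not documented.

Confidence intervals come from a moving-blocks bootstrap whose blocks
are the windows themselves: each replicate resamples as many window
values as there are windows, with replacement, and records the mean;
the percentile interval is reported. Replicate count defaults to 1,000
and the percentile method is used — both our choices, as the original
analysis names neither.

# Triplet similarity

`tripletSimilarityScan()` restricts a bar/checker/donor triplet to
triplet-informative sites (not all three alleles equal, none missing)
and slides a window of 100 informative sites (step 1) across them,
reporting percent identity per pair. Inside an introgressed segment the
checker–donor trace rises toward 100% while bar–checker falls — the
reversal diagnostic; outside the segment the traces swap back.

# Coalescent SNP-count dating

For a pair of sequences separated by $T$ generations in a region of
$L$ bp with mutation rate $\mu$ per site per generation, the expected
number of differences is $2\mu L T$, hence
`coalescentTime(S, mu, L)` $= S/(2\mu L)$ and
`expectedSnps(T, mu, L)` $= 2\mu L T$. With $\mu =$ 1.42e-9 and
$L = 102{,}909$: a 4–5 MY divergence predicts 1169.05–1461.31
differences; the observed 26 ± 8 differences among checker haplotypes
invert to 89 ± 27 thousand years, and the 11 differences between the
checker reference and a de novo checker assembly (over the 92,199 bp
where assemblies intersect) give 42 KY. Reported "KY" assumes one
generation per year; both one- and two-generations-per-year
conversions are provided.

Group similarity at segregating sites, $100(1 - S/K)$ with
$K = 4261$ total segregating sites in the region, is reported two
ways — the mean of per-pair similarities and the similarity of the mean
count — because published group values are consistent with per-pair
averaging but differ in the second decimal from the ratio of means.

The observed-vs-expected comparison is a one-sample t-test of the
per-pair counts against the expected constant. The original methods
mention two-sample t-tests against an expectation *range*; a constant
expectation has no sampling variance, so the one-sample form is the
defensible reduction (the conclusion — observed counts differ
overwhelmingly from the interspecies expectation — is insensitive to
the choice).

`cytbDivergenceTime()` is the mitochondrial clock: 8.0% cytochrome-b
divergence at 1.96% per MY dates the *livia*–*guinea* split to
~4.08 MY, inside the 4–5 MY bracket used for the expectations above.

# EHH and LD-decay age

`ehhCurve()` computes, outward from the focal SNP (1,751,072 in the
published analysis), the probability that two randomly drawn carrier
haplotypes are identical over the whole span:
$\mathrm{EHH} = \sum_h \binom{n_h}{2} / \binom{n}{2}$ over distinct
extended haplotypes. Haplotypes with missing data anywhere in the span
leave both numerator and denominator.

Under a star genealogy (all carriers descend independently from the
founder copy), the probability that a random pair is homozygous out to
genetic distance $r$ Morgans after $g$ generations is
$\Pr[\mathrm{homoz}] = e^{-2rg}$, so

$$g = -\frac{100\,\log \Pr[\mathrm{homoz}]}{2\,r_{\mathrm{cM}}}$$

with natural log (forced by the exponential model) and the factor 100
converting centiMorgans to Morgans. The haplotype end on each side is
the first SNP where EHH drops below 0.25, and
$p = (\Pr[\mathrm{homoz}\mid\mathrm{left}] +
\Pr[\mathrm{homoz}\mid\mathrm{right}])/2$. The published boundary
quantities ($r = 0.0809$ cM, $p$ just under 0.25) give ~857
generations — 857 years at one generation per year, 429 at two.

The CI treats the number of unrecombined carriers as
$N \sim \mathrm{Binom}(n, p)$ (published analysis: $n = 22$,
$p = 0.204$) and inverts exact CDF quantiles of $N/n$ through the age
formula; quantiles are the smallest $N$ with CDF at or above the tail
probability, with no continuity correction. A zero lower quantile
leaves the upper age unbounded and is flagged. Note that this
construction puts the CI on the age given the *estimated* $p$; it does
not propagate uncertainty in the boundary placement itself, which is
one reason coverage in simulation sits below nominal (below).

# CNV genotyping and expression

Copy number is estimated as twice the ratio of mean read depth in the
CNV segment (1,790,000–1,805,600) to mean depth in a non-CNV reference
region (800,000–1,400,000) — exact scale invariance by construction —
and called to the nearest attainable diploid total {2, 3, 4, 5, 6, 8}
(sums of per-chromosome copy states 1, 2, 4), ties rounding down.

Copy–phenotype association uses pairwise Wilcoxon rank-sum tests with
Benjamini–Hochberg adjustment. The pigment regression offers both a
saturating logistic (default, fit by Levenberg–Marquardt nonlinear
least squares) and a straight line, because the original description
mentions both "non-linear least squares" and "linear regression"; the
original nonlinear model is not named, and the logistic is our choice
of saturating monotone form. qPCR expression is summarized as
$2^{-\Delta C_t}$ against the reference gene (β-actin in the original
assays), with a calibrator-relative $\Delta\Delta C_t$ option.
Allele-specific expression normalizes each bird's cDNA checker:bar
signal ratio by its gDNA ratio (controlling amplification bias) and
tests: 1- vs 4-copy classes (two-sample t), ratio-on-copies trend
(regression slope), and each class against 1:1 (Wilcoxon signed-rank;
a class whose ratios are all exactly 1 retains the null with p = 1).

# The synthetic-data generator

`simulateQuartet()` draws deep genealogies from a hand-written
structured coalescent (recipient, donor, outgroup demes; donor merges
into the recipient lineage at `TSplitDonor`, outgroup at `TOut`;
exponential waiting times between coalescences at rate
$\binom{k}{2}/2N_e$ per deme) independently for each chunk of the
focal scaffold (default 20 kb) and each unlinked background locus —
free recombination between chunks, none within. Mutations fall on
branches proportionally to length under infinite sites.

The recent pulse is a star genealogy layered on top: every carrier
haplotype in the checker group descends from a single donor haplotype
sampled `TIntro` generations ago (an ancient-sample tip in each
chunk's genealogy), keeps it intact to recombination breakpoints drawn
per side as Exp(`rho` × `TIntro`) per bp from the focal site, carries
Poisson(`mu` × span × `TIntro`) private mutations, and reverts to an
independent recipient background beyond the breakpoints. This is
exactly the generative model the EHH dating method assumes, which is
the point: the age-recovery test checks the estimator against its own
model, and real data can only be less favorable.

Parameter defaults and the reasoning behind them:

| parameter | default | units | rationale |
|---|---|---|---|
| `mu` | 1.42e-9 | /site/gen | the pigeon rate used in all dating |
| `rho` | 1.65e-8 | /site/gen | ≈1.65 cM/Mb; reproduces the ~0.08 cM focal-to-boundary scale of the published EHH analysis |
| `TIntro` | 857 | gen | the LD-decay point age |
| `TSplitDonor` | 4.5e6 | gen | middle of the 4–5 MY species divergence at 1 gen/yr |
| `TOut` | 7e6 | gen | a plausible deeper *C. palumbus* split; beyond informing polarization, deeper outgroups only add outgroup-private mutations |
| `Ne` recipient/ancestral | 2e6 | diploids | large enough that scaled-down 100 kb background windows retain incomplete lineage sorting and hence informative ABBA/BABA patterns |
| `Ne` donor | 6.5e5 | diploids | implied by the observed ~384 checker–donor differences over the region ($2\mu L \cdot 2N_e \approx 384$) |
| `nBar`/`nChecker` | 20 / 22 | haplotypes | the published panel scale (22 carrier haplotypes enter the binomial CI) |
| generation time | 1 | yr | the convention behind the printed KY values; 2 gen/yr conversions provided |

No effective population sizes are published for this system; the
values above are this package's own documented choices and are not
estimates of pigeon demography.

What the generator deliberately does **not** emulate: read-level error
and coverage heterogeneity (depth is ideal Poisson), phasing and
genotype-calling error (haplotypes are observed directly),
recombination *within* a chunk's deep genealogy (only the recent pulse
recombines, as exponential breakpoints), gene conversion, selection at
linked sites, and population growth or structure within species.
Passing recovery tests therefore demonstrates correctness of the
estimators under their intended model, not robustness to the
technical noise of a resequencing study.

`simulateDepth()` draws per-bin Poisson depth at
coverage × (copies/2) inside the CNV segment; `simulatePigmentPanel()`
puts percent dark area on a logistic curve in copy number
(ymin 10, ymax 80, steepness 0.8, inflection at 4 copies, noise SD 20 —
calibrated once so a mixed 90-bird panel fits with r² ≈ 0.5, the scale
of the published panel) truncated to [0, 100]; `simulateAse()` builds
paired gDNA/cDNA ratio panels with per-class fold changes.

# Numerical and design choices

- **Determinism.** All generators use base R's Mersenne-Twister via
  `set.seed()`; a fixed seed reproduces a byte-identical VCF. Seeds are
  part of the configuration, never hidden state.
- **LRT at equal frequencies.** Statistics within 1e-10 of zero are
  snapped to exactly zero so equal sample frequencies give p = 1.
- **Copy-call ties** (e.g. an estimate of exactly 7) round down.
- **Bootstrap** uses `quantile()` type 7 on replicate means.
- **EHH curves** stop early once all surviving haplotypes are distinct
  (EHH is identically 0 beyond) — a pure optimization with unchanged
  values — and truncate if fewer than two complete haplotypes remain.
- **Degenerate inputs** are handled explicitly rather than warned
  through: constant responses give r² = 0, zero-variance t-tests give
  t = 0 / p = 1 when the mean equals the expectation, all-equal
  bootstrap values give a degenerate CI.

# Problem sizes and observed behaviour

The test suite and the acceptance script scale the study down to sizes
a laptop handles in minutes, chosen as the smallest sizes at which the
qualitative claims are stable: null calibration uses 50 quartets of
4 + 4 recipient haplotypes over 40 × 100 kb background windows with
200 bootstrap replicates; introgression recovery uses 50 pulses at the
full 20 + 22 panel over the real region plus 150 kb flanks and
10 × 50 kb background loci; age recovery uses 50 pulses with 22
carriers and 250 kb flanks; CNV calling uses 100 depth fixtures at
20× coverage.

Under those conditions the pipeline recovers what it should: null
genome-wide D within Monte-Carlo error of zero with ~90% bootstrap CI
coverage of zero; in-region windowed D near 1 against a near-zero
background; the checker–donor similarity reversal and a single merged
significant scan region overlapping the truth tract in ≥95% of
replicates; copy calls essentially error-free. Age-recovery CI
coverage is above the 80% the tests require but below the nominal
95% — the documented cost of estimating $p$ at a data-driven boundary
and of the binomial CI ignoring boundary-placement uncertainty — and
the point age is mildly biased upward (≈ 980 generations against a
truth of 857 in a seed-1 acceptance run), consistent with EHH being
measured at discrete SNP positions at and beyond the 0.25 crossing.

# Known limitations

- The per-site LRT is an allele-count approximation to
  genotype-likelihood-aware scans; published per-SNP p-values from
  such tools are not reproducible from hard calls and are not claimed.
- The published LD-age CI bounds (267–716 years at one labelling,
  534–1,432 generations at the other) cannot be reproduced without the
  original boundary data, and their printed generation-per-year labels
  do not bracket the printed point estimate; this package reports its
  own internally consistent intervals instead.
- The star-genealogy age CI under-covers by design (see above); treat
  it as a lower bound on uncertainty.
- Windowed D on sparse windows is noisy by construction; windows with
  no pattern weight are missing, and downstream averaging ignores
  them. Interpret per-window values only through the bootstrap.
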