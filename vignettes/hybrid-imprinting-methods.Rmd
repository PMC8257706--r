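---
title: "Methods: allele-specific imprinting analysis of hybrid RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allele-specific imprinting analysis of hybrid RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aseimprint)
```

This vignette is the package's account of the model it implements, the
choices made where the design was genuinely open, and what the synthetic
data can and cannot show about real experiments.

## The experimental design being modelled

An F1 hybrid embryonic stem cell line (JF1 × B6) is differentiated towards
neural precursors in a wild-type and a mutant background lacking an
imprinting-maintenance factor. RNA-seq reads are aligned to an N-masked
reference — every strain-discriminating SNP replaced by `N`, so neither
parental allele is favoured during alignment — and each read is assigned
to a parental genome by the bases it shows at SNP positions. Gene-level
allelic ratios then classify imprinted expression per condition, and
comparing conditions identifies loss of imprinting. In parallel, bulk
counts feed a negative-binomial differential-expression analysis, and the
positions of repressor binding sites (ChIP-seq peaks) are related to the
deregulated genes through nearest-distance statistics.

Throughout the package, *genome 1* is the reference strain (B6, the
paternal allele in this cross orientation) and *genome 2* the alternate
strain (JF1, maternal). A `swap_strains` flag in the SNP readers serves
reciprocal crosses.

## Coordinates

All in-memory intervals are 1-based and closed, the native convention of
IRanges/GenomicRanges on which the interval layer is built. Conversion to
and from 0-based half-open coordinates happens only in the BED
reader/writer (via rtracklayer) and nowhere else, so there is exactly one
convention inside the package. Gene-to-peak distances are the gap in bp
between closed intervals (`GenomicRanges::distance`): overlap gives 0, a
half-open gap of *g* bp gives *g*. One consequence is that book-ended
intervals (zero-length gap) get distance 0 without overlapping; the
distance-zero set is therefore "touching or overlapping".

## Read assignment

The assigner walks each read's CIGAR (`M`, `N`, `D` advance the
reference; `I`, `S` advance the read) and looks up the read base at every
SNP position under an `M` segment. Bases equal to the genome-1 allele
count for genome 1, to the genome-2 allele for genome 2; any other base
(a sequencing error) is uninformative. A read or fragment is assigned
when exactly one genome has support, `CONFLICTING` when both do, and
`UNASSIGNED` when no SNP was covered or no base matched. Two deliberate
choices: base qualities are ignored (a deterministic rule that needs no
calibration), and a lone mismatching base leaves a read `UNASSIGNED`
rather than `CONFLICTING`, so isolated errors cannot flip a category.
Mates are combined by summing their tallies, which reproduces the natural
rules (one informative mate decides; opposing mates conflict).
Conflicting fragments are excluded from both output streams — they enter
neither allelic count, matching the convention of SNP-aware read
splitters.

PCR duplicates are removed before assignment with the conventional key
(chromosome, 5′ position, strand, mate position), keeping the first
record of each key group.

## Counting and normalization

A fragment counts for a gene when at least one aligned base overlaps the
gene's exon union, and is discarded as ambiguous when it touches the
exons of more than one gene — the default semantics of fragment-level
`featureCounts`. Genes on the X chromosome are removed first (random X
inactivation mimics imprinting), then genes whose grand total across all
samples is not strictly above 8 fragments; the order of the two filters
does not affect the result.

Size factors are median-of-ratios: with geometric mean
$g_i = (\prod_j k_{ij})^{1/n}$ per gene, sample $j$ gets
$s_j = \mathrm{median}_{i: g_i > 0}\, k_{ij}/g_i$. The median is taken on
the ratio scale (an even reference set averages the two central ratios
arithmetically). Because both parental alleles of a sample come from the
same library, maternal and paternal counts are divided by the *bulk*
size factor of their sample; the within-sample allelic ratio is exactly
invariant under this normalization. Genes then need at least 10
normalized allelic counts (maternal + paternal) in at least one
wild-type replicate.

Marker Z-scores divide each sample by the upper quartile of its nonzero
counts, then by the adjusted value of a housekeeping reference gene
(beta-actin in the motivating design), and standardise each gene across
samples with the sample (n−1) standard deviation — at two samples every
non-constant gene is ±1/√2. Genes constant after adjustment get a zero
row with a warning.

## Allelic classification and imprinting loss

The allelic ratio of a replicate is $r = m/(m+p)$ on normalized counts;
replicates with no allelic counts are excluded from the mean rather than
averaged as zero. Ratios at or below 0.33 are paternal, at or above 0.67
maternal — the boundaries are monoallelic, following the ≤/≥ convention
of the classification bands. The imbalance test pools **raw** integer
counts across replicates (a proportion test needs integers; the shared
divisor cannot change a within-sample proportion) and doubles the
smaller exact binomial tail, capped at 1; a chi-square variant with
continuity correction is available by flag since the exact engine choice
was an open question. By default significance gates nothing; with
`require_significance = TRUE` (the wild-type convention of the motivating
study) monoallelic calls additionally need BH-adjusted q < 0.05. The
mutant condition is classified by interval only, since only wild-type
testing is part of the original design.

Between conditions, a wild-type monoallelic gene is `BIALLELIC_IN_MUTANT`
when its mutant ratio falls strictly inside (0.33, 0.67);
`BIAS_INVERTED` when the bias crosses 0.5 by more than δ;
`BIAS_REDUCED` when it stays monoallelic in the same direction but moves
at least δ closer to 0.5; otherwise `UNCHANGED`. δ = 0.1 by default —
no numeric criterion exists for "reduced", so the margin is configurable
and documented rather than hidden.

## Differential expression

The DE engine is a deliberately simplified NB Wald test: per gene,
$\mu_{ij} = s_j q_i 2^{\beta_i x_j}$ with Var $= \mu + \alpha\mu^2$, no
outlier refitting, no independent filtering, no fold-change shrinkage.
Equivalence with any full-featured tool is not claimed; the engine is
validated on its simulation properties (type-I error, fold-change
recovery, consistency) and cross-checked loosely against an established
NB implementation in the test suite.

Dispersion estimation is the part that matters at two or three
replicates, and three numerical choices are deliberate:

* the raw per-gene estimate is method-of-moments from the pooled
  within-group variance with df = n − groups;
* the trend $\alpha(\mu) = a_0 + a_1/\mu$ is fitted by least squares on
  **all** finite raw estimates (one 5-MAD trimming pass for outliers).
  Truncating at zero or robust median-type fitting looks safer but pulls
  the trend systematically below the true dispersion — the raw estimator
  is unbiased yet right-skewed — which visibly inflates the Wald test;
* gene-wise estimates are shrunk towards the trend in log space with
  prior weight trigamma(df/2)/0.04, i.e. the chi-square sampling variance
  of a log dispersion against a fixed prior variance of 0.04. At n = 3+3
  this pools strongly (the per-gene likelihood is weak); at n = 20+20 the
  gene-wise estimate dominates. Dispersions are floored at 1% of the
  trend.

With these choices the null type-I error at p < 0.05 sits between 0.038
and 0.061 across independent 2,000-gene null simulations (nominal band
0.035–0.065), a planted log₂ fold change of 2 at n = 3+3 is recovered
with bias under 0.1, and at n = 20+20 the bias is below 0.01. Genes with
all-zero counts in both groups report log₂FC 0 and p = 1; coefficients
are clamped at ±30 on the natural-log scale so one-group-zero genes
cannot diverge.

The enrichment universe for the hypergeometric test is the set of genes
that survived the expression filter — the population actually tested —
with the imprinted-gene list supplied as input; whether the original
analysis used all annotated genes instead is unknown, so no numerical
claim is tied to that choice.

## Distance statistics

Peak intersection uses first-set semantics (members of set A with ≥1 bp
overlap in set B, each reported once); merged overlap fragments are
available by flag since the published "overlapping peaks" count could be
read either way. Gene anchors are full gene spans, not TSSs, matching
nearest-feature behaviour on gene records. Genes on peak-free
chromosomes get `NA` and are excluded from the CDFs, as cross-chromosome
"closest" is undefined. The KS p-value is asymptotic (effective size
$n_1 n_2/(n_1+n_2)$, Kolmogorov series truncated at 100 terms, exact at
machine precision for any realistic λ); sample sizes in this analysis
are in the tens to hundreds, where the asymptotic form is adequate, and
no small-sample permutation is implemented — a documented limitation.

## The simulator

`sim_config()` encodes the study-like conditions: 2 × 125 bp paired-end
fragments, 4.5 SNPs per kb between the strains (the JF1/B6 divergence is
above 4/kb), two biological replicates per condition, maternal/paternal
true allelic fractions of 0.95/0.05 and 0.5 for biallelic genes, NB
counts with Var = μ + αμ² (α = 0.05 by default, gene means log-normal
around 200), library-size factors spanning 0.8–1.25, a configurable
fraction (default half) of imprinted genes losing imprinting (ρ → 0.5)
in the mutant, and per-base sequencing errors at 10⁻³. Gene class
proportions default to 70% biallelic / 15% maternal / 15% paternal so
that a 60-gene simulation carries enough imprinted genes to test against;
real transcriptomes have far fewer imprinted genes proportionally, which
affects no per-gene statistic.

Totals are NB; the maternal count is binomial in the total at the true
ρ, so maternal + paternal = bulk holds by construction. Genes are
single-exon and non-overlapping, which isolates the counting logic (an
ambiguity fixture is constructed directly in the tests); a `spliced`
flag emits M–N–M first mates to exercise the intron gap in the CIGAR
walk. Imprinted genes cluster at the left end of each chromosome and
control genes at the right, separated by a buffer wider than the
far-peak distance, so peaks placed within 50 kb of imprinted genes are
guaranteed to be ≥1 Mb from every control gene — the clustered
arrangement of imprinted loci around their control regions, reduced to
its essential geometry.

What the simulator does **not** emulate: isoforms and overlapping
transcription, GC and positional bias, intronic/intergenic reads,
alignment errors (reads are emitted as already-aligned SAM), beta-binomial
overdispersion of allelic fractions between replicates, and any coupling
between imprinting loss and expression change (fold changes are planted
independently of class). Passing tests therefore demonstrate the
correctness of the pipeline's logic and the calibration of its
statistics under the stated model — not robustness to the full
messiness of real libraries.

Every simulator stage seeds its own RNG substream deterministically from
`seed`, so all outputs are byte-reproducible for a given configuration.

## Problem sizes used by the tests

The suite validates the read assigner against a brute-force
CIGAR-expansion oracle on 10,000 mixed-shape reads, interval operations
against quadratic scans at 500 intervals per set, the KS statistic
against exhaustive ECDF evaluation on 100 random sample pairs, the
classifiers on 450-gene three-class simulations with ≥100× allelic
coverage, null calibration on 2,000-gene simulations, and the end-to-end
loss-of-imprinting recovery on a 100-gene study with 10 planted
imprinted genes. These sizes give Monte-Carlo standard errors small
enough for the stated tolerance bands while keeping the whole suite in a
few minutes.

## Known limitations

* Indels are excluded from SNP tables entirely; indel-aware masking and
  assignment are out of scope.
* No multi-mapper handling or quality recalibration; input is assumed
  uniquely aligned.
* The proportion test ignores replicate-level overdispersion of the
  allelic fraction (beta-binomial modelling is a possible extension).
* The DE engine's strong dispersion pooling at two replicates trades
  per-gene dispersion resolution for calibration; genes with genuinely
  outlying dispersion are tested at the trend's scale.
* Distances and the KS comparison inherit the chromosome-local
  definition of "closest"; genes on peak-free chromosomes are silently
  excluded from the comparison.
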