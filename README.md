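# aseimprint

Allele-specific expression (ASE) and genomic-imprinting analysis for
RNA-seq of F1 hybrid mouse cells, built as a reusable, fully tested R
pipeline.

## The problem

In an F1 hybrid cross such as JF1 × C57BL/6 (B6), the two parental genomes
differ at millions of SNPs (more than 4 per kb), so RNA-seq reads covering
a SNP can be assigned to the maternal (JF1) or paternal (B6) allele.
Comparing the allelic balance of each gene between wild-type cells and
cells lacking an imprinting-maintenance factor (e.g. the KRAB zinc-finger
protein ZFP57) reveals which genes *lose imprinting*: genes monoallelic in
the wild type that become biallelic, or shift their bias, in the mutant.
This package implements every computational stage of that analysis for
anyone running hybrid-cross ASE experiments:

1. **genomes** — parse and intersect strain SNP tables (VCF or TSV), build
   an N-masked reference (`N` at every SNP) for unbiased alignment.
2. **allele_split** — remove PCR duplicates and assign each aligned
   read/fragment to a parental genome by walking its CIGAR over the SNPs.
3. **quantify** — count fragments per gene (bulk and per allele), filter
   low-expression genes and the X chromosome, estimate median-of-ratios
   size factors, normalize allelic counts with the *same* per-sample
   factor, and compute marker Z-scores (upper-quartile + housekeeping-gene
   adjusted).
4. **ase** — allelic ratios, exact proportion tests with
   Benjamini–Hochberg correction, imprinting classification, and
   loss-of-imprinting calls between conditions.
5. **de_integration** — a simplified negative-binomial Wald test for
   differential expression, hypergeometric enrichment of imprinted genes,
   and the integration table joining allelic and global changes.
6. **peaks** — interval intersection, gene-to-binding-site distances, and
   the two-sample Kolmogorov–Smirnov comparison of distance
   distributions.
7. **synthetic_data** — a truth-tagged simulator of the whole experiment
   (genomes, SNPs, paired-end SAM, NB counts, peaks), so every stage is
   testable offline against known truth.

## The statistics

For gene *i* with normalized maternal and paternal counts *m*, *p* the
allelic ratio is *r* = *m* / (*m* + *p*) (JF1 / (B6 + JF1)); the mean over
replicates classifies the gene as **paternal** when *r* ≤ 0.33,
**maternal** when *r* ≥ 0.67, biallelic otherwise. Allelic imbalance is
tested on raw pooled counts with an exact binomial proportion test
(two-sided tail doubling, H₀: proportion 0.5), BH-adjusted across genes.
Bulk counts follow the NB model μ<sub>ij</sub> = s<sub>j</sub> q<sub>i</sub>
2^(β<sub>i</sub> x<sub>j</sub>) with Var = μ + αμ²; dispersions are
estimated by method of moments, pooled towards a parametric trend
α(μ) = a₀ + a₁/μ, and β̂ (the log₂ fold change) with its standard error
comes from iteratively reweighted least squares, giving a Wald p-value.
Gene-to-peak distance is 0 for overlap, otherwise the gap in bp to the
nearest peak on the same chromosome; distance distributions are compared
with the two-sample KS statistic D = sup |F̂₁ − F̂₂| and the asymptotic
Kolmogorov p-value at effective size n₁n₂/(n₁+n₂).

## Worked example

The analysis scripts run the whole study on synthetic data with known
truth:

```sh
Rscript analysis/01_simulate.R       # genomes, SNPs, SAM, counts, peaks
Rscript analysis/02_allele_split.R   # dedupe + parental-genome split
Rscript analysis/03_quantify_ase.R   # counting, normalization, ASE calls
Rscript analysis/04_de_integration.R # DE, enrichment, integration table
Rscript analysis/05_peak_distance.R  # distances + KS comparison
```

Step 2 prints the fragment partition and its truth agreement:

```
fragment partition:
         g1          g2  unassigned conflicting       total
       5314        7076        5732           4       18126
truth agreement of informative fragments: 0.9999 (n = 12390)
```

`g1`/`g2` are fragments assigned to the paternal (B6) and maternal (JF1)
genome, `unassigned` fragments covered no informative SNP, and the four
`conflicting` fragments carry simulated sequencing errors; 99.99% of
informative fragments land on their true genome of origin. Step 3 then
recovers every planted imprinted gene:

```
wild-type allelic classes:
BIALLELIC  MATERNAL  PATERNAL
       50         7         3
imprinted-gene recall 1.00, precision 1.00
```

and step 5 shows the spatial association between imprinted genes and
binding-site peaks:

```
distance medians: imprinted 2398 bp, control 1035618 bp
two-sample KS: D = 1.000, p = 1.16e-07 (n = 10 vs 50)
```

All tables land under `results/`.

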