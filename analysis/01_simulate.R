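#!/usr/bin/env Rscript
# Step 1 — generate the synthetic hybrid-cross study.
#
# Emits a complete truth-tagged dataset for an F1 hybrid ESC/NPC-style
# experiment: a two-chromosome reference genome, ~4.5 strain SNPs per kb,
# 60 single-exon genes (15% maternally, 15% paternally expressed, half of
# the imprinted ones losing imprinting in the mutant), NB counts for
# 2 wild-type + 2 mutant replicates, 20,000 truth-tagged paired-end
# alignments of the first wild-type sample, and binding-site peaks placed
# near the imprinted genes.

suppressMessages(library(aseimprint))

out <- "results/simulated_study"
cfg <- sim_config(seed = 20260923L)
sim <- write_simulation(cfg, out, n_fragments = 20000)

cat("simulated study written to ", out, "\n", sep = "")
cat("  chromosomes:", length(sim$genomes$genome),
    "x", unique(Biostrings::width(sim$genomes$genome)), "bp\n")
cat("  SNPs:", nrow(sim$genomes$snps),
    sprintf("(%.2f per kb)\n",
            1000 * nrow(sim$genomes$snps) /
              sum(Biostrings::width(sim$genomes$genome))))
print(table(sim$truth$class))
cat("  imprinted genes losing imprinting in mutant:",
    sum(sim$truth$loses_imprinting), "\n")
cat("  alignments:", nrow(sim$alignments), "records,",
    nrow(attr(sim$alignments, "fragments")), "fragments\n")

# the N-masked reference used for unbiased allele-aware alignment
masked <- mask_genome(sim$genomes$genome, sim$genomes$snps)
write_genome(masked, file.path(out, "reference_nmasked.fa"))
n_masked <- sum(Biostrings::letterFrequency(masked, "N"))
cat("  N-masked genome written (", n_masked, " positions masked)\n", sep = "")
stopifnot(n_masked == nrow(sim$genomes$snps))
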