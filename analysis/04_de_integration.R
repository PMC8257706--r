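#!/usr/bin/env Rscript
# Step 4 — differential expression between mutant and wild type, imprinted
# gene enrichment among the DE genes, and the integration table joining
# wild-type allelic class, mutant transition and global expression change.

suppressMessages(library(aseimprint))

dir <- "results/simulated_study"
truth <- data.table::fread(file.path(dir, "truth_genes.tsv"))
read_counts <- function(layer) {
  d <- data.table::fread(file.path(dir, paste0("counts_", layer, ".tsv")))
  m <- as.matrix(d[, -1]); rownames(m) <- d$gene_id; m
}
bulk <- read_counts("bulk"); mat <- read_counts("mat"); pat <- read_counts("pat")
res <- run_ase_pipeline(bulk, mat, pat,
                        wt_sample_ids = c("wt1", "wt2"),
                        mut_sample_ids = c("mut1", "mut2"))

de <- res$de
n_sig <- sum(de$padj < 0.05, na.rm = TRUE)
cat(n_sig, "of", nrow(de), "genes differentially expressed (padj < 0.05)\n")
data.table::fwrite(de, "results/04_differential_expression.tsv", sep = "\t")
cat(sprintf("fold-change recovery on planted DE genes: mean |err| = %.3f\n",
            mean(abs(de$log2_fc - truth$log2_fc[match(de$gene_id,
                                                      truth$gene_id)]),
                 na.rm = TRUE)))

# enrichment of (truth-)imprinted genes among the DE genes, universe =
# genes that passed the expression filter. The default generator plants
# fold changes independently of imprinting class, so this is a null
# sanity check of the operation: p should be unremarkable here, unlike in
# a real cross where imprinting loss and expression change are coupled.
imprinted <- truth$gene_id[truth$class != "biallelic"]
universe <- de$gene_id
de_genes <- de$gene_id[de$padj < 0.05 & !is.na(de$padj)]
k <- sum(de_genes %in% imprinted)
p_enr <- hypergeom_enrichment(k, sum(universe %in% imprinted),
                              length(de_genes), length(universe))
cat(sprintf("imprinted among DE: %d/%d (universe %d, imprinted %d) p = %.3g\n",
            k, length(de_genes), length(universe),
            sum(universe %in% imprinted), p_enr))

tab <- res$integration
cat("integration table (wild-type imprinted genes):\n")
print(tab[, c("gene_id", "wt_allelic_class", "mut_transition",
              "global_change")])
data.table::fwrite(tab, "results/04_integration_table.tsv", sep = "\t")
loi <- truth[truth$loses_imprinting == TRUE]
m <- merge(tab, loi, by = "gene_id")
cat(sprintf("planted imprinting-loss genes called biallelic in mutant: %d/%d\n",
            sum(m$transition == "BIALLELIC_IN_MUTANT"), nrow(loi)))
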