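#!/usr/bin/env Rscript
# Step 5 — binding-site distance analysis: distance of every gene to its
# nearest peak, the near-threshold gene set, and the two-sample
# Kolmogorov-Smirnov comparison of imprinted vs control distance
# distributions.

suppressMessages(library(aseimprint))

dir <- "results/simulated_study"
truth <- data.table::fread(file.path(dir, "truth_genes.tsv"))
models <- read_gene_models(file.path(dir, "genes.gtf"))
peaks <- read_peaks(file.path(dir, "peaks.bed"))

d <- nearest_peak_distance(models, peaks)
d <- merge(d, truth[, c("gene_id", "class")], by = "gene_id")
data.table::fwrite(d, "results/05_gene_peak_distances.tsv", sep = "\t")

cfg <- ase_config()
near <- within_distance(d, cfg$distance_threshold_bp)
cat(length(near), "genes within", cfg$distance_threshold_bp / 1000,
    "kb of a peak;",
    sum(truth$class[match(near, truth$gene_id)] != "biallelic"),
    "of them are imprinted\n")

imp <- d$distance_bp[d$class != "biallelic"]
ctl <- d$distance_bp[d$class == "biallelic"]
cat(sprintf("distance medians: imprinted %.0f bp, control %.0f bp\n",
            median(imp, na.rm = TRUE), median(ctl, na.rm = TRUE)))
ks <- ks_two_sample(imp, ctl)
cat(sprintf("two-sample KS: D = %.3f, p = %.3g (n = %d vs %d)\n",
            ks$D, ks$p_value, ks$n_x, ks$n_y))

ec <- rbind(cbind(ecdf_points(imp), group = "imprinted"),
            cbind(ecdf_points(ctl), group = "control"))
data.table::fwrite(ec, "results/05_distance_ecdf.tsv", sep = "\t")

# peak-set intersection demo on two offset copies of the peak set
half <- peaks[seq(1, length(peaks), by = 2)]
shifted <- GenomicRanges::shift(peaks, 150L)
cat(length(intersect_peaks(half, shifted)), "of", length(half),
    "peaks overlap a 150 bp-shifted copy of the full set\n")
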