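#!/usr/bin/env Rscript
# Unsupervised structure: (i) complete-linkage clustering of samples with
# Pearson-correlation distance on the stratum-modulated miRNAs, checked
# against the planted strata; (ii) four-archetype classification of the
# FAP/MP x TGFb1 design; (iii) the intersection of stratum-modulated and
# archetype miRNA sets.

suppressMessages(library(fibromiR))

counts <- as.matrix(read.delim("results/data/cohort_counts.tsv",
                               row.names = 1, check.names = FALSE))
samples <- read.delim("results/data/cohort_samples.tsv")
de_strata <- read.delim("results/de_high_vs_low.tsv")
dcounts <- as.matrix(read.delim("results/data/design_counts.tsv",
                                row.names = 1, check.names = FALSE))
dsamples <- read.delim("results/data/design_samples.tsv")
dtruth <- read.delim("results/data/design_mirna_truth.tsv")

mod <- de_strata$mirna_id[de_strata$padj < 0.05 & abs(de_strata$log2FC) >= 1]
z <- zscore_rows(normalized_log2(counts)[mod, , drop = FALSE])
hc <- hac_complete(z, axis = "cols")
cl <- cutree(hc, k = 2)
clusters <- data.frame(sample_id = names(cl), cluster = unname(cl))
write.table(clusters, "results/sample_clusters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

agree <- table(cluster = cl, class = samples$latent_class)
cat("sample clusters vs planted class:\n")
print(agree)

cm <- condition_means(dcounts, dsamples$condition)
calls <- classify_archetypes(cm)
write.table(calls, "results/archetypes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
conf <- table(truth = dtruth$class, call = calls$class)
cat("archetype confusion (planted vs called):\n")
print(conf)

venn <- intersect_modulated(mod,
                            calls$mirna_id[calls$class != "unclassified"])
write.table(venn$membership, "results/venn_membership.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("set intersection: %d stratum-only, %d shared, %d archetype-only\n",
            venn$n_a_only, venn$n_both, venn$n_b_only))
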