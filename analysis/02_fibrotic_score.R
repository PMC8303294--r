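#!/usr/bin/env Rscript
# Score every sample from its COL1A1/FN1/ACTA2 relative expression,
# stratify at the 0.25 threshold, and select the fibrosis miRNA signature
# (top 25 miRNAs with Pearson r > 0.5 against the score).

suppressMessages(library(fibromiR))

markers <- read.delim("results/data/cohort_markers.tsv")
samples <- read.delim("results/data/cohort_samples.tsv")
counts <- as.matrix(read.delim("results/data/cohort_counts.tsv",
                               row.names = 1, check.names = FALSE))
truth <- read.delim("results/data/cohort_mirna_truth.tsv")

ann <- annotate_fibrosis(markers, groups = samples$group)
write.table(ann, "results/fibrosis_annotation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

dmd <- ann$group == "DMD"
cat(sprintf("fibrotic scores: %.2f-%.2f; DMD split %d Low / %d High\n",
            min(ann$score), max(ann$score),
            sum(ann$stratum[dmd] == "Low"), sum(ann$stratum[dmd] == "High")))

sig <- select_signature(correlate_with_score(normalized_log2(counts), ann))
write.table(sig, "results/signature.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

sel <- sig$mirna_id[sig$selected]
planted <- truth$mirna_id[truth$class == "fibromiR"]
cat(sprintf("signature: %d miRNAs selected (r > 0.5, k = 25); %d/%d planted fibromiRs recovered\n",
            length(sel), sum(planted %in% sel), length(planted)))
cat(sprintf("best correlate: %s (r = %.3f)\n",
            sig$mirna_id[which.min(sig$rank)], max(sig$r, na.rm = TRUE)))
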