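#!/usr/bin/env Rscript
# Generate the two synthetic datasets used throughout the analysis:
# (i) a biopsy cohort (3 control + 8 dystrophic samples) whose latent
# fibrosis level drives three marker genes and planted fibromiR/myomiR
# sets, and (ii) a 2x2 FAP/MP x TGFb1 design with four planted profile
# archetypes. Everything downstream reads the TSVs written here.

suppressMessages(library(fibromiR))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260930

cohort <- simulate_cohort(seed = seed)
design <- simulate_design(seed = seed + 1)

write_mat <- function(m, path, id = "mirna_id") {
  df <- data.frame(id = rownames(m), as.data.frame(m), check.names = FALSE)
  names(df)[1] <- id
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
write_mat(cohort$counts, file.path(out, "cohort_counts.tsv"))
write.table(cohort$markers, file.path(out, "cohort_markers.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cohort$samples, file.path(out, "cohort_samples.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cohort$mirnas, file.path(out, "cohort_mirna_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_mat(design$counts, file.path(out, "design_counts.tsv"))
write.table(design$samples, file.path(out, "design_samples.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(design$mirnas, file.path(out, "design_mirna_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf(
  "cohort: %d miRNAs x %d samples (%s); planted %d fibromiRs, %d myomiRs\n",
  nrow(cohort$counts), ncol(cohort$counts),
  paste(table(cohort$samples$group), collapse = " control / "),
  sum(cohort$mirnas$class == "fibromiR"),
  sum(cohort$mirnas$class == "myomiR")
))
cat(sprintf("design: %d miRNAs x %d samples across %s\n",
            nrow(design$counts), ncol(design$counts),
            paste(unique(design$samples$condition), collapse = ", ")))
cat("written to", out, "\n")
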