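#!/usr/bin/env Rscript
# Seed-site scanning in the style of a 3'UTR target analysis: scan a
# synthetic UTR carrying planted miR-214-3p sites, then knock the
# validated-site analogue out by point mutations and rescan. The UTR is
# synthetic (a real FGFR1 3'UTR sequence is not bundled); site coordinates
# follow the 1-based inclusive convention of printed intervals.

suppressMessages(library(fibromiR))

mir214_3p <- "ACAGCAGGCACAGACAGGCAGU"  # mature hsa-miR-214-3p, 5'->3'

planted <- data.frame(position = c(120, 450, 900, 1887),
                      site_type = c("7mer-A1", "6mer", "7mer-m8", "7mer-m8"))
utr <- simulate_utr_sites(2100, mir214_3p, planted, seed = 20260930)
dir.create("results", showWarnings = FALSE)
write_fasta(c(synthetic_FGFR1_3UTR = utr$sequence),
            "results/synthetic_utr.fa")

sites <- seed_sites(mir214_3p, utr$sequence, utr_id = "synthetic_FGFR1_3UTR")
write.table(sites, "results/seed_sites.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(sites_to_bed(sites), "results/seed_sites.bed", sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)
cat(sprintf("%d sites found:\n", nrow(sites)))
print(sites)

# mutate three bases inside the 1887 site and rescan
res <- mutate_and_rescan(mir214_3p, utr$sequence,
                         data.frame(position = c(1888, 1890, 1892),
                                    base = c("A", "A", "A")),
                         utr_id = "synthetic_FGFR1_3UTR")
cat(sprintf("after mutating the 1887 site: %d lost, %d gained\n",
            nrow(res$lost), nrow(res$gained)))
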