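# fibromiR

Fibrosis in Duchenne muscular dystrophy (DMD) muscle is driven by
fibro-adipogenic progenitors (FAPs) that differentiate into myofibroblasts
under TGFβ1, and this program is mirrored in the muscle's microRNA
repertoire: "fibromiRs" rise with fibrosis while muscle-enriched "myomiRs"
fall. `fibromiR` is an R toolkit for the computational side of such a
study: it scores the fibrotic state of biopsies from three marker genes,
relates the miRNome to that score, contrasts FAP and myogenic-progenitor
(MP) miRNA profiles under TGFβ1, and scans 3′UTRs for miRNA seed-match
sites. It is aimed at transcriptomics analysts working with small-RNA
count matrices and qPCR panels.

All stages are exercised on seeded synthetic data with known planted
structure, so every claim the package makes is testable without access to
the original sequencing data.

## Methods at a glance

**Fibrotic score.** Each sample s is scored from the relative expression
of COL1A1, FN1 and ACTA2:

    FS(s) = 1/3 [ Exp_s(COL1A1)/ExpMax(COL1A1)
                + Exp_s(FN1)/ExpMax(FN1)
                + Exp_s(ACTA2)/ExpMax(ACTA2) ]

with ExpMax the per-marker cohort maximum, so FS ∈ (0, 1]. Samples with
FS > 0.25 are stratified "High", the rest "Low".

**Differential expression.** Median-of-ratios size factors; per-miRNA
method-of-moments NB dispersion α (variance = μ + αμ²); a conditional
exact test on the summed normalized counts of the two groups (the
two-sided p-value sums all split probabilities not exceeding the observed
one); Benjamini–Hochberg FDR.

**Signature and clustering.** miRNAs are ranked by the Pearson
correlation of log2 normalized expression with the fibrotic score; the
signature is the top 25 with r > 0.5. Samples and miRNAs are clustered by
complete linkage on the 1 − r Pearson distance of Z-scored log2 profiles.

**Archetypes.** FAP/MP ± TGFβ1 profiles are classified by cell-type
enrichment (log2 FAP/MP) and TGFβ1 response in the enriched cell type:
C1 (MP-enriched, repressed), C2 (MP-enriched, unresponsive),
C3 (FAP-enriched, repressed), C4 (FAP-enriched, induced).

**qPCR.** Comparative-CT quantification: relative expression 2^−ΔCt
against a reference gene, fold changes 2^−ΔΔCt on per-arm mean ΔCt.

**Seed scanning.** Canonical TargetScan site classes (8mer, 7mer-m8,
7mer-A1, 6mer) by perfect Watson–Crick complementarity to the miRNA seed
(nt 2–8), 1-based inclusive coordinates on the UTR sense strand.

## Worked example

The numbered drivers under `analysis/` run the whole study-shaped
analysis on synthetic data (`Rscript analysis/01_simulate.R`, then 02–06).
On the default seeds they print:

```
fibrotic scores: 0.12-1.00; DMD split 3 Low / 5 High
signature: 25 miRNAs selected (r > 0.5, k = 25); 20/20 planted fibromiRs recovered
DMD vs control: 0/300 miRNAs modulated (padj < 0.05, |log2FC| >= 1)
High vs Low stratum: 29/300 miRNAs modulated (padj < 0.05, |log2FC| >= 1)
```

The 3 Low / 5 High split is the planted cohort structure recovered from
the marker panel alone. The stratum contrast, not the pooled DMD-vs-control
contrast, carries the differential signal: mixing low- and high-fibrotic
biopsies in one group inflates the within-group dispersion estimate
(see the methods vignette). Clustering the samples on those 29 modulated
miRNAs separates the strata exactly, and the archetype rules recover all
four planted FAP/MP profile classes without error. The seed scanner run
(`analysis/05_seed_scan.R`) reports, on a synthetic UTR:

```
                utr_id start  end site_type site_seq
4 synthetic_FGFR1_3UTR  1887 1893   7mer-m8  CCTGCTG
after mutating the 1887 site: 1 lost, 0 gained
```

i.e. a miR-214-3p site at 1887–1893 destroyed by three point mutations,
and `analysis/06_qpcr.R` recovers planted 2-, 3- and 10-fold marker
inductions from simulated Ct tables.

Equivalent one-call orchestration is available as
`run_pipeline(list(seed = 4), out_dir = "out")`, which writes all stage
TSVs plus a machine-readable `report.json`.

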