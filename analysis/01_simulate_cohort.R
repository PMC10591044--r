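#!/usr/bin/env Rscript
# Stage 1: simulate the default two-arm cohort (15 WT controls with a flat
# mutational background, 15 CAG-A3B-like tumors with SBS2-dominant mixtures,
# early-replication bias, ES-coupled indel and SV loads) and write its
# reference genome, timing track, per-sample VCFs and truth ledgers.
#
# Usage: Rscript analysis/01_simulate_cohort.R [seed]

suppressMessages(library(apobecsig))
seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L
outdir <- "results/cohort"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- default_config(seed)
cohort <- simulate_cohort(cfg)

write_genome_fasta(cohort$genome, file.path(outdir, "genome.fa"))
write_timing_bedgraph(cohort$timing, file.path(outdir, "timing.bedgraph"))
for (sid in names(cohort$samples)) {
  smp <- cohort$samples[[sid]]
  write_somatic_vcf(smp$variants, file.path(outdir, paste0(sid, ".vcf")),
                    genome = cohort$genome, sample_name = sid,
                    sv_records = smp$sv_records)
  write_truth_ledger(smp$ledger, file.path(outdir, paste0(sid, ".truth.json")))
}
sheet <- data.frame(sample_id = names(cohort$samples),
                    group = vapply(cohort$samples, `[[`, "", "group"),
                    vcf = paste0(names(cohort$samples), ".vcf"))
write.table(sheet, file.path(outdir, "sample_sheet.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Simulated", length(cohort$samples), "samples on a",
    format(sum(nchar(cohort$genome$contigs)), big.mark = ","), "bp genome;",
    "outputs in", outdir, "\n")
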