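#!/usr/bin/env Rscript
# Stage 3: APOBEC TCW enrichment scores. Applies the four enrichment
# exclusions (SBS only, C:G reference pairs, no chrM, no C>A / G>T), runs
# the 41-base window census, one-sided exact test, cohort-wide BH
# adjustment, and ES_high / ES_low stratification at q < 0.1.
#
# Run after 02_filter_and_spectra.R.

suppressMessages(library(apobecsig))
indir <- "results/cohort"
outdir <- "results/enrichment"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

genome <- read_genome_fasta(file.path(indir, "genome.fa"))
index <- genome_context_index(genome)
sheet <- read.delim(file.path(indir, "sample_sheet.tsv"))

kept <- list()
for (i in seq_len(nrow(sheet))) {
  sid <- sheet$sample_id[i]
  v <- read_somatic_vcf(file.path(indir, sheet$vcf[i]), sid)
  kept[[sid]] <- apply_quality_filters(v[v$variant_class != "SV", ])$kept
}
enr <- apobec_enrichment(kept, genome, index = index)
enr <- merge(enr, sheet[, c("sample_id", "group")], by = "sample_id", sort = FALSE)
write.table(enr, file.path(outdir, "enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("ES_high:", sum(enr$stratum == "ES_high"), "of", nrow(enr), "samples;",
    "score range",
    paste(round(range(enr$score), 2), collapse = " - "), "\n")
print(table(enr$group, enr$stratum))
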