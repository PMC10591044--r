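#!/usr/bin/env Rscript
# Stage 2: read the simulated per-sample VCFs back, apply the read-support
# quality filters (alt >= 3, depth >= 10, VAF > 0.05, caller PASS), and
# build the SBS-96, indel and SV spectra. Writes the catalog tables and a
# filter report.
#
# Run after 01_simulate_cohort.R.

suppressMessages(library(apobecsig))
indir <- "results/cohort"
outdir <- "results/spectra"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

genome <- read_genome_fasta(file.path(indir, "genome.fa"))
index <- genome_context_index(genome)
sheet <- read.delim(file.path(indir, "sample_sheet.tsv"))

catalogs <- list(); filt_rows <- list(); indel_rows <- list(); sv_rows <- list()
for (i in seq_len(nrow(sheet))) {
  sid <- sheet$sample_id[i]
  v <- read_somatic_vcf(file.path(indir, sheet$vcf[i]), sid)
  snvs <- v[v$variant_class != "SV", ]
  fl <- apply_quality_filters(snvs)
  cat96 <- build_sbs_catalog(fl$kept, genome, sample_id = sid, index = index)
  ind <- build_indel_catalog(fl$kept, genome, sample_id = sid)
  svt <- tally_structural_variants(read_sv_vcf(file.path(indir, sheet$vcf[i]), sid),
                                   sample_id = sid)
  catalogs[[sid]] <- cat96
  filt_rows[[sid]] <- data.frame(sample_id = sid, n_input = nrow(snvs),
                                 n_kept = nrow(fl$kept), n_removed = nrow(fl$removed))
  indel_rows[[sid]] <- data.frame(sample_id = sid, t(as.integer(ind)))
  sv_rows[[sid]] <- data.frame(sample_id = sid, sv_total = attr(svt, "total"))
}
write_catalog_tsv(catalogs, file.path(outdir, "sbs96_catalogs.tsv"))
filt <- do.call(rbind, filt_rows)
write.table(filt, file.path(outdir, "filter_report.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
ind_tab <- do.call(rbind, indel_rows)
names(ind_tab)[-1] <- indel_categories()
write.table(ind_tab, file.path(outdir, "indel_catalogs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, sv_rows), file.path(outdir, "sv_totals.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Filtered", sum(filt$n_input), "calls ->", sum(filt$n_kept), "kept;",
    "spectra in", outdir, "\n")
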