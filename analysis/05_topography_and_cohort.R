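#!/usr/bin/env Rscript
# Stage 5: mutation topography and cohort statistics. Replication-timing
# quintile distributions (tumors vs controls, chi-square), TC-to-TT
# percentages per quintile, kataegis/omikli cluster calls, ES correlations
# with %SBS2 and indel load, and the ES-stratified structural-variation
# comparison.
#
# Run after stages 1-4.

suppressMessages(library(apobecsig))
indir <- "results/cohort"
outdir <- "results/cohort_stats"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

genome <- read_genome_fasta(file.path(indir, "genome.fa"))
index <- genome_context_index(genome)
sheet <- read.delim(file.path(indir, "sample_sheet.tsv"))
enr <- read.delim("results/enrichment/enrichment.tsv")
expo <- read.delim("results/signatures/exposures_percent.tsv", check.names = FALSE)
svt <- read.delim("results/spectra/sv_totals.tsv")
ind <- read.delim("results/spectra/indel_catalogs.tsv")

kept <- list()
for (i in seq_len(nrow(sheet))) {
  sid <- sheet$sample_id[i]
  v <- read_somatic_vcf(file.path(indir, sheet$vcf[i]), sid)
  kept[[sid]] <- apply_quality_filters(v[v$variant_class != "SV", ])$kept
}

# timing quintiles: transgenic arm vs controls
track <- read_timing_bedgraph(file.path(indir, "timing.bedgraph"))
quint <- assign_timing_quintiles(track)      # high value = early
grab <- function(grp) {
  ids <- sheet$sample_id[sheet$group == grp]
  v <- do.call(rbind, kept[ids])
  v[v$variant_class == "SBS" & v$contig != "chrM", ]
}
mq <- mutations_per_quintile(grab("CAG_A3B"), quint, comparison = grab("WT"))
tct <- tcw_to_t_fraction_per_quintile(grab("CAG_A3B"), quint, genome, index = index)
write.table(data.frame(quintile = paste0("Q", 1:5),
                       tumor_counts = as.integer(mq$counts),
                       tumor_normalized = as.numeric(mq$normalized),
                       control_counts = as.integer(mq$comparison_counts),
                       tct_to_tt_pct = as.numeric(tct)),
            file.path(outdir, "timing_quintiles.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("Quintile chi-square p (tumors vs controls):", mq$chisq_p, "\n")

# cluster classes in the transgenic arm
cl <- detect_clusters(grab("CAG_A3B"))
cat("Cluster classes:\n"); print(tapply(cl$n_members, cl$class, sum))

# feature table and cohort statistics
tab <- Reduce(function(a, b) merge(a, b, by = "sample_id"), list(
  enr[, c("sample_id", "group", "score", "q_value", "stratum")],
  expo[, c("sample_id", "SBS2")],
  svt,
  data.frame(sample_id = ind$sample_id,
             indel_total = rowSums(ind[, -1]))))
names(tab)[names(tab) == "SBS2"] <- "pct_sbs2"
write.table(tab, file.path(outdir, "sample_features.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

a3b <- tab[tab$group == "CAG_A3B", ]
cat("\nES vs %SBS2 (Pearson, transgenic arm):\n")
print(unlist(correlate(a3b$score, a3b$pct_sbs2, "pearson")[c("coefficient", "p_value")]))
cat("ES vs indel load (Spearman):\n")
print(unlist(correlate(a3b$score, a3b$indel_total, "spearman")[c("coefficient", "p_value")]))

sv_cmp <- es_stratified_sv_comparison(tab)
cat("\nSV totals by stratum (medians):\n"); print(sv_cmp$medians)
cat("Pairwise Mann-Whitney:\n"); print(sv_cmp$pairwise)
es_hi <- tab$sv_total[tab$stratum == "ES_high"]
es_lo <- tab$sv_total[tab$stratum == "ES_low"]
cat("ES_high vs ES_low SV totals, cohort-wide: p =",
    compare_groups(es_hi, es_lo, "mann_whitney")$p_value, "\n")
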