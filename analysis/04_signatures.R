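#!/usr/bin/env Rscript
# Stage 4: signature analysis. Refit each SBS-96 catalog against the
# packaged (synthetic) SBS1-30 + flat reference set to get percent
# contributions (%SBS2 in particular), then extract de novo signatures by
# KL-NMF and match them to the references by cosine similarity.
#
# Run after 02_filter_and_spectra.R.

suppressMessages(library(apobecsig))
outdir <- "results/signatures"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

catalogs <- read_catalog_tsv("results/spectra/sbs96_catalogs.tsv")
refs <- reference_signatures(include_flat = TRUE)

expo <- do.call(rbind, lapply(names(catalogs), function(sid) {
  ex <- refit_exposures(catalogs[[sid]], refs)
  data.frame(sample_id = sid, t(100 * ex$weights), check.names = FALSE)
}))
write.table(expo, file.path(outdir, "exposures_percent.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

catmat <- do.call(cbind, lapply(catalogs, as.integer))
colnames(catmat) <- names(catalogs)
dn <- extract_denovo(catmat, rank = 2, n_restarts = 10, seed = 42)
matches <- match_to_reference(dn$signatures, refs)
write_signature_tsv(dn$signatures, file.path(outdir, "denovo_signatures.tsv"))
write.table(matches, file.path(outdir, "denovo_matches.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Mean %SBS2 by arm:\n")
grp <- ifelse(grepl("^WT", expo$sample_id), "WT", "CAG_A3B")
print(tapply(expo$SBS2, grp, mean))
cat("De novo matches:\n"); print(matches)
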