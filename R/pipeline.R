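# Cohort simulation and end-to-end pipeline orchestration.

#' Default pipeline configuration
#'
#' The default synthetic study: a shared ~0.9 Mb two-autosome (+chrM)
#' genome at mouse-like GC, 15 flat-background "WT" control tumors and 15
#' SBS2-dominant "CAG_A3B" tumors, early-replication bias and ES-coupled
#' indel and SV loads in the transgenic arm. Thresholds default to the
#' analysis constants (alt >= 3, depth >= 10, VAF > 0.05, 41-base windows,
#' q < 0.1).
#'
#' @param seed master seed.
#' @return named list of class `run_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    contig_lengths = c(500000L, 350000L),
    gc_fraction = 0.42,
    n_controls = 15L,
    n_tumors = 15L,
    n_sbs_per_sample = 2500L,
    tumor_sbs2_range = c(0.35, 0.8),
    control_weights = c(flat = 1.0),
    chrM_mutations = 5L,
    timing_bias_tumor = c(2, 1.5, 1, 0.75, 0.5),
    timing_n_bins = 100L,
    indel_base = c(ins_1bp_TA = 6L, ins_1bp_CG = 4L, del_1bp_TA = 6L,
                   del_1bp_CG = 4L, indel_2bp = 2L, indel_3bp = 2L,
                   indel_4bp = 2L, del_2bp_MH = 2L, del_3bp_MH = 2L,
                   del_4bp_MH = 2L, indel_5plus = 3L),
    indel_es_coupling = 10,
    sv_base = 3L,
    sv_es_coupling = 4,
    depth_mean = 30,
    vaf_mean = 0.3,
    contaminant_fraction = 0,
    min_alt_reads = 3L, min_total_reads = 10L, min_vaf_exclusive = 0.05,
    flank = 20L, q_threshold = 0.1,
    refit_prune = 0.06,
    denovo_rank = 2L, denovo_restarts = 10L,
    outdir = NULL
  ), class = "run_config")
}

#' Validate a pipeline configuration
#'
#' Checks key ranges and path existence, reporting every problem at once;
#' unknown keys are rejected as typo guards.
#'
#' @param config a list or `run_config`.
#' @return the validated `run_config`, or an error listing all problems.
#' @export
validate_config <- function(config) {
  ref <- default_config()
  errs <- character(0)
  unknown <- setdiff(names(config), c(names(ref), "vcf_paths", "fasta", "timing_track",
                                      "signature_tsv", "sample_sheet"))
  if (length(unknown)) errs <- c(errs, paste0("unknown key(s): ",
                                              paste(unknown, collapse = ", ")))
  full <- ref
  for (nm in intersect(names(config), names(ref))) full[[nm]] <- config[[nm]]
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(full$gc_fraction > 0 && full$gc_fraction < 1, "gc_fraction must be in (0,1)")
  chk(full$min_vaf_exclusive >= 0 && full$min_vaf_exclusive < 1,
      "min_vaf_exclusive must be in [0,1)")
  chk(full$min_alt_reads >= 0, "min_alt_reads must be nonnegative")
  chk(full$min_total_reads >= 0, "min_total_reads must be nonnegative")
  chk(full$q_threshold > 0 && full$q_threshold <= 1, "q_threshold must be in (0,1]")
  chk(full$flank >= 1, "flank must be >= 1")
  chk(all(full$contig_lengths > 0), "contig_lengths must be positive")
  chk(full$n_controls >= 0 && full$n_tumors >= 1, "need at least one tumor sample")
  for (key in c("fasta", "timing_track", "signature_tsv")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]]))
      errs <- c(errs, paste0(key, " does not exist: ", config[[key]]))
  }
  if (length(errs)) stop("invalid configuration:\n  - ",
                         paste(errs, collapse = "\n  - "))
  class(full) <- "run_config"
  full
}

#' Simulate the default two-arm cohort
#'
#' Generates one shared genome, a replication-timing track, and per-sample
#' variant sets: controls draw all SBS from the flat background uniformly
#' across timing; tumors draw from the configured SBS2-dominant mixture
#' with early-replication bias. Every sample gets a few mitochondrial
#' mutations (so the chrM exclusion is always exercised), read support,
#' ES-coupled indel loads and SV counts in the transgenic arm, and a truth
#' ledger.
#'
#' @param config a `run_config` (see [default_config()]).
#' @return list(genome, index, timing, samples): `samples` is a named list
#'   with per-sample variants, sv_records, group, and truth fields.
#' @export
simulate_cohort <- function(config = default_config()) {
  config <- validate_config(config)
  seed <- config$seed
  genome <- generate_genome(length(config$contig_lengths), config$contig_lengths,
                            config$gc_fraction, seed = seed)
  index <- genome_context_index(genome)
  timing <- generate_timing_track(genome, config$timing_n_bins,
                                  bias = config$timing_bias_tumor, seed = seed + 1L)
  refs <- reference_signatures(include_flat = TRUE)
  autos <- setdiff(names(genome$contigs), "chrM")
  samples <- list()
  ids <- c(sprintf("WT_%02d", seq_len(config$n_controls)),
           sprintf("A3B_%02d", seq_len(config$n_tumors)))
  groups <- c(rep("WT", config$n_controls), rep("CAG_A3B", config$n_tumors))
  # tumors span a range of SBS2 dominance, like the spread of %SBS2 across
  # real transgenic tumors
  sbs2_w <- seq(config$tumor_sbs2_range[1], config$tumor_sbs2_range[2],
                length.out = config$n_tumors)
  for (i in seq_along(ids)) {
    sid <- ids[i]; grp <- groups[i]
    s_seed <- seed + 100L + i
    w <- if (grp == "WT") config$control_weights else {
      s2 <- sbs2_w[i - config$n_controls]
      c(SBS2 = s2, flat = 1 - s2)
    }
    timing_arg <- if (grp == "WT") NULL else timing
    ps <- plant_sbs_from_signatures(genome, config$n_sbs_per_sample, w, refs,
                                    seed = s_seed, contigs = autos,
                                    timing = timing_arg, sample_id = sid,
                                    index = index)
    # chrM is always seeded with a few mutations
    pm <- plant_sbs_from_signatures(genome, config$chrM_mutations,
                                    c(flat = 1), refs, seed = s_seed + 5000L,
                                    contigs = "chrM", sample_id = sid,
                                    index = index)
    # ES-coupled indel load in the transgenic arm
    mult <- if (grp == "WT") 1 else
      1 + config$indel_es_coupling * w[["SBS2"]] / 5
    ind_counts <- pmax(0L, as.integer(round(config$indel_base * mult)))
    names(ind_counts) <- names(config$indel_base)
    pi_ <- plant_indels(genome, ind_counts, seed = s_seed + 10000L,
                        contigs = autos, sample_id = sid)
    variants <- rbind(ps$variants, pm$variants, pi_$variants)
    rs <- attach_read_support(variants, config$depth_mean, config$vaf_mean,
                              config$contaminant_fraction, seed = s_seed + 20000L,
                              ledger = ps$ledger)
    # ES-coupled SV count in the transgenic arm
    sv_n <- config$sv_base + if (grp == "WT") 0L else
      as.integer(round(config$sv_es_coupling * w[["SBS2"]] * 10 / 6))
    sv_counts <- c(deletion = sv_n %/% 3 + sv_n %% 3, duplication = sv_n %/% 3,
                   translocation = sv_n %/% 3)
    sv <- plant_svs(genome, as.list(sv_counts), seed = s_seed + 30000L,
                    sample_id = sid)
    ledger <- rs$ledger
    ledger$planted_indels <- pi_$ledger$planted_indels
    ledger$planted_sv_count <- sv$ledger$planted_sv_count
    ledger$timing_bias <- if (grp == "WT") rep(1, 5) else config$timing_bias_tumor
    ledger$chrM_mutations <- pm$ledger$planted_sbs
    samples[[sid]] <- list(sample_id = sid, group = grp,
                           variants = rs$variants, sv_records = sv$records,
                           ledger = ledger,
                           truth_sbs2 = if (grp == "WT") 0 else w[["SBS2"]],
                           truth_stratum = if (grp == "WT") "ES_low" else "ES_high")
  }
  list(genome = genome, index = index, timing = timing, refs = refs,
       samples = samples, config = config)
}

#' Run the full analysis pipeline
#'
#' Simulates (or accepts) a cohort, then runs quality filtering, SBS-96 /
#' indel / SV spectra, APOBEC enrichment with cohort-wide stratification,
#' signature refitting, de novo extraction, replication-timing and cluster
#' topography, and the cohort statistics. Identical config and seed give an
#' identical report. When `config$outdir` is set, per-stage TSV/JSON
#' outputs are written there.
#'
#' @param config `run_config`.
#' @param cohort optional pre-simulated cohort from [simulate_cohort()].
#' @return list of class `cohort_report`: per_sample data.frame, enrichment
#'   table, exposures, denovo matches, quintile summaries, cluster counts,
#'   group comparisons.
#' @export
run_pipeline <- function(config = default_config(), cohort = NULL) {
  config <- validate_config(config)
  if (is.null(cohort)) cohort <- simulate_cohort(config)
  genome <- cohort$genome; index <- cohort$index
  policy <- filter_policy(config$min_alt_reads, config$min_total_reads,
                          config$min_vaf_exclusive)
  refs <- cohort$refs
  quint <- assign_timing_quintiles(cohort$timing)

  kept_by_sample <- list(); rows <- list(); catalogs <- list()
  for (sid in names(cohort$samples)) {
    smp <- cohort$samples[[sid]]
    fl <- apply_quality_filters(smp$variants, policy)
    kept_by_sample[[sid]] <- fl$kept
    cat96 <- build_sbs_catalog(fl$kept, genome, sample_id = sid, index = index)
    catalogs[[sid]] <- cat96
    exp_ <- refit_exposures(cat96, refs, config$refit_prune)
    indcat <- build_indel_catalog(fl$kept, genome, sample_id = sid)
    svt <- tally_structural_variants(smp$sv_records, sample_id = sid)
    cl <- detect_clusters(fl$kept[fl$kept$variant_class == "SBS", ])
    rows[[sid]] <- data.frame(
      sample_id = sid, group = smp$group,
      n_input = nrow(smp$variants), n_kept = nrow(fl$kept),
      n_removed = nrow(fl$removed),
      sbs_total = sum(cat96),
      pct_sbs2 = sbs2_percentage(exp_),
      indel_total = sum(indcat),
      sv_total = attr(svt, "total"),
      n_kataegis = sum(cl$class == "kataegis"),
      n_omikli = sum(cl$class == "omikli"),
      n_dispersed = sum(cl$class == "dispersed"),
      stringsAsFactors = FALSE)
  }
  per_sample <- do.call(rbind, rows)
  enr <- apobec_enrichment(kept_by_sample, genome, flank = config$flank,
                           q_threshold = config$q_threshold, index = index)
  per_sample <- merge(per_sample, enr[, c("sample_id", "score", "p_value",
                                          "q_value", "stratum")],
                      by = "sample_id", sort = FALSE)
  per_sample <- per_sample[order(match(per_sample$sample_id,
                                       names(cohort$samples))), ]
  rownames(per_sample) <- NULL

  # de novo extraction across the cohort
  catmat <- do.call(cbind, lapply(catalogs, as.integer))
  colnames(catmat) <- names(catalogs)
  dn <- extract_denovo(catmat, rank = config$denovo_rank,
                       n_restarts = config$denovo_restarts,
                       seed = config$seed + 7L)
  matches <- match_to_reference(dn$signatures, refs)

  # timing topography per group
  tum <- do.call(rbind, kept_by_sample[per_sample$sample_id[per_sample$group != "WT"]])
  ctl_ids <- per_sample$sample_id[per_sample$group == "WT"]
  ctl <- if (length(ctl_ids)) do.call(rbind, kept_by_sample[ctl_ids]) else NULL
  tum_sbs <- tum[tum$variant_class == "SBS" & tum$contig != "chrM", ]
  quintiles <- if (!is.null(ctl)) {
    ctl_sbs <- ctl[ctl$variant_class == "SBS" & ctl$contig != "chrM", ]
    mutations_per_quintile(tum_sbs, quint, comparison = ctl_sbs)
  } else mutations_per_quintile(tum_sbs, quint)
  tct <- tcw_to_t_fraction_per_quintile(tum_sbs, quint, genome, index = index)

  comparisons <- list()
  if (any(per_sample$group == "WT")) {
    comparisons$sbs_total <- compare_groups(
      per_sample$sbs_total[per_sample$group == "WT"],
      per_sample$sbs_total[per_sample$group != "WT"], "mann_whitney")
    comparisons$pct_sbs2 <- compare_groups(
      per_sample$pct_sbs2[per_sample$group == "WT"],
      per_sample$pct_sbs2[per_sample$group != "WT"], "mann_whitney")
  }
  es_sv <- es_stratified_sv_comparison(per_sample)
  es_high <- per_sample$sv_total[per_sample$stratum == "ES_high"]
  es_low <- per_sample$sv_total[per_sample$stratum == "ES_low"]
  if (length(es_high) >= 2 && length(es_low) >= 2)
    comparisons$sv_es_high_vs_low <- compare_groups(es_high, es_low, "mann_whitney")
  cor_es_sbs2 <- tryCatch(
    correlate(per_sample$score[per_sample$group != "WT"],
              per_sample$pct_sbs2[per_sample$group != "WT"], "pearson"),
    error = function(e) NULL)
  cor_es_indel <- tryCatch(
    correlate(per_sample$score[per_sample$group != "WT"],
              per_sample$indel_total[per_sample$group != "WT"], "spearman"),
    error = function(e) NULL)

  report <- list(per_sample = per_sample, enrichment = enr,
                 denovo = dn, denovo_matches = matches,
                 quintiles = quintiles, tct_per_quintile = tct,
                 comparisons = comparisons, es_sv = es_sv,
                 cor_es_sbs2 = cor_es_sbs2, cor_es_indel = cor_es_indel,
                 config = config)
  class(report) <- "cohort_report"
  if (!is.null(config$outdir)) write_report(report, cohort, config$outdir)
  report
}

# write the pipeline's tabular outputs (TSV) and a machine-readable JSON
write_report <- function(report, cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$per_sample, file.path(outdir, "per_sample.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$enrichment, file.path(outdir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$denovo_matches, file.path(outdir, "denovo_matches.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  json <- list(per_sample = report$per_sample,
               denovo_matches = report$denovo_matches,
               quintile_counts = report$quintiles$counts,
               quintile_normalized = report$quintiles$normalized,
               tct_per_quintile = report$tct_per_quintile,
               comparisons = report$comparisons,
               seed = report$config$seed)
  jsonlite::write_json(json, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("cohort_report:", nrow(x$per_sample), "samples\n")
  tab <- table(x$per_sample$group, x$per_sample$stratum)
  print(tab)
  invisible(x)
}
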