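# Somatic-variant IO and the quality / enrichment exclusion filters.
#
# Variants are plain data.frames (one row per ALT allele) with columns
# contig, pos (1-based, VCF convention), ref, alt, alt_reads, total_reads,
# vaf, filter, variant_class, sample_id. Coordinates stay 1-based
# throughout; conversion to 0-based half-open happens only at the
# timing-track boundary.

#' Classify a variant by its REF/ALT alleles
#'
#' SBS if both alleles are single bases; INS/DEL by the usual VCF
#' anchored-allele convention; symbolic (`<DEL>` etc.) or breakend alleles
#' are structural (SV); equal-length multi-base alleles are MNV.
#'
#' @param ref_allele,alt_allele character vectors of REF and ALT alleles.
#' @return character vector over {"SBS","INS","DEL","MNV","SV"}.
#' @export
classify_variant <- function(ref_allele, alt_allele) {
  if (any(!nzchar(ref_allele)) || any(!nzchar(alt_allele)))
    stop("classify_variant: empty allele")
  sv <- grepl("[][<>]", alt_allele) | grepl("[][<>]", ref_allele)
  lr <- nchar(ref_allele); la <- nchar(alt_allele)
  out <- ifelse(sv, "SV",
         ifelse(lr == 1L & la == 1L, "SBS",
         ifelse(la > lr & substr(alt_allele, 1L, lr) == ref_allele, "INS",
         ifelse(lr > la & substr(ref_allele, 1L, la) == alt_allele, "DEL",
         ifelse(lr == la, "MNV", "MNV")))))
  out
}

#' Write somatic variants as a VCF 4.2 file
#'
#' Writes one tumor sample column with AD/DP/AF FORMAT fields, suitable for
#' round-tripping through [read_somatic_vcf()]. SV records (from
#' [plant_svs()]) may be appended via `sv_records`.
#'
#' @param variants variant data.frame; if read-support columns are absent the
#'   genotype fields are written as missing.
#' @param path output path.
#' @param genome optional genome for contig header lines.
#' @param sample_name tumor sample column name.
#' @param sv_records optional SV record data.frame (contig, pos, id, ref,
#'   alt, info).
#' @export
write_somatic_vcf <- function(variants, path, genome = NULL,
                              sample_name = "TUMOR", sv_records = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=apobecsig")
  if (!is.null(genome)) {
    seqs <- genome_sequences(genome)
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(seqs), nchar(seqs)))
  }
  hdr <- c(hdr,
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end\">",
    "##INFO=<ID=MATEID,Number=1,Type=String,Description=\"Breakend mate\">",
    "##INFO=<ID=EVENT,Number=1,Type=String,Description=\"SV event id\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_name))
  body <- character(0)
  if (nrow(variants)) {
    has_support <- all(c("alt_reads", "total_reads") %in% names(variants))
    filt <- if ("filter" %in% names(variants)) variants$filter else "PASS"
    gt <- if (has_support) {
      sprintf("0/1:%d,%d:%d:%.6g",
              variants$total_reads - variants$alt_reads, variants$alt_reads,
              variants$total_reads, variants$alt_reads / variants$total_reads)
    } else rep("0/1:.:.:.", nrow(variants))
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t.\tGT:AD:DP:AF\t%s",
                    variants$contig, variants$pos, variants$ref, variants$alt,
                    filt, gt)
  }
  svb <- character(0)
  if (!is.null(sv_records) && nrow(sv_records)) {
    svb <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t%s\tGT:AD:DP:AF\t0/1:.:.:.",
                   sv_records$contig, sv_records$pos, sv_records$id,
                   sv_records$ref, sv_records$alt, sv_records$info)
  }
  writeLines(c(hdr, body, svb), path)
  invisible(path)
}

#' Read a somatic VCF into a variant table
#'
#' One row per ALT allele (multi-allelic records are split, with AD summed
#' into the per-allele depth). The tumor sample column is `sample_id` if a
#' column of that name exists, otherwise the first genotype column. Requires
#' AD and DP (or AD alone, from which DP is summed); a record without them
#' raises a format error naming the record.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param sample_id sample label for the output (also used to pick the
#'   genotype column when present).
#' @return variant data.frame (see file header for columns); the FILTER
#'   column is retained in `filter`.
#' @export
read_somatic_vcf <- function(path, sample_id = "sample") {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("read_somatic_vcf: VCF parse error in ",
                                         path, ": ", conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  if (n == 0) return(cbind(empty_variants(), alt_reads = integer(),
                           total_reads = integer(), vaf = numeric(),
                           filter = character()))
  gt <- v@gt
  scol <- if (!is.null(colnames(gt)) && sample_id %in% colnames(gt)[-1])
    sample_id else colnames(gt)[2]
  fmt <- gt[, 1]; smp <- gt[, scol]
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    keys <- strsplit(fmt[i], ":", fixed = TRUE)[[1]]
    vals <- strsplit(smp[i], ":", fixed = TRUE)[[1]]
    ad <- vals[match("AD", keys)]
    dp <- vals[match("DP", keys)]
    is_sv <- any(grepl("[][<>]", alts))
    if (is.na(ad) || identical(ad, ".")) {
      # symbolic / breakend records carry no allele depths; anything else
      # without AD is a format error
      if (!is_sv)
        stop("read_somatic_vcf: record ", fix[i, "CHROM"], ":", fix[i, "POS"],
             " lacks AD depth field")
      altd <- rep(NA_integer_, length(alts)); total <- NA_integer_
    } else {
      adv <- suppressWarnings(as.integer(strsplit(ad, ",", fixed = TRUE)[[1]]))
      total <- if (!is.na(dp) && dp != ".") as.integer(dp) else sum(adv, na.rm = TRUE)
      altd <- adv[-1]
      if (length(altd) < length(alts))
        stop("read_somatic_vcf: record ", fix[i, "CHROM"], ":", fix[i, "POS"],
             " AD has fewer entries than ALT alleles")
    }
    rows[[i]] <- data.frame(
      contig = unname(fix[i, "CHROM"]), pos = as.integer(fix[i, "POS"]),
      ref = unname(fix[i, "REF"]), alt = alts,
      alt_reads = altd[seq_along(alts)], total_reads = total,
      filter = unname(ifelse(is.na(fix[i, "FILTER"]), ".", fix[i, "FILTER"])),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$vaf <- ifelse(out$total_reads > 0, out$alt_reads / out$total_reads, NA_real_)
  out$variant_class <- classify_variant(out$ref, out$alt)
  out$sample_id <- sample_id
  out
}

#' Read Manta-style SV records from a VCF
#'
#' @param path VCF path.
#' @param sample_id sample label.
#' @return data.frame (contig, pos, id, ref, alt, svtype, end, mateid,
#'   event, sample_id).
#' @export
read_sv_vcf <- function(path, sample_id = "sample") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  info_get <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    ifelse(lengths(regmatches(info, gregexpr(paste0("(^|;)", key, "="), info))) > 0,
           sub(paste0(".*", key, "="), "", m), NA_character_)
  }
  info <- fix[, "INFO"]
  svtype <- vapply(info, function(x) {
    m <- regmatches(x, regexpr("SVTYPE=[^;]*", x))
    if (length(m)) sub("SVTYPE=", "", m) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  getk <- function(key) vapply(info, function(x) {
    m <- regmatches(x, regexpr(paste0(key, "=[^;]*"), x))
    if (length(m)) sub(paste0(key, "="), "", m) else NA_character_
  }, character(1), USE.NAMES = FALSE)
  out <- data.frame(contig = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                    id = fix[, "ID"], ref = fix[, "REF"], alt = fix[, "ALT"],
                    svtype = svtype, end = suppressWarnings(as.integer(getk("END"))),
                    mateid = getk("MATEID"), event = getk("EVENT"),
                    sample_id = sample_id, stringsAsFactors = FALSE)
  out[!is.na(out$svtype), , drop = FALSE]
}

#' Quality-filter policy
#'
#' The thresholds applied to Mutect2-style calls before any downstream
#' analysis: at least 3 reads supporting the variant, at least 10 total reads
#' at the site, variant allele fraction strictly over 0.05, caller FILTER
#' equal to PASS, and no excluded contigs.
#'
#' @param min_alt_reads minimum alt-supporting reads (inclusive).
#' @param min_total_reads minimum total depth (inclusive).
#' @param min_vaf_exclusive VAF must be strictly greater than this.
#' @param excluded_contigs contig names dropped outright.
#' @param require_caller_pass require FILTER == "PASS".
#' @return list of class `filter_policy`.
#' @export
filter_policy <- function(min_alt_reads = 3L, min_total_reads = 10L,
                          min_vaf_exclusive = 0.05,
                          excluded_contigs = "chrM",
                          require_caller_pass = TRUE) {
  if (min_alt_reads < 0 || min_total_reads < 0)
    stop("filter_policy: thresholds must be nonnegative")
  if (min_vaf_exclusive < 0 || min_vaf_exclusive >= 1)
    stop("filter_policy: min_vaf_exclusive must be in [0,1)")
  structure(list(min_alt_reads = min_alt_reads,
                 min_total_reads = min_total_reads,
                 min_vaf_exclusive = min_vaf_exclusive,
                 excluded_contigs = excluded_contigs,
                 require_caller_pass = require_caller_pass),
            class = "filter_policy")
}

#' Apply the read-support quality filters
#'
#' Keeps a variant iff alt_reads >= 3 AND total_reads >= 10 AND
#' vaf > 0.05 (strict) AND its contig is not excluded AND (when required)
#' the caller FILTER is PASS. Every removed variant carries the full set of
#' reason codes it violated.
#'
#' @param variants variant data.frame with read-support columns.
#' @param policy a [filter_policy()].
#' @return list(kept, removed): `removed` gains a `reasons` column
#'   (comma-joined codes from low_alt, low_depth, low_vaf, excluded_contig,
#'   caller_fail, missing_support).
#' @export
apply_quality_filters <- function(variants, policy = filter_policy()) {
  n <- nrow(variants)
  if (n == 0) return(list(kept = variants, removed = cbind(variants, reasons = character())))
  miss <- !(c("alt_reads", "total_reads", "vaf") %in% names(variants))
  if (any(miss)) {
    removed <- variants; removed$reasons <- "missing_support"
    return(list(kept = variants[0, , drop = FALSE], removed = removed))
  }
  no_support <- is.na(variants$alt_reads) | is.na(variants$total_reads)
  low_alt <- !no_support & variants$alt_reads < policy$min_alt_reads
  low_depth <- !no_support & variants$total_reads < policy$min_total_reads
  low_vaf <- !no_support & !(variants$vaf > policy$min_vaf_exclusive)
  excl <- variants$contig %in% policy$excluded_contigs
  fail <- if (policy$require_caller_pass && "filter" %in% names(variants))
    !(variants$filter %in% c("PASS", ".")) else rep(FALSE, n)
  reasons <- mapply(function(a, d, v, e, f, m) {
    paste(c(if (m) "missing_support", if (a) "low_alt", if (d) "low_depth",
            if (v) "low_vaf", if (e) "excluded_contig", if (f) "caller_fail"),
          collapse = ",")
  }, low_alt, low_depth, low_vaf, excl, fail, no_support)
  drop <- nzchar(reasons)
  removed <- variants[drop, , drop = FALSE]
  removed$reasons <- reasons[drop]
  list(kept = variants[!drop, , drop = FALSE], removed = removed)
}

#' Exclusions for the APOBEC enrichment analysis
#'
#' Applies the four-step organization of the enrichment-score input on
#' quality-filtered calls: keep single-base substitutions only, keep only
#' C:G reference base pairs, remove mitochondrial mutations, and remove
#' C-to-A substitutions (and their reverse-strand G-to-T equivalents), which
#' are confounded by other mutagenic processes.
#'
#' @param variants quality-filtered variant data.frame.
#' @param mito_contigs mitochondrial contig names.
#' @return the retained subset.
#' @export
exclude_for_enrichment <- function(variants, mito_contigs = c("chrM", "MT")) {
  keep <- variants$variant_class == "SBS" &
    variants$ref %in% c("C", "G") &
    !(variants$contig %in% mito_contigs) &
    !(variants$ref == "C" & variants$alt == "A") &
    !(variants$ref == "G" & variants$alt == "T")
  variants[keep, , drop = FALSE]
}
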