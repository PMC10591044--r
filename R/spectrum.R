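# Pyrimidine-normalized SBS-96 catalogs, indel classification with
# microhomology, and structural-variant tallies.

#' Trinucleotide channel of an SBS
#'
#' Returns the SBS-96 channel index (1..96) of each substitution. Variants
#' whose reference base is a purine are reverse-complemented so the mutated
#' base is reported as a pyrimidine. Variants at a contig end
#' (`truncated_context`) or with a non-ACGT base in the trinucleotide
#' (`ambiguous_context`) get NA, with the reason in the `reason` attribute.
#'
#' @param variants SBS variant data.frame (contig, pos, ref, alt).
#' @param genome genome object.
#' @param index optional precomputed [genome_context_index()].
#' @return integer vector of channel indices (NA where excluded), with
#'   attribute `reason`.
#' @export
trinucleotide_context <- function(variants, genome, index = NULL) {
  if (is.null(index)) index <- genome_context_index(genome)
  ch <- sbs_channels()
  n <- nrow(variants)
  out <- rep(NA_integer_, n)
  reason <- rep(NA_character_, n)
  if (n == 0) return(structure(out, reason = reason))
  sub_of <- function(refp, altp) paste0(refp, ">", altp)
  for (cg in unique(variants$contig)) {
    sel <- which(variants$contig == cg)
    ix <- index[[cg]]
    if (is.null(ix)) stop("trinucleotide_context: contig ", cg, " not in reference")
    pos <- variants$pos[sel]
    at_end <- pos <= 1L | pos >= ix$length
    ctx <- ifelse(at_end, NA_integer_, ix$ctx[pmin(pmax(pos, 1L), ix$length)])
    reason[sel][at_end] <- "truncated_context"
    reason[sel][!at_end & is.na(ctx)] <- "ambiguous_context"
    pur <- ix$purine[pos]
    # pyrimidine-strand substitution
    refp <- ifelse(pur, chartr("ACGT", "TGCA", variants$ref[sel]), variants$ref[sel])
    altp <- ifelse(pur, chartr("ACGT", "TGCA", variants$alt[sel]), variants$alt[sel])
    subp <- sub_of(refp, altp)
    s <- match(subp, c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"))
    # context id -> (five, three) within the 16-block
    block <- ((ctx - 1L) %% 16L)
    chan <- (s - 1L) * 16L + block + 1L
    bad_sub <- is.na(s)
    reason[sel][!is.na(ctx) & bad_sub] <- "not_snv"
    out[sel] <- ifelse(is.na(ctx) | bad_sub, NA_integer_, chan)
  }
  structure(out, reason = reason)
}

#' Build an SBS-96 catalog
#'
#' Tallies quality-filtered single-base substitutions into the 96 canonical
#' channels. The catalog sums to the number of classifiable SBS; variants
#' with truncated or ambiguous context are dropped (count reported in the
#' `dropped` attribute).
#'
#' @param variants variant data.frame (non-SBS rows are ignored).
#' @param genome genome object.
#' @param sample_id label stored on the catalog.
#' @param index optional context index.
#' @return named integer 96-vector of class `sbs_catalog`.
#' @export
build_sbs_catalog <- function(variants, genome, sample_id = "sample",
                              index = NULL) {
  variants <- variants[variants$variant_class == "SBS", , drop = FALSE]
  chan <- trinucleotide_context(variants, genome, index)
  counts <- tabulate(chan[!is.na(chan)], nbins = 96L)
  names(counts) <- sbs_channels()$channel
  structure(as.integer(counts), names = names(counts), class = "sbs_catalog",
            sample_id = sample_id, dropped = sum(is.na(chan)))
}

#' Left-align and trim an indel to its canonical representation
#'
#' Trims shared suffix then shared prefix (keeping the VCF anchor base) and
#' shifts the event left while the base preceding the anchor equals the last
#' base of the inserted/deleted span. VCF permits several equivalent
#' representations; classification happens on this canonical one.
#'
#' @param contig,pos,ref,alt a single indel record.
#' @param genome genome object.
#' @return list(pos, ref, alt).
#' @export
left_align_indel <- function(contig, pos, ref, alt, genome) {
  s <- genome_sequences(genome)[[contig]]
  # trim common suffix
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1); alt <- substr(alt, 1, nchar(alt) - 1)
  }
  # trim common prefix beyond the anchor
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1) &&
         substr(ref, 2, 2) == substr(alt, 2, 2)) {
    ref <- substr(ref, 2, nchar(ref)); alt <- substr(alt, 2, nchar(alt)); pos <- pos + 1L
  }
  # left shift: the event can move one base left exactly when the last base
  # of the longer allele equals the anchor base (its first base)
  repeat {
    if (pos <= 1L) break
    longer <- if (nchar(ref) > nchar(alt)) ref else alt
    if (substr(longer, nchar(longer), nchar(longer)) != substr(longer, 1L, 1L)) break
    prev <- substr(s, pos - 1L, pos - 1L)
    ref <- paste0(prev, substr(ref, 1, nchar(ref) - 1))
    alt <- paste0(prev, substr(alt, 1, nchar(alt) - 1))
    pos <- pos - 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Classify an indel into the landscape categories
#'
#' Categories: 1 bp insertions/deletions split by T/A vs C/G base;
#' 2-4 bp events (`indel_2bp`..`indel_4bp`); 2-4 bp deletions whose deleted
#' span shares an identical prefix of >= 2 bp with the sequence immediately
#' 3' of the deletion are microhomology deletions (`del_2bp_MH` etc., taking
#' precedence over the plain category); 5-200 bp events are `indel_5plus`.
#' Events over 200 bp return NA (routed to the SV tally, not this spectrum).
#' Classification is performed on the left-aligned representation.
#'
#' @param variants indel variant data.frame.
#' @param genome genome object.
#' @param mh_min minimum homology length (default 2).
#' @return character vector of categories (NA for events > 200 bp).
#' @export
classify_indel <- function(variants, genome, mh_min = 2L) {
  seqs <- genome_sequences(genome)
  n <- nrow(variants)
  out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    la <- left_align_indel(variants$contig[i], variants$pos[i],
                           variants$ref[i], variants$alt[i], genome)
    lr <- nchar(la$ref); lal <- nchar(la$alt)
    L <- abs(lr - lal)
    if (L == 0) stop("classify_indel: zero-length indel at ",
                     variants$contig[i], ":", variants$pos[i])
    is_del <- lr > lal
    span <- if (is_del) substr(la$ref, lal + 1L, lr) else substr(la$alt, lr + 1L, lal)
    if (L > 200L) next
    if (L == 1L) {
      kind <- if (span %in% c("T", "A")) "1bp_TA" else "1bp_CG"
      out[i] <- paste0(if (is_del) "del_" else "ins_", kind)
    } else if (L <= 4L) {
      mh <- FALSE
      if (is_del) {
        s <- seqs[[variants$contig[i]]]
        flank <- substr(s, la$pos + L + 1L, la$pos + 2L * L)
        m <- 0L
        while (m < L && m < nchar(flank) &&
               substr(span, m + 1, m + 1) == substr(flank, m + 1, m + 1)) m <- m + 1L
        mh <- m >= mh_min
      }
      out[i] <- if (mh) paste0("del_", L, "bp_MH") else paste0("indel_", L, "bp")
    } else {
      out[i] <- "indel_5plus"
    }
  }
  out
}

#' Indel category labels, in display order
#' @export
indel_categories <- function() {
  c("ins_1bp_TA", "ins_1bp_CG", "del_1bp_TA", "del_1bp_CG",
    "indel_2bp", "indel_3bp", "indel_4bp",
    "del_2bp_MH", "del_3bp_MH", "del_4bp_MH", "indel_5plus")
}

#' Build an indel catalog
#'
#' @param variants variant data.frame (INS/DEL rows are used).
#' @param genome genome object.
#' @param sample_id label.
#' @return named integer vector over [indel_categories()], class
#'   `indel_catalog`, with attribute `oversize` (events > 200 bp).
#' @export
build_indel_catalog <- function(variants, genome, sample_id = "sample") {
  ind <- variants[variants$variant_class %in% c("INS", "DEL"), , drop = FALSE]
  cats <- classify_indel(ind, genome)
  counts <- table(factor(cats, levels = indel_categories()))
  structure(as.integer(counts), names = indel_categories(),
            class = "indel_catalog", sample_id = sample_id,
            oversize = sum(is.na(cats)))
}

# breakend orientation from an ALT string: "right" for t[p[ , "left" for ]p]t
bnd_side <- function(alt) {
  ifelse(grepl("^[ACGTN]+\\[", alt), "right_fwd",
  ifelse(grepl("^[ACGTN]+\\]", alt), "right_rev",
  ifelse(grepl("^\\]", alt), "left_rev",
  ifelse(grepl("^\\[", alt), "left_fwd", NA_character_))))
}

#' Tally structural variants
#'
#' Counts events by {deletion (> 500 bp), duplication, inversion,
#' translocation, complex}. Symbolic DEL/DUP/INV records are counted
#' directly (deletions only when their span exceeds 500 bp; 201-500 bp
#' events fall in neither the indel spectrum nor this tally and are reported
#' in the `skipped_midsize` attribute). Breakend pairs are deduplicated via
#' MATEID; clusters of >= 3 breakends sharing an EVENT id count once as
#' complex; inter-contig pairs are translocations; intra-contig pairs are
#' classified by bracket orientation (DEL/DUP/INV-type junction); a breakend
#' whose MATEID never appears is counted once as complex, with a warning.
#'
#' @param sv_records data.frame from [read_sv_vcf()] or [plant_svs()].
#' @param sample_id label.
#' @return named integer vector (deletion, duplication, inversion,
#'   translocation, complex) of class `sv_tally` with attribute `total`.
#' @export
tally_structural_variants <- function(sv_records, sample_id = "sample") {
  counts <- c(deletion = 0L, duplication = 0L, inversion = 0L,
              translocation = 0L, complex = 0L)
  skipped <- 0L
  if (is.null(sv_records) || nrow(sv_records) == 0) {
    return(structure(counts, class = "sv_tally", sample_id = sample_id,
                     total = 0L, skipped_midsize = 0L))
  }
  r <- sv_records
  if (!"svtype" %in% names(r)) {
    r$svtype <- sub("SVTYPE=([^;]*).*", "\\1",
                    regmatches(r$info, regexpr("SVTYPE=[^;]*", r$info)))
    r$end <- suppressWarnings(as.integer(sub(".*END=([0-9]+).*", "\\1",
             ifelse(grepl("END=", r$info), r$info, NA))))
    r$mateid <- ifelse(grepl("MATEID=", r$info),
                       sub(".*MATEID=([^;]*).*", "\\1", r$info), NA)
    r$event <- ifelse(grepl("EVENT=", r$info),
                      sub(".*EVENT=([^;]*).*", "\\1", r$info), NA)
  }
  sym <- r[r$svtype %in% c("DEL", "DUP", "INV"), , drop = FALSE]
  if (nrow(sym)) {
    span <- abs(sym$end - sym$pos)
    for (i in seq_len(nrow(sym))) {
      if (sym$svtype[i] == "DEL") {
        if (!is.na(span[i]) && span[i] > 500L) counts["deletion"] <- counts["deletion"] + 1L
        else skipped <- skipped + 1L
      } else if (sym$svtype[i] == "DUP") counts["duplication"] <- counts["duplication"] + 1L
      else counts["inversion"] <- counts["inversion"] + 1L
    }
  }
  bnd <- r[r$svtype == "BND", , drop = FALSE]
  if (nrow(bnd)) {
    # complex clusters first: >= 3 breakends sharing an EVENT
    ev <- bnd$event
    ev_tab <- table(ev[!is.na(ev)])
    cx_events <- names(ev_tab)[ev_tab >= 3]
    counts["complex"] <- counts["complex"] + length(cx_events)
    bnd <- bnd[is.na(ev) | !(ev %in% cx_events), , drop = FALSE]
    seen <- character(0)
    for (i in seq_len(nrow(bnd))) {
      if (bnd$id[i] %in% seen) next
      mate <- bnd$mateid[i]
      j <- if (!is.na(mate)) which(bnd$id == mate) else integer(0)
      if (length(j) == 0) {
        warning("tally_structural_variants: dangling MATEID for ", bnd$id[i],
                "; counted once as complex")
        counts["complex"] <- counts["complex"] + 1L
        seen <- c(seen, bnd$id[i])
        next
      }
      j <- j[1]
      seen <- c(seen, bnd$id[i], bnd$id[j])
      if (bnd$contig[i] != bnd$contig[j]) {
        counts["translocation"] <- counts["translocation"] + 1L
      } else {
        s1 <- bnd_side(bnd$alt[i]); s2 <- bnd_side(bnd$alt[j])
        lo <- if (bnd$pos[i] <= bnd$pos[j]) s1 else s2
        hi <- if (bnd$pos[i] <= bnd$pos[j]) s2 else s1
        span <- abs(bnd$pos[i] - bnd$pos[j])
        if (identical(lo, "right_fwd") && identical(hi, "left_rev")) {
          if (span > 500L) counts["deletion"] <- counts["deletion"] + 1L
          else skipped <- skipped + 1L
        } else if (identical(lo, "left_rev") && identical(hi, "right_fwd")) {
          counts["duplication"] <- counts["duplication"] + 1L
        } else {
          counts["inversion"] <- counts["inversion"] + 1L
        }
      }
    }
  }
  structure(counts, class = "sv_tally", sample_id = sample_id,
            total = sum(counts), skipped_midsize = skipped)
}

#' Write / read catalogs as COSMIC-layout TSV (channels x samples)
#'
#' @param catalogs a list of `sbs_catalog` (or a single one).
#' @param path output path.
#' @export
write_catalog_tsv <- function(catalogs, path) {
  if (inherits(catalogs, "sbs_catalog")) catalogs <- list(catalogs)
  m <- do.call(cbind, lapply(catalogs, as.integer))
  colnames(m) <- vapply(catalogs, function(x) attr(x, "sample_id"), character(1))
  tab <- data.frame(channel = sbs_channels()$channel, m, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog_tsv
#' @export
read_catalog_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labs <- tab[[1]]
  m <- as.matrix(tab[, -1, drop = FALSE])
  m <- m[match(sbs_channels()$channel, labs), , drop = FALSE]
  lapply(stats::setNames(colnames(m), colnames(m)), function(s)
    structure(as.integer(m[, s]), names = sbs_channels()$channel,
              class = "sbs_catalog", sample_id = s, dropped = 0L))
}
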