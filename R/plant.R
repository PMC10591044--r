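# Synthetic-variant planting: every operation records exact truth in a
# ledger so downstream recovery can be tested without external data.

empty_variants <- function() {
  data.frame(contig = character(), pos = integer(), ref = character(),
             alt = character(), variant_class = character(),
             sample_id = character(), stringsAsFactors = FALSE)
}

new_truth_ledger <- function(seed) {
  structure(list(
    signature_weights = NULL,
    planted_sbs = NULL,
    planted_indels = NULL,
    planted_sv_count = 0L,
    timing_bias = NULL,
    read_support_model = NULL,
    contaminated = character(),
    seed = seed
  ), class = "truth_ledger")
}

# positions eligible per pyrimidine context, optionally restricted to some
# contigs and weighted by a timing track
context_site_pools <- function(index, contigs = NULL) {
  if (is.null(contigs)) contigs <- names(index)
  pools <- vector("list", 32L)
  for (cg in contigs) {
    ctx <- index[[cg]]$ctx
    ok <- which(!is.na(ctx))
    sp <- split(ok, ctx[ok])
    for (nm in names(sp)) {
      i <- as.integer(nm)
      pools[[i]] <- rbind(pools[[i]],
                          data.frame(contig = cg, pos = sp[[nm]],
                                     stringsAsFactors = FALSE))
    }
  }
  pools
}

#' Plant single-base substitutions from a signature mixture
#'
#' Each mutation is drawn by (i) sampling a 96-channel from the mixture
#' `weights %*% signatures`, then (ii) sampling uniformly (or
#' timing-weighted) among genome positions whose pyrimidine-strand
#' trinucleotide matches the channel context, without replacement. A site
#' hosts at most one event. The returned ledger records the channel of every
#' planted event.
#'
#' @param genome genome object.
#' @param n_mutations number of SBS to plant.
#' @param weights named numeric vector of mixture weights over columns of
#'   `signatures`; must sum to 1.
#' @param signatures a [signature_set()].
#' @param seed integer seed.
#' @param contigs contigs eligible for planting (default: all).
#' @param timing optional timing track (see [generate_timing_track()]); when
#'   given, site sampling within each context is weighted by the track's
#'   per-quintile relative rate, and positions outside the track get weight 0.
#' @param sample_id sample label attached to the variants.
#' @param index optional precomputed [genome_context_index()].
#' @return list with `variants` (data.frame of SomaticVariant fields) and
#'   `ledger` (a `truth_ledger` whose `planted_sbs` carries contig, pos, ref,
#'   alt and channel of every event).
#' @export
plant_sbs_from_signatures <- function(genome, n_mutations, weights, signatures,
                                      seed, contigs = NULL, timing = NULL,
                                      sample_id = "sample", index = NULL) {
  if (abs(sum(weights) - 1) > 1e-9) stop("plant_sbs_from_signatures: weights must sum to 1")
  if (!all(names(weights) %in% colnames(signatures)))
    stop("plant_sbs_from_signatures: unknown signature in weights")
  set.seed(seed)
  ledger <- new_truth_ledger(seed)
  ledger$signature_weights <- weights
  ch <- sbs_channels()
  if (n_mutations == 0) {
    ledger$planted_sbs <- cbind(empty_variants(), channel = integer())
    return(list(variants = empty_variants(), ledger = ledger))
  }
  if (is.null(index)) index <- genome_context_index(genome)
  p96 <- as.numeric(unclass(signatures)[, names(weights), drop = FALSE] %*% weights)
  n_per_channel <- as.integer(stats::rmultinom(1, n_mutations, p96))
  ch2ctx <- channel_to_context()
  pools <- context_site_pools(index, contigs)

  site_weight <- NULL
  if (!is.null(timing)) {
    bias <- attr(timing, "bias")
    site_weight <- function(cg, pos) {
      q <- timing_quintile_at(timing, cg, pos)
      w <- ifelse(is.na(q), 0, bias[q])
      w
    }
  }

  rows <- list()
  for (cx in 1:32) {
    channels <- which(ch2ctx == cx)
    need <- n_per_channel[channels]
    k <- sum(need)
    if (k == 0) next
    pool <- pools[[cx]]
    if (is.null(pool) || nrow(pool) == 0)
      stop("plant_sbs_from_signatures: no eligible site for context ", pyr_contexts()[cx])
    if (k > nrow(pool))
      stop("plant_sbs_from_signatures: ", k, " mutations requested for context ",
           pyr_contexts()[cx], " but only ", nrow(pool), " eligible sites")
    prob <- NULL
    if (!is.null(site_weight)) {
      prob <- site_weight(pool$contig, pool$pos)
      if (sum(prob > 0) < k)
        stop("plant_sbs_from_signatures: timing track leaves too few weighted sites")
    }
    pick <- sample.int(nrow(pool), k, prob = prob)
    chosen <- pool[pick, , drop = FALSE]
    # assign alt alleles channel-by-channel within this context
    alt_pyr <- rep(ch$alt[channels], need)
    purine <- mapply(function(cg, p) index[[cg]]$purine[p], chosen$contig, chosen$pos)
    refb <- mapply(function(cg, p) substr(genome_sequences(genome)[[cg]], p, p),
                   chosen$contig, chosen$pos)
    altb <- ifelse(purine, chartr("ACGT", "TGCA", alt_pyr), alt_pyr)
    rows[[length(rows) + 1L]] <- data.frame(
      contig = chosen$contig, pos = chosen$pos, ref = unname(refb),
      alt = unname(altb), channel = rep(channels, need),
      stringsAsFactors = FALSE)
  }
  planted <- do.call(rbind, rows)
  planted <- planted[order(match(planted$contig, names(genome_sequences(genome))),
                           planted$pos), , drop = FALSE]
  rownames(planted) <- NULL
  variants <- data.frame(contig = planted$contig, pos = planted$pos,
                         ref = planted$ref, alt = planted$alt,
                         variant_class = "SBS", sample_id = sample_id,
                         stringsAsFactors = FALSE)
  ledger$planted_sbs <- planted
  list(variants = variants, ledger = ledger)
}

#' Plant cytosine mutations with a controlled TCW enrichment
#'
#' Null / planted-enrichment generator for the enrichment-score analyses:
#' mutated positions are drawn among cytosine (C:G) sites such that the
#' probability that a mutated cytosine sits in a TCW motif equals
#' `fold` times the genome-wide TCW fraction among cytosines. `fold = 1`
#' is the uniform null (every C:G site equally likely). Alt alleles are C>T
#' (pyrimidine strand), so all variants survive the enrichment exclusions.
#'
#' @param genome genome object.
#' @param n number of mutations.
#' @param fold enrichment factor over the background TCW fraction; the
#'   implied TCW probability `fold * background` must be at most 1.
#' @param seed integer seed.
#' @param contigs contigs to plant on (default: all non-chrM).
#' @param sample_id sample label.
#' @param index optional precomputed context index.
#' @return list(variants, ledger); the ledger records the background TCW
#'   fraction and the realized TCW status of every planted site.
#' @export
plant_enriched_cytosine_mutations <- function(genome, n, fold = 1, seed,
                                              contigs = NULL,
                                              sample_id = "sample",
                                              index = NULL) {
  if (is.null(index)) index <- genome_context_index(genome)
  if (is.null(contigs)) contigs <- setdiff(names(index), "chrM")
  set.seed(seed)
  tcw <- list(); ntcw <- list()
  for (cg in contigs) {
    ix <- index[[cg]]
    csite <- which(ix$is_c & !is.na(ix$ctx))
    t <- csite[ix$is_tcw[csite]]
    tcw[[cg]] <- data.frame(contig = cg, pos = t, stringsAsFactors = FALSE)
    nt <- csite[!ix$is_tcw[csite]]
    ntcw[[cg]] <- data.frame(contig = cg, pos = nt, stringsAsFactors = FALSE)
  }
  tcw <- do.call(rbind, tcw); ntcw <- do.call(rbind, ntcw)
  bg <- nrow(tcw) / (nrow(tcw) + nrow(ntcw))
  p <- fold * bg
  if (p > 1) stop("plant_enriched_cytosine_mutations: fold * background > 1")
  k <- stats::rbinom(1, n, p)
  if (k > nrow(tcw) || (n - k) > nrow(ntcw))
    stop("plant_enriched_cytosine_mutations: not enough eligible sites")
  pick <- rbind(cbind(tcw[sample.int(nrow(tcw), k), , drop = FALSE], in_tcw = TRUE),
                cbind(ntcw[sample.int(nrow(ntcw), n - k), , drop = FALSE], in_tcw = FALSE))
  seqs <- genome_sequences(genome)
  refb <- mapply(function(cg, p_) substr(seqs[[cg]], p_, p_), pick$contig, pick$pos)
  altb <- ifelse(refb == "C", "T", "A")   # C>T (or G>A on the purine strand)
  variants <- data.frame(contig = pick$contig, pos = pick$pos,
                         ref = unname(refb), alt = unname(altb),
                         variant_class = "SBS", sample_id = sample_id,
                         stringsAsFactors = FALSE)
  o <- order(match(variants$contig, names(seqs)), variants$pos)
  ledger <- new_truth_ledger(seed)
  ledger$planted_sbs <- cbind(variants, in_tcw = pick$in_tcw)[o, ]
  ledger$background_tcw_fraction <- bg
  ledger$fold <- fold
  list(variants = variants[o, ], ledger = ledger)
}

#' Attach read-support metadata to planted variants
#'
#' Gives each variant (alt_reads, total_reads, vaf). Clean variants always
#' satisfy the downstream quality filter (alt >= 3, depth >= 10, vaf > 0.05):
#' total reads are drawn as `10 + Poisson(depth_mean - 10)` and alt reads as
#' binomial(vaf_mean) clamped into the passing region. A `contaminant_fraction`
#' of variants is instead given support below exactly one of the three
#' thresholds and flagged in the ledger.
#'
#' @param variants variant data.frame.
#' @param depth_mean mean total depth, >= 10 for the clean model.
#' @param vaf_mean mean variant allele fraction of clean variants.
#' @param contaminant_fraction fraction of variants planted sub-threshold.
#' @param seed integer seed.
#' @param ledger optional ledger to extend (its `contaminated` field gets the
#'   `contig:pos` keys of the sub-threshold variants).
#' @return list(variants, ledger): variants gain alt_reads, total_reads, vaf,
#'   filter (always "PASS": sub-threshold support models contamination that
#'   the caller did not catch).
#' @export
attach_read_support <- function(variants, depth_mean = 30, vaf_mean = 0.3,
                                contaminant_fraction = 0, seed,
                                ledger = NULL) {
  if (depth_mean < 1) stop("attach_read_support: depth_mean must be >= 1")
  if (contaminant_fraction < 0 || contaminant_fraction > 1)
    stop("attach_read_support: contaminant_fraction must be in [0,1]")
  set.seed(seed)
  n <- nrow(variants)
  if (is.null(ledger)) ledger <- new_truth_ledger(seed)
  ledger$read_support_model <- list(depth_mean = depth_mean, vaf_mean = vaf_mean,
                                    contaminant_fraction = contaminant_fraction)
  if (n == 0) {
    variants$alt_reads <- integer(); variants$total_reads <- integer()
    variants$vaf <- numeric(); variants$filter <- character()
    return(list(variants = variants, ledger = ledger))
  }
  total <- 10L + stats::rpois(n, max(0, depth_mean - 10))
  alt <- stats::rbinom(n, total, vaf_mean)
  alt <- pmax(alt, 3L)
  low_vaf <- alt / total <= 0.05
  alt[low_vaf] <- floor(0.05 * total[low_vaf]) + 1L
  alt <- pmin(alt, total)

  n_bad <- round(contaminant_fraction * n)
  bad <- sample.int(n, n_bad)
  mode <- sample(c("low_alt", "low_depth", "low_vaf"), n_bad, replace = TRUE)
  for (j in seq_along(bad)) {
    i <- bad[j]
    if (mode[j] == "low_alt") {        # alt < 3, depth and vaf can't rescue
      total[i] <- max(10L, total[i]); alt[i] <- sample(0:2, 1)
    } else if (mode[j] == "low_depth") { # depth < 10
      total[i] <- sample(3:9, 1); alt[i] <- min(total[i], max(3L, stats::rbinom(1, total[i], vaf_mean)))
    } else {                            # vaf <= 0.05 with alt >= 3
      total[i] <- 80L; alt[i] <- sample(3:4, 1)
    }
  }
  variants$alt_reads <- as.integer(alt)
  variants$total_reads <- as.integer(total)
  variants$vaf <- alt / total
  variants$filter <- "PASS"
  ledger$contaminated <- paste0(variants$contig[bad], ":", variants$pos[bad])
  list(variants = variants, ledger = ledger)
}

#' Plant small insertions and deletions by category
#'
#' Plants indels whose classification by [classify_indel()] is guaranteed by
#' construction. Sites are searched (seeded, uniformly) so that the planted
#' representation is already left-aligned and canonical: the anchor base
#' differs from the base closing the deleted/inserted span, microhomology
#' sites are required to carry (for `del_*_MH`) or to lack (for plain 2-4 bp
#' deletions) a >= 2 bp identity between the deleted span and the immediate
#' 3' flank.
#'
#' @param genome genome object.
#' @param counts_by_category named integer vector over the categories of
#'   [classify_indel()]: `ins_1bp_TA`, `ins_1bp_CG`, `del_1bp_TA`,
#'   `del_1bp_CG`, `indel_2bp`, `indel_3bp`, `indel_4bp`, `del_2bp_MH`,
#'   `del_3bp_MH`, `del_4bp_MH`, `indel_5plus`.
#' @param seed integer seed.
#' @param contigs contigs to plant on (default all non-chrM).
#' @param sample_id sample label.
#' @return list(variants, ledger); `ledger$planted_indels` records the
#'   intended category of every event.
#' @export
plant_indels <- function(genome, counts_by_category, seed, contigs = NULL,
                         sample_id = "sample") {
  known <- c("ins_1bp_TA", "ins_1bp_CG", "del_1bp_TA", "del_1bp_CG",
             "indel_2bp", "indel_3bp", "indel_4bp",
             "del_2bp_MH", "del_3bp_MH", "del_4bp_MH", "indel_5plus")
  bad <- setdiff(names(counts_by_category), known)
  if (length(bad)) stop("plant_indels: unknown categories: ", paste(bad, collapse = ", "))
  set.seed(seed)
  seqs <- genome_sequences(genome)
  if (is.null(contigs)) contigs <- setdiff(names(seqs), "chrM")
  ledger <- new_truth_ledger(seed)
  if (length(counts_by_category) == 0 || sum(counts_by_category) == 0) {
    ledger$planted_indels <- cbind(empty_variants(), category = character())
    return(list(variants = empty_variants(), ledger = ledger))
  }
  used <- new.env()  # occupied intervals per contig, coarse collision guard
  claim <- function(cg, from, to) {
    key <- paste0(cg, ":", seq(from, to))
    if (any(vapply(key, exists, logical(1), envir = used))) return(FALSE)
    for (k in key) assign(k, TRUE, envir = used)
    TRUE
  }
  mh_len <- function(s, deleted_start, L, cg) {
    # length of identity between deleted span and immediate 3' flank
    del <- substr(s, deleted_start, deleted_start + L - 1L)
    fl <- substr(s, deleted_start + L, deleted_start + 2L * L - 1L)
    m <- 0L
    while (m < L && m < nchar(fl) &&
           substr(del, m + 1, m + 1) == substr(fl, m + 1, m + 1)) m <- m + 1L
    m
  }
  draw_site <- function(want) {
    # want: list(kind, L, base, mh). Returns one planted row or NULL.
    for (try in 1:5000) {
      cg <- sample(contigs, 1)
      s <- seqs[[cg]]
      Lc <- nchar(s)
      L <- want$L
      p <- sample.int(Lc - 3L * L - 10L, 1) + 2L   # anchor position
      anchor <- substr(s, p, p)
      if (want$kind == "del") {
        span <- substr(s, p + 1L, p + L)
        if (anchor == substr(span, L, L)) next     # keep representation canonical
        if (substr(s, p + L + 1L, p + L + 1L) == substr(span, 1, 1) &&
            is.null(want$mh)) { }                  # handled below via mh_len
        m <- mh_len(s, p + 1L, L, cg)
        if (!is.null(want$mh) && want$mh && m < 2L) next
        if (!is.null(want$mh) && !want$mh && m >= 2L) next
        if (!is.null(want$base) && !(substr(span, 1, 1) %in% want$base)) next
        if (L == 1L && substr(s, p + 2L, p + 2L) == span) next  # no homopolymer shift
        if (!claim(cg, p, p + L)) next
        return(data.frame(contig = cg, pos = p, ref = paste0(anchor, span),
                          alt = anchor, stringsAsFactors = FALSE))
      } else {
        ins <- paste(sample(c("A", "C", "G", "T"),
                            if (is.null(want$base)) L else 0, replace = TRUE),
                     collapse = "")
        if (!is.null(want$base)) ins <- sample(want$base, 1)
        if (substr(ins, nchar(ins), nchar(ins)) == anchor) next
        if (substr(ins, 1, 1) == substr(s, p + 1L, p + 1L)) next  # no right shift
        if (!claim(cg, p, p + 1L)) next
        return(data.frame(contig = cg, pos = p, ref = anchor,
                          alt = paste0(anchor, ins), stringsAsFactors = FALSE))
      }
    }
    stop("plant_indels: could not find a site (genome too small?)")
  }
  spec <- list(
    ins_1bp_TA = list(kind = "ins", L = 1L, base = c("T", "A"), mh = NULL),
    ins_1bp_CG = list(kind = "ins", L = 1L, base = c("C", "G"), mh = NULL),
    del_1bp_TA = list(kind = "del", L = 1L, base = c("T", "A"), mh = NULL),
    del_1bp_CG = list(kind = "del", L = 1L, base = c("C", "G"), mh = NULL),
    indel_2bp  = list(kind = "del", L = 2L, base = NULL, mh = FALSE),
    indel_3bp  = list(kind = "del", L = 3L, base = NULL, mh = FALSE),
    indel_4bp  = list(kind = "del", L = 4L, base = NULL, mh = FALSE),
    del_2bp_MH = list(kind = "del", L = 2L, base = NULL, mh = TRUE),
    del_3bp_MH = list(kind = "del", L = 3L, base = NULL, mh = TRUE),
    del_4bp_MH = list(kind = "del", L = 4L, base = NULL, mh = TRUE),
    indel_5plus = list(kind = "del", L = NA, base = NULL, mh = NULL)
  )
  rows <- list()
  for (cat in names(counts_by_category)) {
    for (i in seq_len(counts_by_category[[cat]])) {
      want <- spec[[cat]]
      if (cat == "indel_5plus") want$L <- sample(5:200, 1)
      r <- draw_site(want)
      r$category <- cat
      rows[[length(rows) + 1L]] <- r
    }
  }
  planted <- do.call(rbind, rows)
  planted <- planted[order(match(planted$contig, names(seqs)), planted$pos), ]
  rownames(planted) <- NULL
  variants <- data.frame(contig = planted$contig, pos = planted$pos,
                         ref = planted$ref, alt = planted$alt,
                         variant_class = ifelse(nchar(planted$ref) > nchar(planted$alt),
                                                "DEL", "INS"),
                         sample_id = sample_id, stringsAsFactors = FALSE)
  ledger$planted_indels <- planted
  list(variants = variants, ledger = ledger)
}

#' Plant Manta-style structural variants
#'
#' Emits symbolic DEL/DUP/INV records (deletions always span > 500 bp),
#' translocations as properly mated breakend (BND) pairs, and complex events
#' as >= 3 breakend records sharing an EVENT id.
#'
#' @param genome genome object.
#' @param counts named vector over `deletion`, `duplication`, `inversion`,
#'   `translocation`, `complex`.
#' @param seed integer seed.
#' @param sample_id sample label.
#' @return list(records, ledger): `records` is a data.frame of VCF-style SV
#'   rows (contig, pos, id, ref, alt, info); `ledger$planted_sv_count` is the
#'   number of events (a BND pair or complex cluster counts once).
#' @export
plant_svs <- function(genome, counts, seed, sample_id = "sample") {
  known <- c("deletion", "duplication", "inversion", "translocation", "complex")
  bad <- setdiff(names(counts), known)
  if (length(bad)) stop("plant_svs: unknown SV types: ", paste(bad, collapse = ", "))
  set.seed(seed)
  seqs <- genome_sequences(genome)
  autos <- setdiff(names(seqs), "chrM")
  rows <- list(); idn <- 0L
  nid <- function() { idn <<- idn + 1L; sprintf("sv%04d", idn) }
  basef <- function(cg, p) substr(seqs[[cg]], p, p)
  for (ty in names(counts)) for (i in seq_len(counts[[ty]])) {
    if (ty %in% c("deletion", "duplication", "inversion")) {
      cg <- sample(autos, 1)
      span <- if (ty == "deletion") sample(501:3000, 1) else sample(200:3000, 1)
      p <- sample.int(nchar(seqs[[cg]]) - span - 2L, 1) + 1L
      svtype <- c(deletion = "DEL", duplication = "DUP", inversion = "INV")[[ty]]
      rows[[length(rows) + 1L]] <- data.frame(
        contig = cg, pos = p, id = nid(), ref = basef(cg, p),
        alt = paste0("<", svtype, ">"),
        info = sprintf("SVTYPE=%s;END=%d", svtype, p + span),
        stringsAsFactors = FALSE)
    } else if (ty == "translocation") {
      if (length(autos) < 2)
        stop("plant_svs: translocations need at least two non-chrM contigs")
      cgs <- sample(autos, 2)
      p1 <- sample.int(nchar(seqs[[cgs[1]]]) - 2L, 1) + 1L
      p2 <- sample.int(nchar(seqs[[cgs[2]]]) - 2L, 1) + 1L
      i1 <- nid(); i2 <- nid()
      rows[[length(rows) + 1L]] <- data.frame(
        contig = cgs[1], pos = p1, id = i1, ref = basef(cgs[1], p1),
        alt = sprintf("%s[%s:%d[", basef(cgs[1], p1), cgs[2], p2),
        info = sprintf("SVTYPE=BND;MATEID=%s", i2), stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        contig = cgs[2], pos = p2, id = i2, ref = basef(cgs[2], p2),
        alt = sprintf("]%s:%d]%s", cgs[1], p1, basef(cgs[2], p2)),
        info = sprintf("SVTYPE=BND;MATEID=%s", i1), stringsAsFactors = FALSE)
    } else { # complex: 3 breakends sharing an EVENT, one mate dangling
      cg <- sample(autos, 1)
      ps <- sort(sample.int(nchar(seqs[[cg]]) - 2L, 3) + 1L)
      ev <- paste0("ev", idn)
      ids <- c(nid(), nid(), nid())
      mates <- c(ids[2], ids[1], "missing_mate")
      for (j in 1:3) rows[[length(rows) + 1L]] <- data.frame(
        contig = cg, pos = ps[j], id = ids[j], ref = basef(cg, ps[j]),
        alt = sprintf("%s[%s:%d[", basef(cg, ps[j]), cg, ps[(j %% 3) + 1]),
        info = sprintf("SVTYPE=BND;MATEID=%s;EVENT=%s", mates[j], ev),
        stringsAsFactors = FALSE)
    }
  }
  records <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(), pos = integer(), id = character(),
               ref = character(), alt = character(), info = character())
  records$sample_id <- sample_id
  ledger <- new_truth_ledger(seed)
  ledger$planted_sv_count <- sum(unlist(counts))
  ledger$planted_sv_types <- counts
  list(records = records, ledger = ledger)
}

#' Generate a replication-timing track
#'
#' Tiles the non-mitochondrial contigs with contiguous fixed-width bins and
#' assigns each bin a distinct timing value (high = early by the package's
#' default convention). The generator's intended quintile of every bin is
#' stored so quintile assignment can be round-trip tested, and the `bias`
#' map (quintile -> relative mutation rate) is attached for use by
#' [plant_sbs_from_signatures()].
#'
#' @param genome genome object.
#' @param n_bins total number of bins (>= 5).
#' @param bias numeric vector of length 5, relative mutation rate per
#'   quintile (quintile 1 = earliest).
#' @param seed integer seed.
#' @return data.frame (contig, start \[0-based\], end, value) with attributes
#'   `quintile` (intended quintile per bin) and `bias`.
#' @export
generate_timing_track <- function(genome, n_bins, bias = rep(1, 5), seed) {
  if (n_bins < 5) stop("generate_timing_track: need at least 5 bins")
  if (length(bias) != 5) stop("generate_timing_track: bias must have 5 entries")
  set.seed(seed)
  seqs <- genome_sequences(genome)
  autos <- setdiff(names(seqs), "chrM")
  lens <- nchar(seqs[autos])
  width <- floor(sum(lens) / n_bins)
  if (width < 1 || width > min(lens))
    stop("generate_timing_track: bins wider than the smallest contig")
  rows <- list()
  for (cg in autos) {
    starts <- seq(0L, nchar(seqs[[cg]]) - width, by = width)
    rows[[cg]] <- data.frame(contig = cg, start = starts, end = starts + width,
                             stringsAsFactors = FALSE)
  }
  track <- do.call(rbind, rows)
  rownames(track) <- NULL
  nb <- nrow(track)
  # distinct values; rank determines quintile (high value = early)
  track$value <- sample(seq_len(nb)) + 0
  r <- rank(-track$value, ties.method = "first")   # 1 = earliest
  q <- ceiling(r / (nb / 5))
  q[q > 5] <- 5L
  attr(track, "quintile") <- as.integer(q)
  attr(track, "bias") <- bias / max(bias)
  track
}

# quintile (1..5) of the generator track bin containing (contig, pos); NA if
# outside the track
timing_quintile_at <- function(track, contig, pos) {
  q <- attr(track, "quintile")
  out <- rep(NA_integer_, length(pos))
  for (cg in unique(contig)) {
    sel <- contig == cg
    bins <- which(track$contig == cg)
    if (!length(bins)) next
    i <- findInterval(pos[sel] - 1L, track$start[bins])
    ok <- i >= 1 & (pos[sel] - 1L) < track$end[bins][pmax(i, 1)]
    out[sel][ok] <- q[bins][i[ok]]
  }
  out
}

#' Write a timing track as bedGraph
#'
#' @param track timing track data.frame (contig, start, end, value).
#' @param path output path.
#' @export
write_timing_bedgraph <- function(track, path) {
  utils::write.table(track[, c("contig", "start", "end", "value")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph / 4-column BED timing track
#'
#' @param path bedGraph path.
#' @return data.frame (contig, start, end, value).
#' @export
read_timing_bedgraph <- function(path) {
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("read_timing_bedgraph: need 4 columns")
  stats::setNames(tab[, 1:4], c("contig", "start", "end", "value"))
}

#' Write / read the truth ledger as JSON
#'
#' @param ledger truth_ledger.
#' @param path output path.
#' @export
write_truth_ledger <- function(ledger, path) {
  jsonlite::write_json(unclass(ledger), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_ledger
#' @export
read_truth_ledger <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "truth_ledger")
}
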