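# Replication-timing quintiles and mutation-cluster (kataegis / omikli)
# detection.

#' Assign timing-track bins to quintiles
#'
#' Bins are ranked by timing value (by default high value = early; set
#' `early_is_high = FALSE` for the opposite dialect — the convention is
#' reference-dependent and must be chosen explicitly for real tracks) and
#' split, earliest first, into 5 groups of equal assayed length (within one
#' bin). Ties are broken deterministically by genomic order.
#'
#' @param track data.frame (contig, start \[0-based half-open\], end, value).
#' @param early_is_high does a high timing value mean early replication?
#' @return the track with a `quintile` column (1 = earliest), class
#'   `timing_quintiles`.
#' @export
assign_timing_quintiles <- function(track, early_is_high = TRUE) {
  if (nrow(track) == 0) stop("assign_timing_quintiles: empty track")
  v <- if (early_is_high) -track$value else track$value
  r <- rank(v, ties.method = "first")
  nb <- nrow(track)
  q <- ceiling(r / (nb / 5))
  q[q > 5] <- 5L
  track$quintile <- as.integer(q)
  class(track) <- c("timing_quintiles", class(track))
  track
}

# quintile of each variant position; NA when outside the assayed track
variant_quintiles <- function(variants, quintiles) {
  out <- rep(NA_integer_, nrow(variants))
  for (cg in unique(variants$contig)) {
    sel <- which(variants$contig == cg)
    bins <- which(quintiles$contig == cg)
    if (!length(bins)) next
    o <- order(quintiles$start[bins])
    bins <- bins[o]
    p0 <- variants$pos[sel] - 1L            # 1-based VCF -> 0-based half-open
    i <- findInterval(p0, quintiles$start[bins])
    ok <- i >= 1 & p0 < quintiles$end[bins][pmax(i, 1L)]
    out[sel[ok]] <- quintiles$quintile[bins][i[ok]]
  }
  out
}

#' Mutation counts per replication-timing quintile
#'
#' Raw and normalized (count / max count) per-quintile mutation counts;
#' when a comparison group is supplied, the chi-square p value of the 2x5
#' contingency between groups is included. Variants outside the assayed
#' track are dropped (count reported).
#'
#' @param variants variant data.frame.
#' @param quintiles a [assign_timing_quintiles()] result.
#' @param comparison optional second variant data.frame.
#' @return list(counts, normalized, dropped, chisq_p (when compared),
#'   comparison_counts).
#' @export
mutations_per_quintile <- function(variants, quintiles, comparison = NULL) {
  q <- variant_quintiles(variants, quintiles)
  counts <- tabulate(q[!is.na(q)], nbins = 5L)
  names(counts) <- paste0("Q", 1:5)
  if (sum(counts) == 0) stop("mutations_per_quintile: no mutations on the assayed track")
  out <- list(counts = counts, normalized = counts / max(counts),
              dropped = sum(is.na(q)))
  if (!is.null(comparison)) {
    q2 <- variant_quintiles(comparison, quintiles)
    c2 <- tabulate(q2[!is.na(q2)], nbins = 5L)
    if (sum(c2) == 0) stop("mutations_per_quintile: comparison group has no mutations")
    out$comparison_counts <- stats::setNames(c2, paste0("Q", 1:5))
    out$chisq_p <- stats::chisq.test(rbind(counts, c2))$p.value
  }
  out
}

#' TC-to-TT fraction per quintile
#'
#' The percentage of mutations in each quintile that are C>T substitutions
#' with a 5' T (pyrimidine-normalized), the APOBEC-preferred TC-to-TT class,
#' among all mutations in that quintile. Empty quintiles yield NA (flagged,
#' not zero).
#'
#' @param variants variant data.frame.
#' @param quintiles timing quintiles.
#' @param genome genome object.
#' @param index optional context index.
#' @return named numeric vector of percentages (Q1..Q5, NA where empty).
#' @export
tcw_to_t_fraction_per_quintile <- function(variants, quintiles, genome,
                                           index = NULL) {
  if (is.null(index)) index <- genome_context_index(genome)
  q <- variant_quintiles(variants, quintiles)
  chan <- trinucleotide_context(variants, genome, index)
  ch <- sbs_channels()
  is_tct <- !is.na(chan) & ch$sub[chan] == "C>T" & ch$five[chan] == "T"
  out <- rep(NA_real_, 5)
  for (k in 1:5) {
    nk <- sum(q == k, na.rm = TRUE)
    if (nk > 0) out[k] <- 100 * sum(is_tct & !is.na(q) & q == k) / nk
  }
  stats::setNames(out, paste0("Q", 1:5))
}

#' Detect clustered mutations (kataegis / omikli)
#'
#' Maximal runs of consecutive mutations with inter-mutation distance at
#' most `kataegis_imd` and at least `kataegis_min` members are kataegis;
#' among the remaining mutations, runs of 2-5 members with inter-mutation
#' distance at most `omikli_imd` are omikli; everything else is dispersed.
#' Every variant is classified exactly once. The thresholds follow the
#' conventions of the clustered-mutagenesis literature and are configurable.
#'
#' @param variants variant data.frame (any order; sorted internally).
#' @param kataegis_imd,kataegis_min kataegis inter-mutation distance (bp)
#'   and minimum run size.
#' @param omikli_imd,omikli_max omikli inter-mutation distance (bp) and
#'   maximum run size (minimum 2).
#' @return data.frame of cluster calls: contig, start, end, n_members,
#'   span, class; singleton dispersed calls included, so
#'   `sum(n_members)` equals the input size.
#' @export
detect_clusters <- function(variants, kataegis_imd = 1000L, kataegis_min = 6L,
                            omikli_imd = 10000L, omikli_max = 5L) {
  if (nrow(variants) == 0)
    return(data.frame(contig = character(), start = integer(), end = integer(),
                      n_members = integer(), span = integer(), class = character()))
  v <- variants[order(variants$contig, variants$pos), ]
  calls <- list()
  runs_of <- function(pos, imd) {
    if (length(pos) == 1) return(rep(1L, 1))
    cumsum(c(1L, as.integer(diff(pos) > imd)))
  }
  for (cg in unique(v$contig)) {
    pos <- v$pos[v$contig == cg]
    kat_run <- runs_of(pos, kataegis_imd)
    kept <- rep(TRUE, length(pos))
    for (rn in unique(kat_run)) {
      m <- which(kat_run == rn)
      if (length(m) >= kataegis_min) {
        calls[[length(calls) + 1L]] <- data.frame(
          contig = cg, start = pos[m[1]], end = pos[m[length(m)]],
          n_members = length(m), span = pos[m[length(m)]] - pos[m[1]],
          class = "kataegis", stringsAsFactors = FALSE)
        kept[m] <- FALSE
      }
    }
    rem <- pos[kept]
    if (length(rem)) {
      om_run <- runs_of(rem, omikli_imd)
      for (rn in unique(om_run)) {
        m <- which(om_run == rn)
        cls <- if (length(m) >= 2 && length(m) <= omikli_max) "omikli" else "dispersed"
        if (cls == "omikli") {
          calls[[length(calls) + 1L]] <- data.frame(
            contig = cg, start = rem[m[1]], end = rem[m[length(m)]],
            n_members = length(m), span = rem[m[length(m)]] - rem[m[1]],
            class = "omikli", stringsAsFactors = FALSE)
        } else {
          calls[[length(calls) + 1L]] <- data.frame(
            contig = cg, start = rem[m], end = rem[m],
            n_members = rep(1L, length(m)), span = rep(0L, length(m)),
            class = "dispersed", stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}
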