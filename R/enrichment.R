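# The APOBEC TCW enrichment score: 41-base window census, double-ratio
# score, one-sided exact significance, BH adjustment, ES stratification.

#' Collect enrichment counts over 41-base windows
#'
#' For each informative variant (already passed [exclude_for_enrichment()]:
#' an SBS at a C:G pair, off the mitochondrial contig, not C-to-A), the
#' substitution is pyrimidine-normalized and a window of `flank` bases up-
#' and downstream of the mutated position (41 bases for the default
#' `flank = 20`) is censused:
#'
#' * `mut_c` gains 1; `mut_tcw` gains 1 iff the mutated cytosine sits in
#'   5'-TCW-3' (W = A or T) on the pyrimidine strand;
#' * `con_c` gains the number of cytosine-strand positions in the window
#'   (C on the plus strand, plus G positions counted as reverse-strand
#'   cytosines); `con_tcw` the number of those in TCW context (TCW or its
#'   reverse complement WGA on the plus strand).
#'
#' Windows are clipped at contig ends; overlapping windows double-count by
#' design (the census is made per substitution and the values aggregated).
#' Positions with N in their trinucleotide are skipped in the Con tallies.
#'
#' @param variants informative variant data.frame.
#' @param genome genome object.
#' @param flank window half-width in bp (default 20).
#' @param motif `"TCW"` (default; W = A or T) or `"TCA"` for the
#'   TCA-only variant of the numerator motif.
#' @param index optional precomputed [genome_context_index()].
#' @return list of class `enrichment_counts`: mut_tcw, mut_c, con_tcw,
#'   con_c, n_windows, motif, flank.
#' @export
collect_enrichment_counts <- function(variants, genome, flank = 20L,
                                      motif = c("TCW", "TCA"), index = NULL) {
  motif <- match.arg(motif)
  if (nrow(variants) == 0) stop("no_informative_mutations")
  if (is.null(index)) index <- genome_context_index(genome)
  motif_ids <- if (motif == "TCW") c(13L, 16L) else 13L  # TCA (,TCT)
  mut_tcw <- 0L; mut_c <- 0L; con_tcw <- 0; con_c <- 0; nw <- 0L
  for (cg in unique(variants$contig)) {
    ix <- index[[cg]]
    if (is.null(ix)) stop("collect_enrichment_counts: contig ", cg, " not in reference")
    pos <- variants$pos[variants$contig == cg]
    in_motif <- if (motif == "TCW") ix$is_tcw[pos] else
      (!is.na(ix$ctx[pos]) & ix$ctx[pos] == 13L)
    usable <- !is.na(ix$ctx[pos])   # a truncated/ambiguous center has no motif call
    mut_c <- mut_c + length(pos)
    mut_tcw <- mut_tcw + sum(in_motif & usable)
    lo <- pmax(1L, pos - flank); hi <- pmin(ix$length, pos + flank)
    cum_c0 <- c(0, ix$cum_c); cum_t0 <- c(0, ix$cum_tcw)
    if (motif == "TCA") {
      is_tca <- !is.na(ix$ctx) & ix$ctx == 13L
      cum_t0 <- c(0, cumsum(is_tca))
    }
    con_c <- con_c + sum(cum_c0[hi + 1L] - cum_c0[lo])
    con_tcw <- con_tcw + sum(cum_t0[hi + 1L] - cum_t0[lo])
    nw <- nw + length(pos)
  }
  structure(list(mut_tcw = as.integer(mut_tcw), mut_c = as.integer(mut_c),
                 con_tcw = as.numeric(con_tcw), con_c = as.numeric(con_c),
                 n_windows = nw, motif = motif, flank = flank),
            class = "enrichment_counts")
}

#' APOBEC enrichment score
#'
#' The double ratio (Mut_TCW / Con_TCW) / (Mut_C / Con_C): the TCW fraction
#' of mutated cytosines relative to the TCW fraction of background cytosines
#' in the aggregated 41-base windows.
#'
#' @param counts an `enrichment_counts` object (or a list with fields
#'   mut_tcw, mut_c, con_tcw, con_c).
#' @return the score, a nonnegative ratio.
#' @export
apobec_enrichment_score <- function(counts) {
  with(counts, {
    if (mut_c <= 0 || con_tcw <= 0 || con_c <= 0)
      stop("apobec_enrichment_score: undefined (zero denominator)")
    (mut_tcw / con_tcw) / (mut_c / con_c)
  })
}

#' One-sided exact significance of TCW enrichment
#'
#' Tests the 2x2 table \[mut_tcw, mut_c - mut_tcw; con_tcw,
#' con_c - con_tcw\] for an excess of TCW among mutated cytosines, by exact
#' hypergeometric tail summation (one-sided Fisher test, alternative:
#' mutated TCW ratio greater than background). Con tallies are rounded to
#' integers for the exact test.
#'
#' @param counts an `enrichment_counts` object.
#' @return list(p_value, odds_direction) where odds_direction is
#'   "enrichment" or "depletion" by comparing the two ratios.
#' @export
enrichment_significance <- function(counts) {
  a <- counts$mut_tcw; b <- counts$mut_c - counts$mut_tcw
  cc <- round(counts$con_tcw); d <- round(counts$con_c - counts$con_tcw)
  if (any(c(a, b, cc, d) < 0)) stop("enrichment_significance: negative table cell")
  # P(X >= a), X ~ Hypergeometric(white = a+cc, black = b+d, drawn = a+b)
  kmax <- min(a + b, a + cc)
  ks <- a:kmax
  p <- if (a == 0) 1 else sum(stats::dhyper(ks, a + cc, b + d, a + b))
  p <- min(1, p)
  dir <- if ((a / max(1, a + b)) >= (cc / max(1, cc + d))) "enrichment" else "depletion"
  list(p_value = p, odds_direction = dir)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate correction (wraps
#' [stats::p.adjust()] with input validation).
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return q-values, same order as input.
#' @export
adjust_bh <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("adjust_bh: p values must be in [0,1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Stratify samples into ES_high / ES_low
#'
#' A sample is ES_high iff its q value is below `q_threshold` AND its score
#' exceeds 1 (so that a significant depletion is never labeled high);
#' everything else is ES_low.
#'
#' @param results data.frame with columns `score` and `q_value`.
#' @param q_threshold FDR threshold (default 0.1).
#' @return `results` with a `stratum` column.
#' @export
stratify_samples <- function(results, q_threshold = 0.1) {
  results$stratum <- ifelse(results$q_value < q_threshold & results$score > 1,
                            "ES_high", "ES_low")
  results
}

#' Per-sample APOBEC enrichment over a cohort
#'
#' Runs the enrichment exclusions, window census, score, one-sided exact
#' test, cohort-wide BH adjustment and stratification for a list of
#' per-sample variant tables. Samples with fewer than `warn_below`
#' informative mutations are kept but flagged with a warning.
#'
#' @param variants_by_sample named list of quality-filtered variant
#'   data.frames.
#' @param genome genome object.
#' @param flank window half-width.
#' @param q_threshold ES_high FDR threshold.
#' @param motif numerator motif, see [collect_enrichment_counts()].
#' @param index optional precomputed context index.
#' @param warn_below informative-mutation count under which a warning is
#'   logged (default 50).
#' @return data.frame: sample_id, mut_tcw, mut_c, con_tcw, con_c, score,
#'   p_value, q_value, stratum.
#' @export
apobec_enrichment <- function(variants_by_sample, genome, flank = 20L,
                              q_threshold = 0.1, motif = "TCW",
                              index = NULL, warn_below = 50L) {
  if (is.null(index)) index <- genome_context_index(genome)
  rows <- lapply(names(variants_by_sample), function(s) {
    inf <- exclude_for_enrichment(variants_by_sample[[s]])
    if (nrow(inf) < warn_below)
      warning("apobec_enrichment: sample ", s, " has only ", nrow(inf),
              " informative mutations")
    cnt <- collect_enrichment_counts(inf, genome, flank = flank,
                                     motif = motif, index = index)
    data.frame(sample_id = s, mut_tcw = cnt$mut_tcw, mut_c = cnt$mut_c,
               con_tcw = cnt$con_tcw, con_c = cnt$con_c,
               score = apobec_enrichment_score(cnt),
               p_value = enrichment_significance(cnt)$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- adjust_bh(out$p_value)
  stratify_samples(out, q_threshold)
}
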