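# Cohort-level statistics: correlations, group comparisons, ES-stratified
# structural-variation comparison, and the IHC H-score arithmetic.

#' Correlation between two sample features
#'
#' Pearson product-moment or Spearman rank correlation with a two-sided p
#' value (wraps [stats::cor.test()]); missing values are excluded pairwise.
#' For Pearson, the fitted least-squares line is returned.
#'
#' @param x,y paired numeric vectors.
#' @param method "pearson" or "spearman".
#' @return list(coefficient, p_value, n, and for pearson `intercept`,
#'   `slope`).
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("correlate: need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlate: constant vector, coefficient undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         alternative = "two.sided", exact = FALSE))
  out <- list(coefficient = unname(ct$estimate), p_value = ct$p.value,
              n = length(x), method = method)
  if (method == "pearson") {
    fit <- stats::lm(y ~ x)
    out$intercept <- unname(stats::coef(fit)[1])
    out$slope <- unname(stats::coef(fit)[2])
  }
  out
}

#' Compare two groups
#'
#' Mann-Whitney U (exact for small tie-free samples, normal approximation
#' with tie correction otherwise; wraps [stats::wilcox.test()]), Fisher's
#' exact 2x2 test, or the chi-square test. Two-sided by default.
#'
#' @param values_a,values_b numeric vectors (for mann_whitney) or the two
#'   rows of a contingency table (for fisher_2x2 / chi_square).
#' @param test one of "mann_whitney", "fisher_2x2", "chi_square".
#' @param alternative passed through for mann_whitney / fisher_2x2.
#' @return list(p_value, statistic, test, df where applicable).
#' @export
compare_groups <- function(values_a, values_b,
                           test = c("mann_whitney", "fisher_2x2", "chi_square"),
                           alternative = "two.sided") {
  test <- match.arg(test)
  if (length(values_a) == 0 || length(values_b) == 0)
    stop("compare_groups: empty group")
  if (test == "mann_whitney") {
    wt <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                              alternative = alternative))
    list(p_value = wt$p.value, statistic = unname(wt$statistic),
         test = "mann_whitney")
  } else if (test == "fisher_2x2") {
    tab <- rbind(values_a, values_b)
    if (!all(dim(tab) == c(2, 2))) stop("compare_groups: fisher_2x2 needs a 2x2 table")
    ft <- stats::fisher.test(tab, alternative = alternative)
    list(p_value = ft$p.value, statistic = unname(ft$estimate),
         test = "fisher_2x2")
  } else {
    tab <- rbind(values_a, values_b)
    cq <- suppressWarnings(stats::chisq.test(tab))
    list(p_value = cq$p.value, statistic = unname(cq$statistic),
         df = unname(cq$parameter), test = "chi_square")
  }
}

#' ES-stratified structural-variation comparison
#'
#' Compares total structural-variation counts across the WT group and the
#' ES_low / ES_high strata of the transgenic group, with pairwise
#' Mann-Whitney p values. Strata with fewer than 2 samples are skipped with
#' a notice.
#'
#' @param table data.frame with columns sample_id, group, stratum,
#'   sv_total; rows with `group == wt_label` form the WT arm, the others
#'   are split by `stratum`.
#' @param wt_label group label of the control arm (default "WT").
#' @return list(strata = named list of per-stratum sv counts, medians,
#'   pairwise = data.frame(a, b, p_value), skipped = character notices).
#' @export
es_stratified_sv_comparison <- function(table, wt_label = "WT") {
  need <- c("group", "stratum", "sv_total")
  if (!all(need %in% names(table)))
    stop("es_stratified_sv_comparison: table needs columns ",
         paste(need, collapse = ", "))
  strata <- list(
    WT = table$sv_total[table$group == wt_label],
    ES_low = table$sv_total[table$group != wt_label & table$stratum == "ES_low"],
    ES_high = table$sv_total[table$group != wt_label & table$stratum == "ES_high"]
  )
  medians <- vapply(strata, function(x) if (length(x)) stats::median(x) else NA_real_,
                    numeric(1))
  pairs <- utils::combn(names(strata), 2, simplify = FALSE)
  rows <- list(); skipped <- character(0)
  for (pr in pairs) {
    a <- strata[[pr[1]]]; b <- strata[[pr[2]]]
    if (length(a) < 2 || length(b) < 2) {
      skipped <- c(skipped, paste0(pr[1], " vs ", pr[2],
                                   ": fewer than 2 samples in a stratum"))
      next
    }
    p <- compare_groups(a, b, "mann_whitney")$p_value
    rows[[length(rows) + 1L]] <- data.frame(a = pr[1], b = pr[2], p_value = p,
                                            stringsAsFactors = FALSE)
  }
  list(strata = strata, medians = medians,
       pairwise = if (length(rows)) do.call(rbind, rows) else
         data.frame(a = character(), b = character(), p_value = numeric()),
       skipped = skipped)
}

#' IHC H-score
#'
#' H-score = 1 x (% weak-positive cells) + 2 x (% moderate-positive cells)
#' + 3 x (% strong-positive cells), range 0-300.
#'
#' @param pct_weak,pct_moderate,pct_strong staining percentages; their sum
#'   must not exceed 100 (the remainder is negative cells).
#' @return H-score in \[0, 300\].
#' @export
h_score <- function(pct_weak, pct_moderate, pct_strong) {
  p <- c(pct_weak, pct_moderate, pct_strong)
  if (any(p < 0 | p > 100)) stop("h_score: percentages must be in [0,100]")
  if (pct_weak + pct_moderate + pct_strong > 100 + 1e-9)
    stop("h_score: percentages sum to more than 100")
  1 * pct_weak + 2 * pct_moderate + 3 * pct_strong
}
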