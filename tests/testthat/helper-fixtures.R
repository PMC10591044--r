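# Shared fixtures (built once per run) and independent brute-force oracles.
# Oracles are deliberately written with naive string/enumeration logic so
# they share no code with the implementation they check.

.fixtures <- new.env(parent = emptyenv())

test_genome <- function() {
  if (is.null(.fixtures$g)) {
    .fixtures$g <- generate_genome(1, 150000L, 0.42, seed = 101)
    .fixtures$ix <- genome_context_index(.fixtures$g)
  }
  .fixtures$g
}
test_index <- function() { test_genome(); .fixtures$ix }
test_refs <- function() {
  if (is.null(.fixtures$refs)) .fixtures$refs <- reference_signatures(include_flat = TRUE)
  .fixtures$refs
}

empty_variants_df <- function() {
  data.frame(contig = character(), pos = integer(), ref = character(),
             alt = character(), variant_class = character(),
             sample_id = character(), stringsAsFactors = FALSE)
}

string_genome <- function(...) {
  seqs <- c(...)
  structure(list(contigs = seqs, gc_fraction = NA, seed = NA),
            class = "synthetic_genome")
}

# naive pyrimidine-strand trinucleotide at position p (NA at ends / Ns)
oracle_pyr_tri <- function(s, p) {
  if (p <= 1 || p >= nchar(s)) return(NA_character_)
  tri <- substr(s, p - 1, p + 1)
  if (grepl("[^ACGT]", tri)) return(NA_character_)
  cen <- substr(tri, 2, 2)
  if (cen %in% c("A", "G")) {
    rc <- chartr("ACGT", "TGCA", tri)
    tri <- paste(rev(strsplit(rc, "")[[1]]), collapse = "")
  }
  tri
}

oracle_is_tcw <- function(s, p) {
  tri <- oracle_pyr_tri(s, p)
  if (is.na(tri)) return(NA)
  tri %in% c("TCA", "TCT")
}

# naive 41-base window census for one mutated position
oracle_window_census <- function(s, p, flank = 20L) {
  con_c <- 0L; con_tcw <- 0L
  for (j in max(1, p - flank):min(nchar(s), p + flank)) {
    cen <- substr(s, j, j)
    if (cen %in% c("C", "G")) con_c <- con_c + 1L
    if (isTRUE(oracle_is_tcw(s, j))) con_tcw <- con_tcw + 1L
  }
  mut_tcw <- as.integer(isTRUE(oracle_is_tcw(s, p)))
  c(mut_tcw = mut_tcw, mut_c = 1L, con_tcw = con_tcw, con_c = con_c)
}

# one-sided Fisher (enrichment alternative) by direct enumeration of the
# hypergeometric tail from binomial coefficients
oracle_fisher_greater <- function(a, b, cc, d) {
  n1 <- a + b; n2 <- cc + d; K <- a + cc; N <- n1 + n2
  ks <- max(0, K - n2):min(n1, K)
  logp <- lchoose(n1, ks) + lchoose(n2, K - ks) - lchoose(N, K)
  sum(exp(logp[ks >= a]))
}

# brute-force Benjamini-Hochberg: q_i = min over {j : p_j >= p_i} of m p_j / rank_j
oracle_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "max")
  vapply(seq_len(m), function(i) {
    cand <- which(p >= p[i] - 1e-15)
    min(1, min(m * p[cand] / r[cand]))
  }, numeric(1))
}

# exact two-sided Mann-Whitney p by enumerating all group assignments of the
# observed pooled values (tie-free inputs only)
oracle_mw_two_sided <- function(a, b) {
  na <- length(a); nb <- length(b)
  pool <- c(a, b)
  u_of <- function(x, y) sum(outer(x, y, ">")) # U for first sample
  u_obs <- u_of(a, b)
  combos <- utils::combn(na + nb, na)
  us <- apply(combos, 2, function(idx) u_of(pool[idx], pool[-idx]))
  p_le <- mean(us <= u_obs); p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# naive microhomology length between a deleted span and its 3' flank
oracle_mh_length <- function(deleted, flank) {
  m <- 0L
  while (m < nchar(deleted) && m < nchar(flank) &&
         substr(deleted, m + 1, m + 1) == substr(flank, m + 1, m + 1)) m <- m + 1L
  m
}
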