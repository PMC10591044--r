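#' SBS-96 channel table
#'
#' The canonical COSMIC single-base-substitution classification: six
#' pyrimidine-strand substitutions (C>A, C>G, C>T, T>A, T>C, T>G), each split
#' by the 5' and 3' flanking base, in the standard ordering (substitution
#' major, then 5' base A,C,G,T, then 3' base A,C,G,T).
#'
#' @return A 96-row data.frame with columns `channel` (label such as
#'   `"T[C>T]A"`), `sub`, `ref`, `alt`, `five`, `three` and `context`
#'   (the pyrimidine-strand trinucleotide, e.g. `"TCA"`).
#' @export
sbs_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(three = bases, five = bases, sub = subs,
                      stringsAsFactors = FALSE)[, c("sub", "five", "three")]
  ref <- substr(grid$sub, 1, 1)
  alt <- substr(grid$sub, 3, 3)
  data.frame(
    channel = paste0(grid$five, "[", grid$sub, "]", grid$three),
    sub = grid$sub, ref = ref, alt = alt,
    five = grid$five, three = grid$three,
    context = paste0(grid$five, ref, grid$three),
    stringsAsFactors = FALSE
  )
}

# The 32 pyrimidine-strand trinucleotide contexts, in the order implied by
# sbs_channels(): 16 C-centered then 16 T-centered.
pyr_contexts <- function() {
  bases <- c("A", "C", "G", "T")
  g <- expand.grid(three = bases, five = bases, stringsAsFactors = FALSE)
  c(paste0(g$five, "C", g$three), paste0(g$five, "T", g$three))
}

# channel index (1..96) -> pyrimidine context index (1..32)
channel_to_context <- function() {
  ch <- sbs_channels()
  match(ch$context, pyr_contexts())
}

base_codes <- c(A = 1L, C = 2L, G = 3L, T = 4L)
comp_code <- function(code) 5L - code

#' Reverse complement of a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors.
#'
#' @param x character vector of DNA strings (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Cosine similarity between two nonnegative spectra
#'
#' @param a,b numeric vectors of equal length, nonnegative, not all zero.
#' @return similarity in \[0, 1\].
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (any(a < 0) || any(b < 0)) stop("cosine_similarity: negative entries")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine_similarity: zero vector")
  sum(a * b) / (na * nb)
}
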