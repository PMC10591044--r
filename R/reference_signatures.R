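#' Signature set constructor
#'
#' A signature set is a 96 x K column-stochastic matrix (each column a
#' mutational signature summing to 1) with named columns, rows in canonical
#' SBS-96 channel order.
#'
#' @param matrix numeric 96 x K matrix, nonnegative; columns are normalized
#'   to sum to 1.
#' @param names optional column names (taken from `colnames(matrix)` if
#'   absent).
#' @return An object of class `signature_set`: the normalized matrix with
#'   rownames set to the 96 channel labels.
#' @export
signature_set <- function(matrix, names = colnames(matrix)) {
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != 96L) stop("signature_set: matrix must have 96 rows")
  if (any(matrix < 0)) stop("signature_set: negative entries")
  cs <- colSums(matrix)
  if (any(cs == 0)) stop("signature_set: zero column")
  matrix <- sweep(matrix, 2, cs, "/")
  if (is.null(names)) names <- paste0("S", seq_len(ncol(matrix)))
  colnames(matrix) <- names
  rownames(matrix) <- sbs_channels()$channel
  structure(matrix, class = c("signature_set", "matrix", "array"))
}

#' Uniform ("flat") background signature
#'
#' The uniform distribution over the 96 channels, used as the aging-like
#' background in the synthetic cohorts. Deliberately not a COSMIC signature:
#' it requires no external data and makes planted mixtures exactly known.
#'
#' @return signature_set with one column named `"flat"`.
#' @export
uniform_signature <- function() {
  signature_set(matrix(rep(1 / 96, 96), ncol = 1), names = "flat")
}

#' Synthetic stand-in for the COSMIC SBS1-SBS30 reference set
#'
#' A fully synthetic 96 x 30 reference signature matrix with the same layout
#' as the COSMIC v2 SBS1-SBS30 set. It is NOT the COSMIC data: the three
#' signatures this package's analyses depend on are hand-specified with the
#' biological structure they are known for, and the remainder are sparse
#' random profiles (fixed internal seed) that play the role of decoy
#' signatures during refitting:
#'
#' * `SBS1`: C>T concentrated at NCG contexts (CpG deamination-like);
#' * `SBS2`: C>T concentrated at TCN, dominated by TCA/TCT/TCC (APOBEC-like);
#' * `SBS5`: near-flat across all 96 channels (clock-like background);
#' * `SBS13`: C>G (plus some C>A) concentrated at TCN (APOBEC-like).
#'
#' Any real 96-row COSMIC-layout TSV can be substituted via
#' [read_signature_tsv()].
#'
#' @param include_flat if TRUE, append the exact uniform background signature
#'   (column `"flat"`) used by the synthetic generator.
#' @return signature_set with 30 (or 31) columns named `SBS1`..`SBS30`
#'   (, `"flat"`).
#' @export
reference_signatures <- function(include_flat = FALSE) {
  ch <- sbs_channels()
  K <- 30L
  mat <- matrix(0, 96L, K, dimnames = list(ch$channel, paste0("SBS", 1:K)))

  # SBS1-like: C>T at NCG
  w <- as.numeric(ch$sub == "C>T" & ch$three == "G")
  mat[, "SBS1"] <- w * c(1.0, 0.9, 1.1, 0.8)[match(ch$five, c("A", "C", "G", "T"))]

  # SBS2-like: C>T at TCN with the APOBEC TCW preference
  w <- as.numeric(ch$sub == "C>T" & ch$five == "T")
  mat[, "SBS2"] <- w * c(A = 0.38, C = 0.14, G = 0.07, T = 0.36)[ch$three] +
    # trace mass elsewhere so the profile is not exactly degenerate
    as.numeric(ch$sub == "C>T") * 0.002

  # SBS5-like: broad clock-like profile with the characteristic T>C tilt
  # (kept clearly distinct from the exactly uniform "flat" background so
  # refitting stays identifiable)
  mat[, "SBS5"] <- 0.5 + 2.5 * as.numeric(ch$sub == "T>C") +
    0.5 * as.numeric(ch$sub == "C>T")

  # SBS13-like: C>G (and some C>A) at TCN
  mat[, "SBS13"] <- as.numeric(ch$sub == "C>G" & ch$five == "T") * 0.8 +
    as.numeric(ch$sub == "C>A" & ch$five == "T") * 0.2

  # remaining signatures: sparse random decoy profiles, fixed seed
  rest <- setdiff(colnames(mat), c("SBS1", "SBS2", "SBS5", "SBS13"))
  rng <- local({
    set.seed(19870426)
    lapply(rest, function(nm) stats::rgamma(96, shape = 0.25, rate = 1))
  })
  for (i in seq_along(rest)) mat[, rest[i]] <- rng[[i]] + 1e-6

  ss <- signature_set(mat)
  if (include_flat) {
    ss <- signature_set(cbind(ss, uniform_signature()),
                        names = c(colnames(ss), "flat"))
  }
  ss
}

#' Read / write a COSMIC-layout signature TSV
#'
#' The on-disk format is a tab-separated table whose first column holds the
#' 96 channel labels (`A[C>A]A`, ...) in canonical order and whose remaining
#' columns are signatures.
#'
#' @param path file path.
#' @return `read_signature_tsv`: a signature_set.
#' @export
read_signature_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labs <- tab[[1]]
  if (!identical(sort(labs), sort(sbs_channels()$channel)))
    stop("read_signature_tsv: first column must hold the 96 SBS channel labels")
  m <- as.matrix(tab[, -1, drop = FALSE])
  m <- m[match(sbs_channels()$channel, labs), , drop = FALSE]
  signature_set(m)
}

#' @rdname read_signature_tsv
#' @param sigs signature_set to write.
#' @export
write_signature_tsv <- function(sigs, path) {
  tab <- data.frame(channel = rownames(sigs), as.data.frame(unclass(sigs)),
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
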