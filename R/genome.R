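#' Generate a synthetic reference genome
#'
#' Draws contig sequences as i.i.d. bases with the requested GC content.
#' The last contig is always the designated mitochondrial contig `"chrM"`;
#' autosome-like contigs are named `chr1`, `chr2`, ... No `N` bases are ever
#' emitted, so the truth about every planted variant is exact.
#'
#' @param n_contigs number of non-mitochondrial contigs.
#' @param lengths integer vector of contig lengths (bp), length `n_contigs`.
#' @param gc_fraction target GC content, strictly inside (0, 1).
#' @param seed integer seed; the genome is fully determined by the arguments.
#' @param chrM_length length of the mitochondrial contig (default 16299,
#'   mouse-mitochondrion-sized).
#' @return An object of class `synthetic_genome`: a named list with element
#'   `contigs`, a named character vector of uppercase A/C/G/T sequences.
#' @export
generate_genome <- function(n_contigs, lengths, gc_fraction, seed,
                            chrM_length = 16299L) {
  if (length(lengths) != n_contigs) stop("generate_genome: lengths must have n_contigs entries")
  if (any(lengths <= 0) || chrM_length <= 0) stop("generate_genome: non-positive contig length")
  if (!(gc_fraction > 0 && gc_fraction < 1)) stop("generate_genome: gc_fraction must be in (0,1)")
  set.seed(seed)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  draw <- function(n) paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
  contigs <- vapply(lengths, draw, character(1))
  names(contigs) <- paste0("chr", seq_len(n_contigs))
  contigs <- c(contigs, chrM = "")
  names(contigs)[n_contigs + 1L] <- "chrM"
  contigs["chrM"] <- draw(chrM_length)
  structure(list(contigs = contigs, gc_fraction = gc_fraction, seed = seed),
            class = "synthetic_genome")
}

# Normalize genome-like inputs (synthetic_genome, DNAStringSet, named
# character vector) to a named character vector of sequences.
genome_sequences <- function(genome) {
  if (inherits(genome, "synthetic_genome")) return(genome$contigs)
  if (methods::is(genome, "DNAStringSet")) {
    x <- as.character(genome)
    return(x)
  }
  if (is.character(genome) && !is.null(names(genome))) return(genome)
  stop("unsupported genome representation")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  len <- nchar(x$contigs)
  cat("synthetic_genome:", length(len), "contigs,",
      format(sum(len), big.mark = ","), "bp total\n")
  for (nm in names(len)) cat(" ", nm, ":", format(len[[nm]], big.mark = ","), "bp\n")
  invisible(x)
}

#' Per-position trinucleotide context index
#'
#' Precomputes, for every position of every contig, the pyrimidine-strand
#' trinucleotide context (purine-centered positions are reverse-complemented)
#' plus the cumulative tallies the enrichment-score window census needs.
#' Positions at contig ends or with a non-ACGT base in the trinucleotide get
#' `NA` context and are skipped in motif tallies.
#'
#' @param genome a `synthetic_genome`, `DNAStringSet`, or named character
#'   vector of contig sequences.
#' @return list of class `genome_context_index`, one element per contig with
#'   fields `ctx` (integer 1..32 into [pyr_contexts()] or NA), `purine`
#'   (logical: reference base is A/G), `is_c` (reference base is C or G),
#'   `is_tcw` (pyrimidine context is TCA or TCT), and cumulative sums
#'   `cum_c`, `cum_tcw` for O(1) window censuses.
#' @export
genome_context_index <- function(genome) {
  seqs <- genome_sequences(genome)
  ctxs <- pyr_contexts()
  out <- lapply(seqs, function(s) {
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    code <- unname(base_codes[v])            # NA for non-ACGT
    L <- length(code)
    five <- c(NA_integer_, code[-L])
    three <- c(code[-1], NA_integer_)
    cent <- code
    pur <- !is.na(cent) & (cent == 1L | cent == 3L)
    # reverse-complement purine-centered triplets
    f <- ifelse(pur, comp_code(three), five)
    t3 <- ifelse(pur, comp_code(five), three)
    cpy <- ifelse(pur, comp_code(cent), cent)  # 2 = C, 4 = T
    ctx <- ifelse(is.na(f) | is.na(t3) | is.na(cpy), NA_integer_,
                  (cpy == 4L) * 16L + (f - 1L) * 4L + t3)
    is_c <- !is.na(cent) & (cent == 2L | cent == 3L)
    is_tcw <- !is.na(ctx) & (ctx == 13L | ctx == 16L)  # TCA, TCT
    list(ctx = as.integer(ctx), purine = pur, is_c = is_c, is_tcw = is_tcw,
         cum_c = cumsum(is_c), cum_tcw = cumsum(is_tcw), length = L)
  })
  stopifnot(identical(ctxs[13L], "TCA"), identical(ctxs[16L], "TCT"))
  structure(out, class = "genome_context_index")
}

#' Write / read a genome as FASTA with a plain-text index
#'
#' FASTA IO goes through Biostrings; alongside the FASTA a samtools-style
#' `.fai` index (name, length, offset, linebases, linewidth) is written as
#' plain text.
#'
#' @param genome a genome (see [genome_context_index()] for accepted forms).
#' @param path output FASTA path.
#' @return the path, invisibly; `read_genome_fasta` returns a
#'   `synthetic_genome`.
#' @export
write_genome_fasta <- function(genome, path) {
  seqs <- genome_sequences(genome)
  dss <- Biostrings::DNAStringSet(seqs)
  width <- 70L
  Biostrings::writeXStringSet(dss, path, width = width)
  # plain-text .fai
  lens <- nchar(seqs)
  offsets <- numeric(length(seqs))
  off <- 0
  for (i in seq_along(seqs)) {
    off <- off + nchar(names(seqs)[i]) + 2  # ">name\n"
    offsets[i] <- off
    nlines <- ceiling(lens[i] / width)
    off <- off + lens[i] + nlines           # sequence + newlines
  }
  fai <- data.frame(names(seqs), lens, format(offsets, scientific = FALSE, trim = TRUE),
                    width, width + 1L)
  utils::write.table(fai, paste0(path, ".fai"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  contigs <- as.character(dss)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  structure(list(contigs = contigs, gc_fraction = NA_real_, seed = NA_integer_),
            class = "synthetic_genome")
}

#' Reverse-complement an entire genome
#'
#' Utility for strand-symmetry property checks: every contig is
#' reverse-complemented (coordinates flip end-for-end).
#'
#' @param genome genome object.
#' @return a `synthetic_genome` with reverse-complemented contigs.
#' @export
revcomp_genome <- function(genome) {
  seqs <- genome_sequences(genome)
  structure(list(contigs = stats::setNames(revcomp(seqs), names(seqs)),
                 gc_fraction = NA_real_, seed = NA_integer_),
            class = "synthetic_genome")
}
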