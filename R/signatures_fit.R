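# Signature refitting (iterative one-dimensional weight search with a
# discard threshold, after the deconstructSigs scheme) and de novo
# extraction by KL-divergence multiplicative-update NMF.

#' Refit a catalog against reference signatures
#'
#' The catalog is normalized to channel frequencies and nonnegative weights
#' over the reference signatures are found by iterated one-dimensional line
#' search (golden-section via [stats::optimize()]) minimizing the squared
#' reconstruction error, one signature at a time, until the error stops
#' improving. Signatures whose fitted weight falls below `prune_threshold`
#' of the total are zeroed and the fit repeated until stable. Reported
#' weights are fractions of explained mass (they sum to 1); the residual
#' fraction of the fit mass is reported as `unexplained`.
#'
#' @param catalog `sbs_catalog` or numeric 96-vector of counts.
#' @param refs a [signature_set()].
#' @param prune_threshold discard threshold for small weights (default 0.06).
#' @return list of class `exposure_vector`: sample_id, weights (named, sum
#'   1), unexplained, error (final squared reconstruction error).
#' @export
refit_exposures <- function(catalog, refs, prune_threshold = 0.06) {
  counts <- as.numeric(catalog)
  if (length(counts) != 96L) stop("refit_exposures: catalog must have 96 channels")
  if (sum(counts) <= 0) stop("refit_exposures: zero catalog")
  t0 <- counts / sum(counts)
  S <- unclass(refs)
  K <- ncol(S)
  sse <- function(w) sum((t0 - as.numeric(S %*% w))^2)
  fit_once <- function(active, max_sweeps = 200L) {
    w <- rep(0, K)
    err <- sse(w)
    for (sweep in seq_len(max_sweeps)) {
      improved <- FALSE
      for (k in which(active)) {
        f <- function(x) { wk <- w; wk[k] <- x; sse(wk) }
        o <- stats::optimize(f, interval = c(0, 2), tol = 1e-9)
        if (o$objective < err - 1e-10) {
          w[k] <- o$minimum; err <- o$objective; improved <- TRUE
        }
      }
      if (!improved) break
    }
    list(w = w, err = err)
  }
  active <- rep(TRUE, K)
  repeat {
    ft <- fit_once(active)
    tot <- sum(ft$w)
    if (tot <= 0) stop("refit_exposures: degenerate fit (all weights zero)")
    frac <- ft$w / tot
    small <- active & frac > 0 & frac < prune_threshold
    if (!any(small)) break
    active <- active & frac >= prune_threshold
    if (!any(active)) active <- seq_len(K) == which.max(ft$w)
  }
  w <- ft$w
  # polish: exact least-squares solve on the surviving active set (accepted
  # only if it stays nonnegative and improves the objective), which makes
  # refitting a reconstruction reproduce its own exposure to solver precision
  act <- which(w > 0)
  if (length(act)) {
    coefs <- tryCatch(qr.coef(qr(S[, act, drop = FALSE]), t0),
                      error = function(e) NULL)
    if (!is.null(coefs) && !anyNA(coefs) && all(coefs >= 0)) {
      w2 <- rep(0, K); w2[act] <- coefs
      if (sse(w2) <= ft$err) { w <- w2; ft$err <- sse(w2) }
    }
  }
  weights <- w / sum(w)
  names(weights) <- colnames(S)
  recon <- as.numeric(S %*% w)
  structure(list(sample_id = attr(catalog, "sample_id"),
                 weights = weights,
                 unexplained = max(0, 1 - sum(w)),
                 error = ft$err,
                 reconstruction = recon),
            class = "exposure_vector")
}

#' Fraction of a catalog attributed to one signature, in percent
#'
#' Convenience accessor used for the %SBS2 axis of the cohort analyses.
#'
#' @param exposures an `exposure_vector` from [refit_exposures()].
#' @param signature signature name (default `"SBS2"`).
#' @return percentage in \[0, 100\].
#' @export
sbs2_percentage <- function(exposures, signature = "SBS2") {
  w <- exposures$weights
  if (!signature %in% names(w)) return(0)
  100 * unname(w[[signature]])
}

# generalized KL divergence D(V || WH), the NMF objective
kl_div <- function(V, WH) {
  eps <- 1e-12
  sum(V * log((V + eps) / (WH + eps)) - V + WH)
}

#' De novo signature extraction by NMF
#'
#' Factorizes a 96 x S count matrix as W H with multiplicative updates
#' minimizing the generalized Kullback-Leibler divergence, taking the best
#' of `n_restarts` seeded random initializations. Signature columns are
#' normalized to sum 1 with exposures rescaled compensatingly. Deterministic
#' for a fixed seed.
#'
#' @param catalog_matrix 96 x S nonnegative matrix (samples in columns).
#' @param rank number of signatures to extract (1 <= rank <= S).
#' @param n_restarts random restarts (default 10).
#' @param seed integer seed.
#' @param max_iter,tol iteration cap and relative-improvement tolerance.
#' @param trace if TRUE, record the KL divergence at every iteration of the
#'   best restart (attribute `divergence_trace` on the result); the
#'   multiplicative updates guarantee it is non-increasing.
#' @return list(signatures = signature_set (96 x rank, columns
#'   `denovo1`..), exposures = rank x S matrix, divergence = final KL).
#' @export
extract_denovo <- function(catalog_matrix, rank, n_restarts = 10L, seed = 1L,
                           max_iter = 2000L, tol = 1e-9, trace = FALSE) {
  V <- as.matrix(catalog_matrix)
  if (any(V < 0)) stop("extract_denovo: negative counts")
  if (any(colSums(V) == 0)) stop("extract_denovo: all-zero sample column")
  S <- ncol(V)
  if (rank < 1 || rank > S) stop("extract_denovo: rank must be in [1, n_samples]")
  set.seed(seed)
  eps <- 1e-12
  best <- NULL
  for (r in seq_len(n_restarts)) {
    W <- matrix(stats::runif(96 * rank, 0.1, 1), 96, rank)
    H <- matrix(stats::runif(rank * S, 0.1, 1), rank, S)
    d_prev <- Inf
    dtrace <- if (trace) numeric(0) else NULL
    for (it in seq_len(max_iter)) {
      WH <- W %*% H
      H <- H * (t(W) %*% (V / (WH + eps))) / (colSums(W) + eps)
      WH <- W %*% H
      W <- W * ((V / (WH + eps)) %*% t(H)) / rep(rowSums(H) + eps, each = 96)
      if (trace) dtrace <- c(dtrace, kl_div(V, W %*% H))
      if (it %% 10 == 0) {
        d <- kl_div(V, W %*% H)
        if (is.finite(d_prev) && (d_prev - d) < tol * max(1, d_prev)) break
        d_prev <- d
      }
    }
    d <- kl_div(V, W %*% H)
    if (is.null(best) || d < best$divergence)
      best <- list(W = W, H = H, divergence = d, trace = dtrace)
  }
  cs <- colSums(best$W)
  W <- sweep(best$W, 2, cs, "/")
  H <- sweep(best$H, 1, cs, "*")
  colnames(W) <- paste0("denovo", seq_len(rank))
  rownames(H) <- colnames(W)
  colnames(H) <- colnames(V)
  out <- list(signatures = signature_set(W), exposures = H,
              divergence = best$divergence)
  if (trace) attr(out, "divergence_trace") <- best$trace
  out
}

#' Match de novo signatures to a reference set
#'
#' For each extracted signature, the reference with the highest cosine
#' similarity (ties broken by reference order, with a warning). Matching
#' never fails: a poor best match is reported with its (low) similarity.
#'
#' @param denovo,refs signature_sets.
#' @return data.frame: denovo, best_ref, similarity.
#' @export
match_to_reference <- function(denovo, refs) {
  D <- unclass(denovo); R <- unclass(refs)
  rows <- lapply(colnames(D), function(d) {
    sims <- apply(R, 2, function(r) cosine_similarity(D[, d], r))
    best <- which.max(sims)
    if (sum(abs(sims - sims[best]) < 1e-12) > 1)
      warning("match_to_reference: tie for ", d, "; keeping reference order")
    data.frame(denovo = d, best_ref = colnames(R)[best],
               similarity = unname(sims[best]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
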