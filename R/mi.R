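# Corrected mutual information: weighted frequencies with a low-count
# correction, MI in nats, average product correction, and z-scores against a
# shuffle null that destroys covariation while preserving per-column
# composition.

#' Weighted amino-acid frequencies with a low-count correction
#'
#' Single-column frequencies `f_i(a)` use a per-cell pseudocount `lambda`
#' over the 20 amino-acid states and are normalized over rows that are
#' non-gap at column i. Pair frequencies `f_ij(a,b)` are counted over
#' pair-complete rows only (non-gap at both columns) with `lambda` per cell
#' over the 400 cells. Gaps and the unknown symbol `X` contribute nothing.
#'
#' @param x A reference-trimmed `msa`.
#' @param weights A `sequence_weights` (e.g. from [cluster_weights()]);
#'   defaults to uniform weights.
#' @param lambda Per-cell pseudocount (default 0.05).
#' @param pairs Compute the pair-frequency array too (needed by
#'   [mutual_information()]; quadratic in memory).
#' @return A `weighted_freqs`: list with `single` (L x 20 matrix), `pair`
#'   (20 x 20 x L x L array, or NULL), `lambda`, `meff`.
#' @export
weighted_frequencies <- function(x, weights = uniform_weights(x),
                                 lambda = 0.05, pairs = TRUE) {
  enc <- encode_msa(x, "mi")
  w <- weights$weights
  stopifnot(length(w) == nrow(enc))
  L <- ncol(enc)
  q <- 20L
  empty <- colSums(enc > 0L) == 0L
  if (any(empty))
    stop("column ", which(empty)[1L], " has no non-gap residues")
  single <- matrix(0, L, q, dimnames = list(NULL, AA20))
  for (i in seq_len(L)) {
    ok <- enc[, i] > 0L
    cnt <- vapply(seq_len(q), function(a) sum(w[ok & enc[, i] == a]),
                  numeric(1L))
    single[i, ] <- (lambda + cnt) / (q * lambda + sum(w[ok]))
  }
  pair <- NULL
  if (pairs) {
    pair <- array(0, dim = c(q, q, L, L))
    for (i in seq_len(L)) {
      for (j in seq_len(L)) {
        if (j <= i) next
        ok <- enc[, i] > 0L & enc[, j] > 0L
        cnt <- matrix(0, q, q)
        for (r in which(ok))
          cnt[enc[r, i], enc[r, j]] <- cnt[enc[r, i], enc[r, j]] + w[r]
        fij <- (lambda + cnt) / (q * q * lambda + sum(w[ok]))
        pair[, , i, j] <- fij
        pair[, , j, i] <- t(fij)
      }
    }
  }
  structure(list(single = single, pair = pair, lambda = lambda,
                 meff = weights$meff),
            class = "weighted_freqs")
}

#' Mutual information between all column pairs
#'
#' `MI(i,j) = sum_ab f_ij(a,b) log(f_ij(a,b) / (f_i(a) f_j(b)))` in natural
#' log units (nats), with `0 log 0 := 0`. Pseudocounted marginals can leave
#' tiny negative values; these are clamped to zero.
#'
#' @param freqs A `weighted_freqs` computed with `pairs = TRUE`.
#' @return Symmetric L x L matrix; diagonal set to 0 (undefined).
#' @export
mutual_information <- function(freqs) {
  if (is.null(freqs$pair))
    stop("pair frequencies missing; recompute with pairs = TRUE")
  L <- nrow(freqs$single)
  mi <- matrix(0, L, L)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (j <= i) next
      fij <- freqs$pair[, , i, j]
      ind <- outer(freqs$single[i, ], freqs$single[j, ])
      term <- fij * log(fij / ind)
      term[fij == 0] <- 0
      mi[i, j] <- mi[j, i] <- max(0, sum(term))
    }
  }
  mi
}

#' Average product correction
#'
#' `APC(i,j) = mean_i(MI) * mean_j(MI) / mean_all(MI)`, with row means and
#' the grand mean taken off-diagonal, subtracts the background component of
#' a pairwise score matrix; `mip = mi - apc`. When the grand mean is zero
#' the correction is defined as zero.
#'
#' @param mi Symmetric score matrix (L >= 3).
#' @return List with matrices `apc` and `mip`.
#' @export
apc_correct <- function(mi) {
  L <- nrow(mi)
  stopifnot(L >= 3L, L == ncol(mi))
  off <- mi
  diag(off) <- NA
  row_mean <- rowMeans(off, na.rm = TRUE)
  grand <- mean(off[upper.tri(off)])
  if (grand == 0) {
    apc <- matrix(0, L, L)
  } else {
    apc <- outer(row_mean, row_mean) / grand
    diag(apc) <- 0
  }
  mip <- mi - apc
  diag(mip) <- 0
  list(apc = apc, mip = mip)
}

# fast MI path used for the shuffle replicates (same definition as
# mutual_information(weighted_frequencies(...)), compiled)
mi_matrix_fast <- function(enc, w, lambda) {
  cpp_mi_matrix(enc, w, lambda, 20L)
}

#' Corrected MI with shuffle-null z-scores
#'
#' Computes raw MI, its APC correction, and z-scores of the APC-corrected
#' score against a null built from randomized alignments: each replicate
#' independently permutes the residues of every column across rows, which
#' preserves per-column composition (and hence conservation) while
#' destroying covariation. The null mean and standard deviation are pooled
#' over all pairs and replicates;
#' `z(i,j) = (mip(i,j) - null_mean) / null_sd`.
#'
#' @param x A reference-trimmed `msa`.
#' @param weights A `sequence_weights`; default Hobohm-1 cluster weights at
#'   the 62\% identity threshold.
#' @param lambda Pseudocount passed to the frequency model.
#' @param n_replicates Number of randomized alignments (>= 2, default 100).
#' @param seed Integer seed; replicate r permutes under `seed + r`.
#' @return A `mi_scores` object: list with matrices `raw_mi`, `apc`, `mip`,
#'   `zscore` and a `null` list (`n_replicates`, `seed`, `null_mean`,
#'   `null_sd`).
#' @export
mi_zscores <- function(x, weights = cluster_weights(hobohm1(x)),
                       lambda = 0.05, n_replicates = 100, seed = 1) {
  if (n_replicates < 2L) stop("at least 2 null replicates are required")
  enc <- encode_msa(x, "mi")
  empty <- colSums(enc > 0L) == 0L
  if (any(empty))
    stop("column ", which(empty)[1L], " has no non-gap residues")
  w <- weights$weights
  L <- ncol(enc)
  ut <- upper.tri(matrix(0, L, L))
  raw <- mi_matrix_fast(enc, w, lambda)
  obs <- apc_correct(raw)
  null_vals <- numeric(n_replicates * sum(ut))
  for (r in seq_len(n_replicates)) {
    set.seed(seed + r)
    shuf <- apply(enc, 2L, sample)
    storage.mode(shuf) <- "integer"
    rep_mip <- apc_correct(mi_matrix_fast(shuf, w, lambda))$mip
    null_vals[((r - 1L) * sum(ut) + 1L):(r * sum(ut))] <- rep_mip[ut]
  }
  null_mean <- mean(null_vals)
  null_sd <- sd(null_vals)
  if (!is.finite(null_sd) || null_sd <= 0)
    stop("degenerate null: zero variance across randomized alignments")
  z <- (obs$mip - null_mean) / null_sd
  diag(z) <- 0
  structure(list(raw_mi = raw, apc = obs$apc, mip = obs$mip, zscore = z,
                 null = list(n_replicates = n_replicates, seed = seed,
                             null_mean = null_mean, null_sd = null_sd)),
            class = "mi_scores")
}

#' @export
print.mi_scores <- function(x, ...) {
  L <- nrow(x$raw_mi)
  cat("corrected MI over ", L, " columns; null: ", x$null$n_replicates,
      " shuffles, mean ", signif(x$null$null_mean, 4), ", sd ",
      signif(x$null$null_sd, 4), "\n", sep = "")
  cat("max z-score: ", signif(max(x$zscore), 4), "\n", sep = "")
  invisible(x)
}

#' Per-position conservation (Kullback-Leibler divergence)
#'
#' `KL(i) = sum_a f_i(a) log(f_i(a) / q_a)` against a background
#' distribution; zero exactly when the column matches the background, and at
#' most `log 20` (a fully conserved column against a uniform background).
#'
#' @param freqs A `weighted_freqs` (pair array not required).
#' @param background Background amino-acid distribution (length 20, sums to
#'   1, strictly positive); default uniform.
#' @return Numeric vector, one value per column.
#' @export
position_conservation <- function(freqs, background = rep(1 / 20, 20)) {
  stopifnot(length(background) == 20L,
            abs(sum(background) - 1) < 1e-6)
  if (any(background <= 0)) stop("background must be strictly positive")
  f <- freqs$single
  term <- f * log(sweep(f, 2L, background, "/"))
  term[f == 0] <- 0
  pmax(rowSums(term), 0)
}
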