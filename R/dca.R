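# Direct-coupling analysis: mean-field inversion scored by direct
# information, and pseudo-likelihood Potts fits scored by APC-corrected
# Frobenius norms of the coupling blocks. Both operate at q = 21 states
# (20 amino acids + gap).

# index of unordered pair (i, j), i < j, in the i-major enumeration
pair_index <- function(i, j, L) {
  stopifnot(i < j)
  (i - 1L) * L - (i - 1L) * i / 2L + (j - i)
}

#' Construct a Potts coupling model
#'
#' Container for fields and pairwise couplings over q states. Couplings are
#' stored once per unordered pair `i < j` as a q x q block `e[, , p]` with
#' rows indexing the state at i, in the i-major pair enumeration.
#'
#' @param h L x q field matrix.
#' @param e q x q x (L(L-1)/2) coupling array.
#' @param q Number of states.
#' @param gap_state Whether state q is the gap (excluded from Frobenius
#'   scores).
#' @param f_single Optional L x q single-site marginals used by
#'   [direct_information()].
#' @param method,gauge,meff,converged Metadata.
#' @return A `coupling_model`.
#' @export
coupling_model <- function(h, e, q, gap_state = TRUE, f_single = NULL,
                           method = "manual", gauge = "none", meff = NA_real_,
                           converged = TRUE) {
  L <- nrow(h)
  stopifnot(ncol(h) == q, dim(e)[1] == q, dim(e)[2] == q,
            dim(e)[3] == L * (L - 1) / 2)
  structure(list(h = h, e = e, q = q, L = L, gap_state = gap_state,
                 f_single = f_single, method = method, gauge = gauge,
                 meff = meff, converged = converged),
            class = "coupling_model")
}

#' @export
print.coupling_model <- function(x, ...) {
  cat("Potts coupling model (", x$method, "): L = ", x$L, ", q = ", x$q,
      ", gauge = ", x$gauge, "\n", sep = "")
  if (is.finite(x$meff)) cat("Meff = ", format(x$meff), "\n", sep = "")
  if (!x$converged) cat("warning: fit did not converge\n")
  invisible(x)
}

#' Identity-based sequence reweighting for DCA
#'
#' Each record r gets weight `1 / m_r` where `m_r` is the number of records
#' (itself included) at identity >= `theta` with r; `Meff` is the summed
#' weight. Identity uses the [percent_identity()] definition
#' (both-non-gap columns).
#'
#' @param x A reference-trimmed `msa`.
#' @param theta Identity threshold (default 0.8, the standard DCA choice).
#' @return A `sequence_weights`.
#' @export
reweight_sequences <- function(x, theta = 0.8) {
  enc <- encode_msa(x, "identity")
  counts <- cpp_identity_neighbors(enc, theta)
  w <- 1 / counts
  structure(list(weights = w, meff = sum(w)), class = "sequence_weights")
}

# Weighted single/pair frequencies at q states with mean-field pseudocount
# mixing: f <- (1 - pc) f_data + pc / q (singles) or pc / q^2 (pairs, i != j).
dca_frequencies <- function(enc, w, q, pc) {
  L <- ncol(enc)
  Fmat <- cpp_pair_freqs(enc, w, q)
  Fmix <- (1 - pc) * Fmat + pc / q^2
  f1 <- matrix(0, L, q)
  for (i in seq_len(L)) {
    idx <- ((i - 1L) * q + 1L):(i * q)
    f1[i, ] <- (1 - pc) * diag(Fmat[idx, idx, drop = FALSE]) + pc / q
  }
  list(f1 = f1, f2 = Fmix)
}

#' Mean-field DCA fit
#'
#' Infers direct couplings by inverting the connected-correlation matrix of
#' the pseudocounted frequencies: with the last state gauged out,
#' `C[(i,a),(j,b)] = f_ij(a,b) - f_i(a) f_j(b)` over q-1 states per site and
#' `e = -C^{-1}` read off in per-pair blocks, embedded back to q states in
#' the zero-sum gauge. Deterministic.
#'
#' @param x A reference-trimmed `msa`.
#' @param weights A `sequence_weights`; default [reweight_sequences()] at
#'   theta = 0.8.
#' @param pseudocount_fraction Mixing fraction pc in
#'   `f <- (1-pc) f_data + pc/q` (default 0.5).
#' @return A `coupling_model` with `f_single` set (used by
#'   [direct_information()]).
#' @export
mfdca_fit <- function(x, weights = reweight_sequences(x),
                      pseudocount_fraction = 0.5) {
  enc <- encode_msa(x, "dca")
  q <- 21L
  L <- ncol(enc)
  stopifnot(L >= 2L)
  fr <- dca_frequencies(enc, weights$weights, q, pseudocount_fraction)
  qm1 <- q - 1L
  keep <- as.vector(outer(seq_len(qm1), (seq_len(L) - 1L) * q, "+"))
  C <- fr$f2[keep, keep, drop = FALSE]
  f1v <- as.vector(t(fr$f1))[keep]
  C <- C - outer(f1v, f1v)
  # diagonal blocks: f_i(a) delta_ab - f_i(a) f_i(b)
  for (i in seq_len(L)) {
    idx <- ((i - 1L) * qm1 + 1L):(i * qm1)
    fi <- fr$f1[i, seq_len(qm1)]
    C[idx, idx] <- diag(fi) - outer(fi, fi)
  }
  Cinv <- tryCatch(solve(C), error = function(err)
    stop("correlation matrix is singular; increase the pseudocount ",
         "fraction (", conditionMessage(err), ")"))
  e <- array(0, dim = c(q, q, L * (L - 1L) / 2L))
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      blk <- matrix(0, q, q)
      blk[seq_len(qm1), seq_len(qm1)] <-
        -Cinv[((i - 1L) * qm1 + 1L):(i * qm1),
              ((j - 1L) * qm1 + 1L):(j * qm1)]
      e[, , pair_index(i, j, L)] <- zero_sum_block(blk)
    }
  }
  h <- log(fr$f1)
  h <- h - rowMeans(h)
  coupling_model(h = h, e = e, q = q, gap_state = TRUE, f_single = fr$f1,
                 method = "mfdca", gauge = "zero_sum", meff = weights$meff)
}

zero_sum_block <- function(blk) {
  blk - outer(rowMeans(blk), rep(1, ncol(blk))) -
    outer(rep(1, nrow(blk)), colMeans(blk)) + mean(blk)
}

#' Transform a model to the zero-sum gauge
#'
#' Shifts every coupling block to zero row/column sums and compensates the
#' fields so that all site-conditional distributions (and therefore the
#' pseudo-likelihood) are unchanged.
#'
#' @param model A `coupling_model`.
#' @return The gauged `coupling_model`.
#' @export
zero_sum_gauge <- function(model) {
  L <- model$L; q <- model$q
  h <- model$h
  e <- model$e
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      p <- pair_index(i, j, L)
      blk <- e[, , p]
      m <- mean(blk)
      h[i, ] <- h[i, ] + rowMeans(blk) - m
      h[j, ] <- h[j, ] + colMeans(blk) - m
      e[, , p] <- zero_sum_block(blk)
    }
  }
  model$h <- h
  model$e <- e
  model$gauge <- "zero_sum"
  model
}

#' Direct information of a coupling model
#'
#' For each pair, builds the two-site distribution
#' `P_dir(a,b) ~ exp(e_ij(a,b)) mu_i(a) mu_j(b)` with auxiliary fields
#' iterated until its marginals match the single-site frequencies within
#' `tol`, and reports its mutual information (the direct information, >= 0).
#'
#' @param model A fitted `coupling_model`.
#' @param f_single Optional L x q marginal matrix; defaults to the model's.
#' @param tol Marginal-matching tolerance (default 1e-6).
#' @param max_iter Iteration cap per pair (default 1000).
#' @return Symmetric L x L matrix of direct information, diagonal 0.
#' @export
direct_information <- function(model, f_single = model$f_single,
                               tol = 1e-6, max_iter = 1000) {
  if (is.null(f_single))
    stop("single-site frequencies are required (model$f_single is NULL)")
  L <- model$L; q <- model$q
  di <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      W <- exp(model$e[, , pair_index(i, j, L)])
      fi <- f_single[i, ]; fj <- f_single[j, ]
      mu1 <- rep(1 / q, q); mu2 <- rep(1 / q, q)
      ok <- FALSE
      for (it in seq_len(max_iter)) {
        new1 <- fi / as.vector(W %*% mu2)
        new1 <- new1 / sum(new1)
        new2 <- fj / as.vector(crossprod(W, new1))
        new2 <- new2 / sum(new2)
        P <- outer(new1, new2) * W
        P <- P / sum(P)
        if (max(abs(rowSums(P) - fi), abs(colSums(P) - fj)) < tol) {
          mu1 <- new1; mu2 <- new2
          ok <- TRUE
          break
        }
        mu1 <- new1; mu2 <- new2
      }
      if (!ok)
        stop("direct-information marginal matching did not converge for ",
             "pair (", i, ", ", j, ")")
      ind <- outer(fi, fj)
      term <- P * log(P / ind)
      term[P == 0] <- 0
      di[i, j] <- di[j, i] <- max(0, sum(term))
    }
  }
  di
}

#' Pseudo-likelihood DCA fit
#'
#' Minimizes the negative weighted pseudo-log-likelihood of a Potts model
#' with symmetric couplings and L2 regularization,
#' `sum_r w_r sum_i -log P(x_i^r | x_-i^r) + lambda_h ||h||^2 +
#' lambda_e ||e||^2`, from a zero initialization with L-BFGS-B (projected
#' gradient tolerance 1e-4). Deterministic given the data.
#'
#' @param x A reference-trimmed `msa`.
#' @param weights A `sequence_weights`; default [reweight_sequences()].
#' @param lambda_h Field regularizer (default 0.01).
#' @param lambda_e Coupling regularizer (default `0.2 * (L - 1)`).
#' @param max_iter L-BFGS-B iteration cap (default 500).
#' @return A `coupling_model` (`converged` flags optimizer status;
#'   non-convergence also raises a warning).
#' @export
plmdca_fit <- function(x, weights = reweight_sequences(x), lambda_h = 0.01,
                       lambda_e = NULL, max_iter = 500) {
  enc <- encode_msa(x, "dca")
  q <- 21L
  L <- ncol(enc)
  stopifnot(L >= 2L)
  if (weights$meff < 2)
    stop("at least 2 effective sequences are required")
  if (is.null(lambda_e)) lambda_e <- 0.2 * (L - 1)
  w <- weights$weights
  npar <- q * L + (L * (L - 1L) / 2L) * q * q
  # optim() requests fn and gr separately at the same point; evaluate once
  cache <- new.env(parent = emptyenv())
  eval_at <- function(p) {
    if (is.null(cache$par) || !identical(p, cache$par)) {
      cache$res <- cpp_plm_obj_grad(p, enc, w, lambda_h, lambda_e, q)
      cache$par <- p
    }
    cache$res
  }
  fn <- function(p) eval_at(p)$value
  gr <- function(p) eval_at(p)$gradient
  fit <- optim(numeric(npar), fn = fn, gr = gr, method = "L-BFGS-B",
               control = list(maxit = max_iter, pgtol = 1e-4, factr = 1e7))
  converged <- fit$convergence == 0L
  if (!converged)
    warning("pseudo-likelihood optimizer stopped before convergence (",
            fit$message, "); returning the best iterate")
  h <- matrix(fit$par[seq_len(q * L)], nrow = L, ncol = q, byrow = TRUE)
  e <- array(fit$par[-seq_len(q * L)], dim = c(q, q, L * (L - 1L) / 2L))
  # small-pseudocount marginals, for optional DI on this model
  fr <- dca_frequencies(enc, w, q, 0.01)
  model <- coupling_model(h = h, e = e, q = q, gap_state = TRUE,
                          f_single = fr$f1, method = "plmdca",
                          gauge = "plm", meff = weights$meff,
                          converged = converged)
  model$npll <- fit$value
  model
}

#' Evaluate the negative weighted pseudo-log-likelihood of a model
#'
#' @param model A `coupling_model`.
#' @param x The `msa` it was fitted on.
#' @param weights Matching `sequence_weights`.
#' @param lambda_h,lambda_e Regularizers (0 for the bare pseudo-likelihood).
#' @return A single number.
#' @export
pseudolikelihood <- function(model, x, weights = uniform_weights(x),
                             lambda_h = 0, lambda_e = 0) {
  enc <- encode_msa(x, "dca")
  par <- c(as.vector(t(model$h)), as.vector(model$e))
  cpp_plm_obj_grad(par, enc, weights$weights, lambda_h, lambda_e,
                   model$q)$value
}

#' APC-corrected Frobenius norms of the coupling blocks
#'
#' For each pair, the Frobenius norm of the coupling block over the
#' non-gap states after a zero-sum gauge fix of that block, followed by the
#' average product correction ([apc_correct()]).
#'
#' @param model A fitted `coupling_model`.
#' @return List with matrices `raw` (norms) and `fapc` (APC-corrected).
#' @export
frobenius_apc_score <- function(model) {
  L <- model$L; q <- model$q
  states <- if (model$gap_state) seq_len(q - 1L) else seq_len(q)
  raw <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) {
    for (j in (i + 1L):L) {
      blk <- model$e[states, states, pair_index(i, j, L)]
      blk <- zero_sum_block(blk)
      raw[i, j] <- raw[j, i] <- sqrt(sum(blk^2))
    }
  }
  list(raw = raw, fapc = apc_correct(raw)$mip)
}
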