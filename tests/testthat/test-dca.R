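# A single small planted-coupling fixture shared across the DCA tests
# (L = 12, q = 6, 3 planted cross-segment pairs, strength 1.5).
potts_fix <- local({
  spec <- planted_potts_spec(L = 12, q = 6, n_sequences = 400,
                             segment_split = 6, n_planted = 3,
                             coupling_strength = 1.5, burn_in = 100,
                             seed = 7)
  sam <- sample_potts_msa(spec)
  sam$weights <- reweight_sequences(sam$msa)
  sam
})

planted_key <- paste(potts_fix$planted_pairs$i, potts_fix$planted_pairs$j)

test_that("identity reweighting counts neighbors at the theta threshold", {
  m <- msa(rep("ACDEFGHIKL", 5))
  w <- reweight_sequences(m, 0.8)
  expect_equal(w$weights, rep(1 / 5, 5))
  expect_equal(w$meff, 1)

  m2 <- msa(c("AAAAAAAAAA", "CCCCCCCCCC", "DDDDDDDDDD"))
  w2 <- reweight_sequences(m2, 0.8)
  expect_equal(w2$weights, rep(1, 3))
  expect_equal(w2$meff, 3)

  # one near-duplicate pair at 0.9 identity -> weights {1/2, 1/2, 1, 1}
  m3 <- msa(c("AAAAAAAAAA", "AAAAAAAAAC", "CCCCCCCCCC", "DDDDDDDDDD"))
  expect_equal(reweight_sequences(m3, 0.8)$weights, c(0.5, 0.5, 1, 1))
})

test_that("mean-field couplings match an independent inversion oracle", {
  m <- msa(c("AC", "AC", "CA", "CA", "AA", "CC", "AC", "CA"))
  w <- uniform_weights(m)
  model <- mfdca_fit(m, w, pseudocount_fraction = 0.5)

  # oracle: count frequencies directly, build the connected-correlation
  # matrix over q-1 states and invert with solve(), all outside the package
  q <- 21L; pc <- 0.5
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y","-")
  rows <- strsplit(msa_sequences(m), "")
  n <- length(rows)
  f1 <- matrix(pc / q, 2, q)
  f2 <- matrix(pc / q^2, q, q)
  for (r in rows) {
    a <- match(r[1], aa); b <- match(r[2], aa)
    f1[1, a] <- f1[1, a] + (1 - pc) / n
    f1[2, b] <- f1[2, b] + (1 - pc) / n
    f2[a, b] <- f2[a, b] + (1 - pc) / n
  }
  C <- matrix(0, 2 * (q - 1), 2 * (q - 1))
  s <- seq_len(q - 1)
  C[s, s] <- diag(f1[1, s]) - outer(f1[1, s], f1[1, s])
  C[s + q - 1, s + q - 1] <- diag(f1[2, s]) - outer(f1[2, s], f1[2, s])
  C[s, s + q - 1] <- f2[s, s] - outer(f1[1, s], f1[2, s])
  C[s + q - 1, s] <- t(C[s, s + q - 1])
  e_oracle <- matrix(0, q, q)
  e_oracle[s, s] <- -solve(C)[s, s + q - 1]
  # compare in the zero-sum gauge
  zs <- function(b) b - outer(rowMeans(b), rep(1, q)) -
    outer(rep(1, q), colMeans(b)) + mean(b)
  expect_equal(model$e[, , 1], zs(e_oracle), tolerance = 1e-8)
})

test_that("planted couplings dominate both DCA scores and MI agrees", {
  w <- potts_fix$weights
  segs <- potts_fix$msa$segments
  model <- mfdca_fit(potts_fix$msa, w)
  di <- direct_information(model)
  rk_di <- rank_pairs(score_table(di, segs, "mfdca"))
  expect_true(all(planted_key %in% paste(rk_di$i, rk_di$j)[1:3]))

  pl <- plmdca_fit(potts_fix$msa, w)
  fr <- frobenius_apc_score(pl)
  rk_f <- rank_pairs(score_table(fr$fapc, segs, "plmdca"))
  expect_true(all(planted_key %in% paste(rk_f$i, rk_f$j)[1:3]))

  # the plm Frobenius norms of non-planted (null) pairs stay comparable
  raw <- fr$raw[upper.tri(fr$raw)]
  ut <- which(upper.tri(fr$raw), arr.ind = TRUE)
  null_norms <- raw[!(paste(ut[, 1], ut[, 2]) %in% planted_key)]
  expect_lt(max(null_norms) / stats::median(null_norms), 3)

})

test_that("DCA scores track corrected MI on a graded-coupling alignment", {
  # every cross-segment pair carries a planted coupling of graded strength,
  # so all methods must broadly agree on the pair ordering
  grid <- expand.grid(i = 1:4, j = 5:8)
  grid$strength <- seq(0.2, 2, length.out = nrow(grid))
  spec <- planted_potts_spec(L = 8, q = 6, n_sequences = 500,
                             segment_split = 4, planted_pairs = grid,
                             burn_in = 100, seed = 19)
  sam <- sample_potts_msa(spec)
  w <- reweight_sequences(sam$msa)
  di <- direct_information(mfdca_fit(sam$msa, w))
  fapc <- frobenius_apc_score(plmdca_fit(sam$msa, w))$fapc
  z <- mi_zscores(sam$msa, uniform_weights(sam$msa),
                  n_replicates = 10, seed = 3)
  utm <- upper.tri(di)
  expect_gt(cor(di[utm], z$mip[utm], method = "spearman"), 0.5)
  expect_gt(cor(fapc[utm], z$mip[utm], method = "spearman"), 0.5)
})

test_that("DCA scores are invariant under row permutation of the alignment", {
  set.seed(21)
  perm <- sample(n_records(potts_fix$msa))
  m_perm <- structure(list(seqs = potts_fix$msa$seqs[perm, ],
                           ids = potts_fix$msa$ids[perm],
                           taxids = potts_fix$msa$taxids[perm]),
                      class = "msa")
  w <- potts_fix$weights
  w_perm <- structure(list(weights = w$weights[perm], meff = w$meff),
                      class = "sequence_weights")
  di1 <- direct_information(mfdca_fit(potts_fix$msa, w))
  di2 <- direct_information(mfdca_fit(m_perm, w_perm))
  expect_equal(di1, di2, tolerance = 1e-9)

  f1 <- frobenius_apc_score(plmdca_fit(potts_fix$msa, w))$fapc
  f2 <- frobenius_apc_score(plmdca_fit(m_perm, w_perm))$fapc
  expect_equal(f1, f2, tolerance = 1e-4)
})

test_that("direct information is zero without coupling, analytic at 2 states", {
  # e = 0 -> product distribution -> DI = 0
  L <- 3; q <- 4
  e0 <- array(0, dim = c(q, q, 3))
  f <- matrix(1 / q, L, q)
  m0 <- coupling_model(h = matrix(0, L, q), e = e0, q = q,
                       gap_state = FALSE, f_single = f)
  expect_equal(max(direct_information(m0)), 0)

  # symmetric 2-state coupling, uniform marginals: closed-form MI
  for (J in c(0.5, 1, 3)) {
    e <- array(0, dim = c(2, 2, 1))
    e[, , 1] <- matrix(c(J, 0, 0, J), 2, 2)
    mJ <- coupling_model(h = matrix(0, 2, 2), e = e, q = 2,
                         gap_state = FALSE,
                         f_single = matrix(0.5, 2, 2))
    p_same <- exp(J) / (2 * exp(J) + 2)
    p_diff <- 1 / (2 * exp(J) + 2)
    analytic <- 2 * p_same * log(4 * p_same) + 2 * p_diff * log(4 * p_diff)
    expect_equal(direct_information(mJ)[1, 2], analytic, tolerance = 1e-6)
  }
})

test_that("field shrinkage is monotone in the field regularizer", {
  m <- msa(c("AC", "AC", "AC", "CC", "CA", "AA"))
  w <- uniform_weights(m)
  norms <- vapply(c(0.01, 0.1, 1, 10), function(lh)
    sqrt(sum(plmdca_fit(m, w, lambda_h = lh, lambda_e = 10)$h^2)),
    numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("zero-sum gauge fix leaves the pseudo-likelihood unchanged", {
  pl <- plmdca_fit(potts_fix$msa, potts_fix$weights)
  gauged <- zero_sum_gauge(pl)
  # couplings satisfy the gauge: zero row/column sums per block
  blk <- gauged$e[, , 5]
  expect_lt(max(abs(rowSums(blk))), 1e-6)
  expect_lt(max(abs(colSums(blk))), 1e-6)
  v1 <- pseudolikelihood(pl, potts_fix$msa, potts_fix$weights)
  v2 <- pseudolikelihood(gauged, potts_fix$msa, potts_fix$weights)
  expect_equal(v1, v2, tolerance = 1e-6)
})

test_that("Frobenius-APC scores follow their two-loop oracle", {
  q <- 21; L <- 6
  npair <- L * (L - 1) / 2
  set.seed(31)
  e <- array(rnorm(q * q * npair, sd = 0.3), dim = c(q, q, npair))
  model <- coupling_model(h = matrix(0, L, q), e = e, q = q,
                          gap_state = TRUE)
  sc <- frobenius_apc_score(model)

  # oracle: explicit double loop over pairs, zero-sum gauge by hand
  raw <- matrix(0, L, L)
  p <- 0
  for (i in 1:(L - 1)) for (j in (i + 1):L) {
    p <- p + 1
    b <- e[1:20, 1:20, p]
    b <- b - outer(rowMeans(b), rep(1, 20)) -
      outer(rep(1, 20), colMeans(b)) + mean(b)
    raw[i, j] <- raw[j, i] <- sqrt(sum(b^2))
  }
  expect_equal(sc$raw, raw, tolerance = 1e-12)
  expect_equal(sc$fapc[upper.tri(raw)], oracle_apc(raw)[upper.tri(raw)],
               tolerance = 1e-12)

  # degenerate cases: all-zero couplings, and constant norms cancel under APC
  z <- coupling_model(h = matrix(0, L, q),
                      e = array(0, dim = c(q, q, npair)), q = q)
  expect_equal(max(frobenius_apc_score(z)$raw), 0)
  const <- array(0, dim = c(q, q, npair))
  const[1, 1, ] <- 2 # every block has identical Frobenius norm after gauge
  cm <- coupling_model(h = matrix(0, L, q), e = const, q = q)
  expect_lt(max(abs(frobenius_apc_score(cm)$fapc[upper.tri(raw)])), 1e-10)
})
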