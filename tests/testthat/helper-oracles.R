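# Independent oracles: deliberately naive double-loop implementations used
# to freeze expected values; they share no code with the package internals.

# MI by direct counting: per-column singles over non-gap rows, per-pair
# joints over pair-complete rows, per-cell pseudocount, natural log.
oracle_mi <- function(seq_strings, w, lambda) {
  rows <- strsplit(seq_strings, "")
  n <- length(rows)
  L <- length(rows[[1]])
  aa <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
  is_res <- function(ch) ch %in% aa
  f1 <- function(i) {
    tot <- 0; cnt <- setNames(numeric(20), aa)
    for (r in seq_len(n)) {
      ch <- rows[[r]][i]
      if (is_res(ch)) { cnt[ch] <- cnt[ch] + w[r]; tot <- tot + w[r] }
    }
    (lambda + cnt) / (20 * lambda + tot)
  }
  mi <- matrix(0, L, L)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (j <= i) next
    fi <- f1(i); fj <- f1(j)
    cnt <- matrix(0, 20, 20, dimnames = list(aa, aa)); tot <- 0
    for (r in seq_len(n)) {
      a <- rows[[r]][i]; b <- rows[[r]][j]
      if (is_res(a) && is_res(b)) { cnt[a, b] <- cnt[a, b] + w[r]; tot <- tot + w[r] }
    }
    s <- 0
    for (a in aa) for (b in aa) {
      fab <- (lambda + cnt[a, b]) / (400 * lambda + tot)
      if (fab > 0) s <- s + fab * log(fab / (fi[a] * fj[b]))
    }
    mi[i, j] <- mi[j, i] <- max(0, s)
  }
  mi
}

# APC by the row-mean / grand-mean formula, element by element.
oracle_apc <- function(M) {
  L <- nrow(M)
  rm <- sapply(seq_len(L), function(i) mean(M[i, -i]))
  gm <- mean(M[upper.tri(M)])
  A <- matrix(0, L, L)
  for (i in seq_len(L)) for (j in seq_len(L))
    if (i != j) A[i, j] <- rm[i] * rm[j] / gm
  M - A
}

# ROC AUC as the normalized Mann-Whitney U statistic (rank-sum identity).
oracle_auc <- function(scores, positive) {
  r <- rank(scores)
  np <- sum(positive); nn <- sum(!positive)
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

# brute-force links_needed: scan prefixes
oracle_links_needed <- function(classes, target, n) {
  hit <- if (target == "both") rep(TRUE, length(classes))
         else if (target == "inter") classes == "inter"
         else grepl("^intra", classes)
  for (k in seq_along(classes)) if (sum(hit[seq_len(k)]) >= n) return(k)
  NA_integer_
}

# a small alignment with two perfectly covarying columns (3 and 7) planted
# among otherwise shuffled ones
planted_pair_msa <- function(n = 60, L = 8, seed = 42) {
  set.seed(seed)
  aa <- c("A","C","D","E","F","G","H","I","K","L")
  mat <- matrix(sample(aa, n * L, replace = TRUE), n, L)
  states <- sample(c("A", "C"), n, replace = TRUE)
  mat[, 3] <- states
  mat[, 7] <- ifelse(states == "A", "D", "E")
  msa(apply(mat, 1, paste, collapse = ""))
}
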