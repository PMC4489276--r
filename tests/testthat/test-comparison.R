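two_seg <- data.frame(label = c("A", "B"), start = c(1L, 31L),
                      end = c(30L, 70L))

random_table <- function(L, segs, method = "m", seed = 1) {
  set.seed(seed)
  sc <- matrix(0, L, L)
  sc[upper.tri(sc)] <- runif(L * (L - 1) / 2)
  sc <- sc + t(sc)
  score_table(sc, segs, method)
}

test_that("pair classification follows the segment map", {
  cls <- classify_pairs(two_seg, 70L)
  expect_equal(cls[5, 10], "intra:A")
  expect_equal(cls[5, 40], "inter")
  expect_equal(cls[30, 31], "inter") # boundary
  expect_equal(cls[31, 70], "intra:B")
  expect_error(classify_pairs(two_seg, 80L), "outside")
})

test_that("ranking is score-descending with deterministic tie-breaks", {
  segs <- data.frame(label = c("A", "B"), start = c(1L, 2L), end = c(1L, 3L))
  sc <- matrix(0, 3, 3)
  sc[1, 2] <- sc[2, 1] <- 3
  sc[1, 3] <- sc[3, 1] <- 1
  sc[2, 3] <- sc[3, 2] <- 2
  rk <- rank_pairs(score_table(sc, segs))
  expect_equal(rk$i, c(1L, 2L, 1L))
  expect_equal(rk$j, c(2L, 3L, 3L))

  # all-equal scores: lexicographic (i, then j)
  sc2 <- matrix(1, 3, 3); diag(sc2) <- 0
  rk2 <- rank_pairs(score_table(sc2, segs))
  expect_equal(rk2[, c("i", "j")],
               data.frame(i = c(1L, 1L, 2L), j = c(2L, 3L, 3L)),
               ignore_attr = TRUE)

  # random table equals the sort oracle
  st <- random_table(6, data.frame(label = c("A", "B"), start = c(1L, 4L),
                                   end = c(3L, 6L)), seed = 2)
  rk3 <- rank_pairs(st)
  expect_equal(rk3$score, sort(st$scores[upper.tri(st$scores)],
                               decreasing = TRUE))

  sc_na <- sc; sc_na[1, 2] <- sc_na[2, 1] <- NaN
  expect_error(rank_pairs(score_table(sc_na, segs)), "NaN")
})

test_that("links_needed counts prefix ranks and agrees with brute force", {
  segs <- data.frame(label = c("A", "B"), start = c(1L, 3L), end = c(2L, 4L))
  # construct a table whose ranking classes are inter, intra, inter, ...
  sc <- matrix(0, 4, 4)
  sc[1, 3] <- 6; sc[1, 2] <- 5; sc[1, 4] <- 4; sc[3, 4] <- 3; sc[2, 3] <- 2
  sc[2, 4] <- 1
  sc <- sc + t(sc)
  rk <- rank_pairs(score_table(sc, segs))
  expect_equal(rk$class[1:3], c("inter", "intra:A", "inter"))
  expect_equal(links_needed(rk, "inter", 2), 3L)

  # exhaustive agreement with the brute-force scan for every feasible n
  st <- random_table(10, data.frame(label = c("A", "B"), start = c(1L, 5L),
                                    end = c(4L, 10L)), seed = 3)
  rk2 <- rank_pairs(st)
  for (target in c("inter", "intra", "both")) {
    total <- sum(match_class <- switch(target,
      both = rep(TRUE, nrow(rk2)),
      inter = rk2$class == "inter",
      intra = startsWith(rk2$class, "intra")))
    for (n in seq_len(total)) {
      expect_equal(links_needed(rk2, target, n),
                   oracle_links_needed(rk2$class, target, n))
    }
    # monotone in n, and "both" never needs more ranks than one class
    ks <- vapply(seq_len(total), function(n) links_needed(rk2, target, n),
                 integer(1))
    expect_true(all(diff(ks) >= 0))
  }
  expect_lte(links_needed(rk2, "both", 5), links_needed(rk2, "inter", 5))

  expect_error(links_needed(rk2, "inter", 1000), "available")
})

test_that("class counts partition all pairs", {
  st <- random_table(12, data.frame(label = c("A", "B", "C"),
                                    start = c(1L, 5L, 9L),
                                    end = c(4L, 8L, 12L)), seed = 4)
  d <- density_summary(st)
  expect_equal(d$inter$count + d$intra$count, 12 * 11 / 2)
  expect_equal(d$both$count, 12 * 11 / 2)
  # two segments: inter count is the product of segment lengths
  st2 <- random_table(10, data.frame(label = c("A", "B"), start = c(1L, 5L),
                                     end = c(4L, 10L)), seed = 5)
  expect_equal(density_summary(st2)$inter$count, 4 * 6)
  # quantiles match the sort-based oracle
  sc <- st2$scores[upper.tri(st2$scores)]
  expect_equal(unname(density_summary(st2)$both$quantiles),
               unname(quantile(sc, c(.01, .05, .25, .5, .75, .95, .99))))
})

test_that("top overlap intersects class-restricted top sets", {
  segs <- data.frame(label = c("A", "B"), start = c(1L, 5L), end = c(4L, 8L))
  base <- random_table(8, segs, "m1", seed = 6)
  rk <- rank_pairs(base)
  # identical tables: overlap is the top-n of the class
  ov <- top_overlap(list(rank_pairs(base), rank_pairs(base)), "inter", 5)
  top5 <- rk[rk$class == "inter", ][1:5, ]
  expect_equal(nrow(ov$overlap), 5L)
  expect_setequal(paste(ov$overlap$i, ov$overlap$j),
                  paste(top5$i, top5$j))

  # disjoint top sets: empty overlap
  inv <- base
  inv$scores <- -base$scores
  ov2 <- top_overlap(list(rank_pairs(base), rank_pairs(inv)), "inter", 3)
  expect_equal(nrow(ov2$overlap), 0L)

  # four crafted tables built to share exactly 3 interprotein pairs
  shared <- data.frame(i = c(1, 2, 3), j = c(5, 6, 7))
  tabs <- lapply(1:4, function(k) {
    sc <- matrix(0, 8, 8)
    sc[cbind(shared$i, shared$j)] <- 100 + k + c(3, 2, 1)
    sc[4, 4 + k] <- 50 # a private top interprotein pair per method
    sc[upper.tri(sc) & sc == 0] <- runif(sum(upper.tri(sc) & sc == 0))
    sc <- sc + t(sc)
    st <- score_table(sc, segs, paste0("m", k))
    rank_pairs(st)
  })
  ov3 <- top_overlap(tabs, "inter", 4)
  expect_equal(nrow(ov3$overlap), 3L)
  expect_setequal(paste(ov3$overlap$i, ov3$overlap$j),
                  paste(shared$i, shared$j))
  # union reports per-method ranks with NA where absent from a top set
  expect_true(any(is.na(as.matrix(ov3$union[, grep("rank_",
                                                   names(ov3$union))]))))
  # monotone in n
  sizes <- vapply(1:4, function(n)
    nrow(top_overlap(tabs, "inter", n)$overlap), integer(1))
  expect_true(all(diff(sizes) >= 0))

  short <- random_table(6, data.frame(label = c("A", "B"), start = c(1L, 4L),
                                      end = c(3L, 6L)))
  expect_error(top_overlap(list(rk, rank_pairs(short)), "inter", 2),
               "different numbers of positions")
})

test_that("external score import validates and round-trips rankings", {
  segs <- data.frame(label = c("A", "B"), start = c(1L, 3L), end = c(2L, 4L))
  f <- tempfile(fileext = ".tsv")
  writeLines(c("i\tj\tscore", "1\t2\t0.5", "1\t3\t0.9", "1\t4\t0.1",
               "2\t3\t0.7", "2\t4\t0.3", "3\t4\t0.2"), f)
  st <- import_external_scores(f, segs, 4L, method = "psicov")
  expect_equal(st$method, "psicov")
  expect_equal(st$scores[2, 3], 0.7)
  expect_equal(st$scores[3, 2], 0.7)

  # conflicting duplicates are rejected
  writeLines(c("5\t2\t0.1", "2\t5\t0.9"), f)
  expect_error(import_external_scores(f, segs, 6L), "conflicting")

  # incomplete listing needs sparse = TRUE
  writeLines(c("1\t2\t0.5"), f)
  expect_error(import_external_scores(f, segs, 4L), "missing")
  sp <- import_external_scores(f, segs, 4L, sparse = TRUE)
  rk <- rank_pairs(sp)
  expect_equal(rk$i[1], 1L)
  expect_equal(rk$j[1], 2L)

  # export -> import preserves the ranking
  st0 <- random_table(4, segs, seed = 8)
  pm_stub <- structure(list(seqs = matrix("A", 2, 4),
                            ids = c("r", "x"), taxids = c(NA, NA),
                            segments = segs),
                       class = c("paired_msa", "msa"))
  out <- tempfile(fileext = ".tsv")
  export_scores(pm_stub, list(score = st0$scores), out)
  back <- read.delim(out)
  f2 <- tempfile(fileext = ".tsv")
  write.table(back[, c("pos_i", "pos_j", "score")], f2, sep = "\t",
              row.names = FALSE, quote = FALSE)
  st1 <- import_external_scores(f2, segs, 4L)
  expect_equal(rank_pairs(st1)[, c("i", "j")], rank_pairs(st0)[, c("i", "j")],
               ignore_attr = TRUE)
})
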