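test_that("toy structures round-trip through the PDB reader", {
  chains <- list(H = data.frame(resno = 1:2, aa = c("A", "G"),
                                x = c(0, 11), y = 0, z = 0))
  fx <- make_toy_structure(chains, tempfile(fileext = ".pdb"))
  ch <- load_structure_chains(fx$path, "H")[[1]]
  expect_equal(length(ch$resno), 2L)
  expect_equal(ch$aa, c("A", "G"))
  expect_equal(ch$xyz[, 1], c(0, 11))
  expect_error(load_structure_chains(fx$path, c("H", "Z")), "Z")
  expect_error(make_toy_structure(list(H = data.frame()), tempfile()),
               "empty chain")
})

test_that("altloc picks highest occupancy and only model 1 is read", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA A   1       5.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA  GLY A   2       3.000   0.000   0.000  1.00  0.00           C",
    "HETATM    4  CA  HOH A   9       9.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      5  CA  ALA A   1      50.000   0.000   0.000  1.00  0.00           C",
    "ATOM      6  CA  GLY A   2      53.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "END"), pdb)
  ch <- load_structure_chains(pdb, "A")[[1]]
  expect_equal(length(ch$resno), 2L) # HETATM skipped
  expect_equal(ch$xyz[1, 1], 0)     # altloc A (occupancy 0.6) kept
  expect_equal(ch$xyz[2, 1], 3)     # model 1, not model 2
})

test_that("reference-to-chain mapping follows the global alignment", {
  chain <- list(chain_id = "H", resno = 11:16,
                aa = c("M", "K", "V", "L", "W", "G"),
                xyz = matrix(0, 6, 3))
  # identical sequences: identity mapping onto residue numbers
  m1 <- map_reference_to_chain("MKVLWG", chain)
  expect_equal(m1$mapping, 11:16)
  expect_equal(m1$coverage, 1)
  # chain missing two N-terminal residues: first two columns unmapped
  chain2 <- list(chain_id = "H", resno = 13:16, aa = c("V", "L", "W", "G"),
                 xyz = matrix(0, 4, 3))
  m2 <- map_reference_to_chain("MKVLWG", chain2)
  expect_equal(m2$mapping, c(NA, NA, 13:16))
  # an internal point mutation still maps every position
  chain3 <- list(chain_id = "H", resno = 21:26,
                 aa = c("M", "K", "A", "L", "W", "G"), xyz = matrix(0, 6, 3))
  m3 <- map_reference_to_chain("MKVLWG", chain3)
  expect_equal(m3$mapping, 21:26)
  # hopeless coverage is flagged as a wrong chain
  expect_error(map_reference_to_chain(strrep("E", 50), chain),
               "wrong chain")
})

toy_eval_setup <- function(coords_b_x = c(5, 30)) {
  # two single-residue-per-position chains laid out on a line
  chains <- list(
    H = data.frame(resno = 1:2, aa = c("A", "C"), x = c(0, 10), y = 0, z = 0),
    G = data.frame(resno = 1:2, aa = c("D", "E"), x = coords_b_x, y = 0,
                   z = 0))
  fx <- make_toy_structure(chains, tempfile(fileext = ".pdb"))
  loaded <- load_structure_chains(fx$path, c("H", "G"))
  pm <- paired_msa(msa(c("ACDE", "ACDE"), ids = c("ref", "row")),
                   data.frame(label = c("A", "B"), start = c(1L, 3L),
                              end = c(2L, 4L)))
  assignments <- list(
    A = list(chain = loaded[[1]],
             mapping = map_reference_to_chain("AC", loaded[[1]])$mapping),
    B = list(chain = loaded[[2]],
             mapping = map_reference_to_chain("DE", loaded[[2]])$mapping))
  list(pm = pm, assignments = assignments)
}

test_that("contacts use a strict threshold at exactly 12 Angstrom", {
  # distances from position 1: 10 (intra), 11.9 and 12.0 (inter)
  s <- toy_eval_setup(coords_b_x = c(11.9, 12.0))
  cm <- contact_map(s$pm, s$assignments, threshold = 12)
  expect_true(cm$contact[1, 3])   # 11.9 A -> contact
  expect_false(cm$contact[1, 4])  # 12.0 A -> not a contact (strict)
  expect_true(cm$contact[1, 2])   # 10 A intra
  expect_false(cm$contact[1, 1])  # diagonal
  expect_equal(cm$distance[1, 4], 12)
})

test_that("a collinear chain at 5 A spacing contacts exactly |di| <= 2", {
  chains <- list(H = data.frame(resno = 1:6, aa = "A",
                                x = 5 * (0:5), y = 0, z = 0))
  fx <- make_toy_structure(chains, tempfile(fileext = ".pdb"))
  expect_true(all(fx$expected[abs(row(fx$expected) - col(fx$expected)) %in%
                                1:2]))
  expect_false(any(fx$expected[abs(row(fx$expected) - col(fx$expected)) > 2]))
})

test_that("prediction metrics: perfect oracle, rank-sum identity, monotonicity", {
  set.seed(17)
  L <- 20
  segs <- data.frame(label = c("A", "B"), start = c(1L, 11L),
                     end = c(10L, 20L))
  sc <- matrix(0, L, L)
  sc[upper.tri(sc)] <- runif(L * (L - 1) / 2)
  sc <- sc + t(sc)
  rk <- rank_pairs(score_table(sc, segs, "m"))
  contact <- matrix(FALSE, L, L)
  ut <- which(upper.tri(contact), arr.ind = TRUE)
  pos <- sample(nrow(ut), 60)
  contact[ut[pos, , drop = FALSE]] <- TRUE
  contact <- contact | t(contact)
  cmap <- structure(list(contact = contact, distance = NULL,
                         mapped = rep(TRUE, L), threshold = 12),
                    class = "contact_map")
  res <- evaluate_predictions(rk, cmap, "both", k = 10)
  is_contact <- contact[cbind(rk$i, rk$j)]
  expect_equal(res$auc, oracle_auc(rk$score, is_contact), tolerance = 1e-12)

  # scores that perfectly separate contacts give AUC 1 and precision 1
  sc2 <- matrix(0, L, L)
  sc2[contact] <- 5
  sc2 <- sc2 + matrix(runif(L * L, 0, 0.1), L, L)
  sc2 <- (sc2 + t(sc2)) / 2
  rk2 <- rank_pairs(score_table(sc2, segs, "m2"))
  res2 <- evaluate_predictions(rk2, cmap, "both", k = 10)
  expect_equal(res2$auc, 1)
  expect_equal(res2$precision_at_k, 1)

  # AUC is invariant under strictly monotone transforms of the scores
  sc3 <- exp(3 * sc)
  rk3 <- rank_pairs(score_table(sc3, segs, "m3"))
  expect_equal(evaluate_predictions(rk3, cmap, "both", k = 10)$auc, res$auc,
               tolerance = 1e-12)

  # unmapped endpoints are skipped and counted
  cmap_um <- cmap
  cmap_um$mapped[1:3] <- FALSE
  res4 <- evaluate_predictions(rk, cmap_um, "both", k = 10)
  expect_equal(res4$n_skipped_unmapped, nrow(rk) - res4$n_pairs)
  expect_gt(res4$n_skipped_unmapped, 0)

  # degenerate maps make the AUC undefined
  allpos <- cmap
  allpos$contact <- matrix(TRUE, L, L)
  expect_error(evaluate_predictions(rk, allpos, "both"), "AUC undefined")
})

test_that("precision at k grows with the contact threshold", {
  s <- toy_eval_setup(coords_b_x = c(11, 25))
  sc <- matrix(0, 4, 4)
  sc[1, 3] <- 3; sc[2, 4] <- 2; sc[1, 4] <- 1; sc[2, 3] <- 0.5
  sc <- sc + t(sc)
  rk <- rank_pairs(score_table(sc, s$pm$segments, "m"))
  prec <- vapply(c(6, 12, 30), function(thr) {
    cm <- contact_map(s$pm, s$assignments, threshold = thr)
    sum(cm$contact[cbind(rk$i, rk$j)][1:3]) / 3
  }, numeric(1))
  expect_true(all(diff(prec) >= 0))
})
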