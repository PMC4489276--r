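# Seeded generators for every input class the package consumes: paired
# alignments sampled from a planted-coupling Potts model, homolog hit
# tables with controlled taxID/paralog structure, and toy PDB structures.
# All outputs are bit-reproducible given their seed.

#' Specification of a planted-coupling Potts alignment
#'
#' Describes a two-segment alignment sampled from
#' `P(x) ~ exp(sum_planted strength * [x_i = x_j])`: an Ising-like diagonal
#' coupling on each planted cross-segment pair, no fields, all other
#' columns independent and uniform. With `strength = 0` every column is
#' i.i.d. uniform over the q states.
#'
#' @param L Alignment length (default 40).
#' @param q Number of states, mapped onto the first q amino acids
#'   (default 8).
#' @param n_sequences Number of sampled rows (default 2000).
#' @param segment_split Last column of the first segment (default `L / 2`).
#' @param n_planted Number of planted cross-segment pairs, drawn without
#'   replacement under the seed (default 10); ignored when `planted_pairs`
#'   is given.
#' @param planted_pairs Optional data frame (`i`, `j`, optionally a
#'   per-pair `strength`) of planted pairs with `i <= segment_split < j`.
#' @param coupling_strength Coupling scalar (default 1.5).
#' @param burn_in Discarded Gibbs sweeps per independent chain
#'   (default 200).
#' @param seed Integer seed (default 1).
#' @return A `planted_potts_spec` list.
#' @export
planted_potts_spec <- function(L = 40, q = 8, n_sequences = 2000,
                               segment_split = L %/% 2, n_planted = 10,
                               planted_pairs = NULL, coupling_strength = 1.5,
                               burn_in = 200, seed = 1) {
  stopifnot(segment_split > 0, segment_split < L, q >= 2, q <= 20,
            n_sequences >= 1)
  if (!is.null(planted_pairs)) {
    planted_pairs <- as.data.frame(planted_pairs)
    stopifnot(all(planted_pairs$i <= segment_split),
              all(planted_pairs$j > segment_split),
              !anyDuplicated(planted_pairs[, c("i", "j")]))
    if (is.null(planted_pairs$strength))
      planted_pairs$strength <- coupling_strength
  }
  structure(list(L = as.integer(L), q = as.integer(q),
                 n_sequences = as.integer(n_sequences),
                 segment_split = as.integer(segment_split),
                 n_planted = as.integer(n_planted),
                 planted_pairs = planted_pairs,
                 coupling_strength = coupling_strength,
                 burn_in = as.integer(burn_in), seed = as.integer(seed)),
            class = "planted_potts_spec")
}

#' Sample a paired alignment from a planted-coupling Potts model
#'
#' Runs one independent Gibbs chain per sequence (uniform random start,
#' `burn_in` full sweeps discarded, final state kept), maps states to amino
#' acids and assembles a two-segment `paired_msa` with taxIDs `1..n`; the
#' first sampled row serves as the (gap-free) reference.
#'
#' @param spec A `planted_potts_spec`.
#' @return List with `msa` (a `paired_msa`), `planted_pairs` (data frame
#'   `i`, `j` in alignment coordinates) and `spec`.
#' @export
sample_potts_msa <- function(spec) {
  stopifnot(inherits(spec, "planted_potts_spec"))
  set.seed(spec$seed)
  pairs <- spec$planted_pairs
  if (is.null(pairs)) {
    avail <- expand.grid(i = seq_len(spec$segment_split),
                         j = (spec$segment_split + 1L):spec$L)
    pick <- sample(nrow(avail), spec$n_planted)
    pairs <- avail[pick, , drop = FALSE]
    pairs$strength <- spec$coupling_strength
    rownames(pairs) <- NULL
  }
  states <- cpp_potts_gibbs(spec$n_sequences, spec$L, spec$q,
                            as.matrix(pairs[, c("i", "j")]) - 1L,
                            pairs$strength, spec$burn_in)
  seqs <- apply(matrix(AA20[states], nrow = spec$n_sequences), 1L,
                paste, collapse = "")
  m <- msa(seqs, ids = paste0("tax", seq_len(spec$n_sequences)),
           taxids = seq_len(spec$n_sequences))
  pm <- paired_msa(m, data.frame(label = c("A", "B"),
                                 start = c(1L, spec$segment_split + 1L),
                                 end = c(spec$segment_split, spec$L)))
  list(msa = pm, planted_pairs = pairs, spec = spec)
}

#' Write homolog hit-table fixtures with known expected output
#'
#' Emits BLAST-tabular hit files (qseqid, sseqid, staxids, evalue, bitscore,
#' aligned_seq) exercising the pairing rules, together with the expected
#' paired alignment written out by hand from the rules' definitions --
#' a golden file the pairing code must reproduce byte for byte.
#'
#' Plans: `"paralog_evalue"` (a duplicate taxID where the lower E-value hit
#' must win), `"bitscore_tie"` (equal E-values, higher bit-score wins),
#' `"empty_intersection"` (no shared taxID; pairing must error), and
#' `"three_proteins"` (taxID sets of sizes 5/4/6 whose three-way
#' intersection has 3 taxa; checks segment arithmetic).
#'
#' @param dir Output directory (created if needed).
#' @param plan One of the plan names above.
#' @return List with `proteins` (input list for [build_paired_msa()]),
#'   `hit_paths`, `expected_fasta` (path to the hand-written golden FASTA,
#'   or `NULL`), `expected_segments` (data frame or `NULL`) and
#'   `expect_error` (logical).
#' @export
make_hit_fixture <- function(dir, plan = c("paralog_evalue", "bitscore_tie",
                                           "empty_intersection",
                                           "three_proteins")) {
  plan <- match.arg(plan)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_hits <- function(name, rows) {
    path <- file.path(dir, paste0(name, "_hits.tsv"))
    writeLines(vapply(rows, paste, character(1L), collapse = "\t"), path)
    path
  }
  golden <- function(lines) {
    path <- file.path(dir, "expected_paired.fasta")
    writeLines(lines, path)
    path
  }
  if (plan == "paralog_evalue") {
    # taxid 7 of protein A is duplicated; sA1 (1e-10) beats sA2 (1e-8)
    pa <- write_hits("protA", list(
      c("refA", "sA1", "7", "1e-10", "100", "ACDEF"),
      c("refA", "sA2", "7", "1e-08", "300", "AAAAA"),
      c("refA", "sA3", "8", "1e-05", "50", "ACDEA")))
    pb <- write_hits("protB", list(
      c("refB", "sB1", "7", "1e-09", "200", "GHIKLM"),
      c("refB", "sB2", "8", "1e-04", "40", "GHIKLA")))
    proteins <- list(
      A = list(reference = list(id = "refA", seq = "ACDEF"),
               hits = read_hit_table(pa)),
      B = list(reference = list(id = "refB", seq = "GHIKLM"),
               hits = read_hit_table(pb)))
    exp_fa <- golden(c(">reference|refA|refB", "ACDEFGHIKLM",
                       ">7|sA1|sB1", "ACDEFGHIKLM",
                       ">8|sA3|sB2", "ACDEAGHIKLA"))
    exp_seg <- data.frame(label = c("A", "B"), start = c(1L, 6L),
                          end = c(5L, 11L))
    return(list(proteins = proteins, hit_paths = c(pa, pb),
                expected_fasta = exp_fa, expected_segments = exp_seg,
                expect_error = FALSE))
  }
  if (plan == "bitscore_tie") {
    # taxid 5 of protein A: equal E-values, sA2 wins on bit-score 200 > 150
    pa <- write_hits("protA", list(
      c("refA", "sA1", "5", "1e-06", "150", "CCCC"),
      c("refA", "sA2", "5", "1e-06", "200", "ACDE")))
    pb <- write_hits("protB", list(
      c("refB", "sB1", "5", "1e-07", "90", "FGH")))
    proteins <- list(
      A = list(reference = list(id = "refA", seq = "ACDE"),
               hits = read_hit_table(pa)),
      B = list(reference = list(id = "refB", seq = "FGH"),
               hits = read_hit_table(pb)))
    exp_fa <- golden(c(">reference|refA|refB", "ACDEFGH",
                       ">5|sA2|sB1", "ACDEFGH"))
    exp_seg <- data.frame(label = c("A", "B"), start = c(1L, 5L),
                          end = c(4L, 7L))
    return(list(proteins = proteins, hit_paths = c(pa, pb),
                expected_fasta = exp_fa, expected_segments = exp_seg,
                expect_error = FALSE))
  }
  if (plan == "empty_intersection") {
    pa <- write_hits("protA", list(
      c("refA", "sA1", "1", "1e-06", "100", "ACDE"),
      c("refA", "sA2", "2", "1e-06", "100", "ACDE")))
    pb <- write_hits("protB", list(
      c("refB", "sB1", "3", "1e-06", "100", "FGH"),
      c("refB", "sB2", "4", "1e-06", "100", "FGH")))
    proteins <- list(
      A = list(reference = list(id = "refA", seq = "ACDE"),
               hits = read_hit_table(pa)),
      B = list(reference = list(id = "refB", seq = "FGH"),
               hits = read_hit_table(pb)))
    return(list(proteins = proteins, hit_paths = c(pa, pb),
                expected_fasta = NULL, expected_segments = NULL,
                expect_error = TRUE))
  }
  # three_proteins: taxid sets {1,2,3,5,9} / {2,3,5,8} / {1,2,3,5,6,7};
  # three-way intersection = {2,3,5} -> reference + 3 rows
  pa <- write_hits("protA", list(
    c("refA", "a1", "1", "1e-06", "100", "MKVL"),
    c("refA", "a2", "2", "1e-06", "100", "MKVI"),
    c("refA", "a3", "3", "1e-06", "100", "MKLL"),
    c("refA", "a5", "5", "1e-06", "100", "MRVL"),
    c("refA", "a9", "9", "1e-06", "100", "MKVV")))
  pb <- write_hits("protB", list(
    c("refB", "b2", "2", "1e-06", "100", "WGC"),
    c("refB", "b3", "3", "1e-06", "100", "WGS"),
    c("refB", "b5", "5", "1e-06", "100", "WAC"),
    c("refB", "b8", "8", "1e-06", "100", "WGA")))
  pc <- write_hits("protC", list(
    c("refC", "c1", "1", "1e-06", "100", "DERTY"),
    c("refC", "c2", "2", "1e-06", "100", "DERTF"),
    c("refC", "c3", "3", "1e-06", "100", "DERSY"),
    c("refC", "c5", "5", "1e-06", "100", "DARTY"),
    c("refC", "c6", "6", "1e-06", "100", "DERTT"),
    c("refC", "c7", "7", "1e-06", "100", "DERTW")))
  proteins <- list(
    A = list(reference = list(id = "refA", seq = "MKVL"),
             hits = read_hit_table(pa)),
    B = list(reference = list(id = "refB", seq = "WGC"),
             hits = read_hit_table(pb)),
    C = list(reference = list(id = "refC", seq = "DERTY"),
             hits = read_hit_table(pc)))
  exp_fa <- golden(c(">reference|refA|refB|refC", "MKVLWGCDERTY",
                     ">2|a2|b2|c2", "MKVIWGCDERTF",
                     ">3|a3|b3|c3", "MKLLWGSDERSY",
                     ">5|a5|b5|c5", "MRVLWACDARTY"))
  exp_seg <- data.frame(label = c("A", "B", "C"), start = c(1L, 5L, 8L),
                        end = c(4L, 7L, 12L))
  list(proteins = proteins, hit_paths = c(pa, pb, pc),
       expected_fasta = exp_fa, expected_segments = exp_seg,
       expect_error = FALSE)
}

#' Write a minimal C-alpha-only PDB and its expected contact map
#'
#' Builds a single-model PDB with one C-alpha atom per residue at the given
#' coordinates. The expected contact map is computed by a direct
#' double-loop over Euclidean distances (independent of [contact_map()]).
#'
#' @param chains Named list (chain id -> data frame with columns `resno`,
#'   `aa` (one-letter), `x`, `y`, `z` in Angstrom).
#' @param path Output PDB path.
#' @param threshold Contact threshold in Angstrom (default 12, strict `<`).
#' @return List with `path` and `expected` (symmetric logical matrix over
#'   the concatenated residues of all chains, in input order).
#' @export
make_toy_structure <- function(chains, path, threshold = 12) {
  if (any(vapply(chains, nrow, integer(1L)) == 0L))
    stop("empty chain in toy structure")
  lines <- character(0)
  serial <- 0L
  coords <- NULL
  for (ch in names(chains)) {
    df <- chains[[ch]]
    for (r in seq_len(nrow(df))) {
      serial <- serial + 1L
      res3 <- bio3d::aa123(df$aa[r])
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, res3, ch, df$resno[r], df$x[r], df$y[r], df$z[r],
        1.00, 0.00, "C"))
      coords <- rbind(coords, c(df$x[r], df$y[r], df$z[r]))
    }
  }
  writeLines(c(lines, "END"), path)
  n <- nrow(coords)
  expected <- matrix(FALSE, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (i != j)
        expected[i, j] <- sqrt(sum((coords[i, ] - coords[j, ])^2)) < threshold
  list(path = path, expected = expected)
}
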