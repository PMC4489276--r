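# Evaluation against a structure: C-alpha contact maps at a distance
# threshold, mapping of reference positions onto PDB chains, and
# precision / ROC metrics split by link class.

#' Load C-alpha coordinates for selected chains of a PDB file
#'
#' Reads the first model only; HETATM records are skipped; alternate
#' locations are resolved to the highest occupancy, then first in file
#' order. Residues without a C-alpha are absent from the result.
#'
#' @param pdb_path Path to a PDB file.
#' @param chain_ids Character vector of chain identifiers.
#' @return List of `chain_coordinates`: each a list with `chain_id`,
#'   `resno` (increasing residue numbers), `aa` (one-letter codes) and
#'   `xyz` (n x 3 matrix, Angstrom).
#' @export
load_structure_chains <- function(pdb_path, chain_ids) {
  if (!file.exists(pdb_path)) stop("no such file: ", pdb_path)
  pdb <- bio3d::read.pdb(pdb_path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  missing <- setdiff(chain_ids, unique(at$chain))
  if (length(missing))
    stop("chain(s) not found in ", pdb_path, ": ",
         paste(missing, collapse = ", "))
  lapply(chain_ids, function(ch) {
    a <- at[at$chain == ch, , drop = FALSE]
    # altloc: keep highest occupancy, then first occurrence, per residue
    occ <- ifelse(is.na(a$o), 1, a$o)
    ord <- order(a$resno, -occ, seq_len(nrow(a)))
    a <- a[ord, , drop = FALSE]
    a <- a[!duplicated(a$resno), , drop = FALSE]
    structure(list(chain_id = ch,
                   resno = a$resno,
                   aa = unname(bio3d::aa321(a$resid)),
                   xyz = cbind(a$x, a$y, a$z)),
              class = "chain_coordinates")
  })
}

#' Map reference positions onto a structure chain
#'
#' Globally aligns the reference segment sequence against the chain's
#' one-letter sequence (match +1, mismatch 0, linear gap -1); every aligned
#' residue pair (match or mismatch) maps that reference position to the
#' chain residue number.
#'
#' @param reference_seq Ungapped reference segment sequence (string).
#' @param chain A `chain_coordinates`.
#' @param min_coverage Error below this mapped fraction of the reference
#'   (default 0.3) -- a sign the wrong chain was supplied.
#' @return List with `mapping` (integer vector over reference positions;
#'   `NA` where unmapped; values are chain residue numbers) and `coverage`.
#' @export
map_reference_to_chain <- function(reference_seq, chain,
                                   min_coverage = 0.3) {
  ref <- toupper(reference_seq)
  ch <- paste(chain$aa, collapse = "")
  if (!nzchar(ref) || !nzchar(ch)) stop("empty sequence")
  alpha <- unique(strsplit(paste0(ref, ch), "")[[1]])
  subst <- matrix(0, length(alpha), length(alpha),
                  dimnames = list(alpha, alpha))
  diag(subst) <- 1
  aln <- Biostrings::pairwiseAlignment(ref, ch, type = "global",
                                       substitutionMatrix = subst,
                                       gapOpening = 0, gapExtension = 1)
  pat <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  mapping <- rep(NA_integer_, nchar(ref))
  pi <- 0L; si <- 0L
  for (k in seq_along(pat)) {
    if (pat[k] != "-") pi <- pi + 1L
    if (sub[k] != "-") si <- si + 1L
    if (pat[k] != "-" && sub[k] != "-") mapping[pi] <- chain$resno[si]
  }
  coverage <- mean(!is.na(mapping))
  if (coverage < min_coverage)
    stop("only ", round(coverage * 100), "% of the reference maps onto ",
         "chain ", chain$chain_id, " -- wrong chain?")
  list(mapping = mapping, coverage = coverage)
}

#' Contact map over paired-alignment reference positions
#'
#' A pair of mapped positions is a contact when the Euclidean C-alpha
#' distance is strictly below `threshold` Angstrom (a distance of exactly
#' the threshold is not a contact). Positions without a structural mapping
#' are flagged and excluded from all downstream metrics.
#'
#' @param pm A `paired_msa`.
#' @param assignments Named list (one entry per segment label) of lists with
#'   `chain` (a `chain_coordinates`) and `mapping` (from
#'   [map_reference_to_chain()], over that segment's positions).
#' @param threshold Distance threshold in Angstrom (default 12).
#' @return A `contact_map`: list with `contact` (L x L logical), `distance`
#'   (L x L, `NA` where unmapped), `mapped` (logical per position),
#'   `threshold`.
#' @export
contact_map <- function(pm, assignments, threshold = 12) {
  L <- n_columns(pm)
  coords <- matrix(NA_real_, L, 3L)
  for (k in seq_len(nrow(pm$segments))) {
    lab <- pm$segments$label[k]
    if (is.null(assignments[[lab]])) next
    a <- assignments[[lab]]
    cols <- pm$segments$start[k]:pm$segments$end[k]
    stopifnot(length(a$mapping) == length(cols))
    ridx <- match(a$mapping, a$chain$resno)
    ok <- !is.na(ridx)
    coords[cols[ok], ] <- a$chain$xyz[ridx[ok], , drop = FALSE]
  }
  mapped <- !is.na(coords[, 1L])
  if (sum(mapped) < 2L) stop("fewer than two mapped positions")
  d <- as.matrix(stats::dist(coords))
  d[!mapped, ] <- NA
  d[, !mapped] <- NA
  contact <- !is.na(d) & d < threshold
  diag(contact) <- FALSE
  structure(list(contact = contact, distance = d, mapped = mapped,
                 threshold = threshold),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  n <- sum(x$mapped)
  cat("contact map: ", length(x$mapped), " positions (", n, " mapped), ",
      sum(x$contact[upper.tri(x$contact)]), " contacts at < ",
      x$threshold, " A\n", sep = "")
  invisible(x)
}

# Area under the ROC curve by cumulative TPR/FPR with trapezoids;
# tied scores advance the curve jointly.
roc_auc <- function(scores, positive) {
  ord <- order(-scores)
  scores <- scores[ord]; positive <- positive[ord]
  grp <- cumsum(!duplicated(scores))
  tp <- cumsum(positive); fp <- cumsum(!positive)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / sum(positive))
  fpr <- c(0, fp[last] / sum(!positive))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

#' Evaluate ranked predictions against a contact map
#'
#' Restricts the ranking to the requested link class and to pairs with both
#' endpoints structurally mapped, then reports precision at rank `k`
#' (fraction of the first k such pairs that are contacts) and the ROC AUC
#' over all of them (contacts as positives).
#'
#' @param ranked A `ranked_pairs`.
#' @param cmap A `contact_map` over the same positions.
#' @param class_filter `"both"`, `"inter"` or `"intra"`.
#' @param k Rank cutoff for precision (default 10).
#' @return List: `precision_at_k`, `k`, `auc`, `n_pairs` (evaluated),
#'   `n_skipped_unmapped`, `n_positives`, `n_negatives`.
#' @export
evaluate_predictions <- function(ranked, cmap,
                                 class_filter = c("both", "inter", "intra"),
                                 k = 10) {
  class_filter <- match.arg(class_filter)
  if (length(cmap$mapped) != attr(ranked, "L"))
    stop("ranking and contact map cover different position sets")
  keep_class <- match_class(ranked$class, class_filter)
  sel <- ranked[keep_class, , drop = FALSE]
  mapped <- cmap$mapped[sel$i] & cmap$mapped[sel$j]
  n_skip <- sum(!mapped)
  sel <- sel[mapped, , drop = FALSE]
  if (nrow(sel) == 0L) stop("no mapped pairs to evaluate")
  is_contact <- cmap$contact[cbind(sel$i, sel$j)]
  kk <- min(k, nrow(sel))
  prec <- mean(is_contact[seq_len(kk)])
  if (!any(is_contact) || all(is_contact))
    stop("AUC undefined: need both contact and non-contact pairs ",
         "(got ", sum(is_contact), " positives of ", nrow(sel), ")")
  auc <- roc_auc(sel$score, is_contact)
  list(precision_at_k = prec, k = kk, auc = auc, n_pairs = nrow(sel),
       n_skipped_unmapped = n_skip, n_positives = sum(is_contact),
       n_negatives = sum(!is_contact))
}

#' Annotated per-pair evaluation TSV
#'
#' Writes rank, positions, score, class, C-alpha distance and contact flag
#' for every evaluated pair.
#'
#' @param ranked A `ranked_pairs`.
#' @param cmap A `contact_map`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_evaluation_tsv <- function(ranked, cmap, path) {
  df <- data.frame(rank = ranked$rank, i = ranked$i, j = ranked$j,
                   score = ranked$score, class = ranked$class,
                   distance_A = cmap$distance[cbind(ranked$i, ranked$j)],
                   contact = cmap$contact[cbind(ranked$i, ranked$j)])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
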