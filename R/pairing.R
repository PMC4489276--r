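# TaxID pairing: build the concatenated multiprotein alignment from
# per-protein homolog hit sets, keeping one protein per NCBI taxID.

#' Read a homolog hit table
#'
#' Reads a BLAST-tabular-style TSV describing the homologs of one query
#' protein. Expected columns (no header): qseqid, sseqid, staxids, evalue,
#' bitscore and optionally a sixth column with the subject sequence aligned
#' in query coordinates (gapped, same length as the query reference).
#' When the sixth column is absent, `aligned_fasta` must name an aligned
#' FASTA file keyed by sseqid. Multi-valued staxids cells
#' (semicolon-separated) replicate the hit once per taxID.
#'
#' The package consumes such tables rather than running the search itself;
#' the search defaults used to produce them in the original protocol were an
#' E-value threshold of 1e-5 over 3 PSI-BLAST iterations.
#'
#' @param path Path to the TSV.
#' @param aligned_fasta Optional aligned FASTA with one record per sseqid.
#' @return A `hit_table` data frame with columns `sseqid`, `taxid`,
#'   `evalue`, `bitscore`, `aligned_seq`.
#' @export
read_hit_table <- function(path, aligned_fasta = NULL) {
  df <- read.delim(path, header = FALSE, sep = "\t",
                   colClasses = "character", comment.char = "#")
  if (ncol(df) < 5L)
    stop("hit table needs at least 5 columns ",
         "(qseqid, sseqid, staxids, evalue, bitscore)")
  names(df)[1:5] <- c("qseqid", "sseqid", "staxids", "evalue", "bitscore")
  aligned <- if (ncol(df) >= 6L) df[[6L]] else NULL
  if (is.null(aligned)) {
    if (is.null(aligned_fasta))
      stop("no aligned-sequence column and no companion aligned FASTA")
    set <- Biostrings::readBStringSet(aligned_fasta)
    ids <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1L), 1L)
    idx <- match(df$sseqid, ids)
    if (anyNA(idx))
      stop("sseqid '", df$sseqid[which(is.na(idx))[1L]],
           "' missing from ", aligned_fasta)
    aligned <- as.character(set)[idx]
  }
  hits <- data.frame(sseqid = df$sseqid,
                     taxid = df$staxids,
                     evalue = as.numeric(df$evalue),
                     bitscore = as.numeric(df$bitscore),
                     aligned_seq = toupper(aligned),
                     stringsAsFactors = FALSE)
  if (any(hits$evalue < 0)) stop("negative E-value")
  # expand semicolon-separated taxid cells
  tax <- strsplit(hits$taxid, ";", fixed = TRUE)
  hits <- hits[rep(seq_len(nrow(hits)), lengths(tax)), , drop = FALSE]
  hits$taxid <- as.integer(unlist(tax))
  if (anyNA(hits$taxid) || any(hits$taxid <= 0))
    stop("taxids must be positive integers")
  rownames(hits) <- NULL
  class(hits) <- c("hit_table", "data.frame")
  hits
}

#' Keep the best hit per taxID
#'
#' Within each taxID, paralogs are resolved by keeping the hit with the
#' lowest E-value; on an E-value tie the higher bit-score wins, and a
#' residual tie is broken by the lexicographically smallest sseqid so the
#' selection is a total order. The result is independent of row order.
#'
#' @param hits A `hit_table` (one query protein).
#' @return A `hit_table` with exactly one row per taxID, ascending taxID.
#' @export
best_hit_per_taxid <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$taxid, hits$evalue, -hits$bitscore, hits$sseqid)
  hits <- hits[ord, , drop = FALSE]
  hits <- hits[!duplicated(hits$taxid), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Construct a paired (concatenated) alignment container
#'
#' @param x An `msa`.
#' @param segments Data frame with columns `label`, `start`, `end`
#'   (1-based, inclusive) that partitions the columns in order.
#' @return A `paired_msa` (also an `msa`).
#' @export
paired_msa <- function(x, segments) {
  stopifnot(inherits(x, "msa"),
            all(c("label", "start", "end") %in% names(segments)))
  segments <- as.data.frame(segments)[, c("label", "start", "end")]
  if (nrow(segments) < 2L || nrow(segments) > 6L)
    stop("a paired msa joins between two and six proteins")
  if (segments$start[1L] != 1L ||
      segments$end[nrow(segments)] != n_columns(x) ||
      (nrow(segments) > 1L &&
       any(segments$start[-1L] != segments$end[-nrow(segments)] + 1L)))
    stop("segments must partition the columns contiguously")
  x$segments <- segments
  class(x) <- c("paired_msa", "msa")
  x
}

#' @export
print.paired_msa <- function(x, ...) {
  cat("paired msa: ", n_records(x), " records x ", n_columns(x),
      " columns; segments:\n", sep = "")
  for (k in seq_len(nrow(x$segments)))
    cat("  ", x$segments$label[k], ": ", x$segments$start[k], "-",
        x$segments$end[k], "\n", sep = "")
  invisible(x)
}

# Map each column to its segment index (1-based).
segment_of_column <- function(segments, L) {
  seg <- integer(L)
  for (k in seq_len(nrow(segments)))
    seg[segments$start[k]:segments$end[k]] <- k
  if (any(seg == 0L)) stop("position outside all segments")
  seg
}

# Re-trim a paired msa to its reference and apply the coverage filter,
# shrinking segment bounds consistently with the dropped columns.
paired_trim_filter <- function(pm, min_fraction = 0.5) {
  segs <- pm$segments
  seg_idx <- segment_of_column(segs, n_columns(pm))
  trimmed <- trim_to_reference(unclass_msa(pm))
  kept <- attr(trimmed, "kept_columns")
  kept_seg <- seg_idx[kept]
  new_segs <- segs[sort(unique(kept_seg)), , drop = FALSE]
  counts <- tabulate(kept_seg, nbins = nrow(segs))[sort(unique(kept_seg))]
  if (nrow(new_segs) < 2L)
    stop("trimming removed all columns of a protein segment")
  new_segs$end <- cumsum(counts)
  new_segs$start <- c(1L, new_segs$end[-length(counts)] + 1L)
  rownames(new_segs) <- NULL
  out <- paired_msa(filter_coverage(trimmed, min_fraction), new_segs)
  attr(out, "kept_columns") <- kept
  out
}

unclass_msa <- function(x) {
  structure(list(seqs = x$seqs, ids = x$ids, taxids = x$taxids),
            class = "msa")
}

#' Build a paired MSA from per-protein homolog sets
#'
#' Pairs the proteins organism-by-organism: the row set is the intersection
#' of the taxIDs present for every protein (after per-taxID paralog
#' resolution with [best_hit_per_taxid()]), in ascending taxID order, and
#' each row concatenates that organism's selected homolog for each protein
#' in input order. The first row concatenates the reference sequences. The
#' concatenated alignment is then gap-trimmed to the reference and rows
#' covering less than `min_fraction` of it are removed.
#'
#' @param proteins Named list (2-6 entries, names become segment labels);
#'   each entry is a list with `reference` (a list or named vector with
#'   `id` and `seq`, gap-free) and `hits` (a `hit_table`).
#' @param min_fraction Coverage threshold passed to [filter_coverage()].
#' @param max_total_length Warn when the summed reference length exceeds
#'   this guard (default 2000).
#' @return A `paired_msa`; row ids are `taxid|sseqidA|sseqidB|...` and the
#'   reference row is `reference|idA|idB|...`.
#' @export
build_paired_msa <- function(proteins, min_fraction = 0.5,
                             max_total_length = 2000) {
  np <- length(proteins)
  if (np < 2L || np > 6L)
    stop("between two and six proteins are required (got ", np, ")")
  labels <- names(proteins)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("proteins must be a named list")
  refs <- lapply(proteins, function(p) {
    r <- as.list(p$reference)
    if (grepl("-", r$seq, fixed = TRUE))
      stop("reference '", r$id, "' must be gap-free")
    r
  })
  ref_len <- vapply(refs, function(r) nchar(r$seq), integer(1L))
  if (sum(ref_len) > max_total_length)
    warning("total reference length ", sum(ref_len), " exceeds the guard of ",
            max_total_length, " residues")
  sel <- lapply(seq_len(np), function(k) {
    h <- best_hit_per_taxid(proteins[[k]]$hits)
    bad <- nchar(h$aligned_seq) != ref_len[k]
    if (any(bad))
      stop("aligned_seq length mismatch for hit '", h$sseqid[which(bad)[1L]],
           "' of protein '", labels[k], "'")
    h
  })
  common <- Reduce(intersect, lapply(sel, `[[`, "taxid"))
  if (length(common) == 0L) stop("no common taxa across the proteins")
  common <- sort(common)
  rows <- vapply(common, function(tx) {
    paste(vapply(sel, function(h) h$aligned_seq[h$taxid == tx],
                 character(1L)), collapse = "")
  }, character(1L))
  ids <- vapply(seq_along(common), function(r) {
    paste(c(common[r],
            vapply(sel, function(h) h$sseqid[h$taxid == common[r]],
                   character(1L))), collapse = "|")
  }, character(1L))
  ref_row <- paste(vapply(refs, `[[`, character(1L), "seq"), collapse = "")
  ref_id <- paste(c("reference", vapply(refs, `[[`, character(1L), "id")),
                  collapse = "|")
  m <- msa(c(ref_row, rows), ids = c(ref_id, ids),
           taxids = c(NA_integer_, common))
  ends <- cumsum(ref_len)
  segs <- data.frame(label = labels,
                     start = c(1L, head(ends, -1L) + 1L),
                     end = ends)
  paired_trim_filter(paired_msa(m, segs), min_fraction)
}

#' Validate and concatenate user-supplied per-protein alignments
#'
#' The alignments must have the same number of records and, where taxIDs are
#' present, identical taxIDs row by row (the same organism in the same row of
#' every alignment). Rows are concatenated in input order, then the result is
#' gap-trimmed to the reference and coverage-filtered.
#'
#' @param msas Named list of 2-6 `msa` objects (names become segment labels).
#' @param min_fraction Coverage threshold passed to [filter_coverage()].
#' @return A `paired_msa`.
#' @export
validate_user_paired_msas <- function(msas, min_fraction = 0.5) {
  np <- length(msas)
  if (np < 2L) stop("at least two proteins are required")
  if (np > 6L) stop("at most six proteins can be paired (got ", np, ")")
  labels <- names(msas)
  if (is.null(labels)) labels <- paste0("protein", seq_len(np))
  nrec <- vapply(msas, n_records, integer(1L))
  if (length(unique(nrec)) != 1L)
    stop("alignments must have the same number of sequences (got ",
         paste(nrec, collapse = ", "), ")")
  tax <- vapply(msas, function(m) m$taxids, integer(nrec[1L]))
  tax <- matrix(tax, nrow = nrec[1L])
  for (r in seq_len(nrec[1L])) {
    tr <- tax[r, ]
    tr <- tr[!is.na(tr)]
    if (length(unique(tr)) > 1L)
      stop("taxid mismatch at row ", r, ": ",
           paste(unique(tr), collapse = " vs "))
  }
  seqs <- do.call(cbind, lapply(msas, `[[`, "seqs"))
  ids <- apply(vapply(msas, `[[`, character(nrec[1L]), "ids"),
               1L, paste, collapse = "|")
  if (is.null(dim(tax))) tax <- matrix(tax, nrow = 1L)
  taxids <- apply(tax, 1L, function(tr) {
    tr <- tr[!is.na(tr)]
    if (length(tr)) tr[1L] else NA_integer_
  })
  m <- msa(apply(seqs, 1L, paste, collapse = ""), ids = ids,
           taxids = taxids)
  ends <- cumsum(vapply(msas, n_columns, integer(1L)))
  segs <- data.frame(label = labels,
                     start = c(1L, head(ends, -1L) + 1L), end = ends)
  paired_trim_filter(paired_msa(m, segs), min_fraction)
}

#' Write a paired MSA and its segment sidecar
#'
#' @param pm A `paired_msa`.
#' @param fasta_path Output FASTA path.
#' @param segments_path Output TSV path (protein_label, start_1based,
#'   end_1based_inclusive).
#' @return `fasta_path`, invisibly.
#' @export
write_paired_msa <- function(pm, fasta_path, segments_path) {
  write_fasta_msa(pm, fasta_path)
  segs <- data.frame(protein_label = pm$segments$label,
                     start_1based = pm$segments$start,
                     end_1based_inclusive = pm$segments$end)
  write.table(segs, segments_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(fasta_path)
}
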