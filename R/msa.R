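# Alignment container and the trimming / coverage / clustering rules applied
# to every MSA before scoring. The first record is always the reference.

#' Construct an aligned sequence set
#'
#' Creates an `msa` object from gapped sequences. Residues are upper-cased,
#' `.` is converted to `-`, and any character that is not one of the 20 amino
#' acids or the gap is normalized to the unknown symbol `X`. The first record
#' is taken as the reference sequence.
#'
#' @param sequences Character vector of equal-length gapped sequences.
#' @param ids Character vector of record identifiers (unique, non-empty).
#' @param taxids Optional integer vector of NCBI taxonomic identifiers
#'   (`NA` where unknown).
#' @return An object of class `msa`: a list with `seqs` (character matrix,
#'   one row per record, one column per alignment position), `ids`, and
#'   `taxids`.
#' @export
msa <- function(sequences, ids = paste0("seq", seq_along(sequences)),
                taxids = NULL) {
  if (length(sequences) < 1L) stop("an msa needs at least one record")
  if (any(!nzchar(sequences))) stop("empty sequence record")
  if (any(!nzchar(ids))) stop("empty record id")
  if (anyDuplicated(ids)) stop("duplicated record ids: ",
                               ids[duplicated(ids)][1L])
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1L])[1L]
    stop("ragged alignment: record '", ids[bad], "' has length ", lens[bad],
         " but the reference has length ", lens[1L])
  }
  seqs <- matrix(unlist(strsplit(toupper(sequences), "")),
                 nrow = length(sequences), byrow = TRUE)
  seqs[seqs == "."] <- "-"
  seqs[!(seqs %in% c(AA20, "-"))] <- "X"
  if (is.null(taxids)) taxids <- rep(NA_integer_, length(sequences))
  taxids <- as.integer(taxids)
  if (any(!is.na(taxids) & taxids < 0)) stop("negative taxid")
  structure(list(seqs = seqs, ids = as.character(ids), taxids = taxids),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("msa: ", n_records(x), " records x ", n_columns(x), " columns\n",
      sep = "")
  cat("reference: ", x$ids[1L], "\n", sep = "")
  if (any(!is.na(x$taxids)))
    cat("taxids present for ", sum(!is.na(x$taxids)), " records\n", sep = "")
  invisible(x)
}

#' Number of records / columns in an msa
#' @param x An `msa`.
#' @return Integer.
#' @export
n_records <- function(x) nrow(x$seqs)

#' @rdname n_records
#' @export
n_columns <- function(x) ncol(x$seqs)

#' Extract record sequences as strings
#' @param x An `msa`.
#' @return Character vector of gapped sequences.
#' @export
msa_sequences <- function(x) apply(x$seqs, 1L, paste, collapse = "")

subset_records <- function(x, idx) {
  x$seqs <- x$seqs[idx, , drop = FALSE]
  x$ids <- x$ids[idx]
  x$taxids <- x$taxids[idx]
  x
}

#' Read an aligned FASTA file
#'
#' Parses a gapped FASTA alignment; the first record is the reference.
#' Optionally extracts a taxID from each header with a regular expression
#' whose first capture group is the numeric taxID (e.g. `"OX=([0-9]+)"` for
#' UniProt headers).
#'
#' @param path Path to an aligned FASTA file.
#' @param taxid_pattern Optional regex with one capture group matching the
#'   taxID inside the header; records whose header does not match get `NA`.
#' @return An `msa`.
#' @export
read_fasta_msa <- function(path, taxid_pattern = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- vapply(strsplit(headers, "[ \t]"), `[`, character(1L), 1L)
  taxids <- rep(NA_integer_, length(set))
  if (!is.null(taxid_pattern)) {
    m <- regmatches(headers, regexec(taxid_pattern, headers))
    hit <- lengths(m) >= 2L
    taxids[hit] <- as.integer(vapply(m[hit], `[`, character(1L), 2L))
  }
  widths <- Biostrings::width(set)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop("ragged alignment in ", path, ": record '", ids[bad],
         "' has length ", widths[bad], " but the reference has length ",
         widths[1L])
  }
  msa(as.character(set), ids = ids, taxids = taxids)
}

#' Write an msa as aligned FASTA
#' @param x An `msa`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_msa <- function(x, path) {
  lines <- character(2L * n_records(x))
  lines[c(TRUE, FALSE)] <- paste0(">", x$ids)
  lines[c(FALSE, TRUE)] <- msa_sequences(x)
  writeLines(lines, path)
  invisible(path)
}

#' Remove columns that are gaps in the reference
#'
#' Drops every alignment column at which the reference (first) record has a
#' gap, from all records. The surviving columns are recorded in the
#' `kept_columns` attribute (old 1-based column indices, in order), which maps
#' trimmed positions back to the original alignment.
#'
#' @param x An `msa`.
#' @return The trimmed `msa`, with attribute `kept_columns`.
#' @export
trim_to_reference <- function(x) {
  keep <- which(x$seqs[1L, ] != "-")
  if (length(keep) == 0L) stop("empty reference: the reference is all gaps")
  x$seqs <- x$seqs[, keep, drop = FALSE]
  attr(x, "kept_columns") <- keep
  x
}

#' Drop records with low reference coverage
#'
#' After trimming to the reference, removes every record whose non-gap
#' residue count is strictly below `min_fraction` of the alignment length;
#' a record at exactly the boundary is kept. The reference is always kept.
#'
#' @param x A reference-trimmed `msa`.
#' @param min_fraction Minimum kept fraction of non-gap positions
#'   (default 0.5).
#' @return The filtered `msa`.
#' @export
filter_coverage <- function(x, min_fraction = 0.5) {
  L <- n_columns(x)
  cov <- rowSums(x$seqs != "-") / L
  keep <- cov >= min_fraction
  keep[1L] <- TRUE
  subset_records(x, which(keep))
}

#' Pairwise percent identity between two aligned sequences
#'
#' Identity is counted over columns where both sequences are non-gap;
#' the unknown symbol `X` never matches. Returns 0 when no column is
#' comparable.
#'
#' @param a,b Gapped sequences of equal length (strings).
#' @return Fraction in `[0, 1]`.
#' @export
percent_identity <- function(a, b) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  if (length(av) != length(bv))
    stop("sequences have unequal lengths (", length(av), " vs ",
         length(bv), ")")
  comp <- av != "-" & bv != "-"
  if (!any(comp)) return(0)
  sum(av[comp] == bv[comp] & av[comp] != "X") / sum(comp)
}

#' Hobohm-1 redundancy clustering
#'
#' Greedy single pass in record order: each record joins the first existing
#' cluster whose representative (the cluster's founding record) is at least
#' `identity_threshold` identical to it, otherwise it founds a new cluster.
#' Identity uses the [percent_identity()] definition (both-non-gap columns).
#'
#' @param x An `msa`.
#' @param identity_threshold Identity cutoff in `(0, 1]` (default 0.62).
#' @return A `cluster_assignment`: list with `cluster_id` (integer per
#'   record), `identity_threshold` and `n_clusters`.
#' @export
hobohm1 <- function(x, identity_threshold = 0.62) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  enc <- encode_msa(x, alphabet = "identity")
  cl <- cpp_hobohm1(enc, identity_threshold)
  structure(list(cluster_id = as.integer(cl),
                 identity_threshold = identity_threshold,
                 n_clusters = max(cl)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("Hobohm-1 clustering at ", x$identity_threshold * 100, "% identity: ",
      x$n_clusters, " clusters over ", length(x$cluster_id), " records\n",
      sep = "")
  invisible(x)
}

#' Cluster-based sequence weights
#'
#' Every record gets weight `1 / (size of its cluster)`; the effective number
#' of sequences Meff is then exactly the number of clusters.
#'
#' @param clusters A `cluster_assignment` from [hobohm1()].
#' @return A `sequence_weights`: list with `weights` (per record) and `meff`.
#' @export
cluster_weights <- function(clusters) {
  sizes <- table(clusters$cluster_id)
  w <- 1 / as.numeric(sizes[as.character(clusters$cluster_id)])
  structure(list(weights = w, meff = length(sizes)),
            class = "sequence_weights")
}

#' Uniform sequence weights
#' @param x An `msa`.
#' @return A `sequence_weights` with all weights 1 and `meff = n` records.
#' @export
uniform_weights <- function(x) {
  structure(list(weights = rep(1, n_records(x)), meff = n_records(x)),
            class = "sequence_weights")
}

#' @export
print.sequence_weights <- function(x, ...) {
  cat("sequence weights for ", length(x$weights), " records, Meff = ",
      format(x$meff), "\n", sep = "")
  invisible(x)
}

#' Write a cluster / weight report
#'
#' Writes the per-record TSV (record_id, cluster_id, weight) that accompanies
#' every scored alignment.
#'
#' @param x The clustered `msa`.
#' @param clusters A `cluster_assignment`.
#' @param weights A `sequence_weights`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(x, clusters, weights, path) {
  df <- data.frame(record_id = x$ids,
                   cluster_id = clusters$cluster_id,
                   weight = weights$weights)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
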