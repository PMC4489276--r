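# Comparison layer: inter/intra classification, ranking, links-needed
# thresholds, cross-method overlap and score-density summaries.

#' Construct a score table
#'
#' Bundles one method's symmetric pairwise score matrix with the segment map
#' of the paired alignment it was computed on.
#'
#' @param scores Symmetric L x L numeric matrix (diagonal ignored).
#' @param segments Segment data frame (`label`, `start`, `end`, 1-based
#'   inclusive) partitioning the L columns.
#' @param method Method label (e.g. `"mi"`, `"mfdca"`, `"plmdca"`).
#' @return A `score_table`.
#' @export
score_table <- function(scores, segments, method = "scores") {
  L <- nrow(scores)
  stopifnot(L == ncol(scores))
  seg_idx <- segment_of_column(segments, L)
  if (max(abs(scores - t(scores)), na.rm = TRUE) > 1e-8)
    stop("score matrix is not symmetric")
  structure(list(method = method, L = L, segments = segments,
                 scores = scores, segment_index = seg_idx),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat("score table (", x$method, "): ", x$L, " positions, ",
      x$L * (x$L - 1) / 2, " pairs, ", nrow(x$segments), " segments\n",
      sep = "")
  invisible(x)
}

#' Classify every position pair as inter- or intraprotein
#'
#' A pair is `inter` when its endpoints lie in different protein segments,
#' otherwise `intra:<label>` of the shared segment.
#'
#' @param segments Segment data frame partitioning `[1, L]`.
#' @param L Number of positions.
#' @return L x L character matrix (diagonal empty).
#' @export
classify_pairs <- function(segments, L) {
  seg_idx <- segment_of_column(segments, L)
  lab <- paste0("intra:", segments$label)
  cls <- matrix("", L, L)
  same <- outer(seg_idx, seg_idx, "==")
  cls[same] <- lab[seg_idx[row(cls)[same]]]
  cls[!same] <- "inter"
  diag(cls) <- ""
  cls
}

# classes of the pairs (i, j) given the segment index per column
class_of_pairs <- function(st, i, j) {
  si <- st$segment_index[i]
  sj <- st$segment_index[j]
  ifelse(si == sj, paste0("intra:", st$segments$label[si]), "inter")
}

#' Rank all pairs of a score table
#'
#' Descending by score; ties broken by smaller i, then smaller j, so the
#' ranking is a deterministic total order.
#'
#' @param st A `score_table`.
#' @return A `ranked_pairs` data frame: `rank`, `i`, `j`, `score`, `class`
#'   over the `L(L-1)/2` upper-triangle pairs, carrying the table's
#'   `method`, `L` and `segments` as attributes.
#' @export
rank_pairs <- function(st) {
  L <- st$L
  ut <- which(upper.tri(st$scores), arr.ind = TRUE)
  sc <- st$scores[ut]
  if (any(is.na(sc) | is.nan(sc)))
    stop("NaN scores cannot be ranked")
  ord <- order(-sc, ut[, 1L], ut[, 2L])
  out <- data.frame(rank = seq_along(ord),
                    i = ut[ord, 1L], j = ut[ord, 2L],
                    score = sc[ord],
                    class = class_of_pairs(st, ut[ord, 1L], ut[ord, 2L]),
                    stringsAsFactors = FALSE)
  attr(out, "method") <- st$method
  attr(out, "L") <- L
  attr(out, "segments") <- st$segments
  class(out) <- c("ranked_pairs", "data.frame")
  out
}

match_class <- function(class_vec, target_class) {
  switch(target_class,
         both = rep(TRUE, length(class_vec)),
         inter = class_vec == "inter",
         intra = startsWith(class_vec, "intra"),
         stop("unknown target class: ", target_class))
}

#' Ranks to inspect to observe n links of a class
#'
#' The smallest k such that the top-k ranked pairs contain at least `n`
#' pairs of the target class: how deep into the full ranking one must look
#' to collect, say, 100 interprotein links.
#'
#' @param ranked A `ranked_pairs`.
#' @param target_class `"inter"`, `"intra"` or `"both"`.
#' @param n Number of links wanted (>= 1).
#' @return Integer k.
#' @export
links_needed <- function(ranked, target_class = c("inter", "intra", "both"),
                         n) {
  target_class <- match.arg(target_class)
  stopifnot(n >= 1)
  is_target <- match_class(ranked$class, target_class)
  total <- sum(is_target)
  if (total < n)
    stop("only ", total, " ", target_class,
         " pairs are available (requested ", n, ")")
  which(cumsum(is_target) >= n)[1L]
}

#' Overlap of the top links across methods
#'
#' Each method's top set is its first `n` ranked pairs of the target class
#' (equivalently: its first `links_needed(target_class, n)` ranked pairs
#' restricted to that class). With `mode = "overall"` the top set is instead
#' the first `n` ranked pairs overall, filtered to the class. The overlap is
#' the intersection of the top sets; per-method ranks are reported for the
#' union.
#'
#' @param tables List of 2-4 `ranked_pairs` over the same L and segments.
#' @param target_class `"inter"`, `"intra"` or `"both"`.
#' @param n Top-set size per method.
#' @param mode `"class"` (default) or `"overall"` (see above).
#' @return List with `overlap` (data frame: `i`, `j`, `class`, one rank
#'   column per method) and `union` (same columns, `NA` rank where a pair is
#'   absent from a method's top set).
#' @export
top_overlap <- function(tables, target_class = c("inter", "intra", "both"),
                        n, mode = c("class", "overall")) {
  target_class <- match.arg(target_class)
  mode <- match.arg(mode)
  stopifnot(length(tables) >= 2L, length(tables) <= 4L)
  Ls <- vapply(tables, attr, numeric(1L), "L")
  if (length(unique(Ls)) != 1L)
    stop("ranked tables cover different numbers of positions: ",
         paste(Ls, collapse = ", "))
  methods <- vapply(seq_along(tables), function(k) {
    m <- attr(tables[[k]], "method")
    if (is.null(m)) paste0("method", k) else m
  }, character(1L))
  top_sets <- lapply(tables, function(tb) {
    keep <- match_class(tb$class, target_class)
    if (mode == "class") {
      sel <- tb[keep, , drop = FALSE]
      sel[seq_len(min(n, nrow(sel))), , drop = FALSE]
    } else {
      tb[keep & tb$rank <= n, , drop = FALSE]
    }
  })
  keys <- lapply(top_sets, function(s) paste(s$i, s$j))
  union_keys <- Reduce(union, keys)
  inter_keys <- Reduce(intersect, keys)
  build <- function(kset) {
    if (length(kset) == 0L)
      return(data.frame(i = integer(), j = integer(),
                        class = character()))
    ij <- do.call(rbind, strsplit(kset, " "))
    df <- data.frame(i = as.integer(ij[, 1L]), j = as.integer(ij[, 2L]),
                     class = NA_character_)
    for (k in seq_along(tables)) {
      m <- match(kset, paste(tables[[k]]$i, tables[[k]]$j))
      df[[paste0("rank_", methods[k])]] <- tables[[k]]$rank[m]
      df$class <- tables[[k]]$class[m]
    }
    df[order(df[[4L]]), , drop = FALSE]
  }
  res <- build(union_keys)
  if (nrow(res)) {
    in_top <- vapply(seq_along(tables), function(k)
      paste(res$i, res$j) %in% keys[[k]], logical(nrow(res)))
    in_top <- matrix(in_top, nrow = nrow(res))
    for (k in seq_along(tables))
      res[[paste0("rank_", methods[k])]][!in_top[, k]] <- NA_integer_
  }
  list(overlap = build(inter_keys), union = res)
}

#' Score-density summary per link class
#'
#' Empirical distribution of the scores for the interprotein, intraprotein
#' and pooled pair sets: counts, moments, quantiles and binned densities
#' over shared break points.
#'
#' @param st A `score_table`.
#' @param n_bins Number of histogram bins (default 50).
#' @return A `density_summary`: list with one entry per class
#'   (`inter`, `intra`, `both`), each holding `count`, `mean`, `sd`,
#'   `quantiles` (1/5/25/50/75/95/99\%) and `density` (data frame `mid`,
#'   `density`).
#' @export
density_summary <- function(st, n_bins = 50) {
  ut <- which(upper.tri(st$scores), arr.ind = TRUE)
  sc <- st$scores[ut]
  cls <- class_of_pairs(st, ut[, 1L], ut[, 2L])
  breaks <- seq(min(sc), max(sc), length.out = n_bins + 1L)
  if (breaks[1L] == breaks[n_bins + 1L])
    breaks <- breaks[1L] + c(-0.5, seq_len(n_bins) / n_bins - 0.5)
  probs <- c(0.01, 0.05, 0.25, 0.5, 0.75, 0.95, 0.99)
  one <- function(v) {
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    list(count = length(v),
         mean = if (length(v)) mean(v) else NA_real_,
         sd = if (length(v) > 1L) sd(v) else NA_real_,
         quantiles = if (length(v)) quantile(v, probs, names = TRUE)
                     else setNames(rep(NA_real_, length(probs)), probs),
         density = data.frame(mid = h$mids, density = h$density))
  }
  structure(list(method = st$method,
                 inter = one(sc[cls == "inter"]),
                 intra = one(sc[startsWith(cls, "intra")]),
                 both = one(sc)),
            class = "density_summary")
}

#' Import an externally computed score file
#'
#' Plug-in point for methods not implemented here (e.g. PSICOV or native
#' CCMpred output): a TSV of `i`, `j`, `score` with 1-based positions,
#' with or without a header line. The listing must cover every pair unless
#' `sparse = TRUE`, in which case missing pairs get `-Inf` (ranked last).
#' Duplicate entries must agree.
#'
#' @param path TSV path.
#' @param segments Segment data frame of the paired alignment.
#' @param L Number of positions.
#' @param method Method tag (default from the file name).
#' @param sparse Allow incomplete listings.
#' @return A `score_table`.
#' @export
import_external_scores <- function(path, segments, L,
                                   method = sub("[.][^.]*$", "",
                                                basename(path)),
                                   sparse = FALSE) {
  raw <- read.delim(path, header = FALSE, sep = "\t",
                    colClasses = "character", comment.char = "#")
  if (ncol(raw) < 3L) stop("expected 3 columns (i, j, score)")
  if (is.na(suppressWarnings(as.numeric(raw[1L, 1L]))))
    raw <- raw[-1L, , drop = FALSE]
  i <- as.integer(raw[[1L]]); j <- as.integer(raw[[2L]])
  s <- as.numeric(raw[[3L]])
  if (anyNA(i) || anyNA(j) || anyNA(s)) stop("malformed score file")
  if (any(i < 1L | i > L | j < 1L | j > L | i == j))
    stop("positions out of range 1..", L)
  key <- paste(pmin(i, j), pmax(i, j))
  agg <- tapply(s, key, function(v) length(unique(v)))
  if (any(agg > 1L))
    stop("conflicting duplicate entries for pair ",
         names(agg)[which(agg > 1L)[1L]])
  scores <- matrix(-Inf, L, L)
  scores[cbind(i, j)] <- s
  scores[cbind(j, i)] <- s
  diag(scores) <- 0
  missing <- upper.tri(scores) & is.infinite(scores)
  if (any(missing) && !sparse)
    stop(sum(missing), " pairs missing from ", path,
         " (use sparse = TRUE to rank them last)")
  score_table(scores, segments, method = method)
}

#' Export a score table as an annotated TSV
#'
#' Writes one row per upper-triangle pair with 1-based positions, the
#' reference residues and protein labels at both endpoints, one column per
#' score matrix, and the inter/intra class.
#'
#' @param pm The `paired_msa` the scores were computed on.
#' @param matrices Named list of symmetric L x L score matrices
#'   (e.g. `list(raw_mi = ..., mip = ..., zscore = ...)`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
export_scores <- function(pm, matrices, path) {
  L <- n_columns(pm)
  st0 <- score_table(matrices[[1L]], pm$segments,
                     method = names(matrices)[1L])
  ut <- which(upper.tri(matrices[[1L]]), arr.ind = TRUE)
  ord <- order(ut[, 1L], ut[, 2L])
  ut <- ut[ord, , drop = FALSE]
  refres <- pm$seqs[1L, ]
  df <- data.frame(pos_i = ut[, 1L], pos_j = ut[, 2L],
                   res_i = refres[ut[, 1L]], res_j = refres[ut[, 2L]],
                   protein_i = pm$segments$label[st0$segment_index[ut[, 1L]]],
                   protein_j = pm$segments$label[st0$segment_index[ut[, 2L]]],
                   stringsAsFactors = FALSE)
  for (nm in names(matrices)) df[[nm]] <- matrices[[nm]][ut]
  df$class <- class_of_pairs(st0, ut[, 1L], ut[, 2L])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
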