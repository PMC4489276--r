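# Static figures mirroring the server-style displays: a circos view with
# residue, conservation and protein tracks plus Bezier chords for the
# selected top links, and an upper-triangular score-matrix view with
# rank-banded colors. Both are assembled as SVG text, so rendering is a
# deterministic function of its inputs.

SEGMENT_COLORS <- c("#2ca02c", "#9467bd", "#1f77b4", "#ff7f0e",
                    "#8c564b", "#17becf")
INTER_COLOR <- "#d62728"

lerp_color <- function(t, low = c(0, 0, 255), high = c(255, 0, 0)) {
  t <- pmin(1, pmax(0, t))
  rgb <- round(outer(t, high) + outer(1 - t, low))
  sprintf("#%02x%02x%02x", rgb[, 1], rgb[, 2], rgb[, 3])
}

svg_header <- function(size) c(
  sprintf("<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%d\" height=\"%d\" viewBox=\"0 0 %d %d\">",
          size, size, size, size),
  sprintf("<rect width=\"%d\" height=\"%d\" fill=\"white\"/>", size, size))

#' Render a circos figure of the top covariation links
#'
#' Four concentric tracks: reference residue type and number; per-position
#' conservation colored red (high) to blue (low), with the color ramp
#' anchored at the 5th and 95th percentiles of the conservation values;
#' the protein segment track (green, violet, ...); and Bezier chords for
#' the selected top links -- red when interprotein, otherwise the color of
#' the shared segment.
#'
#' @param st A `score_table`.
#' @param conservation Per-position conservation values (length L), e.g.
#'   from [position_conservation()].
#' @param selection List with `class` (`"inter"`, `"intra"` or `"both"`)
#'   and `n` (number of top links of that class to draw).
#' @param path Output SVG path.
#' @return `path`, invisibly.
#' @export
render_circos <- function(st, conservation,
                          selection = list(class = "both", n = 10),
                          path) {
  L <- st$L
  stopifnot(length(conservation) == L)
  ranked <- rank_pairs(st)
  links_needed(ranked, selection$class, selection$n) # errors if unavailable
  links <- ranked[match_class(ranked$class, selection$class), ,
                  drop = FALSE][seq_len(selection$n), , drop = FALSE]
  size <- 640
  cx <- size / 2
  theta <- 2 * pi * (seq_len(L) - 0.5) / L - pi / 2
  px <- function(r) cx + r * cos(theta)
  py <- function(r) cx + r * sin(theta)
  qs <- quantile(conservation, c(0.05, 0.95))
  tcons <- if (qs[2] > qs[1])
    (conservation - qs[1]) / (qs[2] - qs[1]) else rep(0.5, L)
  cons_col <- lerp_color(tcons)
  seg_col <- SEGMENT_COLORS[st$segment_index]
  refres <- attr(st, "reference_residues")
  if (is.null(refres)) refres <- rep("", L)
  out <- svg_header(size)
  # residue labels
  lab_step <- max(1L, ceiling(L / 120))
  for (i in seq(1L, L, by = lab_step)) {
    deg <- theta[i] * 180 / pi
    out <- c(out, sprintf(
      "<text class=\"residue\" x=\"%.1f\" y=\"%.1f\" font-size=\"8\" text-anchor=\"middle\" transform=\"rotate(%.1f %.1f %.1f)\">%s%d</text>",
      px(296)[i], py(296)[i], deg + 90, px(296)[i], py(296)[i],
      refres[i], i))
  }
  tick <- function(r0, r1, col, cls) sprintf(
    "<line class=\"%s\" x1=\"%.1f\" y1=\"%.1f\" x2=\"%.1f\" y2=\"%.1f\" stroke=\"%s\" stroke-width=\"%.1f\"/>",
    cls, px(r0), py(r0), px(r1), py(r1), col,
    max(1, 2 * pi * 250 / L - 0.5))
  out <- c(out, tick(258, 278, cons_col, "conservation"))
  out <- c(out, tick(234, 252, seg_col, "segment"))
  for (k in seq_len(nrow(links))) {
    i <- links$i[k]; j <- links$j[k]
    col <- if (links$class[k] == "inter") INTER_COLOR
           else SEGMENT_COLORS[st$segment_index[i]]
    r <- 228
    c1x <- cx + 0.25 * (px(r)[i] - cx); c1y <- cx + 0.25 * (py(r)[i] - cx)
    c2x <- cx + 0.25 * (px(r)[j] - cx); c2y <- cx + 0.25 * (py(r)[j] - cx)
    out <- c(out, sprintf(
      "<path class=\"chord\" d=\"M %.1f %.1f C %.1f %.1f %.1f %.1f %.1f %.1f\" fill=\"none\" stroke=\"%s\" stroke-width=\"1.2\" opacity=\"0.75\"/>",
      px(r)[i], py(r)[i], c1x, c1y, c2x, c2y, px(r)[j], py(r)[j], col))
  }
  out <- c(out, "</svg>")
  writeLines(out, path)
  invisible(path)
}

#' Render the upper-triangular score-matrix figure
#'
#' Pairs are drawn as points colored by score rank: ranks 1-100 dark red,
#' 101-500 orange, 501-2500 yellow; lower-ranked pairs are not drawn. Only
#' the upper triangle is shown, with segment boundaries marked.
#'
#' @param st A `score_table`.
#' @param path Output path.
#' @param format `"svg"` (default), `"png"` or `"pdf"`.
#' @return `path`, invisibly.
#' @export
render_matrix <- function(st, path, format = c("svg", "png", "pdf")) {
  format <- match.arg(format)
  ranked <- rank_pairs(st)
  bands <- list(list(lo = 1L, hi = 100L, col = "#8b0000"),
                list(lo = 101L, hi = 500L, col = "#ffa500"),
                list(lo = 501L, hi = 2500L, col = "#ffd700"))
  sel <- ranked[ranked$rank <= 2500L, , drop = FALSE]
  sel$col <- bands[[1L]]$col
  sel$col[sel$rank > 100L] <- bands[[2L]]$col
  sel$col[sel$rank > 500L] <- bands[[3L]]$col
  L <- st$L
  if (format != "svg") {
    if (format == "png") grDevices::png(path, 800, 800)
    else grDevices::pdf(path, 8, 8)
    on.exit(grDevices::dev.off())
    graphics::plot(NA, xlim = c(1, L), ylim = c(L, 1), asp = 1,
                   xlab = "position j", ylab = "position i",
                   main = st$method)
    graphics::points(sel$j, sel$i, pch = 15, cex = 0.5, col = sel$col)
    graphics::abline(v = st$segments$end + 0.5, h = st$segments$end + 0.5,
                     col = "grey40", lty = 2)
    return(invisible(path))
  }
  size <- 640
  margin <- 40
  sc <- (size - 2 * margin) / L
  xy <- function(p) margin + (p - 0.5) * sc
  out <- svg_header(size)
  for (b in st$segments$end[-nrow(st$segments)]) {
    out <- c(out, sprintf(
      "<line class=\"boundary\" x1=\"%.1f\" y1=\"%.1f\" x2=\"%.1f\" y2=\"%.1f\" stroke=\"grey\" stroke-dasharray=\"4 3\"/>",
      xy(b + 0.5), margin, xy(b + 0.5), size - margin),
      sprintf(
      "<line class=\"boundary\" x1=\"%.1f\" y1=\"%.1f\" x2=\"%.1f\" y2=\"%.1f\" stroke=\"grey\" stroke-dasharray=\"4 3\"/>",
      margin, xy(b + 0.5), size - margin, xy(b + 0.5)))
  }
  if (nrow(sel)) {
    radius <- max(1, sc * 0.45)
    # draw yellow first so the top ranks stay visible
    sel <- sel[order(-sel$rank), , drop = FALSE]
    out <- c(out, sprintf(
      "<circle class=\"cell\" cx=\"%.1f\" cy=\"%.1f\" r=\"%.1f\" fill=\"%s\"/>",
      xy(sel$j), xy(sel$i), radius, sel$col))
  }
  out <- c(out, "</svg>")
  writeLines(out, path)
  invisible(path)
}
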