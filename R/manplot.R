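## Manhattan plots: cumulative genomic coordinates, optional -log10
## transform, alternating chromosome colours and suggestive lines.

#' Natural chromosome order
#'
#' Numeric identifiers ascending, then X, Y, MT, then anything else
#' lexically.
#'
#' @param chroms character vector of chromosome identifiers.
#' @return The identifiers in natural order.
#' @export
naturalChromOrder <- function(chroms) {
  chroms <- unique(chroms)
  num <- suppressWarnings(as.numeric(chroms))
  isNum <- !is.na(num)
  special <- c("X", "Y", "MT")
  sp <- toupper(chroms) %in% special & !isNum
  other <- !isNum & !sp
  c(chroms[isNum][order(num[isNum])],
    chroms[sp][order(match(toupper(chroms[sp]), special))],
    sort(chroms[other]))
}

#' Cumulative genomic coordinates for a Manhattan plot
#'
#' Arranges chromosomes sequentially along the x-axis: each chromosome's
#' span is the maximum bp observed on it, its offset is the sum of the
#' spans of all preceding chromosomes (chromosomes abut, no gap), and
#' every record is placed at x = offset + bp. Chromosome ticks sit at
#' offset + span / 2. The layout is a pure function of the records plus
#' the chromosome order; input row order never matters.
#'
#' @param table an [AssocTable-class].
#' @param chromOrder optional explicit chromosome order; every record's
#'   chromosome must appear in it. Default is [naturalChromOrder()].
#' @param nColors number of alternating colours; each chromosome gets
#'   colour index `(rank - 1) %% nColors` (0-based).
#' @return A [ManhattanLayout-class].
#' @export
cumulativeCoordinates <- function(table, chromOrder = NULL, nColors = 2) {
  stopifnot(is(table, "AssocTable"))
  r <- table@records
  if (!nrow(r)) stop("association table is empty", call. = FALSE)
  if (is.null(chromOrder)) {
    chromOrder <- naturalChromOrder(r$chrom)
  } else {
    missing <- setdiff(unique(r$chrom), chromOrder)
    if (length(missing))
      stop("records on chromosome(s) not in chromOrder: ",
           paste(missing, collapse = ", "), call. = FALSE)
    chromOrder <- chromOrder[chromOrder %in% r$chrom]
  }
  span <- vapply(chromOrder, function(ch) max(r$bp[r$chrom == ch]),
                 numeric(1))
  offset <- cumsum(c(0, span[-length(span)]))
  ci <- data.frame(chrom = chromOrder, offset = offset, span = span,
                   tick = offset + span / 2, stringsAsFactors = FALSE)
  rank <- match(r$chrom, chromOrder)
  pts <- data.frame(chrom = r$chrom, bp = r$bp,
                    x = offset[rank] + r$bp, y = r$value,
                    colorIndex = (rank - 1) %% nColors,
                    stringsAsFactors = FALSE)
  pts <- pts[order(rank, pts$bp), ]
  rownames(pts) <- rownames(ci) <- NULL
  new("ManhattanLayout", points = pts, chromInfo = ci)
}

#' Transform association statistics to -log10 scale
#'
#' With `logp = TRUE`, p-values in (0, 1] become -log10(p); otherwise
#' values pass through unchanged. Values are never transformed silently:
#' generic statistics (Fst, nucleotide diversity, ...) are plotted as
#' given.
#'
#' @param table an [AssocTable-class].
#' @param logp apply the -log10 transform.
#' @return An [AssocTable-class] on the plotted scale.
#' @export
transformValues <- function(table, logp = FALSE) {
  stopifnot(is(table, "AssocTable"))
  if (!logp) return(table)
  r <- table@records
  bad <- which(r$value <= 0 | r$value > 1)
  if (length(bad))
    stop(sprintf(
      "-log10 transform needs p-values in (0, 1]; value %.4g at row %d",
      r$value[bad[1]], bad[1]), call. = FALSE)
  r$value <- -log10(r$value)
  new("AssocTable", records = r)
}

#' Render a Manhattan plot
#'
#' Points at their cumulative coordinates with chromosome-alternating
#' colours cycling through `nColors` palette colours, chromosome name
#' ticks at the chromosome midpoints, and up to two horizontal suggestive
#' threshold lines interpreted on the plotted scale.
#'
#' @param layout a [ManhattanLayout-class] from
#'   [cumulativeCoordinates()].
#' @param path output figure path.
#' @param palette colormap for the alternating colours.
#' @param nColors number of alternating colours.
#' @param alpha point alpha blending in [0, 1].
#' @param pointSize point size.
#' @param sug1,sug2 optional suggestive threshold levels (plotted scale).
#' @param ylab y-axis label.
#' @param format,width,height,dpi,fontSize see [renderDensityHeatmap()].
#' @return Invisibly, a `gvFigure`; its `layout` records threshold lines,
#'   tick positions and the colour cycle.
#' @export
renderManhattan <- function(layout, path, palette = "viridis",
                            nColors = 2, alpha = 0.8, pointSize = 0.8,
                            sug1 = NULL, sug2 = NULL, ylab = "Statistic",
                            format = NULL, width = 10, height = 4,
                            dpi = 300, fontSize = 11) {
  stopifnot(is(layout, "ManhattanLayout"))
  if (length(alpha) != 1 || is.na(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]", call. = FALSE)
  fmt <- resolveFormat(path, format)
  pts <- layout@points
  ci <- layout@chromInfo
  rank <- match(pts$chrom, ci$chrom)
  pts$colorIndex <- (rank - 1) %% nColors
  cols <- gvPalette(palette, max(nColors + 1, 3))[seq_len(nColors)]
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = x, y = y,
                                         colour = factor(colorIndex))) +
    ggplot2::geom_point(alpha = alpha, size = pointSize) +
    ggplot2::scale_colour_manual(values = cols, guide = "none") +
    ggplot2::scale_x_continuous(breaks = ci$tick, labels = ci$chrom,
                                expand = c(0.01, 0)) +
    ggplot2::labs(x = "Chromosome", y = ylab) +
    .gvTheme(fontSize)
  thresholds <- c(sug1 = if (is.null(sug1)) NA else sug1,
                  sug2 = if (is.null(sug2)) NA else sug2)
  thresholds <- thresholds[!is.na(thresholds)]
  if (length(thresholds))
    p <- p + ggplot2::geom_hline(yintercept = unname(thresholds),
                                 colour = c("red", "blue")[
                                   seq_along(thresholds)],
                                 linetype = "dashed")
  .gvWriteFigure(p, path, fmt, width, height, dpi)
  out <- list(
    nPoints = nrow(pts), ticks = ci$tick, tickLabels = ci$chrom,
    colorCycle = unname(pts$colorIndex[!duplicated(pts$chrom)]),
    nColors = nColors, colors = cols, alpha = alpha,
    thresholds = thresholds, format = fmt)
  invisible(.gvFigure(path, p, out))
}
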