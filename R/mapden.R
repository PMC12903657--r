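#' SNP density in fixed-size bins
#'
#' Divides every indexed chromosome into non-overlapping, fixed-size bins
#' and counts the markers falling in each. Genomic extent always comes
#' from the genome index: a chromosome with no markers still contributes
#' `ceiling(length / binSize)` zero bins, and the last bin is short when
#' the bin size does not divide the chromosome length.
#'
#' A marker at 1-based position p lands in bin `floor((p - 1) / binSize)`
#' (0-based), i.e. bin b spans `[b * binSize + 1, min((b + 1) * binSize,
#' length)]`; a marker exactly at `k * binSize` belongs to the earlier
#' bin.
#'
#' @param markers a [MarkerMap-class].
#' @param index a [GenomeIndex-class]; every marker's chromosome must be
#'   indexed and no marker may lie beyond its chromosome's length (either
#'   is an error — it signals an assembly/index mismatch).
#' @param binSize bin width in bp; default 1e6 (1 Mb).
#' @return A [BinDensity-class]; the total of all counts equals the
#'   number of input markers.
#' @examples
#' idx <- GenomeIndex(c("1", "2"), c(10, 12))
#' mm <- MarkerMap(c("1", "1"), c("rs1", "rs2"), c(0, 0), c(1, 10))
#' binCounts(computeBinCounts(mm, idx, binSize = 5))
#' @export
computeBinCounts <- function(markers, index, binSize = 1e6) {
  stopifnot(is(markers, "MarkerMap"), is(index, "GenomeIndex"))
  if (length(binSize) != 1 || is.na(binSize) || binSize < 1 ||
      binSize != round(binSize))
    stop("binSize must be a single integer >= 1", call. = FALSE)
  r <- markers@records
  lens <- chromLengths(index)
  unknown <- setdiff(unique(r$chrom), index@chrom)
  if (length(unknown))
    stop("markers on unindexed chromosome(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  mlen <- lens[r$chrom]
  bad <- which(r$bp > mlen)
  if (length(bad))
    stop(sprintf(
      "marker '%s' at bp %.0f lies beyond chromosome %s (length %.0f)",
      r$snp_id[bad[1]], r$bp[bad[1]], r$chrom[bad[1]], mlen[bad[1]]),
      call. = FALSE)
  counts <- lapply(seq_along(index@chrom), function(i) {
    nbin <- ceiling(index@length[i] / binSize)
    bp <- r$bp[r$chrom == index@chrom[i]]
    as.integer(tabulate(floor((bp - 1) / binSize) + 1, nbins = nbin))
  })
  new("BinDensity", chrom = index@chrom, length = index@length,
      binSize = as.numeric(binSize), counts = counts)
}

#' Render a SNP density heatmap
#'
#' One horizontal track per chromosome in genome-index order, drawn to
#' scale (track length proportional to chromosome length), with a shared
#' colour scale and colourbar for the per-bin marker counts.
#'
#' @param density a [BinDensity-class] from [computeBinCounts()].
#' @param path output figure path; format inferred from the extension
#'   (see [resolveFormat()]).
#' @param colormap colormap name for [gvPalette()].
#' @param format optional explicit output format.
#' @param width,height figure size in inches.
#' @param dpi raster resolution.
#' @param fontSize base font size in points.
#' @return Invisibly, a `gvFigure` with the written file and a `layout`
#'   list (`tracks` with per-chromosome drawn widths, `binSize`,
#'   `colormap`).
#' @export
renderDensityHeatmap <- function(density, path, colormap = "viridis",
                                 format = NULL, width = 8, height = 5,
                                 dpi = 300, fontSize = 11) {
  stopifnot(is(density, "BinDensity"))
  if (!length(density@chrom))
    stop("empty density: nothing to render", call. = FALSE)
  fmt <- resolveFormat(path, format)
  nChrom <- length(density@chrom)
  rects <- do.call(rbind, lapply(seq_len(nChrom), function(i) {
    cnt <- density@counts[[i]]
    b <- seq_along(cnt) - 1
    data.frame(chrom = density@chrom[i],
               xmin = b * density@binSize,
               xmax = pmin((b + 1) * density@binSize, density@length[i]),
               y = nChrom - i + 1, count = cnt,
               stringsAsFactors = FALSE)
  }))
  p <- ggplot2::ggplot(rects) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = xmin, xmax = xmax,
      ymin = y - 0.4, ymax = y + 0.4,
      fill = count)) +
    ggplot2::scale_fill_gradientn(colours = gvPalette(colormap),
                                  name = "SNPs / bin") +
    ggplot2::scale_y_continuous(breaks = rev(seq_len(nChrom)),
                                labels = density@chrom,
                                expand = c(0.01, 0.01)) +
    ggplot2::scale_x_continuous(labels = function(x) sprintf("%g", x / 1e6),
                                expand = c(0.005, 0)) +
    ggplot2::labs(x = "Position (Mb)", y = "Chromosome") +
    .gvTheme(fontSize)
  .gvWriteFigure(p, path, fmt, width, height, dpi)
  layout <- list(
    tracks = data.frame(chrom = density@chrom,
                        y = nChrom - seq_len(nChrom) + 1,
                        widthBp = density@length,
                        nBins = lengths(density@counts),
                        stringsAsFactors = FALSE),
    binSize = density@binSize, colormap = colormap, format = fmt)
  invisible(.gvFigure(path, p, layout))
}
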