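#' Average pairwise relationships between and within populations
#'
#' Collapses a sample-by-sample relationship matrix to a population-by-
#' population matrix of average pairwise relationships. Between two
#' populations, the mean of all cross pairs; within a population, the
#' mean over unordered distinct pairs, excluding the diagonal (self)
#' entries — diagonals encode the 1 + F inbreeding scale and would bias
#' group relatedness. A singleton population has no distinct pairs, so
#' its within value falls back to the sample's diagonal entry and a
#' warning is issued.
#'
#' @param matrix a [RelationshipMatrix-class] with population labels.
#' @return A [PopAverageMatrix-class]; population order follows first
#'   appearance in the sample labels. The result is invariant under
#'   sample permutation.
#' @examples
#' m <- diag(3); m[upper.tri(m)] <- m[lower.tri(m)] <- 0.2
#' rm <- RelationshipMatrix(m, c("a", "b", "c"), rep("P", 3))
#' as.matrix(populationAverage(rm))
#' @export
populationAverage <- function(matrix) {
  stopifnot(is(matrix, "RelationshipMatrix"))
  v <- matrix@values
  if (!nrow(v)) stop("empty relationship matrix", call. = FALSE)
  pops <- unique(matrix@popLabels)
  p <- length(pops)
  idx <- lapply(pops, function(g) which(matrix@popLabels == g))
  out <- base::matrix(NA_real_, p, p)
  for (i in seq_len(p)) {
    gi <- idx[[i]]
    for (j in seq_len(i)) {
      if (i == j) {
        if (length(gi) == 1) {
          out[i, i] <- v[gi, gi]
          warning(sprintf(
            "population '%s' has a single sample; within-population %s",
            pops[i], "average falls back to its diagonal entry"),
            call. = FALSE)
        } else {
          sub <- v[gi, gi, drop = FALSE]
          out[i, i] <- mean(sub[upper.tri(sub)])
        }
      } else {
        out[i, j] <- out[j, i] <- mean(v[gi, idx[[j]], drop = FALSE])
      }
    }
  }
  new("PopAverageMatrix", popIds = pops, values = out)
}

#' Render a relationship heatmap
#'
#' Heatmap of a sample-level [RelationshipMatrix-class] (samples ordered
#' so population blocks are contiguous: population label first-appearance
#' order, then input order) or of a population-level
#' [PopAverageMatrix-class]. The diagonal can be masked and cell values
#' annotated (2 decimal places).
#'
#' @param matrix a [RelationshipMatrix-class] or
#'   [PopAverageMatrix-class].
#' @param path output figure path.
#' @param showLabels show axis sample/population labels.
#' @param maskDiagonal blank the diagonal cells.
#' @param annotate write the relationship value inside each (unmasked)
#'   cell.
#' @param colormap colormap name (see [gvPalette()]).
#' @param axisFontSize axis tick label size in points.
#' @param format,width,height,dpi,fontSize see [renderDensityHeatmap()].
#' @return Invisibly, a `gvFigure`; its `layout` records cell order,
#'   masked cells and annotation entries.
#' @export
renderRelationshipHeatmap <- function(matrix, path, showLabels = TRUE,
                                      maskDiagonal = FALSE,
                                      annotate = FALSE,
                                      colormap = "viridis",
                                      axisFontSize = 8, format = NULL,
                                      width = 7, height = 6, dpi = 300,
                                      fontSize = 11) {
  fmt <- resolveFormat(path, format)
  if (is(matrix, "RelationshipMatrix")) {
    ord <- order(match(matrix@popLabels, unique(matrix@popLabels)))
    ids <- matrix@sampleIds[ord]
    v <- matrix@values[ord, ord, drop = FALSE]
  } else if (is(matrix, "PopAverageMatrix")) {
    ids <- matrix@popIds
    v <- matrix@values
  } else stop("matrix must be a RelationshipMatrix or PopAverageMatrix",
              call. = FALSE)
  n <- length(ids)
  cells <- expand.grid(row = seq_len(n), col = seq_len(n))
  cells$value <- v[cbind(cells$row, cells$col)]
  cells$masked <- maskDiagonal & cells$row == cells$col
  cells$value[cells$masked] <- NA_real_
  p <- ggplot2::ggplot(cells, ggplot2::aes(x = col, y = row,
                                           fill = value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradientn(colours = gvPalette(colormap),
                                  name = "Relationship",
                                  na.value = "grey92") +
    ggplot2::scale_x_continuous(
      breaks = if (showLabels) seq_len(n) else NULL,
      labels = if (showLabels) ids else NULL, expand = c(0, 0)) +
    ggplot2::scale_y_reverse(
      breaks = if (showLabels) seq_len(n) else NULL,
      labels = if (showLabels) ids else NULL, expand = c(0, 0)) +
    ggplot2::labs(x = NULL, y = NULL) +
    .gvTheme(fontSize) +
    ggplot2::theme(axis.text = ggplot2::element_text(size = axisFontSize),
                   axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
  annotations <- cells[!cells$masked, , drop = FALSE]
  if (annotate) {
    annotations$label <- sprintf("%.2f", annotations$value)
    p <- p + ggplot2::geom_text(data = annotations,
                                ggplot2::aes(label = label),
                                size = fontSize / 4)
  }
  .gvWriteFigure(p, path, fmt, width, height, dpi)
  layout <- list(
    ids = ids, n = n,
    maskedCells = cells[cells$masked, c("row", "col")],
    annotations = if (annotate)
      annotations[c("row", "col", "label")] else
      data.frame(row = integer(), col = integer(), label = character()),
    showLabels = showLabels, axisFontSize = axisFontSize,
    colormap = colormap, format = fmt)
  invisible(.gvFigure(path, p, layout))
}
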