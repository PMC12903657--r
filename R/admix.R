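#' Sort individuals for an admixture barplot
#'
#' Population groups keep their first-appearance order. Within each
#' group the dominant ancestry component — the component with the
#' largest within-group mean proportion (ties broken toward the lowest
#' component index) — is identified, and individuals are sorted ascending
#' by their proportion of that component (stable on ties, so fully tied
#' groups keep input order).
#'
#' @param table an [AncestryTable-class].
#' @return An [AdmixLayout-class].
#' @examples
#' at <- AncestryTable(rep("P", 4), c("a", "b", "c", "d"),
#'                     cbind(c(0.9, 0.2, 0.5, 0.7),
#'                           c(0.1, 0.8, 0.5, 0.3)))
#' individuals(sortIndividuals(at))
#' @export
sortIndividuals <- function(table) {
  stopifnot(is(table, "AncestryTable"))
  if (!length(table@individual))
    stop("ancestry table is empty", call. = FALSE)
  pops <- unique(table@population)
  ord <- integer(0)
  grp <- data.frame(population = pops, first = NA_integer_,
                    last = NA_integer_, dominant = NA_integer_,
                    stringsAsFactors = FALSE)
  for (g in seq_along(pops)) {
    idx <- which(table@population == pops[g])
    groupMean <- colMeans(table@proportions[idx, , drop = FALSE])
    dom <- which.max(groupMean)  # which.max takes the first on ties
    vals <- table@proportions[idx, dom]
    idx <- idx[order(vals, seq_along(vals))]  # explicit stable tie-break
    grp$first[g] <- length(ord) + 1L
    grp$last[g] <- length(ord) + length(idx)
    grp$dominant[g] <- as.integer(dom)
    ord <- c(ord, idx)
  }
  new("AdmixLayout", population = table@population[ord],
      individual = table@individual[ord],
      proportions = table@proportions[ord, , drop = FALSE],
      groups = grp)
}

#' Render an admixture stacked barplot
#'
#' One stacked bar per individual with K colour segments; bars are placed
#' in [sortIndividuals()] order, population names sit under their group
#' spans, and individual ID tick labels appear only when `showLabels`.
#'
#' @param layout an [AdmixLayout-class] (or an [AncestryTable-class],
#'   which is sorted first).
#' @param path output figure path.
#' @param showLabels show individual IDs as x tick labels.
#' @param palette colormap used to draw the K component colours.
#' @param format,width,height,dpi,fontSize see [renderDensityHeatmap()].
#' @return Invisibly, a `gvFigure`; its `layout` records segments, bar
#'   totals and group spans.
#' @export
renderAdmixBarplot <- function(layout, path, showLabels = FALSE,
                               palette = "viridis", format = NULL,
                               width = 10, height = 4, dpi = 300,
                               fontSize = 11) {
  if (is(layout, "AncestryTable")) layout <- sortIndividuals(layout)
  stopifnot(is(layout, "AdmixLayout"))
  fmt <- resolveFormat(path, format)
  k <- ncol(layout@proportions)
  n <- length(layout@individual)
  segs <- data.frame(
    x = rep(seq_len(n), k),
    individual = rep(layout@individual, k),
    component = factor(rep(seq_len(k), each = n)),
    prop = as.vector(layout@proportions))
  cols <- gvPalette(palette, k)
  g <- layout@groups
  g$mid <- (g$first + g$last) / 2
  p <- ggplot2::ggplot(segs, ggplot2::aes(x = x, y = prop,
                                          fill = component)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(values = cols, name = "Component",
                               labels = sprintf("K%d", seq_len(k))) +
    ggplot2::scale_x_continuous(
      breaks = if (showLabels) seq_len(n) else g$mid,
      labels = if (showLabels) layout@individual else g$population,
      expand = c(0.002, 0)) +
    ggplot2::scale_y_continuous(expand = c(0, 0)) +
    ggplot2::geom_vline(xintercept = g$first[-1] - 0.5,
                        colour = "white", linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "Ancestry proportion") +
    .gvTheme(fontSize) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(
      angle = if (showLabels) 90 else 0,
      vjust = 0.5, size = if (showLabels) fontSize * 0.5 else fontSize))
  .gvWriteFigure(p, path, fmt, width, height, dpi)
  barTotals <- rowSums(layout@proportions)
  out <- list(
    nSegments = nrow(segs), k = k, nBars = n,
    barTotals = barTotals,
    groupSpans = g[c("population", "first", "last", "mid")],
    tickLabels = if (showLabels) layout@individual else character(),
    palette = palette, colors = cols, format = fmt)
  invisible(.gvFigure(path, p, out))
}
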