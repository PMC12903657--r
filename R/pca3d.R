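#' Percentage of variance explained per principal component
#'
#' Standard definition: 100 * lambda_i / sum(lambda). Scale-invariant;
#' the result sums to 100 within 1e-9.
#'
#' @param eigenvalues non-negative eigenvalues with a positive sum.
#' @return Numeric vector of percentages.
#' @examples
#' varianceExplained(c(3, 1))
#' @export
varianceExplained <- function(eigenvalues) {
  if (!length(eigenvalues) || anyNA(eigenvalues) || any(eigenvalues < 0))
    stop("eigenvalues must be non-negative", call. = FALSE)
  s <- sum(eigenvalues)
  if (s <= 0)
    stop("all eigenvalues are zero; variance explained is undefined",
         call. = FALSE)
  100 * eigenvalues / s
}

## Orthographic azimuth/elevation camera (matplotlib-style semantics):
## azim rotates about the vertical axis, elev tilts the viewpoint above
## the xy plane; coordinates are normalised to [-1, 1] per axis first so
## angles act on shape, not scale.
.project3d <- function(xyz, elev = 30, azim = -60) {
  rng <- apply(xyz, 2, range)
  span <- rng[2, ] - rng[1, ]
  span[span == 0] <- 1
  u <- sweep(sweep(xyz, 2, colMeans(rng)), 2, span / 2, "/")
  a <- azim * pi / 180
  e <- elev * pi / 180
  px <- -sin(a) * u[, 1] + cos(a) * u[, 2]
  py <- -cos(a) * sin(e) * u[, 1] - sin(a) * sin(e) * u[, 2] +
    cos(e) * u[, 3]
  cbind(px = px, py = py)
}

#' Render a 2D or 3D PCA scatter plot
#'
#' Points are coloured by population label with a legend; axis labels
#' carry the PC index and its variance-explained percentage. In 3D the
#' view is a solid orthographic projection at the requested elevation and
#' azimuth; the `snapshot` argument renders several camera angles as
#' panels of one figure (the reproducible counterpart of interactively
#' rotating the cloud).
#'
#' @param data an [EigenData-class].
#' @param path output figure path.
#' @param dims 2 or 3.
#' @param pcX,pcY,pcZ 1-based PC indices (distinct, each <= available k);
#'   `pcZ` is ignored when `dims = 2`.
#' @param mode `"solid"` (deterministic, always available) or
#'   `"interactive"`; interactive rotation needs an interactive graphics
#'   session, so in non-interactive sessions it falls back to solid with
#'   a warning.
#' @param elev,azim camera angles in degrees (solid 3D mode).
#' @param snapshot optional list of `c(elev, azim)` pairs; each becomes a
#'   panel.
#' @param pointSize scatter point size.
#' @param format,width,height,dpi,fontSize see [renderDensityHeatmap()].
#' @return Invisibly, a `gvFigure`; its `layout` records axis labels,
#'   legend entries and the camera angles actually used.
#' @export
renderPca <- function(data, path, dims = 3, pcX = 1, pcY = 2, pcZ = 3,
                      mode = c("solid", "interactive"), elev = 30,
                      azim = -60, snapshot = NULL, pointSize = 2,
                      format = NULL, width = 7, height = 6, dpi = 300,
                      fontSize = 11) {
  stopifnot(is(data, "EigenData"))
  mode <- match.arg(mode)
  fmt <- resolveFormat(path, format)
  if (!dims %in% c(2, 3)) stop("dims must be 2 or 3", call. = FALSE)
  k <- ncol(data@components)
  want <- if (dims == 3) c(pcX, pcY, pcZ) else c(pcX, pcY)
  if (any(want > k) || any(want < 1))
    stop(sprintf("requested PC unavailable: have %d PCs, asked for %s",
                 k, paste(want, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(want))
    stop("requested PC indices must be distinct", call. = FALSE)
  if (mode == "interactive" && !interactive()) {
    warning("interactive mode needs an interactive session; ",
            "rendering solid instead", call. = FALSE)
    mode <- "solid"
  }
  ve <- varianceExplained(data@eigenvalues)
  axisLab <- function(i) sprintf("PC%d (%.1f%%)", i, ve[i])
  pops <- unique(data@popLabels)
  popCols <- stats::setNames(.gvGroupColors(length(pops)), pops)
  angles <- if (dims == 3) {
    if (is.null(snapshot)) list(c(elev, azim)) else snapshot
  } else list(NULL)
  pts <- do.call(rbind, lapply(seq_along(angles), function(ai) {
    if (dims == 3) {
      pr <- .project3d(data@components[, c(pcX, pcY, pcZ), drop = FALSE],
                       elev = angles[[ai]][1], azim = angles[[ai]][2])
      data.frame(px = pr[, "px"], py = pr[, "py"],
                 population = data@popLabels,
                 panel = sprintf("elev = %g, azim = %g",
                                 angles[[ai]][1], angles[[ai]][2]),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(px = data@components[, pcX],
                 py = data@components[, pcY],
                 population = data@popLabels, panel = "2d",
                 stringsAsFactors = FALSE)
    }
  }))
  p <- ggplot2::ggplot(pts, ggplot2::aes(px, py, colour = population)) +
    ggplot2::geom_point(size = pointSize) +
    ggplot2::scale_colour_manual(values = popCols, name = "Population") +
    .gvTheme(fontSize)
  if (dims == 3) {
    p <- p + ggplot2::labs(
      x = sprintf("view of %s / %s", axisLab(pcX), axisLab(pcY)),
      y = axisLab(pcZ)) +
      ggplot2::coord_equal()
    if (length(angles) > 1 || !is.null(snapshot))
      p <- p + ggplot2::facet_wrap(~panel)
    else
      p <- p + ggplot2::ggtitle(pts$panel[1])
  } else {
    p <- p + ggplot2::labs(x = axisLab(pcX), y = axisLab(pcY))
  }
  .gvWriteFigure(p, path, fmt, width, height, dpi)
  layout <- list(
    dims = dims, mode = mode,
    pcs = if (dims == 3) c(pcX, pcY, pcZ) else c(pcX, pcY),
    axisLabels = vapply(want, axisLab, character(1)),
    legendEntries = pops,
    camera = if (dims == 3) angles else NULL,
    pointSize = pointSize, format = fmt)
  invisible(.gvFigure(path, p, layout))
}
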