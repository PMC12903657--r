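## Shared figure plumbing: output-format resolution, graphics devices and
## colour palettes. Every render function returns (invisibly) a
## "gvFigure": the written file, the ggplot object, and a `layout` list
## describing what was drawn — lanes, tracks, annotations, camera angles
## — so figure structure can be inspected programmatically.

.gvFormats <- c("pdf", "svg", "svgz", "png", "tif", "tiff", "jpg", "jpeg",
                "eps", "ps")

#' Resolve the output format of a figure path
#'
#' The format is inferred from the file extension unless given
#' explicitly. Supported: pdf, svg, svgz, png, tif, tiff, jpg, jpeg, eps,
#' ps.
#'
#' @param path output path.
#' @param format optional explicit format overriding the extension.
#' @return The validated lower-case format string.
#' @export
resolveFormat <- function(path, format = NULL) {
  fmt <- tolower(if (is.null(format) || !nzchar(format))
    tools::file_ext(path) else format)
  if (!fmt %in% .gvFormats)
    stop(sprintf("unsupported output format '%s'; allowed formats: %s",
                 fmt, paste(.gvFormats, collapse = ", ")), call. = FALSE)
  fmt
}

## Open a device, print the plot, close, handling svgz via gzip copy.
.gvWriteFigure <- function(plot, path, format = NULL, width = 7,
                           height = 5, dpi = 300) {
  fmt <- resolveFormat(path, format)
  target <- path
  if (fmt == "svgz") target <- tempfile(fileext = ".svg")
  switch(fmt,
    pdf = grDevices::cairo_pdf(target, width = width, height = height),
    svg = , svgz = grDevices::svg(target, width = width, height = height),
    png = grDevices::png(target, width = width, height = height,
                         units = "in", res = dpi, type = "cairo"),
    tif = , tiff = grDevices::tiff(target, width = width, height = height,
                                   units = "in", res = dpi, type = "cairo"),
    jpg = , jpeg = grDevices::jpeg(target, width = width, height = height,
                                   units = "in", res = dpi, type = "cairo"),
    eps = , ps = grDevices::cairo_ps(target, width = width, height = height))
  ok <- FALSE
  tryCatch({ print(plot); ok <- TRUE }, finally = grDevices::dev.off())
  if (!ok) stop("rendering failed for ", path, call. = FALSE)
  if (fmt == "svgz") {
    con <- gzfile(path, "wb")
    writeLines(readLines(target, warn = FALSE), con)
    close(con)
    unlink(target)
  }
  if (!file.exists(path))
    stop("figure was not written: ", path, call. = FALSE)
  invisible(path)
}

.gvFigure <- function(file, plot, layout) {
  structure(list(file = file, plot = plot, layout = layout),
            class = "gvFigure")
}

#' @export
print.gvFigure <- function(x, ...) {
  cat(sprintf("popgenviz figure: %s\n", x$file))
  invisible(x)
}

## Colormap aliases: common matplotlib names mapped onto the closest
## grDevices::hcl.colors() palette.
.cmapAliases <- c(viridis = "Viridis", plasma = "Plasma",
                  inferno = "Inferno", magma = "Rocket", cividis = "Cividis",
                  coolwarm = "Blue-Red 2", rdbu = "Blue-Red",
                  ylorrd = "YlOrRd", ylgnbu = "YlGnBu", blues = "Blues",
                  reds = "Reds", greens = "Greens", spectral = "Spectral",
                  turbo = "Viridis", jet = "Viridis")

#' Sequential colour palette by name
#'
#' Resolves a colormap name (any `grDevices::hcl.colors()` palette, or a
#' common matplotlib alias such as "viridis") to n colours.
#'
#' @param name palette name, case-insensitive.
#' @param n number of colours.
#' @return Character vector of n colours.
#' @export
gvPalette <- function(name = "viridis", n = 64) {
  pals <- grDevices::hcl.pals()
  hit <- pals[match(tolower(name), tolower(pals))]
  if (is.na(hit)) hit <- unname(.cmapAliases[tolower(name)])
  if (is.na(hit) || is.null(hit))
    stop(sprintf("unknown colormap '%s'; use an hcl.colors palette name %s",
                 name, "(e.g. viridis, plasma, inferno, Blues, Spectral)"),
         call. = FALSE)
  grDevices::hcl.colors(n, hit)
}

## Qualitative colours for population groups.
.gvGroupColors <- function(n) {
  if (n <= 8) grDevices::hcl.colors(max(n, 3), "Dark 3")[seq_len(n)]
  else grDevices::hcl.colors(n, "Dynamic")
}

.gvTheme <- function(fontSize = 11) {
  ggplot2::theme_minimal(base_size = fontSize) +
    ggplot2::theme(panel.grid.minor = ggplot2::element_blank())
}
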