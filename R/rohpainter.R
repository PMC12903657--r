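## Runs-of-homozygosity (or CNV) visualization: per-individual interval
## merging, sweep-line detection of regions shared by at least a
## threshold fraction of individuals, and lane-per-individual track
## rendering.

#' Merge overlapping segments within each individual
#'
#' Per (individual, chromosome), overlapping or book-ended intervals
#' (gap of 0 bases, i.e. end + 1 == next start) are merged into maximal
#' disjoint intervals; a 1-base gap is preserved. Intervals are closed,
#' 1-based. Prevents one individual from being counted twice over the
#' same base by the shared-region caller.
#'
#' @param records an [IntervalTable-class].
#' @return An [IntervalTable-class] with disjoint per-individual
#'   segments; each individual's population label is preserved.
#' @export
mergeIndividualIntervals <- function(records) {
  stopifnot(is(records, "IntervalTable"))
  r <- records@records
  if (!nrow(r)) return(records)
  popOf <- r$population[!duplicated(r$individual)]
  names(popOf) <- r$individual[!duplicated(r$individual)]
  key <- paste(r$individual, r$chrom, sep = "\r")
  parts <- split(seq_len(nrow(r)), factor(key, levels = unique(key)))
  out <- lapply(parts, function(idx) {
    red <- IRanges::reduce(IRanges::IRanges(start = r$start[idx],
                                            end = r$end[idx]))
    data.frame(population = popOf[[r$individual[idx[1]]]],
               individual = r$individual[idx[1]],
               chrom = r$chrom[idx[1]],
               start = as.numeric(IRanges::start(red)),
               end = as.numeric(IRanges::end(red)),
               stringsAsFactors = FALSE)
  })
  merged <- do.call(rbind, out)
  rownames(merged) <- NULL
  new("IntervalTable", records = merged)
}

## Required coverage for a frequency threshold: integer arithmetic with a
## guard so exact fractions (0.6 * 5) never float-round up an individual.
.requiredCount <- function(threshold, n) {
  max(1L, as.integer(ceiling(threshold * n - 1e-9)))
}

#' Detect genomic intervals shared by many individuals
#'
#' After per-individual merging, a sweep line over +1 events at segment
#' starts and -1 events at end + 1 yields per-base coverage (number of
#' individuals whose merged segments span the base). Maximal runs with
#' coverage >= ceiling(threshold * N) are reported per chromosome, where
#' N is the number of distinct individuals in the whole table
#' (populations pooled). Ties exactly at the threshold are included.
#'
#' @param records an [IntervalTable-class].
#' @param threshold minimum frequency of individuals in (0, 1].
#' @return A [SharedIntervals-class]; each region's `count` is the
#'   minimum coverage across the region and `frequency = count / N`.
#'   Regions are sorted by (chromosome order of first appearance in the
#'   input, start).
#' @examples
#' it <- IntervalTable("P", "A", "1", 100, 200)
#' regions(computeSharedIntervals(it, 1.0))
#' @export
computeSharedIntervals <- function(records, threshold) {
  stopifnot(is(records, "IntervalTable"))
  if (length(threshold) != 1 || is.na(threshold) || threshold <= 0 ||
      threshold > 1)
    stop("threshold must lie in (0, 1]", call. = FALSE)
  r <- records@records
  if (!nrow(r)) stop("interval table is empty", call. = FALSE)
  n <- length(unique(r$individual))
  need <- .requiredCount(threshold, n)
  m <- mergeIndividualIntervals(records)@records
  chromOrder <- unique(r$chrom)
  out <- lapply(chromOrder, function(ch) {
    seg <- m[m$chrom == ch, ]
    ev <- rbind(data.frame(pos = seg$start, d = 1),
                data.frame(pos = seg$end + 1, d = -1))
    ev <- stats::aggregate(d ~ pos, data = ev, sum)
    ev <- ev[order(ev$pos), ]
    cov <- cumsum(ev$d)
    nSeg <- nrow(ev) - 1L
    if (nSeg < 1) return(NULL)
    hit <- which(cov[seq_len(nSeg)] >= need)
    if (!length(hit)) return(NULL)
    runStart <- hit[c(TRUE, diff(hit) > 1)]
    runEnd <- hit[c(diff(hit) > 1, TRUE)]
    data.frame(chrom = ch,
               start = ev$pos[runStart],
               end = ev$pos[runEnd + 1] - 1,
               count = vapply(seq_along(runStart), function(i)
                 min(cov[runStart[i]:runEnd[i]]), numeric(1)),
               stringsAsFactors = FALSE)
  })
  reg <- do.call(rbind, out)
  if (is.null(reg))
    reg <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), count = numeric(),
                      stringsAsFactors = FALSE)
  reg$frequency <- if (nrow(reg)) reg$count / n else numeric()
  rownames(reg) <- NULL
  new("SharedIntervals", regions = reg, nIndividuals = n,
      threshold = threshold)
}

#' Write / read the shared-intervals side file
#'
#' Tab-delimited with header `chrom start end count frequency`; the
#' conventional name is `shared_intervals.txt` next to the figure.
#' Reading the file back round-trips the region table.
#'
#' @param x a [SharedIntervals-class].
#' @param path output path.
#' @export
writeSharedIntervals <- function(x, path) {
  stopifnot(is(x, "SharedIntervals"))
  r <- x@regions
  writeLines(c("chrom\tstart\tend\tcount\tfrequency",
               sprintf("%s\t%.0f\t%.0f\t%.0f\t%.12g", r$chrom, r$start,
                       r$end, r$count, r$frequency)), path)
  invisible(path)
}

#' @rdname writeSharedIntervals
#' @export
readSharedIntervals <- function(path) {
  tl <- .dropHeader(.readTokenLines(path), numericCols = c(2L, 3L, 4L, 5L))
  if (!length(tl$tokens)) {
    reg <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), count = numeric(),
                      frequency = numeric(), stringsAsFactors = FALSE)
    return(new("SharedIntervals", regions = reg, nIndividuals = NA_real_,
               threshold = NA_real_))
  }
  .checkNCol(tl, 5L, "shared intervals file")
  reg <- data.frame(chrom = .col(tl, 1), start = .asNum(.col(tl, 2)),
                    end = .asNum(.col(tl, 3)), count = .asNum(.col(tl, 4)),
                    frequency = .asNum(.col(tl, 5)),
                    stringsAsFactors = FALSE)
  if (anyNA(reg$start) || anyNA(reg$end) || anyNA(reg$count) ||
      anyNA(reg$frequency))
    stop("shared intervals file: non-numeric fields", call. = FALSE)
  n <- if (nrow(reg)) round(reg$count[1] / reg$frequency[1]) else NA_real_
  new("SharedIntervals", regions = reg, nIndividuals = n,
      threshold = NA_real_)
}

#' Render per-individual ROH/CNV tracks for one chromosome
#'
#' One horizontal lane per individual, grouped and labelled by
#' population; the x-axis spans the full chromosome length from the
#' genome index. Shared regions, when given, are marked by vertical
#' boundary lines.
#'
#' @param records an [IntervalTable-class]; every chromosome must be in
#'   `index`.
#' @param index a [GenomeIndex-class].
#' @param path output figure path.
#' @param shared optional [SharedIntervals-class] whose regions on the
#'   rendered chromosome are marked.
#' @param chrom chromosome to render; required when the table spans more
#'   than one chromosome.
#' @param showLabels show individual IDs on the y axis.
#' @param thresholdLineWidth,thresholdLineColor style of the shared-region
#'   boundary lines.
#' @param format,width,height,dpi,fontSize see [renderDensityHeatmap()].
#' @return Invisibly, a `gvFigure`; its `layout` lists the lanes (one per
#'   individual), shared-region markers and label visibility.
#' @export
renderRohPlot <- function(records, index, path, shared = NULL,
                          chrom = NULL, showLabels = TRUE,
                          thresholdLineWidth = 0.5,
                          thresholdLineColor = "black", format = NULL,
                          width = 8, height = 6, dpi = 300, fontSize = 11) {
  stopifnot(is(records, "IntervalTable"), is(index, "GenomeIndex"))
  fmt <- resolveFormat(path, format)
  r <- records@records
  unknown <- setdiff(unique(r$chrom), index@chrom)
  if (length(unknown))
    stop("intervals on unindexed chromosome(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  present <- unique(r$chrom)
  if (is.null(chrom)) {
    if (length(present) > 1)
      stop(paste0("interval table spans ", length(present), " chromosomes;",
                  " render one at a time via the chrom argument"),
           call. = FALSE)
    chrom <- present
  }
  r <- r[r$chrom == chrom, , drop = FALSE]
  if (!nrow(r))
    stop("no intervals on chromosome ", chrom, call. = FALSE)
  chromLen <- unname(chromLengths(index)[chrom])
  ## lane order: populations by first appearance, individuals within
  indTab <- r[!duplicated(r$individual), c("individual", "population")]
  indTab <- indTab[order(match(indTab$population,
                               unique(indTab$population))), ]
  indTab$lane <- seq_len(nrow(indTab))
  r$lane <- indTab$lane[match(r$individual, indTab$individual)]
  sharedReg <- NULL
  if (!is.null(shared)) {
    stopifnot(is(shared, "SharedIntervals"))
    sharedReg <- shared@regions[shared@regions$chrom == chrom, ,
                                drop = FALSE]
  }
  pops <- unique(indTab$population)
  popCols <- stats::setNames(.gvGroupColors(length(pops)), pops)
  p <- ggplot2::ggplot(r) +
    ggplot2::geom_rect(ggplot2::aes(xmin = start, xmax = end,
                                    ymin = lane - 0.38, ymax = lane + 0.38,
                                    fill = population)) +
    ggplot2::scale_fill_manual(values = popCols, name = "Population") +
    ggplot2::scale_x_continuous(
      limits = c(1, chromLen),
      labels = function(x) sprintf("%g", x / 1e6),
      expand = c(0.005, 0)) +
    ggplot2::scale_y_continuous(
      breaks = if (showLabels) indTab$lane else NULL,
      labels = if (showLabels) indTab$individual else NULL,
      expand = c(0.01, 0.5)) +
    ggplot2::labs(x = sprintf("Chromosome %s position (Mb)", chrom),
                  y = NULL) +
    .gvTheme(fontSize)
  markers <- numeric()
  if (!is.null(sharedReg) && nrow(sharedReg)) {
    markers <- sort(unique(c(sharedReg$start, sharedReg$end)))
    p <- p + ggplot2::geom_vline(xintercept = markers,
                                 linewidth = thresholdLineWidth,
                                 colour = thresholdLineColor)
  }
  .gvWriteFigure(p, path, fmt, width, height, dpi)
  layout <- list(
    lanes = indTab[c("individual", "population", "lane")],
    chrom = chrom, xlim = c(1, chromLen),
    sharedMarkers = markers,
    nSharedRegions = if (is.null(sharedReg)) 0L else nrow(sharedReg),
    showLabels = showLabels,
    thresholdLine = list(width = thresholdLineWidth,
                         color = thresholdLineColor),
    format = fmt)
  invisible(.gvFigure(path, p, layout))
}
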