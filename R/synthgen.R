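## Seeded generators for every input dialect, with programmatic ground
## truth, so all modules are testable at arbitrary scale without real
## data. Ground truth is always returned in-memory, never re-parsed from
## the emitted files.

#' Configuration for the synthetic-data generators
#'
#' @param seed RNG seed; a fixed seed yields byte-identical output files.
#' @param nChroms number of chromosomes.
#' @param chromLengthRange inclusive range chromosome lengths are drawn
#'   from (bp).
#' @param nMarkers total number of markers (map generator).
#' @param nIndividuals number of individuals.
#' @param nPopulations number of populations.
#' @param K number of ancestry components.
#' @param nAssocRecords number of association records.
#' @param nSignal number of planted signal loci (association generator).
#' @return A validated `SynthConfig` list.
#' @export
synthConfig <- function(seed = 1, nChroms = 3,
                        chromLengthRange = c(10e6, 50e6), nMarkers = 1000,
                        nIndividuals = 20, nPopulations = 2, K = 3,
                        nAssocRecords = 1000, nSignal = 5) {
  cfg <- list(seed = seed, nChroms = nChroms,
              chromLengthRange = chromLengthRange, nMarkers = nMarkers,
              nIndividuals = nIndividuals, nPopulations = nPopulations,
              K = K, nAssocRecords = nAssocRecords, nSignal = nSignal)
  counts <- c(nChroms = nChroms, nMarkers = nMarkers,
              nIndividuals = nIndividuals, nPopulations = nPopulations,
              K = K, nAssocRecords = nAssocRecords)
  bad <- names(counts)[counts < 1 | counts != round(counts)]
  if (length(bad))
    stop("SynthConfig counts must be integers >= 1: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (K < 2) stop("K must be >= 2", call. = FALSE)
  if (nSignal < 0 || nSignal > nAssocRecords)
    stop("nSignal must lie in [0, nAssocRecords]", call. = FALSE)
  if (length(chromLengthRange) != 2 || chromLengthRange[1] < 1 ||
      diff(chromLengthRange) < 0)
    stop("chromLengthRange must be an increasing pair >= 1", call. = FALSE)
  structure(cfg, class = "SynthConfig")
}

.genChroms <- function(cfg) {
  GenomeIndex(as.character(seq_len(cfg$nChroms)),
              round(stats::runif(cfg$nChroms, cfg$chromLengthRange[1],
                                 cfg$chromLengthRange[2])))
}

.popAssignment <- function(cfg) {
  pops <- sprintf("POP%d", seq_len(cfg$nPopulations))
  ind <- sprintf("IND%03d", seq_len(cfg$nIndividuals))
  assignment <- pops[((seq_len(cfg$nIndividuals) - 1) %%
                        cfg$nPopulations) + 1]
  ord <- order(match(assignment, pops))
  list(pops = pops, individual = ind[ord], population = assignment[ord])
}

#' Generate a marker map with its genome index
#'
#' Chromosome lengths are uniform over `chromLengthRange`; markers are
#' allocated to chromosomes proportional to length (the per-chromosome
#' counts always sum to `nMarkers`) and placed uniformly on
#' `[1, length]`, sorted within chromosome.
#'
#' @param cfg a [synthConfig()].
#' @param dir output directory; created if missing.
#' @return List with `mapPath`, `indexPath`, the in-memory `markers` and
#'   `index`, and `perChromCounts` (ground truth).
#' @export
genMapAndIndex <- function(cfg, dir = tempfile("synth")) {
  stopifnot(inherits(cfg, "SynthConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  index <- .genChroms(cfg)
  counts <- as.vector(stats::rmultinom(1, cfg$nMarkers,
                                       index@length / sum(index@length)))
  rec <- do.call(rbind, lapply(seq_len(cfg$nChroms), function(i) {
    if (!counts[i]) return(NULL)
    data.frame(chrom = index@chrom[i],
               bp = sort(round(stats::runif(counts[i], 1,
                                            index@length[i]))),
               stringsAsFactors = FALSE)
  }))
  markers <- MarkerMap(rec$chrom, sprintf("rs%06d", seq_len(nrow(rec))),
                       rep(0, nrow(rec)), rec$bp)
  mapPath <- file.path(dir, "markers.map")
  indexPath <- file.path(dir, "genome.idx")
  writePlinkMap(markers, mapPath)
  writeGenomeIndex(index, indexPath)
  list(mapPath = mapPath, indexPath = indexPath, markers = markers,
       index = index, perChromCounts = stats::setNames(counts,
                                                       index@chrom))
}

#' Generate an ROH/CNV interval table with a planted shared region
#'
#' Each individual receives random background segments; additionally a
#' planted region on chromosome 1 is covered by exactly
#' `round(plantedFraction * nIndividuals)` individuals, and background
#' segments on chromosome 1 keep a >= 2 bp gap from it, so the planted
#' region's coverage is exactly its carrier count. Shared-region
#' recovery is therefore governed by the ceiling rule alone: the region
#' is called at threshold t iff
#' `round(f * N) >= ceiling(t * N)`.
#'
#' @param cfg a [synthConfig()].
#' @param dir output directory.
#' @param plantedFraction fraction f of individuals carrying the planted
#'   region (0 disables planting).
#' @param nSegmentsPerInd background segments per individual.
#' @return List with `path`, the in-memory `table` and `index`, and
#'   `planted` (chrom/start/end/carriers/fraction ground truth; NULL
#'   when f = 0).
#' @export
genIntervals <- function(cfg, dir = tempfile("synth"),
                         plantedFraction = 0.8, nSegmentsPerInd = 5) {
  stopifnot(inherits(cfg, "SynthConfig"))
  if (plantedFraction < 0 || plantedFraction > 1)
    stop("plantedFraction must lie in [0, 1]", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  index <- .genChroms(cfg)
  pa <- .popAssignment(cfg)
  n <- cfg$nIndividuals
  len1 <- index@length[1]
  pStart <- round(len1 * 0.45)
  pEnd <- round(len1 * 0.55)
  nCarriers <- round(plantedFraction * n)
  carriers <- if (nCarriers) pa$individual[seq_len(nCarriers)] else
    character()
  rec <- list()
  for (i in seq_len(n)) {
    for (s in seq_len(nSegmentsPerInd)) {
      ch <- sample(cfg$nChroms, 1)
      chLen <- index@length[ch]
      w <- round(stats::runif(1, chLen * 0.01, chLen * 0.08))
      if (ch == 1 && nCarriers > 0) {
        ## keep background clear of the planted region (2 bp guard so
        ## book-ended segments cannot merge into it)
        leftMax <- pStart - 2 - w
        rightMin <- pEnd + 2
        canLeft <- leftMax >= 1
        canRight <- rightMin + w <= chLen
        if (!canLeft && !canRight) next
        goLeft <- canLeft && (!canRight || stats::runif(1) < 0.5)
        st <- if (goLeft) round(stats::runif(1, 1, leftMax))
              else round(stats::runif(1, rightMin, chLen - w))
      } else {
        st <- round(stats::runif(1, 1, chLen - w))
      }
      rec[[length(rec) + 1]] <- data.frame(
        population = pa$population[i], individual = pa$individual[i],
        chrom = index@chrom[ch], start = st, end = st + w,
        stringsAsFactors = FALSE)
    }
  }
  for (id in carriers) {
    rec[[length(rec) + 1]] <- data.frame(
      population = pa$population[match(id, pa$individual)],
      individual = id, chrom = index@chrom[1], start = pStart,
      end = pEnd, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rec)
  table <- IntervalTable(tab$population, tab$individual, tab$chrom,
                         tab$start, tab$end)
  path <- file.path(dir, "intervals.txt")
  indexPath <- file.path(dir, "genome.idx")
  writeIntervalTable(table, path)
  writeGenomeIndex(index, indexPath)
  planted <- if (nCarriers) list(chrom = index@chrom[1], start = pStart,
                                 end = pEnd, carriers = carriers,
                                 fraction = plantedFraction) else NULL
  list(path = path, indexPath = indexPath, table = table, index = index,
       planted = planted)
}

#' Generate a block-structured relationship matrix
#'
#' Within-population cells take base value `within`, between-population
#' cells `between` (within > between), diagonals 1 + within, plus
#' independent symmetric Gaussian noise of sd `noiseSd` on the
#' off-diagonal cells. [populationAverage()] must recover `within` and
#' `between` up to the pair-count-scaled noise.
#'
#' @param cfg a [synthConfig()].
#' @param dir output directory.
#' @param within,between block base values.
#' @param noiseSd per-cell noise standard deviation (0 for exact
#'   recovery).
#' @param popSizes optional explicit population sizes overriding the
#'   near-even split of `nIndividuals`.
#' @return List with `matPath`, `idsPath`, the in-memory `matrix`, and
#'   ground truth `within`, `between`, `noiseSd`, `popSizes`.
#' @export
genRelationship <- function(cfg, dir = tempfile("synth"), within = 0.5,
                            between = 0.1, noiseSd = 0, popSizes = NULL) {
  stopifnot(inherits(cfg, "SynthConfig"))
  if (within <= between)
    stop("within must exceed between", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  if (is.null(popSizes)) {
    pa <- .popAssignment(cfg)
    popLabels <- pa$population
    ind <- pa$individual
  } else {
    popLabels <- rep(sprintf("POP%d", seq_along(popSizes)), popSizes)
    ind <- sprintf("IND%03d", seq_along(popLabels))
  }
  n <- length(ind)
  same <- outer(popLabels, popLabels, "==")
  m <- ifelse(same, within, between)
  diag(m) <- 1 + within
  if (noiseSd > 0) {
    e <- matrix(0, n, n)
    e[upper.tri(e)] <- stats::rnorm(n * (n - 1) / 2, 0, noiseSd)
    m <- m + e + t(e)
  }
  rel <- RelationshipMatrix(m, ind, popLabels)
  matPath <- file.path(dir, "grm.mat")
  idsPath <- file.path(dir, "grm.ids")
  writeRelationship(rel, matPath, "mat", idsPath)
  list(matPath = matPath, idsPath = idsPath, matrix = rel,
       within = within, between = between, noiseSd = noiseSd,
       popSizes = as.vector(table(factor(popLabels,
                                         levels = unique(popLabels)))))
}

#' Generate PCA eigenvector/eigenvalue files
#'
#' Gaussian population clusters in PC space: population g's mean on the
#' first two PCs is `separation` cluster-sds away from the others;
#' higher PCs are pure noise. Eigenvalues decrease geometrically.
#'
#' @param cfg a [synthConfig()].
#' @param dir output directory.
#' @param nPCs number of PC columns.
#' @param separation cluster-mean separation in units of the cluster sd.
#' @return List with `evecPath`, `evalPath`, the in-memory `eigen`, and
#'   ground-truth cluster `means`.
#' @export
genEigen <- function(cfg, dir = tempfile("synth"), nPCs = 10,
                     separation = 5) {
  stopifnot(inherits(cfg, "SynthConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  pa <- .popAssignment(cfg)
  n <- cfg$nIndividuals
  g <- match(pa$population, pa$pops)
  angles <- 2 * pi * (seq_len(cfg$nPopulations) - 1) / cfg$nPopulations
  means <- cbind(separation * cos(angles), separation * sin(angles))
  comp <- matrix(stats::rnorm(n * nPCs), n, nPCs)
  comp[, 1] <- comp[, 1] + means[g, 1]
  comp[, 2] <- comp[, 2] + means[g, 2]
  evals <- 10 * 0.7^(seq_len(nPCs) - 1)
  ed <- EigenData(comp, evals, pa$individual, pa$population)
  evecPath <- file.path(dir, "pca.evec")
  evalPath <- file.path(dir, "pca.eval")
  writeEigen(ed, evecPath, evalPath)
  list(evecPath = evecPath, evalPath = evalPath, eigen = ed,
       means = means)
}

#' Generate an admixture proportion table
#'
#' Per-population Dirichlet proportions with one dominant component
#' (component `((g - 1) %% K) + 1` for population g gets concentration
#' `domAlpha`, the rest `baseAlpha`), so rows sum to 1 by construction.
#'
#' @param cfg a [synthConfig()].
#' @param dir output directory.
#' @param domAlpha,baseAlpha Dirichlet concentrations of the dominant
#'   and background components.
#' @return List with `path`, the in-memory `table`, and ground-truth
#'   `dominantComponent` per population.
#' @export
genAncestry <- function(cfg, dir = tempfile("synth"), domAlpha = 8,
                        baseAlpha = 0.5) {
  stopifnot(inherits(cfg, "SynthConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  pa <- .popAssignment(cfg)
  k <- cfg$K
  g <- match(pa$population, pa$pops)
  dom <- ((seq_len(cfg$nPopulations) - 1) %% k) + 1
  props <- t(vapply(seq_len(cfg$nIndividuals), function(i) {
    a <- rep(baseAlpha, k)
    a[dom[g[i]]] <- domAlpha
    x <- stats::rgamma(k, a)
    x / sum(x)
  }, numeric(k)))
  at <- AncestryTable(pa$population, pa$individual, props)
  path <- file.path(dir, "ancestry.q")
  writeAncestry(at, path)
  list(path = path, table = at,
       dominantComponent = stats::setNames(dom, pa$pops))
}

#' Generate an association table with planted signals
#'
#' Uniform(0, 1) p-values over positions uniform on each chromosome,
#' with `nSignal` random records forced below 1e-7.
#'
#' @param cfg a [synthConfig()].
#' @param dir output directory.
#' @return List with `path`, the in-memory `table` and `index`, and
#'   ground-truth `signalRows` (row indices of planted signals).
#' @export
genAssoc <- function(cfg, dir = tempfile("synth")) {
  stopifnot(inherits(cfg, "SynthConfig"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  index <- .genChroms(cfg)
  nrec <- cfg$nAssocRecords
  share <- index@length / sum(index@length)
  counts <- as.vector(stats::rmultinom(1, nrec, share))
  rec <- do.call(rbind, lapply(seq_len(cfg$nChroms), function(i) {
    if (!counts[i]) return(NULL)
    data.frame(chrom = index@chrom[i],
               bp = sort(round(stats::runif(counts[i], 1,
                                            index@length[i]))),
               stringsAsFactors = FALSE)
  }))
  rec$value <- stats::runif(nrow(rec))
  signalRows <- if (cfg$nSignal) sort(sample(nrow(rec), cfg$nSignal)) else
    integer()
  rec$value[signalRows] <- stats::runif(length(signalRows), 1e-12, 1e-7)
  at <- AssocTable(rec$chrom, rec$bp, rec$value)
  path <- file.path(dir, "assoc.txt")
  writeAssocTable(at, path)
  list(path = path, table = at, index = index, signalRows = signalRows)
}
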