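---
title: "popgenviz: methods, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{popgenviz: methods, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgenviz)
```

popgenviz turns the plain-text outputs of standard population-genomics
pipelines (PLINK and compatible tools) into six figure families. This
vignette documents the procedures behind each figure, the parameters
that matter, the numerical conventions, and the choices made where more
than one defensible design existed. Nothing here states an empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## Coordinate conventions

All genomic positions are 1-based; intervals are inclusive on both
ends, following the PLINK `.hom` convention that the input dialects
mirror. Positions are stored as doubles, so cumulative coordinates
beyond 2^31 are representable; interval *merging* routes through
IRanges and therefore requires individual segment coordinates below
2^31, which holds for every published genome assembly.

## SNP density (mapden)

Each chromosome of length L is divided into `ceiling(L / binSize)`
non-overlapping bins; a marker at 1-based position p lands in bin
`floor((p − 1) / binSize)`. Two consequences worth stating explicitly:

* a marker exactly at `k * binSize` belongs to the *earlier* bin;
* genomic extent comes from the genome index, never from the last SNP —
  chromosomes without markers still contribute all-zero bins, and the
  final bin is short when binSize does not divide L. Plotting tools that
  infer extent from the last observed SNP under-draw chromosome ends;
  using the index avoids that.

A marker beyond its chromosome's indexed length is an error, not
clamped: it signals a genome-assembly/index mismatch that the
validation layer exists to catch. The default bin size is 1 Mb, the
conventional resolution for array-scale SNP density. Total bin counts
always equal the number of input markers; the test suite checks this
conservation plus equality with a per-marker linear-scan oracle on
random instances, and a refinement property (halving the bin size
splits each bin's count exactly).

## Shared ROH regions (rohpainter)

Let N be the number of distinct individuals in the input table,
populations pooled. The caller proceeds in two stages:

1. **Per-individual merging.** Overlapping or book-ended segments
   (end + 1 == next start, i.e. a gap of zero bases) merge into maximal
   disjoint intervals; a 1-base gap is preserved. This prevents an
   individual with fragmented calls from being counted twice on a base.
2. **Sweep line.** +1 events at merged-segment starts and −1 events at
   end + 1 give base-level coverage; maximal runs with coverage
   ≥ ⌈tN⌉ are emitted, each carrying its minimum coverage as `count`
   and `count / N` as `frequency`.

The threshold comparison uses integer arithmetic with a guard,
`ceiling(t * N − 1e-9)`, so that exact fractions such as t = 0.6 with
N = 5 require 3 individuals, not 4 via floating-point round-up. Ties
exactly at the threshold are *included* (a region in exactly 70% of
individuals passes t = 0.7).

Two semantics were genuinely open:

* **Denominator.** Frequency is computed against all individuals in the
  table, populations pooled — the same semantics as the `threshold`
  argument of detectRUNS' `tableRuns`. Per-population calling can be
  had by subsetting the table first.
* **Region count.** A region of varying coverage reports its *minimum*
  coverage, the most conservative single number for the whole interval.

Correctness is checked against an independent per-base coverage-array
oracle (boolean membership per individual, integer sums, run-length
extraction) on hundreds of random instances, along with monotonicity in
t (raising t never enlarges the emitted union) and the t = 1/N identity
(the merged union of all individuals).

## Population-average relationships (relmap)

Within-population averages use unordered distinct pairs and exclude the
diagonal. The diagonal of a genomic relationship matrix estimates
1 + F (self-relationship plus inbreeding) and sits on a different scale
from pairwise relatedness; including it would inflate within-population
averages, most strongly for small groups. Since upstream tools differ
and the convention is rarely stated, this is documented behaviour
rather than an attempt to replicate any one tool. A singleton
population has no distinct pairs; its within value falls back to the
sample's diagonal entry, with a warning, rather than NA — a visible
value with a caveat beats a hole in the heatmap. The averaging is
invariant under sample permutation (tested), and heatmap ordering makes
population blocks contiguous (population first-appearance order, input
order within).

## PCA scatter (pca3d)

Variance explained is the standard `100 * lambda_i / sum(lambda)`,
scale-invariant and summing to 100; it feeds the axis labels
("PC1 (45.2%)"). The 3D view is an orthographic projection with
matplotlib-style camera semantics — azimuth rotates about the vertical
axis, elevation tilts above the plane; defaults (30, −60) match that
convention — applied after per-axis normalisation so angles act on
shape, not scale. Solid mode is a pure function of its inputs: repeated
renders of the same data to SVG are byte-identical (tested). True
interactive rotation requires an interactive graphics session; in
non-interactive use the function warns and renders solid, and the
`snapshot` argument (a list of elev/azim pairs rendered as panels) is
the reproducible way to show several viewing angles of one cloud.

## Ancestry barplots (admix)

Population groups keep their input order. Within a group, individuals
sort *ascending* by the group's **dominant component** — the component
with the largest within-group mean proportion, ties broken toward the
lowest component index. The alternative reading (per-individual argmax)
would interleave individuals dominated by different components and
destroy the monotone colour wedge that makes grouped admixture plots
readable; ordering the whole group by a single component is the only
reading that produces it. The sort is stable, so fully tied groups
(e.g. uniform 1/K rows) keep input order, and sorting is idempotent.
Bar totals are conserved at 1 within the 0.01 simplex tolerance
enforced at parse time.

## Manhattan plots (manplot)

Chromosome span is the maximum observed bp on that chromosome (the
association-table interface carries no genome index), offsets are
cumulative sums of preceding spans with chromosomes abutting (zero
gap), and x = offset + bp. Chromosome order defaults to natural sort —
numeric identifiers ascending, then X, Y, MT, then anything else
lexically — and can be overridden. The −log10 transform is strictly
opt-in: the input column is a generic statistic (p-values, Fst,
nucleotide diversity, ...) and silent transformation would corrupt
non-p-value inputs. Suggestive lines are always interpreted on the
plotted scale. Layout properties under test: chromosome x-ranges are
disjoint, x is monotone in bp within a chromosome, ticks sit at
offset + span/2, appending a new last chromosome never moves earlier
points, and colour indices cycle `(rank − 1) %% nColors`.

## Validation and file dialects

Readers throw on malformed files with the original file's row number
(comment and blank lines are skipped but counted); `validateInput()`
instead *reports* every violation of loaded objects — unknown
chromosomes, out-of-range positions, asymmetry beyond 1e-9, missing
cells, dimensional mismatches — so pipelines can surface all problems
at once. Header lines are auto-detected: a first line whose
numeric-expected columns fail numeric parsing is treated as a header,
with two deliberate refinements: missing-value literals ("NA", "NaN",
"Inf") count as numeric (they must surface as missing-value errors,
not vanish as a header), and a first line with too few columns is
malformed data, not a header. In the columnar relationship dialect,
pairs given in one orientation are mirrored; pairs given twice must
agree within 1e-9; the diagonal is mandatory. Population labels come
from the ids file's first column, overridable by a two-column
(individual, population) file.

Figures export to pdf, svg, svgz, png, tif, tiff, jpg, jpeg, eps and
ps — the formats the available graphics devices render. Requests for
anything else fail with the allowed list.

## Synthetic data: what it emulates, what it does not

The seeded generators produce every input dialect with programmatic
ground truth (returned in memory, never re-parsed from the files, so
tests are not circular): length-proportional marker placement; per-
individual background ROH segments plus a region planted in an exact
fraction f of individuals, kept ≥ 2 bp clear of background on its
chromosome so its coverage equals its carrier count and recovery is
governed by the ceiling rule alone; block-structured relationship
matrices (within 0.5, between 0.1 by default, symmetric Gaussian noise
on the off-diagonal); Gaussian PC clusters; per-population Dirichlet
ancestry with one dominant component; uniform p-values with planted
signals below 1e-7. Defaults (3 chromosomes of 10–50 Mb, 20
individuals in 2 populations, K = 3, 1000 markers/records) are sized
like a small livestock SNP-array cohort.

What passing tests therefore show: the layout arithmetic, interval
algebra, averaging and sorting are correct on inputs whose truth is
known exactly. What they do not show: behaviour on real LD structure,
coalescent noise, assembly quirks or array ascertainment — the
generators make no attempt at those, and no claim about real-data
statistical performance follows from these tests.

## Problem sizes and runtime choices

The shipped suite exercises: 200 random binning instances (up to 10^4
markers, 5 chromosomes) against the linear-scan oracle; 200 random
interval instances (genomes up to 10 kb, up to 10 individuals, four
thresholds) against the per-base oracle; 50-seed planted-region
recovery (f = 0.8 found at t = 0.7, rejected at t = 0.9); 50-seed
block-matrix recovery at noise sd 0.01, asserted within 3 standard
errors of the pair mean with the 99.9% binomial allowance for
three-sigma exceedances (at 150 checks, demanding zero exceedances
would be statistically unsound); 100-instance layout-property batches;
and full end-to-end runs of all six subcommands in png, pdf and svg
with magic-byte checks. `scripts/acceptance.R` recomputes the same
quantities from scratch at a caller-supplied seed.

## Known limitations

* Interval merging requires segment coordinates < 2^31 (IRanges).
* No binary PLINK (.bed/.grm.bin), VCF or gzip ingestion.
* No dendrogram/clustering reorder of relationship heatmaps.
* Interactive 3D rotation needs an interactive session; headless use
  gets solid renders and snapshots.
* One figure per ROH plot chromosome: multi-chromosome tables must be
  rendered per chromosome (the error message says so).
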