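#' Build a binned genome model
#'
#' Lays a fixed-width bin grid over a set of chromosomes and attaches the
#' per-bin GC fraction and mappability flags that the rest of the pipeline
#' needs. Counting, normalization and segmentation all operate on the
#' mappable bins of this grid; a trailing partial bin (when a chromosome
#' length is not a multiple of `bin_size`) is always marked unmappable so
#' that every analysed bin has the full width.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths in base
#'   pairs. Names are the chromosome labels (e.g. `"chr1"`, `"chrX"`); the
#'   order given is the genome order used everywhere downstream.
#' @param bin_size Bin width in base pairs (default 20,000).
#' @param gc_profile Either a numeric vector with one GC fraction in
#'   \[0, 1\] per bin (in grid order), or a function
#'   `f(chrom, midpoint_bp)` returning the GC fraction at a bin midpoint,
#'   or `NULL` for a smooth default profile peaking near GC 0.42.
#' @param unmappable_intervals Optional `data.frame` with columns `chrom`,
#'   `start`, `end` (0-based half-open, base pairs). Any bin overlapping
#'   one of these intervals is flagged unmappable (think centromeres,
#'   repetitive regions).
#'
#' @return An object of class `GenomeModel`: a list with
#'   \describe{
#'     \item{bins}{`data.frame` with `chrom`, `start`, `end` (0-based
#'       half-open), `gc`, `mappable` for every bin of the grid.}
#'     \item{bin_size}{the bin width.}
#'     \item{chrom_lengths}{the input lengths.}
#'     \item{effective_length}{named vector, mappable bins × bin size per
#'       chromosome — the denominator of the variants-per-megabase
#'       statistic.}
#'   }
#' @export
#' @examples
#' gm <- build_genome_model(c(chrA = 1e6), bin_size = 20000)
#' sum(gm$bins$mappable)          # 50 bins
#' gm$effective_length            # 1,000,000
build_genome_model <- function(chrom_lengths, bin_size = 20000,
                               gc_profile = NULL,
                               unmappable_intervals = NULL) {
  if (is.null(names(chrom_lengths)) || any(!nzchar(names(chrom_lengths))))
    stop("chrom_lengths must be a named vector")
  if (any(chrom_lengths <= 0))
    stop("zero-length chromosome: ",
         paste(names(chrom_lengths)[chrom_lengths <= 0], collapse = ", "))
  if (bin_size <= 0) stop("bin_size must be positive")

  bins <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    n_full <- len %/% bin_size
    starts <- seq.int(0L, by = bin_size, length.out = n_full + (len %% bin_size > 0))
    ends <- pmin(starts + bin_size, len)
    data.frame(chrom = ch, start = starts, end = ends,
               mappable = (ends - starts) == bin_size,
               stringsAsFactors = FALSE)
  }))
  rownames(bins) <- NULL

  mid <- (bins$start + bins$end) / 2
  gc <- if (is.null(gc_profile)) {
    default_gc_profile(bins$chrom, mid)
  } else if (is.function(gc_profile)) {
    gc_profile(bins$chrom, mid)
  } else {
    if (length(gc_profile) != nrow(bins))
      stop("gc_profile vector must have one value per bin (", nrow(bins), ")")
    as.numeric(gc_profile)
  }
  if (any(!is.finite(gc)) || any(gc < 0 | gc > 1))
    stop("gc values must lie in [0, 1]")
  bins$gc <- gc

  if (!is.null(unmappable_intervals) && nrow(unmappable_intervals) > 0) {
    ui <- unmappable_intervals
    if (!all(c("chrom", "start", "end") %in% names(ui)))
      stop("unmappable_intervals needs columns chrom, start, end")
    if (any(ui$end <= ui$start)) stop("unmappable interval with end <= start")
    for (r in seq_len(nrow(ui))) {
      hit <- bins$chrom == ui$chrom[r] &
        bins$start < ui$end[r] & bins$end > ui$start[r]
      bins$mappable[hit] <- FALSE
    }
  }

  eff <- vapply(names(chrom_lengths), function(ch) {
    sum(bins$mappable[bins$chrom == ch]) * bin_size
  }, numeric(1))

  structure(list(bins = bins, bin_size = bin_size,
                 chrom_lengths = chrom_lengths,
                 effective_length = eff),
            class = "GenomeModel")
}

#' Default smooth GC profile
#'
#' Deterministic, smoothly varying GC fraction along each chromosome:
#' a baseline of 0.42 modulated by two sine waves (a slow isochore-like
#' component and a faster local one, phase-shifted per chromosome),
#' clipped to \[0.30, 0.60\]. Purely synthetic, but it gives the LOESS
#' stage a realistic GC range to invert.
#'
#' @param chrom Character vector of chromosome labels, one per bin.
#' @param midpoint_bp Numeric vector of bin midpoints in base pairs.
#' @return Numeric vector of GC fractions.
#' @export
default_gc_profile <- function(chrom, midpoint_bp) {
  offset <- (as.integer(factor(chrom, levels = unique(chrom))) - 1) * 0.9
  gc <- 0.42 +
    0.06 * sin(2 * pi * midpoint_bp / 13e6 + offset) +
    0.05 * sin(2 * pi * midpoint_bp / 1.7e6 + 2.1 * offset)
  pmin(pmax(gc, 0.30), 0.60)
}

#' Desk-scale toy genome
#'
#' A small five-chromosome genome (four autosomes plus X, 30-48 Mb each,
#' ~196 Mb total) with a 2 Mb centromere-like unmappable band in the
#' middle of every chromosome. Full pipeline runs on it take seconds
#' rather than hours; real hg19-scale lengths can be passed to
#' [build_genome_model()] instead when needed.
#'
#' @param bin_size Bin width in base pairs (default 20,000).
#' @return A `GenomeModel`.
#' @export
toy_genome <- function(bin_size = 20000) {
  lens <- c(chr1 = 48e6, chr2 = 40e6, chr3 = 36e6, chr4 = 32e6, chrX = 40e6)
  cen <- do.call(rbind, lapply(names(lens), function(ch) {
    m <- lens[[ch]] / 2
    data.frame(chrom = ch, start = m - 1e6, end = m + 1e6)
  }))
  build_genome_model(lens, bin_size = bin_size, unmappable_intervals = cen)
}

#' @export
print.GenomeModel <- function(x, ...) {
  cat("GenomeModel:", length(x$chrom_lengths), "chromosomes,",
      nrow(x$bins), "bins of", x$bin_size, "bp (",
      sum(x$bins$mappable), "mappable )\n")
  invisible(x)
}

# Autosome indicator used throughout: anything not labelled X/Y.
is_autosome <- function(chrom) {
  !(chrom %in% c("chrX", "chrY", "X", "Y"))
}

# Indices (within the mappable-bin vector) of autosomal bins.
autosome_index <- function(model) {
  which(is_autosome(model$bins$chrom[model$bins$mappable]))
}

# The mappable-bin table (the coordinate frame of counts/ratio vectors).
mappable_bins <- function(model) {
  model$bins[model$bins$mappable, , drop = FALSE]
}
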