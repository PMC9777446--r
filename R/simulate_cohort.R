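#' Catalog of copy-number variants to inject
#'
#' Builds (and validates) a truth catalog for the simulator. Each row is a
#' variant locus with a maternal or fetal carrier mode and a population
#' frequency; carriers are drawn per sample by independent Bernoulli trials
#' at simulation time. One heterozygous event per carrier — in the
#' frequency regime of recurrent maternal CNVs (well under 2%),
#' Hardy-Weinberg homozygotes are vanishingly rare and are not modelled.
#'
#' @param chrom,start_bp,end_bp Locus coordinates (0-based half-open).
#' @param copy_state Integer copies carried over the interval: 1 = het
#'   loss, 3 = het gain (0 and 4 allowed for homozygous states).
#' @param carrier `"maternal"` or `"fetal"`. Maternal variants are carried
#'   by the mother (and, through inheritance, by the placenta, so the bin
#'   ratio is copies/2 regardless of fetal fraction); fetal variants sit
#'   only on the fetal fraction of the cfDNA.
#' @param frequency Population frequency in \[0, 1\].
#' @return A `data.frame` of class `variant_catalog`.
#' @export
variant_catalog <- function(chrom, start_bp, end_bp, copy_state,
                            carrier = "maternal", frequency) {
  cat_df <- data.frame(chrom = chrom, start_bp = start_bp, end_bp = end_bp,
                       copy_state = as.integer(copy_state),
                       carrier = carrier, frequency = frequency,
                       stringsAsFactors = FALSE)
  if (any(cat_df$end_bp <= cat_df$start_bp)) stop("variant with end <= start")
  if (!all(cat_df$copy_state %in% c(0L, 1L, 3L, 4L)))
    stop("copy_state must be one of 0, 1, 3, 4")
  if (!all(cat_df$carrier %in% c("maternal", "fetal")))
    stop("carrier must be 'maternal' or 'fetal'")
  if (any(cat_df$frequency < 0 | cat_df$frequency > 1))
    stop("frequency must lie in [0, 1]")
  class(cat_df) <- c("variant_catalog", "data.frame")
  cat_df
}

#' Cohort simulation settings
#'
#' Bundles every knob of the synthetic-cohort generator. Defaults emulate
#' the low-coverage NIPT regime: 0.12-0.5x coverage (at least 5 million
#' reads on a full human grid), a fetal-fraction background around 10%,
#' a smooth unimodal GC bias peaking near GC 0.42, rank-2 low-amplitude
#' batch artifacts, and mild negative-binomial overdispersion.
#'
#' @param n_samples Number of pregnancies to simulate.
#' @param reads_range Length-2 range of total reads per sample, or `NULL`
#'   to derive reads from `coverage_range`.
#' @param coverage_range Length-2 sequencing-depth range; used when
#'   `reads_range` is `NULL`. Reads = coverage × genome size /
#'   `read_length`. Default `c(0.12, 0.5)`.
#' @param read_length Nominal read length in bp used for the
#'   coverage-to-reads conversion (default 50).
#' @param fetal_fraction_mean,fetal_fraction_sd Normal parameters of the
#'   fetal fraction, truncated to \[0.01, 0.25\] (the screening-range
#'   regime; fetal-only signal then never approaches the maternal
#'   calling threshold).
#' @param gc_bias_strength Curvature of the log-quadratic GC bias
#'   `g(gc) = exp(-strength * (gc - peak)^2)`; 0 disables GC bias.
#' @param gc_bias_peak GC fraction at which the bias curve peaks.
#' @param batch_rank Number of low-rank batch-artifact components.
#' @param batch_scale Per-bin SD of the batch loadings (log scale).
#' @param dispersion Negative-binomial overdispersion phi
#'   (variance = mu + phi mu^2); 0 gives an exact multinomial partition
#'   of the total reads (Poisson-like noise).
#' @param variant_catalog A [variant_catalog()] or `NULL` for an
#'   all-diploid cohort.
#' @param seed Integer seed; the whole cohort is reproducible bit for bit.
#' @return A list of class `CohortSpec`.
#' @export
cohort_spec <- function(n_samples,
                        reads_range = NULL,
                        coverage_range = c(0.12, 0.5),
                        read_length = 50,
                        fetal_fraction_mean = 0.10,
                        fetal_fraction_sd = 0.04,
                        gc_bias_strength = 15,
                        gc_bias_peak = 0.42,
                        batch_rank = 2,
                        batch_scale = 0.08,
                        dispersion = 0.005,
                        variant_catalog = NULL,
                        seed = 1L) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (batch_rank < 0) stop("batch_rank must be >= 0")
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (fetal_fraction_mean < 0 || fetal_fraction_mean > 1)
    stop("fetal fraction mean outside [0, 1]")
  if (!is.null(reads_range) && length(reads_range) != 2)
    stop("reads_range must have length 2")
  structure(list(n_samples = as.integer(n_samples),
                 reads_range = reads_range,
                 coverage_range = coverage_range,
                 read_length = read_length,
                 fetal_fraction_mean = fetal_fraction_mean,
                 fetal_fraction_sd = fetal_fraction_sd,
                 gc_bias_strength = gc_bias_strength,
                 gc_bias_peak = gc_bias_peak,
                 batch_rank = as.integer(batch_rank),
                 batch_scale = batch_scale,
                 dispersion = dispersion,
                 variant_catalog = variant_catalog,
                 seed = as.integer(seed)),
            class = "CohortSpec")
}

# Human autosomal+X mappable size the 5M-read floor is anchored to.
.HUMAN_GENOME_BP <- 2.875e9
.MIN_READS_HUMAN <- 5e6

#' Simulate a binned cfDNA cohort
#'
#' Generates per-sample bin counts with a known truth set. For sample with
#' total reads R, the expected count of mappable bin b is
#' `mu_b = R * w_b / sum(w)` with
#' `w_b = g(GC_b) * exp(sum_k s_k L_kb) * c_b`:
#' `g` the GC bias curve, `L` low-rank batch loadings with per-sample
#' N(0,1) scores `s`, and `c_b` the copy ratio
#' `(1 - ff) * maternal/2 + ff * fetal/2`. Counts are drawn
#' negative-binomially with the spec's dispersion (multinomial partition
#' of R when dispersion = 0, so counts then sum exactly to R).
#'
#' The minimum-reads floor (5 million on a full human grid) is enforced
#' relative to genome size, so a desk-scale toy genome can be simulated at
#' the same 0.12-0.5x coverage.
#'
#' @param model A [build_genome_model()] result.
#' @param spec A [cohort_spec()].
#' @return A list of class `SimulatedCohort`:
#'   `samples` (list of `BinnedSample`: `sample_id`, `counts` over mappable
#'   bins, `total_reads`, `fetal_fraction`, `truth` rows carried),
#'   `truth` (long `data.frame` sample × variant), `batch_loadings`
#'   (rank × bins matrix actually used), `model`, `spec`.
#' @export
simulate_cohort <- function(model, spec) {
  stopifnot(inherits(model, "GenomeModel"), inherits(spec, "CohortSpec"))
  bins <- mappable_bins(model)
  n_bins <- nrow(bins)
  genome_bp <- sum(model$chrom_lengths)

  reads_range <- spec$reads_range
  if (is.null(reads_range))
    reads_range <- spec$coverage_range * genome_bp / spec$read_length
  min_reads <- .MIN_READS_HUMAN * genome_bp / .HUMAN_GENOME_BP
  if (reads_range[1] < min_reads)
    stop(sprintf(
      "reads_range[1] = %.3g below the minimum for this genome (%.3g reads, the 5M floor scaled to genome size)",
      reads_range[1], min_reads))

  set.seed(spec$seed)

  gc_w <- if (spec$gc_bias_strength > 0)
    exp(-spec$gc_bias_strength * (bins$gc - spec$gc_bias_peak)^2)
  else rep(1, n_bins)

  L <- if (spec$batch_rank > 0) {
    raw <- matrix(stats::rnorm(spec$batch_rank * n_bins), nrow = spec$batch_rank)
    # orthogonalize rows, then rescale to the requested per-bin amplitude
    q <- qr.Q(qr(t(raw)))[, seq_len(spec$batch_rank), drop = FALSE]
    t(q) * sqrt(n_bins) * spec$batch_scale
  } else matrix(numeric(0), nrow = 0, ncol = n_bins)

  catalog <- spec$variant_catalog
  # map each variant to the mappable bins whose midpoint it covers
  var_bins <- if (!is.null(catalog) && nrow(catalog) > 0) {
    mid <- (bins$start + bins$end) / 2
    lapply(seq_len(nrow(catalog)), function(v) {
      which(bins$chrom == catalog$chrom[v] &
              mid >= catalog$start_bp[v] & mid < catalog$end_bp[v])
    })
  } else list()

  samples <- vector("list", spec$n_samples)
  truth_rows <- list()
  for (s in seq_len(spec$n_samples)) {
    sid <- sprintf("S%04d", s)
    total_reads <- round(stats::runif(1, reads_range[1], reads_range[2]))
    ff <- stats::rnorm(1, spec$fetal_fraction_mean, spec$fetal_fraction_sd)
    ff <- min(max(ff, 0.01), 0.25)

    copy_ratio <- rep(1, n_bins)
    carried <- integer(0)
    if (length(var_bins)) {
      carrier_draw <- stats::runif(nrow(catalog)) < catalog$frequency
      carried <- which(carrier_draw)
      for (v in carried) {
        idx <- var_bins[[v]]
        if (!length(idx)) next
        cs <- catalog$copy_state[v]
        cr <- if (catalog$carrier[v] == "maternal") cs / 2
        else (1 - ff) + ff * cs / 2
        copy_ratio[idx] <- cr
      }
    }

    w <- gc_w * copy_ratio
    if (nrow(L) > 0) {
      scores <- stats::rnorm(nrow(L))
      w <- w * exp(colSums(L * scores))
    }
    mu <- total_reads * w / sum(w)
    counts <- if (spec$dispersion > 0)
      stats::rnbinom(n_bins, mu = mu, size = 1 / spec$dispersion)
    else as.integer(stats::rmultinom(1, total_reads, prob = w))

    truth_s <- if (length(carried))
      cbind(sample_id = sid,
            catalog[carried, , drop = FALSE],
            fetal_fraction = ff)
    else NULL
    if (!is.null(truth_s)) truth_rows[[length(truth_rows) + 1]] <- truth_s

    samples[[s]] <- structure(
      list(sample_id = sid, counts = as.numeric(counts),
           total_reads = total_reads, fetal_fraction = ff,
           truth = truth_s),
      class = "BinnedSample")
  }

  truth <- if (length(truth_rows)) {
    out <- do.call(rbind, truth_rows)
    rownames(out) <- NULL
    class(out) <- "data.frame"
    out
  } else data.frame(sample_id = character(0), chrom = character(0),
                    start_bp = numeric(0), end_bp = numeric(0),
                    copy_state = integer(0), carrier = character(0),
                    frequency = numeric(0), fetal_fraction = numeric(0))

  structure(list(samples = samples, truth = truth, batch_loadings = L,
                 model = model, spec = spec),
            class = "SimulatedCohort")
}

#' @export
print.SimulatedCohort <- function(x, ...) {
  cat("SimulatedCohort:", length(x$samples), "samples,",
      nrow(mappable_bins(x$model)), "mappable bins,",
      nrow(x$truth), "injected variant carriages\n")
  invisible(x)
}
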