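# Shared builders and independent oracles for the test suite.

# Single-autosome genome for fast unit tests (len bp, 20 kb bins).
mini_genome <- function(len = 6e6, bin_size = 20000, name = "chrA",
                        gc_profile = NULL) {
  lens <- stats::setNames(len, name)
  build_genome_model(lens, bin_size = bin_size, gc_profile = gc_profile)
}

# A two-autosome genome, still small.
duo_genome <- function() {
  build_genome_model(c(chrA = 8e6, chrB = 6e6), bin_size = 20000)
}

# Exhaustive-arc oracle for the circular split statistic: enumerates every
# arc (i, j] explicitly, computing group means and the pooled SD from
# per-group sums of squares. Ties broken by smallest i then smallest j;
# complementary edge arcs have exactly equal |Z|, so an improvement must
# beat the incumbent by a relative margin for the tie-break to be
# well-defined in floating point.
cbs_oracle <- function(x) {
  n <- length(x)
  best <- list(t_max = -1, arc_start = NA_integer_, arc_end = NA_integer_)
  for (i in 0:(n - 1)) {
    for (j in (i + 1):n) {
      k <- j - i
      if (k == n) next
      arc <- x[(i + 1):j]
      out <- x[-((i + 1):j)]
      ssq <- sum((arc - mean(arc))^2) + sum((out - mean(out))^2)
      s2 <- ssq / (n - 2)
      z <- if (s2 <= 0) {
        if (mean(arc) != mean(out)) Inf else 0
      } else {
        abs(mean(arc) - mean(out)) / sqrt(s2 * (1 / k + 1 / (n - k)))
      }
      better <- if (best$t_max <= 0) z > best$t_max
                else z > best$t_max * (1 + 1e-12)
      if (better)
        best <- list(t_max = z, arc_start = i + 1L, arc_end = j)
    }
  }
  if (best$t_max == 0)
    best <- list(t_max = 0, arc_start = NA_integer_, arc_end = NA_integer_)
  best
}

# Textbook chi-squared oracle: builds the 2x2 table explicitly and sums
# (O - E)^2 / E over the four cells.
chi2_oracle <- function(cohort_n, cohort_N, db_n, db_N) {
  obs <- matrix(c(cohort_n, cohort_N - cohort_n, db_n, db_N - db_n),
                nrow = 2, byrow = TRUE)
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  sum((obs - expd)^2 / expd)
}

# Build a CNVCallTable row-by-row without going through segmentation.
make_calls <- function(sample_id, chrom, start_bp, end_bp, type,
                       mean_ratio = ifelse(type == "gain", 1.5, 0.5)) {
  df <- data.frame(sample_id = sample_id, chrom = chrom,
                   start_bp = start_bp, end_bp = end_bp, type = type,
                   length_bp = end_bp - start_bp, mean_ratio = mean_ratio,
                   deviation = abs(mean_ratio - 1) / 0.5,
                   z_score = NA_real_, stringsAsFactors = FALSE)
  class(df) <- c("CNVCallTable", "data.frame")
  df
}

# Mappable-bin index of an interval on a model.
bins_in <- function(model, chrom, start_bp, end_bp) {
  b <- model$bins[model$bins$mappable, ]
  which(b$chrom == chrom & (b$start + b$end) / 2 >= start_bp &
          (b$start + b$end) / 2 < end_bp)
}
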