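#' Call maternal CNVs from a segment table
#'
#' A segment becomes a maternal call iff it is at least `min_length_bp`
#' long and its signal deviation exceeds `deviation_threshold`. Deviation
#' is expressed as a fraction of the heterozygous single-copy shift
#' (0.5 in diploid-ratio units): `deviation = |mean_ratio - 1| / 0.5`, so
#' a maternal heterozygous gain or loss sits at deviation 1 while a
#' fetal-only event at fetal fraction ff sits near ff — far below the
#' default 0.75 cut, which is what designates surviving segments as
#' maternal. Equivalently, calls require `mean_ratio <= 0.625` or
#' `>= 1.375` at the defaults. Adjacent qualifying segments are not
#' merged: one segment, one call.
#'
#' @param segments A `SegmentTable` from [segment_profile()].
#' @param sample_id Sample label attached to the calls.
#' @param min_length_bp Minimal call length in bp (default 200,000).
#' @param deviation_threshold Minimal deviation, exclusive (default 0.75).
#' @return `data.frame` of class `CNVCallTable`: `sample_id`, `chrom`,
#'   `start_bp`, `end_bp` (0-based half-open, bin-aligned), `type`
#'   (`"gain"`/`"loss"`), `length_bp`, `mean_ratio`, `deviation`,
#'   `z_score`. Empty input gives an empty table.
#' @export
call_maternal_cnvs <- function(segments, sample_id = "sample",
                               min_length_bp = 200000,
                               deviation_threshold = 0.75) {
  if (min_length_bp <= 0 || deviation_threshold <= 0)
    stop("thresholds must be positive")
  empty <- data.frame(sample_id = character(0), chrom = character(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      type = character(0), length_bp = numeric(0),
                      mean_ratio = numeric(0), deviation = numeric(0),
                      z_score = numeric(0), stringsAsFactors = FALSE)
  class(empty) <- c("CNVCallTable", "data.frame")
  if (is.null(segments) || nrow(segments) == 0) return(empty)

  dev <- abs(segments$mean_ratio - 1) / 0.5
  len <- segments$end_bp - segments$start_bp
  keep <- len >= min_length_bp & dev > deviation_threshold
  if (!any(keep)) return(empty)

  s <- segments[keep, , drop = FALSE]
  calls <- data.frame(
    sample_id = sample_id,
    chrom = s$chrom,
    start_bp = s$start_bp, end_bp = s$end_bp,
    type = ifelse(s$mean_ratio > 1, "gain", "loss"),
    length_bp = s$end_bp - s$start_bp,
    mean_ratio = s$mean_ratio,
    deviation = dev[keep],
    z_score = s$z_score,
    stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  class(calls) <- c("CNVCallTable", "data.frame")
  calls
}
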