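#' Maximal circular split statistic
#'
#' Treats `values` as a circle and, for every arc, compares the mean
#' inside the arc with the mean outside via the two-sample statistic
#' `Z = (mean_in - mean_out) / (s * sqrt(1/k + 1/(n-k)))`, `s` being the
#' pooled SD and `k` the arc length. Returns the maximal `|Z|` and its
#' arc; ties are broken toward the smallest start, then the smallest end.
#' A perfectly constant input has `s = 0` everywhere and is defined to
#' have `t_max = 0` (nothing to segment); a noiseless step yields
#' `t_max = Inf` on the exact arc.
#'
#' @param values Numeric vector, length at least 4.
#' @return List with `t_max`, `arc_start`, `arc_end` (1-based inclusive:
#'   the arc is `values[arc_start:arc_end]`).
#' @export
#' @examples
#' cbs_split_statistic(c(0, 0, 0, 0, 5, 5, 5, 5, 0, 0, 0, 0))
cbs_split_statistic <- function(values) {
  if (length(values) < 4) stop("need at least 4 values")
  if (anyNA(values)) stop("values must not contain NA")
  res <- .cbs_tmax_cpp(as.numeric(values), 1L)
  if (res$t_max == 0)
    list(t_max = 0, arc_start = NA_integer_, arc_end = NA_integer_)
  else
    list(t_max = res$t_max, arc_start = res$i + 1L, arc_end = res$j)
}

#' Circular binary segmentation of one signal
#'
#' Recursive changepoint search: compute the maximal circular split
#' statistic of the current segment, assess it by permutation (the
#' p-value is the fraction of `n_perm` shuffles of the segment's values
#' whose maximal statistic is at least the observed one), and if
#' `p <= alpha` split at the arc boundaries — two breakpoints for an
#' interior arc, one when the arc touches a segment edge — then recurse
#' on each part. Pieces shorter than `min_width` bins are never created:
#' the split arc is chosen among arcs whose resulting pieces are all
#' either empty or at least `min_width` long. Deterministic given `seed`.
#'
#' @param values Numeric vector of per-bin signal.
#' @param alpha Significance level for accepting a split (default 0.01).
#' @param n_perm Number of permutations (default 1000; at least 100).
#' @param min_width Minimal segment width in bins (default 2).
#' @param seed Optional integer seed; if `NULL` the current RNG state is
#'   used.
#' @return Sorted integer vector of segment end positions (1-based,
#'   inclusive); the last element is always `length(values)`, so `m`
#'   segments are returned as `m` ends.
#' @export
cbs_segment <- function(values, alpha = 0.01, n_perm = 1000,
                        min_width = 2, seed = NULL) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (n_perm < 100) stop("n_perm must be at least 100")
  if (anyNA(values)) stop("values must not contain NA")
  n <- length(values)
  if (n == 0) return(integer(0))
  if (!is.null(seed)) set.seed(seed)

  ends <- integer(0)
  recurse <- function(lo, hi) {
    m <- hi - lo + 1
    if (m < 4 || m < 2 * min_width) {
      ends[[length(ends) + 1]] <<- hi
      return(invisible(NULL))
    }
    seg <- values[lo:hi]
    res <- .cbs_perm_cpp(as.numeric(seg), as.integer(n_perm), alpha)
    split <- res$t_max > 0 && res$p <= alpha
    if (split) {
      # re-maximize under the min-width constraint to place the cut
      arc <- .cbs_tmax_cpp(as.numeric(seg), as.integer(min_width))
      if (arc$i < 0 || arc$t_max <= 0) split <- FALSE
      else {
        cuts <- integer(0)
        if (arc$i > 0) cuts <- c(cuts, arc$i)       # relative end of left piece
        if (arc$j < m) cuts <- c(cuts, arc$j)       # relative end of middle piece
        if (length(cuts) == 0) split <- FALSE
        else {
          bounds <- c(0L, cuts, m)
          for (p in seq_len(length(bounds) - 1))
            recurse(lo + bounds[p], lo + bounds[p + 1] - 1)
        }
      }
    }
    if (!split) ends[[length(ends) + 1]] <<- hi
    invisible(NULL)
  }
  recurse(1L, n)
  sort(unique(as.integer(ends)))
}

#' Approximated z-score of a segment
#'
#' `z = (mean_ratio - 1) * sqrt(n_bins) / noise_sd`: the departure of the
#' segment mean from the diploid expectation, in units of the standard
#' error implied by the profile's per-bin noise level.
#'
#' @param mean_ratio Segment mean of the normalized ratio.
#' @param n_bins Number of bins in the segment.
#' @param noise_sd Robust per-bin SD of the profile (must be > 0).
#' @return The z-score.
#' @export
#' @examples
#' segment_zscore(1.5, 16, 0.2)  # 10
segment_zscore <- function(mean_ratio, n_bins, noise_sd) {
  if (any(noise_sd <= 0)) stop("noise_sd must be positive (degenerate profile)")
  (mean_ratio - 1) * sqrt(n_bins) / noise_sd
}

#' Segment a normalized profile chromosome by chromosome
#'
#' Runs [cbs_segment()] on each chromosome's mappable-bin ratios and
#' assembles the genome-wide segment table. Segments partition every
#' chromosome's mappable bins without gap or overlap; genomic coordinates
#' are those of the bounding bins (so a segment spanning an unmappable
#' gap covers it).
#'
#' @param profile A `NormalizedProfile`.
#' @param model The `GenomeModel` of the profile.
#' @param alpha,n_perm,min_width See [cbs_segment()].
#' @param seed Optional seed (set once; chromosomes consume the RNG
#'   stream in genome order).
#' @return `data.frame` of class `SegmentTable`: `chrom`, `start_bin`,
#'   `end_bin` (1-based inclusive per-chromosome mappable-bin indices),
#'   `start_bp`, `end_bp` (0-based half-open), `n_bins`, `mean_ratio`,
#'   `z_score`.
#' @export
segment_profile <- function(profile, model, alpha = 0.01, n_perm = 1000,
                            min_width = 2, seed = NULL) {
  stopifnot(inherits(model, "GenomeModel"))
  bins <- mappable_bins(model)
  if (length(profile$ratio) != nrow(bins))
    stop("profile and model bin grids differ")
  if (!is.null(seed)) set.seed(seed)

  out <- list()
  for (ch in names(model$chrom_lengths)) {
    idx <- which(bins$chrom == ch)
    if (!length(idx)) next
    v <- profile$ratio[idx]
    ends <- cbs_segment(v, alpha = alpha, n_perm = n_perm,
                        min_width = min_width, seed = NULL)
    starts <- c(1L, utils::head(ends, -1) + 1L)
    mr <- vapply(seq_along(ends), function(s)
      mean(v[starts[s]:ends[s]]), numeric(1))
    out[[ch]] <- data.frame(
      chrom = ch,
      start_bin = starts, end_bin = ends,
      start_bp = bins$start[idx[starts]],
      end_bp = bins$end[idx[ends]],
      n_bins = ends - starts + 1L,
      mean_ratio = mr,
      stringsAsFactors = FALSE)
  }
  seg <- do.call(rbind, out)
  rownames(seg) <- NULL
  seg$z_score <- segment_zscore(seg$mean_ratio, seg$n_bins, profile$noise_sd)
  class(seg) <- c("SegmentTable", "data.frame")
  seg
}
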