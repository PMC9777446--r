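#' Cohort frequency of a recurrent variant
#'
#' `100 * n / N`, rounded to 3 decimals for reporting — the convention of
#' the cohort MOV tables (e.g. 126 occurrences in 6422 samples → 1.962).
#'
#' @param n Occurrence count.
#' @param N Cohort size.
#' @param digits Decimals to round to (default 3; `NA` for no rounding).
#' @return Frequency in percent.
#' @export
mov_frequency <- function(n, N, digits = 3) {
  if (any(N < 1)) stop("cohort size must be >= 1")
  f <- 100 * n / N
  if (!is.na(digits)) f <- round(f, digits)
  f
}

#' Cluster per-sample calls into recurrent variants (MOVs)
#'
#' Same-type calls on the same chromosome are linked whenever their
#' reciprocal overlap reaches `min_reciprocal_overlap` (the intersection
#' must cover that fraction of *each* call); connected components of this
#' link graph are the clusters. A cluster observed in two or more
#' distinct samples is a multiple occurring variant (MOV). The
#' representative interval is the modal (most frequent exact) interval of
#' the component, ties broken leftmost then shortest. Gains and losses at
#' the same locus are never merged.
#'
#' @param calls A `CNVCallTable` (typically `rbind` of per-sample calls).
#' @param cohort_size Number of samples `N` in the cohort (denominator of
#'   the frequency).
#' @param min_reciprocal_overlap Linking threshold in \[0, 1\] (default
#'   0.75).
#' @return `data.frame` of class `MOVTable`, one row per cluster:
#'   `chrom`, `start_bp`, `end_bp`, `type`, `n_occurrences` (distinct
#'   samples), `frequency_pct` (unrounded; see [mov_frequency()] for the
#'   reporting convention), `is_mov`, `member_sample_ids`
#'   (comma-separated). Ordered by genome position.
#' @export
cluster_movs <- function(calls, cohort_size,
                         min_reciprocal_overlap = 0.75) {
  if (cohort_size < 1) stop("cohort_size must be >= 1")
  empty <- data.frame(chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), type = character(0),
                      n_occurrences = integer(0), frequency_pct = numeric(0),
                      is_mov = logical(0), member_sample_ids = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("MOVTable", "data.frame")
  if (is.null(calls) || nrow(calls) == 0) return(empty)

  # canonical order makes clustering independent of input call order
  ord <- order(calls$chrom, calls$type, calls$start_bp, calls$end_bp,
               calls$sample_id)
  calls <- calls[ord, , drop = FALSE]

  groups <- split(seq_len(nrow(calls)),
                  paste(calls$chrom, calls$type, sep = "\r"))
  rows <- list()
  for (g in groups) {
    st <- calls$start_bp[g]; en <- calls$end_bp[g]
    m <- length(g)
    parent <- seq_len(m)
    find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
    for (a in seq_len(m)) for (b in seq_len(m)) {
      if (b <= a) next
      inter <- min(en[a], en[b]) - max(st[a], st[b])
      if (inter <= 0) next
      ro <- min(inter / (en[a] - st[a]), inter / (en[b] - st[b]))
      if (ro >= min_reciprocal_overlap) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
    roots <- vapply(seq_len(m), find, integer(1))
    for (r in unique(roots)) {
      mem <- which(roots == r)
      ids <- unique(calls$sample_id[g[mem]])
      # modal exact interval; ties -> leftmost, then shortest
      key <- paste(st[mem], en[mem])
      tab <- table(key)
      cand <- names(tab)[tab == max(tab)]
      cs <- as.numeric(vapply(strsplit(cand, " "), `[`, character(1), 1))
      ce <- as.numeric(vapply(strsplit(cand, " "), `[`, character(1), 2))
      pick <- order(cs, ce - cs)[1]
      rows[[length(rows) + 1]] <- data.frame(
        chrom = calls$chrom[g[1]],
        start_bp = cs[pick], end_bp = ce[pick],
        type = calls$type[g[1]],
        n_occurrences = length(ids),
        frequency_pct = 100 * length(ids) / cohort_size,
        is_mov = length(ids) >= 2,
        member_sample_ids = paste(sort(ids), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start_bp, out$end_bp, out$type), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("MOVTable", "data.frame")
  out
}

#' Chi-squared contrast of a cohort frequency against a database
#'
#' Databases publish frequencies, not carrier counts, so the database
#' carrier count is reconstructed as `round(db_freq_pct/100 * db_N)`; the
#' 2×2 carriers/non-carriers × cohort/database table is then tested with
#' Pearson's chi-squared (1 df, no continuity correction).
#'
#' @param cohort_n Carriers observed in the cohort.
#' @param cohort_N Cohort size.
#' @param db_freq_pct Database frequency in percent.
#' @param db_N Database cohort size.
#' @param label Optional locus label carried into the result.
#' @return One-row `data.frame`: `label`, `cohort_n`, `cohort_N`,
#'   `cohort_freq_pct`, `db_n`, `db_N`, `db_freq_pct`, `chi2_stat`,
#'   `p_value`, `degenerate`. When any expected cell is 0 (both
#'   frequencies 0) the test is undefined: `chi2_stat`/`p_value` are `NA`
#'   and `degenerate` is `TRUE`.
#' @export
compare_to_db <- function(cohort_n, cohort_N, db_freq_pct, db_N,
                          label = NA_character_) {
  if (cohort_N < 1 || db_N < 1) stop("cohort sizes must be >= 1")
  if (db_freq_pct < 0 || db_freq_pct > 100)
    stop("db_freq_pct must lie in [0, 100]")
  if (cohort_n < 0 || cohort_n > cohort_N)
    stop("cohort_n must lie in [0, cohort_N]")
  db_n <- round(db_freq_pct / 100 * db_N)
  tab <- matrix(c(cohort_n, cohort_N - cohort_n, db_n, db_N - db_n),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("cohort", "database"),
                                c("carrier", "non_carrier")))
  degenerate <- any(colSums(tab) == 0) || any(rowSums(tab) == 0)
  if (degenerate) {
    warning("expected cell count of 0; chi-squared undefined")
    chi2 <- NA_real_; p <- NA_real_
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    chi2 <- unname(ct$statistic); p <- ct$p.value
  }
  data.frame(label = label, cohort_n = cohort_n, cohort_N = cohort_N,
             cohort_freq_pct = 100 * cohort_n / cohort_N,
             db_n = db_n, db_N = db_N, db_freq_pct = db_freq_pct,
             chi2_stat = chi2, p_value = p, degenerate = degenerate,
             stringsAsFactors = FALSE)
}

#' Variants-per-megabase outlier test across chromosomes
#'
#' For each chromosome the observed variant count is divided by its
#' effective length (chromosome size after removal of unmappable and
#' repetitive regions) in megabases. The per-Mb values are assumed
#' normally distributed across chromosomes; their mean and *sample*
#' (n−1) standard deviation are estimated, and each chromosome gets the
#' lower-tail probability `p = Phi((per_mb - mean)/sd)`. Chromosomes with
#' `p < 0.05` are flagged as depleted outliers; high-tail extremity is
#' not flagged by default (set `two_sided = TRUE` to flag both tails).
#'
#' @param variant_counts Named integer vector, one count per chromosome.
#' @param effective_lengths Named numeric vector of effective lengths in
#'   bp, same names as `variant_counts`.
#' @param two_sided If `TRUE`, `significant` flags `min(p, 1-p) < 0.025`.
#' @return `data.frame` of class `DensityTable`: `chrom`,
#'   `effective_length_bp`, `n_variants`, `per_mb`, `p_value`,
#'   `significant`.
#' @export
chromosome_density <- function(variant_counts, effective_lengths,
                               two_sided = FALSE) {
  chroms <- names(variant_counts)
  if (is.null(chroms)) stop("variant_counts must be named by chromosome")
  if (length(variant_counts) < 3) stop("need at least 3 chromosomes")
  if (is.null(names(effective_lengths)))
    stop("effective_lengths must be named by chromosome")
  if (!all(chroms %in% names(effective_lengths)))
    stop("effective length missing for: ",
         paste(setdiff(chroms, names(effective_lengths)), collapse = ", "))
  el <- effective_lengths[chroms]
  if (any(el <= 0)) stop("effective lengths must be positive")

  per_mb <- as.numeric(variant_counts) / (as.numeric(el) / 1e6)
  s <- stats::sd(per_mb)
  if (s == 0) {
    warning("all per-Mb densities identical; p = 0.5 everywhere")
    p <- rep(0.5, length(per_mb))
  } else {
    p <- stats::pnorm((per_mb - mean(per_mb)) / s)
  }
  sig <- if (two_sided) pmin(p, 1 - p) < 0.025 else p < 0.05
  if (s == 0) sig <- rep(FALSE, length(p))
  out <- data.frame(chrom = chroms,
                    effective_length_bp = as.numeric(el),
                    n_variants = as.numeric(variant_counts),
                    per_mb = per_mb, p_value = p, significant = sig,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("DensityTable", "data.frame")
  out
}

#' Cohort-level summary of calls and clusters
#'
#' Counts distinct CNVs (clusters), MOVs, gains vs losses among distinct
#' variants, and per-chromosome totals, and lays out the recurrent
#' variants as a report-style table (label, size, coordinates, n,
#' frequency %).
#'
#' @param movs A `MOVTable` from [cluster_movs()].
#' @param calls The `CNVCallTable` the clusters were built from.
#' @return List: `n_calls`, `n_distinct`, `n_mov`, `n_gain`, `n_loss`
#'   (distinct variants by type), `per_chromosome` (named vector of
#'   distinct-variant counts), `mov_table` (`data.frame` with `label`,
#'   `size_kb`, `coordinates`, `type`, `n`, `frequency_pct`, MOVs only,
#'   by descending n).
#' @export
summarize_cohort <- function(movs, calls) {
  if (is.null(movs) || nrow(movs) == 0) {
    return(list(n_calls = if (is.null(calls)) 0L else nrow(calls),
                n_distinct = 0L, n_mov = 0L, n_gain = 0L, n_loss = 0L,
                per_chromosome = integer(0),
                mov_table = data.frame(label = character(0),
                                       size_kb = numeric(0),
                                       coordinates = character(0),
                                       type = character(0), n = integer(0),
                                       frequency_pct = numeric(0),
                                       stringsAsFactors = FALSE)))
  }
  mv <- movs[movs$is_mov, , drop = FALSE]
  mv <- mv[order(-mv$n_occurrences, mv$chrom, mv$start_bp), , drop = FALSE]
  mov_table <- data.frame(
    label = paste(ifelse(mv$type == "gain", "dup", "del"), mv$chrom),
    size_kb = (mv$end_bp - mv$start_bp) / 1e3,
    coordinates = format_locus(mv$chrom, mv$start_bp, mv$end_bp),
    type = mv$type,
    n = mv$n_occurrences,
    frequency_pct = round(mv$frequency_pct, 3),
    stringsAsFactors = FALSE)
  rownames(mov_table) <- NULL
  list(n_calls = if (is.null(calls)) 0L else nrow(calls),
       n_distinct = nrow(movs),
       n_mov = sum(movs$is_mov),
       n_gain = sum(movs$type == "gain"),
       n_loss = sum(movs$type == "loss"),
       per_chromosome = vapply(split(movs$chrom, movs$chrom), length,
                               integer(1)),
       mov_table = mov_table)
}
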