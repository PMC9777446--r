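#' Pipeline configuration
#'
#' Bundles every stage's parameters with the anchored defaults: 20 kb
#' bins, LOESS span 0.3, 3 PCA components, CBS at alpha 0.01 with 1000
#' permutations and minimal width 2 bins, maternal calling at 200 kb /
#' 75% deviation, MOV clustering at 0.75 reciprocal overlap.
#'
#' @param genome A `GenomeModel` (default [toy_genome()]).
#' @param span,k Normalization parameters (see [normalize_cohort()]).
#' @param alpha,n_perm,min_width Segmentation parameters (see
#'   [cbs_segment()]).
#' @param min_length_bp,deviation_threshold Calling thresholds (see
#'   [call_maternal_cnvs()]).
#' @param min_reciprocal_overlap MOV clustering threshold (see
#'   [cluster_movs()]).
#' @param seed Integer seed governing simulation and segmentation.
#' @return List of class `PipelineConfig`.
#' @export
pipeline_config <- function(genome = toy_genome(),
                            span = 0.3, k = 3,
                            alpha = 0.01, n_perm = 1000, min_width = 2,
                            min_length_bp = 200000,
                            deviation_threshold = 0.75,
                            min_reciprocal_overlap = 0.75,
                            seed = 1L) {
  structure(list(genome = genome, span = span, k = k, alpha = alpha,
                 n_perm = n_perm, min_width = min_width,
                 min_length_bp = min_length_bp,
                 deviation_threshold = deviation_threshold,
                 min_reciprocal_overlap = min_reciprocal_overlap,
                 seed = as.integer(seed)),
            class = "PipelineConfig")
}

.stage_log <- function(stage, n_in, n_out, t0, quiet) {
  if (!quiet)
    message(sprintf("[%s] n_in=%s n_out=%s elapsed=%.1fs", stage,
                    n_in, n_out, as.numeric(proc.time()[3]) - t0))
}

#' Run the full maternal-CNV pipeline
#'
#' simulate (optional) → normalize (LOESS then leave-one-out PCA) →
#' segment (CBS) → call (length/deviation thresholds) → cluster (MOVs) →
#' density (variants per Mb across chromosomes). Re-running with the
#' same config and seed reproduces every table exactly.
#'
#' @param config A [pipeline_config()].
#' @param samples List of `BinnedSample`s, or `NULL` to simulate
#'   `cohort_spec` first.
#' @param cohort_spec A [cohort_spec()] used when `samples` is `NULL`.
#' @param out_dir Optional directory; when given, per-stage TSV/BED
#'   tables are written there.
#' @param quiet Suppress per-stage log lines.
#' @return List of class `PipelineResult`: `cohort` (if simulated),
#'   `profiles`, `segments` (per-sample list), `calls` (one
#'   `CNVCallTable`), `movs`, `density`, `summary`, `config`.
#' @export
run_pipeline <- function(config, samples = NULL, cohort_spec = NULL,
                         out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "PipelineConfig"))
  model <- config$genome
  cohort <- NULL

  if (is.null(samples)) {
    if (is.null(cohort_spec)) stop("either samples or cohort_spec required")
    t0 <- as.numeric(proc.time()[3])
    cohort <- simulate_cohort(model, cohort_spec)
    samples <- cohort$samples
    .stage_log("simulate", cohort_spec$n_samples, length(samples), t0, quiet)
  }
  n <- length(samples)

  t0 <- as.numeric(proc.time()[3])
  profiles <- normalize_cohort(samples, model, span = config$span,
                               k = config$k)
  .stage_log("normalize", n, length(profiles), t0, quiet)

  t0 <- as.numeric(proc.time()[3])
  set.seed(config$seed)
  segments <- lapply(profiles, segment_profile, model = model,
                     alpha = config$alpha, n_perm = config$n_perm,
                     min_width = config$min_width, seed = NULL)
  .stage_log("segment", n, sum(vapply(segments, nrow, integer(1))), t0, quiet)

  t0 <- as.numeric(proc.time()[3])
  calls <- do.call(rbind, lapply(seq_len(n), function(i)
    call_maternal_cnvs(segments[[i]], sample_id = profiles[[i]]$sample_id,
                       min_length_bp = config$min_length_bp,
                       deviation_threshold = config$deviation_threshold)))
  class(calls) <- c("CNVCallTable", "data.frame")
  .stage_log("call", sum(vapply(segments, nrow, integer(1))), nrow(calls),
             t0, quiet)

  t0 <- as.numeric(proc.time()[3])
  movs <- cluster_movs(calls, cohort_size = n,
                       min_reciprocal_overlap = config$min_reciprocal_overlap)
  .stage_log("cohort", nrow(calls), nrow(movs), t0, quiet)

  t0 <- as.numeric(proc.time()[3])
  counts <- table(factor(movs$chrom, levels = names(model$chrom_lengths)))
  vc <- as.integer(counts); names(vc) <- names(counts)
  density <- if (length(vc) >= 3)
    chromosome_density(vc, model$effective_length)
  else NULL
  .stage_log("density", length(vc), if (is.null(density)) 0 else nrow(density),
             t0, quiet)

  summary <- summarize_cohort(movs, calls)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(cohort)) write_cohort(cohort, file.path(out_dir, "cohort"))
    seg_all <- do.call(rbind, lapply(seq_len(n), function(i)
      cbind(sample_id = profiles[[i]]$sample_id, segments[[i]])))
    utils::write.table(seg_all, file.path(out_dir, "segments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_calls_bed(calls, file.path(out_dir, "calls.bed"))
    utils::write.table(movs, file.path(out_dir, "movs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(density))
      utils::write.table(density, file.path(out_dir, "density.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summary$mov_table, file.path(out_dir, "mov_table.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  structure(list(cohort = cohort, profiles = profiles, segments = segments,
                 calls = calls, movs = movs, density = density,
                 summary = summary, config = config),
            class = "PipelineResult")
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat("PipelineResult:", length(x$profiles), "samples,",
      nrow(x$calls), "maternal calls,",
      x$summary$n_distinct, "distinct variants (",
      x$summary$n_mov, "MOVs )\n")
  invisible(x)
}
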