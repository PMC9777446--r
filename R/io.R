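#' @name counts_io
#' @title Read and write per-bin count tables
#'
#' @description
#' The on-disk counts dialect is a tab-separated table with header
#' `chrom start end gc count`, coordinates 0-based half-open on the bin
#' grid. `write_counts_tsv()` writes one sample; `read_counts_tsv()`
#' reads it back as a `BinnedSample` aligned to a `GenomeModel`
#' (round-trips are loss-free).
#'
#' @param sample A `BinnedSample`.
#' @param model The `GenomeModel` of the bin grid.
#' @param path File path.
#' @param sample_id Sample label for the reader.
#' @return `read_counts_tsv()` returns a `BinnedSample`.
NULL

#' @rdname counts_io
#' @export
write_counts_tsv <- function(sample, model, path) {
  bins <- mappable_bins(model)
  stopifnot(length(sample$counts) == nrow(bins))
  df <- data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                   gc = bins$gc, count = sample$counts)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname counts_io
#' @export
read_counts_tsv <- function(path, model, sample_id = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "count")
  if (!all(need %in% names(df)))
    stop("counts TSV must have columns ", paste(need, collapse = ", "))
  bad <- which(df$end <= df$start)
  if (length(bad)) stop("malformed row ", bad[1] + 1L, ": end <= start")
  if (any(df$count < 0)) stop("negative counts in ", path)
  bins <- mappable_bins(model)
  if (nrow(df) != nrow(bins) ||
      !all(df$chrom == bins$chrom & df$start == bins$start))
    stop("counts TSV does not match the model's mappable-bin grid")
  if (is.null(sample_id))
    sample_id <- sub("\\.tsv$", "", basename(path))
  structure(list(sample_id = sample_id, counts = as.numeric(df$count),
                 total_reads = sum(df$count), fetal_fraction = NA_real_,
                 truth = NULL),
            class = "BinnedSample")
}

#' Write a simulated cohort to disk
#'
#' One counts TSV per sample, a truth BED (`chrom start end copy_state
#' carrier sample_id`, 0-based half-open) and a cohort manifest TSV
#' (`sample_id`, `file`, `total_reads`, `fetal_fraction`).
#'
#' @param cohort A `SimulatedCohort`.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "SimulatedCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- vapply(cohort$samples, function(s) {
    f <- file.path(dir, paste0(s$sample_id, ".counts.tsv"))
    write_counts_tsv(s, cohort$model, f)
    basename(f)
  }, character(1))
  manifest <- data.frame(
    sample_id = vapply(cohort$samples, `[[`, character(1), "sample_id"),
    file = files,
    total_reads = vapply(cohort$samples, `[[`, numeric(1), "total_reads"),
    fetal_fraction = vapply(cohort$samples, `[[`, numeric(1),
                            "fetal_fraction"))
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- cohort$truth
  bed <- if (nrow(tr)) data.frame(chrom = tr$chrom, start = tr$start_bp,
                                  end = tr$end_bp,
                                  copy_state = tr$copy_state,
                                  carrier = tr$carrier,
                                  sample_id = tr$sample_id)
  else data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                  copy_state = integer(0), carrier = character(0),
                  sample_id = character(0))
  utils::write.table(bed, file.path(dir, "truth.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Write/read maternal CNV calls as BED5+
#'
#' Columns: `chrom`, `start`, `end` (0-based half-open), `name` (the call
#' type), `score` (z-score), then `deviation` and `sample_id`.
#'
#' @param calls A `CNVCallTable`.
#' @param path File path.
#' @return `read_calls_bed()` returns a `CNVCallTable`.
#' @export
write_calls_bed <- function(calls, path) {
  df <- data.frame(chrom = calls$chrom, start = calls$start_bp,
                   end = calls$end_bp, name = calls$type,
                   score = calls$z_score, deviation = calls$deviation,
                   sample_id = calls$sample_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_calls_bed
#' @export
read_calls_bed <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "deviation", "sample_id"))
  bad <- which(df$start >= df$end)
  if (length(bad)) stop("malformed BED record at line ", bad[1],
                        ": start >= end")
  out <- data.frame(sample_id = df$sample_id, chrom = df$chrom,
                    start_bp = df$start, end_bp = df$end, type = df$name,
                    length_bp = df$end - df$start,
                    mean_ratio = NA_real_, deviation = df$deviation,
                    z_score = df$score, stringsAsFactors = FALSE)
  class(out) <- c("CNVCallTable", "data.frame")
  out
}

#' Parse and render human-readable locus labels
#'
#' Report tables print grid-aligned loci 1-based inclusive with thousands
#' separators, e.g. `"chr6:168,340,000-168,580,000"` (an en dash is also
#' accepted). Internally everything is 0-based half-open, so a printed
#' start of 168,340,000 round-trips to `start_bp = 168340000` only
#' because these labels are bin-aligned: the printed range is taken
#' verbatim as the half-open interval, matching the 20 kb-grid
#' convention of the source tables.
#'
#' @param label Character vector of locus labels.
#' @return `parse_locus()`: `data.frame` with `chrom`, `start_bp`,
#'   `end_bp`.
#' @export
#' @examples
#' parse_locus("chr6:168,340,000-168,580,000")
parse_locus <- function(label) {
  x <- gsub(",", "", label)
  x <- gsub("–", "-", x)  # en dash as printed in reports
  x <- gsub("\\s", "", x)
  m <- regmatches(x, regexec("^(\\w+):(\\d+)-(\\d+)$", x))
  bad <- vapply(m, length, integer(1)) != 4
  if (any(bad)) stop("unparseable locus label: ", label[bad][1])
  out <- data.frame(
    chrom = vapply(m, `[`, character(1), 2),
    start_bp = as.numeric(vapply(m, `[`, character(1), 3)),
    end_bp = as.numeric(vapply(m, `[`, character(1), 4)),
    stringsAsFactors = FALSE)
  if (any(out$end_bp <= out$start_bp))
    stop("locus with end <= start: ", label[out$end_bp <= out$start_bp][1])
  out
}

#' @rdname parse_locus
#' @param chrom,start_bp,end_bp Locus coordinates (0-based half-open,
#'   bin-aligned).
#' @export
format_locus <- function(chrom, start_bp, end_bp) {
  sprintf("%s:%s-%s", chrom,
          formatC(start_bp, format = "d", big.mark = ","),
          formatC(end_bp, format = "d", big.mark = ","))
}

#' Read an external population frequency table
#'
#' TSV with header `locus freq_pct cohort_size source` — the layout used
#' for database (dbVar/DGV, gnomAD SVs) frequency fixtures.
#'
#' @param path File path.
#' @return `data.frame` with the parsed locus columns appended.
#' @export
read_db_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("locus", "freq_pct", "cohort_size", "source")
  if (!all(need %in% names(df)))
    stop("db table must have columns ", paste(need, collapse = ", "))
  cbind(df, parse_locus(df$locus))
}

#' Packaged report-table fixtures
#'
#' The package ships two small TSV fixtures under `inst/extdata`: the
#' 30 most frequent maternal MOVs of a 6422-sample NIPT cohort
#' (`mov_table.tsv`: label, size, hg19 coordinates, occurrence count,
#' frequency %, database frequencies) and the per-chromosome variant
#' density table (`chromosome_density.tsv`: effective length, variant
#' count, per-Mb ratio, lower-tail p). Useful as worked inputs for the
#' cohort statistics.
#'
#' @param which `"mov"` or `"density"`.
#' @return `data.frame`.
#' @export
load_report_fixture <- function(which = c("mov", "density")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   if (which == "mov") "mov_table.tsv"
                   else "chromosome_density.tsv",
                   package = "niptcnv", mustWork = TRUE)
  utils::read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
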