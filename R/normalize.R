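#' LOESS GC correction
#'
#' First normalization step: a locally weighted regression (tricube
#' weights, local degree 1, robustness iterations) of bin count on GC
#' fraction, fitted on autosomal mappable bins and evaluated everywhere.
#' The corrected per-bin ratio is `count / fit(GC)`, rescaled so the
#' autosomal median is exactly 1 — a diploid bin then sits at 1.0 and a
#' heterozygous maternal gain/loss at 1.5/0.5.
#'
#' @param sample A `BinnedSample` (from [simulate_cohort()] or
#'   [read_counts_tsv()]).
#' @param model The `GenomeModel` the counts were binned on.
#' @param span LOESS span (fraction of points in each local window),
#'   default 0.3.
#' @return A `NormalizedProfile`: list with `sample_id`, `ratio` (one
#'   value per mappable bin, diploid expectation 1.0), `noise_sd`
#'   (robust per-bin SD, 1.4826 × MAD of autosomal ratios).
#' @export
loess_gc_correct <- function(sample, model, span = 0.3) {
  stopifnot(inherits(model, "GenomeModel"))
  bins <- mappable_bins(model)
  counts <- sample$counts
  if (length(counts) != nrow(bins))
    stop("counts length (", length(counts),
         ") does not match mappable bins (", nrow(bins), ")")
  if (nrow(bins) < 200) stop("need at least 200 mappable bins")
  if (all(counts == 0)) stop("all-zero sample cannot be normalized")

  auto <- is_autosome(bins$chrom)
  gc <- bins$gc

  if (diff(range(gc[auto])) < 1e-8) {
    warning("degenerate GC range; skipping GC correction, median-scaling only")
    fit_all <- rep(stats::median(counts[auto]), length(counts))
  } else {
    lw <- stats::lowess(gc[auto], counts[auto], f = span, iter = 3)
    # lowess returns the fit at sorted unique-ish x; interpolate to every
    # bin's GC, clamping beyond the fitted support
    fit_all <- stats::approx(lw$x, lw$y, xout = gc, rule = 2, ties = mean)$y
  }
  floor_fit <- max(stats::median(fit_all[auto]) * 1e-6, 1e-12)
  fit_all <- pmax(fit_all, floor_fit)

  ratio <- counts / fit_all
  med <- stats::median(ratio[auto])
  if (med <= 0) stop("non-positive autosomal median ratio")
  ratio <- ratio / med

  structure(list(sample_id = sample$sample_id, ratio = ratio,
                 noise_sd = stats::mad(ratio[auto])),
            class = "NormalizedProfile")
}

#' Fit a PCA reference panel
#'
#' Second normalization step, part 1: learn the dominant higher-order
#' artifact directions from a panel of GC-corrected profiles. The
#' autosomal ratio matrix (samples × bins) is mean-centered and
#' decomposed by SVD; the top-k right singular directions are retained.
#' The panel is presumed CNV-sparse: individual CNVs are rare enough not
#' to dominate any leading component. Components are sign-fixed (largest
#' magnitude coordinate positive) so the fit is deterministic.
#'
#' @param profiles List of `NormalizedProfile`s on a shared bin grid.
#' @param model The shared `GenomeModel`.
#' @param k Number of components to retain (default 3); `k = 0` keeps the
#'   mean profile only.
#' @return A `ReferencePanel`: `mean_profile` (all mappable bins),
#'   `components` (autosomal bins × k orthonormal matrix), `k`,
#'   `auto_idx` (autosomal indices into the mappable-bin vector),
#'   `n_bins`.
#' @export
fit_reference_panel <- function(profiles, model, k = 3) {
  stopifnot(inherits(model, "GenomeModel"))
  n <- length(profiles)
  if (k >= n) stop("k (", k, ") must be smaller than the number of panel samples (", n, ")")
  if (n < k + 2) stop("need at least k + 2 panel samples")
  n_bins <- length(profiles[[1]]$ratio)
  X <- do.call(rbind, lapply(profiles, function(p) {
    if (length(p$ratio) != n_bins) stop("panel profiles on different grids")
    p$ratio
  }))
  auto_idx <- autosome_index(model)
  if (length(auto_idx) == 0) stop("no autosomal bins to fit the panel on")

  mean_profile <- colMeans(X)
  comp <- matrix(numeric(0), nrow = length(auto_idx), ncol = 0)
  if (k > 0) {
    Xa <- sweep(X[, auto_idx, drop = FALSE], 2, mean_profile[auto_idx])
    sv <- svd(Xa, nu = 0, nv = min(k, n - 1))
    tol <- max(sv$d) * 1e-8
    k_eff <- min(k, sum(sv$d > tol))
    if (k_eff < k)
      warning("panel rank ", k_eff, " below requested k = ", k,
              "; retaining ", k_eff, " component(s)")
    comp <- sv$v[, seq_len(k_eff), drop = FALSE]
    # deterministic sign: largest-magnitude coordinate positive
    for (j in seq_len(ncol(comp))) {
      i_max <- which.max(abs(comp[, j]))
      if (comp[i_max, j] < 0) comp[, j] <- -comp[, j]
    }
  }
  structure(list(mean_profile = mean_profile, components = comp,
                 k = ncol(comp), auto_idx = auto_idx, n_bins = n_bins),
            class = "ReferencePanel")
}

#' PCA projection-removal against a reference panel
#'
#' Second normalization step, part 2: on autosomal bins the profile's
#' departure from the panel mean is cleaned of its projection onto the
#' panel components,
#' `ratio' = 1 + (ratio - mean) - sum_k <ratio - mean, v_k> v_k`,
#' and the result is rescaled to autosomal median 1. X-chromosome bins
#' are scaled by the autosomal median only — the artifact model is fitted
#' on autosomes, and every subject is a pregnant woman, so X is expected
#' diploid but is deliberately left out of the projection. The profile's
#' `noise_sd` is recomputed as 1.4826 × MAD of the cleaned autosomal
#' ratios.
#'
#' @param profile A `NormalizedProfile`.
#' @param panel A [fit_reference_panel()] result on the same grid.
#' @return The denoised `NormalizedProfile`.
#' @export
pca_denoise <- function(profile, panel) {
  stopifnot(inherits(panel, "ReferencePanel"))
  if (length(profile$ratio) != panel$n_bins)
    stop("profile and panel bin grids differ (",
         length(profile$ratio), " vs ", panel$n_bins, ")")
  ratio <- profile$ratio
  ai <- panel$auto_idx
  centered <- ratio[ai] - panel$mean_profile[ai]
  if (panel$k > 0) {
    scores <- drop(crossprod(panel$components, centered))
    centered <- centered - drop(panel$components %*% scores)
  }
  out <- ratio
  out[ai] <- 1 + centered
  med <- stats::median(out[ai])
  if (med <= 0) stop("non-positive autosomal median after denoising")
  out <- out / med
  structure(list(sample_id = profile$sample_id, ratio = out,
                 noise_sd = stats::mad(out[ai])),
            class = "NormalizedProfile")
}

#' Two-step normalization of a whole cohort
#'
#' Runs [loess_gc_correct()] on every sample, then [pca_denoise()] with a
#' leave-one-out panel: each sample is projected against components
#' fitted on the other samples, so a sample's own CNVs can never be
#' subtracted away by its own panel membership.
#'
#' @param samples List of `BinnedSample`s (e.g. `cohort$samples`).
#' @param model The shared `GenomeModel`.
#' @param span LOESS span, default 0.3.
#' @param k Panel components, default 3.
#' @param leave_one_out If `FALSE`, one panel is fitted on the full
#'   cohort and applied to everyone (appropriate when the analysed sample
#'   is not part of the panel).
#' @return List of denoised `NormalizedProfile`s.
#' @export
normalize_cohort <- function(samples, model, span = 0.3, k = 3,
                             leave_one_out = TRUE) {
  profiles <- lapply(samples, loess_gc_correct, model = model, span = span)
  n <- length(profiles)
  if (n < 2) return(profiles)  # no panel possible: GC correction only
  if (k == 0 || n < k + 3) {
    panel <- fit_reference_panel(profiles, model, k = min(k, max(n - 2, 0)))
    return(lapply(profiles, pca_denoise, panel = panel))
  }
  if (!leave_one_out) {
    panel <- fit_reference_panel(profiles, model, k = k)
    return(lapply(profiles, pca_denoise, panel = panel))
  }
  lapply(seq_len(n), function(i) {
    panel <- fit_reference_panel(profiles[-i], model, k = k)
    pca_denoise(profiles[[i]], panel)
  })
}

#' @export
print.NormalizedProfile <- function(x, ...) {
  cat("NormalizedProfile", x$sample_id, "-", length(x$ratio),
      "bins, noise_sd =", signif(x$noise_sd, 4), "\n")
  invisible(x)
}
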