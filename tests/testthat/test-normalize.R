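test_that("a pure GC trend is flattened to ratio 1 everywhere", {
  gm <- mini_genome()
  bins <- gm$bins[gm$bins$mappable, ]
  # noiseless counts proportional to a smooth (linear) function of GC
  counts <- 1000 * (0.2 + bins$gc)
  s <- list(sample_id = "s1", counts = counts)
  p <- loess_gc_correct(s, gm)
  # exact away from the extreme edges of the GC support
  q <- stats::quantile(bins$gc, c(0.02, 0.98))
  interior <- bins$gc > q[1] & bins$gc < q[2]
  expect_lt(max(abs(p$ratio[interior] - 1)), 1e-6)
})

test_that("GC-flat counts pass through; a spike keeps ratio 2", {
  gm <- mini_genome(gc_profile = function(chrom, mid) rep(0.45, length(mid)))
  n <- sum(gm$bins$mappable)
  counts <- rep(10, n)
  counts[120] <- 20
  s <- list(sample_id = "s1", counts = counts)
  expect_warning(p <- loess_gc_correct(s, gm), "degenerate GC")
  expect_equal(p$ratio[120], 2, tolerance = 1e-9)
  expect_equal(stats::median(p$ratio), 1, tolerance = 1e-12)
})

test_that("LOESS removes a noisy quadratic GC bias (|corr| < 0.05)", {
  gm <- mini_genome(len = 2e7)
  sp <- cohort_spec(1, seed = 13, batch_rank = 0)
  co <- simulate_cohort(gm, sp)
  p <- loess_gc_correct(co$samples[[1]], gm)
  bins <- gm$bins[gm$bins$mappable, ]
  expect_lt(abs(stats::cor(p$ratio, bins$gc)), 0.05)
})

test_that("degenerate samples are rejected", {
  gm <- mini_genome()
  n <- sum(gm$bins$mappable)
  expect_error(loess_gc_correct(list(sample_id = "z", counts = rep(0, n)), gm),
               "all-zero")
  small <- build_genome_model(c(chrA = 1e6), 20000)
  expect_error(loess_gc_correct(list(sample_id = "z", counts = rep(1, 50)),
                                small),
               "at least 200")
})

test_that("panel of identical profiles degenerates to rank 0 beyond the mean", {
  gm <- mini_genome()
  n <- sum(gm$bins$mappable)
  prof <- structure(list(sample_id = "p", ratio = rep(1, n), noise_sd = 0.1),
                    class = "NormalizedProfile")
  profs <- list(prof, prof, prof, prof, prof)
  expect_warning(panel <- fit_reference_panel(profs, gm, k = 2),
                 "rank")
  expect_lt(panel$k, 2)
  expect_error(fit_reference_panel(profs, gm, k = 5), "smaller")
  p0 <- fit_reference_panel(profs, gm, k = 0)
  expect_equal(p0$k, 0)
  expect_equal(p0$mean_profile, rep(1, n))
})

test_that("fitted components recover the generator's batch subspace", {
  # conditions where the linearized low-rank model holds and the panel is
  # large enough for the spiked directions to concentrate
  gm <- mini_genome(len = 2e7)
  sp <- cohort_spec(100, seed = 19, gc_bias_strength = 0,
                    coverage_range = c(0.4, 0.5),
                    batch_rank = 2, batch_scale = 0.15, dispersion = 0.002)
  co <- simulate_cohort(gm, sp)
  profs <- lapply(co$samples, loess_gc_correct, model = gm)
  panel <- fit_reference_panel(profs, gm, k = 2)
  # principal angle between fitted and true loading subspaces < 10 degrees
  B_true <- qr.Q(qr(t(co$batch_loadings)))     # bins x 2 orthonormal
  B_fit <- panel$components                    # bins x 2 orthonormal
  cosines <- svd(crossprod(B_true, B_fit))$d
  max_angle <- acos(min(pmin(cosines, 1))) * 180 / pi
  expect_lt(max_angle, 10)
})

test_that("pca_denoise maps the panel mean to 1 and removes components", {
  gm <- mini_genome()
  n <- sum(gm$bins$mappable)
  set.seed(101)
  base <- 1 + 0.05 * sin(seq_len(n) / 40)
  profs <- lapply(1:8, function(i) {
    structure(list(sample_id = paste0("p", i),
                   ratio = base + stats::rnorm(n, 0, 0.02), noise_sd = 0.02),
              class = "NormalizedProfile")
  })
  panel <- fit_reference_panel(profs, gm, k = 1)
  # profile equal to the panel mean -> identically 1
  pm <- structure(list(sample_id = "m", ratio = panel$mean_profile,
                       noise_sd = 0.02), class = "NormalizedProfile")
  out <- pca_denoise(pm, panel)
  expect_lt(max(abs(out$ratio - 1)), 1e-12)
  # mean + 0.3 * v1 -> the component is removed, flat output
  v1 <- numeric(n); v1[panel$auto_idx] <- panel$components[, 1]
  p1 <- structure(list(sample_id = "v", ratio = panel$mean_profile + 0.3 * v1,
                       noise_sd = 0.02), class = "NormalizedProfile")
  out1 <- pca_denoise(p1, panel)
  expect_lt(max(abs(out1$ratio - 1)), 1e-12)
  # grid mismatch rejected
  bad <- structure(list(sample_id = "b", ratio = rep(1, n - 1),
                        noise_sd = 0.02), class = "NormalizedProfile")
  expect_error(pca_denoise(bad, panel), "grids differ")
})

test_that("denoising is idempotent when recentering is neutral", {
  gm <- mini_genome()
  n <- sum(gm$bins$mappable)
  set.seed(202)
  v <- stats::rnorm(n); v <- v / sqrt(sum(v^2))
  # paired +/- scores make the panel mean exactly 1
  profs <- lapply(c(-2, -1, 1, 2, -1.5, 1.5), function(a)
    structure(list(sample_id = paste0("p", a), ratio = 1 + a * 0.1 * v,
                   noise_sd = 0.02), class = "NormalizedProfile"))
  panel <- fit_reference_panel(profs, gm, k = 1)
  expect_lt(max(abs(panel$mean_profile - 1)), 1e-12)
  # sparse CNV-like bump, made orthogonal to the component within its own
  # support so the off-bump bins stay exactly zero (median-neutral)
  v1 <- numeric(n); v1[panel$auto_idx] <- panel$components[, 1]
  sup <- 101:120
  bump <- numeric(n)
  bump[sup] <- 0.5 - v1[sup] * (0.5 * sum(v1[sup])) / sum(v1[sup]^2)
  stopifnot(abs(sum(bump * v1)) < 1e-12)
  prof <- structure(list(sample_id = "s", ratio = 1 + 0.3 * v + bump,
                         noise_sd = 0.02), class = "NormalizedProfile")
  d1 <- pca_denoise(prof, panel)
  d2 <- pca_denoise(d1, panel)
  expect_lt(max(abs(d2$ratio - d1$ratio)), 1e-10)
  # and the bump survived denoising
  expect_equal(mean(d1$ratio[sup] - 1), mean(bump[sup]), tolerance = 1e-10)
})

test_that("X bins are median-scaled but never projected", {
  gm <- build_genome_model(c(chrA = 4e6, chrX = 2e6), 20000)
  n <- nrow(gm$bins)
  auto <- is_autosome(gm$bins$chrom)
  set.seed(33)
  profs <- lapply(1:6, function(i)
    structure(list(sample_id = paste0("p", i),
                   ratio = 1 + stats::rnorm(n, 0, 0.03), noise_sd = 0.03),
              class = "NormalizedProfile"))
  panel <- fit_reference_panel(profs, gm, k = 1)
  prof <- profs[[1]]
  out <- pca_denoise(prof, panel)
  med <- stats::median((1 + (prof$ratio - panel$mean_profile)[auto] -
    panel$components[, 1] *
      sum((prof$ratio - panel$mean_profile)[auto] * panel$components[, 1])))
  expect_equal(out$ratio[!auto], prof$ratio[!auto] / med, tolerance = 1e-12)
})
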