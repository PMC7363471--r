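test_that("static correlation matches the hand-expanded definition", {
  x <- c(1.2, -0.4, 0.9, 2.2, -1.5)
  y <- c(0.3, 0.1, -0.8, 1.9, 0.4)
  m <- cbind(a = x, b = y, c = -x)
  sp <- static_pcc(m)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(sp["a", "b"], hand, tolerance = 1e-12)
  expect_equal(diag(unclass(sp)), c(a = 1, b = 1, c = 1))
  expect_equal(sp["a", "c"], -1, tolerance = 1e-12)
  expect_equal(unclass(sp), t(unclass(sp)))
  expect_warning(static_pcc(cbind(x, rep(1, 5))), "zero-variance")
  expect_error(static_pcc(m[1:2, ]), "3 time points")
})

test_that("sPCC comparison correlates strictly-upper triangles", {
  set.seed(2)
  A <- static_pcc(matrix(rnorm(80), 20, 4))
  expect_equal(compare_spcc(A, A), 1)
  B <- -unclass(A); diag(B) <- 1
  expect_equal(compare_spcc(A, B), -1)
  # 4x4 brute force
  C2 <- static_pcc(matrix(rnorm(80), 20, 4))
  iu <- upper.tri(A)
  expect_equal(compare_spcc(A, C2), stats::cor(A[iu], C2[iu]),
               tolerance = 1e-12)
  expect_error(compare_spcc(A, static_pcc(matrix(rnorm(60), 20, 3))),
               "size")
})

test_that("sliding-window FCD reproduces the 328-window arithmetic", {
  set.seed(4)
  m <- matrix(rnorm(344 * 10), 344, 10)
  attr(m, "tr") <- 3.6
  fcd <- sliding_window_fcd(m)  # 60 s windows, 1-TR step
  expect_equal(attr(fcd, "window_len"), 17)   # ceiling(60 / 3.6)
  expect_equal(dim(fcd), c(328, 328))
  expect_equal(diag(unclass(fcd)), rep(1, 328))
  expect_equal(unclass(fcd), t(unclass(fcd)))
  expect_true(all(abs(fcd) <= 1 + 1e-12))
  # stationary iid input: far-apart windows are near-uncorrelated
  far <- upper_triangle(fcd, exclude_band = 17)
  expect_lt(abs(stats::median(far)), 0.1)
  expect_lt(stats::quantile(abs(far), 0.9), 0.35)
  expect_error(sliding_window_fcd(m[1:10, ], tr = 3.6), "shorter")
})

test_that("K-S distance equals the brute-force ECDF supremum", {
  expect_equal(ks_distance(c(1, 2, 3), c(2, 3, 4)), 1 / 3)
  expect_equal(ks_distance(1:5, 1:5), 0)
  expect_equal(ks_distance(1:5, 6:10), 1)  # disjoint supports
  set.seed(6)
  for (k in 1:20) {
    x <- rnorm(sample(3:40, 1)); y <- rnorm(sample(3:40, 1), mean = runif(1))
    expect_equal(ks_distance(x, y), oracle_ks(x, y), tolerance = 1e-12)
    expect_equal(ks_distance(x, y),
                 unname(suppressWarnings(stats::ks.test(x, y)$statistic)),
                 tolerance = 1e-12)
  }
  expect_error(ks_distance(numeric(0), 1:3), "non-empty")
})

test_that("instantaneous phase matches analytic-signal closed forms", {
  t <- seq(0, 100, by = 0.5)
  w <- 2 * pi * 0.1
  m <- cbind(cos(w * t), sin(w * t), -cos(w * t))
  ph <- instantaneous_phase(m, trim = 0.1)
  # linear unwrap slope equals the angular frequency
  slopes <- apply(ph, 2, function(p) stats::median(diff(p) %% (2 * pi)))
  expect_equal(unname(slopes), rep(w * 0.5, 3), tolerance = 1e-3)
  # sin lags cos by pi/2; -cos is offset by pi
  d12 <- (ph[, 1] - ph[, 2]) %% (2 * pi)
  expect_equal(stats::median(d12), pi / 2, tolerance = 1e-2)
  d13 <- (ph[, 1] - ph[, 3]) %% (2 * pi)
  expect_equal(stats::median(d13), pi, tolerance = 1e-2)
  expect_error(instantaneous_phase(cbind(rep(1, 50), rnorm(50))), "constant")
})

test_that("Kuramoto order parameter spans its boundary cases", {
  expect_equal(kuramoto_order(matrix(c(0.7, 0.7, 0.7), 1)), 1)
  # phases uniformly spaced on the circle cancel exactly
  expect_lt(kuramoto_order(matrix(seq(0, 2 * pi, length.out = 6)[-6], 1)),
            1e-12)
  expect_lt(kuramoto_order(matrix(c(0, pi), 1)), 1e-12)
  expect_error(kuramoto_order(matrix(0.3, 2, 1)), "2 regions")
  set.seed(1)
  R <- kuramoto_order(matrix(runif(300, -pi, pi), 100, 3))
  expect_true(all(R >= 0 & R <= 1))
})

test_that("coherence and metastability are the mean and SD of R(t)", {
  cm <- coherence_metastability(rep(0.4, 50))
  expect_equal(cm$coherence, 0.4)
  expect_equal(cm$metastability, 0)
  cm2 <- coherence_metastability(rep(c(0, 1), 25))
  expect_equal(cm2$coherence, 0.5)
  expect_error(coherence_metastability(numeric(0)), "empty")
})

test_that("coarse-graining is block averaging with floor length", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_identical(coarse_grain(x, 1), x)
  expect_equal(coarse_grain(x, 2), c(1.5, 3.5, 5.5))
  expect_equal(coarse_grain(x, 3), c(2, 5))
  expect_length(coarse_grain(rnorm(10), 3), 3)
  expect_error(coarse_grain(x, 7), "exceeds")
  expect_error(coarse_grain(x, 0), "positive")
})

test_that("sample entropy equals the brute-force template counter", {
  set.seed(9)
  for (k in 1:12) {
    n <- sample(c(30, 50, 80, 120, 200), 1)
    m <- sample(1:2, 1)
    x <- as.numeric(arima.sim(list(ar = runif(1, -0.5, 0.8)), n))
    r <- 0.35 * stats::sd(x)
    expect_equal(sample_entropy(x, m = m, r = r),
                 oracle_sampen(x, m = m, r = r), tolerance = 1e-12)
  }
  # white noise is less predictable than a pure tone of the same length
  set.seed(10)
  noise <- rnorm(300)
  tone <- sin(2 * pi * 0.05 * seq_len(300))
  expect_gt(sample_entropy(noise), sample_entropy(tone))
  # constant series: zero tolerance, degenerate
  const <- sample_entropy(rep(2, 60))
  expect_false(is.finite(const))
  expect_true(isTRUE(attr(const, "degenerate")))
})

test_that("MSE profiles follow the multiscale conventions", {
  set.seed(11)
  m <- matrix(rnorm(400 * 2), 400, 2)
  prof <- mse_profile(m)
  expect_equal(dim(prof), c(2, 13))          # 13 scales per region
  expect_equal(attr(prof, "scales"), 1:13)
  # tolerance fixed from the scale-1 SD: scale-1 entry equals plain SampEn
  expect_equal(unname(unclass(prof)[1, 1]),
               as.numeric(sample_entropy(m[, 1], r = 0.35 * sd(m[, 1]))))
  # white noise loses entropy with scale; an AR(1) signal stays flatter
  white <- rnorm(1200)
  ar <- as.numeric(arima.sim(list(ar = 0.9), 1200))
  pw <- unclass(mse_profile(cbind(white)))[1, ]
  pa <- unclass(mse_profile(cbind(ar)))[1, ]
  expect_lt(pw[13] / pw[1], 0.6)
  expect_gt(pa[13] / pa[1], pw[13] / pw[1])
  expect_error(mse_profile(m[1:50, ]), "scale 6")
})

test_that("RMSD is the root mean squared elementwise difference", {
  p1 <- matrix(1:6 / 2, 2, 3)
  expect_equal(rmsd(p1, p1), 0)
  expect_equal(rmsd(p1, p1 + 0.7), 0.7)
  p2 <- matrix(c(0.1, 0.5, 0.3, 0.9, 0.2, 0.4), 2, 3)
  expect_equal(rmsd(p1, p2), sqrt(mean((p1 - p2)^2)), tolerance = 1e-12)
  expect_error(rmsd(p1, matrix(0, 3, 2)), "shape")
})

test_that("FC metrics are invariant to per-region affine rescaling", {
  set.seed(12)
  m <- matrix(rnorm(120 * 4), 120, 4)
  attr(m, "tr") <- 3.6
  m2 <- sweep(sweep(m, 2, c(2, 0.5, 3, 10), "*"), 2, c(1, -4, 0.3, 2), "+")
  attr(m2, "tr") <- 3.6
  expect_equal(unclass(static_pcc(m2)), unclass(static_pcc(m)),
               tolerance = 1e-10)
  expect_equal(unclass(sliding_window_fcd(m2)),
               unclass(sliding_window_fcd(m)), tolerance = 1e-8)
})

test_that("Global Similarity normalises to [1,2] and preserves the argmin", {
  set.seed(13)
  fits <- tibble::tibble(corr = runif(10, -0.2, 0.9), ks = runif(10),
                         d_coh = runif(10, 0, 0.3),
                         d_meta = runif(10, 0, 0.2),
                         rmsd_mse = runif(10, 0, 0.6))
  # a perfect-fit point dominates the sweep
  fits$corr[4] <- 1; fits$ks[4] <- 0; fits$d_coh[4] <- 0
  fits$d_meta[4] <- 0; fits$rmsd_mse[4] <- 0
  g <- global_similarity(fits)
  expect_true(all(g$gs >= 1 - 1e-12 & g$gs <= 2 + 1e-12))
  expect_equal(attr(g, "optimum"), 4)
  expect_equal(g$gs[4], 1)
  # normalisation preserves the raw-score ranking
  expect_equal(order(g$gs), order(g$gs_raw))
  # raw score depends quadratically on the entropy distance only
  f2 <- fits; f2$rmsd_mse[1] <- 2 * fits$rmsd_mse[1]
  g2 <- global_similarity(f2)
  expect_equal(g2$gs_raw[1] - g$gs_raw[1],
               f2$rmsd_mse[1]^2 - fits$rmsd_mse[1]^2, tolerance = 1e-12)
  # degenerate sweep: warning, all ones
  same <- fits[c(1, 1, 1), ]
  expect_warning(gd <- global_similarity(same), "degenerate")
  expect_equal(gd$gs, rep(1, 3))
  expect_error(global_similarity(fits[1, ]), "2 sweep points")
})
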