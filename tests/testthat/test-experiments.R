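zones4 <- function(regions = paste0("R", 1:4)) {
  tibble::tibble(region = regions,
                 zone = c("EZ_IZ1", "PZ_IZ2", "NIZ", "NIZ")[seq_along(regions)])
}

test_that("epileptogenicity maps encode the three scenarios", {
  z <- zones4()
  sf <- build_epi_map(z, "spike_free", a = 1.8)
  expect_equal(sf$p, rep(0.1, 4))
  expect_equal(sf$x0, rep(-2.5, 4))
  expect_equal(sf$a, rep(1.8, 4))

  sp <- build_epi_map(z, "spiking")
  expect_equal(sp$p, c(0.9, 0.7, 0.1, 0.1))
  expect_equal(sp$x0, c(-2.07, -2.25, -2.55, -2.55))
  # PZ/NIZ defaults are the stated offsets below the seizure threshold
  expect_equal(sp$x0[2], -2.05 - 0.2)
  expect_equal(sp$x0[3], -2.05 - 0.5)
  expect_equal(sp$a, rep(1.74, 4))

  hy <- build_epi_map(z, "hyperexcitable", a_hyper = 2.1)
  expect_equal(hy$a, c(2.1, 2.1, 1.74, 1.74))
  expect_equal(hy$p, rep(0.1, 4))

  # zone aliases and overrides
  alias <- build_epi_map(tibble::tibble(region = "R1", zone = "EZ"),
                         "spiking")
  expect_equal(alias$p, 0.9)
  ovr <- build_epi_map(z, "spiking", p_zone = c(NIZ = 0.2))
  expect_equal(ovr$p[3:4], c(0.2, 0.2))

  expect_error(build_epi_map(z, "bursting"), "arg")
  expect_error(build_epi_map(tibble::tibble(region = "R1", zone = "XX"),
                             "spiking"), "unknown zone")
})

test_that("zones files round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(region = c("R1", "R2"), zone = c("EZ", "NIZ")),
                   path, row.names = FALSE)
  z <- read_zones(path)
  expect_equal(z$zone, c("EZ_IZ1", "NIZ"))
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_zones(bad), "columns")
})

test_that("rank-sum comparison matches the rank arithmetic oracle", {
  # identical samples: no effect
  same <- compare_connectivity(1:10 / 10, 1:10 / 10)
  expect_equal(same$z, 0, tolerance = 1e-12)
  expect_false(same$significant)

  # large shift with n = 20 each: clearly significant
  set.seed(20)
  x <- rnorm(20); y <- rnorm(20) + 5
  res <- compare_connectivity(x, y)
  expect_gt(abs(res$z), 1.96)
  expect_true(res$significant)
  expect_equal(res$direction, -1)

  # z and p agree with the normal-approximation rank-sum test
  for (k in 1:10) {
    a <- rnorm(sample(5:25, 1)); b <- rnorm(sample(5:25, 1), runif(1))
    ours <- compare_connectivity(a, b)
    ref <- suppressWarnings(stats::wilcox.test(a, b, correct = FALSE,
                                               exact = FALSE))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
    # significance at p < 0.05 coincides with |z| > 1.96
    expect_identical(ours$significant, abs(ours$z) > 1.96)
    expect_identical(unname(ours$p_value < 0.05), unname(ours$significant))
  }

  expect_error(compare_connectivity(1, 1:5), "at least 2")
})

test_that("null experiment: identical map and seed give a perfect fit", {
  conn <- toy_connectome(4)
  cfg <- short_config(duration = 140, seed = 31)
  map <- build_epi_map(tibble::tibble(region = rownames(conn), zone = "NIZ"),
                       "spike_free")
  mk <- function() {
    tr <- simulate_network(conn, map, coupling_parameters(k_rs = 10), cfg)
    neural_to_bold(tr)
  }
  b1 <- mk(); b2 <- mk()
  f <- fit_summary(b1, b2, scales = 1:3)
  expect_equal(f$corr, 1)
  expect_equal(f$ks, 0)
  expect_equal(f$d_coh, 0)
  expect_equal(f$d_meta, 0)
  expect_equal(f$rmsd_mse, 0)
})

test_that("sweep cells record their seeds and reproduce bit for bit", {
  conn <- toy_connectome(4)
  cfg <- short_config(duration = 160, seed = 300)
  ref <- pseudo_empirical_bold(conn, a = 1.74, k_rs = 10, seed = 999,
                               config = cfg)
  sw <- working_point_sweep(conn, ref, a_grid = 1.74, krs_grid = c(0, 10),
                            config = cfg, scales = 1:2)
  expect_equal(nrow(sw), 2)
  expect_equal(sw$seed, c(301, 302))
  expect_true(all(!sw$failed))
  expect_true(all(sw$gs >= 1 & sw$gs <= 2))
  # recompute one cell from its recorded seed
  cfg2 <- cfg; cfg2$seed <- sw$seed[2]
  map <- build_epi_map(tibble::tibble(region = rownames(conn), zone = "NIZ"),
                       "spike_free", a = sw$a[2])
  tr <- simulate_network(conn, map, coupling_parameters(k_rs = sw$k_rs[2]),
                         cfg2)
  f <- fit_summary(neural_to_bold(tr), ref, scales = 1:2)
  expect_equal(f$corr, sw$corr[2], tolerance = 1e-12)
  expect_equal(f$ks, sw$ks[2], tolerance = 1e-12)
  expect_equal(f$rmsd_mse, sw$rmsd_mse[2], tolerance = 1e-12)
})

test_that("a single-cell sweep is trivially its own optimum", {
  conn <- toy_connectome(4)
  cfg <- short_config(duration = 160, seed = 55)
  ref <- pseudo_empirical_bold(conn, a = 1.74, k_rs = 10, seed = 56,
                               config = cfg)
  sw <- working_point_sweep(conn, ref, a_grid = 1.74, krs_grid = 10,
                            config = cfg, scales = 1:2)
  expect_equal(nrow(sw), 1)
  expect_equal(attr(sw, "optimum"), 1L)
  expect_equal(sw$gs, 1)
})

test_that("stronger diffusive coupling raises BOLD phase coherence", {
  conn <- fixture("conn8", synthetic_connectome(8, seed = 42))
  cfg <- short_config(duration = 320, seed = 5)
  coh <- vapply(c(0, 30), function(krs) {
    b <- pseudo_empirical_bold(conn, a = 1.74, k_rs = krs, seed = 5,
                               config = cfg, global_regress = FALSE)
    coherence_metastability(kuramoto_order(instantaneous_phase(b)))$coherence
  }, numeric(1))
  expect_gt(coh[2], coh[1] + 0.2)
})

test_that("glance and tidy summarise sweeps and matrices", {
  conn <- toy_connectome(3)
  cfg <- short_config(duration = 160, seed = 81)
  ref <- pseudo_empirical_bold(conn, 1.74, 5, seed = 82, config = cfg)
  sw <- working_point_sweep(conn, ref, a_grid = c(1.7, 1.74),
                            krs_grid = 5, config = cfg, scales = 1:2)
  gl <- glance(sw)
  expect_equal(gl$n_cells, 2)
  expect_true(gl$a_opt %in% c(1.7, 1.74))

  td <- tidy(static_pcc(matrix(rnorm(60), 20, 3)))
  expect_equal(nrow(td), 9)
  expect_named(td, c("row", "col", "value"))
})
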