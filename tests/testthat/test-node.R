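test_that("node drift matches an independent transcription of the equations", {
  set.seed(42)
  for (k in 1:8) {
    st <- c(runif(1, -2, 1), runif(1, -15, 2), runif(1, 2, 5),
            runif(1, -2, 1), runif(1, -1, 2), runif(1, -1, 1),
            runif(1, -2, 2), runif(1, -2, 2))
    x0 <- runif(1, -2.6, -1.8); a <- runif(1, 1.3, 2.2)
    b2 <- runif(1, 1, 6); cz <- runif(1, -1, 1); cx <- runif(1, -5, 5)
    pars <- node_parameters(x0 = x0, a = a, p = 0.5, b2 = b2)
    got <- node_drift(st, pars, coupling_z = cz, coupling_x3 = cx)
    expect_equal(unname(got), oracle_drift(st, x0, a, 0.5, b2, cz, cx),
                 tolerance = 1e-12)
  }
})

test_that("node drift rejects non-finite states", {
  expect_error(node_drift(c(NA, rep(0, 7))), "blow-up|finite")
  expect_error(node_drift(c(Inf, rep(0, 7))), "blow-up|finite")
})

test_that("fixed point of the subcritical node has vanishing drift", {
  pars <- node_parameters(x0 = -2.5, a = 1.5)
  fp <- node_fixed_point(pars)
  expect_lt(sqrt(sum(node_drift(fp, pars)^2)), 1e-10)
  # the rest state is interictal: x1 below the firing branch, z near 4(x1-x0)
  expect_lt(fp["x1"], 0)
  expect_equal(unname(fp["z"]), unname(4 * (fp["x1"] - pars$x0)),
               tolerance = 1e-8)
})

test_that("subcritical noise-free node settles to its equilibrium", {
  pars <- node_parameters(x0 = -2.5, a = 1.5)
  fp <- node_fixed_point(pars)
  init <- fp + c(0.05, 0, 0, 0.05, 0, 0, 0.2, 0)
  tr <- simulate_node(pars, integration_config(duration = 120, discard = 0,
                                               noise_x2y2 = 0, noise_x3 = 0,
                                               seed = 1),
                      init = init, store_states = TRUE)
  final <- tr$states[dim(tr$states)[1], 1, ]
  expect_equal(unname(final), unname(fp), tolerance = 1e-3)
})

test_that("mixed output obeys the boundary and linearity contracts", {
  st <- c(x1 = -1.3, y1 = -8, z = 3, x2 = -1, y2 = 0.4, g = -0.1,
          x3 = 0.7, y3 = 0.2)
  # p = 0: no epileptiform contribution
  expect_equal(mixed_output(st, 0), unname(st["x3"]))
  # p = 1: no healthy contribution
  expect_equal(mixed_output(st, 1), unname(st["x2"] - st["x1"]))
  # affine in p between the boundary outputs
  u0 <- mixed_output(st, 0); u1 <- mixed_output(st, 1)
  for (p in c(0.2, 0.5, 0.85))
    expect_equal(mixed_output(st, p), (1 - p) * u0 + p * u1,
                 tolerance = 1e-12)
  expect_error(mixed_output(st, 1.2), "\\[0, 1\\]")
})

test_that("network drift couples nodes exactly as the weighted differences", {
  # identical states across nodes: both coupling pathways vanish
  conn <- toy_connectome(3)
  map <- build_epi_map(tibble::tibble(region = rownames(conn), zone = "NIZ"),
                       "spike_free")
  st1 <- c(-1.4, -9, 3.1, -1.1, 0.2, -0.14, 0.5, 0.8)
  states <- matrix(st1, 8, 3)
  nd <- network_drift(states, conn, map,
                      coupling_parameters(k_s = 0.3, k_rs = 12))
  iso <- node_drift(st1, node_parameters(x0 = map$x0[1], a = map$a[1],
                                         p = map$p[1], b2 = map$b2[1]))
  for (i in 1:3) expect_equal(unname(nd[, i]), unname(iso), tolerance = 1e-12)

  # zero matrix: network drift equals independent single-node drifts
  zeroC <- connectome(matrix(0, 3, 3), normalise = FALSE)
  states2 <- states + matrix(rnorm(24, sd = 0.05), 8, 3)
  nd0 <- network_drift(states2, zeroC, map, coupling_parameters(0.3, 12))
  for (i in 1:3)
    expect_equal(unname(nd0[, i]),
                 unname(node_drift(states2[, i],
                                   node_parameters(x0 = map$x0[i],
                                                   a = map$a[i],
                                                   p = map$p[i],
                                                   b2 = map$b2[i]))),
                 tolerance = 1e-12)

  # 3-node line graph, hand-set states: coupling equals the weighted sums
  C <- matrix(0, 3, 3); C[1, 2] <- C[2, 1] <- 0.5; C[2, 3] <- C[3, 2] <- 1
  line <- connectome(C, normalise = FALSE)
  ks <- 0.1; krs <- 7
  ndl <- network_drift(states2, line, map, coupling_parameters(ks, krs))
  for (i in 1:3) {
    cz <- ks * sum(C[i, ] * (states2[1, ] - states2[1, i]))
    cx <- krs * sum(C[i, ] * (states2[7, ] - states2[7, i]))
    expect_equal(unname(ndl[, i]),
                 oracle_drift(states2[, i], map$x0[i], map$a[i], map$p[i],
                              map$b2[i], cz, cx),
                 tolerance = 1e-12)
  }

  expect_error(network_drift(states[, 1:2], conn, map,
                             coupling_parameters()), "8 x n")
  expect_error(network_drift(states, conn, map[1:2, ],
                             coupling_parameters()), "map")
})
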