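p0 <- model_params()
plat0 <- platform_params()

test_that("pTRE flux hits the Hill anchors", {
  expect_equal(ptre_flux(0, 10, p0), 10 * p0$a_f)
  expect_equal(ptre_flux(1e9, 10, p0), 10 * p0$b_f, tolerance = 1e-6)
  for (n in c(1, 2, 3.5)) {
    p <- model_params(n_dox = n)
    expect_equal(ptre_flux(p$K_dox, 10, p), 10 * (p$a_f + p$b_f) / 2)
  }
  expect_error(ptre_flux(-1, 10, p0), ">= 0")
})

test_that("shRNA flux follows the topology definitions", {
  expect_equal(shrna_flux(c(0, 50, 225), 20, "NO_SHRNA", p0), c(0, 0, 0))
  expect_equal(shrna_flux(0, 20, "CONSTANT", p0),
               shrna_flux(225, 20, "CONSTANT", p0))
  expect_equal(shrna_flux(1e9, 20, "FEEDFORWARD", p0), 0, tolerance = 1e-6)
  expect_gt(shrna_flux(0, 20, "FEEDFORWARD", p0),
            shrna_flux(225, 20, "FEEDFORWARD", p0))
  expect_error(shrna_flux(0, 20, "WHATEVER", p0))
})

test_that("titration closed forms: limits and numeric equilibrium", {
  expect_equal(titrate_flux(10, 0, 5), 10)
  expect_equal(titrate_flux(10, 4, 1e-14), 6, tolerance = 1e-9)
  expect_equal(titrate_flux(4, 10, 1e-14), 0, tolerance = 1e-9)
  expect_equal(titrate_flux(10, 10, 5), 5)
  expect_equal(titrate_flux(10, 4, 0), 6)
  expect_equal(titrate_flux(4, 10, 0), 0)
  set.seed(31)
  m <- 10^runif(300, -2, 3); s <- 10^runif(300, -2, 3)
  K <- 10^runif(300, -3, 2)
  phi <- titrate_flux(m, s, K)
  oracle <- mapply(function(m, s, K)
    stats::uniroot(function(x) x^2 + (s + K - m) * x - K * m,
                   c(0, m + K + 1), tol = 1e-14)$root, m, s, K)
  expect_lt(max(abs(phi - oracle) / pmax(oracle, 1e-300)), 1e-8)
  # bounds: 0 <= phi <= m and phi >= m - s
  expect_true(all(phi >= pmax(0, m - s) - 1e-12) && all(phi <= m + 1e-12))
})

test_that("single-cell degenerate regimes behave", {
  dose <- list(copies_flp = 50, copies_shrna = 20, copies_reporter = 80,
               copies_cfp = 40, delay_h = 5)
  tg <- seq(0, 96, by = 8)
  p_noleak <- model_params(a_f = 0)
  tr <- simulate_cell(dose, 0, "CONSTANT", p_noleak, plat0, tg)
  expect_equal(max(abs(tr$F)), 0)
  expect_equal(max(tr$r), 0)
  expect_equal(max(tr$ofp), 0)
  p_norec <- model_params(c = 0)
  tr2 <- simulate_cell(dose, 225, "CONSTANT", p_norec, plat0, tg)
  expect_equal(max(tr2$r), 0)
  expect_equal(max(tr2$ofp), 0)
  expect_gt(max(tr2$F), 0)
})

test_that("over-repression suppresses output below 1% of the no-shRNA level", {
  dose <- list(copies_flp = 50, copies_shrna = 200, copies_reporter = 80,
               copies_cfp = 40, delay_h = 5)
  p_over <- model_params(b_s = 10, K_d = 0.1)
  tg <- c(0, 96)
  free <- simulate_cell(dose, 225, "NO_SHRNA", p_over, plat0, tg)
  rep_ <- simulate_cell(dose, 225, "CONSTANT", p_over, plat0, tg)
  expect_lt(rep_$ofp[2], 0.01 * free$ofp[2])
})

test_that("recombined fraction is monotone in [0,1] across random parameterizations", {
  set.seed(32)
  tg <- seq(0, 96, by = 4)
  for (i in 1:8) {
    p <- model_params(a_f = runif(1, 0, 0.1), b_f = runif(1, 0.5, 4),
                      b_s = runif(1, 0, 3), K_d = 10^runif(1, -2, 1),
                      c = 10^runif(1, -5, -3), h_rec = sample(1:2, 1))
    dose <- list(copies_flp = sample(1:200, 1), copies_shrna = sample(0:200, 1),
                 copies_reporter = 100, copies_cfp = 50, delay_h = runif(1, 0, 12))
    tr <- simulate_cell(dose, sample(c(0, 80, 225), 1),
                        sample(c("CONSTANT", "FEEDFORWARD"), 1), p, plat0, tg)
    expect_true(all(tr$r >= 0 & tr$r <= 1))
    expect_true(all(diff(tr$r) >= -1e-6))  # solver tolerance headroom
    expect_true(all(tr$ofp >= 0))
  }
})

test_that("vectorized population solver agrees with the adaptive ODE path", {
  set.seed(33)
  doses <- data.frame(copies_flp = c(90, 20, 150), copies_shrna = c(15, 40, 5),
                      copies_reporter = c(130, 60, 200), copies_cfp = c(65, 30, 90),
                      delay_h = c(6, 2.5, 9.1))
  m0 <- ptre_flux(225, doses$copies_flp, p0)
  s0 <- shrna_flux(225, doses$copies_shrna, "CONSTANT", p0)
  dyn <- digitizerlab:::cell_dynamics(doses, m0, s0, p0, plat0, 48, n_grid = 481)
  for (i in 1:3) {
    tr <- simulate_cell(as.list(doses[i, ]), 225, "CONSTANT", p0, plat0, c(0, 48))
    expect_equal(dyn$ofp[i], tr$ofp[2], tolerance = 5e-3)
    expect_equal(dyn$ifp[i], tr$ifp[2], tolerance = 5e-3)
    expect_equal(dyn$r[i], tr$r[2], tolerance = 5e-3)
  }
})

test_that("increasing shRNA flux never increases output", {
  dose <- list(copies_flp = 80, copies_shrna = 30, copies_reporter = 100,
               copies_cfp = 50, delay_h = 4)
  tg <- seq(0, 96, by = 4)
  prev <- simulate_cell(dose, 80, "CONSTANT", model_params(b_s = 0), plat0, tg)
  for (bs in c(0.5, 1, 2, 5)) {
    cur <- simulate_cell(dose, 80, "CONSTANT", model_params(b_s = bs), plat0, tg)
    expect_true(all(cur$ofp <= prev$ofp + 1e-9))
    prev <- cur
  }
})

test_that("zero shRNA copies make all topologies identical", {
  dose <- list(copies_flp = 80, copies_shrna = 0, copies_reporter = 100,
               copies_cfp = 50, delay_h = 4)
  tg <- seq(0, 96, by = 8)
  a <- simulate_cell(dose, 80, "NO_SHRNA", p0, plat0, tg)
  b <- simulate_cell(dose, 80, "CONSTANT", p0, plat0, tg)
  d <- simulate_cell(dose, 80, "FEEDFORWARD", p0, plat0, tg)
  expect_equal(b$ofp, a$ofp)
  expect_equal(d$ofp, a$ofp)
})

test_that("QSS reduction tracks the explicit fast/slow reference model", {
  set.seed(34)
  for (i in 1:4) {
    p <- model_params(b_f = runif(1, 1, 3), b_s = runif(1, 0.5, 2),
                      K_d = runif(1, 0.3, 3))
    dose <- list(copies_flp = sample(20:120, 1), copies_shrna = sample(5:60, 1),
                 copies_reporter = 120, copies_cfp = 50, delay_h = 5)
    a <- simulate_cell(dose, 80, "CONSTANT", p, plat0, c(0, 96))
    b <- simulate_cell_unreduced(dose, 80, "CONSTANT", p, plat0, c(0, 96))
    expect_equal(a$ofp[2], b$ofp[2], tolerance = 0.02)
  }
})

test_that("dimensionless groups scale as defined and predict trajectory collapse", {
  d <- list(copies_flp = 80, copies_shrna = 0, copies_reporter = 100,
            copies_cfp = 50, delay_h = 0)
  g <- nondimensional_groups(p0, d)
  expect_equal(nondimensional_groups(model_params(K_d = 2 * p0$K_d), d)$eKd,
               2 * g$eKd)
  expect_equal(nondimensional_groups(model_params(b_f = 2 * p0$b_f), d)$eKd,
               g$eKd / 2)
  # identical groups (with b_s co-scaled) => identical r(delta_F t)
  p2 <- model_params(b_f = 2 * p0$b_f, K_d = 2 * p0$K_d, a_f = 2 * p0$a_f,
                     b_s = 2 * p0$b_s, c = p0$c / 2)
  g2 <- nondimensional_groups(p2, d)
  expect_equal(g2$eKd, g$eKd)
  expect_equal(g2$scaled_recombination, g$scaled_recombination)
  expect_equal(g2$basal_fraction, g$basal_fraction)
  tg <- seq(0, 96, by = 8)
  r1 <- simulate_cell(d, 225, "NO_SHRNA", p0, plat0, tg)$r
  r2 <- simulate_cell(d, 225, "NO_SHRNA", p2, plat0, tg)$r
  expect_equal(r1, r2, tolerance = 1e-6)
})

test_that("fluorescence-to-copy inversion round-trips and guards its domain", {
  cop <- 1:100
  cfp <- plat0$gamma * cop * (48 - plat0$mu_delay)
  expect_identical(copies_from_fluorescence(cfp, 48, plat0), as.integer(cop))
  expect_identical(copies_from_fluorescence(0, 48, plat0), 0L)
  expect_error(copies_from_fluorescence(100, plat0$mu_delay, plat0),
               "undefined")
})

test_that("population simulation is seed-deterministic and respects null circuits", {
  a <- simulate_population(300, dose_map(35, 5), 225, "CONSTANT", seed = 9)
  b <- simulate_population(300, dose_map(35, 5), 225, "CONSTANT", seed = 9)
  expect_identical(a, b)
  null <- simulate_population(400, dose_map(0, 0), 225, "CONSTANT", seed = 10)
  for (ch in c("ifp", "ofp")) {
    gm <- geometric_stats(channel_values(null, ch))$geomean
    expect_equal(gm, uptake_params()$autofluorescence_mu, tolerance = 0.25)
  }
  ind <- simulate_population(800, dose_map(35, 5), 225, "CONSTANT", seed = 11)
  uni <- simulate_population(800, dose_map(35, 5), 0, "CONSTANT", seed = 12)
  expect_gt(geometric_stats(channel_values(gate_top_fraction(ind), "ofp"))$geomean,
            geometric_stats(channel_values(gate_top_fraction(uni), "ofp"))$geomean)
})
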