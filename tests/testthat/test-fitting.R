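# Fitting tests run on reduced problem sizes (fewer cells/levels than the
# characterization-scale runs in test-acceptance.R) to stay fast.

small_cfg <- function(...) {
  fit_config(free = c("a_f", "b_f", "K_d"), n_cells_sim = 400, ...)
}

make_dr_table <- function(seed = 61, n_cells = 1200, topology = "CONSTANT",
                          flp = 35, sh = 5,
                          dox = c(0, 10, 40, 225)) {
  generate_experiment(dose_response_design(topology, flp, sh,
                                           dox_levels = dox,
                                           n_cells = n_cells),
                      seed = seed)
}

test_that("fit initialized at the truth stays at the truth", {
  tab <- make_dr_table()
  cfg <- small_cfg()
  fit <- fit_dose_response(tab, "CONSTANT", cfg, seed = 3)
  expect_lt(fit$loss, 0.05)
  expect_equal(fit$params$b_f, model_params()$b_f, tolerance = 0.5)
  expect_lte(fit$loss, fit$initial_loss)
})

test_that("fit is deterministic under a fixed seed", {
  tab <- make_dr_table()
  cfg <- small_cfg()
  sv <- c(a_f = 0.06, b_f = 1, K_d = 2)
  f1 <- fit_dose_response(tab, "CONSTANT", cfg, seed = 4, start_values = sv)
  f2 <- fit_dose_response(tab, "CONSTANT", cfg, seed = 4, start_values = sv)
  expect_identical(f1$free, f2$free)
  expect_identical(f1$loss, f2$loss)
})

test_that("precondition violations are rejected", {
  tab <- make_dr_table(n_cells = 100, dox = c(0, 5, 10, 40, 225))
  no_uninduced <- tab[tab$dox_nM > 0, ]  # still 4 induced levels
  expect_error(fit_dose_response(no_uninduced, "CONSTANT", small_cfg(), 1),
               "dox = 0")
  few <- tab[tab$dox_nM %in% c(0, 225), ]
  expect_error(fit_dose_response(few, "CONSTANT", small_cfg(), 1),
               "4 distinct dox levels")
  mixed <- tab
  mixed$flp_ng[seq_len(10)] <- 7
  expect_error(fit_dose_response(mixed, "CONSTANT", small_cfg(), 1),
               "single Flp:shRNA ratio")
})

test_that("multistart landscape bookkeeping and monotone improvement", {
  tab <- make_dr_table(n_cells = 800)
  cfg <- fit_config(free = c("b_f", "K_d"), n_cells_sim = 300,
                    lower_mult = 0.05, upper_mult = 20, maxit = 60)
  ls <- multistart_landscape(tab, "CONSTANT", n_starts = 4, seed = 5,
                             config = cfg)
  expect_equal(nrow(ls), 4)
  expect_true(!is.unsorted(ls$loss))
  expect_true(all(c("init_b_f", "final_K_d") %in% names(ls)))
})

test_that("recombination rate c is locally insensitive near the optimum", {
  tab <- make_dr_table()
  cfg <- small_cfg()
  obj <- digitizerlab:::make_dose_objective(tab, "CONSTANT", cfg, seed = 6)
  base <- obj$objective(model_params())
  hi <- obj$objective(model_params(c = model_params()$c * 3))
  lo <- obj$objective(model_params(c = model_params()$c / 3))
  far_hi <- obj$objective(model_params(c = model_params()$c * 100))
  far_lo <- obj$objective(model_params(c = model_params()$c / 100))
  # few-fold changes in c move the loss an order of magnitude less than
  # hundred-fold changes do: c is the least-constrained parameter
  expect_lt(max(abs(hi - base), abs(lo - base)),
            min(abs(far_hi - base), abs(far_lo - base)) / 5)
})

test_that("ridge scan bookkeeping and grid preconditions", {
  tab <- make_dr_table(n_cells = 800)
  cfg <- small_cfg()
  b_grid <- model_params()$b_f * 10^seq(-0.4, 0.4, length.out = 5)
  k_grid <- model_params()$K_d * 10^seq(-1, 1, length.out = 9)
  rs <- ridge_scan(tab, "CONSTANT", b_grid, k_grid, cfg, seed = 7)
  expect_equal(nrow(rs$ridge), 5)
  expect_lte(sum(!rs$ridge$flat), 5)
  expect_equal(nrow(rs$profile), 45)
  expect_error(ridge_scan(tab, "CONSTANT", b_grid[1:3], k_grid, cfg, 7),
               ">= 5")
})

test_that("platform controls: parameter recovery and delay-model comparison", {
  p <- model_params(); plat <- platform_params(); up <- uptake_params()
  # early time points (commensurate with the onset delay) are what
  # discriminate the delay-distribution shape; later ones only see the mean
  des <- do.call(rbind, lapply(c(8, 12, 16, 24, 48, 96), function(t)
    data.frame(topology = "NO_SHRNA", flp_ng = 0, shrna_ng = 0, dox_nM = 0,
               time_h = t, replicate = 1L, n_cells = 2000)))
  ctrl <- generate_experiment(des, p, plat, up, seed = 8,
                              reporter_ng = 0, cfp_ng = 25)
  pf <- fit_platform_controls(ctrl, up, cfp_mass_fraction = 1)
  expect_equal(pf$platform$gamma, p$b_c, tolerance = 0.10)
  expect_lt(pf$platform$delta_p, 0.005)
  expect_true(pf$gaussian_better)
  expect_error(fit_platform_controls(ctrl[ctrl$time_h < 15, ], up),
               "3 distinct time points")
})
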