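test_that("geometric statistics match hand values and reject non-positive data", {
  gs <- geometric_stats(c(10, 1000))
  expect_equal(gs$geomean, 100)
  gs7 <- geometric_stats(c(7, 7, 7))
  expect_equal(gs7$geomean, 7)
  expect_equal(gs7$geosd, 1)
  expect_equal(geometric_stats(42)$geosd, 1)
  expect_error(geometric_stats(c(0, 5)), "positive")
})

test_that("fold change is the ratio of geometric means", {
  expect_equal(fold_change(c(100, 100, 100), c(10, 10, 10)), 10)
  expect_equal(fold_change(c(3, 14, 159), c(3, 14, 159)), 1)
  expect_equal(fold_change(c(10, 1000), c(10, 10)), 10)
})

test_that("empirical AUC anchors, hand case, and tie handling", {
  x <- c(2.5, 10, 400, 3)
  expect_equal(empirical_auc(x, x)$auc, 0.5)
  expect_equal(empirical_auc(c(5, 6), c(1, 2))$auc, 1.0)
  expect_equal(empirical_auc(c(1, 3), 2)$auc, 0.5)
  expect_error(empirical_auc(numeric(0), 1), "non-empty")
})

test_that("AUC equals brute-force pairwise concordance with ties", {
  set.seed(11)
  for (i in 1:25) {
    pos <- sample(1:12, sample(3:40, 1), replace = TRUE)
    neg <- sample(1:12, sample(3:40, 1), replace = TRUE)
    expect_equal(empirical_auc(pos, neg)$auc, auc_bruteforce(pos, neg))
  }
})

test_that("AUC complementarity on tie-free data", {
  set.seed(12)
  for (i in 1:10) {
    pos <- rlnorm(30, 4); neg <- rlnorm(20, 3)
    expect_equal(empirical_auc(pos, neg)$auc + empirical_auc(neg, pos)$auc, 1)
  }
})

test_that("mixture EM recovers a planted two-mode population", {
  set.seed(21)
  x <- 10^c(rnorm(1000, 2, 0.2), rnorm(1000, 5, 0.2))
  fit <- fit_log_mixture2(x, seed = 1)
  expect_false(fit$unimodal)
  expect_equal(fit$mu_off, 2, tolerance = 0.05 / 2)
  expect_equal(fit$mu_on, 5, tolerance = 0.05 / 5)
  expect_equal(fit$w_on, 0.5, tolerance = 0.1)
  expect_true(fit$sd_off > 0 && fit$sd_on > 0)
  expect_equal(fit$w_off + fit$w_on, 1, tolerance = 1e-9)
})

test_that("mixture EM flags unimodal data and is deterministic", {
  set.seed(22)
  x <- 10^rnorm(500, 3, 0.25)
  fit <- fit_log_mixture2(x, seed = 5)
  expect_true(fit$unimodal)
  fit2 <- fit_log_mixture2(x, seed = 5)
  expect_identical(fit, fit2)
  expect_error(fit_log_mixture2(1:5), "n >= 10")
})

test_that("mixture EM agrees with an independent EM implementation", {
  skip_if_not_installed("mclust")
  set.seed(23)
  x <- 10^c(rnorm(800, 2.2, 0.25), rnorm(1200, 4.4, 0.3))
  fit <- fit_log_mixture2(x, seed = 1)
  mc <- withr::with_package("mclust", quiet = TRUE,
    Mclust(log10(x), G = 2, modelNames = "V", verbose = FALSE))
  mus <- unname(sort(mc$parameters$mean))
  expect_equal(fit$mu_off, mus[1], tolerance = 0.02)
  expect_equal(fit$mu_on, mus[2], tolerance = 0.02)
})

test_that("SNR report arithmetic matches closed forms", {
  expect_equal(snr_report(1, 1, 0, 0)$snr_db, 0)
  expect_equal(snr_report(1, 0.5, 0, 0)$snr_db, 10 * log10(4))
  r <- snr_report(2, 0.3, 0.1, 0.05)
  expect_equal(r$fail_power, 0.15 * 4)
  expect_equal(r$snr_db, 10 * log10(4 / (0.09 + 0.6)))
})

test_that("identical unimodal induced/uninduced data yields the undefined sentinel", {
  set.seed(24)
  x <- 10^rnorm(400, 3, 0.2)
  rep <- snr_db(x, x)
  expect_false(rep$defined)
  expect_identical(rep$snr_db, -Inf)
  ms <- new_metric_set(1, 0.5, rep)
  expect_error(delta_metrics(ms, ms), "undefined")
})

test_that("printed average input/output SNRs subtract to the printed amplification", {
  input <- new_metric_set(fc = 2, auc = 0.6, snr = -4.05)
  output <- new_metric_set(fc = 8, auc = 0.9, snr = -1.32)
  d <- delta_metrics(input, output)
  expect_equal(d$delta_snr_db, 2.73)
  expect_equal(d$delta_fc, 6)
  expect_equal(d$delta_auc, 0.3, tolerance = 1e-12)
  same <- delta_metrics(input, input)
  expect_equal(unlist(same[1:3]), c(0, 0, 0), ignore_attr = TRUE)
})

test_that("FC and SNR are invariant under common positive scaling", {
  set.seed(25)
  for (i in 1:5) {
    on <- 10^rnorm(300, 4, 0.3)
    off <- 10^rnorm(300, 2.5, 0.3)
    k <- 10^runif(1, -2, 2)
    expect_equal(fold_change(on * k, off * k), fold_change(on, off))
    expect_equal(snr_db(on * k, off * k, floor = 0)$snr_db,
                 snr_db(on, off, floor = 0)$snr_db, tolerance = 1e-6)
  }
})

test_that("SNR decreases in fail probability and increases in amplitude", {
  p <- seq(0, 0.45, by = 0.05)
  snrs <- vapply(p, function(q) snr_report(1.5, 0.3, q, q)$snr_db, 0)
  expect_true(all(diff(snrs) < 0))
  dd <- seq(0.2, 3, by = 0.2)
  snrs2 <- vapply(dd, function(d) snr_report(d, 0.3, 0.1, 0.1)$snr_db, 0)
  expect_true(all(diff(snrs2) > 0))
})

test_that("unimodal symmetric pair reduces to the square-wave moment formula", {
  set.seed(26)
  on <- 10^rnorm(600, 4.2, 0.25)
  off <- 10^rnorm(600, 2.4, 0.22)
  rep <- snr_db(on, off)
  expect_equal(rep$p_dud + rep$p_leaky, 0)
  dmu <- mean(log10(on)) - mean(log10(off))
  sbar <- (sd(log10(on)) + sd(log10(off))) / 2
  expect_equal(rep$snr_db, 10 * log10(dmu^2 / sbar^2), tolerance = 1e-10)
})

test_that("metric sets bundle consistently across channels", {
  set.seed(27)
  ind <- make_pop(cfp = 10^rnorm(300, 3, .2), ifp = 10^rnorm(300, 3.5, .2),
                  ofp = 10^rnorm(300, 4.5, .2), dox_nM = 225)
  uni <- make_pop(cfp = 10^rnorm(300, 3, .2), ifp = 10^rnorm(300, 2.4, .2),
                  ofp = 10^rnorm(300, 2.3, .2))
  ms_ofp <- metric_set(ind, uni, "ofp")
  ms_ifp <- metric_set(ind, uni, "ifp")
  expect_gt(ms_ofp$auc, 0.99)
  expect_true(ms_ofp$snr$defined)
  expect_equal(ms_ofp$fc,
               fold_change(channel_values(ind, "ofp"),
                           channel_values(uni, "ofp")))
  expect_false(isTRUE(all.equal(ms_ofp$fc, ms_ifp$fc)))
  same <- metric_set(uni, uni, "ofp")
  expect_equal(same$fc, 1)
  expect_equal(same$auc, 0.5)
})
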