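# Fitting the digitizer model to dose-response tables, fitting the
# transfection platform to constitutive-control time series, and
# identifiability diagnostics (multistart landscapes, the b_f-K_d ridge).
#
# The dose-response objective compares observed and simulated log10
# geometric means of gated IFP and OFP. Simulation inside the objective
# uses common random numbers: transfection doses, measurement-noise draws
# and gate membership are frozen per seed, so the objective is a smooth
# deterministic function of the parameters.

#' Fit configuration for dose-response fitting
#'
#' @param free Character vector of \code{\link{model_params}} names to
#'   optimize; the rest stay at \code{start}.
#' @param start \code{model_params} supplying fixed values and the
#'   optimization start (defaults to package defaults).
#' @param lower_mult,upper_mult Box bounds for each free rate as
#'   multiples of its start value; Hill coefficients are bounded in
#'   [1, 4] regardless.
#' @param n_cells_sim Cells simulated per condition inside the objective.
#' @param gate_fraction Top-fraction CFP gate applied to both observed
#'   and simulated populations.
#' @param reporter_ng,cfp_ng Fixed plasmid masses of the simulated mix.
#' @param plat,uptake Platform and uptake parameters used in simulation.
#' @param n_grid Integrator grid resolution.
#' @param maxit Optimizer iteration cap.
#' @return List of class \code{"fit_config"}.
#' @export
fit_config <- function(free = c("a_f", "b_f", "K_d", "K_dox"),
                       start = model_params(),
                       lower_mult = 1e-4, upper_mult = 1e4,
                       n_cells_sim = 1000, gate_fraction = 0.3,
                       reporter_ng = 50, cfp_ng = 25,
                       plat = platform_params(), uptake = uptake_params(),
                       n_grid = 121, maxit = 300) {
  stopifnot(all(free %in% names(start)))
  structure(list(free = free, start = start, lower_mult = lower_mult,
                 upper_mult = upper_mult, n_cells_sim = n_cells_sim,
                 gate_fraction = gate_fraction, reporter_ng = reporter_ng,
                 cfp_ng = cfp_ng, plat = plat, uptake = uptake,
                 n_grid = n_grid, maxit = maxit),
            class = "fit_config")
}

HILL_PARAMS <- c("n_dox", "n_rep", "h_rec")

param_bounds <- function(config) {
  start <- config$start
  lo <- hi <- numeric(length(config$free))
  names(lo) <- names(hi) <- config$free
  for (nm in config$free) {
    if (nm %in% HILL_PARAMS) {
      lo[nm] <- 1; hi[nm] <- 4
    } else {
      if (start[[nm]] <= 0)
        stop("fit start for free rate '", nm, "' must be > 0")
      lo[nm] <- start[[nm]] * config$lower_mult
      hi[nm] <- start[[nm]] * config$upper_mult
    }
  }
  list(lower = lo, upper = hi)
}

gated_log_means <- function(pop, fraction, floor = 1) {
  g <- gate_top_fraction(pop, "cfp", fraction)
  c(ifp = mean(log10(pmax(channel_values(g, "ifp"), floor))),
    ofp = mean(log10(pmax(channel_values(g, "ofp"), floor))))
}

# Precompute everything seed-dependent once, return a deterministic
# objective over model-parameter lists.
make_dose_objective <- function(table, topology, config, seed) {
  pops <- split_populations(table)
  conds <- lapply(pops, `[[`, "condition")
  dox_all <- vapply(conds, `[[`, 0, "dox_nM")
  if (length(unique(dox_all)) < 4)
    stop("dose-response fit needs >= 4 distinct dox levels")
  if (!any(dox_all == 0))
    stop("dose-response fit needs uninduced (dox = 0) conditions")
  ratio <- unique(t(vapply(conds, function(cn) c(cn$flp_ng, cn$shrna_ng),
                           numeric(2))))
  if (nrow(ratio) != 1)
    stop("dose-response fit expects a single Flp:shRNA ratio")
  t_h <- unique(vapply(conds, `[[`, 0, "time_h"))
  if (length(t_h) != 1)
    stop("dose-response fit expects a single time point")

  # observed gated log10 geomeans averaged over replicates per dox level
  obs_per_pop <- t(vapply(pops, gated_log_means, numeric(2),
                          fraction = config$gate_fraction))
  dox_levels <- sort(unique(dox_all))
  obs <- t(vapply(dox_levels, function(d)
    colMeans(obs_per_pop[dox_all == d, , drop = FALSE]), numeric(2)))

  identical_obs <- stats::sd(obs) < 1e-6

  # frozen per-level simulation inputs (common random numbers)
  doses_ng <- dose_map(ratio[1, 1], ratio[1, 2],
                       config$reporter_ng, config$cfp_ng)
  sim <- lapply(seq_along(dox_levels), function(j) {
    doses <- sample_transfection(config$n_cells_sim, doses_ng,
                                 config$uptake, config$plat,
                                 seed = derive_seed(seed, 500 + j))
    set.seed(derive_seed(seed, 900 + j))
    n <- nrow(doses)
    noise <- list(
      af  = matrix(stats::rlnorm(3 * n, log(config$uptake$autofluorescence_mu),
                                 0.25), n, 3),
      eps = matrix(stats::rnorm(3 * n, 0, config$uptake$sigma_m), n, 3))
    # gate on observed CFP at start parameters (CFP does not depend on the
    # default free parameters, so the gate is frozen across evaluations)
    dyn0 <- cell_dynamics(doses, rep(0, n), rep(0, n), config$start,
                          config$plat, t_h, config$n_grid)
    cfp_obs <- pmax((dyn0$cfp + noise$af[, 1]) * 10^noise$eps[, 1], 1)
    k <- ceiling(config$gate_fraction * n)
    gate <- sort(order(-cfp_obs, seq_len(n))[seq_len(k)])
    list(doses = doses[gate, , drop = FALSE],
         af = noise$af[gate, , drop = FALSE],
         eps = noise$eps[gate, , drop = FALSE])
  })

  objective <- function(p) {
    loss <- 0
    for (j in seq_along(dox_levels)) {
      s <- sim[[j]]
      m0 <- ptre_flux(dox_levels[j], s$doses$copies_flp, p)
      s0 <- shrna_flux(dox_levels[j], s$doses$copies_shrna, topology, p)
      dyn <- cell_dynamics(s$doses, m0, s0, p, config$plat, t_h,
                           config$n_grid)
      ifp_obs <- pmax((dyn$ifp + s$af[, 2]) * 10^s$eps[, 2], 1)
      ofp_obs <- pmax((dyn$ofp + s$af[, 3]) * 10^s$eps[, 3], 1)
      loss <- loss + (mean(log10(ifp_obs)) - obs[j, "ifp"])^2 +
                     (mean(log10(ofp_obs)) - obs[j, "ofp"])^2
    }
    loss
  }
  list(objective = objective, dox_levels = dox_levels, t_h = t_h,
       ratio = ratio[1, ], identical_obs = identical_obs)
}

with_free <- function(start, free, values) {
  p <- start
  for (i in seq_along(free)) p[[free[i]]] <- unname(values[i])
  p
}

#' Fit model parameters to dose-response data
#'
#' Minimizes the sum over dox levels of squared differences between
#' observed and simulated log10 geometric means of gated IFP and OFP, by
#' bounded quasi-Newton (L-BFGS-B) over the log10 of the free parameters.
#' The simulation inside the objective uses common random numbers derived
#' from \code{seed}, so the fit is deterministic.
#'
#' @param table \code{experiment_table} holding one Flp:shRNA ratio at
#'   one time point with >= 4 distinct dox levels including 0.
#' @param topology Circuit topology of the data.
#' @param config \code{\link{fit_config}}.
#' @param seed Integer seed for the frozen simulation draws.
#' @param start_values Optional named numeric overriding the start values
#'   of the free parameters (used by the multistart driver).
#' @param start_id Integer tag recorded in the result.
#' @return Object of class \code{"fit_result"}: \code{params} (fitted
#'   \code{model_params}), \code{loss}, \code{initial_loss},
#'   \code{n_iter}, \code{start_id}, \code{converged}, and
#'   \code{unidentifiable} (flagged when all observations are identical).
#' @export
fit_dose_response <- function(table, topology, config = fit_config(),
                              seed = 1L, start_values = NULL,
                              start_id = 0L) {
  obj <- make_dose_objective(table, topology, config, seed)
  if (obj$identical_obs)
    warning("fit_dose_response: all observations identical; parameters unidentifiable")
  b <- param_bounds(config)
  theta0 <- vapply(config$free, function(nm) config$start[[nm]], 0)
  if (!is.null(start_values)) theta0[names(start_values)] <- start_values
  theta0 <- pmin(pmax(theta0, b$lower), b$upper)
  fn <- function(lth) obj$objective(with_free(config$start, config$free, 10^lth))
  init_loss <- fn(log10(theta0))
  opt <- stats::optim(log10(theta0), fn, method = "L-BFGS-B",
                      lower = log10(b$lower), upper = log10(b$upper),
                      control = list(maxit = config$maxit,
                                     factr = 1e7))
  if (opt$value <= init_loss) {
    final <- 10^opt$par; loss <- opt$value
  } else {  # monotone improvement contract
    final <- theta0; loss <- init_loss
  }
  structure(list(params = with_free(config$start, config$free, final),
                 free = stats::setNames(final, config$free),
                 loss = loss, initial_loss = init_loss,
                 n_iter = opt$counts[["function"]],
                 start_id = as.integer(start_id),
                 converged = opt$convergence == 0,
                 unidentifiable = obj$identical_obs),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> loss=%.4g (start %.4g), %d evals%s\n",
              x$loss, x$initial_loss, x$n_iter,
              if (x$converged) "" else " [not converged]"))
  print(round(unlist(x$free), 5))
  invisible(x)
}

#' Multistart fit landscape
#'
#' Re-runs \code{\link{fit_dose_response}} from \code{n_starts}
#' log-uniform draws of the free parameters within their bounds and
#' tabulates every endpoint, exposing basins and ridges in the fit
#' landscape.
#'
#' @inheritParams fit_dose_response
#' @param n_starts Number of starts (>= 2).
#' @return Data frame of class \code{"landscape_table"}, one row per
#'   start (\code{start_id}, initial and final free-parameter values,
#'   \code{loss}, \code{converged}), sorted by loss.
#' @export
multistart_landscape <- function(table, topology, n_starts = 8,
                                 seed = 1L, config = fit_config()) {
  stopifnot(n_starts >= 2)
  b <- param_bounds(config)
  set.seed(derive_seed(seed, 77))
  starts <- vapply(seq_len(n_starts), function(i)
    10^stats::runif(length(config$free), log10(b$lower), log10(b$upper)),
    numeric(length(config$free)))
  starts <- matrix(starts, nrow = length(config$free))
  rownames(starts) <- config$free
  rows <- lapply(seq_len(n_starts), function(i) {
    sv <- stats::setNames(starts[, i], config$free)
    fit <- tryCatch(
      fit_dose_response(table, topology, config, seed,
                        start_values = sv, start_id = i),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    out <- data.frame(start_id = i, loss = fit$loss,
                      converged = fit$converged)
    for (nm in config$free) {
      out[[paste0("init_", nm)]] <- sv[[nm]]
      out[[paste0("final_", nm)]] <- fit$free[[nm]]
    }
    out
  })
  res <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  res <- res[order(res$loss), ]
  rownames(res) <- NULL
  class(res) <- c("landscape_table", "data.frame")
  res
}

#' Profile the b_f-K_d identifiability ridge
#'
#' For each value of the maximal Flp production rate \code{b_f}, profiles
#' the titration threshold \code{K_d} over a grid (all other parameters
#' fixed at the supplied values), locates the loss-minimizing \code{K_d}
#' (with parabolic refinement in log10 space), and fits a line to the
#' (log10 b_f, log10 K_d) ridge points. Under the titration model the two
#' parameters trade off along a line of constant effective Kd, so the
#' ridge is close to linear with slope near 1.
#'
#' @inheritParams fit_dose_response
#' @param b_f_grid,K_d_grid Numeric grids (>= 5 values each).
#' @return List of class \code{"ridge_scan"}: \code{ridge} data frame
#'   (\code{b_f}, \code{K_d_min}, \code{loss_min}, \code{flat}),
#'   \code{profile} (full loss grid), \code{r_squared}, \code{slope},
#'   \code{intercept} of the log-log ridge line.
#' @export
ridge_scan <- function(table, topology, b_f_grid, K_d_grid,
                       config = fit_config(), seed = 1L) {
  stopifnot(length(b_f_grid) >= 5, length(K_d_grid) >= 5)
  obj <- make_dose_objective(table, topology, config, seed)
  K_d_grid <- sort(K_d_grid)
  lk <- log10(K_d_grid)
  prof <- expand.grid(b_f = sort(b_f_grid), K_d = K_d_grid)
  prof$loss <- NA_real_
  ridge <- data.frame(b_f = sort(b_f_grid), K_d_min = NA_real_,
                      loss_min = NA_real_, flat = FALSE)
  for (i in seq_along(ridge$b_f)) {
    losses <- vapply(K_d_grid, function(kd) {
      p <- config$start; p$b_f <- ridge$b_f[i]; p$K_d <- kd
      obj$objective(p)
    }, 0)
    prof$loss[prof$b_f == ridge$b_f[i]] <- losses
    j <- which.min(losses)
    flat <- diff(range(losses)) < 1e-10 * (1 + min(losses)) ||
      j == 1 || j == length(losses)
    kd_min <- K_d_grid[j]
    if (!flat) {  # parabolic refinement of the minimizer in log10(K_d)
      x <- lk[(j - 1):(j + 1)]; y <- losses[(j - 1):(j + 1)]
      d21 <- x[2] - x[1]; d32 <- x[3] - x[2]
      denom <- 2 * (d21 * (y[2] - y[3]) - d32 * (y[2] - y[1]))
      if (abs(denom) > 0) {
        xs <- x[2] - (d21^2 * (y[2] - y[3]) - d32^2 * (y[2] - y[1])) / denom
        if (xs > x[1] && xs < x[3]) kd_min <- 10^xs
      }
    }
    ridge$K_d_min[i] <- kd_min
    ridge$loss_min[i] <- losses[j]
    ridge$flat[i] <- flat
  }
  ok <- !ridge$flat
  if (sum(ok) >= 2) {
    fit <- stats::lm(log10(K_d_min) ~ log10(b_f), data = ridge[ok, ])
    r2 <- summary(fit)$r.squared
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
  } else {
    r2 <- NA_real_; slope <- NA_real_; intercept <- NA_real_
  }
  structure(list(ridge = ridge, profile = prof, r_squared = r2,
                 slope = slope, intercept = intercept),
            class = "ridge_scan")
}

#' @export
print.ridge_scan <- function(x, ...) {
  cat(sprintf("<ridge_scan> %d ridge points (%d flat), log-log R^2=%.3f slope=%.3f\n",
              nrow(x$ridge), sum(x$ridge$flat), x$r_squared, x$slope))
  invisible(x)
}

# probability-midpoint quadrature nodes for a standard normal
norm_nodes <- function(n) stats::qnorm((seq_len(n) - 0.5) / n)

platform_pred_logmeans <- function(times, gamma, mu_delay, sd_delay,
                                   delta_p, mu_copies, sd_copies,
                                   autofl, n_nodes = 21, uniform = FALSE) {
  zn <- norm_nodes(n_nodes)
  dly <- if (uniform) (seq_len(n_nodes) - 0.5) / n_nodes * 2 * mu_delay
         else pmax(0, mu_delay + sd_delay * zn)
  ncop <- 10^(mu_copies + sd_copies * zn)
  vapply(times, function(t) {
    td <- pmax(0, t - dly)
    acc <- if (delta_p > 0) (1 - exp(-delta_p * td)) / delta_p else td
    mean(log10(gamma * outer(ncop, acc) + autofl))
  }, 0)
}

#' Fit platform parameters to constitutive-control time series
#'
#' Fits the fluorescence-to-copy scale \code{gamma}, the Gaussian onset
#' delay (\code{mu_delay}, \code{sd_delay}) and the plasmid dilution rate
#' \code{delta_p} to the log10 geometric means of a constitutive
#' single-color (CFP) time series, by bounded least squares against the
#' accumulation model averaged over the delay and copy-number
#' distributions. Also fits a uniform-delay alternative (delay ~
#' U(0, 2 mu_delay), the cell-division-driven hypothesis) and reports
#' which delay model fits better.
#'
#' @param controls \code{experiment_table} of constitutive controls with
#'   >= 3 distinct time points (only the \code{cfp} channel is used).
#' @param uptake \code{\link{uptake_params}} describing the copy-number
#'   scale of the controls (gamma and mean copies only enter as a
#'   product, so the copy scale must be supplied to separate them).
#' @param cfp_mass_fraction Mass fraction of the constitutive plasmid in
#'   the transfection mix.
#' @param start Optional \code{\link{platform_params}} start point.
#' @return List of class \code{"platform_fit"}: \code{platform} (fitted
#'   \code{platform_params}), \code{sse_gaussian}, \code{sse_uniform},
#'   \code{gaussian_better}, \code{observed} (per-time log10 means).
#' @export
fit_platform_controls <- function(controls, uptake = uptake_params(),
                                  cfp_mass_fraction = 1,
                                  start = platform_params()) {
  pops <- split_populations(controls)
  times <- vapply(pops, function(p) p$condition$time_h, 0)
  if (length(unique(times)) < 3)
    stop("fit_platform_controls: need >= 3 distinct time points")
  tl <- sort(unique(times))
  obs <- vapply(tl, function(t) {
    vals <- unlist(lapply(pops[times == t], function(p)
      pmax(channel_values(p, "cfp"), 1)))
    mean(log10(vals))
  }, 0)
  mu_cop <- uptake$mu_uptake + log10(cfp_mass_fraction)
  sse <- function(th, uniform) {
    pred <- platform_pred_logmeans(tl, 10^th[1], th[2], 10^th[3], th[4],
                                   mu_cop, uptake$sd_uptake,
                                   uptake$autofluorescence_mu,
                                   uniform = uniform)
    sum((pred - obs)^2)
  }
  th0 <- c(log10(start$gamma), start$mu_delay,
           log10(max(start$sd_delay, 0.5)), start$delta_p)
  lower <- c(log10(start$gamma) - 3, 0, log10(0.1), 0)
  upper <- c(log10(start$gamma) + 3, 24, log10(12), 0.2)
  og <- stats::optim(th0, sse, uniform = FALSE, method = "L-BFGS-B",
                     lower = lower, upper = upper)
  ou <- stats::optim(th0, sse, uniform = TRUE, method = "L-BFGS-B",
                     lower = lower, upper = upper)
  th <- og$par
  structure(list(platform = platform_params(gamma = 10^th[1],
                                            mu_delay = th[2],
                                            sd_delay = 10^th[3],
                                            delta_p = th[4]),
                 sse_gaussian = og$value, sse_uniform = ou$value,
                 gaussian_better = og$value < ou$value,
                 observed = stats::setNames(obs, tl)),
            class = "platform_fit")
}

#' @export
print.platform_fit <- function(x, ...) {
  p <- x$platform
  cat(sprintf("<platform_fit> gamma=%.3g MEFL/copy/h, delay %.2f +/- %.2f h, delta_p=%.4g /h\n",
              p$gamma, p$mu_delay, p$sd_delay, p$delta_p))
  cat(sprintf("  SSE gaussian=%.4g, uniform=%.4g (%s delay model preferred)\n",
              x$sse_gaussian, x$sse_uniform,
              if (x$gaussian_better) "gaussian" else "uniform"))
  invisible(x)
}
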