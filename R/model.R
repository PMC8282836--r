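# Quasi-steady-state reduced per-cell model of the recombinase digitizer on
# a transient-transfection platform. Fast RNA species (Flp mRNA, shRNA and
# their complex) are eliminated by taking the fast/slow separation limit;
# what remains is a molecular-titration nonlinearity acting on the Flp
# production flux, a first-order Flp activity pool, an irreversible
# recombination state r in [0,1], and linear fluorescent-protein
# accumulation.

#' Kinetic parameters of the digitizer model
#'
#' All rates are per hour. Fluxes are transcription-proportional rates per
#' plasmid copy; fluorescence production rates are MEFL per copy per hour.
#'
#' @param a_f Leaky pTRE transcription flux per copy (h^-1).
#' @param b_f Maximal pTRE transcription flux per copy (h^-1).
#' @param K_dox Doxycycline half-max (nM) of pTRE induction.
#' @param n_dox Hill coefficient of induction (>= 1).
#' @param b_s shRNA transcription flux per copy (h^-1).
#' @param K_rep Dox half-max (nM) of tetO feedforward repression.
#' @param n_rep Hill coefficient of repression (>= 1).
#' @param K_d Titration threshold (flux units h^-1): the scaled
#'   dissociation constant of the shRNA:mRNA interaction; sets the leak
#'   flux the shRNA pool can absorb.
#' @param delta_F Flp activity decay rate (h^-1).
#' @param c Scaled cleavage-and-dissociation rate of recombination (per
#'   Flp-activity unit per hour).
#' @param h_rec Recombination Hill order (>= 1); 1 by default, exposed to
#'   probe recombinase multimer cooperativity.
#' @param b_g,b_i,b_c MEFL production per recombined-reporter copy, per
#'   unit total pTRE flux, and per constitutive plasmid copy, per hour.
#' @return Named list of class \code{"model_params"}.
#' @export
model_params <- function(a_f = 0.03, b_f = 2, K_dox = 50, n_dox = 2,
                         b_s = 1, K_rep = 25, n_rep = 2,
                         K_d = 1, delta_F = 0.1, c = 1e-4, h_rec = 1,
                         b_g = 5, b_i = 1, b_c = 5) {
  p <- list(a_f = a_f, b_f = b_f, K_dox = K_dox, n_dox = n_dox,
            b_s = b_s, K_rep = K_rep, n_rep = n_rep,
            K_d = K_d, delta_F = delta_F, c = c, h_rec = h_rec,
            b_g = b_g, b_i = b_i, b_c = b_c)
  rates <- p[setdiff(names(p), c("n_dox", "n_rep", "h_rec"))]
  if (any(unlist(rates) < 0)) stop("model_params: rates must be >= 0")
  if (n_dox < 1 || n_rep < 1 || h_rec < 1)
    stop("model_params: Hill coefficients must be >= 1")
  structure(p, class = "model_params")
}

#' Transient-transfection platform parameters
#'
#' @param gamma MEFL per plasmid copy per hour; scale of the
#'   fluorescence-to-copy map for constitutive controls.
#' @param mu_delay,sd_delay Mean and SD (hours) of the Gaussian
#'   distribution of transcription onset delays after transfection
#'   (samples are truncated at 0).
#' @param delta_p Plasmid dilution rate (h^-1); 0 by default, reflecting
#'   no observable dilution over 96 h on this platform.
#' @return Named list of class \code{"platform_params"}.
#' @export
platform_params <- function(gamma = 5, mu_delay = 6, sd_delay = 2,
                            delta_p = 0) {
  stopifnot(gamma > 0, sd_delay >= 0, delta_p >= 0, mu_delay >= 0)
  structure(list(gamma = gamma, mu_delay = mu_delay, sd_delay = sd_delay,
                 delta_p = delta_p),
            class = "platform_params")
}

#' pTRE transcription flux
#'
#' Hill induction by doxycycline on top of a leaky basal flux:
#' \code{copies * (a_f + (b_f - a_f) * dox^n / (K_dox^n + dox^n))}.
#'
#' @param dox Doxycycline (nM), non-negative; vectorized.
#' @param copies Plasmid copy number.
#' @param p \code{\link{model_params}}.
#' @return Total transcription flux (h^-1).
#' @export
ptre_flux <- function(dox, copies, p) {
  if (any(dox < 0)) stop("ptre_flux: dox must be >= 0")
  h <- dox^p$n_dox / (p$K_dox^p$n_dox + dox^p$n_dox)
  h[dox == 0] <- 0  # covers K_dox == 0 edge
  copies * (p$a_f + (p$b_f - p$a_f) * h)
}

#' shRNA transcription flux
#'
#' Topology-dependent: absent (\code{NO_SHRNA}), constitutive
#' (\code{CONSTANT}), or dox-repressed via the tetO site
#' (\code{FEEDFORWARD}), where induction simultaneously activates Flp and
#' shuts off its repressor (a coherent feedforward loop).
#'
#' @inheritParams ptre_flux
#' @param topology One of \code{"NO_SHRNA"}, \code{"CONSTANT"},
#'   \code{"FEEDFORWARD"}.
#' @return Total shRNA flux (h^-1).
#' @export
shrna_flux <- function(dox, copies, topology, p) {
  if (any(dox < 0)) stop("shrna_flux: dox must be >= 0")
  topology <- match.arg(topology, TOPOLOGIES)
  switch(topology,
         NO_SHRNA = rep(0, max(length(dox), length(copies))),
         CONSTANT = copies * p$b_s + 0 * dox,
         FEEDFORWARD = {
           rep_f <- p$K_rep^p$n_rep / (p$K_rep^p$n_rep + dox^p$n_rep)
           rep_f[dox == 0] <- 1
           copies * p$b_s * rep_f
         })
}

#' Molecular titration of the Flp production flux
#'
#' The QSS limit of fast shRNA:mRNA sequestration leaves the free
#' (translation-competent) flux as the positive root of
#' \code{phi^2 + (s + K_d - m) phi - K_d m = 0}:
#' \deqn{\phi = \tfrac12\left[(m - s - K_d) +
#'   \sqrt{(m - s - K_d)^2 + 4 K_d m}\right]}
#' which is continuous, bounded by \code{0 <= phi <= m}, at least
#' \code{m - s}, non-decreasing in \code{m} and non-increasing in
#' \code{s}. As \code{K_d -> 0} it sharpens to \code{max(0, m - s)}: the
#' shRNA imposes a hard threshold on Flp production.
#'
#' @param m_flux Flp mRNA production flux (h^-1), >= 0; vectorized.
#' @param s_flux shRNA production flux (h^-1), >= 0.
#' @param K_d Titration threshold (h^-1), >= 0.
#' @return Free flux (h^-1), same length as the longest argument.
#' @export
titrate_flux <- function(m_flux, s_flux, K_d) {
  if (any(m_flux < 0) || any(s_flux < 0) || any(K_d < 0))
    stop("titrate_flux: arguments must be >= 0")
  b <- s_flux + K_d - m_flux
  disc <- sqrt(b * b + 4 * K_d * m_flux)
  # numerically stable root selection (avoids cancellation when b > 0)
  phi <- ifelse(b <= 0, (disc - b) / 2,
                2 * K_d * m_flux / (b + disc))
  phi[m_flux == 0] <- 0
  phi
}

# -- vectorized trajectory core ---------------------------------------------
# Integrates many cells at once on a shared absolute time grid using an
# exponential-trapezoid update for the Flp pool and cumulative trapezoids
# for the downstream integrals. Deterministic and smooth in the parameters,
# which the fitting objective relies on.
#
# doses: data.frame(copies_flp, copies_shrna, copies_reporter, copies_cfp,
#        delay_h); m0, s0: per-cell onset fluxes (vectors). Returns a list
# of endpoint vectors plus (optionally) the full matrices.
cell_dynamics <- function(doses, m0, s0, p, plat, t_end, n_grid = 161,
                          full = FALSE) {
  n <- nrow(doses)
  tk <- seq(0, t_end, length.out = n_grid)
  h <- if (n_grid > 1) tk[2] - tk[1] else 0
  delay <- doses$delay_h
  F_ <- numeric(n); I <- numeric(n); OFPI <- numeric(n)
  IFPI <- numeric(n); CFPI <- numeric(n)
  E <- exp(-p$delta_F * h)
  prev <- NULL
  if (full) {
    Fm <- matrix(0, n, n_grid); rm_ <- matrix(0, n, n_grid)
  }
  for (k in seq_len(n_grid)) {
    tau <- tk[k] - delay
    act <- as.numeric(tau > 0)
    dec <- act * exp(-plat$delta_p * pmax(tau, 0))
    mk <- m0 * dec
    sk <- s0 * dec
    phik <- titrate_flux(mk, sk, p$K_d)
    fk <- F_^p$h_rec
    rk <- 1 - exp(-I)
    ofp_rate <- rk * doses$copies_reporter * dec
    ifp_rate <- mk
    cfp_rate <- doses$copies_cfp * dec
    if (k > 1) {
      # Flp pool: exact homogeneous decay + trapezoid source over the step
      F_ <- F_ * E + h / 2 * (prev$phi * E + phik)
      fk2 <- F_^p$h_rec
      I <- I + h / 2 * p$c * (prev$f + fk2)
      rk2 <- 1 - exp(-I)
      OFPI <- OFPI + h / 2 * (prev$ofp_rate + rk2 * doses$copies_reporter * dec)
      IFPI <- IFPI + h / 2 * (prev$ifp_rate + mk)
      CFPI <- CFPI + h / 2 * (prev$cfp_rate + cfp_rate)
      fk <- fk2; rk <- rk2
      ofp_rate <- rk2 * doses$copies_reporter * dec
    }
    if (full) { Fm[, k] <- F_; rm_[, k] <- rk }
    prev <- list(phi = phik, f = fk, ofp_rate = ofp_rate,
                 ifp_rate = mk, cfp_rate = cfp_rate)
  }
  out <- list(F = F_, r = 1 - exp(-I),
              ofp = p$b_g * OFPI, ifp = p$b_i * IFPI, cfp = p$b_c * CFPI)
  if (full) { out$t <- tk; out$F_mat <- Fm; out$r_mat <- rm_ }
  out
}

#' Simulate a single cell trajectory
#'
#' Integrates the reduced per-cell model with an adaptive stiff-capable
#' solver (\code{deSolve::lsoda}, rtol 1e-8, atol 1e-10). Before the
#' cell's onset delay all productions are zero; afterwards plasmid copies
#' decay at \code{delta_p} and
#' \deqn{dF/dt = titrate(m, s, K_d) - \delta_F F, \quad
#'       dr/dt = c\,F^{h_{rec}} (1 - r),}
#' with linear accumulation of the three fluorescent proteins (IFP tracks
#' total pTRE flux independent of the shRNA titration, which acts only on
#' Flp).
#'
#' @param dose List/row with integer \code{copies_flp, copies_shrna,
#'   copies_reporter, copies_cfp} and \code{delay_h} (hours).
#' @param dox Doxycycline (nM).
#' @param topology Circuit topology.
#' @param p \code{\link{model_params}}.
#' @param plat \code{\link{platform_params}}.
#' @param t_grid Increasing time grid (hours) starting at 0.
#' @return Object of class \code{"cell_trajectory"}: list with \code{t},
#'   \code{F} (Flp activity), \code{r} (recombined fraction, monotone in
#'   [0,1]), \code{ifp}, \code{ofp}, \code{cfp} (MEFL, noise-free).
#' @export
simulate_cell <- function(dose, dox, topology, p, plat,
                          t_grid = seq(0, 96, by = 1)) {
  stopifnot(t_grid[1] == 0, !is.unsorted(t_grid, strictly = TRUE))
  m0 <- ptre_flux(dox, dose$copies_flp, p)
  s0 <- shrna_flux(dox, dose$copies_shrna, topology, p)
  d <- dose$delay_h
  post <- t_grid[t_grid > d]
  ny <- 5
  traj <- matrix(0, length(t_grid), ny,
                 dimnames = list(NULL, c("F", "r", "ofp", "ifp", "cfp")))
  if (length(post) > 0) {
    rhs <- function(tau, y, parms) {
      dec <- exp(-plat$delta_p * tau)
      phi <- titrate_flux(m0 * dec, s0 * dec, p$K_d)
      list(c(phi - p$delta_F * y[1],
             p$c * y[1]^p$h_rec * (1 - y[2]),
             p$b_g * y[2] * dose$copies_reporter * dec,
             p$b_i * m0 * dec,
             p$b_c * dose$copies_cfp * dec))
    }
    times <- c(0, post - d)
    sol <- deSolve::lsoda(y = numeric(ny), times = times, func = rhs,
                          parms = NULL, rtol = 1e-8, atol = 1e-10)
    if (any(!is.finite(sol)))
      stop("simulate_cell: non-finite state; dose=", paste(unlist(dose), collapse = ","),
           " dox=", dox, " topology=", topology)
    traj[t_grid > d, ] <- sol[-1, -1, drop = FALSE]
  }
  structure(list(t = t_grid, F = traj[, "F"],
                 r = pmin(pmax(traj[, "r"], 0), 1),
                 ofp = traj[, "ofp"], ifp = traj[, "ifp"],
                 cfp = traj[, "cfp"]),
            class = "cell_trajectory")
}

#' Simulate a single cell with explicit fast RNA species
#'
#' Reference (non-reduced) model retaining Flp mRNA \code{M} and shRNA
#' \code{S} with production fluxes \code{m, s}, first-order decay at
#' \code{delta_fast = sep * delta_F} and bimolecular sequestration at
#' \code{k = delta_fast^2 / K_d}; Flp is translated at \code{delta_fast *
#' M}. Its quasi-steady state reproduces \code{\link{titrate_flux}}
#' exactly, so trajectories converge to \code{\link{simulate_cell}} as
#' \code{sep} grows. Used to validate the QSS reduction numerically.
#'
#' @inheritParams simulate_cell
#' @param sep Fast/slow rate separation factor (default 1000).
#' @return A \code{"cell_trajectory"} (with extra fields \code{M},
#'   \code{S}).
#' @export
simulate_cell_unreduced <- function(dose, dox, topology, p, plat,
                                    t_grid = seq(0, 96, by = 1),
                                    sep = 1000) {
  stopifnot(t_grid[1] == 0, !is.unsorted(t_grid, strictly = TRUE))
  m0 <- ptre_flux(dox, dose$copies_flp, p)
  s0 <- shrna_flux(dox, dose$copies_shrna, topology, p)
  df <- sep * p$delta_F
  kb <- if (p$K_d > 0) df^2 / p$K_d else Inf
  if (!is.finite(kb))
    stop("simulate_cell_unreduced: K_d = 0 has no finite binding rate")
  d <- dose$delay_h
  post <- t_grid[t_grid > d]
  nm <- c("M", "S", "F", "r", "ofp", "ifp", "cfp")
  traj <- matrix(0, length(t_grid), length(nm), dimnames = list(NULL, nm))
  if (length(post) > 0) {
    rhs <- function(tau, y, parms) {
      dec <- exp(-plat$delta_p * tau)
      bind <- kb * y[1] * y[2]
      list(c(m0 * dec - df * y[1] - bind,
             s0 * dec - df * y[2] - bind,
             df * y[1] - p$delta_F * y[3],
             p$c * max(y[3], 0)^p$h_rec * (1 - y[4]),
             p$b_g * y[4] * dose$copies_reporter * dec,
             p$b_i * m0 * dec,
             p$b_c * dose$copies_cfp * dec))
    }
    times <- c(0, post - d)
    sol <- deSolve::lsoda(y = numeric(length(nm)), times = times, func = rhs,
                          parms = NULL, rtol = 1e-8, atol = 1e-12)
    if (any(!is.finite(sol)))
      stop("simulate_cell_unreduced: non-finite state")
    traj[t_grid > d, ] <- sol[-1, -1, drop = FALSE]
  }
  structure(list(t = t_grid, M = traj[, "M"], S = traj[, "S"],
                 F = traj[, "F"], r = pmin(pmax(traj[, "r"], 0), 1),
                 ofp = traj[, "ofp"], ifp = traj[, "ifp"],
                 cfp = traj[, "cfp"]),
            class = "cell_trajectory")
}

# measurement model: observed = (true + autofluorescence draw) * 10^eps,
# eps ~ N(0, sigma_m); clamped at the 1 MEFL detection floor.
apply_measurement_noise <- function(true_df, uptake, seed) {
  set.seed(seed)
  n <- nrow(true_df)
  out <- true_df
  for (ch in CHANNEL_COLS) {
    af <- stats::rlnorm(n, log(uptake$autofluorescence_mu), 0.25)
    eps <- stats::rnorm(n, 0, uptake$sigma_m)
    out[[ch]] <- pmax((true_df[[ch]] + af) * 10^eps, 1)
  }
  out
}

#' Simulate a cell population under one condition
#'
#' Draws per-cell transfection doses (\code{\link{sample_transfection}}),
#' propagates every cell to time \code{t} with the reduced model, and
#' applies the measurement model (additive autofluorescence, multiplicative
#' lognormal noise, 1 MEFL floor). Identical seeds give identical output.
#'
#' @param n_cells Number of cells (>= 1).
#' @param doses_ng Named numeric: plasmid masses in ng for \code{flp},
#'   \code{shrna}, \code{reporter}, \code{cfp}.
#' @param dox Doxycycline (nM).
#' @param topology Circuit topology.
#' @param p \code{\link{model_params}}; \code{plat}
#'   \code{\link{platform_params}}; \code{uptake}
#'   \code{\link{uptake_params}}.
#' @param plat,uptake Platform and uptake parameter objects.
#' @param t Measurement time (hours post transfection/induction).
#' @param seed Integer seed controlling doses and noise.
#' @param replicate Replicate index recorded in the condition metadata.
#' @param n_grid Time-grid resolution of the vectorized integrator.
#' @return A \code{\link{sample_population}}.
#' @export
simulate_population <- function(n_cells, doses_ng, dox, topology,
                                p = model_params(), plat = platform_params(),
                                uptake = uptake_params(), t = 48,
                                seed = 1L, replicate = 1L, n_grid = 161) {
  stopifnot(n_cells >= 1)
  doses <- sample_transfection(n_cells, doses_ng, uptake, plat,
                               seed = derive_seed(seed, 1))
  m0 <- ptre_flux(dox, doses$copies_flp, p)
  s0 <- shrna_flux(dox, doses$copies_shrna, topology, p)
  dyn <- cell_dynamics(doses, m0, s0, p, plat, t, n_grid)
  true_df <- data.frame(cfp = dyn$cfp, ifp = dyn$ifp, ofp = dyn$ofp)
  obs <- apply_measurement_noise(true_df, uptake, derive_seed(seed, 2))
  cn <- condition(topology,
                  flp_ng = as.numeric(doses_ng[["flp"]]),
                  shrna_ng = if (topology == "NO_SHRNA") 0 else as.numeric(doses_ng[["shrna"]]),
                  dox_nM = dox, time_h = t, replicate = replicate)
  sample_population(obs, cn)
}

#' Dimensionless parameter groups of the digitizer
#'
#' Scaling time by \code{delta_F} and Flp activity by its maximal steady
#' state \code{b_f * copies / delta_F} collapses the model onto four
#' groups. The headline group is the effective Kd,
#' \code{eKd = K_d / (b_f * copies_flp)}: the shRNA-imposed threshold
#' relative to maximal Flp production capacity, a tolerance-to-leak
#' metric. Parameter sets sharing all groups produce identical scaled
#' recombination curves \code{r(delta_F t)}.
#'
#' @param p \code{\link{model_params}}.
#' @param dose List/row with \code{copies_flp} > 0.
#' @return List with \code{eKd}, \code{scaled_time_rate} (\code{delta_F},
#'   h^-1), \code{scaled_recombination}
#'   (\code{(c/delta_F)(b_f copies/delta_F)^h_rec}) and
#'   \code{basal_fraction} (\code{a_f/b_f}).
#' @export
nondimensional_groups <- function(p, dose) {
  if (p$b_f <= 0 || dose$copies_flp <= 0 || p$delta_F <= 0)
    stop("nondimensional_groups: b_f, delta_F and copies_flp must be > 0")
  cap <- p$b_f * dose$copies_flp
  list(eKd = p$K_d / cap,
       scaled_time_rate = p$delta_F,
       scaled_recombination = p$c / p$delta_F * (cap / p$delta_F)^p$h_rec,
       basal_fraction = p$a_f / p$b_f)
}

#' Invert the constitutive fluorescence-to-copy map
#'
#' Constitutive controls accumulate fluorescence linearly after the mean
#' onset delay: \code{cfp = gamma * copies * (t - mu_delay)}. This inverts
#' that map, rounding to the nearest non-negative integer copy number.
#'
#' @param cfp Fluorescence (MEFL), >= 0; vectorized.
#' @param t Measurement time (hours); must exceed \code{mu_delay}.
#' @param plat \code{\link{platform_params}}.
#' @return Integer copy numbers.
#' @export
copies_from_fluorescence <- function(cfp, t, plat) {
  if (t <= plat$mu_delay)
    stop("copies_from_fluorescence: t <= mu_delay (", plat$mu_delay,
         " h); inversion undefined")
  if (any(cfp < 0)) stop("copies_from_fluorescence: negative fluorescence")
  as.integer(round(cfp / (plat$gamma * (t - plat$mu_delay))))
}
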