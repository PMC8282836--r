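# Synthetic-data generator: transfection doses, full virtual experiments in
# the canonical table schema, and weak graded synNotch-like inputs. All
# randomness flows from one integer seed through a documented splitting
# scheme (one substream per condition), so subsetting a design leaves the
# other conditions' data unchanged.

# deterministic seed splitter; Lehmer-style update kept exact in doubles
# and below 2^31 so it is a valid R seed.
derive_seed <- function(seed, k) {
  as.integer(((as.numeric(seed) %% 2147483647) * 48271 + k * 7919 + 1) %%
               2147483647)
}

#' Plasmid uptake and measurement-noise parameters
#'
#' Transiently transfected cells take up widely varying total plasmid
#' loads; the total is modeled lognormal on the log10 scale and
#' partitioned among co-delivered plasmids in proportion to their mass
#' fractions (transfection complexes co-deliver, which also creates the
#' CFP/copy-number correlation the top-fraction gate exploits).
#'
#' @param mu_uptake,sd_uptake Mean and SD of log10 total plasmid copies.
#' @param autofluorescence_mu Median autofluorescence (MEFL) added per
#'   channel by the measurement model.
#' @param sigma_m Multiplicative measurement noise SD (log10 units).
#' @return Named list of class \code{"uptake_params"}.
#' @export
uptake_params <- function(mu_uptake = 2.5, sd_uptake = 0.4,
                          autofluorescence_mu = 100, sigma_m = 0.1) {
  stopifnot(sd_uptake >= 0, sigma_m >= 0, autofluorescence_mu >= 0)
  structure(list(mu_uptake = mu_uptake, sd_uptake = sd_uptake,
                 autofluorescence_mu = autofluorescence_mu,
                 sigma_m = sigma_m),
            class = "uptake_params")
}

#' Sample per-cell transfection doses
#'
#' Total uptake per cell is drawn lognormal (log10 parameters in
#' \code{uptake}) and partitioned multinomially among the plasmids with
#' probabilities proportional to their mass fractions. Onset delays are
#' Gaussian (\code{plat$mu_delay}, \code{plat$sd_delay}) truncated at 0.
#'
#' @param n_cells Number of cells (>= 1).
#' @param doses_ng Named numeric plasmid masses (ng): \code{flp},
#'   \code{shrna}, \code{reporter}, \code{cfp}. All-zero masses yield
#'   all-zero copies (valid degenerate case).
#' @param uptake \code{\link{uptake_params}}.
#' @param plat \code{\link{platform_params}}.
#' @param seed Integer seed.
#' @return Data frame with integer columns \code{copies_flp,
#'   copies_shrna, copies_reporter, copies_cfp} and numeric
#'   \code{delay_h}.
#' @export
sample_transfection <- function(n_cells, doses_ng, uptake = uptake_params(),
                                plat = platform_params(), seed = 1L) {
  stopifnot(n_cells >= 1)
  ng <- c(flp = 0, shrna = 0, reporter = 0, cfp = 0)
  ng[names(doses_ng)] <- as.numeric(doses_ng)
  if (any(ng < 0)) stop("sample_transfection: negative plasmid mass")
  set.seed(seed)
  total <- round(10^stats::rnorm(n_cells, uptake$mu_uptake, uptake$sd_uptake))
  delay <- pmax(0, stats::rnorm(n_cells, plat$mu_delay, plat$sd_delay))
  if (sum(ng) == 0) {
    copies <- matrix(0L, n_cells, 4)
  } else {
    pr <- ng / sum(ng)
    copies <- t(vapply(total,
                       function(s) stats::rmultinom(1, s, pr)[, 1],
                       integer(4)))
  }
  data.frame(copies_flp = copies[, 1], copies_shrna = copies[, 2],
             copies_reporter = copies[, 3], copies_cfp = copies[, 4],
             delay_h = delay)
}

#' Standard plasmid dose map
#'
#' The digitizer mix varies the Flp and shRNA plasmid masses while the
#' frt-STOP-frt reporter and constitutive-marker plasmids are held at
#' fixed masses.
#'
#' @param flp_ng,shrna_ng Variable component masses (ng).
#' @param reporter_ng,cfp_ng Fixed masses (ng) of the output reporter and
#'   constitutive marker plasmids.
#' @return Named numeric vector for \code{\link{sample_transfection}}.
#' @export
dose_map <- function(flp_ng, shrna_ng, reporter_ng = 50, cfp_ng = 25) {
  c(flp = unname(flp_ng), shrna = unname(shrna_ng),
    reporter = unname(reporter_ng), cfp = unname(cfp_ng))
}

#' Named component-ratio presets
#'
#' Flp:shRNA plasmid-mass configurations spanning the three operating
#' regimes tested per topology: well-balanced, over-repressed (too much
#' shRNA; induction fails) and under-repressed (too little shRNA; leaky
#' basal activation), plus a representative no-shRNA configuration.
#'
#' @param name One of \code{"constant-balanced"} (35:5),
#'   \code{"constant-over"} (1:5), \code{"constant-under"} (35:1),
#'   \code{"feedforward-balanced"} (15:20), \code{"feedforward-over"}
#'   (1:20), \code{"feedforward-under"} (15:1), \code{"no-shrna"} (1:0).
#' @return List with \code{topology}, \code{flp_ng}, \code{shrna_ng}.
#' @export
digitizer_preset <- function(name) {
  presets <- list(
    "constant-balanced"    = list(topology = "CONSTANT",    flp_ng = 35, shrna_ng = 5),
    "constant-over"        = list(topology = "CONSTANT",    flp_ng = 1,  shrna_ng = 5),
    "constant-under"       = list(topology = "CONSTANT",    flp_ng = 35, shrna_ng = 1),
    "feedforward-balanced" = list(topology = "FEEDFORWARD", flp_ng = 15, shrna_ng = 20),
    "feedforward-over"     = list(topology = "FEEDFORWARD", flp_ng = 1,  shrna_ng = 20),
    "feedforward-under"    = list(topology = "FEEDFORWARD", flp_ng = 15, shrna_ng = 1),
    "no-shrna"             = list(topology = "NO_SHRNA",    flp_ng = 1,  shrna_ng = 0))
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  presets[[name]]
}

#' Build a dose-response experiment design
#'
#' One row per (dox level, replicate) at a fixed component ratio and time
#' point; the standard characterization design.
#'
#' @param topology Circuit topology.
#' @param flp_ng,shrna_ng Component masses (ng).
#' @param dox_levels Doxycycline levels (nM); should include 0.
#' @param time_h Measurement time (hours).
#' @param n_cells Cells per condition.
#' @param replicates Number of replicates.
#' @return Data frame design for \code{\link{generate_experiment}}.
#' @export
dose_response_design <- function(topology, flp_ng, shrna_ng,
                                 dox_levels = c(0, 5, 15, 40, 80, 150, 225, 450),
                                 time_h = 48, n_cells = 1000, replicates = 1) {
  grid <- expand.grid(dox_nM = dox_levels, replicate = seq_len(replicates))
  data.frame(topology = topology, flp_ng = flp_ng, shrna_ng = shrna_ng,
             dox_nM = grid$dox_nM, time_h = time_h,
             replicate = grid$replicate, n_cells = n_cells,
             stringsAsFactors = FALSE)
}

#' Generate a full virtual experiment
#'
#' Runs \code{\link{simulate_population}} for every design row with a
#' per-condition derived seed and binds the results into the canonical
#' per-cell table. The seed plus the row index fully determine each
#' condition's data.
#'
#' @param design Data frame with columns \code{topology, flp_ng,
#'   shrna_ng, dox_nM, time_h, replicate, n_cells} (see
#'   \code{\link{dose_response_design}}).
#' @param p,plat,uptake Model, platform and uptake parameters.
#' @param seed Integer master seed.
#' @param reporter_ng,cfp_ng Fixed plasmid masses.
#' @return An \code{experiment_table}.
#' @export
generate_experiment <- function(design, p = model_params(),
                                plat = platform_params(),
                                uptake = uptake_params(), seed = 1L,
                                reporter_ng = 50, cfp_ng = 25) {
  stopifnot(nrow(design) >= 1)
  pops <- lapply(seq_len(nrow(design)), function(j) {
    row <- design[j, ]
    simulate_population(
      n_cells = row$n_cells,
      doses_ng = dose_map(row$flp_ng, row$shrna_ng, reporter_ng, cfp_ng),
      dox = row$dox_nM, topology = row$topology,
      p = p, plat = plat, uptake = uptake, t = row$time_h,
      seed = derive_seed(seed, j * 101), replicate = row$replicate)
  })
  bind_populations(pops)
}

#' Generate a weak graded synNotch-like input
#'
#' Draws per-cell IFP values from a two-component lognormal mixture whose
#' defaults give a weakly separated input (ON/OFF mode separation of
#' about one component SD), emulating the weak graded response of a
#' synNotch sensor: the resulting input SNR is negative, leaving headroom
#' for a digitizer to amplify.
#'
#' @param n_cells Number of cells.
#' @param w_on Weight of the ON component in [0, 1].
#' @param mu_off,mu_on Component means (log10-MEFL), \code{mu_on >=
#'   mu_off}.
#' @param sd Component SD (log10-MEFL).
#' @param seed Integer seed.
#' @return Numeric vector of IFP values (MEFL).
#' @export
generate_synnotch_input <- function(n_cells, w_on = 0.5, mu_off = 2.5,
                                    mu_on = 3.1, sd = 0.4, seed = 1L) {
  if (w_on < 0 || w_on > 1) stop("generate_synnotch_input: w_on must be in [0,1]")
  if (mu_on < mu_off) stop("generate_synnotch_input: mu_on must be >= mu_off")
  set.seed(seed)
  on <- stats::rbinom(n_cells, 1, w_on)
  10^stats::rnorm(n_cells, ifelse(on == 1, mu_on, mu_off), sd)
}
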