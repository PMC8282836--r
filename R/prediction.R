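# Forward prediction: metric heatmaps over Flp:shRNA component-ratio
# grids, transduction of empirical graded input distributions into
# predicted output populations (the synNotch use case), and
# predicted-vs-observed comparison.

#' Metric heatmap over a Flp:shRNA ratio grid
#'
#' Simulates an induced/uninduced population pair at every grid point,
#' gates the top CFP fraction, and computes the OFP metric set (FC, AUC,
#' SNR) plus the OFP-minus-IFP SNR difference of the same populations
#' (positive values mean the circuit amplifies its input).
#'
#' @param p,plat,uptake Model, platform and uptake parameters.
#' @param flp_list,shrna_list Strictly increasing ng grids (non-empty).
#' @param topology Circuit topology.
#' @param dox_induced Induced doxycycline concentration (nM); the
#'   uninduced member of each pair is at 0 nM.
#' @param t Measurement time (hours).
#' @param n_cells Cells per population.
#' @param seed Integer seed (one derived substream per grid point).
#' @param gate_fraction Top CFP gate fraction.
#' @param reporter_ng,cfp_ng Fixed plasmid masses.
#' @return Data frame of class \code{"metric_heatmap"} with one row per
#'   grid point: \code{flp_ng, shrna_ng, fc, auc, snr_db,
#'   delta_snr_db}; the full \code{metric_set} objects are in
#'   \code{attr(, "cells")}.
#' @export
sweep_ratio_grid <- function(p, plat, uptake, flp_list, shrna_list,
                             topology, dox_induced = 225, t = 48,
                             n_cells = 1000, seed = 1L,
                             gate_fraction = 0.3,
                             reporter_ng = 50, cfp_ng = 25) {
  stopifnot(length(flp_list) >= 1, length(shrna_list) >= 1,
            !is.unsorted(flp_list, strictly = TRUE),
            !is.unsorted(shrna_list, strictly = TRUE))
  grid <- expand.grid(flp_ng = flp_list, shrna_ng = shrna_list)
  cells <- vector("list", nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    fng <- grid$flp_ng[i]; sng <- grid$shrna_ng[i]
    dm <- dose_map(fng, sng, reporter_ng, cfp_ng)
    ind <- simulate_population(n_cells, dm, dox_induced, topology, p, plat,
                               uptake, t, derive_seed(seed, i * 13 + 1))
    uni <- simulate_population(n_cells, dm, 0, topology, p, plat,
                               uptake, t, derive_seed(seed, i * 13 + 2))
    gi <- gate_top_fraction(ind, "cfp", gate_fraction)
    gu <- gate_top_fraction(uni, "cfp", gate_fraction)
    ms_ofp <- metric_set(gi, gu, "ofp", seed = derive_seed(seed, i * 13 + 3))
    ms_ifp <- metric_set(gi, gu, "ifp", seed = derive_seed(seed, i * 13 + 4))
    cells[[i]] <<- list(ofp = ms_ofp, ifp = ms_ifp)
    dsnr <- if (ms_ofp$snr$defined && ms_ifp$snr$defined)
      ms_ofp$snr$snr_db - ms_ifp$snr$snr_db else NA_real_
    data.frame(flp_ng = fng, shrna_ng = sng, fc = ms_ofp$fc,
               auc = ms_ofp$auc,
               snr_db = if (ms_ofp$snr$defined) ms_ofp$snr$snr_db else -Inf,
               delta_snr_db = dsnr)
  })
  out <- do.call(rbind, rows)
  attr(out, "cells") <- cells
  attr(out, "topology") <- topology
  class(out) <- c("metric_heatmap", "data.frame")
  out
}

# invert the per-copy pTRE Hill at activity alpha to an equivalent dox
equivalent_dox <- function(alpha, p) {
  if (p$b_f <= p$a_f) stop("equivalent_dox: requires b_f > a_f")
  frac <- pmin(pmax((alpha - p$a_f) / (p$b_f - p$a_f), 0), 1 - 1e-12)
  p$K_dox * (frac / (1 - frac))^(1 / p$n_dox)
}

#' Transduce an empirical input distribution through a digitizer
#'
#' The mixed phenotypic/mechanistic mapping: each input cell's measured
#' IFP is converted to a per-copy pTRE activity via the IFP accumulation
#' relation (\code{ifp ~ b_i * activity * copies_ref * (t - mu_delay)}),
#' that activity replaces the Hill induction term (it is held constant
#' over the simulation window), and the per-cell model is run at the
#' requested component ratio to collect noisy OFP readouts. For the
#' feedforward topology the same activity is mapped back to an
#' equivalent dox level that drives the tetO repression of the shRNA.
#'
#' @param ifp_samples Positive numeric vector: per-cell input IFP (MEFL).
#' @param p,plat,uptake Model, platform and uptake parameters.
#' @param topology Circuit topology.
#' @param ratio Length-2 numeric \code{c(flp_ng, shrna_ng)}.
#' @param t Simulation endpoint (hours).
#' @param seed Integer seed.
#' @param copies_ref Reference copy number of the IFP reporter unit used
#'   in the activity inversion.
#' @param t_input_ref Accumulation time (hours) assumed for the input
#'   measurement; defaults to \code{t}.
#' @param reporter_ng,cfp_ng Fixed plasmid masses.
#' @return A \code{\link{sample_population}} whose \code{ofp} and
#'   \code{cfp} are simulated (with measurement noise) and whose
#'   \code{ifp} column carries the input samples through unchanged.
#' @export
transduce_distribution <- function(ifp_samples, p, plat, uptake, topology,
                                   ratio, t = 48, seed = 1L,
                                   copies_ref = 50, t_input_ref = t,
                                   reporter_ng = 50, cfp_ng = 25) {
  if (any(ifp_samples <= 0)) stop("transduce_distribution: inputs must be positive")
  n <- length(ifp_samples)
  acc_t <- max(t_input_ref - plat$mu_delay, 1e-6)
  alpha <- pmax(0, ifp_samples - uptake$autofluorescence_mu) /
    (p$b_i * copies_ref * acc_t)
  doses <- sample_transfection(n, dose_map(ratio[1], ratio[2],
                                           reporter_ng, cfp_ng),
                               uptake, plat, seed = derive_seed(seed, 1))
  m0 <- alpha * doses$copies_flp
  s0 <- switch(match.arg(topology, TOPOLOGIES),
               NO_SHRNA = rep(0, n),
               CONSTANT = p$b_s * doses$copies_shrna,
               FEEDFORWARD = {
                 dq <- equivalent_dox(alpha, p)
                 rep_f <- p$K_rep^p$n_rep / (p$K_rep^p$n_rep + dq^p$n_rep)
                 p$b_s * doses$copies_shrna * rep_f
               })
  dyn <- cell_dynamics(doses, m0, s0, p, plat, t)
  true_df <- data.frame(cfp = dyn$cfp, ifp = dyn$ifp, ofp = dyn$ofp)
  obs <- apply_measurement_noise(true_df, uptake, derive_seed(seed, 2))
  obs$ifp <- ifp_samples  # input carried through as measured
  cn <- condition(topology, flp_ng = ratio[1],
                  shrna_ng = if (topology == "NO_SHRNA") 0 else ratio[2],
                  dox_nM = 0, time_h = t)
  sample_population(obs, cn)
}

#' Compare predicted and observed metric tables
#'
#' @param predicted,observed Either numeric vectors of equal length or
#'   data frames sharing key columns (e.g. \code{flp_ng, shrna_ng}) and a
#'   \code{value_col}; data frames are matched by key.
#' @param value_col Metric column name when data frames are given.
#' @return List of class \code{"comparison_report"}: \code{pearson_r},
#'   \code{mean_abs_error}, \code{n_points}.
#' @export
compare_predicted_observed <- function(predicted, observed,
                                       value_col = "fc") {
  if (is.data.frame(predicted) && is.data.frame(observed)) {
    keys <- setdiff(intersect(names(predicted), names(observed)),
                    c(value_col, "auc", "snr_db", "delta_snr_db", "fc"))
    m <- merge(predicted[, c(keys, value_col)],
               observed[, c(keys, value_col)],
               by = keys, suffixes = c("_pred", "_obs"))
    x <- m[[paste0(value_col, "_pred")]]
    y <- m[[paste0(value_col, "_obs")]]
  } else {
    x <- as.numeric(predicted); y <- as.numeric(observed)
    if (length(x) != length(y))
      stop("compare_predicted_observed: length mismatch")
  }
  if (length(x) < 3) stop("compare_predicted_observed: need n >= 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("compare_predicted_observed: zero variance; correlation undefined")
  structure(list(pearson_r = stats::cor(x, y),
                 mean_abs_error = mean(abs(x - y)),
                 n_points = length(x)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> r=%.4f, MAE=%.4g over %d points\n",
              x$pearson_r, x$mean_abs_error, x$n_points))
  invisible(x)
}
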