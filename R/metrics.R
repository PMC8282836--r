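# Signal-quality metrics for ON/OFF single-cell fluorescence populations:
# geometric fold change, empirical ROC/AUC, and an extended SNR whose noise
# term combines the average geometric spread with a "fail power" carried by
# dud (OFF-when-should-be-ON) and leaky (ON-when-should-be-OFF) cells.

#' Geometric mean and geometric standard deviation
#'
#' @param values Positive numeric vector (fluorescence, MEFL).
#' @return List with \code{geomean} (same units as input) and \code{geosd}
#'   (dimensionless, >= 1; 1 for a single value), computed as
#'   \code{exp(mean(log v))} and \code{exp(sd(log v))} with the sample
#'   (n-1) denominator.
#' @export
geometric_stats <- function(values) {
  if (length(values) < 1) stop("geometric_stats: empty input")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("geometric_stats: all values must be positive and finite")
  lv <- log(values)
  gs <- if (length(values) == 1) 1 else exp(stats::sd(lv))
  list(geomean = exp(mean(lv)), geosd = gs)
}

#' Geometric fold change between ON and OFF populations
#'
#' Fold change is the mean ON-state expression divided by the mean
#' OFF-state expression; means are geometric, matching the lognormal-like
#' character of fluorescence distributions.
#'
#' @param on_pop,off_pop Positive numeric vectors of per-cell fluorescence.
#' @return Dimensionless fold change (> 0).
#' @export
fold_change <- function(on_pop, off_pop) {
  geometric_stats(on_pop)$geomean / geometric_stats(off_pop)$geomean
}

#' Empirical ROC curve and AUC
#'
#' Builds the receiver operating characteristic by sweeping a threshold
#' over the combined range of both samples (all distinct observed values
#' plus infinite endpoints); at each threshold a cell counts as ON if its
#' value exceeds the threshold. The area under the curve is computed by
#' trapezoid, which gives tied values half credit, so the AUC equals the
#' Mann-Whitney U statistic divided by \code{n_pos * n_neg} with tie
#' correction. AUC 0.5 means the populations are indistinguishable; AUC 1
#' means completely distinguishable.
#'
#' @param pos,neg Numeric vectors: the putative ON (positive) and OFF
#'   (negative) populations.
#' @return List with \code{auc} and \code{roc}, a data frame of
#'   \code{(threshold, fpr, tpr)} rows ordered by decreasing threshold.
#' @export
empirical_auc <- function(pos, neg) {
  if (length(pos) == 0 || length(neg) == 0)
    stop("empirical_auc: both populations must be non-empty")
  thr <- c(-Inf, sort(unique(c(pos, neg))), Inf)
  np <- length(pos); nn <- length(neg)
  # survival counts: number of values strictly above each threshold
  tpr <- vapply(thr, function(t) sum(pos > t), 0) / np
  fpr <- vapply(thr, function(t) sum(neg > t), 0) / nn
  roc <- data.frame(threshold = thr, fpr = fpr, tpr = tpr)
  # integrate TPR d(FPR); fpr is non-increasing along thr
  o <- order(roc$fpr, roc$tpr)
  x <- roc$fpr[o]; y <- roc$tpr[o]
  auc <- sum(diff(x) * (head2(y) + tail2(y)) / 2)
  list(auc = auc, roc = roc)
}

head2 <- function(x) x[-length(x)]
tail2 <- function(x) x[-1]

#' Fit a two-component Gaussian mixture in log10 space
#'
#' Deterministic EM on \code{log10(values)} with k = 2, initialized from
#' the 25th/75th percentile split (means at those quantiles, both standard
#' deviations at the pooled value, equal weights). Components are returned
#' sorted by mean. The fit is flagged unimodal when the fitted means
#' differ by less than 0.05 log10 units, when the components are not
#' separated relative to their spreads (Ashman's D below 2, the point at
#' which a two-Gaussian mixture loses its second mode), or when BIC
#' prefers a single Gaussian; without these checks the EM happily splits
#' one broad mode into two overlapping components, or spends a component
#' on a handful of outliers.
#'
#' @param values Positive numeric vector, length >= 10.
#' @param seed Integer; accepted for interface uniformity. The EM itself
#'   is deterministic, so the seed does not influence the result.
#' @param max_iter,tol,var_floor EM controls: iteration cap, relative
#'   tolerance, and variance floor (log10 units squared) preventing
#'   component collapse. Convergence requires both the log-likelihood and
#'   the parameters to stabilize: on overlapping data the EM crosses long
#'   likelihood plateaus where the parameters still drift, and stopping on
#'   the likelihood alone leaves an endpoint that is not a stable function
#'   of the input.
#' @return Object of class \code{"mixture_fit"} with fields \code{w_off,
#'   w_on, mu_off, mu_on, sd_off, sd_on} (log10-MEFL), \code{loglik},
#'   \code{converged}, \code{unimodal}.
#' @export
fit_log_mixture2 <- function(values, seed = 1L, max_iter = 5000,
                             tol = 1e-8, var_floor = 1e-4) {
  if (length(values) < 10) stop("fit_log_mixture2: need n >= 10")
  if (any(values <= 0)) stop("fit_log_mixture2: values must be positive")
  x <- log10(values)
  # center so that common positive scaling of the input (a shift in log
  # space) cancels exactly instead of to float precision
  ctr <- mean(x)
  x <- x - ctr
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, type = 7)
  mu <- c(q[1], q[2])
  s0 <- max(stats::sd(x), sqrt(var_floor))
  sd_ <- c(s0, s0)
  w <- c(0.5, 0.5)
  ll_old <- -Inf; theta_old <- rep(Inf, 6); converged <- FALSE; ll <- NA_real_
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sd_[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sd_[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r2 <- d2 / tot
    ll <- sum(log(tot))
    theta <- c(w, mu, sd_)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * (abs(ll_old) + 1) &&
        max(abs(theta - theta_old)) <= tol * (max(abs(theta_old)) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    theta_old <- theta
    n2 <- sum(r2); n1 <- length(x) - n2
    w <- c(n1, n2) / length(x)
    w <- pmin(pmax(w, 1e-12), 1 - 1e-12)
    mu[1] <- sum((1 - r2) * x) / max(n1, 1e-12)
    mu[2] <- sum(r2 * x) / max(n2, 1e-12)
    v1 <- sum((1 - r2) * (x - mu[1])^2) / max(n1, 1e-12)
    v2 <- sum(r2 * (x - mu[2])^2) / max(n2, 1e-12)
    sd_ <- sqrt(pmax(c(v1, v2), var_floor))
  }
  if (mu[1] > mu[2]) { mu <- rev(mu); sd_ <- rev(sd_); w <- rev(w) }
  # Unimodality: means essentially equal; or components unseparated
  # relative to their spreads (Ashman's D < 2, below which a two-Gaussian
  # mixture has a single mode); or the two-component fit not worth its
  # extra parameters against a single Gaussian by BIC (catches a tiny
  # outlier-chasing component whose narrow sd inflates D)
  ashman_d <- sqrt(2) * (mu[2] - mu[1]) / sqrt(sd_[1]^2 + sd_[2]^2)
  n <- length(x)
  bic2 <- -2 * ll + 5 * log(n)
  bic1 <- -2 * sum(stats::dnorm(x, mean(x), stats::sd(x) * sqrt((n - 1) / n),
                                log = TRUE)) + 2 * log(n)
  structure(list(w_off = w[1], w_on = w[2],
                 mu_off = mu[1] + ctr, mu_on = mu[2] + ctr,
                 sd_off = sd_[1], sd_on = sd_[2],
                 loglik = ll, converged = converged,
                 ashman_d = ashman_d,
                 unimodal = (mu[2] - mu[1]) < 0.05 || ashman_d < 2 ||
                   bic1 <= bic2,
                 pooled_mu = ctr,
                 pooled_sd = max(stats::sd(x), sqrt(var_floor))),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit> OFF: w=%.3f mu=%.3f sd=%.3f | ON: w=%.3f mu=%.3f sd=%.3f%s%s\n",
              x$w_off, x$mu_off, x$sd_off, x$w_on, x$mu_on, x$sd_on,
              if (x$unimodal) " [unimodal]" else "",
              if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

#' Assemble an SNR report from its components
#'
#' The extended SNR treats the log10 separation between the ON mode of the
#' induced population and the OFF mode of the uninduced population as the
#' signal amplitude, and the noise as the average mode spread plus the
#' "fail power" contributed by misclassified cells:
#' \deqn{SNR_{dB} = 10 \log_{10}\frac{\Delta\mu^2}
#'   {\bar\sigma^2 + (P_{Dud} + P_{Leaky})\,\Delta\mu^2}}
#' A dud cell is OFF when it should be ON; a leaky cell is ON when it
#' should be OFF. Each misclassified cell contributes a full-amplitude
#' squared error, which keeps the fail term dimensionally commensurate
#' with the spread term.
#'
#' @param delta_mu Signal amplitude (log10-MEFL); if <= 0 the SNR is
#'   undefined and the report carries a negative-infinite sentinel.
#' @param sigma_bar Average component standard deviation (log10-MEFL).
#' @param p_dud,p_leaky Fail probabilities in [0, 1].
#' @return Object of class \code{"snr_report"} with fields \code{snr_db,
#'   delta_mu, sigma_bar, p_dud, p_leaky, fail_power, defined}.
#' @export
snr_report <- function(delta_mu, sigma_bar, p_dud = 0, p_leaky = 0) {
  stopifnot(p_dud >= 0, p_dud <= 1, p_leaky >= 0, p_leaky <= 1,
            sigma_bar >= 0)
  fail_power <- (p_dud + p_leaky) * delta_mu^2
  defined <- is.finite(delta_mu) && delta_mu > 0
  snr <- if (defined)
    10 * log10(delta_mu^2 / (sigma_bar^2 + fail_power)) else -Inf
  structure(list(snr_db = snr, delta_mu = delta_mu, sigma_bar = sigma_bar,
                 p_dud = p_dud, p_leaky = p_leaky,
                 fail_power = fail_power, defined = defined),
            class = "snr_report")
}

#' @export
print.snr_report <- function(x, ...) {
  if (x$defined)
    cat(sprintf("<snr_report> %.2f dB (delta_mu=%.3f, sigma_bar=%.3f, P_Dud=%.3f, P_Leaky=%.3f)\n",
                x$snr_db, x$delta_mu, x$sigma_bar, x$p_dud, x$p_leaky))
  else cat("<snr_report> undefined (zero signal amplitude)\n")
  invisible(x)
}

as_channel_values <- function(x, channel, floor = 1) {
  v <- if (inherits(x, "sample_population")) channel_values(x, channel) else x
  pmax(v, floor)
}

#' Extended signal-to-noise ratio of an induced/uninduced pair
#'
#' Fits a two-component log10 Gaussian mixture to each population. The ON
#' mode of the induced fit and the OFF mode of the uninduced fit set the
#' signal amplitude \code{delta_mu}; their spreads average to
#' \code{sigma_bar}; \code{p_dud} is the weight of the OFF-like component
#' in the induced fit and \code{p_leaky} the weight of the ON-like
#' component in the uninduced fit. If a fit is flagged unimodal its pooled
#' mean/sd are used and its fail weight is 0 (a unimodal population has no
#' misclassified mode). If the resulting amplitude is zero or negative the
#' report carries a negative-infinite sentinel rather than erroring.
#'
#' @param induced,uninduced \code{sample_population} objects or numeric
#'   vectors of fluorescence values.
#' @param channel Channel to analyze when populations are given.
#' @param seed Passed to \code{\link{fit_log_mixture2}}.
#' @param floor Detection floor (MEFL) applied before the log transform.
#' @return An \code{\link{snr_report}}.
#' @export
snr_db <- function(induced, uninduced, channel = "ofp", seed = 1L, floor = 1) {
  on_v  <- as_channel_values(induced, channel, floor)
  off_v <- as_channel_values(uninduced, channel, floor)
  fit_on  <- fit_log_mixture2(on_v, seed)
  fit_off <- fit_log_mixture2(off_v, seed)
  if (fit_on$unimodal) {
    mu_on <- fit_on$pooled_mu; sd_on <- fit_on$pooled_sd; p_dud <- 0
  } else {
    mu_on <- fit_on$mu_on; sd_on <- fit_on$sd_on; p_dud <- fit_on$w_off
  }
  if (fit_off$unimodal) {
    mu_off <- fit_off$pooled_mu; sd_off <- fit_off$pooled_sd; p_leaky <- 0
  } else {
    mu_off <- fit_off$mu_off; sd_off <- fit_off$sd_off; p_leaky <- fit_off$w_on
  }
  delta_mu <- mu_on - mu_off
  rep <- snr_report(delta_mu, (sd_on + sd_off) / 2, p_dud, p_leaky)
  rep$fit_induced <- fit_on
  rep$fit_uninduced <- fit_off
  rep
}

#' Construct a metric set from precomputed components
#'
#' @param fc Fold change (> 0).
#' @param auc AUC in [0, 1].
#' @param snr An \code{\link{snr_report}} (or bare dB value, wrapped with
#'   zero fail probabilities and unit amplitude bookkeeping).
#' @return Object of class \code{"metric_set"}.
#' @export
new_metric_set <- function(fc, auc, snr) {
  stopifnot(fc > 0, auc >= 0, auc <= 1)
  if (!inherits(snr, "snr_report")) {
    db <- snr
    snr <- snr_report(1, 1)  # placeholder geometry
    snr$snr_db <- db
    snr$defined <- is.finite(db)
  }
  structure(list(fc = fc, auc = auc, snr = snr), class = "metric_set")
}

#' Full metric set for an induced/uninduced population pair
#'
#' Bundles the three signal-quality metrics for one channel: geometric
#' fold change, empirical AUC, and extended SNR.
#'
#' @inheritParams snr_db
#' @return A \code{metric_set} with fields \code{fc}, \code{auc},
#'   \code{snr} (an \code{\link{snr_report}}).
#' @export
metric_set <- function(induced, uninduced, channel = "ofp", seed = 1L,
                       floor = 1) {
  on_v  <- as_channel_values(induced, channel, floor)
  off_v <- as_channel_values(uninduced, channel, floor)
  ms <- new_metric_set(fold_change(on_v, off_v),
                       empirical_auc(on_v, off_v)$auc,
                       snr_db(on_v, off_v, channel, seed, floor))
  ms
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("<metric_set> FC=%.3g  AUC=%.3f  SNR=%s dB\n",
              x$fc, x$auc,
              if (x$snr$defined) sprintf("%.2f", x$snr$snr_db) else "-Inf"))
  invisible(x)
}

#' Output-minus-input metric differences
#'
#' Measures how a signal changes as it propagates through a circuit: each
#' delta is the output metric minus the input metric. A positive
#' \code{delta_snr_db} indicates amplification.
#'
#' @param input_ms,output_ms \code{metric_set} objects (input, e.g. IFP;
#'   output, e.g. OFP).
#' @return List of class \code{"delta_report"} with \code{delta_snr_db},
#'   \code{delta_fc}, \code{delta_auc}.
#' @export
delta_metrics <- function(input_ms, output_ms) {
  stopifnot(inherits(input_ms, "metric_set"), inherits(output_ms, "metric_set"))
  if (!input_ms$snr$defined || !output_ms$snr$defined)
    stop("delta_metrics: undefined SNR sentinel in input; deltas are undefined")
  structure(list(delta_snr_db = output_ms$snr$snr_db - input_ms$snr$snr_db,
                 delta_fc = output_ms$fc - input_ms$fc,
                 delta_auc = output_ms$auc - input_ms$auc),
            class = "delta_report")
}

#' @export
print.delta_report <- function(x, ...) {
  cat(sprintf("<delta_report> dSNR=%.2f dB  dFC=%.3g  dAUC=%.3f\n",
              x$delta_snr_db, x$delta_fc, x$delta_auc))
  invisible(x)
}

#' Fraction of cells above a threshold
#'
#' Simple ON-state classifier used for regime checks (e.g. an
#' over-repressed circuit fails to induce: ON fraction below 10\%).
#'
#' @param pop \code{sample_population} or numeric vector.
#' @param channel Channel name when a population is given.
#' @param threshold MEFL threshold separating OFF from ON. The default,
#'   3000 MEFL, is the geometric midpoint between the typical OFF level
#'   (a few hundred MEFL including autofluorescence) and the typical
#'   fully-ON level (a few tens of thousands of MEFL) of the default
#'   parameterization.
#' @return Proportion of cells with channel value above \code{threshold}.
#' @export
on_fraction <- function(pop, channel = "ofp", threshold = 3000) {
  v <- if (inherits(pop, "sample_population")) channel_values(pop, channel) else pop
  mean(v > threshold)
}
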