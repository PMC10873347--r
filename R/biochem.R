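#' Fit a sigmoidal dose-response (Hill) curve
#'
#' Fits the four-parameter variable-slope logistic
#' `S(C) = bottom + (top - bottom) * C^h / (K05^h + C^h)` by nonlinear
#' least squares (Levenberg-Marquardt). `K05` is read directly as the
#' midpoint: the concentration at half-maximal signal. The slope is a free
#' nuisance parameter. The orientation (rising or falling with dose) is
#' taken from the data. A case-resampling bootstrap gives the K_0.5
#' confidence interval.
#'
#' @param curve Data frame with columns `concentration` and `signal`
#'   (optionally `replicate`), e.g. from [simulate_binding_curve()].
#' @param bootstrap_n Bootstrap resamples for the K_0.5 CI (0 disables).
#' @param conf_level Bootstrap CI level.
#' @param seed Integer seed for the bootstrap.
#' @return List of class `hill_fit`: `K05`, `h`, `top`, `bottom`, `K05_ci`
#'   (percentile bootstrap), `rss`, `converged`, `n_boot_ok`.
#' @export
fit_dose_response <- function(curve, bootstrap_n = 1000, conf_level = 0.95,
                              seed = 1) {
  stopifnot(all(c("concentration", "signal") %in% names(curve)))
  curve <- curve[complete.cases(curve[, c("concentration", "signal")]), ]
  if (length(unique(curve$concentration)) < 5)
    stop("need at least 5 distinct concentrations")
  if (diff(range(curve$signal)) == 0) stop("all-flat signal")
  fit <- hill_nls(curve)
  if (!fit$converged)
    return(structure(c(fit, list(K05_ci = c(NA_real_, NA_real_),
                                 n_boot_ok = 0L)), class = "hill_fit"))
  ci <- c(NA_real_, NA_real_)
  n_ok <- 0L
  if (bootstrap_n > 0) {
    old <- set_local_seed(seed)
    on.exit(restore_seed(old))
    k <- rep(NA_real_, bootstrap_n)
    n <- nrow(curve)
    for (b in seq_len(bootstrap_n)) {
      bs <- curve[sample.int(n, n, replace = TRUE), ]
      if (length(unique(bs$concentration)) < 5) next
      bf <- tryCatch(hill_nls(bs), error = function(e) NULL)
      if (!is.null(bf) && bf$converged) k[b] <- bf$K05
    }
    n_ok <- sum(!is.na(k))
    if (n_ok > 0) {
      a <- (1 - conf_level) / 2
      ci <- unname(quantile(k, c(a, 1 - a), na.rm = TRUE))
    }
  }
  structure(c(fit, list(K05_ci = ci, n_boot_ok = n_ok)),
            class = "hill_fit")
}

# Core Hill least squares. Initial guesses: plateaus from the signals at
# the dose extremes, K05 from the half-max crossing, h = 1.
hill_nls <- function(curve) {
  conc <- curve$concentration
  sig <- curve$signal
  ord <- order(conc)
  lo_sig <- mean(sig[conc == min(conc)])
  hi_sig <- mean(sig[conc == max(conc)])
  k0 <- halfmax_crossing(conc[ord], sig[ord], lo_sig, hi_sig)
  pos <- conc[conc > 0]
  if (!is.finite(k0) || k0 <= 0) k0 <- exp(mean(log(pos)))
  resid_fn <- function(par) {
    pred <- hill_signal(conc, par[["K"]], par[["h"]], par[["b0"]],
                        par[["b1"]])
    sig - pred
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(b0 = lo_sig, b1 = hi_sig, K = k0, h = 1),
      lower = c(b0 = -Inf, b1 = -Inf, K = 1e-9, h = 1e-9),
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info < 1 || fit$info > 4)
    return(list(K05 = NA_real_, h = NA_real_, top = NA_real_,
                bottom = NA_real_, rss = NA_real_, converged = FALSE))
  cf <- coef(fit)
  # b0 is the zero-dose plateau, b1 the saturating plateau; top/bottom
  # reported so that bottom <= top regardless of curve orientation.
  plateaus <- sort(c(cf[["b0"]], cf[["b1"]]))
  list(K05 = cf[["K"]], h = cf[["h"]], top = plateaus[2],
       bottom = plateaus[1], rss = fit$deviance,
       converged = TRUE)
}

# Linear interpolation of the concentration at half-maximal signal, used
# both as the K05 starting value and as an independent oracle on dense
# noiseless curves.
halfmax_crossing <- function(conc, sig, s0, s1) {
  half <- (s0 + s1) / 2
  d <- sig - half
  i <- which(d[-1] * d[-length(d)] <= 0)[1]
  if (is.na(i)) return(NA_real_)
  c1 <- conc[i]; c2 <- conc[i + 1]
  if (d[i + 1] == d[i]) return((c1 + c2) / 2)
  c1 + (c2 - c1) * (half - sig[i]) / (sig[i + 1] - sig[i])
}

#' Calibrate a radiolabel standard curve
#'
#' Least-squares line through the origin relating phosphor-imager signal
#' to nCi of the ATP standards: `slope = sum(signal * nCi) / sum(nCi^2)`.
#'
#' @param standards Data frame with columns `nCi` and `signal` (>= 1
#'   point; a single point gives exact proportionality with a warning).
#' @return List: `slope` (signal per nCi), `to_nCi` (function converting
#'   signal to nCi), `n`.
#' @export
calibrate_standard_curve <- function(standards) {
  stopifnot(all(c("nCi", "signal") %in% names(standards)))
  standards <- standards[complete.cases(standards[, c("nCi", "signal")]), ]
  if (nrow(standards) == 0) stop("no standards")
  if (all(standards$nCi == 0)) stop("zero-variance standards")
  if (nrow(standards) == 1)
    warning("single standard point: slope from one-point proportionality")
  slope <- sum(standards$signal * standards$nCi) / sum(standards$nCi^2)
  list(slope = slope, to_nCi = function(signal) signal / slope,
       n = nrow(standards))
}

#' Fit Michaelis-Menten kinetics from a kinase time course
#'
#' Per-substrate rates come from an ordinary least-squares line through
#' the origin over the time-course points (`rate = sum(p * t) / sum(t^2)`,
#' i.e. using the entire time course); the rate-vs-substrate curve
#' `v = Vmax * S / (KM + S)` is then fit by nonlinear least squares, and
#' `kcat = Vmax / [E]` with its standard error from `SE(Vmax) / [E]`.
#'
#' @param data A `kinetics_dataset` (from [simulate_kinase_timecourse()])
#'   or a list with `timecourse` (`substrate_uM`, `time_min`,
#'   `product_uM`) and `enzyme_nM`.
#' @param through_origin Fit the per-substrate rate line through the
#'   origin (default) or with a free intercept.
#' @return List of class `mm_fit`: `kcat`, `kcat_se`, `KM`, `KM_se`,
#'   `Vmax` (uM/s), `rates` (per-substrate data frame), `converged`,
#'   `initial_rate_ok`.
#' @export
fit_michaelis_menten <- function(data, through_origin = TRUE) {
  tc <- data$timecourse
  stopifnot(all(c("substrate_uM", "time_min", "product_uM") %in% names(tc)))
  E <- data$enzyme_nM / 1000  # uM
  S <- sort(unique(tc$substrate_uM), decreasing = TRUE)
  if (length(S) < 3) stop("fewer than 3 substrate concentrations")
  rates <- vapply(S, function(s) {
    d <- tc[tc$substrate_uM == s, ]
    t_s <- d$time_min * 60
    if (through_origin) sum(d$product_uM * t_s) / sum(t_s^2)
    else coef(lm(product_uM ~ t_s, data = d))[["t_s"]] # nolint
  }, numeric(1))
  if (any(rates < 0)) stop("negative fitted rate")
  initial_rate_ok <- all(tc$product_uM <= 0.1 * tc$substrate_uM + 1e-12)
  rdf <- data.frame(substrate_uM = S, rate_uM_s = rates)
  start <- list(Vmax = max(rates), KM = median(S))
  # Relative weighting (1/rate^2): radiolabel quantification errors are
  # multiplicative, so proportional-error weighting keeps the low-substrate
  # rates informative and the parameter SEs consistent with the noise.
  w <- 1 / pmax(rates, .Machine$double.eps)^2
  fit <- tryCatch(
    minpack.lm::nlsLM(rate_uM_s ~ Vmax * substrate_uM / (KM + substrate_uM),
                      data = rdf, start = start, weights = w,
                      lower = c(Vmax = 0, KM = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(structure(list(kcat = NA_real_, kcat_se = NA_real_,
                          KM = NA_real_, KM_se = NA_real_, Vmax = NA_real_,
                          rates = rdf, converged = FALSE,
                          initial_rate_ok = initial_rate_ok),
                     class = "mm_fit"))
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e)
    c(Vmax = NA_real_, KM = NA_real_))
  structure(list(kcat = cf[["Vmax"]] / E, kcat_se = se[["Vmax"]] / E,
                 KM = cf[["KM"]], KM_se = se[["KM"]],
                 Vmax = cf[["Vmax"]], rates = rdf, converged = TRUE,
                 initial_rate_ok = initial_rate_ok),
            class = "mm_fit")
}

#' Normalize phosphorylation rates to a reference substrate
#'
#' @param rates Named numeric vector of rates.
#' @param reference Name of the reference (default `"WT"`).
#' @return Named vector of `rate / rate_reference`; the reference maps
#'   to 1.
#' @export
normalize_rate_to_wt <- function(rates, reference = "WT") {
  if (!reference %in% names(rates)) stop("reference rate missing")
  if (!is.finite(rates[[reference]]) || rates[[reference]] <= 0)
    stop("reference rate must be positive")
  rates / rates[[reference]]
}

#' Phosphorylated fraction from Phos-tag band intensities
#'
#' @param upper_band Intensity of the phosphorylated (upper) band.
#' @param lower_band Intensity of the unphosphorylated (lower) band.
#' @return `upper / (upper + lower)`, in [0, 1].
#' @export
phospho_fraction <- function(upper_band, lower_band) {
  if (any(upper_band < 0) || any(lower_band < 0))
    stop("band intensities must be >= 0")
  tot <- upper_band + lower_band
  if (any(tot == 0)) stop("both bands zero")
  upper_band / tot
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: K0.5 = %.4g [%.4g, %.4g], h = %.3g, plateaus %.3g-%.3g\n",
              x$K05, x$K05_ci[1], x$K05_ci[2], x$h, x$bottom, x$top))
  invisible(x)
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("MM fit: kcat = %.3g +/- %.2g 1/s, KM = %.3g +/- %.2g uM\n",
              x$kcat, x$kcat_se, x$KM, x$KM_se))
  invisible(x)
}
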