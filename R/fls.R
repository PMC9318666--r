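# Fluorescence lifetime stage: biexponential TCSPC fits, intensity-weighted
# mean lifetimes, Forster-Hoffman calibration and microviscosity inversion.

#' Intensity-weighted mean fluorescence lifetime
#'
#' \eqn{\langle\tau\rangle = \sum a_i \tau_i^2 / \sum a_i \tau_i}: each
#' component weighted by its steady-state intensity contribution
#' \eqn{a_i \tau_i}. Always lies between the smallest and largest component
#' lifetime.
#'
#' @param amplitudes non-negative component amplitudes, not all zero.
#' @param lifetimes_ns positive component lifetimes (ns), same length.
#' @return Mean lifetime in ns.
#' @examples
#' intensity_weighted_lifetime(c(0.5, 0.5), c(10, 20))  # 16.67 ns
#' @export
intensity_weighted_lifetime <- function(amplitudes, lifetimes_ns) {
  if (length(amplitudes) != length(lifetimes_ns))
    stop_invalid("amplitudes and lifetimes must have equal length")
  if (any(!is.finite(amplitudes)) || any(amplitudes < 0) || sum(amplitudes) == 0)
    stop_invalid("amplitudes must be non-negative and not all zero")
  if (any(!is.finite(lifetimes_ns)) || any(lifetimes_ns <= 0))
    stop_invalid("lifetimes must be positive")
  sum(amplitudes * lifetimes_ns^2) / sum(amplitudes * lifetimes_ns)
}

# model expectation per bin; optionally convolved with a normalized IRF
.decay_model <- function(t, a, tau, bg, irf = NULL) {
  y <- rowSums(vapply(seq_along(a),
                      function(j) a[j] * exp(-t / tau[j]), numeric(length(t))))
  if (!is.null(irf)) {
    k <- irf / sum(irf)
    n <- length(y)
    y <- stats::convolve(y, rev(k), type = "open")[seq_len(n)]
  }
  y + bg
}

#' Fit a biexponential decay to a TCSPC histogram
#'
#' Weighted least squares on photon counts with Poisson weights
#' (\eqn{w_i = 1/\max(c_i, 1)}), model
#' \eqn{c(t) = s[f_1 e^{-t/\tau_1} + (1-f_1) e^{-t/\tau_2}] + b}, fitted
#' from the peak bin onward (tail fitting). When an instrument response is
#' stored in the histogram and `use_irf = TRUE` the model is convolved with
#' the normalized IRF. Components are ordered \eqn{\tau_1 \le \tau_2}; when
#' they collapse within 5% the fit is rerun as a single exponential and a
#' `collapsed` flag is set. Amplitudes are reported as fractions summing to
#' one plus a common scale.
#'
#' @param hist a [decay_histogram()] with at least 1e4 total counts and 100
#'   bins past the peak.
#' @param use_irf convolve with the stored IRF (default `FALSE`; tail
#'   fitting past the peak usually makes deconvolution unnecessary for
#'   lifetimes much longer than the IRF).
#' @return Object of class `"tcspc_fit"`: `amplitudes` (fractional),
#'   `lifetimes_ns` (tau1 <= tau2), `tau_avg_ns` (intensity weighted),
#'   `chi2_reduced`, `background`, `scale`, `converged`, `collapsed`.
#' @seealso [gen_decay_histogram()], [intensity_weighted_lifetime()]
#' @export
fit_biexponential <- function(hist, use_irf = FALSE) {
  stopifnot(inherits(hist, "decay_histogram"))
  if (sum(hist$counts) < 1e4)
    stop_invalid("need at least 1e4 total counts")
  if (sum(hist$counts) == 0 || max(hist$counts) == 0)
    stop_invalid("all-zero histogram")
  ipk <- which.max(hist$counts)
  if (length(hist$counts) - ipk < 100)
    stop_invalid("need at least 100 bins past the peak")
  t <- hist$time_ns[ipk:length(hist$time_ns)] - hist$time_ns[ipk]
  y <- hist$counts[ipk:length(hist$counts)]
  w <- 1 / pmax(y, 1)
  irf <- if (use_irf && !is.null(hist$irf_counts))
    hist$irf_counts[ipk:length(hist$irf_counts)] else NULL

  # initial lifetimes: log-linear slope of the late tail and of the early decay
  tail_idx <- seq(floor(0.6 * length(t)), length(t))
  early_idx <- seq_len(max(10, floor(0.15 * length(t))))
  slope_fit <- function(idx) {
    pos <- idx[y[idx] > 0]
    if (length(pos) < 5) return(NA_real_)
    -1 / unname(stats::coef(stats::lm(log(y[pos]) ~ t[pos]))[2])
  }
  tau2_0 <- slope_fit(tail_idx); tau1_0 <- slope_fit(early_idx)
  if (!is.finite(tau2_0) || tau2_0 <= 0) tau2_0 <- max(t) / 3
  if (!is.finite(tau1_0) || tau1_0 <= 0 || tau1_0 >= tau2_0) tau1_0 <- tau2_0 / 3
  s0 <- max(y); bg0 <- max(stats::median(y[tail_idx]) / 10, 1e-3)

  sw <- sqrt(w)
  lm_fit <- function(par, model_fn, lower, upper) {
    out <- tryCatch(
      minpack.lm::nls.lm(par = par,
                         fn = function(p) sw * (y - model_fn(p)),
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 1000)),
      error = function(e) NULL)
    if (is.null(out) || !(out$info %in% 1:4) || any(!is.finite(out$par)))
      return(NULL)
    out
  }
  model2 <- function(p) .decay_model(t, c(p[["s"]] * p[["f1"]],
                                          p[["s"]] * (1 - p[["f1"]])),
                                     c(p[["tau1"]], p[["tau2"]]), p[["bg"]], irf)
  model1 <- function(p) .decay_model(t, p[["s"]], p[["tau1"]], p[["bg"]], irf)

  # the biexponential SSR surface has local minima (e.g. one rate sliding to
  # zero to mimic the background); a small deterministic grid of starts with
  # the lowest weighted SSR kept makes the fit reliable without randomness
  starts <- list()
  for (f0 in c(0.3, 0.6))
    for (r0 in c(0.1, 0.3, 0.6))
      for (b0 in unique(c(1e-3, bg0)))
        starts[[length(starts) + 1]] <-
          c(s = s0, f1 = f0, tau1 = r0 * tau2_0, tau2 = tau2_0, bg = b0)
  if (is.finite(tau1_0) && tau1_0 < tau2_0)
    starts[[length(starts) + 1]] <-
      c(s = s0, f1 = 0.5, tau1 = tau1_0, tau2 = tau2_0, bg = 1e-3)
  fit2 <- NULL
  for (st in starts) {
    cand <- lm_fit(st, model2,
                   lower = c(s = 0, f1 = 0, tau1 = 1e-6, tau2 = 1e-6, bg = 0),
                   upper = c(s = Inf, f1 = 1, tau1 = Inf, tau2 = Inf, bg = Inf))
    if (!is.null(cand) &&
        (is.null(fit2) || cand$deviance < fit2$deviance)) fit2 <- cand
  }

  collapsed <- FALSE
  if (!is.null(fit2)) {
    co <- fit2$par
    taus <- sort(c(co[["tau1"]], co[["tau2"]]))
    fr <- if (co[["tau1"]] <= co[["tau2"]]) c(co[["f1"]], 1 - co[["f1"]])
          else c(1 - co[["f1"]], co[["f1"]])
    if (diff(taus) / taus[2] < 0.05 || min(fr) < 1e-4) collapsed <- TRUE
  }
  if (is.null(fit2) || collapsed) {
    fit1 <- lm_fit(c(s = s0, tau1 = tau2_0, bg = bg0), model1,
                   lower = c(s = 0, tau1 = 1e-6, bg = 0),
                   upper = c(s = Inf, tau1 = Inf, bg = Inf))
    if (is.null(fit1)) {
      return(structure(list(converged = FALSE, collapsed = collapsed,
                            amplitudes = c(NA_real_, NA_real_),
                            lifetimes_ns = c(NA_real_, NA_real_),
                            tau_avg_ns = NA_real_, chi2_reduced = NA_real_,
                            background = NA_real_, scale = NA_real_,
                            hist = hist),
                       class = "tcspc_fit"))
    }
    co <- fit1$par
    dof <- length(y) - 3
    res <- structure(list(converged = TRUE, collapsed = TRUE,
                          amplitudes = c(1, 0),
                          lifetimes_ns = c(co[["tau1"]], co[["tau1"]]),
                          tau_avg_ns = co[["tau1"]],
                          chi2_reduced = sum((y - model1(co))^2 / pmax(y, 1)) / dof,
                          background = co[["bg"]], scale = co[["s"]],
                          hist = hist),
                     class = "tcspc_fit")
    if (collapsed) warning("biexponential components collapsed; single-exponential fit reported")
    return(res)
  }

  co <- fit2$par
  ord <- order(c(co[["tau1"]], co[["tau2"]]))
  taus <- c(co[["tau1"]], co[["tau2"]])[ord]
  fracs <- c(co[["f1"]], 1 - co[["f1"]])[ord]
  dof <- length(y) - 5
  structure(list(converged = TRUE, collapsed = FALSE,
                 amplitudes = fracs, lifetimes_ns = taus,
                 tau_avg_ns = intensity_weighted_lifetime(fracs, taus),
                 chi2_reduced = sum((y - model2(co))^2 / pmax(y, 1)) / dof,
                 background = co[["bg"]], scale = co[["s"]], hist = hist),
            class = "tcspc_fit")
}

#' @export
print.tcspc_fit <- function(x, ...) {
  if (!x$converged) {
    cat("TCSPC fit: did not converge\n"); return(invisible(x))
  }
  cat(sprintf(paste0("TCSPC %s fit: tau = (%.3f, %.3f) ns, fractions ",
                     "(%.3f, %.3f)\n  tau_avg = %.3f ns, chi2_red = %.3f, ",
                     "background = %.3g counts/bin\n"),
              if (x$collapsed) "single-exponential (collapsed)" else "biexponential",
              x$lifetimes_ns[1], x$lifetimes_ns[2],
              x$amplitudes[1], x$amplitudes[2],
              x$tau_avg_ns, x$chi2_reduced, x$background))
  invisible(x)
}

#' @export
coef.tcspc_fit <- function(object, ...) {
  c(f1 = object$amplitudes[1], f2 = object$amplitudes[2],
    tau1 = object$lifetimes_ns[1], tau2 = object$lifetimes_ns[2],
    tau_avg = object$tau_avg_ns, background = object$background,
    scale = object$scale)
}

#' @export
predict.tcspc_fit <- function(object, time_ns = object$hist$time_ns, ...) {
  if (!object$converged) stop_invalid("cannot predict from a failed fit")
  ipk <- which.max(object$hist$counts)
  t <- time_ns - object$hist$time_ns[ipk]
  y <- .decay_model(pmax(t, 0), object$scale * object$amplitudes,
                    object$lifetimes_ns, object$background)
  y[t < 0] <- NA_real_
  y
}

#' @export
residuals.tcspc_fit <- function(object, ...) {
  object$hist$counts - predict(object)
}

#' Fit a Forster-Hoffman lifetime-viscosity calibration
#'
#' Molecular-rotor calibration \eqn{\ln\tau = A + B\ln\eta} fitted by
#' ordinary least squares of \eqn{\ln\tau} on \eqn{\ln\eta} over solvent
#' pairs of known viscosity (e.g. a methanol-glycerol series); with exactly
#' two pairs the fit is the exact two-point solution. Natural logarithms
#' are used throughout; the inversion in
#' [microviscosity_from_lifetime()] is exact algebra, so the base cancels.
#'
#' @param tau_ns fluorescence lifetimes (ns), > 0.
#' @param eta_cP solvent viscosities (cP = mPa*s), > 0, same length >= 2.
#' @param temperature_C calibration temperature (Celsius); metadata.
#' @return Object of class `"fh_calibration"`: `intercept_A` (ln-ns scale),
#'   `slope_B`, `temperature_C`, `pairs` (data.frame).
#' @examples
#' cal <- fit_forster_hoffman(c(24.01, 20.61), c(28.75, 1.02), 35)
#' coef(cal)   # B ~ 0.0457
#' @export
fit_forster_hoffman <- function(tau_ns, eta_cP, temperature_C = NA_real_) {
  if (length(tau_ns) != length(eta_cP) || length(tau_ns) < 2)
    stop_invalid("need >= 2 (tau, eta) pairs of equal length")
  if (any(!is.finite(tau_ns)) || any(tau_ns <= 0) ||
      any(!is.finite(eta_cP)) || any(eta_cP <= 0))
    stop_invalid("tau and eta must be positive")
  x <- log(eta_cP); y <- log(tau_ns)
  if (stats::var(x) == 0)
    stop_invalid("all viscosities identical: calibration line is singular")
  fit <- stats::lm(y ~ x)
  structure(list(intercept_A = unname(stats::coef(fit)[1]),
                 slope_B = unname(stats::coef(fit)[2]),
                 temperature_C = temperature_C,
                 pairs = data.frame(tau_ns = tau_ns, eta_cP = eta_cP)),
            class = "fh_calibration")
}

#' @export
print.fh_calibration <- function(x, ...) {
  cat(sprintf("Forster-Hoffman calibration%s: ln(tau/ns) = %.4f + %.5f ln(eta/cP) (%d pairs)\n",
              if (is.finite(x$temperature_C))
                sprintf(" at %g C", x$temperature_C) else "",
              x$intercept_A, x$slope_B, nrow(x$pairs)))
  invisible(x)
}

#' @export
coef.fh_calibration <- function(object, ...) {
  c(A = object$intercept_A, B = object$slope_B)
}

#' @export
predict.fh_calibration <- function(object, eta_cP = object$pairs$eta_cP, ...) {
  exp(object$intercept_A + object$slope_B * log(eta_cP))
}

#' Invert a Forster-Hoffman calibration to a microviscosity
#'
#' \eqn{\eta = \exp[(\ln\tau - A)/B]}: the local viscosity of the probe's
#' microenvironment implied by its measured mean lifetime. Exact inverse of
#' [predict.fh_calibration()], so a lifetime equal to a calibration anchor
#' returns that anchor's viscosity.
#'
#' @param tau_ns measured mean lifetime (ns), > 0.
#' @param calibration an [fit_forster_hoffman()] result (slope must be
#'   nonzero).
#' @return Microviscosity in cP.
#' @examples
#' cal <- fit_forster_hoffman(c(24.01, 20.61), c(28.75, 1.02), 35)
#' microviscosity_from_lifetime(23.91, cal)  # ~26.24 cP
#' @export
microviscosity_from_lifetime <- function(tau_ns, calibration) {
  stopifnot(inherits(calibration, "fh_calibration"))
  if (any(!is.finite(tau_ns)) || any(tau_ns <= 0))
    stop_invalid("tau must be positive")
  if (calibration$slope_B == 0)
    stop_invalid("calibration slope is zero: not invertible")
  exp((log(tau_ns) - calibration$intercept_A) / calibration$slope_B)
}
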