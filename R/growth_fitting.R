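#' Growth-curve fitting configuration
#'
#' Collects the tunable constants of kinetic-parameter extraction. Defaults
#' follow the microplate design this package targets: a 24 h analysis window
#' and a latency threshold of OD600 = 0.25.
#'
#' @param window_h Analysis window in hours; curves are truncated to
#'   `[0, window_h]` before any computation.
#' @param latency_threshold OD600 value whose first exceedance defines latency.
#' @param interpolate_latency Linearly interpolate the crossing time between
#'   the two bracketing samples (recommended on a 30-min grid); `FALSE` gives
#'   the step-function alternative (first sample time above threshold).
#' @param max_restarts Number of jittered restarts attempted when the
#'   nonlinear least-squares fit does not converge.
#' @param restart_seed Sub-seed controlling restart jitter (fixed so fits are
#'   reproducible).
#' @param min_od_range Minimum observed OD range below which a curve is
#'   declared non-growing and not fitted.
#' @return A list of class `"fit_config"`.
#' @export
fit_config <- function(window_h = 24, latency_threshold = 0.25,
                       interpolate_latency = TRUE, max_restarts = 5,
                       restart_seed = 421L, min_od_range = 0.05) {
  stopifnot(window_h > 0, latency_threshold > 0, max_restarts >= 0,
            min_od_range >= 0)
  structure(
    list(window_h = window_h, latency_threshold = latency_threshold,
         interpolate_latency = interpolate_latency,
         max_restarts = max_restarts, restart_seed = as.integer(restart_seed),
         min_od_range = min_od_range),
    class = "fit_config"
  )
}

#' Fit the logistic growth model to one OD curve
#'
#' Nonlinear least squares (Levenberg–Marquardt) fit of
#' \eqn{N(t) = K/(1 + ((K-N_0)/N_0) e^{-rt})} to OD600 readings. Starting
#' values are data-driven (`K` from the maximum OD, `N0` from the first
#' reading, `r` from the log-slope of the early exponential points) and the
#' parameters are box-bounded to `K <= 3 max(od)`, `r <= 10` h^-1. A curve
#' whose OD range never exceeds `min_od_range` is flagged non-growing and
#' returned unconverged; fits that fail are retried from jittered starts.
#'
#' @param times Hours, strictly increasing, length >= 6 for fitting.
#' @param od Non-negative OD600 readings, same length as `times`.
#' @param config A [fit_config()].
#' @return A list of class `"logistic_fit"` with elements `K`, `r`, `N0`,
#'   `rss`, `converged`, `n`, `note`.
#' @export
#' @examples
#' t <- seq(0, 24, 0.5)
#' fit_logistic(t, logistic_od(t, K = 2, r = 0.4, N0 = 0.01))
fit_logistic <- function(times, od, config = fit_config()) {
  check_curve(times, od)
  n <- length(times)
  failed <- function(note) {
    structure(list(K = NA_real_, r = NA_real_, N0 = NA_real_,
                   rss = NA_real_, converged = FALSE, n = n, note = note),
              class = "logistic_fit")
  }
  if (n < 6) {
    return(failed("too_few_points"))
  }
  if (diff(range(od)) < config$min_od_range) {
    return(failed("non_growing"))
  }

  K0 <- max(od)
  N00 <- max(od[1], 1e-3)
  # slope of log-OD over the early rise for the r start value
  rise <- which(od > 1.5 * N00 & od < 0.8 * K0 & od > 0)
  r0 <- if (length(rise) >= 2) {
    s <- coef(lm(log(od[rise]) ~ times[rise]))[2]
    min(max(s, 0.05), 5)
  } else {
    0.5
  }
  start <- c(K = K0, r = r0, N0 = min(N00, 0.9 * K0))
  lower <- c(K = 1e-8, r = 1e-6, N0 = 1e-9)
  upper <- c(K = 3 * max(od), r = 10, N0 = 3 * max(od))

  df <- data.frame(t = times, y = od)
  try_fit <- function(st, up = upper) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ K / (1 + ((K - N0) / N0) * exp(-r * t)),
        data = df, start = as.list(st), lower = lower, upper = up,
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                             ptol = 1e-12)
      ),
      error = function(e) NULL, warning = function(w) NULL
    )
  }

  # A curve still far from plateau at the window end leaves K weakly
  # identified and the first start can stall in a flat region, so several
  # K start candidates are tried and the lowest-RSS fit kept; the search
  # stops early once the residuals are numerically zero (exact model data).
  rss_of <- function(f) if (is.null(f)) Inf else sum((fitted(f) - od)^2)
  fit <- NULL
  for (kf in c(1, 1.5, 2.5)) {
    st <- start
    st[["K"]] <- min(kf * K0, upper[["K"]] * 0.999)
    cand <- try_fit(st)
    if (rss_of(cand) < rss_of(fit)) {
      fit <- cand
    }
    if (rss_of(fit) < 1e-12 * n) {
      break
    }
  }
  attempt <- 0L
  while (is.null(fit) && attempt < config$max_restarts) {
    attempt <- attempt + 1L
    set.seed(derive_seed(config$restart_seed, attempt))
    jit <- exp(rnorm(3, 0, 0.3))
    st <- pmin(pmax(start * jit, lower * 1.01), upper * 0.99)
    fit <- try_fit(st)
  }
  if (is.null(fit)) {
    return(failed("no_convergence"))
  }
  # A curve that has not plateaued can have a true K above 3*max(od); when
  # the solution sits on the K cap, escalate the bound and refit.
  esc <- 0L
  up <- upper
  while (esc < 3L && is.finite(coef(fit)[["K"]]) &&
         coef(fit)[["K"]] >= 0.999 * up[["K"]]) {
    esc <- esc + 1L
    up[["K"]] <- up[["K"]] * 5
    up[["N0"]] <- up[["K"]]
    st <- coef(fit)
    st[["K"]] <- min(st[["K"]] * 2, up[["K"]] * 0.99)
    refit <- try_fit(st, up)
    if (is.null(refit) || rss_of(refit) >= rss_of(fit)) {
      break
    }
    fit <- refit
  }
  p <- coef(fit)
  if (!all(is.finite(p)) || p[["N0"]] >= p[["K"]] || p[["K"]] <= 0 ||
      p[["r"]] <= 0) {
    return(failed("degenerate_parameters"))
  }
  structure(
    list(K = unname(p[["K"]]), r = unname(p[["r"]]), N0 = unname(p[["N0"]]),
         rss = sum((fitted(fit) - od)^2), converged = TRUE, n = n,
         note = NA_character_),
    class = "logistic_fit"
  )
}

#' Latency: time for the OD to first exceed a threshold
#'
#' A lag-phase proxy measured directly on the readings. With interpolation,
#' the crossing time is placed by linear interpolation between the last
#' sample at or below the threshold and the first above it; without, it is
#' the first sample time above the threshold. A curve that never exceeds the
#' threshold has undefined latency (`NA`), which is a valid outcome, not an
#' error.
#'
#' @param times Hours, strictly increasing.
#' @param od OD600 readings.
#' @param threshold Positive OD threshold (default 0.25).
#' @param interpolate Interpolate between bracketing samples (default TRUE).
#' @return Hours (>= 0), or `NA` if the threshold is never exceeded.
#' @export
latency <- function(times, od, threshold = 0.25, interpolate = TRUE) {
  check_curve(times, od, min_len = 1)
  stopifnot(threshold > 0)
  i <- which(od > threshold)
  if (length(i) == 0) {
    return(NA_real_)
  }
  i <- i[1]
  if (i == 1) {
    return(0)
  }
  if (!interpolate) {
    return(times[i])
  }
  t0 <- times[i - 1]
  t1 <- times[i]
  y0 <- od[i - 1]
  y1 <- od[i]
  t0 + (threshold - y0) / (y1 - y0) * (t1 - t0)
}

#' Maximum observed OD within the analysis window
#'
#' @inheritParams latency
#' @param window_h Upper time bound in hours (default 24).
#' @return The peak OD reading in `[0, window_h]`.
#' @export
max_od <- function(times, od, window_h = 24) {
  check_curve(times, od, min_len = 1)
  keep <- times <= window_h + 1e-9
  if (!any(keep)) {
    stop("no readings inside the analysis window")
  }
  max(od[keep])
}

#' Extract the four kinetic parameters from one growth curve
#'
#' Truncates the curve to the analysis window, then reports latency and
#' maximum OD measured directly on the readings, and the intrinsic growth
#' rate `r` and model-based AUC from the logistic fit. When the fit fails,
#' `r`/`auc` are `NA` while the direct measures are still reported. The
#' empirical trapezoid AUC is included as a diagnostic column.
#'
#' @inheritParams fit_logistic
#' @return A one-row [tibble::tibble] with columns `latency_h`, `r_per_h`,
#'   `max_od`, `auc_odh`, `auc_empirical_odh`, `K`, `N0`, `rss`, `converged`,
#'   `fit_note`.
#' @export
extract_growth_parameters <- function(times, od, config = fit_config()) {
  check_curve(times, od)
  keep <- times <= config$window_h + 1e-9
  times <- times[keep]
  od <- od[keep]
  fit <- fit_logistic(times, od, config)
  auc <- if (fit$converged) logistic_auc(fit, t_end = config$window_h) else NA_real_
  tibble(
    latency_h = latency(times, od, config$latency_threshold,
                        config$interpolate_latency),
    r_per_h = if (fit$converged) fit$r else NA_real_,
    max_od = max_od(times, od, config$window_h),
    auc_odh = auc,
    auc_empirical_odh = trapz(times, od),
    K = fit$K, N0 = fit$N0, rss = fit$rss,
    converged = fit$converged, fit_note = fit$note
  )
}

#' Extract growth parameters for every curve of a dataset
#'
#' Applies [extract_growth_parameters()] per culture and binds the results.
#'
#' @param curves Long tibble with columns `well`, `time_h`, `od600` (as read
#'   by [read_timeseries()]).
#' @param config A [fit_config()].
#' @return Tibble with one row per well.
#' @export
fit_growth <- function(curves, config = fit_config()) {
  stopifnot(all(c("well", "time_h", "od600") %in% names(curves)))
  res <- lapply(split(curves, curves$well), function(d) {
    d <- d[order(d$time_h), ]
    out <- extract_growth_parameters(d$time_h, d$od600, config)
    out$well <- d$well[1]
    out
  })
  out <- dplyr::bind_rows(res)
  dplyr::relocate(out, "well")
}

# Shared validation of a (times, od) curve.
check_curve <- function(times, od, min_len = 4) {
  if (length(times) != length(od)) {
    stop("`times` and `od` must have the same length.")
  }
  if (length(times) < min_len) {
    stop(sprintf("curve must have at least %d points.", min_len))
  }
  if (any(!is.finite(times)) || any(!is.finite(od))) {
    stop("`times` and `od` must be finite.")
  }
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing.")
  }
  if (any(od < 0)) {
    stop("`od` must be non-negative.")
  }
  invisible(TRUE)
}
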