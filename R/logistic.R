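#' Logistic growth curve
#'
#' Evaluates the three-parameter logistic model
#' \eqn{N(t) = K / (1 + A e^{-rt})} with \eqn{A = (K - N_0)/N_0}: the
#' standard model for batch microbial growth measured as optical density,
#' with carrying capacity `K`, intrinsic growth rate `r` (per hour) and
#' initial population `N0`.
#'
#' @param t Time(s) in hours.
#' @param K Carrying capacity (OD units), `K > 0`.
#' @param r Intrinsic growth rate (h^-1), `r > 0`.
#' @param N0 Initial population size (OD units), `0 < N0 <= K`.
#' @return OD values at `t`.
#' @export
#' @examples
#' logistic_od(0:24, K = 2, r = 0.4, N0 = 0.01)
logistic_od <- function(t, K, r, N0) {
  stopifnot(K > 0, r > 0, N0 > 0, N0 <= K)
  A <- (K - N0) / N0
  K / (1 + A * exp(-r * t))
}

#' Closed-form area under a fitted logistic curve
#'
#' Integrates the logistic model analytically on `[0, t_end]`:
#' \deqn{AUC = (K/r) [\ln(A + e^{r t_{end}}) - \ln(A + 1)]}
#' with \eqn{A = (K - N_0)/N_0}. This is the model-based AUC (not the
#' empirical trapezoid over the raw readings). Computed with log1p to stay
#' stable for large `r * t_end`.
#'
#' @param fit A logistic fit (list with elements `K`, `r`, `N0`), as returned
#'   by [fit_logistic()], or a named numeric vector with those elements.
#' @param t_end Upper integration limit in hours, `> 0`.
#' @return AUC in OD·hours.
#' @export
#' @examples
#' logistic_auc(list(K = 2, r = 0.4, N0 = 0.01), t_end = 24)
logistic_auc <- function(fit, t_end = 24) {
  if (!is.numeric(t_end) || length(t_end) != 1 || !is.finite(t_end) || t_end <= 0) {
    stop("`t_end` must be a single positive number of hours.")
  }
  K <- fit[["K"]]
  r <- fit[["r"]]
  N0 <- fit[["N0"]]
  if (anyNA(c(K, r, N0))) {
    return(NA_real_)
  }
  stopifnot(K > 0, r > 0, N0 > 0, N0 <= K)
  A <- (K - N0) / N0
  # log(A + exp(r t)) = r t + log1p(A exp(-r t)), overflow-safe
  (K / r) * ((r * t_end + log1p(A * exp(-r * t_end))) - log1p(A))
}

# Time at which the noiseless logistic crosses `od`; NA if never (od >= K).
logistic_crossing_time <- function(K, r, N0, od) {
  if (od >= K || od <= 0) {
    return(NA_real_)
  }
  if (od <= N0) {
    return(0)
  }
  A <- (K - N0) / N0
  log(A * od / (K - od)) / r
}
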