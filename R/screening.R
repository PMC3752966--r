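#' Prevalence of the preclinical detectable phase
#'
#' Probability of being in the preclinical detectable phase at the time of a
#' screening test, under the two independence structures.
#'
#' `prevalence_catchup()` assumes the time of clinical diagnosis `X` is
#' independent of the sojourn time `Y` ("catch-up time model"): prevalence is
#' the expected cumulative clinical incidence from the screen to `Y` years
#' later, which for quadratic incidence and exponential sojourn reduces to
#' `I(t) * mu + beta2 * mu^2`.
#'
#' `prevalence_classic()` assumes the onset time `Z` is independent of `Y`
#' (classic Markov model): prevalence is the mean cumulative onset incidence
#' over the sojourn window before the screen. With exponential sojourn this is
#' `I(t) * mu` regardless of the trend (the Zelen–Feinleib identity); the
#' `"quadrature"` method instead integrates the onset incidence numerically,
#' clamping it at zero below its positivity bound.
#'
#' @param model A [quad_incidence()] model.
#' @param sojourn An [exp_sojourn()] distribution (or numeric mean).
#' @param t Screening time in years since entry (default 0).
#' @param method For the classic model: `"closed"` (default) or
#'   `"quadrature"`.
#' @return Prevalence (probability).
#' @examples
#' m <- quad_incidence(0.0034342704, 2 * 0.0001796227)
#' prevalence_catchup(m, exp_sojourn(6.804261)) # ~0.04
#' prevalence_classic(m, exp_sojourn(11.64731)) # ~0.04
#' @export
prevalence_catchup <- function(model, sojourn, t = 0) {
  stopifnot(inherits(model, "quad_incidence"))
  sojourn <- as_sojourn(sojourn)
  check_domain(model, t, "t")
  mu <- sojourn$mu
  # E[C_t(Y)] = I(t) E(Y) + (beta2/2) E(Y^2) with E(Y^2) = 2 mu^2
  incidence_at(model, t) * mu + model$beta2 * mu^2
}

#' @rdname prevalence_catchup
#' @export
prevalence_classic <- function(model, sojourn, t = 0,
                               method = c("closed", "quadrature")) {
  stopifnot(inherits(model, "quad_incidence"))
  sojourn <- as_sojourn(sojourn)
  method <- match.arg(method)
  check_domain(model, t, "t")
  mu <- sojourn$mu
  if (method == "closed") {
    return(incidence_at(model, t) * mu)
  }
  # E[ integral_{t-Y}^{t} I_o(u) du ] with I_o clamped at 0 below its bound
  u0 <- if (model$beta2 > 0) -model$beta1 / model$beta2 - mu else -Inf
  inner <- function(y) {
    vapply(y, function(yi) {
      lo <- max(t - yi, u0)
      if (lo >= t) return(0)
      stats::integrate(function(u) model$beta1 + model$beta2 * (u + mu),
                       lo, t, rel.tol = 1e-10)$value
    }, numeric(1))
  }
  stats::integrate(function(y) sojourn_density_(mu, y) * inner(y),
                   0, 60 * mu, rel.tol = 1e-9, subdivisions = 1000L)$value
}

#' Interval-cancer incidence after a screening test
#'
#' Incidence of clinically surfacing (interval) cancers `x` years after a
#' screen at time `t` with episode sensitivity `s`, under each model. Both
#' start at `(1 - s) * I(t)` just after the screen and rise back to the
#' background incidence as the prevalent pool surfaces.
#'
#' Under the catch-up time model the screen removes, with probability `s`,
#' the cancers whose sojourn covers the screen, giving
#' `I_s(t + x) = I(t + x) * (1 - s * exp(-x / mu))`.
#'
#' Under the classic model cancers surfacing at `t + x` either arose after the
#' screen or escaped detection; for quadratic incidence and exponential
#' sojourn the closed form is `I(t + x) - s * I(t) * exp(-x / mu)`. The
#' `"quadrature"` method evaluates the two onset-convolution integrals
#' directly (reference implementation; onset clamped at its positivity bound).
#'
#' @inheritParams prevalence_catchup
#' @param s Episode sensitivity of the test, in `[0, 1]`.
#' @param x Years since the screen (vectorised, nonnegative).
#' @param method For the classic model: `"closed"` (default) or
#'   `"quadrature"`.
#' @return Incidence rate(s) in cases per person-year.
#' @examples
#' m <- quad_incidence(0.0034342704, 2 * 0.0001796227)
#' interval_incidence_catchup(m, exp_sojourn(6.80), s = 1, x = 1)
#' interval_incidence_classic(m, exp_sojourn(11.64), s = 1, x = 1)
#' @export
interval_incidence_catchup <- function(model, sojourn, s, x, t = 0) {
  stopifnot(inherits(model, "quad_incidence"))
  sojourn <- as_sojourn(sojourn)
  check_sensitivity(s)
  if (any(x < 0)) stop("`x` must be nonnegative.", call. = FALSE)
  incidence_at(model, t + x) * (1 - s * exp(-x / sojourn$mu))
}

#' @rdname interval_incidence_catchup
#' @export
interval_incidence_classic <- function(model, sojourn, s, x, t = 0,
                                       method = c("closed", "quadrature")) {
  stopifnot(inherits(model, "quad_incidence"))
  sojourn <- as_sojourn(sojourn)
  method <- match.arg(method)
  check_sensitivity(s)
  if (any(x < 0)) stop("`x` must be nonnegative.", call. = FALSE)
  mu <- sojourn$mu
  if (method == "closed") {
    return(incidence_at(model, t + x) -
             s * incidence_at(model, t) * exp(-x / mu))
  }
  u0 <- if (model$beta2 > 0) -model$beta1 / model$beta2 - mu else -60 * mu + t
  io <- function(z) model$beta1 + model$beta2 * (z + mu)
  vapply(x, function(xi) {
    # onset before the screen, missed with probability (1 - s)
    pre <- stats::integrate(function(z) io(z) * sojourn_density_(mu, t + xi - z),
                            u0, t, rel.tol = 1e-10, subdivisions = 500L)$value
    post <- if (xi > 0) {
      stats::integrate(function(z) io(z) * sojourn_density_(mu, t + xi - z),
                       t, t + xi, rel.tol = 1e-10, subdivisions = 500L)$value
    } else 0
    (1 - s) * pre + post
  }, numeric(1))
}

check_sensitivity <- function(s) {
  stopifnot(is.numeric(s), length(s) == 1L)
  if (is.na(s) || s < 0 || s > 1) {
    stop("sensitivity `s` must lie in [0, 1].", call. = FALSE)
  }
  invisible(TRUE)
}

# exact antiderivatives over a bin [a, b) since the screen at time t:
#   int I(t+x) dx, int I(t+x) e^{-x/mu} dx, int e^{-x/mu} dx
bin_integrals <- function(beta1, beta2, mu, t, a, b) {
  i0 <- (beta1 + beta2 * t) * (b - a) + beta2 * (b^2 - a^2) / 2
  e0 <- mu * (exp(-a / mu) - exp(-b / mu))
  # int x e^{-x/mu} dx = mu(x + mu) e^{-x/mu} evaluated downward
  e1 <- (mu * a + mu^2) * exp(-a / mu) - (mu * b + mu^2) * exp(-b / mu)
  list(int_I = i0, int_exp = e0, int_I_exp = (beta1 + beta2 * t) * e0 + beta2 * e1)
}

#' Expected interval-cancer count in a follow-up bin
#'
#' Expected number of interval cancers in the bin `[start, end)` years after
#' the screen, given `py` person-years observed in the bin: the mean interval
#' incidence over the bin times the person-years,
#' `py * (1 / (end - start)) * integral I_s(t + x) dx`. Bin integrals are
#' exact (closed-form antiderivatives), matching the Poisson likelihood used
#' in [fit_screening_mle()].
#'
#' @inheritParams interval_incidence_catchup
#' @param start,end Bin edges in years since the screen, `0 <= start < end`.
#' @param py Person-years observed in the bin (positive).
#' @param kind `"catchup"` or `"classic"`.
#' @return Expected case count.
#' @export
expected_interval_count <- function(model, sojourn, s, start, end, py,
                                    t = 0, kind = c("catchup", "classic")) {
  stopifnot(inherits(model, "quad_incidence"))
  sojourn <- as_sojourn(sojourn)
  kind <- match.arg(kind)
  check_sensitivity(s)
  if (any(end <= start) || any(start < 0)) {
    stop("bins must satisfy 0 <= start < end.", call. = FALSE)
  }
  if (any(py < 0)) stop("`py` must be nonnegative.", call. = FALSE)
  bi <- bin_integrals(model$beta1, model$beta2, sojourn$mu, t, start, end)
  integral <- if (kind == "catchup") {
    bi$int_I - s * bi$int_I_exp
  } else {
    bi$int_I - s * incidence_at(model, t) * bi$int_exp
  }
  py * integral / (end - start)
}

#' Expected number of screen-detected cancers
#'
#' `n_screened * s * p(t)` with the prevalence `p` from the chosen model:
#' detection applies to persons screened, not person-years.
#'
#' @inheritParams expected_interval_count
#' @param n_screened Number of persons tested.
#' @return Expected detected count.
#' @export
expected_detected <- function(model, sojourn, s, n_screened, t = 0,
                              kind = c("catchup", "classic")) {
  kind <- match.arg(kind)
  check_sensitivity(s)
  p <- if (kind == "catchup") prevalence_catchup(model, sojourn, t)
       else prevalence_classic(model, sojourn, t)
  n_screened * s * p
}

#' Predicted post-screen incidence curves
#'
#' Tabulates the background incidence and the interval-cancer incidence
#' predicted by the two models on a grid of years since the screen — the
#' tabular counterpart of the usual "incidence deficit" figure. Each model
#' can carry its own fitted mean sojourn time.
#'
#' @inheritParams interval_incidence_catchup
#' @param mu_catchup,mu_classic Mean sojourn times (years) used by the
#'   catch-up and classic curves.
#' @param x Grid of years since the screen.
#' @return A tibble with columns `x_years`, `background_rate`, `classic_rate`,
#'   `catchup_rate` (per person-year).
#' @examples
#' m <- quad_incidence(0.0034342704, 2 * 0.0001796227)
#' predict_interval_incidence(m, mu_catchup = 6.80, mu_classic = 11.64, s = 1)
#' @export
predict_interval_incidence <- function(model, mu_catchup, mu_classic, s = 1,
                                       t = 0, x = seq(0, 10, by = 0.25)) {
  stopifnot(inherits(model, "quad_incidence"))
  tibble::tibble(
    x_years = x,
    background_rate = incidence_at(model, t + x),
    classic_rate = interval_incidence_classic(
      model, exp_sojourn(mu_classic), s, x, t),
    catchup_rate = interval_incidence_catchup(
      model, exp_sojourn(mu_catchup), s, x, t)
  )
}
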