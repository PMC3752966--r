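#' Simulation configuration for a single-screen trial
#'
#' Defines an individual-level data-generating process under one of the two
#' independence structures. Under `"catchup"`, clinical-diagnosis times `X`
#' follow a nonhomogeneous Poisson process with the background incidence
#' `I(x)` as intensity and the sojourn time `Y` is drawn independently
#' (onset `Z = X - Y`). Under `"classic"`, onset times `Z` follow the onset
#' incidence `I_o(z) = beta1 + beta2 (z + mu)` (truncated at its positivity
#' bound — rates are never negative) and `Y` is drawn independently
#' (`X = Z + Y`). Cancers in the preclinical phase at the screen are
#' detected with probability `s` and removed from follow-up; the rest
#' surface clinically at `X` if within the follow-up window.
#'
#' @param kind `"catchup"` or `"classic"`.
#' @param beta1,beta2 Background-incidence quadratic (per person-year).
#' @param mu Mean sojourn time in years.
#' @param s Episode sensitivity in `[0, 1]`.
#' @param n_subjects Cohort size (positive integer).
#' @param screen_time Screening time in years since entry (default 0).
#' @param follow_up Follow-up horizon in years since entry.
#' @param seed Integer seed; a given seed fully determines the cohort.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(kind = c("catchup", "classic"), beta1, beta2, mu, s,
                       n_subjects, screen_time = 0, follow_up, seed = 1L) {
  kind <- match.arg(kind)
  model <- quad_incidence(beta1, beta2) # validates
  check_sensitivity(s)
  stopifnot(is.numeric(n_subjects), length(n_subjects) == 1L,
            is.numeric(follow_up), length(follow_up) == 1L,
            is.numeric(seed), length(seed) == 1L)
  if (n_subjects < 1) stop("`n_subjects` must be positive.", call. = FALSE)
  if (follow_up <= 0) stop("`follow_up` must be positive.", call. = FALSE)
  d <- exp_sojourn(mu)
  structure(
    list(kind = kind, model = model, sojourn = d, s = s,
         n_subjects = as.integer(n_subjects), screen_time = screen_time,
         follow_up = follow_up, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @param json JSON string or path with the `sim_config` fields.
#' @export
sim_config_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  sim_config(kind = x$model_kind %||% x$kind, beta1 = x$beta1,
             beta2 = x$beta2, mu = x$mu, s = x$s,
             n_subjects = x$n_subjects,
             screen_time = x$screen_time %||% 0,
             follow_up = x$follow_up, seed = x$seed %||% 1L)
}

# nonhomogeneous Poisson events on (lo, hi] for n subjects by thinning with
# a constant envelope (the intensity is increasing, so rate(hi) dominates)
nhpp_events <- function(n, rate_fn, lo, hi) {
  lambda <- rate_fn(hi)
  counts <- stats::rpois(n, lambda * (hi - lo))
  total <- sum(counts)
  if (total == 0L) {
    return(tibble::tibble(id = integer(0), time = numeric(0)))
  }
  id <- rep.int(seq_len(n), counts)
  tt <- stats::runif(total, lo, hi)
  keep <- stats::runif(total) < rate_fn(tt) / lambda
  tibble::tibble(id = id[keep], time = tt[keep])
}

#' Simulate an individual-level screening cohort
#'
#' Generates cancer events for `n_subjects` under the configured model as an
#' exact nonhomogeneous Poisson process (a subject can, rarely, carry more
#' than one event; prevalence and detection identities hold at the event
#' level, matching the models' expected-count semantics). The catch-up kind
#' extends the event horizon past the follow-up window (to `12 * mu` beyond
#' the screen) so the prevalent pool at the screen is complete.
#'
#' @param config A [sim_config()].
#' @return A tibble of event records with columns `id`, `z` (onset), `y`
#'   (sojourn), `x` (clinical-diagnosis time, `x = z + y`), `screen_detected`,
#'   `event` (`"screen_detected"`, `"interval_case"`, `"prescreen_case"` or
#'   `"censored"`), `event_time` and `lead` (`x - screen_time` for detected
#'   cases, else `NA`). The configuration is attached as attribute `config`.
#' @examples
#' cfg <- sim_config("catchup", 0.0034342704, 2 * 0.0001796227,
#'                   mu = 6.8, s = 1, n_subjects = 1e4, follow_up = 10,
#'                   seed = 42)
#' records <- simulate_cohort(cfg)
#' mean(records$screen_detected) # events prevalent-and-detected per event
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  model <- config$model; mu <- config$sojourn$mu
  t <- config$screen_time; fu <- config$follow_up
  window_events <- cumulative_incidence(model, fu)
  if (window_events >= 1) {
    stop("expected events per subject over the follow-up window exceed 1; ",
         "shrink the window.", call. = FALSE)
  }
  if (window_events >= 0.1) {
    warning("expected events per subject over the follow-up window exceed ",
            "0.1; the cohort reading of event records weakens.", call. = FALSE)
  }
  records <- withr::with_seed(config$seed, {
    if (config$kind == "catchup") {
      hi <- max(fu, t + 12 * mu)
      ev <- nhpp_events(config$n_subjects,
                        function(x) model$beta1 + model$beta2 * x, 0, hi)
      x <- ev$time
      y <- stats::rexp(length(x), rate = 1 / mu)
      z <- x - y
    } else {
      bound <- if (model$beta2 > 0) -model$beta1 / model$beta2 - mu
               else t - 15 * mu
      if (bound > t - 5 * mu) {
        warning("onset positivity bound is within 5 mean sojourn times of ",
                "the screen; simulated prevalence will exceed the ",
                "straight-line closed form.", call. = FALSE)
      }
      ev <- nhpp_events(config$n_subjects,
                        function(z) model$beta1 + model$beta2 * (z + mu),
                        bound, fu)
      z <- ev$time
      y <- stats::rexp(length(z), rate = 1 / mu)
      x <- z + y
    }
    prevalent <- z <= t & x > t
    detected <- prevalent & stats::runif(length(x)) < config$s
    event <- dplyr::case_when(
      detected ~ "screen_detected",
      x <= t ~ "prescreen_case",
      x <= fu ~ "interval_case",
      TRUE ~ "censored"
    )
    tibble::tibble(
      id = ev$id, z = z, y = y, x = x,
      screen_detected = detected,
      event = event,
      event_time = dplyr::case_when(
        detected ~ t, x <= fu ~ x, TRUE ~ fu),
      lead = dplyr::if_else(detected, x - t, NA_real_)
    )
  })
  attr(records, "config") <- config
  records
}

#' Empirical interval-cancer rates from simulated records
#'
#' Interval-case counts per bin of years since the screen, divided by the
#' cohort's person-years in the bin. Person-years use the population
#' convention (`n_subjects` times the bin width): the models' interval
#' incidence is an intensity over the whole screened cohort, with the
#' detected cases' removal already carried by the deficit term.
#'
#' @param records A tibble from [simulate_cohort()].
#' @param bins Data frame with columns `start`, `end` (years since screen).
#' @return A tibble `start`, `end`, `cases`, `py`, `rate`.
#' @export
empirical_interval_rates <- function(records, bins) {
  config <- attr(records, "config")
  if (is.null(config)) stop("`records` must come from simulate_cohort().",
                            call. = FALSE)
  stopifnot(is.data.frame(bins), all(c("start", "end") %in% names(bins)))
  if (any(bins$end <= bins$start)) {
    stop("bins must have end > start.", call. = FALSE)
  }
  if (any(config$screen_time + bins$end > config$follow_up)) {
    stop("bins extend beyond the follow-up window: empty risk set.",
         call. = FALSE)
  }
  t <- config$screen_time
  xs <- records$x[records$event == "interval_case"] - t
  purrr::map_dfr(seq_len(nrow(bins)), function(i) {
    a <- bins$start[i]; b <- bins$end[i]
    py <- config$n_subjects * (b - a)
    tibble::tibble(start = a, end = b,
                   cases = sum(xs >= a & xs < b), py = py,
                   rate = sum(xs >= a & xs < b) / py)
  })
}

#' Tabulate simulated records into a screening count table
#'
#' Bins a screened cohort (and optionally a separate unscreened control
#' cohort) into the [trial_counts()] structure consumed by
#' [fit_screening_mle()]. Interval and control person-years use the
#' population convention (cohort size times bin width), matching the Poisson
#' expectations of [screening_nll()].
#'
#' @param records Screened-cohort records from [simulate_cohort()].
#' @param interval_bins Data frame `start`, `end` in years since the screen.
#' @param control_records Records from an unscreened (`s = 0`) cohort, used
#'   for the control stratum; its clinical cases by bin estimate the
#'   background incidence.
#' @param control_bins Data frame `start`, `end` in years since entry.
#' @param label Label for the resulting table.
#' @return A [trial_counts()] object.
#' @export
tabulate_trial_counts <- function(records, interval_bins,
                                  control_records, control_bins,
                                  label = "simulated") {
  config <- attr(records, "config")
  ctrl_config <- attr(control_records, "config")
  if (is.null(config) || is.null(ctrl_config)) {
    stop("records must come from simulate_cohort().", call. = FALSE)
  }
  iv <- empirical_interval_rates(records, interval_bins)
  ctrl_x <- control_records$x[control_records$x <= ctrl_config$follow_up]
  ctrl <- purrr::map_dfr(seq_len(nrow(control_bins)), function(i) {
    a <- control_bins$start[i]; b <- control_bins$end[i]
    tibble::tibble(start = a, end = b,
                   cases = sum(ctrl_x >= a & ctrl_x < b),
                   py = ctrl_config$n_subjects * (b - a))
  })
  trial_counts(
    control = ctrl,
    screen_n = config$n_subjects,
    screen_detected = sum(records$screen_detected),
    interval = iv[, c("start", "end", "cases", "py")],
    label = label
  )
}
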