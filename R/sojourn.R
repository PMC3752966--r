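#' Exponential sojourn-time distribution
#'
#' Duration of the preclinical detectable phase (PCDP), assumed exponential
#' with mean `mu` years: density `f(y) = (1/mu) exp(-y/mu)`. The exponential
#' is the standard working assumption in screening models because its
#' memorylessness makes the residual time from screen detection to clinical
#' surfacing exponential with the same mean, tying the lead-time and
#' sojourn-time distributions together.
#'
#' @param mu Mean sojourn time in years; must be positive.
#' @return An object of class `exp_sojourn`.
#' @examples
#' d <- exp_sojourn(6.8)
#' sojourn_survival(d, 1)
#' sojourn_moment(d, 2) # 2 * mu^2
#' @export
exp_sojourn <- function(mu) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu))
  if (mu <= 0) stop("`mu` must be positive.", call. = FALSE)
  structure(list(mu = mu), class = "exp_sojourn")
}

#' @export
print.exp_sojourn <- function(x, ...) {
  cat(sprintf("<exp_sojourn> mean sojourn time mu = %.6g years\n", x$mu))
  invisible(x)
}

sojourn_density_ <- function(mu, y) exp(-y / mu) / mu

#' @rdname exp_sojourn
#' @param d An `exp_sojourn` object.
#' @param y Sojourn time(s) in years, nonnegative.
#' @export
sojourn_density <- function(d, y) {
  stopifnot(inherits(d, "exp_sojourn"), is.numeric(y))
  if (any(y < 0)) stop("`y` must be nonnegative.", call. = FALSE)
  sojourn_density_(d$mu, y)
}

#' @rdname exp_sojourn
#' @export
sojourn_survival <- function(d, y) {
  stopifnot(inherits(d, "exp_sojourn"), is.numeric(y))
  if (any(y < 0)) stop("`y` must be nonnegative.", call. = FALSE)
  exp(-y / d$mu)
}

#' @rdname exp_sojourn
#' @param k Moment order, a positive integer: `E(Y^k) = k! * mu^k`.
#' @export
sojourn_moment <- function(d, k) {
  stopifnot(inherits(d, "exp_sojourn"), is.numeric(k))
  if (any(k < 1) || any(k != round(k))) {
    stop("`k` must be a positive integer.", call. = FALSE)
  }
  factorial(k) * d$mu^k
}

#' @rdname exp_sojourn
#' @param n Number of random draws.
#' @export
sojourn_draw <- function(d, n) {
  stopifnot(inherits(d, "exp_sojourn"))
  stats::rexp(n, rate = 1 / d$mu)
}

#' @rdname exp_sojourn
#' @param json JSON string or path with fields `family` ("exponential") and `mu`.
#' @export
sojourn_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  fam <- x$family %||% "exponential"
  if (!identical(fam, "exponential")) {
    stop(sprintf("unsupported sojourn family '%s'.", fam), call. = FALSE)
  }
  exp_sojourn(x$mu)
}

#' @rdname exp_sojourn
#' @export
sojourn_to_json <- function(d) {
  stopifnot(inherits(d, "exp_sojourn"))
  jsonlite::toJSON(list(family = "exponential", mu = d$mu),
                   auto_unbox = TRUE, digits = NA)
}

as_sojourn <- function(x) {
  if (inherits(x, "exp_sojourn")) x else exp_sojourn(x)
}
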