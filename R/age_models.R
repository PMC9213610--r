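#' Relative age
#'
#' Relative age is chronological age divided by the species' maximum
#' lifespan, the normalization that puts species with very different
#' lifespans (e.g., 4.2 vs 122.5 years, a ~29-fold ratio) on a common
#' \[0, 1\] scale. Values above 1 are possible for an animal outliving
#' the recorded maximum and are returned unclamped (with a warning).
#'
#' @param age_years Non-negative chronological age(s) in years.
#' @param max_lifespan_years Positive species maximum lifespan in years.
#' @return `age_years / max_lifespan_years`.
#' @export
relative_age <- function(age_years, max_lifespan_years) {
  if (any(max_lifespan_years <= 0)) stop("max_lifespan_years must be > 0")
  if (any(age_years < 0)) stop("age_years must be >= 0")
  out <- age_years / max_lifespan_years
  if (any(out > 1)) warning("relative age above 1 (sample older than recorded maximum lifespan)")
  out
}

#' Piecewise log-linear age transform (forward)
#'
#' Logarithmic before the species' age at sexual maturity `m`, linear
#' after, continuous at the knot with value 0 at `age = m`:
#' `log((age + k) / (m + k))` for `age < m`, else `(age - m) / (m + k)`.
#' The offset `k` (years) keeps the logarithm finite at age 0. Used as
#' the target scale of dual-species chronological-age clocks, where it
#' compresses the fast developmental phase.
#'
#' @param age_years Non-negative age(s) in years.
#' @param maturity_years Positive age at sexual maturity `m` (years).
#' @param k Positive offset in years (default 1).
#' @return Transformed age(s); strictly increasing in `age_years`.
#' @export
loglinear_forward <- function(age_years, maturity_years, k = 1) {
  if (any(maturity_years <= 0)) stop("maturity_years must be > 0")
  if (any(k <= 0)) stop("k must be > 0")
  if (any(age_years < 0)) stop("age_years must be >= 0")
  ifelse(age_years < maturity_years,
         log((age_years + k) / (maturity_years + k)),
         (age_years - maturity_years) / (maturity_years + k))
}

#' Piecewise log-linear age transform (inverse)
#'
#' Exact inverse of [loglinear_forward()]:
#' `exp(y) * (m + k) - k` for `y < 0`, else `y * (m + k) + m`, floored
#' at 0 so predictions cannot be negative ages.
#'
#' @param y Transformed age(s).
#' @param maturity_years Positive age at sexual maturity `m` (years).
#' @param k Positive offset in years (default 1).
#' @return Age(s) in years.
#' @export
loglinear_inverse <- function(y, maturity_years, k = 1) {
  if (any(maturity_years <= 0)) stop("maturity_years must be > 0")
  if (any(k <= 0)) stop("k must be > 0")
  out <- ifelse(y < 0,
                exp(y) * (maturity_years + k) - k,
                y * (maturity_years + k) + maturity_years)
  pmax(out, 0)
}

#' Age-transform specification
#'
#' A small S3 object naming the target scale of a clock: `identity`
#' (years), `relative` (age / maximum lifespan) or `loglinear`
#' (piecewise log-linear around maturity). Species parameters (maximum
#' lifespan, maturity) are not stored here; they are taken per sample
#' from the sample sheet at (inverse-)transform time, which is what
#' makes one fitted clock serve several species.
#'
#' @param kind One of `"identity"`, `"relative"`, `"loglinear"`.
#' @param k Offset in years for the log-linear transform.
#' @return An object of class `age_transform`.
#' @export
age_transform <- function(kind = c("identity", "relative", "loglinear"), k = 1) {
  kind <- match.arg(kind)
  if (k <= 0) stop("k must be > 0")
  structure(list(kind = kind, k = k), class = "age_transform")
}

#' @export
print.age_transform <- function(x, ...) {
  cat("age transform:", x$kind)
  if (x$kind == "loglinear") cat(" (k =", x$k, "years)")
  cat("\n")
  invisible(x)
}

#' Apply an age transform using per-sample species constants
#'
#' @param transform An [age_transform()] object.
#' @param age_years Ages in years.
#' @param samples Sample sheet rows aligned with `age_years`, supplying
#'   `max_lifespan_years` and `maturity_years`.
#' @return Transformed ages on the clock's target scale.
#' @export
transform_age <- function(transform, age_years, samples) {
  stopifnot(inherits(transform, "age_transform"))
  switch(transform$kind,
         identity = age_years,
         relative = relative_age(age_years, samples$max_lifespan_years),
         loglinear = loglinear_forward(age_years, samples$maturity_years,
                                       transform$k))
}

#' Invert an age transform using per-sample species constants
#'
#' @param transform An [age_transform()] object.
#' @param y Values on the transformed scale.
#' @param samples Sample sheet rows aligned with `y`.
#' @return Ages in years.
#' @export
invert_age <- function(transform, y, samples) {
  stopifnot(inherits(transform, "age_transform"))
  switch(transform$kind,
         identity = y,
         relative = y * samples$max_lifespan_years,
         loglinear = loglinear_inverse(y, samples$maturity_years, transform$k))
}
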