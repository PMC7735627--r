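## Closed-form hazard fixtures. Defaults span the entropy range from ~1
## (constant hazard, the REC-degenerate limit) down to a few percent
## (near-rectangular survival), so every downstream measure is exercised
## in both well-posed and boundary regimes without external data.

.fixtureDefaults <- list(
  constant          = list(rate = 0.1),
  gompertz          = list(a = 1e-4, b = 0.1),
  gompertz_makeham  = list(a = 1e-4, b = 0.1, c = 5e-4),
  near_rectangular  = list(a = 1e-12, b = 0.5)
)

.fixtureParams <- function(family, dots) {
  defaults <- .fixtureDefaults[[family]]
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown))
    .err("invalid_argument",
         sprintf("unknown parameter(s) for family '%s': %s", family,
                 paste(unknown, collapse = ", ")))
  pars <- utils::modifyList(defaults, dots)
  bad <- !vapply(pars, function(v) is.numeric(v) && length(v) == 1L &&
                   is.finite(v) && v > 0, logical(1))
  if (any(bad))
    .err("invalid_argument",
         sprintf("fixture rate constants must be positive: %s",
                 paste(names(pars)[bad], collapse = ", ")))
  if (family == "near_rectangular" && pars$b < 0.5)
    .err("invalid_argument",
         "near_rectangular requires b >= 0.5 (deaths concentrated near one age)")
  pars
}

#' Closed-form hazard fixtures
#'
#' Hazard schedules with known analytic structure:
#' \describe{
#'   \item{constant}{\eqn{\mu(x) = rate}; exponential survival, entropy 1,
#'     threshold age 0.}
#'   \item{gompertz}{\eqn{\mu(x) = a e^{bx}}; survival
#'     \eqn{\exp\{-(a/b)(e^{bx}-1)\}}.}
#'   \item{gompertz_makeham}{\eqn{\mu(x) = a e^{bx} + c}.}
#'   \item{near_rectangular}{a Gompertz with steep slope (\eqn{b \ge
#'     0.5}), concentrating deaths near one age; \eqn{e^\dagger \approx
#'     1/b}, the compression limit.}
#' }
#'
#' @param family fixture family name.
#' @param grid an [AgeGrid-class].
#' @param ... family rate constants overriding the defaults listed above
#'   (\code{rate}; \code{a}, \code{b}; \code{a}, \code{b}, \code{c}).
#' @return a [HazardSchedule-class].
#' @examples
#' lifetableEntropy(lifeTable(hazardFixture("constant")))        # ~ 1
#' lifetableEntropy(lifeTable(hazardFixture("near_rectangular"))) # ~ 0.04
#' @export
hazardFixture <- function(family = c("constant", "gompertz",
                                     "gompertz_makeham",
                                     "near_rectangular"),
                          grid = makeAgeGrid(), ...) {
  if (length(family) == 1L && !family %in% names(.fixtureDefaults))
    .err("invalid_argument",
         sprintf("unknown fixture family '%s'", family))
  family <- match.arg(family)
  p <- .fixtureParams(family, list(...))
  x <- grid@ages
  mu <- switch(family,
    constant         = rep(p$rate, length(x)),
    gompertz         = p$a * exp(p$b * x),
    gompertz_makeham = p$a * exp(p$b * x) + p$c,
    near_rectangular = p$a * exp(p$b * x))
  hazardSchedule(mu, grid)
}

#' Closed-form reference values for a fixture
#'
#' Independent analytic references for families with elementary closed
#' forms: the survival function and life expectancy at birth on
#' \code{[0, omega]}. For the constant family \eqn{e^0 = (1 -
#' e^{-c\omega})/c} exactly; for the Gompertz families \eqn{e^0} is
#' obtained by adaptive quadrature of the closed-form survival
#' (independent of the package's grid integration). The
#' \code{near_rectangular} family is deliberately unsupported so tests
#' must treat it through the generic pipeline only.
#'
#' @param family fixture family name.
#' @param grid an [AgeGrid-class] (fixes \code{omega}).
#' @param ... family rate constants as in [hazardFixture()].
#' @return list with \code{survival} (a function of age) and \code{e0}
#'   (years).
#' @examples
#' fixtureExpectedValues("constant", rate = 0.1)$e0   # 9.99994
#' @export
fixtureExpectedValues <- function(family, grid = makeAgeGrid(), ...) {
  if (!family %in% c("constant", "gompertz", "gompertz_makeham"))
    .err("unsupported",
         sprintf("no closed-form reference values for family '%s'", family))
  p <- .fixtureParams(family, list(...))
  om <- grid@omega
  surv <- switch(family,
    constant = function(x) exp(-p$rate * x),
    gompertz = function(x) exp(-(p$a / p$b) * (exp(p$b * x) - 1)),
    gompertz_makeham =
      function(x) exp(-p$c * x - (p$a / p$b) * (exp(p$b * x) - 1)))
  e0 <- if (family == "constant") {
    (1 - exp(-p$rate * om)) / p$rate
  } else {
    stats::integrate(surv, 0, om, rel.tol = 1e-10)$value
  }
  list(survival = surv, e0 = e0)
}
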