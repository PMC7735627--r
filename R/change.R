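## Change decomposition: age-specific rates of mortality decline, discrete
## component growth rates (log-differences), and the sensitivity-integral
## route evaluated on the mid-interval schedule.

#' Age-specific relative rates of mortality decline
#'
#' The finite-difference form of \eqn{\rho(x,t) = -\dot\mu(x,t)/\mu(x,t)}:
#' \deqn{\rho(x) = -(\log \mu_2(x) - \log \mu_1(x)) / dt.}
#'
#' Ages where either hazard is zero get \code{NA} (the relative decline is
#' undefined there) with a warning; downstream integrals treat those ages
#' as contributing nothing.
#'
#' @param h1,h2 [HazardSchedule-class] objects on the same grid, \code{dt}
#'   years apart.
#' @param dt elapsed time in years, positive.
#' @return numeric vector of decline rates per year, one per grid age.
#' @examples
#' h1 <- hazardFixture("gompertz")
#' h2 <- hazardSchedule(hazardRate(h1) * exp(-0.01 * 10), ageGrid(h1))
#' range(rhoField(h1, h2, 10))   # uniform 0.01 per year
#' @export
rhoField <- function(h1, h2, dt) {
  stopifnot(is(h1, "HazardSchedule"), is(h2, "HazardSchedule"))
  if (!identical(h1@grid@ages, h2@grid@ages))
    .err("invalid_argument", "'h1' and 'h2' must share the same age grid")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    .err("invalid_argument", "'dt' must be a single positive number")
  bad <- h1@mu <= 0 | h2@mu <= 0
  rho <- rep(NA_real_, length(h1@mu))
  rho[!bad] <- -(log(h2@mu[!bad]) - log(h1@mu[!bad])) / dt
  if (any(bad))
    warning(sprintf(
      "rho undefined at %d age(s) with zero hazard; set to NA and excluded from integrals",
      sum(bad)))
  rho
}

#' Component growth rates from published component values
#'
#' Log-difference rates of the compression and expansion components over an
#' interval: \code{rateEC = log(ec2/ec1)/dt}, \code{rateEE =
#' log(ee2/ee1)/dt}, and the REC change rate \code{dlnREC = rateEE -
#' rateEC}, which equals \code{(log REC_2 - log REC_1)/dt} identically.
#'
#' @param ec1,ee1 compression and expansion components (years) at the first
#'   time point.
#' @param ec2,ee2 the same at the second time point.
#' @param dt elapsed time in years.
#' @return a [ChangeDecomposition-class] with the discrete rates filled in
#'   (sensitivity slots \code{NA}).
#' @examples
#' recChangeRates(9.64, 5.06, 9.82, 6.04, dt = 5)
#' @export
recChangeRates <- function(ec1, ee1, ec2, ee2, dt) {
  v <- c(ec1, ee1, ec2, ee2)
  if (!is.numeric(v) || length(v) != 4L || any(!is.finite(v)) || any(v <= 0))
    .err("undefined_value",
         "components must be positive for log-difference rates")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    .err("invalid_argument", "'dt' must be a single positive number")
  rateEC <- log(ec2 / ec1) / dt
  rateEE <- log(ee2 / ee1) / dt
  new("ChangeDecomposition", dt = dt, rho = numeric(0),
      rateEC = rateEC, rateEE = rateEE, dlnREC = rateEE - rateEC,
      edotC = NA_real_, edotE = NA_real_, edot = NA_real_)
}

#' Component growth rates between two life tables
#'
#' Decomposes each life table at its own threshold age (the thresholds of
#' the two tables generally differ) and applies [recChangeRates()] to the
#' resulting components.
#'
#' @param lt1,lt2 [LifeTable-class] objects, \code{dt} years apart, both
#'   with entropy below 1.
#' @param dt elapsed time in years.
#' @return a [ChangeDecomposition-class] (discrete part only).
#' @export
componentRates <- function(lt1, lt2, dt) {
  d1 <- decomposeDisparity(lt1)
  d2 <- decomposeDisparity(lt2)
  recChangeRates(d1@ec, d1@ee, d2@ec, d2@ee, dt)
}

#' Change rates of the disparity components from the sensitivity integral
#'
#' Evaluates \eqn{\dot e^\dagger_c = \int_0^{a^\dagger} \rho(x) g(x) dx}
#' and \eqn{\dot e^\dagger_e = \int_{a^\dagger}^{\omega} \rho(x) g(x) dx}
#' with \eqn{g} from [sensitivityCurves()] on the supplied (typically
#' mid-interval) life table. Ages with \code{NA} rho (zero hazard) are
#' excluded with a warning.
#'
#' @param ltMid a [LifeTable-class]; for a two-point comparison, the
#'   schedule whose hazard is the geometric mean of the endpoint hazards
#'   reduces first-order bias.
#' @param rho decline rates per year on \code{ltMid}'s grid, as from
#'   [rhoField()].
#' @param aDag threshold age of \code{ltMid}; defaults to
#'   \code{thresholdAge(ltMid)}.
#' @return list with elements \code{edotC}, \code{edotE}, \code{edot}
#'   (years per year).
#' @export
sensitivityChange <- function(ltMid, rho, aDag = thresholdAge(ltMid)) {
  stopifnot(is(ltMid, "LifeTable"))
  if (!is.numeric(rho) || length(rho) != length(ltMid@grid@ages))
    .err("invalid_argument", "'rho' must have one value per grid age")
  if (anyNA(rho)) {
    warning(sprintf("%d NA rho value(s) excluded from the change integrals",
                    sum(is.na(rho))))
    rho[is.na(rho)] <- 0
  }
  sc <- sensitivityCurves(ltMid)
  q <- rho * sc@phi                       # integrand against death density
  q[!is.finite(q)] <- 0                   # extinct tail carries no mass
  edot <- .deathIntegral(ltMid, q, closure = FALSE)
  edotC <- if (aDag > 0) .deathIntegral(ltMid, q, upper = aDag,
                                        closure = FALSE) else 0
  list(edotC = edotC, edotE = edot - edotC, edot = edot)
}

#' Full change decomposition between two hazard schedules
#'
#' Combines the discrete component-growth route ([componentRates()]) with
#' the sensitivity-integral route ([sensitivityChange()]): decline rates
#' from [rhoField()], sensitivity \eqn{g} and threshold age evaluated on
#' the mid-interval schedule whose hazard is the geometric mean
#' \eqn{\sqrt{\mu_1 \mu_2}} of the endpoints.
#'
#' @param h1,h2 [HazardSchedule-class] objects on the same grid.
#' @param dt elapsed time in years.
#' @return a [ChangeDecomposition-class] with all slots filled.
#' @examples
#' h1 <- hazardFixture("gompertz")
#' h2 <- hazardSchedule(hazardRate(h1) * exp(-0.02 * 5), ageGrid(h1))
#' changeDecomposition(h1, h2, dt = 5)
#' @export
changeDecomposition <- function(h1, h2, dt) {
  disc <- componentRates(lifeTable(h1), lifeTable(h2), dt)
  rho <- rhoField(h1, h2, dt)
  muMid <- sqrt(h1@mu * h2@mu)
  ltMid <- lifeTable(hazardSchedule(muMid, h1@grid))
  sens <- suppressWarnings(sensitivityChange(ltMid, rho))
  new("ChangeDecomposition", dt = dt, rho = rho,
      rateEC = disc@rateEC, rateEE = disc@rateEE, dlnREC = disc@dlnREC,
      edotC = sens$edotC, edotE = sens$edotE, edot = sens$edot)
}
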