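## Life-table core: continuous-approximation life tables on a uniform fine
## age grid. Integrals of smooth functions (mu, l) use the composite
## trapezoid rule; integrals against the death density use exact per-cell
## death masses l(x_i) - l(x_{i+1}) (which telescope to 1 - l(omega), so
## total death mass including the closure point mass at omega is exactly 1)
## with the trapezoid average of the integrand over the cell. Both rules are
## second-order accurate in the grid step.

.cumtrapz <- function(x, y) as.vector(pracma::cumtrapz(x, y))

#' Construct a uniform age grid
#'
#' @param omega maximum age in years; must be an exact multiple of
#'   \code{step}.
#' @param step grid spacing in years.
#' @return an [AgeGrid-class] with ages \code{0, step, ..., omega}.
#' @details The defaults (120 years by 0.1) resolve threshold-age
#'   interpolation and keep discretisation error in \eqn{e^0} and
#'   \eqn{e^\dagger} below about \code{1e-4} years for smooth human-like
#'   schedules (see the package vignette for the convergence argument).
#' @examples
#' makeAgeGrid(120, 0.1)
#' makeAgeGrid(1, 0.5)
#' @export
makeAgeGrid <- function(omega = 120, step = 0.1) {
  if (!is.numeric(omega) || length(omega) != 1L || !is.finite(omega) ||
      omega <= 0)
    .err("invalid_argument", "'omega' must be a single positive number")
  if (!is.numeric(step) || length(step) != 1L || !is.finite(step) ||
      step <= 0)
    .err("invalid_argument", "'step' must be a single positive number")
  n <- omega / step
  if (abs(n - round(n)) > 1e-8 * max(1, n))
    .err("invalid_argument",
         sprintf("'omega' (%s) must be an exact multiple of 'step' (%s)",
                 .fmt(omega), .fmt(step)))
  n <- as.integer(round(n))
  a <- (0:n) * step
  a[n + 1L] <- omega            # exact endpoint despite floating-point step
  new("AgeGrid", omega = omega, step = step, ages = a)
}

#' Construct a hazard schedule
#'
#' @param mu either a numeric vector of hazards (one per grid age) or a
#'   function of age returning the hazard.
#' @param grid an [AgeGrid-class]; default 0--120 years by 0.1.
#' @return a [HazardSchedule-class].
#' @examples
#' h <- hazardSchedule(function(x) 1e-4 * exp(0.1 * x))
#' lifeTable(h)
#' @export
hazardSchedule <- function(mu, grid = makeAgeGrid()) {
  if (is.function(mu)) mu <- mu(grid@ages)
  if (!is.numeric(mu))
    .err("invalid_argument", "'mu' must be numeric or a function of age")
  if (length(mu) == 1L) mu <- rep(mu, length(grid@ages))
  if (length(mu) != length(grid@ages))
    .err("invalid_argument", "'mu' must have one value per grid age")
  if (any(!is.finite(mu)) || any(mu < 0))
    .err("invalid_argument", "'mu' must be finite and non-negative")
  if (!any(mu > 0))
    .err("invalid_argument",
         "'mu' is zero everywhere: survival never decays, the death distribution is improper")
  new("HazardSchedule", grid = grid, mu = mu)
}

#' Build a continuous-approximation life table from a hazard schedule
#'
#' Computes \eqn{l(x) = \exp(-\int_0^x \mu)}, \eqn{d(x) = l(x)\mu(x)},
#' \eqn{H(x) = -\log l(x)} and
#' \eqn{e(x) = \int_x^\omega l(a)\,da / l(x)} on the grid of \code{h}.
#' Survival mass remaining at \code{omega} is closed out as deaths at
#' exactly \code{omega} with \eqn{e(\omega) = 0}.
#'
#' At extreme ages \eqn{l(x)} can underflow to zero; there \eqn{e(x)} is
#' set to 0 (no survivors, no remaining lifetime).
#'
#' @param h a [HazardSchedule-class].
#' @return a [LifeTable-class].
#' @examples
#' lt <- lifeTable(hazardFixture("constant", rate = 0.1))
#' expectancy(lt)[1]          # ~ 1 / 0.1 = 10 years
#' @export
lifeTable <- function(h) {
  stopifnot(is(h, "HazardSchedule"))
  validObject(h)
  x <- h@grid@ages
  H <- .cumtrapz(x, h@mu)
  l <- exp(-H)
  Il <- .cumtrapz(x, l)
  e <- ifelse(l > 0, (Il[length(Il)] - Il) / l, 0)
  e[length(e)] <- 0                       # closure at omega
  new("LifeTable", grid = h@grid, mu = h@mu, lx = l, dx = l * h@mu,
      ex = pmax(e, 0), Hx = H)
}

## Exact death mass in each grid cell [x_i, x_{i+1}).
.cellMasses <- function(lt) {
  n <- length(lt@lx)
  lt@lx[-n] - lt@lx[-1L]
}

## Integral of f against the death density over [lower, upper], using exact
## cell masses and the trapezoid average of f. A partial cell is split with
## the integrand q = d*f interpolated linearly across the cell, which keeps
## ec + ee = e-dagger conservation exact. The closure point mass l(omega)
## contributes f(omega) when upper == omega and 'closure' is TRUE.
.deathIntegral <- function(lt, f, lower = 0, upper = lt@grid@omega,
                           closure = TRUE) {
  x <- lt@grid@ages
  n <- length(x)
  m <- .cellMasses(lt)
  favg <- (f[-n] + f[-1L]) / 2
  contrib <- m * favg
  q <- lt@dx * f                          # integrand per year of age

  cellPart <- function(i, from, to) {
    ## fraction of cell i's integral lying in [from, to], linear q
    h <- x[i + 1L] - x[i]
    t1 <- (from - x[i]) / h; t2 <- (to - x[i]) / h
    q1 <- q[i]; q2 <- q[i + 1L]
    tot <- (q1 + q2) / 2
    if (tot <= 0) return(contrib[i] * (t2 - t1))
    qa <- q1 + t1 * (q2 - q1); qb <- q1 + t2 * (q2 - q1)
    contrib[i] * ((t2 - t1) * (qa + qb) / 2) / tot
  }

  i1 <- max(1L, min(n - 1L, findInterval(lower, x)))
  i2 <- max(1L, min(n - 1L, findInterval(upper, x,
                                         rightmost.closed = TRUE)))
  if (i1 == i2) {
    tot <- cellPart(i1, lower, upper)
  } else {
    tot <- cellPart(i1, lower, x[i1 + 1L]) + cellPart(i2, x[i2], upper)
    if (i2 > i1 + 1L) tot <- tot + sum(contrib[(i1 + 1L):(i2 - 1L)])
  }
  if (closure && upper >= x[n]) tot <- tot + lt@lx[n] * f[n]
  tot
}

## Linear interpolation of a grid function at age x.
.gridInterp <- function(lt, f, x) {
  stats::approx(lt@grid@ages, f, xout = x, rule = 1L)$y
}

#' Remaining life expectancy at an arbitrary age
#'
#' Linearly interpolates \eqn{e(x)} between grid ages.
#'
#' @param lt a [LifeTable-class].
#' @param x age in years, within \code{[0, omega]}.
#' @return remaining life expectancy in years.
#' @examples
#' lt <- lifeTable(hazardFixture("constant", rate = 0.1))
#' remainingExpectancy(lt, 50)
#' @export
remainingExpectancy <- function(lt, x) {
  stopifnot(is(lt, "LifeTable"))
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .err("invalid_argument", "'x' must be a single finite age")
  if (x < 0 || x > lt@grid@omega)
    .err("range", sprintf("age %s outside [0, %s]",
                          .fmt(x), .fmt(lt@grid@omega)))
  if (.gridInterp(lt, lt@lx, x) <= 0)
    .err("undefined_value",
         sprintf("survival is zero at age %s: e(x) undefined", .fmt(x)))
  .gridInterp(lt, lt@ex, x)
}
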