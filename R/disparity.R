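## Disparity measures: e-dagger, the sensitivity function g, the threshold
## age, and the compression/expansion decomposition summarised by REC and
## DEC.

#' Life years lost due to death (e-dagger)
#'
#' Computes \eqn{e^\dagger(x) = \int_x^\omega d(a) e(a)\,da / l(x)}, the
#' average remaining life expectancy lost by those dying above age
#' \code{x}. With \code{x = 0} (default) this is the total lifespan
#' disparity \eqn{e^\dagger}. The closure mass at \code{omega} contributes
#' nothing since \eqn{e(\omega) = 0}.
#'
#' @param lt a [LifeTable-class].
#' @param x conditioning age in years (default 0).
#' @return disparity in years.
#' @references For a constant hazard \eqn{\mu}, \eqn{e^\dagger = e^0 =
#'   1/\mu} up to finite-\code{omega} truncation, and life-table entropy is
#'   1; for near-rectangular survival \eqn{e^\dagger \to 0}.
#' @examples
#' lt <- lifeTable(hazardFixture("gompertz", a = 1e-4, b = 0.1))
#' eDagger(lt)
#' eDagger(lt, 70)
#' @export
eDagger <- function(lt, x = 0) {
  stopifnot(is(lt, "LifeTable"))
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 ||
      x > lt@grid@omega)
    .err("range", sprintf("age must lie in [0, %s]", .fmt(lt@grid@omega)))
  if (x == 0)
    return(.deathIntegral(lt, lt@ex))
  lx <- .gridInterp(lt, lt@lx, x)
  if (lx <= 0)
    .err("undefined_value",
         sprintf("survival is zero at age %s: conditional disparity undefined",
                 .fmt(x)))
  .deathIntegral(lt, lt@ex, lower = x) / lx
}

#' Life-table entropy
#'
#' The ratio \eqn{e^\dagger / e^0}: 1 for a constant hazard (exponential
#' survival), approaching 0 as survival becomes rectangular. The threshold
#' age, and hence the compression/expansion decomposition, is defined only
#' for entropy below 1.
#'
#' @param lt a [LifeTable-class].
#' @return dimensionless entropy.
#' @examples
#' lifetableEntropy(lifeTable(hazardFixture("constant", rate = 0.1)))
#' @export
lifetableEntropy <- function(lt) {
  stopifnot(is(lt, "LifeTable"))
  e0 <- lt@ex[1L]
  if (e0 <= 0)
    .err("undefined_value", "life expectancy at birth is zero")
  eDagger(lt) / e0
}

#' Sensitivity of disparity to age-specific mortality decline
#'
#' Computes, at every grid age, the conditional disparity
#' \eqn{e^\dagger(x)}, the bracket term
#' \eqn{\phi(x) = e^\dagger(x) + e(x)(H(x) - 1)} and the sensitivity
#' \eqn{g(x) = d(x)\,\phi(x)}. A proportional mortality reduction
#' concentrated at age \eqn{x} changes \eqn{e^\dagger} with the sign of
#' \eqn{g(x)}: negative below the threshold age (compression), positive
#' above (expansion). Since \eqn{d(x) \ge 0}, the sign structure is carried
#' by \eqn{\phi}, which is used to locate the threshold.
#'
#' Ages where survival has underflowed to zero get \code{NA} curves.
#'
#' @param lt a [LifeTable-class].
#' @return a [SensitivityCurves-class].
#' @examples
#' sc <- sensitivityCurves(lifeTable(hazardFixture("gompertz")))
#' sc@phi[1] < 0   # phi(0) = e-dagger - e0 < 0 when entropy < 1
#' @export
sensitivityCurves <- function(lt) {
  stopifnot(is(lt, "LifeTable"))
  n <- length(lt@lx)
  m <- .cellMasses(lt)
  favg <- (lt@ex[-n] + lt@ex[-1L]) / 2
  ## reverse cumulative sum of cell contributions: integral of d*e above x_i
  above <- c(rev(cumsum(rev(m * favg))), 0)
  edagAbove <- ifelse(lt@lx > 0, above / lt@lx, NA_real_)
  phi <- edagAbove + lt@ex * (lt@Hx - 1)
  new("SensitivityCurves", grid = lt@grid, edagAbove = edagAbove,
      phi = phi, g = lt@dx * phi)
}

#' Threshold age of mortality compression
#'
#' The unique age \eqn{a^\dagger} (for life-table entropy below 1) at which
#' the effect of a mortality reduction on \eqn{e^\dagger} switches from
#' decreasing (compression) to increasing (expansion): the zero crossing of
#' \eqn{\phi(x) = e^\dagger(x) + e(x)(H(x)-1)}, located by a sign-change
#' scan over the grid followed by linear interpolation inside the
#' bracketing cell.
#'
#' The scan is restricted to ages where survival exceeds
#' \code{survivalFloor}: in the extreme tail, \eqn{e^\dagger(x)} is a ratio
#' of two underflowing quantities and spurious sign changes can appear
#' where effectively nobody is left alive. A crossing inside the first grid
#' cell (the exponential limit, whose exact threshold is age 0) is
#' reported as exactly 0.
#'
#' @param lt a [LifeTable-class].
#' @param survivalFloor smallest survival probability at which \eqn{\phi}
#'   is scanned (default \code{1e-9}).
#' @return threshold age in years.
#' @examples
#' thresholdAge(lifeTable(hazardFixture("gompertz", a = 1e-4, b = 0.1)))
#' thresholdAge(lifeTable(hazardFixture("constant", rate = 0.1)))  # 0
#' @export
thresholdAge <- function(lt, survivalFloor = 1e-9) {
  stopifnot(is(lt, "LifeTable"))
  ent <- lifetableEntropy(lt)
  if (ent >= 1)
    .err("no_threshold",
         sprintf("life-table entropy is %.4f >= 1: no threshold age exists",
                 ent),
         data = list(entropy = ent))
  sc <- sensitivityCurves(lt)
  x <- lt@grid@ages
  ok <- which(lt@lx > survivalFloor & is.finite(sc@phi))
  if (length(ok) < 2L)
    .err("no_threshold", "survival decays too fast to scan phi")
  io <- ok[-length(ok)]
  ## adjacent-in-'ok' pairs are adjacent grid cells because lx is monotone
  cross <- io[sign(sc@phi[io]) * sign(sc@phi[io + 1L]) < 0]
  if (length(cross) == 0L) {
    if (sc@phi[ok[1L]] >= 0) return(0)    # phi >= 0 from the start: root at 0
    .err("no_threshold", "phi has no sign change on the grid")
  }
  if (length(cross) > 1L) {
    at <- vapply(cross, function(i) {
      x[i] + (-sc@phi[i]) / (sc@phi[i + 1L] - sc@phi[i]) * (x[i + 1L] - x[i])
    }, numeric(1))
    .err("ambiguous_threshold",
         sprintf("phi changes sign %d times (at ages %s); threshold is ambiguous",
                 length(cross), paste(sprintf("%.2f", at), collapse = ", ")),
         data = list(crossings = at))
  }
  i <- cross
  a <- x[i] + (-sc@phi[i]) / (sc@phi[i + 1L] - sc@phi[i]) * (x[i + 1L] - x[i])
  if (i == 1L && a < x[2L]) return(0)     # below grid resolution: exact root 0
  a
}

.newDisparity <- function(e0, edag, adag, ec, ee, entropy) {
  if (ec > 0) {
    rec <- ee / ec
  } else {
    warning("compression component is zero; REC reported as +Inf")
    rec <- Inf
  }
  new("DisparityResult", e0 = e0, edag = edag, adag = adag, ec = ec,
      ee = ee, rec = rec, dec = ee - ec, entropy = entropy)
}

#' Decompose lifespan disparity into compression and expansion
#'
#' Splits \eqn{e^\dagger = \int_0^\omega d(a)e(a)\,da} at the threshold age
#' into the compression component \eqn{e^\dagger_c = \int_0^{a^\dagger}}
#' and the expansion component \eqn{e^\dagger_e = \int_{a^\dagger}^\omega}
#' (the grid cell containing \eqn{a^\dagger} is split with the integrand
#' interpolated linearly, so the two parts sum to \eqn{e^\dagger}
#' exactly), and summarises them by REC \eqn{= e^\dagger_e/e^\dagger_c}
#' and DEC \eqn{= e^\dagger_e - e^\dagger_c}.
#'
#' @param lt a [LifeTable-class] with entropy below 1.
#' @param survivalFloor passed to [thresholdAge()].
#' @return a [DisparityResult-class].
#' @examples
#' decomposeDisparity(lifeTable(hazardFixture("gompertz")))
#' @export
decomposeDisparity <- function(lt, survivalFloor = 1e-9) {
  stopifnot(is(lt, "LifeTable"))
  adag <- thresholdAge(lt, survivalFloor = survivalFloor)
  edag <- eDagger(lt)
  ec <- if (adag > 0) .deathIntegral(lt, lt@ex, upper = adag,
                                     closure = FALSE) else 0
  ee <- edag - ec
  .newDisparity(e0 = lt@ex[1L], edag = edag, adag = adag, ec = ec, ee = ee,
                entropy = edag / lt@ex[1L])
}

#' Disparity summary from published components
#'
#' Builds a [DisparityResult-class] directly from compression and expansion
#' components (e.g. values printed in a published table), computing their
#' sum \eqn{e^\dagger}, ratio REC and difference DEC. Quantities that
#' require the full life table (\code{e0}, \code{adag}, \code{entropy})
#' are \code{NA} unless supplied.
#'
#' @param ec compression component in years.
#' @param ee expansion component in years.
#' @param e0 optional life expectancy at birth.
#' @param adag optional threshold age.
#' @return a [DisparityResult-class].
#' @examples
#' disparityFromComponents(ec = 9.31, ee = 4.25)   # REC = 0.456...
#' @export
disparityFromComponents <- function(ec, ee, e0 = NA_real_,
                                    adag = NA_real_) {
  if (!is.numeric(ec) || !is.numeric(ee) || length(ec) != 1L ||
      length(ee) != 1L || !is.finite(ec) || !is.finite(ee) ||
      ec < 0 || ee < 0)
    .err("invalid_argument",
         "'ec' and 'ee' must be single non-negative numbers")
  entropy <- if (is.finite(e0) && e0 > 0) (ec + ee) / e0 else NA_real_
  .newDisparity(e0 = as.numeric(e0), edag = ec + ee,
                adag = as.numeric(adag), ec = ec, ee = ee,
                entropy = entropy)
}
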