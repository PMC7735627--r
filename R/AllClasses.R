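#' @import methods
NULL

## Classed conditions used throughout the package. Every error carries a
## condition class "lifeREC_<what>" so callers (and the CLI) can dispatch.
.err <- function(class, msg, ..., data = list()) {
  cond <- errorCondition(msg, ...,
                         class = c(paste0("lifeREC_", class), "lifeREC_error"))
  cond$data <- data
  stop(cond)
}

.fmt <- function(x, digits = 6) format(x, digits = digits, trim = TRUE)

#' AgeGrid: a uniform fine age grid
#'
#' A uniform grid of exact ages \code{0, step, 2 step, ..., omega} on which
#' hazards and all derived life-table functions are evaluated. All integrals
#' in the package are computed on this grid, so \code{step} controls the
#' discretisation error (second order) and \code{omega} is the maximum
#' attainable age: any survivors at \code{omega} are treated as dying exactly
#' there.
#'
#' @slot omega maximum age in years.
#' @slot step grid spacing in years.
#' @slot ages numeric vector of grid ages, strictly increasing, uniformly
#'   spaced, from exactly 0 to exactly \code{omega}.
#' @seealso [makeAgeGrid()]
#' @export
setClass("AgeGrid",
         representation(omega = "numeric", step = "numeric", ages = "numeric"))

setValidity("AgeGrid", function(object) {
  msg <- character()
  if (length(object@omega) != 1L || !is.finite(object@omega) ||
      object@omega <= 0)
    msg <- c(msg, "'omega' must be a single positive number")
  if (length(object@step) != 1L || !is.finite(object@step) ||
      object@step <= 0)
    msg <- c(msg, "'step' must be a single positive number")
  a <- object@ages
  if (length(a) < 2L || a[1L] != 0 || a[length(a)] != object@omega)
    msg <- c(msg, "'ages' must run from exactly 0 to exactly 'omega'")
  else {
    dif <- diff(a)
    if (any(dif <= 0) ||
        max(abs(dif - object@step)) > 1e-9 * max(1, object@step))
      msg <- c(msg, "'ages' must be strictly increasing with uniform spacing 'step'")
  }
  if (length(msg)) msg else TRUE
})

#' HazardSchedule: age-specific force of mortality
#'
#' The force of mortality (hazard of death) \eqn{\mu(x)}, in deaths per
#' person-year, sampled at each age of an [AgeGrid-class].
#'
#' @slot grid an [AgeGrid-class].
#' @slot mu numeric vector of hazards, one per grid age; finite,
#'   non-negative, not all zero.
#' @seealso [hazardSchedule()], [lifeTable()]
#' @export
setClass("HazardSchedule",
         representation(grid = "AgeGrid", mu = "numeric"))

setValidity("HazardSchedule", function(object) {
  msg <- character()
  if (length(object@mu) != length(object@grid@ages))
    msg <- c(msg, "'mu' must have one value per grid age")
  if (!all(is.finite(object@mu)))
    msg <- c(msg, "'mu' must be finite everywhere")
  else {
    if (any(object@mu < 0)) msg <- c(msg, "'mu' must be non-negative")
    if (!any(object@mu > 0)) msg <- c(msg, "'mu' must be positive somewhere")
  }
  if (length(msg)) msg else TRUE
})

#' LifeTable: continuous-approximation life-table functions
#'
#' Survival \eqn{l(x)}, death density \eqn{d(x) = l(x)\mu(x)}, remaining life
#' expectancy \eqn{e(x)} and cumulative hazard \eqn{H(x) = -\log l(x)}
#' derived from a hazard schedule on its age grid. The radix is 1
#' (\eqn{l(0)=1}). Survivors at \code{omega} are closed out as deaths at
#' exactly \code{omega} with \eqn{e(\omega)=0}, so total death mass
#' (integral of \eqn{d} plus \eqn{l(\omega)}) is 1.
#'
#' @slot grid an [AgeGrid-class].
#' @slot mu the hazard the table was built from.
#' @slot lx survival probability at each grid age.
#' @slot dx death density (per year) at each grid age.
#' @slot ex remaining life expectancy (years) at each grid age.
#' @slot Hx cumulative hazard (dimensionless) at each grid age.
#' @seealso [lifeTable()], [eDagger()], [decomposeDisparity()]
#' @export
setClass("LifeTable",
         representation(grid = "AgeGrid", mu = "numeric", lx = "numeric",
                        dx = "numeric", ex = "numeric", Hx = "numeric"))

setValidity("LifeTable", function(object) {
  msg <- character()
  n <- length(object@grid@ages)
  for (s in c("mu", "lx", "dx", "ex", "Hx"))
    if (length(slot(object, s)) != n)
      msg <- c(msg, sprintf("'%s' must have one value per grid age", s))
  if (length(msg)) return(msg)
  l <- object@lx
  if (l[1L] != 1) msg <- c(msg, "l(0) must be 1")
  if (any(diff(l) > 0)) msg <- c(msg, "l must be non-increasing")
  if (any(l < 0 | l > 1)) msg <- c(msg, "l must lie in [0, 1]")
  pos <- l > 1e-300        # below that, log(l) loses precision to denormals
  if (max(abs(object@Hx[pos] + log(l[pos]))) > 1e-10)
    msg <- c(msg, "Hx must equal -log(l)")
  if (any(object@dx < 0)) msg <- c(msg, "d must be non-negative")
  if (any(object@ex < 0)) msg <- c(msg, "e must be non-negative")
  if (length(msg)) msg else TRUE
})

#' SensitivityCurves: sensitivity of disparity to mortality decline
#'
#' Age profiles entering the sensitivity of \eqn{e^\dagger} to age-specific
#' mortality decline: the conditional disparity above each age
#' \eqn{e^\dagger(x)}, the bracket term
#' \eqn{\phi(x) = e^\dagger(x) + e(x)(H(x) - 1)} whose sign change locates
#' the threshold age, and the sensitivity \eqn{g(x) = d(x)\,\phi(x)} giving
#' years of \eqn{e^\dagger} change per unit relative mortality decline at
#' age \eqn{x}.
#'
#' Values at ages where survival has decayed to zero are \code{NA}.
#'
#' @slot grid an [AgeGrid-class].
#' @slot edagAbove conditional disparity \eqn{e^\dagger(x)} in years.
#' @slot phi bracket term in years.
#' @slot g sensitivity \eqn{d(x)\phi(x)}.
#' @seealso [sensitivityCurves()], [thresholdAge()]
#' @export
setClass("SensitivityCurves",
         representation(grid = "AgeGrid", edagAbove = "numeric",
                        phi = "numeric", g = "numeric"))

setValidity("SensitivityCurves", function(object) {
  n <- length(object@grid@ages)
  if (length(object@edagAbove) != n || length(object@phi) != n ||
      length(object@g) != n)
    return("curve slots must have one value per grid age")
  TRUE
})

#' DisparityResult: disparity summary for one mortality schedule
#'
#' The disparity summary of a single life table: life expectancy at birth
#' \eqn{e^0}, life years lost due to death \eqn{e^\dagger}, the threshold
#' age \eqn{a^\dagger}, the compression component \eqn{e^\dagger_c}
#' (disparity accumulated below \eqn{a^\dagger}), the expansion component
#' \eqn{e^\dagger_e} (above \eqn{a^\dagger}), their ratio REC
#' \eqn{= e^\dagger_e / e^\dagger_c}, difference DEC
#' \eqn{= e^\dagger_e - e^\dagger_c}, and life-table entropy
#' \eqn{e^\dagger / e^0}.
#'
#' \code{e0}, \code{adag} and \code{entropy} are \code{NA} when the object
#' was built from published components alone (see
#' [disparityFromComponents()]). \code{rec} is \code{+Inf} when the
#' compression component is zero (degenerate threshold at age 0).
#'
#' @slot e0 life expectancy at birth, years.
#' @slot edag total disparity \eqn{e^\dagger}, years.
#' @slot adag threshold age, years.
#' @slot ec compression component, years.
#' @slot ee expansion component, years.
#' @slot rec ratio of expansion to compression (dimensionless).
#' @slot dec difference expansion minus compression, years.
#' @slot entropy life-table entropy (dimensionless).
#' @seealso [decomposeDisparity()], [disparityFromComponents()]
#' @export
setClass("DisparityResult",
         representation(e0 = "numeric", edag = "numeric", adag = "numeric",
                        ec = "numeric", ee = "numeric", rec = "numeric",
                        dec = "numeric", entropy = "numeric"))

setValidity("DisparityResult", function(object) {
  msg <- character()
  for (s in c("e0", "edag", "adag", "ec", "ee", "rec", "dec", "entropy"))
    if (length(slot(object, s)) != 1L)
      msg <- c(msg, sprintf("'%s' must be a single value", s))
  if (length(msg)) return(msg)
  ec <- object@ec; ee <- object@ee
  if (is.finite(ec) && ec < 0) msg <- c(msg, "'ec' must be non-negative")
  if (is.finite(ee) && ee < 0) msg <- c(msg, "'ee' must be non-negative")
  if (is.finite(ec) && is.finite(ee) && is.finite(object@edag) &&
      abs(ec + ee - object@edag) > 1e-6)
    msg <- c(msg, "'ec' + 'ee' must equal 'edag' within 1e-6")
  if (is.finite(object@adag) && object@adag < 0)
    msg <- c(msg, "'adag' must be non-negative")
  if (length(msg)) msg else TRUE
})

#' ChangeDecomposition: change of disparity and REC between two times
#'
#' Decomposition of the change in \eqn{e^\dagger} and in \eqn{\log REC}
#' between two mortality schedules \code{dt} years apart, by two routes:
#' the discrete component-growth method (log-differences of the compression
#' and expansion components, each table using its own threshold age) and
#' the sensitivity-integral method
#' \eqn{\dot e^\dagger = \int \rho(x) g(x) dx} split at the threshold age
#' of the mid-interval schedule.
#'
#' The identity \code{dlnREC == rateEE - rateEC} holds by construction.
#' Sensitivity slots are \code{NA} when only the discrete part was computed.
#'
#' @slot dt elapsed time in years.
#' @slot rho age-specific relative rate of mortality decline per year
#'   (length 0 when not computed; \code{NA} at ages with zero hazard).
#' @slot rateEC relative change of the compression component per year.
#' @slot rateEE relative change of the expansion component per year.
#' @slot dlnREC relative change of REC per year.
#' @slot edotC change rate of the compression component, years/year, from
#'   the sensitivity integral.
#' @slot edotE change rate of the expansion component, years/year.
#' @slot edot total change rate \code{edotC + edotE}.
#' @seealso [componentRates()], [sensitivityChange()], [changeDecomposition()]
#' @export
setClass("ChangeDecomposition",
         representation(dt = "numeric", rho = "numeric",
                        rateEC = "numeric", rateEE = "numeric",
                        dlnREC = "numeric", edotC = "numeric",
                        edotE = "numeric", edot = "numeric"))

setValidity("ChangeDecomposition", function(object) {
  msg <- character()
  if (length(object@dt) != 1L || !is.finite(object@dt) || object@dt <= 0)
    msg <- c(msg, "'dt' must be a single positive number")
  if (is.finite(object@dlnREC) &&
      abs(object@dlnREC - (object@rateEE - object@rateEC)) > 1e-12)
    msg <- c(msg, "'dlnREC' must equal rateEE - rateEC")
  if (is.finite(object@edot) &&
      abs(object@edot - (object@edotC + object@edotE)) > 1e-9)
    msg <- c(msg, "'edot' must equal edotC + edotE within 1e-9")
  if (length(msg)) msg else TRUE
})

#' SilerParams: a time-declining Siler mortality model
#'
#' Parameters of the Siler hazard with proportional decline over time,
#' \deqn{\mu(x,t) = \alpha_1 e^{-\rho_1 t - \beta_1 x}
#'   + \alpha_2 e^{-\rho_2 t} + \alpha_3 e^{-\rho_3 t + \beta_3 x},}
#' where the three components are infant mortality (declining in age at
#' rate \eqn{\beta_1}), age-constant background mortality, and senescent
#' mortality (rising in age at rate \eqn{\beta_3}). Each component declines
#' over time at its own rate \eqn{\rho}. The senescent decline rate may
#' differ below and above the threshold age of the current schedule
#' (\code{rho3Below} / \code{rho3Above}), which defines the three scenario
#' presets of [scenarioPresets()].
#'
#' @slot alpha1,alpha2,alpha3 component levels at \eqn{x=0,t=0}, per year.
#' @slot beta1 infant-mortality age-decline rate, per year of age.
#' @slot beta3 senescent-mortality age-increase rate, per year of age.
#' @slot rho1,rho2 time-decline rates of components 1 and 2, per year.
#' @slot rho3Below,rho3Above time-decline rate of the senescent component
#'   below / above the threshold age, per year.
#' @slot scenario one of "shifting", "faster_below", "faster_above".
#' @seealso [silerParams()], [scenarioPresets()], [runScenario()]
#' @export
setClass("SilerParams",
         representation(alpha1 = "numeric", alpha2 = "numeric",
                        alpha3 = "numeric", beta1 = "numeric",
                        beta3 = "numeric", rho1 = "numeric",
                        rho2 = "numeric", rho3Below = "numeric",
                        rho3Above = "numeric", scenario = "character"))

setValidity("SilerParams", function(object) {
  msg <- character()
  num <- c("alpha1", "alpha2", "alpha3", "beta1", "beta3",
           "rho1", "rho2", "rho3Below", "rho3Above")
  for (s in num) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v < 0)
      msg <- c(msg, sprintf("'%s' must be a single non-negative number", s))
  }
  if (length(object@scenario) != 1L ||
      !object@scenario %in% c("shifting", "faster_below", "faster_above"))
    msg <- c(msg,
             "'scenario' must be one of 'shifting', 'faster_below', 'faster_above'")
  else if (object@scenario == "shifting" &&
           isTRUE(object@rho3Below != object@rho3Above))
    msg <- c(msg, "shifting scenario requires rho3Below == rho3Above")
  if (length(msg)) msg else TRUE
})

#' ScenarioTrajectory: yearly disparity series from a Siler scenario
#'
#' One row per simulated year with life expectancy at birth, disparity
#' \eqn{e^\dagger}, threshold age, compression and expansion components and
#' their ratio (REC).
#'
#' @slot params the [SilerParams-class] that generated the run.
#' @slot table data.frame with columns \code{year, e0, edag, adag, ec, ee,
#'   rec}.
#' @slot update hazard-update rule used ("closedform" or "stepwise").
#' @slot dt time step in years.
#' @seealso [runScenario()], [recPeakYear()], [writeTrajectory()]
#' @export
setClass("ScenarioTrajectory",
         representation(params = "SilerParams", table = "data.frame",
                        update = "character", dt = "numeric"))

setValidity("ScenarioTrajectory", function(object) {
  need <- c("year", "e0", "edag", "adag", "ec", "ee", "rec")
  if (!all(need %in% names(object@table)))
    return(sprintf("trajectory table must have columns %s",
                   paste(need, collapse = ", ")))
  TRUE
})

#' HmdTable: a parsed HMD-style mortality text file
#'
#' Contents of a Human Mortality Database style whitespace-delimited text
#' file (1x1 period or cohort life table, or an Mx_1x1 death-rate file):
#' two free-text header lines, a column-header line, then one row per
#' (year, age). The open age group \code{"110+"} is stored with
#' \code{Age == 110} and \code{open == TRUE}; the HMD missing marker
#' \code{"."} becomes \code{NA}.
#'
#' @slot kind "mx_1x1" or "life_table_1x1".
#' @slot label free text from the file header (population description).
#' @slot data data.frame with columns \code{Year}, \code{Age},
#'   \code{open}, and the numeric columns of the file.
#' @seealso [readHmd()], [hazardFromHmd()], [writeHmd()]
#' @export
setClass("HmdTable",
         representation(kind = "character", label = "character",
                        data = "data.frame"))

setValidity("HmdTable", function(object) {
  msg <- character()
  if (!object@kind %in% c("mx_1x1", "life_table_1x1"))
    msg <- c(msg, "'kind' must be 'mx_1x1' or 'life_table_1x1'")
  d <- object@data
  if (!all(c("Year", "Age", "open", "mx") %in% names(d)))
    msg <- c(msg, "data must have columns Year, Age, open, mx")
  else if (anyDuplicated(d[c("Year", "Age")]))
    msg <- c(msg, "duplicated (Year, Age) pair")
  if (length(msg)) msg else TRUE
})
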