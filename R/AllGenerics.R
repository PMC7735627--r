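#' Accessors for grid-based objects
#'
#' \code{ages()} returns the grid ages; \code{gridStep()} and
#' \code{maxAge()} the spacing and upper age of the underlying
#' [AgeGrid-class]; \code{hazardRate()}, \code{survival()},
#' \code{deathDensity()}, \code{expectancy()} and
#' \code{cumulativeHazard()} the corresponding life-table function sampled
#' at the grid ages.
#'
#' @param x an [AgeGrid-class], [HazardSchedule-class], [LifeTable-class]
#'   or [SensitivityCurves-class] object, as applicable.
#' @return a numeric vector (scalar for \code{gridStep} and \code{maxAge}).
#' @name grid-accessors
#' @aliases ages gridStep maxAge hazardRate survival deathDensity
#'   expectancy cumulativeHazard
#' @examples
#' lt <- lifeTable(hazardFixture("constant", rate = 0.1))
#' head(ages(lt))
#' survival(lt)[1]      # l(0) = 1
#' maxAge(lt)
NULL

#' @rdname grid-accessors
#' @export
setGeneric("ages", function(x) standardGeneric("ages"))

#' @rdname grid-accessors
#' @export
setGeneric("gridStep", function(x) standardGeneric("gridStep"))

#' @rdname grid-accessors
#' @export
setGeneric("maxAge", function(x) standardGeneric("maxAge"))

#' @rdname grid-accessors
#' @export
setGeneric("hazardRate", function(x) standardGeneric("hazardRate"))

#' @rdname grid-accessors
#' @export
setGeneric("survival", function(x) standardGeneric("survival"))

#' @rdname grid-accessors
#' @export
setGeneric("deathDensity", function(x) standardGeneric("deathDensity"))

#' @rdname grid-accessors
#' @export
setGeneric("expectancy", function(x) standardGeneric("expectancy"))

#' @rdname grid-accessors
#' @export
setGeneric("cumulativeHazard", function(x) standardGeneric("cumulativeHazard"))

#' @rdname ageGrid-methods
#' @export
setGeneric("ageGrid", function(x) standardGeneric("ageGrid"))

## -- grid accessors -------------------------------------------------------

#' @rdname grid-accessors
setMethod("ages", "AgeGrid", function(x) x@ages)
#' @rdname grid-accessors
setMethod("gridStep", "AgeGrid", function(x) x@step)
#' @rdname grid-accessors
setMethod("maxAge", "AgeGrid", function(x) x@omega)

#' Extract the age grid of an object
#'
#' @param x a [HazardSchedule-class], [LifeTable-class] or
#'   [SensitivityCurves-class].
#' @return the underlying [AgeGrid-class].
#' @name ageGrid-methods
#' @aliases ageGrid
NULL

for (cl in c("HazardSchedule", "LifeTable", "SensitivityCurves")) {
  setMethod("ageGrid", cl, function(x) x@grid)
  setMethod("ages", cl, function(x) x@grid@ages)
  setMethod("gridStep", cl, function(x) x@grid@step)
  setMethod("maxAge", cl, function(x) x@grid@omega)
}

#' @rdname grid-accessors
setMethod("hazardRate", "HazardSchedule", function(x) x@mu)
#' @rdname grid-accessors
setMethod("hazardRate", "LifeTable", function(x) x@mu)
#' @rdname grid-accessors
setMethod("survival", "LifeTable", function(x) x@lx)
#' @rdname grid-accessors
setMethod("deathDensity", "LifeTable", function(x) x@dx)
#' @rdname grid-accessors
setMethod("expectancy", "LifeTable", function(x) x@ex)
#' @rdname grid-accessors
setMethod("cumulativeHazard", "LifeTable", function(x) x@Hx)

## -- show methods ---------------------------------------------------------

setMethod("show", "AgeGrid", function(object) {
  cat(sprintf("AgeGrid: %d ages, 0 .. %s by %s years\n",
              length(object@ages), .fmt(object@omega), .fmt(object@step)))
})

setMethod("show", "HazardSchedule", function(object) {
  mu <- object@mu
  cat(sprintf("HazardSchedule on [0, %s] (step %s): mu in [%.3g, %.3g]\n",
              .fmt(object@grid@omega), .fmt(object@grid@step),
              min(mu), max(mu)))
})

setMethod("show", "LifeTable", function(object) {
  cat(sprintf("LifeTable on [0, %s] (step %s)\n",
              .fmt(object@grid@omega), .fmt(object@grid@step)))
  cat(sprintf("  e(0) = %.3f years,  l(omega) = %.3g\n",
              object@ex[1L], object@lx[length(object@lx)]))
})

setMethod("show", "SensitivityCurves", function(object) {
  cat(sprintf("SensitivityCurves on [0, %s]: phi(0) = %.4f years\n",
              .fmt(object@grid@omega), object@phi[1L]))
})

setMethod("show", "DisparityResult", function(object) {
  cat("DisparityResult\n")
  cat(sprintf("  e0      = %8.2f years\n", object@e0))
  cat(sprintf("  e-dag   = %8.2f years   (entropy %.3f)\n",
              object@edag, object@entropy))
  cat(sprintf("  a-dag   = %8.2f years\n", object@adag))
  cat(sprintf("  ec      = %8.2f years   (compression)\n", object@ec))
  cat(sprintf("  ee      = %8.2f years   (expansion)\n", object@ee))
  cat(sprintf("  REC     = %8.2f         DEC = %.2f years\n",
              object@rec, object@dec))
})

setMethod("show", "ChangeDecomposition", function(object) {
  cat(sprintf("ChangeDecomposition over dt = %s years\n", .fmt(object@dt)))
  cat(sprintf("  d ln ee / dt = %8.4f per year\n", object@rateEE))
  cat(sprintf("  d ln ec / dt = %8.4f per year\n", object@rateEC))
  cat(sprintf("  d ln REC/ dt = %8.4f per year\n", object@dlnREC))
  if (is.finite(object@edot))
    cat(sprintf("  edot = %.4f (compression %.4f + expansion %.4f) years/year\n",
                object@edot, object@edotC, object@edotE))
})

setMethod("show", "SilerParams", function(object) {
  cat(sprintf("SilerParams (%s scenario)\n", object@scenario))
  cat(sprintf("  alpha = (%.3g, %.3g, %.3g), beta1 = %.3g, beta3 = %.3g\n",
              object@alpha1, object@alpha2, object@alpha3,
              object@beta1, object@beta3))
  cat(sprintf("  rho1 = rho2 = %.3g; rho3 = %.3g below / %.3g above a-dag\n",
              object@rho1, object@rho3Below, object@rho3Above))
})

setMethod("show", "ScenarioTrajectory", function(object) {
  tb <- object@table
  cat(sprintf("ScenarioTrajectory (%s, %s update): %d years, dt = %s\n",
              object@params@scenario, object@update, nrow(tb),
              .fmt(object@dt)))
  cat(sprintf("  e0: %.2f -> %.2f;  REC: %.3f -> %.3f\n",
              tb$e0[1L], tb$e0[nrow(tb)], tb$rec[1L], tb$rec[nrow(tb)]))
})

setMethod("show", "HmdTable", function(object) {
  d <- object@data
  cat(sprintf("HmdTable (%s): %s\n", object@kind, object@label))
  cat(sprintf("  years %s-%s, ages %d-%d%s, %d rows\n",
              min(d$Year), max(d$Year), min(d$Age), max(d$Age),
              if (any(d$open)) "+" else "", nrow(d)))
})

#' @rawNamespace exportMethods(show, ages, gridStep, maxAge, ageGrid,
#'   hazardRate, survival, deathDensity, expectancy, cumulativeHazard,
#'   as.data.frame)
NULL

#' Coerce a scenario trajectory to a data.frame
#'
#' @param x a [ScenarioTrajectory-class].
#' @param row.names,optional,... passed on for compatibility; unused.
#' @return the yearly data.frame with columns
#'   \code{year, e0, edag, adag, ec, ee, rec}.
#' @method as.data.frame ScenarioTrajectory
#' @export
as.data.frame.ScenarioTrajectory <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  x@table
}

setMethod("as.data.frame", "ScenarioTrajectory",
          as.data.frame.ScenarioTrajectory)
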