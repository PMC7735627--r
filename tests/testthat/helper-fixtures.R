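# Shared fixtures and small oracles. Everything is built in code; the
# standard grid is 0..120 by 0.1 years.

stdGrid <- makeAgeGrid(120, 0.1)

ltConstant <- lifeTable(hazardFixture("constant", grid = stdGrid, rate = 0.1))
ltGompertz <- lifeTable(hazardFixture("gompertz", grid = stdGrid,
                                      a = 1e-4, b = 0.1))
ltMakeham  <- lifeTable(hazardFixture("gompertz_makeham", grid = stdGrid))
ltRect     <- lifeTable(hazardFixture("near_rectangular", grid = stdGrid))

# a declining-hazard schedule whose entropy exceeds 1 (no threshold age)
highEntropyHazard <- function(grid = stdGrid)
  hazardSchedule(function(x) 0.5 * exp(-0.3 * x) + 0.01, grid)

# truncated-exponential closed forms on [0, omega]: remaining expectancy,
# conditional disparity above x, and the bracket term phi
expTrunc <- function(mu, omega) {
  e <- function(x) (1 - exp(-mu * (omega - x))) / mu
  edagAbove <- function(x) {
    s <- omega - x
    (1 / mu) * ((1 - exp(-mu * s)) - mu * s * exp(-mu * s))
  }
  phi <- function(x) edagAbove(x) + e(x) * (mu * x - 1)
  list(e = e, edagAbove = edagAbove, phi = phi)
}

# integral of a grid-sampled function against the death density, computed
# the way a band perturbation is felt by the cumulative-hazard integral
# (trapezoid over the whole grid of the masked integrand)
maskedTrapz <- function(x, y) as.vector(pracma::trapz(x, y))

# memoized full scenario runs shared across test files
.trajCache <- new.env(parent = emptyenv())
getTrajectory <- function(scenario, dt = 1, update = "closedform") {
  key <- paste(scenario, dt, update, sep = "/")
  if (is.null(.trajCache[[key]]))
    .trajCache[[key]] <- runScenario(scenarioPresets()[[scenario]],
                                     horizon = 150, dt = dt,
                                     grid = stdGrid, update = update)
  .trajCache[[key]]
}

# minimal synthetic HMD rate table (midpoint-sampled hazard)
makeMxTable <- function(years, mxFun, label = "Synthetic test population") {
  rows <- expand.grid(Age = 0:110, Year = years)[, c("Year", "Age")]
  rows <- rows[order(rows$Year, rows$Age), ]
  new("HmdTable", kind = "mx_1x1", label = label,
      data = data.frame(Year = rows$Year, Age = rows$Age,
                        open = rows$Age == 110L,
                        mx = mxFun(rows$Age + 0.5)))
}
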