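# Life-table construction from hazards: grid arithmetic, closed-form
# agreement, mass closure, and grid convergence.

test_that("age grid construction enforces commensurate arguments", {
  g <- makeAgeGrid(120, 0.1)
  expect_length(ages(g), 1201L)
  expect_identical(ages(g)[1], 0)
  expect_identical(ages(g)[1201], 120)
  expect_equal(ages(makeAgeGrid(1, 0.5)), c(0, 0.5, 1))
  expect_error(makeAgeGrid(10, 0.3), class = "lifeREC_invalid_argument")
  expect_error(makeAgeGrid(-1, 0.1), class = "lifeREC_invalid_argument")
  expect_error(makeAgeGrid(10, 0), class = "lifeREC_invalid_argument")
})

test_that("hazard schedules reject improper inputs", {
  expect_error(hazardSchedule(rep(0, 1201), stdGrid),
               class = "lifeREC_invalid_argument")
  expect_error(hazardSchedule(c(rep(0.1, 1200), -0.1), stdGrid),
               class = "lifeREC_invalid_argument")
  expect_error(hazardSchedule(c(rep(0.1, 1200), NA), stdGrid),
               class = "lifeREC_invalid_argument")
})

test_that("fixture families enforce their contracts", {
  expect_error(hazardFixture("weibull"), class = "lifeREC_invalid_argument")
  expect_error(hazardFixture("gompertz", a = -1),
               class = "lifeREC_invalid_argument")
  expect_error(hazardFixture("near_rectangular", b = 0.2),
               class = "lifeREC_invalid_argument")
  expect_error(fixtureExpectedValues("near_rectangular"),
               class = "lifeREC_unsupported")
  expect_equal(fixtureExpectedValues("constant", rate = 0.1)$e0,
               (1 - exp(-12)) / 0.1)
})

test_that("constant hazard reproduces the exponential closed forms", {
  lt <- lifeTable(hazardFixture("constant", grid = makeAgeGrid(120, 0.05),
                                rate = 0.1))
  expect_equal(expectancy(lt)[1], (1 - exp(-12)) / 0.1, tolerance = 1e-4)
  x <- ages(lt)
  expect_lt(max(abs(deathDensity(lt) - 0.1 * exp(-0.1 * x))), 1e-6)
  # memoryless up to the finite-omega truncation, e.g. at age 50
  expect_equal(remainingExpectancy(lt, 50), 10 * (1 - exp(-0.1 * 70)),
               tolerance = 1e-3)
  cf <- expTrunc(0.1, 120)
  expect_lt(max(abs(expectancy(lt) - cf$e(x))), 1e-3)
})

test_that("Gompertz survival matches its closed form pointwise", {
  g <- makeAgeGrid(120, 0.05)
  lt <- lifeTable(hazardFixture("gompertz", grid = g, a = 1e-4, b = 0.1))
  cf <- fixtureExpectedValues("gompertz", grid = g, a = 1e-4, b = 0.1)
  expect_lt(max(abs(survival(lt) - cf$survival(ages(g)))), 1e-6)
})

test_that("life expectancy agrees with independent quadrature of the closed-form survival", {
  for (fam in c("constant", "gompertz", "gompertz_makeham")) {
    lt <- lifeTable(hazardFixture(fam, grid = stdGrid))
    cf <- fixtureExpectedValues(fam, grid = stdGrid)
    expect_equal(expectancy(lt)[1], cf$e0, tolerance = 1e-4,
                 label = sprintf("e0 for %s fixture", fam))
  }
})

test_that("death mass closes to one and H matches -log(l) on every fixture", {
  for (lt in list(ltConstant, ltGompertz, ltMakeham, ltRect)) {
    n <- length(ages(lt))
    total <- lifeREC:::.deathIntegral(lt, rep(1, n))  # includes l(omega)
    expect_lt(abs(total - 1), 1e-12)
    pos <- survival(lt) > 1e-300
    expect_lt(max(abs(cumulativeHazard(lt)[pos] + log(survival(lt)[pos]))),
              1e-10)
    expect_true(all(diff(survival(lt)) <= 0))
    expect_identical(survival(lt)[1], 1)
  }
})

test_that("halving the grid step moves e(0) only at second order", {
  e0At <- function(fam, step)
    expectancy(lifeTable(hazardFixture(fam,
                                       grid = makeAgeGrid(120, step))))[1]
  for (fam in c("constant", "gompertz", "gompertz_makeham"))
    expect_lt(abs(e0At(fam, 0.1) - e0At(fam, 0.05)), 1e-4)
  # the steep near-rectangular hazard converges at the same order but from
  # a larger constant (error scales with the squared slope b)
  expect_lt(abs(e0At("near_rectangular", 0.1) -
                  e0At("near_rectangular", 0.05)), 5e-4)
})

test_that("remaining expectancy interpolates and guards its domain", {
  expect_identical(remainingExpectancy(ltGompertz, 120), 0)
  # linear interpolation between grid ages
  mid <- remainingExpectancy(ltGompertz, 50.05)
  e <- expectancy(ltGompertz)
  i <- match(50, ages(ltGompertz))
  expect_equal(mid, (e[i] + e[i + 1]) / 2, tolerance = 1e-12)
  # refined-grid oracle at a tenth of the step
  fine <- lifeTable(hazardFixture("gompertz", grid = makeAgeGrid(120, 0.01)))
  expect_equal(remainingExpectancy(ltGompertz, 0),
               remainingExpectancy(fine, 0), tolerance = 1e-4)
  expect_error(remainingExpectancy(ltGompertz, -1), class = "lifeREC_range")
  expect_error(remainingExpectancy(ltGompertz, 121), class = "lifeREC_range")
  expect_error(remainingExpectancy(ltRect, 119),
               class = "lifeREC_undefined_value")
})
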