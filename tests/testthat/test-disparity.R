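# Disparity measures: e-dagger, sensitivity curves, threshold age, and the
# compression/expansion decomposition.

test_that("e-dagger matches the exponential and refined-grid oracles", {
  # exponential: entropy 1, e-dagger = e0 = 1/mu up to truncation
  expect_lt(abs(eDagger(ltConstant) - expectancy(ltConstant)[1]), 0.02)
  expect_lt(abs(eDagger(ltConstant) - 10), 0.02)
  # refined grid at a tenth of the step
  fine <- lifeTable(hazardFixture("gompertz", grid = makeAgeGrid(120, 0.01)))
  expect_equal(eDagger(ltGompertz), eDagger(fine), tolerance = 1e-3)
  expect_equal(eDagger(ltGompertz, 70), eDagger(fine, 70), tolerance = 1e-3)
})

test_that("conditional disparity reduces to the total at age 0 and obeys closed forms", {
  expect_identical(eDagger(ltGompertz, 0), eDagger(ltGompertz))
  cf <- expTrunc(0.1, 120)
  for (x in c(10, 30, 50, 60))
    expect_equal(eDagger(ltConstant, x), cf$edagAbove(x), tolerance = 1e-3)
  expect_error(eDagger(ltRect, 119), class = "lifeREC_undefined_value")
  expect_error(eDagger(ltGompertz, 130), class = "lifeREC_range")
})

test_that("entropy spans the exponential and rectangular limits", {
  expect_equal(lifetableEntropy(ltConstant), 1, tolerance = 0.01)
  expect_lt(lifetableEntropy(ltRect), 0.05)
  expect_identical(lifetableEntropy(ltGompertz),
                   eDagger(ltGompertz) / expectancy(ltGompertz)[1])
})

test_that("near-rectangular survival approaches the compression limit", {
  prev <- Inf
  for (b in c(0.5, 1, 2, 4)) {
    lt <- lifeTable(hazardFixture("near_rectangular", grid = stdGrid,
                                  a = 1e-12, b = b))
    ed <- eDagger(lt)
    expect_lt(abs(ed * b - 1), 0.02)     # e-dagger ~ 1/b for steep Gompertz
    expect_lt(ed, prev)
    prev <- ed
  }
  expect_lt(prev, 0.3)                   # b = 4: well inside the limit
})

test_that("sensitivity curves match the truncated-exponential closed form", {
  sc <- sensitivityCurves(ltConstant)
  x <- ages(ltConstant)
  cf <- expTrunc(0.1, 120)
  keep <- x <= 110
  expect_lt(max(abs(sc@phi[keep] - cf$phi(x[keep]))), 2e-3)
  # phi(x) ~ x away from the truncation horizon
  near <- x <= 30
  expect_lt(max(abs(sc@phi[near] - x[near])), 0.02)
  expect_equal(sc@g, deathDensity(ltConstant) * sc@phi)
})

test_that("phi starts negative and changes sign exactly once when entropy < 1", {
  for (lt in list(ltGompertz, ltMakeham, ltRect)) {
    sc <- sensitivityCurves(lt)
    expect_equal(sc@phi[1], eDagger(lt) - expectancy(lt)[1],
                 tolerance = 1e-9)
    expect_lt(sc@phi[1], 0)
    ok <- survival(lt) > 1e-9 & is.finite(sc@phi)
    s <- sign(sc@phi[ok])
    expect_identical(sum(diff(s) != 0), 1L)
  }
})

test_that("threshold age handles the degenerate, regular and pathological cases", {
  # exponential: root at age 0, below grid resolution
  expect_identical(thresholdAge(ltConstant), 0)
  # regular case: a-dagger lies a little below life expectancy
  a <- thresholdAge(ltGompertz)
  expect_gt(a, 55); expect_lt(a, expectancy(ltGompertz)[1])
  # near-rectangular: threshold close to (and below) the modal age at death
  mode <- ages(ltRect)[which.max(deathDensity(ltRect))]
  aR <- thresholdAge(ltRect)
  expect_lt(aR, mode)
  expect_lt(mode - aR, 2)
  # entropy >= 1: no threshold exists
  expect_error(thresholdAge(lifeTable(highEntropyHazard())),
               class = "lifeREC_no_threshold")
})

test_that("a mortality reduction changes disparity with the sign and size given by g", {
  sc <- sensitivityCurves(ltGompertz)
  x <- ages(ltGompertz)
  adag <- thresholdAge(ltGompertz)
  eps <- 1e-3
  ed0 <- eDagger(ltGompertz)
  for (x0 in c(10, 30, 50, adag - 5, adag + 5, 90)) {
    band <- x >= x0 & x < x0 + 1
    mu2 <- hazardRate(ltGompertz)
    mu2[band] <- mu2[band] * (1 - eps)
    dE <- eDagger(lifeTable(hazardSchedule(mu2, stdGrid))) - ed0
    pred <- eps * maskedTrapz(x, sc@g * band)
    expect_identical(sign(dE), sign(pred))
    expect_lt(abs(dE - pred) / abs(dE), 0.05)
  }
})

test_that("compression and expansion components conserve e-dagger", {
  for (lt in list(ltGompertz, ltMakeham, ltRect)) {
    d <- decomposeDisparity(lt)
    expect_lt(abs(d@ec + d@ee - d@edag), 1e-6)
    expect_gte(d@ec, 0); expect_gte(d@ee, 0)
    expect_equal(d@rec, d@ee / d@ec)
    expect_equal(d@dec, d@ee - d@ec)
    expect_gte(d@adag, 0); expect_lte(d@adag, 120)
  }
})

test_that("degenerate threshold at zero yields the REC infinity sentinel", {
  expect_warning(d <- decomposeDisparity(ltConstant),
                 "compression component is zero")
  expect_identical(d@ec, 0)
  expect_identical(d@rec, Inf)
  expect_equal(d@ee, d@edag)
})

test_that("disparity summaries can be built from published components", {
  d <- disparityFromComponents(ec = 5, ee = 5)
  expect_identical(d@rec, 1)
  expect_identical(d@dec, 0)
  expect_identical(d@edag, 10)
  expect_true(is.na(d@e0) && is.na(d@adag))
  expect_error(disparityFromComponents(-1, 2),
               class = "lifeREC_invalid_argument")
})
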