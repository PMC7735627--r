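# Siler simulator: hazard evaluation, scenario presets, and long-run
# trajectory properties under the three decline scenarios.

test_that("the Siler hazard evaluates its closed form", {
  p <- silerParams()
  h0 <- silerHazard(p, 0, stdGrid)
  expect_identical(hazardRate(h0)[1], 1e-9 + 3e-4 + 1e-6)
  # all scenarios share the baseline hazard at t = 0
  for (q in scenarioPresets())
    expect_equal(hazardRate(silerHazard(q, 0, stdGrid, splitAge = 80)),
                 hazardRate(h0), tolerance = 1e-15)
  # with an age-constant rho3 the profile argument is optional
  expect_equal(hazardRate(silerHazard(p, 10, stdGrid)),
               hazardRate(silerHazard(p, 10, stdGrid, splitAge = 50)),
               tolerance = 1e-15)
  pa <- scenarioPresets()$faster_above
  expect_error(silerHazard(pa, 10, stdGrid),
               class = "lifeREC_invalid_argument")  # split needed
})

test_that("scenario presets carry the standard rate pattern", {
  pr <- scenarioPresets()
  expect_named(pr, c("shifting", "faster_below", "faster_above"))
  expect_identical(pr$shifting@rho3Below, 0.01)
  expect_identical(pr$shifting@rho3Above, 0.01)
  expect_identical(pr$faster_below@rho3Below, 0.013)
  expect_identical(pr$faster_below@rho3Above, 0.01)
  expect_identical(pr$faster_above@rho3Below, 0.01)
  expect_identical(pr$faster_above@rho3Above, 0.013)
  shared <- function(p) c(p@alpha1, p@alpha2, p@alpha3, p@beta1, p@beta3,
                          p@rho1, p@rho2)
  expect_identical(shared(pr$shifting), shared(pr$faster_above))
  expect_identical(shared(pr$shifting), shared(pr$faster_below))
  expect_error(silerParams(rho3Below = 0.01, rho3Above = 0.013,
                           scenario = "shifting"))
})

test_that("stepwise accumulation reproduces the closed form under constant rho3", {
  sh1 <- getTrajectory("shifting", update = "closedform")
  sh2 <- getTrajectory("shifting", update = "stepwise")
  t1 <- as.data.frame(sh1); t2 <- as.data.frame(sh2)
  for (col in c("e0", "edag", "adag", "rec"))
    expect_lt(max(abs(t1[[col]] - t2[[col]]) / abs(t1[[col]])), 1e-10)
})

test_that("longevity rises and the shifting scenario slowly compresses", {
  sh <- as.data.frame(getTrajectory("shifting"))
  fb <- as.data.frame(getTrajectory("faster_below"))
  fa <- as.data.frame(getTrajectory("faster_above"))
  expect_identical(nrow(sh), 151L)
  for (tb in list(sh, fb, fa)) expect_true(all(diff(tb$e0) > 0))
  expect_true(all(diff(sh$edag) < 0))     # shifting still compresses
  expect_true(all(diff(sh$adag) >= 0))    # threshold age keeps rising
  expect_true(all(diff(sh$rec) > 0))      # REC rises under shifting
  # per-year disparity identities hold along the trajectory
  for (tb in list(sh, fa))
    expect_lt(max(abs(tb$ec + tb$ee - tb$edag)), 1e-6)
})

test_that("life expectancy ranks faster_below > faster_above > shifting", {
  sh <- as.data.frame(getTrajectory("shifting"))
  fb <- as.data.frame(getTrajectory("faster_below"))
  fa <- as.data.frame(getTrajectory("faster_above"))
  i <- -1L                                # scenarios coincide at t = 0
  expect_true(all(fb$e0[i] > fa$e0[i]))
  expect_true(all(fa$e0[i] > sh$e0[i]))
})

test_that("the threshold age tracks life expectancy a couple of years below", {
  gaps <- vapply(c("shifting", "faster_below", "faster_above"),
                 function(s) {
                   tb <- as.data.frame(getTrajectory(s))
                   mean(tb$e0 - tb$adag)
                 }, numeric(1))
  expect_true(all(gaps > 1 & gaps < 3))
})

test_that("faster progress above the threshold gives a reverse-U REC", {
  fa <- as.data.frame(getTrajectory("faster_above"))
  peak <- recPeakYear(getTrajectory("faster_above"))
  expect_gt(peak, 60); expect_lt(peak, 120)
  # rises into the peak region and falls out of it
  expect_gt(fa$rec[which(fa$year == 80)], fa$rec[1])
  expect_lt(fa$rec[151], max(fa$rec))
})

test_that("halving the time step moves the REC peak by at most two years", {
  p1 <- recPeakYear(getTrajectory("faster_above", dt = 1))
  p05 <- recPeakYear(getTrajectory("faster_above", dt = 0.5))
  expect_lt(abs(p1 - p05), 2)
})

test_that("the frozen-threshold variant runs and differs from the updated one", {
  frozen <- runScenario(scenarioPresets()$faster_above, horizon = 30,
                        dt = 1, grid = stdGrid, frozenThreshold = TRUE)
  live <- as.data.frame(getTrajectory("faster_above"))
  tf <- as.data.frame(frozen)
  expect_identical(nrow(tf), 31L)
  expect_false(isTRUE(all.equal(tf$rec, live$rec[1:31], tolerance = 1e-12)))
  expect_true(all(diff(tf$e0) > 0))
})

test_that("scenario parameters round-trip through a key-value config file", {
  f <- withr::local_tempfile()
  writeLines(c("# custom run", "alpha3 = 2e-6", "rho3Above: 0.013",
               "scenario = faster_above"), f)
  p <- readSilerConfig(f)
  expect_identical(p@alpha3, 2e-6)
  expect_identical(p@rho3Above, 0.013)
  expect_identical(p@scenario, "faster_above")
  expect_identical(p@rho3Below, 0.01)      # untouched default
  writeLines("nonsense here", f)
  expect_error(readSilerConfig(f), class = "lifeREC_parse")
  writeLines("gamma = 3", f)
  expect_error(readSilerConfig(f), class = "lifeREC_parse")
})

test_that("a run that loses its threshold aborts with the partial trajectory", {
  # senescence fades much faster than background, so the schedule drifts
  # toward a constant hazard and phi loses its sign change within years
  p <- silerParams(rho1 = 0, rho2 = 0, rho3Below = 0.5, rho3Above = 0.5)
  err <- tryCatch(
    runScenario(p, horizon = 60, dt = 1, grid = makeAgeGrid(120, 0.5)),
    lifeREC_no_threshold_abort = function(e) e)
  expect_s3_class(err, "condition")
  expect_s3_class(err$data$trajectory, "data.frame")
  expect_gt(nrow(err$data$trajectory), 0)
  expect_identical(nrow(err$data$trajectory) + 0, err$data$time)
})
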