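# Synthetic panoramic stimulus generator.

test_that("looming angular size follows the l/|v| kinematics", {
  # |v| * ttc == l: half-angle 45 degrees
  expect_equal(loomingAngularSize(0.5, 1, 1.5, 2), 90)
  expect_lt(loomingAngularSize(0.05, 1, 0, 1e5), 1e-3)
  expect_equal(loomingAngularSize(0.07, 1.4, 0, 1),
               2 * atan(0.05) * 180 / pi)
  expect_equal(loomingAngularSize(0.07, 1.4, 0, 1), 5.7248, tolerance = 1e-4)
  # clipped at contact
  expect_equal(loomingAngularSize(0.05, 1, 2, 1), 170)

  t <- seq(0, 1.9, by = 0.1)
  th <- loomingAngularSize(0.05, 0.3, t, 2)
  expect_true(all(diff(th) > 0))  # strictly increasing in t
  for (tt in c(0, 0.5, 1)) {      # strictly increasing in l at fixed ttc
    expect_true(all(diff(loomingAngularSize(c(0.02, 0.05, 0.1), 0.3,
                                            tt, 2)) > 0))
  }
})

test_that("static stimuli render identical background frames", {
  fs <- renderSequence(stimulusSpec("static", durationS = 0.3,
                                    backgroundGray = 123,
                                    frameDim = c(48L, 48L), noiseSigma = 0))
  expect_true(all(fs@frames == 123))
  d <- dim(fs@frames)
  expect_identical(d[3L], 9L)  # 0.3 s at 30 fps
  expect_identical(nrow(fs@groundTruth), 9L)
})

test_that("rendering is deterministic and receding reverses the paired loom", {
  spec <- stimulusSpec("loom_ltv", durationS = 0.7, seed = 5L,
                       frameDim = c(64L, 64L))
  a <- renderSequence(spec)
  b <- renderSequence(spec)
  expect_identical(a@frames, b@frames)

  rspec <- spec
  rspec@kind <- "recede"
  r <- renderSequence(rspec)
  nT <- dim(a@frames)[3L]
  expect_identical(r@frames, a@frames[, , rev(seq_len(nT))])
  expect_true(all(is.na(r@groundTruth$ttcS)))
  # ground-truth angular size runs backwards
  expect_equal(r@groundTruth$thetaDeg, rev(a@groundTruth$thetaDeg))
})

test_that("whole-field rotation matches exact right-angle rotations", {
  spec <- stimulusSpec("rotate", omegaDegS = 90, durationS = 1.2,
                       frameDim = c(64L, 64L), noiseSigma = 0, seed = 2L)
  fs <- renderSequence(spec)
  rot90ccw <- function(m) t(m[, rev(seq_len(ncol(m)))])
  f1 <- fs@frames[, , 1]
  # 90 deg/s at 30 fps: frame 31 is the first frame rotated a quarter turn
  expect_identical(fs@frames[, , 31], rot90ccw(f1))
  expect_identical(rotateImage(f1, 180), rot90ccw(rot90ccw(f1)))
  expect_identical(rotateImage(f1, 0), f1)
})

test_that("frame-to-frame change separates static, loom and rotation", {
  mad1 <- function(fr) {
    nT <- dim(fr)[3L]
    mean(abs(fr[, , 2:nT] - fr[, , 1:(nT - 1)]))
  }
  st <- renderSequence(stimulusSpec("static", durationS = 0.5,
                                    frameDim = c(64L, 64L), noiseSigma = 0))
  lo <- renderSequence(stimulusSpec("loom_ltv", durationS = 0.5,
                                    frameDim = c(64L, 64L), noiseSigma = 0))
  ro <- renderSequence(stimulusSpec("rotate", omegaDegS = 90, durationS = 0.5,
                                    frameDim = c(64L, 64L), noiseSigma = 0))
  expect_equal(mad1(st@frames), 0)
  expect_gt(mad1(lo@frames), 0)

  # rotation spreads change nearly uniformly across sectors
  geom <- buildSectorGeometry(c(64L, 64L))
  nT <- dim(ro@frames)[3L]
  dframes <- abs(ro@frames[, , 2:nT] - ro@frames[, , 1:(nT - 1)])
  perSector <- vapply(geom@maskIndex, function(ii) {
    mean(vapply(seq_len(nT - 1), function(k) mean(dframes[, , k][ii]),
                numeric(1)))
  }, numeric(1))
  expect_gt(min(perSector), 5)
  expect_lt(max(perSector) / min(perSector), 3)
})

test_that("constant-rate looms and pass-bys follow their declared kinematics", {
  co <- renderSequence(stimulusSpec("loom_const_omega", theta0Deg = 5,
                                    omegaDegS = 40, durationS = 0.5,
                                    frameDim = c(64L, 64L), noiseSigma = 0))
  expect_equal(co@groundTruth$thetaDeg,
               pmin(5 + 40 * (0:14) / 30, 170))
  pb <- renderSequence(stimulusSpec("translate_passby", azimuthDeg = 90,
                                    theta0Deg = 5, omegaDegS = 30,
                                    durationS = 1, frameDim = c(64L, 64L),
                                    noiseSigma = 0))
  expect_true(all(pb@groundTruth$thetaDeg == 5))
  expect_equal(diff(pb@groundTruth$azimuthDeg),
               rep(1, dim(pb@frames)[3L] - 1))
  expect_equal(pb@groundTruth$azimuthDeg[1], 90 - 15)
})

test_that("contact-sized objects are flagged out of field", {
  fs <- renderSequence(stimulusSpec("loom_const_omega", theta0Deg = 150,
                                    omegaDegS = 60, durationS = 0.6,
                                    frameDim = c(64L, 64L), noiseSigma = 0))
  gt <- fs@groundTruth
  expect_false(gt$outOfField[1])
  expect_true(gt$outOfField[nrow(gt)])  # clipped at the contact angle
})

test_that("the fixture suite is complete and reproducible", {
  specs <- makeFixtureSuite(7L, render = FALSE)
  expect_length(specs$contrasts, 6L)  # six gray levels
  expect_identical(names(specs$deviations),
                   c("dev_0", "dev_5", "dev_10", "dev_20"))
  expect_identical(specs$deviations$dev_20@kind, "translate_passby")
  expect_length(specs$speeds, 5L)
  expect_length(specs$sizes, 3L)
  for (s in specs$sizes) expect_lte(round(s@durationS * s@fps), 120)
  for (s in specs$speeds) expect_lte(round(s@durationS * s@fps), 120)

  specs2 <- makeFixtureSuite(7L, render = FALSE)
  expect_identical(specs, specs2)
  a <- renderSequence(specs$adjacent_tie)
  b <- renderSequence(specs2$adjacent_tie)
  expect_identical(a@frames, b@frames)
})

test_that("invalid stimulus specifications are rejected", {
  expect_error(stimulusSpec("loom_ltv", objectGray = 100,
                            backgroundGray = 100), "differ")
  expect_error(stimulusSpec("wobble"), "kind")
  expect_error(stimulusSpec("loom_ltv", durationS = 0), "durationS")
  expect_error(stimulusSpec("loom_ltv", theta0Deg = 200), "theta0Deg")
})
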