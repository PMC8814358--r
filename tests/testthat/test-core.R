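# Layer-by-layer behaviour of the per-sector partial neural network.

cfg <- mlg1Config()

test_that("persistence coefficients follow the logistic form and decay", {
  expect_equal(persistenceCoefficient(0, 1), 0.5)
  expect_equal(persistenceCoefficient(1, 1), 1 / (1 + exp(1)))
  expect_lt(persistenceCoefficient(500, 1), 1e-12)
  a <- persistenceCoefficient(1, 1:6)
  expect_true(all(diff(a) < 0))
  expect_true(all(a > 0 & a < 1))
  expect_error(persistenceCoefficient(1, 0))
})

test_that("photoreceptor output is the persistent luminance change", {
  L0 <- matrix(100, 4, 4)
  expect_equal(photoreceptorUpdate(L0, L0, list(), cfg), matrix(0, 4, 4))

  L1 <- L0
  L1[2, 3] <- 160
  P1 <- photoreceptorUpdate(L1, L0, list(), cfg)
  expect_equal(P1[2, 3], 60)
  expect_equal(sum(P1 != 0), 1L)

  # static follow-up frame: only the persistence term remains
  P2 <- photoreceptorUpdate(L1, L1, list(P1), cfg)
  expect_equal(P2[2, 3], 60 / (1 + exp(1)))
  expect_error(photoreceptorUpdate(L1, matrix(0, 3, 3), list(), cfg))
})

test_that("lateral inhibition spreads the delayed signal through the kernel", {
  imp <- matrix(0, 7, 7)
  imp[4, 4] <- 1
  I <- lateralPathways(imp, imp)$I
  expect_equal(I[4, 3], 0.25)
  expect_equal(I[4, 5], 0.25)
  expect_equal(I[3, 4], 0.25)
  expect_equal(I[5, 4], 0.25)
  expect_equal(I[3, 3], 0.125)
  expect_equal(I[5, 5], 0.125)
  expect_equal(I[4, 4], 0)
  expect_identical(lateralPathways(imp, matrix(0, 7, 7))$I, matrix(0, 7, 7))
  expect_identical(lateralPathways(imp, imp)$E, imp)
})

test_that("convolutions agree with the direct-summation oracle", {
  set.seed(21)
  for (rep in 1:5) {
    x <- matrix(rnorm(8 * 8, sd = 50), 8, 8)
    expect_equal(conv3x3(x, inhibitionKernel()),
                 convBrute(x, inhibitionKernel()), tolerance = 1e-12)
    expect_equal(conv3x3(x, groupingKernel()),
                 convBrute(x, groupingKernel()), tolerance = 1e-12)
  }
  y <- matrix(rnorm(16 * 16, sd = 50), 16, 16)
  expect_equal(conv3x3(y, inhibitionKernel()),
               convBrute(y, inhibitionKernel()), tolerance = 1e-12)
})

test_that("summation combines excitation and inhibition with the chosen sign", {
  E <- matrix(1, 3, 3)
  I <- matrix(1, 3, 3)
  expect_equal(summationLayer(E, I, cfg)[1, 1], 0.7)  # subtractive default
  plus <- mlg1Config(inhibition_sign = +1)
  expect_equal(summationLayer(E, I, plus)[1, 1], 1.3)
  expect_equal(summationLayer(E, matrix(0, 3, 3), cfg), E)
})

test_that("grouping normalises by the frame-wide peak and thresholds weak output", {
  S <- matrix(5, 10, 10)
  g <- groupingLayer(S, cfg)
  # interior average of a constant is the constant
  Ce <- conv3x3(S, groupingKernel())
  expect_true(all(abs(Ce[2:9, 2:9] - 5) < 1e-12))
  expect_equal(g$omega, 0.01 + 5 / 4)
  # interior Gtilde = 25/1.26 ~= 19.8 < T_g = 30: zeroed
  expect_true(all(g$G == 0))
  expect_gt(max(abs(g$Gtilde)), 19)

  S2 <- matrix(20, 10, 10)
  g2 <- groupingLayer(S2, cfg)
  expect_equal(g2$omega, 0.01 + 20 / 4)
  expect_gt(max(g2$G), 30)  # 400/5.01 passes the threshold

  z <- groupingLayer(matrix(0, 5, 5), cfg)
  expect_equal(z$omega, cfg@Delta_c)
  expect_true(all(z$Gtilde == 0))
})

test_that("membrane potential is the rectified masked sum", {
  G <- matrix(0, 4, 4)
  mask <- matrix(FALSE, 4, 4)
  mask[1, 1] <- mask[2, 2] <- TRUE
  expect_equal(membranePotential(G, mask), 0)
  G[1, 1] <- 3
  G[2, 2] <- -4
  G[3, 3] <- 100  # outside the mask
  expect_equal(membranePotential(G, mask), 7)
  expect_equal(membranePotential(G, which(mask)), 7)

  set.seed(3)
  Gr <- matrix(rnorm(36), 6, 6)
  mr <- matrix(runif(36) > 0.5, 6, 6)
  brute <- 0
  for (i in 1:6) for (j in 1:6) if (mr[i, j]) brute <- brute + abs(Gr[i, j])
  expect_equal(membranePotential(Gr, mr), brute, tolerance = 1e-14)
})

test_that("activation is a sigmoid with floor 0.5 and saturation below 1", {
  expect_identical(activationLevel(0, 1, 100), 0.5)
  expect_identical(activationLevel(0, 17.3, 10), 0.5)
  expect_equal(activationLevel(100, 1, 100), 1 / (1 + exp(-1)))
  expect_equal(activationLevel(1e12, 1, 100), 1)
  expect_error(activationLevel(1, 1, 0), "nCell")

  set.seed(4)
  m <- runif(200, 0, 1e4)
  c <- runif(200, 0.01, 10)
  M <- activationLevel(m, c, 500)
  expect_true(all(M >= 0.5 & M <= 1))
  # monotone in m and in c
  expect_true(all(diff(activationLevel(seq(0, 5000, by = 50), 1, 500)) > 0))
  expect_true(all(diff(activationLevel(500, seq(0.1, 5, by = 0.1), 500)) > 0))
})

test_that("discrete derivatives use first and second differences", {
  expect_equal(discreteDerivatives(5, 5, 5, 0.1), list(d1 = 0, d2 = 0))
  expect_equal(discreteDerivatives(7, 5, 3, 0.5), list(d1 = 4, d2 = 0))
  # quadratic m(t) = t^2 at unit frames: second difference is exactly 2
  expect_equal(discreteDerivatives(9, 4, 1, 1)$d2, 2)
  expect_equal(discreteDerivatives(9, NA, 1, 1), list(d1 = 0, d2 = 0))
  expect_error(discreteDerivatives(1, 1, 1, 0))
})

test_that("adaptation rises with accelerating excitation and floors at Delta_c", {
  expect_equal(sfaUpdate(1.0, 1, 0, cfg), 1.5)
  expect_equal(sfaUpdate(1.0, 1, -1, cfg), 1.3)
  expect_equal(sfaUpdate(1.0, 0, 5, cfg), 0.7)
  expect_equal(sfaUpdate(1.0, -1, 5, cfg), 0.7)
  expect_equal(sfaUpdate(0.2, -1, 0, cfg), cfg@Delta_c)  # -0.1 floored

  set.seed(5)
  c <- cfg@Delta_c
  for (k in 1:200) {
    c <- sfaUpdate(c, rnorm(1), rnorm(1), cfg)
    expect_gte(c, cfg@Delta_c)
  }
  off <- mlg1Config(sfa_enabled = FALSE, sfa_fixed_c = 1.7)
  expect_equal(sfaUpdate(5, 1, 1, off), 1.7)
})

test_that("feed-forward inhibition averages |P| over the sector with persistence", {
  P <- matrix(0, 6, 6)
  idx <- 1:12
  expect_equal(ffiUpdate(P, idx, 12L, numeric(0), cfg), 0)
  P[] <- c(rep(-3, 12), rep(99, 24))  # |P| = 3 on the mask
  expect_equal(ffiUpdate(P, idx, 12L, numeric(0), cfg), 3)
  # one-step recursion with the logistic persistence coefficient
  F1 <- 2.5
  expect_equal(ffiUpdate(P, idx, 12L, F1, cfg), 3 + F1 / (1 + exp(1)))
})

test_that("the FFI threshold relaxes toward its fixed point", {
  expect_equal(ffiThreshold(15, cfg), 15.3)
  Tv <- cfg@T_F0
  for (k in 1:60) Tv <- ffiThreshold(Tv, cfg)
  expect_equal(Tv, 15 / 0.98, tolerance = 1e-9)
  tiny <- mlg1Config(a_ffi = 1e-12)
  expect_equal(ffiThreshold(15, tiny), cfg@T_F0, tolerance = 1e-9)
  expect_error(ffiThreshold(0, cfg))
})

test_that("spikes require high activation and quiet feed-forward inhibition", {
  expect_identical(spikeDecision(0.8, 1, 15, cfg), 1L)
  expect_identical(spikeDecision(0.6, 1, 15, cfg), 0L)
  expect_identical(spikeDecision(0.9, 20, 15.3, cfg), 0L)
  expect_identical(spikeDecision(0.7, 14.9, 15, cfg), 1L)  # M == T_s counts
  expect_error(spikeDecision(NaN, 1, 15, cfg))
})

test_that("the collision alarm matches a counting oracle exhaustively", {
  expect_identical(collisionAlarm(c(1L, 1L, 0L, 1L, 1L), cfg), 1L)
  expect_identical(collisionAlarm(rep(0L, 5), cfg), 0L)
  for (buf in asplit(allBits(5), 1)) {
    expect_identical(collisionAlarm(as.integer(buf), cfg),
                     alarmOracle(buf, cfg@n_sp))
  }
  # longer buffer: N_t = 8, n_sp = 4, all 2^8 outcomes
  cfg8 <- mlg1Config(n_sp = 4L, N_t = 8L)
  for (buf in asplit(allBits(8), 1)) {
    expect_identical(collisionAlarm(as.integer(buf), cfg8),
                     alarmOracle(buf, 4L))
  }
  expect_error(collisionAlarm(c(1L, 1L), cfg))
})

test_that("a static scene leaves the whole ensemble at rest", {
  fs <- renderSequence(stimulusSpec("static", durationS = 0.5,
                                    frameDim = c(64L, 64L), noiseSigma = 0))
  run <- runMLG1s(fs)
  expect_true(all(assay(run, "m") == 0))
  expect_true(all(assay(run, "M") == 0.5))
  expect_true(all(assay(run, "spike") == 0L))
  expect_true(all(assay(run, "alarm") == 0L))
  expect_true(all(is.na(colData(run)$lsl)))
})

test_that("configuration validity guards the parameter space", {
  expect_error(mlg1Config(a_ffi = 1.2), "a_ffi")
  expect_error(mlg1Config(n_sp = 6L, N_t = 5L), "n_sp")
  expect_error(mlg1Config(W_I = -0.3), "positive")
  expect_error(mlg1Config(inhibition_sign = 0), "inhibition_sign")
  expect_identical(urbanConfig()@T_s, 0.88)
  expect_identical(urbanConfig()@n_sp, 6L)
  expect_identical(mlg1Config()@N_t, 5L)  # defaults to n_sp + 1
})
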