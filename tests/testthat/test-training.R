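# Training losses, schedules and the autodecoder optimization loop.

test_that("schedules hit their stated endpoints and closed forms", {
  sched <- trainingSchedules()
  expect_equal(curriculumLambda(0, sched), 0)
  expect_equal(curriculumLambda(1800, sched), 0.2)
  expect_equal(curriculumLambda(1900, sched), 0.2)   # constant past the ramp
  lam <- curriculumLambda(0:1800, sched)
  expect_true(all(diff(lam) >= 0))                   # monotone ramp
  # cyclic anneal: beta(0)=0, ramp to 1 at T/2, plateau, periodic
  expect_equal(annealBeta(0, 400), 0)
  expect_equal(annealBeta(199, 400), 2 * 199 / 400)
  expect_equal(annealBeta(300, 400), 1)              # second half of cycle 1
  expect_equal(annealBeta(0:399, 400), annealBeta(400:799, 400))
  expect_identical(sched$totalEpochs / sched$cycleLen, 5)  # 5 cycles fit exactly
  sc0 <- scheduleEval(sched, 0)
  expect_equal(sc0$lambda, 0)
  expect_equal(sc0$wReg, 0)
  expect_equal(sc0$lrNet, 5e-3)
  expect_equal(sc0$lrLatent, 1e-4)
  sc1000 <- scheduleEval(sched, 1000)
  expect_equal(sc1000$lrLatent, 1e-5)
  expect_equal(sc1000$lrNet, 5e-3 * (1 / 1.05)^(1000 / 16.67), tolerance = 1e-12)
  expect_equal(sc1000$lrNet, 2.67e-4, tolerance = 0.01)
  expect_error(scheduleEval(sched, -1), "negative")
})

test_that("curriculum-weighted clamped L1 matches its defining cases", {
  expect_equal(reconLoss(c(0.03, -0.05), c(0.03, -0.05), 0.2, 0.1), 0)
  # lambda = 0 is plain clamped L1
  set.seed(12)
  sp <- rnorm(200, sd = 0.2); st <- rnorm(200, sd = 0.2)
  plain <- mean(abs(pmin(pmax(sp, -0.1), 0.1) - pmin(pmax(st, -0.1), 0.1)))
  expect_equal(reconLoss(sp, st, 0, 0.1), plain)
  # hand-evaluated single point: w = 1.2, loss = 1.2 * 0.07
  expect_equal(reconLoss(-0.02, 0.05, 0.2, 0.1), 0.084)
  # weight bounds 1 - lambda <= w <= 1 + lambda
  l <- reconLoss(sp, st, 0.3, 0.1, details = TRUE)
  w <- attr(l, "weights")
  expect_true(all(w >= 0.7 - 1e-12 & w <= 1.3 + 1e-12))
  expect_error(reconLoss(1:3, 1:2), "mismatch")
  expect_error(reconLoss(1, 1, lambda = 2), "lambda")
})

test_that("latent regularization is sum z_i^2 / sigma^2", {
  expect_equal(latentReg(numeric(16)), 0)
  z <- numeric(16); z[1] <- 100
  expect_equal(latentReg(z, 100), 1)
  set.seed(4)
  z <- rnorm(64)
  expect_equal(latentReg(z, 100), sum(z^2) * 1e-4)
  expect_error(latentReg(z, 0), "positive")
})

test_that("loss gradient matches finite differences including the clamp", {
  set.seed(9)
  sp <- rnorm(50, sd = 0.15); st <- rnorm(50, sd = 0.15)
  g <- NeuralSDF:::reconLossGrad(sp, st, 0.2, 0.1)
  eps <- 1e-7
  fd <- vapply(seq_along(sp), function(i) {
    spp <- sp; spp[i] <- spp[i] + eps
    spm <- sp; spm[i] <- spm[i] - eps
    (reconLoss(spp, st, 0.2, 0.1) - reconLoss(spm, st, 0.2, 0.1)) / (2 * eps)
  }, numeric(1))
  # kinks at clamp/sign boundaries excluded
  smooth <- abs(abs(sp) - 0.1) > 1e-5 & abs(sp - st) > 1e-5
  expect_equal(g[smooth], fd[smooth], tolerance = 1e-5)
})

test_that("a tiny autodecoder run reduces the loss, stays bounded, and is reproducible", {
  suite <- suiteFixture()
  shapes <- suite$population[1:3]
  dataset <- setNames(lapply(shapes, function(s)
    sampleTrainingPoints(normalizeUnitSphere(s$pair)$pair,
                         samplingConfig(nTotal = 4000L),
                         shapeId = s$shapeId)),
    vapply(shapes, `[[`, "", "shapeId"))
  dec <- hybridDecoder(8, 3, 16, 8, 24, delta = 1, seed = 2)
  sched <- trainingSchedules(rampEpochs = 36, warmupEpochs = 2, nCycles = 5,
                             totalEpochs = 40)
  fit1 <- trainNSM(dataset, dec, sched, epochs = 40, batch = batchSpec(512L),
                   seed = 11)
  expect_lt(tail(fit1$trace$reconLoss, 1), fit1$trace$reconLoss[1])
  expect_true(all(is.finite(codebookLatents(fit1$codebook))))
  expect_lt(max(abs(codebookLatents(fit1$codebook))), 10)  # no divergence
  fit2 <- trainNSM(dataset, dec, sched, epochs = 40, batch = batchSpec(512L),
                   seed = 11)
  expect_identical(fit1$trace$loss, fit2$trace$loss)
  expect_identical(codebookLatents(fit1$codebook), codebookLatents(fit2$codebook))
  expect_error(trainNSM(dataset[1], dec, sched), "at least 2")
})
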