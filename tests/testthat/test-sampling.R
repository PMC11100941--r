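# SDF training-point sampling: composition, perturbation statistics, batches.

test_that("sample composition follows the floor-0.45 rounding rule exactly", {
  suite <- suiteFixture()
  nm <- normalizeUnitSphere(suite$constantShell)
  for (n in c(2000L, 4999L)) {
    ss <- sampleTrainingPoints(nm$pair, samplingConfig(nTotal = n), seed = 5)
    for (surf in c("bone", "cartilage")) {
      tab <- tabulate(sampleProvenance(ss[[surf]]), 3)
      expect_identical(tab[1], as.integer(floor(0.45 * n)))
      expect_identical(tab[2], as.integer(floor(0.45 * n)))
      expect_identical(sum(tab), n)
      expect_true(all(abs(sampleCoords(ss[[surf]])) <= 1))
    }
  }
})

test_that("blue-noise surface samples are uniform and deterministic", {
  sph <- icosphereMesh(3, 1)
  pts <- sampleSurfaceBlueNoise(sph, 1000, seed = 9)
  r <- sqrt(rowSums(pts^2))
  expect_lt(max(abs(r - 1)), 0.01)               # faceting tolerance
  # octant occupancy within 4 sigma of n/8 (multinomial)
  oct <- table(factor(paste(pts[, 1] > 0, pts[, 2] > 0, pts[, 3] > 0),
                      levels = apply(expand.grid(c(TRUE, FALSE), c(TRUE, FALSE),
                                                 c(TRUE, FALSE)), 1, paste,
                                     collapse = " ")))
  expmu <- 1000 / 8
  sdv <- sqrt(1000 * (1 / 8) * (7 / 8))
  expect_true(all(abs(oct - expmu) < 4 * sdv))
  pts2 <- sampleSurfaceBlueNoise(sph, 1000, seed = 9)
  expect_identical(pts, pts2)
  expect_identical(nrow(sampleSurfaceBlueNoise(sph, 0)), 0L)
})

test_that("perturbed-point signed distances match the radial-offset oracle", {
  # on a centered sphere, s of a radially perturbed point ~ its radial offset,
  # so the empirical sd of s over sigma-perturbed points approximates sigma
  sph <- icosphereMesh(3, 0.85)
  pair <- TriangleMeshPair(sph, icosphereMesh(1, 0.2))
  ss <- sampleTrainingPoints(pair, samplingConfig(nTotal = 20000L), seed = 31,
                             shapeId = "sphere")
  sOwn <- sampleDistances(ss$bone, "own")
  prov <- sampleProvenance(ss$bone)
  expect_equal(sd(sOwn[prov == 2]), 0.05, tolerance = 0.03)
  expect_equal(sd(sOwn[prov == 1]), 0.016, tolerance = 0.03)
  # sigma -> 0 limit: surface points have s ~ 0
  ss0 <- sampleTrainingPoints(pair, samplingConfig(nTotal = 500L,
                                                   sigmaSmall = 1e-9,
                                                   sigmaLarge = 1e-9),
                              seed = 3)
  expect_lt(max(abs(sampleDistances(ss0$bone, "own")[sampleProvenance(ss0$bone) < 3])),
            1e-3)
  # stored distances against both surfaces are the same points' s per mesh
  idx <- sample(20000, 50)
  expect_equal(sampleDistances(ss$bone, "cartilage")[idx],
               signedDistance(pair@cartilage, sampleCoords(ss$bone)[idx, ]),
               tolerance = 1e-9)
})

test_that("balanced batches have exact sign split for every seed", {
  suite <- suiteFixture()
  nm <- normalizeUnitSphere(suite$constantShell)
  ss <- sampleTrainingPoints(nm$pair, samplingConfig(nTotal = 6000L), seed = 7)
  spec <- batchSpec(1000L)
  for (seed in 1:5) {
    b <- drawBatch(ss$bone, spec, seed = seed)
    s <- sampleDistances(b, "own")
    expect_identical(sum(s < 0), 500L)
    expect_identical(sum(s >= 0), 500L)
  }
  b1 <- drawBatch(ss$bone, spec, seed = 3)
  b2 <- drawBatch(ss$bone, spec, seed = 3)
  expect_identical(sampleCoords(b1), sampleCoords(b2))
  b3 <- drawBatch(ss$bone, spec, seed = 4)
  expect_false(identical(sampleCoords(b1), sampleCoords(b3)))
})

test_that("degenerate one-sign sample sets are redrawn with replacement", {
  pts <- matrix(runif(300, 0, 1), ncol = 3)
  allPos <- SDFSampleSet("x", "bone", pts, runif(100, 0.1, 1),
                         runif(100, 0.1, 1), rep(3L, 100))
  expect_warning(b <- drawBatch(allPos, batchSpec(300L), seed = 2),
                 "replacement")
  expect_true(attr(b, "withReplacement"))
  expect_identical(nrow(sampleCoords(b)), 300L)
  expect_true(all(sampleDistances(b, "own") >= 0))
})

test_that("batch spec validates parity and sampling config validates fractions", {
  expect_error(batchSpec(1001L), "even")
  expect_error(samplingConfig(fracSigmaSmall = 0.6, fracSigmaLarge = 0.6))
  cfg <- samplingConfig()
  expect_identical(cfg$nTotal, 500000L)
  expect_equal(cfg$fracSigmaSmall + cfg$fracSigmaLarge + cfg$fracUniform, 1)
})
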