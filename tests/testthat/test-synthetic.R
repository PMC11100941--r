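# Synthetic population generator: determinism, label/geometry consistency.

test_that("generation is bitwise deterministic under the seed", {
  cfg <- synthConfig(seed = 7L, n = 3L)
  p1 <- generatePopulation(cfg)
  p2 <- generatePopulation(cfg)
  expect_identical(meshVertices(p1[[2]]$pair@bone), meshVertices(p2[[2]]$pair@bone))
  expect_identical(meshVertices(p1[[2]]$pair@cartilage),
                   meshVertices(p2[[2]]$pair@cartilage))
  expect_identical(p1[[3]]$labels, p2[[3]]$labels)
  p3 <- generatePopulation(synthConfig(seed = 8L, n = 3L))
  expect_false(identical(meshVertices(p1[[1]]$pair@bone),
                         meshVertices(p3[[1]]$pair@bone)))
})

test_that("generated meshes are watertight and zero-disease samples are healthy", {
  pop <- generatePopulation(synthConfig(seed = 5L, n = 5L))
  for (s in pop) {
    expect_true(isWatertight(s$pair@bone))
    expect_true(isWatertight(s$pair@cartilage))
    expect_gt(meshVolume(s$pair@cartilage), 0)
  }
  healthy <- pop[[1]]                   # severity cycles from 0
  expect_identical(healthy$labels$kl, 0L)
  expect_identical(healthy$labels$oa, 0L)
  moaksCols <- grep("^(osteophyte|thinning|hole)\\.", names(healthy$labels))
  expect_true(all(healthy$labels[moaksCols] == 0))
})

test_that("measured thickness cross-validates the generator's analytic field", {
  pop <- generatePopulation(synthConfig(seed = 11L, n = 5L))
  for (s in pop[c(1, 3, 5)]) {
    tm <- computeThickness(s$pair)
    # compare inside the cap with a rim margin; normals deviate slightly
    # from the radial construction direction
    v <- s$directions
    polar <- acos(pmin(pmax(v[, 3], -1), 1))
    core <- polar < 0.85 * synthConfig()$capAngle
    err <- abs(tm$thickness[core] - s$thicknessTruth[core])
    expect_lt(mean(err), 0.05 * 2)      # < 5% of the 2 mm base thickness
  }
})

test_that("osteophyte grade strictly orders the added bump volume", {
  cfg <- synthConfig(seed = 3L)
  mkFeatures <- function(grade) {
    f <- NeuralSDF:::.drawFeatures(cfg, 0)   # all-zero scaffold
    f$osteophyte[["lateral-central"]] <- grade
    f
  }
  vols <- vapply(0:2, function(g) {
    s <- NeuralSDF:::.buildSample(cfg, axes = c(1, 1, 1), defCoef = numeric(5),
                                  thickCoef = numeric(3),
                                  features = mkFeatures(g), shapeId = "x")
    meshVolume(s$pair@bone)
  }, numeric(1))
  expect_true(all(diff(vols) > 0))
})

test_that("thinning labels are consistent with patch area at the 10% threshold", {
  pop <- generatePopulation(synthConfig(seed = 13L, n = 10L))
  for (s in pop) {
    for (r in moaksRegions()) {
      raw <- s$labels[[paste0("thinning.", r)]]
      bin <- s$labels[[paste0("thinningBinary.", r)]]
      expect_identical(bin, as.integer(raw >= 2))
      p <- s$features$thinPatch[[r]]
      if (!is.null(p)) expect_identical(as.integer(p$frac > 0.10), bin)
    }
  }
})

test_that("hole footprints have (near) zero thickness in field and measurement", {
  pop <- generatePopulation(synthConfig(seed = 17L, n = 5L))
  s4 <- pop[[5]]                        # severity 4 carries a hole
  holeRegions <- names(Filter(Negate(is.null), s4$features$holePatch))
  expect_gte(length(holeRegions), 1)
  p <- s4$features$holePatch[[holeRegions[1]]]
  d <- s4$directions
  a <- acos(pmin(pmax(d %*% p$center, -1), 1))
  core <- a < 0.7 * p$radius & s4$inCap
  if (any(core)) {
    expect_lt(max(s4$thicknessTruth[core]), 0.01)
    tm <- computeThickness(s4$pair)
    expect_lt(max(tm$thickness[core]), 0.05)
  }
  # the hole binary label follows the raw grade
  expect_identical(s4$labels[[paste0("holeBinary.", holeRegions[1])]], 1L)
})

test_that("labels derive deterministically from burden and span all classes", {
  pop <- generatePopulation(synthConfig(seed = 19L, n = 30L))
  labs <- do.call(rbind, lapply(pop, `[[`, "labels"))
  expect_setequal(unique(labs$kl), 0:4)
  expect_true(all(labs$oa == as.integer(labs$kl >= 2)))
  # future labels only where their definitions allow
  expect_true(all(labs$futureOA[labs$kl >= 2] == 0))
})

test_that("the fixture suite covers its contract", {
  suite <- suiteFixture()
  expect_named(suite, c("sphere", "ellipsoid", "constantShell", "gradedShell",
                        "population", "heldOut"))
  grades <- unlist(lapply(suite$population, function(s)
    unlist(s$features$osteophyte)))
  expect_true(all(c(0, 1, 2) %in% pmin(grades, 2)))
  expect_length(suite$population, 10)
  # held-out shapes differ from every training shape
  for (h in suite$heldOut)
    for (s in suite$population)
      expect_false(isTRUE(all.equal(meshVertices(h$pair@bone),
                                    meshVertices(s$pair@bone))))
  # regions come labeled from the generator
  expect_true(all(suite$population[[1]]$regions5 %in% c(regionNames(), "none")))
  expect_true(all(suite$population[[1]]$regions6 %in% c(moaksRegions(), "none")))
})
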