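# Cartilage thickness: ray-cast recovery, regions, biomarkers, RMSE/SDD.

test_that("constant-thickness shells are recovered within 2%", {
  suite <- suiteFixture()
  tm <- computeThickness(suite$constantShell)
  reg <- assignRegions(pairBone(suite$constantShell), regionAtlas())
  # vertices clearly under the cap (a margin off the rim)
  v <- meshVertices(pairBone(suite$constantShell))
  polar <- acos(v[, 3] / sqrt(rowSums(v^2)))
  core <- polar < 70 * pi / 180
  expect_equal(mean(tm$thickness[core]), 2, tolerance = 0.02)
  expect_true(all(abs(tm$thickness[core] - 2) < 0.04 * 2 + 0.05))
  expect_true(all(tm$thickness[reg == "none" & polar > 80 * pi / 180] == 0))
})

test_that("shell thicknesses 1-4 mm are each recovered within 2%", {
  cap <- 75 * pi / 180
  for (t0 in c(1, 4)) {
    shell <- buildCartilageShell(function(d) rep(20, nrow(rbind(d))),
                                 function(d) rep(t0, nrow(rbind(d))),
                                 cap, nTheta = 16L, gap = 0.1)
    pair <- TriangleMeshPair(icosphereMesh(3, 20), shell)
    tm <- computeThickness(pair)
    v <- meshVertices(pairBone(pair))
    core <- acos(v[, 3] / 20) < 70 * pi / 180
    expect_equal(mean(tm$thickness[core]), t0, tolerance = 0.02)
  }
})

test_that("a linearly graded shell reproduces the construction field vertexwise", {
  suite <- suiteFixture()
  pair <- suite$gradedShell
  tm <- computeThickness(pair)
  v <- meshVertices(pairBone(pair))
  polar <- acos(v[, 3] / sqrt(rowSums(v^2)))
  cap <- 75 * pi / 180
  core <- polar < 0.9 * cap
  truth <- 1 + 2 * polar / cap
  expect_true(all(abs(tm$thickness[core] - truth[core]) / truth[core] < 0.05))
})

test_that("absent cartilage yields an all-zero map", {
  bone <- icosphereMesh(2, 20)
  far <- icosphereMesh(1, 1, center = c(100, 0, 0))
  expect_true(all(computeThickness(TriangleMeshPair(bone, far))$thickness == 0))
})

test_that("region labels partition the cap and swap sides under mirroring", {
  suite <- suiteFixture()
  bone <- pairBone(suite$constantShell)
  atlas <- regionAtlas()
  lab <- assignRegions(bone, atlas)
  expect_true(all(lab %in% c(regionNames(), "none")))
  v <- meshVertices(bone)
  polar <- acos(v[, 3] / sqrt(rowSums(v^2)))
  expect_true(all(lab[polar < atlas$capAngle - 1e-9] != "none"))
  expect_true(all(lab[polar > atlas$capAngle + 1e-9] == "none"))
  # sagittal mirror swaps medial and lateral
  mir <- TriangleMesh(v %*% diag(c(1, -1, 1)), meshFaces(bone)[, c(1, 3, 2)])
  labM <- assignRegions(mir, atlas)
  swap <- c("trochlea" = "trochlea", "none" = "none",
            "medial-central" = "lateral-central",
            "lateral-central" = "medial-central",
            "medial-posterior" = "lateral-posterior",
            "lateral-posterior" = "medial-posterior")
  offPlane <- abs(v[, 2]) > 1e-9        # the y = 0 plane maps to itself
  expect_identical(labM[offPlane], unname(swap[lab])[offPlane])
  # medial/lateral sectors are symmetric in size
  expect_equal(sum(lab == "medial-central"), sum(lab == "lateral-central"),
               tolerance = 0.1)
  expect_error(assignRegions(bone), "atlas")
})

test_that("regional means match brute-force recomputation and handle empties", {
  set.seed(33)
  n <- 500
  lab <- sample(c(regionNames()[1:4], "none"), n, replace = TRUE)
  th <- runif(n, 0, 4)
  map <- structure(list(thickness = th, region = lab), class = "ThicknessMap")
  tab <- regionalMeans(map, shapeId = "s1")
  for (r in regionNames()[1:4])
    expect_equal(tab[[r]], mean(th[lab == r]))
  expect_true(is.na(tab[["lateral-posterior"]]))   # empty region -> missing
  # permutation invariance in vertex order
  p <- sample(n)
  tab2 <- regionalMeans(structure(list(thickness = th[p], region = lab[p]),
                                  class = "ThicknessMap"))
  for (r in regionNames()[1:4]) expect_equal(tab2[[r]], tab[[r]])
  # uniform 2mm map
  uni <- structure(list(thickness = rep(2, 50),
                        region = rep(regionNames(), 10)), class = "ThicknessMap")
  tabU <- regionalMeans(uni)
  expect_true(all(unlist(tabU[regionNames()]) == 2))
})

test_that("RMSE/SDD obey their identities and the bias-variance decomposition", {
  mkTab <- function(vals) {
    df <- data.frame(shapeId = paste0("s", seq_len(nrow(vals))))
    for (k in seq_along(regionNames())) df[[regionNames()[k]]] <- vals[, k]
    df
  }
  set.seed(41)
  ref <- mkTab(matrix(runif(40, 1, 3), 8))
  err0 <- biomarkerErrors(ref, ref)
  expect_true(all(err0$rmse == 0) && all(err0$sdd == 0))
  # constant bias: RMSE = |b|, SDD = 0
  bias <- ref
  for (r in regionNames()) bias[[r]] <- bias[[r]] + 0.1
  errB <- biomarkerErrors(ref, bias)
  expect_equal(unname(errB$rmse), rep(0.1, 6))
  expect_equal(unname(errB$sdd), rep(0, 6))
  # random differences: direct formula, and SDD <= RMSE always
  rec <- ref
  for (r in regionNames()) rec[[r]] <- rec[[r]] + rnorm(8, 0.05, 0.1)
  err <- biomarkerErrors(ref, rec)
  for (r in regionNames()) {
    d <- rec[[r]] - ref[[r]]
    expect_equal(unname(err$rmse[r]), sqrt(mean(d^2)))
    expect_equal(unname(err$sdd[r]), sqrt(mean((d - mean(d))^2)))
    expect_lte(err$sdd[r], err$rmse[r] + 1e-12)
    expect_equal(err$rmse[r]^2, mean(d)^2 + err$sdd[r]^2, tolerance = 1e-12)
  }
  expect_equal(unname(err$rmse["Average"]), mean(err$rmse[regionNames()]))
  bad <- rec; bad$shapeId[1] <- "zzz"
  expect_error(biomarkerErrors(ref, bad), "shapeId")
})
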