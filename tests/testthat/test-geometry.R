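# Mesh geometry: transforms, registration, signed distances, level sets.

test_that("similarity transforms compose, invert and round-trip exactly", {
  m <- icosphereMesh(2, 1.5, center = c(0.3, -0.2, 1))
  expect_equal(meshVertices(applyTransform(m, identityTransform())),
               meshVertices(m))
  set.seed(11)
  for (rep in 1:5) {
    tr <- SimilarityTransform(scale = runif(1, 0.3, 3),
                              rotation = rotationMatrix(rnorm(3), runif(1, 0, pi)),
                              translation = rnorm(3, sd = 4))
    diam <- 3
    back <- applyTransform(applyTransform(m, tr), invertTransform(tr))
    expect_lt(max(abs(back@vertices - m@vertices)), 1e-6 * diam)
    comp <- composeTransforms(invertTransform(tr), tr)
    expect_lt(max(abs(comp@rotation - diag(3))), 1e-9)
    expect_lt(abs(comp@scale - 1), 1e-9)
  }
  expect_error(invertTransform(SimilarityTransform(scale = 1)), NA)
  expect_error(SimilarityTransform(scale = 0), "positive")
})

test_that("unit-sphere normalization centers on the bone and scales all vertices", {
  bone <- icosphereMesh(2, 40, center = c(10, 0, 0))
  cart <- icosphereMesh(1, 10, center = c(10, 0, 0))
  nm <- normalizeUnitSphere(TriangleMeshPair(bone, cart))
  vb <- meshVertices(pairBone(nm$pair))
  expect_lt(max(abs(colMeans(vb))), 1e-9)
  rAll <- sqrt(max(rowSums(rbind(vb, meshVertices(pairCartilage(nm$pair)))^2)))
  expect_equal(rAll, 1, tolerance = 1e-12)
  # transform maps the original frame into the normalized frame
  moved <- applyTransform(bone, nm$transform)
  expect_equal(meshVertices(moved), vb, tolerance = 1e-12)

  # cartilage reaching beyond the bone dictates the scale
  cartBig <- icosphereMesh(1, 60, center = c(10, 0, 0))
  nm2 <- normalizeUnitSphere(TriangleMeshPair(bone, cartBig))
  vc <- meshVertices(pairCartilage(nm2$pair))
  expect_equal(sqrt(max(rowSums(vc^2))), 1, tolerance = 1e-12)
  expect_lt(sqrt(max(rowSums(meshVertices(pairBone(nm2$pair))^2))), 1)

  # an already-normalized pair is unchanged
  nm3 <- normalizeUnitSphere(nm$pair)
  expect_equal(nm3$transform@scale, 1, tolerance = 1e-9)
  expect_equal(meshVertices(pairBone(nm3$pair)), vb, tolerance = 1e-12)
})

test_that("signed distance: sign convention and analytic cases", {
  sph <- icosphereMesh(3, 1)
  s <- signedDistance(sph, rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(s[1], -1, tolerance = 0.01)       # center of the unit sphere
  expect_equal(s[2], 1, tolerance = 0.01)
  # a mesh vertex lies on the surface
  expect_lt(abs(signedDistance(sph, meshVertices(sph)[5, , drop = FALSE])), 1e-9)
  ell <- ellipsoidMesh(c(1, 0.6, 0.4), 3)
  expect_equal(signedDistance(ell, rbind(c(2, 0, 0))), 1, tolerance = 0.01)
  # open meshes are rejected with the open-edge count
  open <- TriangleMesh(meshVertices(sph), meshFaces(sph)[-1, ])
  expect_error(signedDistance(open, rbind(c(0, 0, 0))), "3 open edges")
})

test_that("signed distance agrees with the brute-force oracle", {
  set.seed(21)
  for (mesh in list(icosphereMesh(2, 1),                     # 320 faces
                    ellipsoidMesh(c(1, 0.6, 0.4), 2))) {
    pts <- matrix(runif(100 * 3, -1.4, 1.4), ncol = 3)
    fast <- signedDistance(mesh, pts)
    slow <- vapply(seq_len(nrow(pts)), function(i)
      oracleSignedDistance(pts[i, ], mesh), numeric(1))
    expect_lt(max(abs(fast - slow)), 1e-9)
  }
})

test_that("fast winding approximation matches the exact sum's sign", {
  set.seed(22)
  suite <- suiteFixture()
  cart <- pairCartilage(suite$constantShell)     # thin shell, the hard case
  pts <- matrix(rnorm(400 * 3, sd = 12), ncol = 3)
  we <- NeuralSDF:::cpp_winding_exact(pts, meshVertices(cart), meshFaces(cart))
  wf <- NeuralSDF:::cpp_winding_fast(pts, meshVertices(cart), meshFaces(cart), 2.0)
  # the inside/outside decision agrees everywhere; the dipole approximation
  # is additionally accurate away from the surface (where the winding number
  # sits near its 0/1 plateaus)
  expect_equal(wf >= 0.5, we >= 0.5)
  far <- surfaceDistance(cart, pts) > 1
  expect_lt(max(abs(we[far] - wf[far])), 0.05)
})

test_that("assd is symmetric, zero on identity, and matches analytic/brute-force values", {
  sph <- icosphereMesh(3, 1)
  expect_equal(assd(sph, sph), 0)
  big <- icosphereMesh(3, 1.1)
  expect_equal(assd(sph, big), 0.1, tolerance = 0.01)
  expect_equal(assd(sph, big), assd(big, sph))
  # brute-force agreement on a small translated pair
  a <- icosphereMesh(1, 1)                       # 80 faces
  b <- TriangleMesh(sweep(meshVertices(a), 2, c(0.05, 0, 0), "+"), meshFaces(a))
  expect_equal(assd(a, b), oracleAssd(a, b), tolerance = 1e-12)
  expect_error(assd(TriangleMesh(matrix(numeric(0), 0, 3),
                                 matrix(integer(0), 0, 3)), sph), "empty")
})

test_that("level-set extraction reproduces analytic surfaces within grid spacing", {
  ax64 <- seq(-1, 1, length.out = 64)
  g <- as.matrix(expand.grid(ax64, ax64, ax64))
  sph <- extractSurface(SDFGrid(sqrt(rowSums(g^2)) - 0.7, 64))
  expect_true(isWatertight(sph))
  spacing <- 2 / 63
  expect_lt(assd(sph, icosphereMesh(4, 0.7)), spacing)
  # ellipsoid at resolution 48: within 1.5x spacing
  ax48 <- seq(-1, 1, length.out = 48)
  g48 <- as.matrix(expand.grid(ax48, ax48, ax48))
  sEll <- sqrt((g48[, 1] / 0.8)^2 + (g48[, 2] / 0.5)^2 + (g48[, 3] / 0.35)^2) - 1
  ell <- extractSurface(SDFGrid(sEll, 48))
  # quasi-SDF of the ellipsoid: compare against a finely meshed reference
  ref <- ellipsoidMesh(c(0.8, 0.5, 0.35), 4)
  expect_lt(assd(ell, ref), 1.5 * 2 / 47)
  expect_error(extractSurface(SDFGrid(rep(1, 16^3), 16)), "EmptySurface")
  # sign flip: same geometry, inverted orientation
  flip <- extractSurface(SDFGrid(-(sqrt(rowSums(g^2)) - 0.7), 64))
  expect_equal(assd(flip, sph), 0, tolerance = 1e-9)
  expect_equal(meshVolume(flip), -meshVolume(sph), tolerance = 1e-9)
})

test_that("scaled-ICP registration recovers a known similarity transform", {
  ell <- ellipsoidMesh(c(1, 0.7, 0.5), 3)
  expect_silent({
    idt <- registerSimilarity(ell, ell)
  })
  expect_equal(idt@scale, 1, tolerance = 1e-6)
  expect_lt(rotationAngleDeg(idt@rotation, diag(3)), 1e-3)

  tr <- SimilarityTransform(scale = 2, rotation = rotationMatrix(c(0, 0, 1), pi / 6),
                            translation = c(5, 0, 0))
  mov <- applyTransform(ell, tr)
  rec <- suppressWarnings(registerSimilarity(mov, ell))
  inv <- invertTransform(tr)
  expect_lt(abs(rec@scale - inv@scale) / inv@scale, 0.01)
  expect_lt(rotationAngleDeg(rec@rotation, inv@rotation), 1)
  expect_lt(sqrt(sum((rec@translation - inv@translation)^2)), 0.01 * 2)
  expect_error(registerSimilarity(TriangleMesh(matrix(0, 2, 3),
                                               matrix(integer(0), 0, 3)), ell),
               "degenerate")
})

test_that("mesh accessors and watertightness checks behave", {
  sph <- icosphereMesh(2, 1)
  expect_equal(meshArea(sph), 4 * pi, tolerance = 0.02)
  expect_equal(meshVolume(sph), 4 / 3 * pi, tolerance = 0.05)
  expect_true(isWatertight(sph))
  expect_equal(openEdgeCount(TriangleMesh(meshVertices(sph),
                                          meshFaces(sph)[-1, ])), 3L)
  nrm <- vertexNormals(sph)
  # outward unit normals of a centered sphere point along the radius
  expect_gt(min(rowSums(nrm * meshVertices(sph))), 0.99)
})
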