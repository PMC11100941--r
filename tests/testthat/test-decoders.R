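# Decoder architectures: parameter bookkeeping, forward contracts, gradients.

test_that("implicit-MLP parameter count reproduces the closed-form sum", {
  dec <- mlpDecoder()          # full-scale: width 512, latent 512
  closed <- 2 * (515 * 512 + 512 + 2 * (512^2 + 512) + 1027 * 512 + 512 +
                   4 * (512^2 + 512) + 512 + 1)
  expect_identical(paramCount(dec), as.integer(closed))
  expect_equal(round(paramCount(dec) / 1e6, 1), 4.7)
})

test_that("parameter counts equal the number of allocated weight scalars", {
  countScalars <- function(w) {
    if (is.list(w)) sum(vapply(w, countScalars, numeric(1))) else length(w)
  }
  decs <- list(hybridDecoder(latentLen = 16, nDeconv = 3, channels = 12,
                             planeFeatures = 9, trunkWidth = 20),
               mlpDecoder(latentLen = 12, width = 24),
               mpaDecoder(latentLen = 12, width = 24, depth = 4))
  for (dec in decs)
    expect_identical(paramCount(dec), as.integer(countScalars(decoderWeights(dec))))
})

test_that("decoder outputs are tanh-bounded, deterministic and batch-consistent", {
  set.seed(5)
  decs <- list(hybrid = hybridDecoder(16, 3, 12, 8, 20, delta = 1, seed = 3),
               mlp = mlpDecoder(12, 24, delta = 0.1, seed = 3),
               mpa = mpaDecoder(12, 24, 4, delta = 0.1, seed = 3))
  for (nm in names(decs)) {
    dec <- decs[[nm]]
    z <- rnorm(decoderLatentLen(dec), sd = 0.5)
    x <- matrix(runif(60, -1, 1), 20, 3)
    out1 <- decoderForward(dec, z, x)
    expect_true(all(abs(out1) <= decoderDelta(dec)))
    expect_identical(out1, decoderForward(dec, z, x))
    single <- decoderForward(dec, z, x[7, , drop = FALSE])
    expect_equal(as.numeric(single), as.numeric(out1[7, ]), tolerance = 1e-12)
    expect_error(decoderForward(dec, numeric(3), x), "latent length")
  }
})

test_that("zero-weight MLP decoder outputs exactly zero", {
  dec <- mlpDecoder(8, 16)
  zero <- rapply(decoderWeights(dec), function(w) w * 0, how = "replace")
  dec@weights <- zero
  out <- decoderForward(dec, rnorm(8), matrix(runif(30, -1, 1), 10, 3))
  expect_true(all(out == 0))
})

test_that("bilinear plane reads match direct indexing at nodes and averaging at cell centers", {
  R <- 8
  set.seed(6)
  plane <- matrix(rnorm(R * R * 4), R * R, 4)
  # node (i, j): coordinate u = -1 + 2*i/(R-1)
  toCoord <- function(i) -1 + 2 * i / (R - 1)
  for (rep in 1:10) {
    i <- sample(0:(R - 1), 1); j <- sample(0:(R - 1), 1)
    got <- NeuralSDF:::planeSample(plane, R, toCoord(i), toCoord(j))$feat
    expect_equal(as.numeric(got), plane[i + R * j + 1, ], tolerance = 1e-12)
  }
  # cell center = average of the 4 surrounding node features
  i <- 2; j <- 4
  got <- NeuralSDF:::planeSample(plane, R, toCoord(i + 0.5), toCoord(j + 0.5))$feat
  nodes <- plane[c(i + R * j, i + 1 + R * j, i + R * (j + 1), i + 1 + R * (j + 1)) + 1, ]
  expect_equal(as.numeric(got), colMeans(nodes), tolerance = 1e-12)
})

test_that("out-of-cube coordinates are clamped with a warning (hybrid)", {
  dec <- hybridDecoder(8, 3, 8, 4, 12, seed = 2)
  z <- rnorm(8, sd = 0.3)
  expect_warning(out <- decoderForward(dec, z, rbind(c(1.2, 0, 0))), "clamped")
  ref <- decoderForward(dec, z, rbind(c(1, 0, 0)))
  expect_equal(out, ref)
})

test_that("engineered all-ones modulator reduces the MPA to a plain sinusoidal MLP", {
  dec <- mpaDecoder(6, 10, 3, seed = 8)
  w <- decoderWeights(dec)
  for (l in seq_along(w$mod)) {
    w$mod[[l]]$W <- w$mod[[l]]$W * 0
    w$mod[[l]]$b <- rep(1, length(w$mod[[l]]$b))
  }
  dec@weights <- w
  x <- matrix(runif(15, -1, 1), 5, 3)
  out <- decoderForward(dec, rnorm(6), x)
  # manual sinusoidal MLP with the same synthesizer weights
  h <- x
  for (l in seq_along(w$synth)) {
    om <- if (l == 1) decoderConfig(dec)$omega0 else 1
    h <- sin(om * sweep(h %*% w$synth[[l]]$W, 2, w$synth[[l]]$b, "+"))
  }
  manual <- decoderDelta(dec) * tanh(sweep(h %*% w$head$W, 2, w$head$b, "+"))
  expect_equal(unname(out), unname(manual), tolerance = 1e-12)
})

test_that("analytic latent gradients match finite differences for every decoder", {
  set.seed(17)
  decs <- list(hybridDecoder(10, 3, 8, 6, 12, seed = 4),
               mlpDecoder(8, 14, seed = 4),
               mpaDecoder(8, 14, 3, seed = 4))
  for (dec in decs) {
    z <- rnorm(decoderLatentLen(dec), sd = 0.3)
    x <- matrix(runif(12, -0.8, 0.8), 4, 3)
    tgt <- matrix(rnorm(8, sd = 0.03), 4, 2)
    fw <- decoderForward(dec, z, x, grad = TRUE)
    bk <- NeuralSDF:::decoderBackward(dec, fw$cache, 2 * (fw$out - tgt))
    expect_gt(max(abs(bk$dz)), 0)   # autodecoding needs nonzero dz
    eps <- 1e-6
    fd <- vapply(seq_along(z), function(i) {
      zp <- z; zp[i] <- zp[i] + eps
      zm <- z; zm[i] <- zm[i] - eps
      (sum((decoderForward(dec, zp, x) - tgt)^2) -
         sum((decoderForward(dec, zm, x) - tgt)^2)) / (2 * eps)
    }, numeric(1))
    expect_equal(bk$dz, fd, tolerance = 1e-5)
  }
})

test_that("decoder checkpoints round-trip through save/load", {
  dec <- hybridDecoder(8, 3, 8, 4, 12, seed = 10)
  path <- tempfile(fileext = ".bin")
  saveDecoder(dec, path, extra = list(note = "test"))
  back <- loadDecoder(path)
  z <- rnorm(8, sd = 0.2)
  x <- matrix(runif(30, -1, 1), 10, 3)
  expect_equal(decoderForward(back, z, x), decoderForward(dec, z, x),
               tolerance = 1e-12)
})
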