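#' @title SDF training-point sampling
#' @name sdf-sampling
NULL

#' Sampling configuration
#'
#' Defaults follow the study conditions: 500,000 points per surface, 90%
#' surface-perturbed (split 45%/45% between Gaussian sigma 0.016 and 0.05 in
#' normalized units) and 10% uniform over the cube. The two perturbed classes
#' each take \code{floor(0.45 * nTotal)} points; the uniform class absorbs
#' the remainder so counts always sum to \code{nTotal}.
#'
#' @param nTotal points per surface.
#' @param fracSigmaSmall,fracSigmaLarge fractions perturbed with each sigma.
#' @param sigmaSmall,sigmaLarge Gaussian perturbation scales.
#' @param cubeExtent bounds of the uniform-sample cube.
#' @return named list of class "samplingConfig".
#' @export
samplingConfig <- function(nTotal = 500000L, fracSigmaSmall = 0.45,
                           fracSigmaLarge = 0.45, sigmaSmall = 0.016,
                           sigmaLarge = 0.05, cubeExtent = c(-1, 1)) {
  fracUniform <- 1 - fracSigmaSmall - fracSigmaLarge
  stopifnot(sigmaSmall > 0, sigmaLarge > 0, fracUniform >= 0,
            abs(fracSigmaSmall + fracSigmaLarge + fracUniform - 1) < 1e-12)
  structure(list(nTotal = as.integer(nTotal), fracSigmaSmall = fracSigmaSmall,
                 fracSigmaLarge = fracSigmaLarge, fracUniform = fracUniform,
                 sigmaSmall = sigmaSmall, sigmaLarge = sigmaLarge,
                 cubeExtent = cubeExtent), class = "samplingConfig")
}

#' Blue-noise (Poisson-disk) surface sampling
#'
#' Approximately uniform areal density via dart throwing with rejection
#' radius \code{r = sqrt(area / (n * pi * 0.7))}, topped up by area-weighted
#' uniform sampling if dart throwing underfills. Deterministic under
#' \code{set.seed}.
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param n number of points.
#' @param seed optional RNG seed (set before sampling when given).
#' @return n x 3 matrix of surface points.
#' @export
sampleSurfaceBlueNoise <- function(mesh, n, seed = NULL) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  if (!is.null(seed)) set.seed(seed)
  r <- sqrt(meshArea(mesh) / (n * pi * 0.7))
  cpp_sample_surface_poisson(mesh@vertices, mesh@faces, as.integer(n), r, 30L)
}

#' Sample SDF training points for a normalized mesh pair
#'
#' Per surface: \code{floor(0.45 n)} blue-noise surface points perturbed with
#' isotropic Gaussian noise sigma = 0.016, the same number with sigma = 0.05,
#' and the remainder uniform over the cube. Signed distances of every point
#' are computed and stored against both meshes so one batch can supervise
#' both decoder heads.
#'
#' @param pair a \linkS4class{TriangleMeshPair}, normalized to the unit sphere.
#' @param cfg a \code{\link{samplingConfig}}.
#' @param seed RNG seed.
#' @param shapeId identifier stored in the sample sets.
#' @return list with elements \code{bone} and \code{cartilage}, each an
#'   \linkS4class{SDFSampleSet}.
#' @export
sampleTrainingPoints <- function(pair, cfg = samplingConfig(), seed = NULL,
                                 shapeId = "shape") {
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (surf in c("bone", "cartilage")) {
    mesh <- if (surf == "bone") pair@bone else pair@cartilage
    n <- cfg$nTotal
    nSmall <- floor(cfg$fracSigmaSmall * n)
    nLarge <- floor(cfg$fracSigmaLarge * n)
    nUnif <- n - nSmall - nLarge
    surfPts <- sampleSurfaceBlueNoise(mesh, nSmall + nLarge)
    noise <- matrix(rnorm(3 * (nSmall + nLarge)), ncol = 3) *
      rep(c(cfg$sigmaSmall, cfg$sigmaLarge), c(nSmall, nLarge))
    pts <- rbind(surfPts + noise,
                 matrix(runif(3 * nUnif, cfg$cubeExtent[1], cfg$cubeExtent[2]),
                        ncol = 3))
    # sample-set invariant: coordinates stay inside the cube (signed
    # distances are computed at the clamped location)
    pts <- pmin(pmax(pts, cfg$cubeExtent[1]), cfg$cubeExtent[2])
    prov <- rep(1:3, c(nSmall, nLarge, nUnif))
    sB <- signedDistance(pair@bone, pts)
    sC <- signedDistance(pair@cartilage, pts)
    out[[surf]] <- SDFSampleSet(shapeId, surf, pts, sB, sC, prov)
  }
  out
}

#' Per-step batch specification
#'
#' @param pointsPerStep points drawn per shape/surface per optimizer step
#'   (study condition: 17,000).
#' @param insideFraction fraction with negative signed distance (0.5).
#' @export
batchSpec <- function(pointsPerStep = 17000L, insideFraction = 0.5) {
  if (insideFraction == 0.5 && pointsPerStep %% 2 != 0)
    stop("pointsPerStep must be even when insideFraction is 0.5")
  structure(list(pointsPerStep = as.integer(pointsPerStep),
                 insideFraction = insideFraction), class = "batchSpec")
}

#' Draw a sign-balanced minibatch from a sample set
#'
#' Exactly \code{pointsPerStep} points, half with s < 0 (against the set's
#' own surface) and half with s >= 0, drawn without replacement within each
#' sign class. If a class is too small it is drawn with replacement and the
#' result carries a \code{"withReplacement"} attribute.
#'
#' @param samples an \linkS4class{SDFSampleSet}.
#' @param spec a \code{\link{batchSpec}}.
#' @param seed optional RNG seed.
#' @return an \linkS4class{SDFSampleSet} subset.
#' @export
drawBatch <- function(samples, spec = batchSpec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- sampleDistances(samples, "own")
  nNeg <- round(spec$pointsPerStep * spec$insideFraction)
  nPos <- spec$pointsPerStep - nNeg
  negIdx <- which(s < 0)
  posIdx <- which(s >= 0)
  warned <- FALSE
  pick <- function(idx, k) {
    if (length(idx) >= k) idx[sample.int(length(idx), k)]
    else {
      warned <<- TRUE
      # degenerate: class underfilled (or empty) -> redraw with replacement,
      # falling back to the whole set when the class has no members at all
      pool <- if (length(idx) > 0) idx else seq_along(s)
      c(idx, pool[sample.int(length(pool), k - length(idx), replace = TRUE)])
    }
  }
  sel <- c(pick(negIdx, nNeg), pick(posIdx, nPos))
  out <- SDFSampleSet(samples@shapeId, samples@surfaceId,
                      samples@coords[sel, , drop = FALSE],
                      samples@sBone[sel], samples@sCartilage[sel],
                      samples@provenance[sel])
  attr(out, "withReplacement") <- warned
  if (warned) warning("sign class smaller than requested; drew with replacement")
  out
}
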