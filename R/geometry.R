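#' @title Mesh geometry: transforms, registration, signed distances, surfaces
#' @name geometry
NULL

#' Apply a similarity transform to points or a mesh
#'
#' @param mesh a \linkS4class{TriangleMesh} (or, for \code{transformPoints},
#'   an n x 3 coordinate matrix).
#' @param transform a \linkS4class{SimilarityTransform}.
#' @return The transformed mesh (faces unchanged) or point matrix.
#' @export
applyTransform <- function(mesh, transform) {
  if (transform@scale == 0) stop("zero scale is not invertible")
  TriangleMesh(transformPoints(mesh@vertices, transform), mesh@faces)
}

#' @rdname applyTransform
#' @param points n x 3 coordinate matrix.
#' @export
transformPoints <- function(points, transform) {
  points <- as.matrix(points)
  sweep(transform@scale * points %*% t(transform@rotation), 2,
        transform@translation, "+")
}

#' @rdname applyTransform
#' @export
applyTransformPair <- function(mesh, transform) {
  # mesh: a TriangleMeshPair; both surfaces move together
  TriangleMeshPair(applyTransform(mesh@bone, transform),
                   applyTransform(mesh@cartilage, transform),
                   frameId = paste0(mesh@frameId, "+t"))
}

#' Invert / compose similarity transforms
#'
#' \code{invertTransform(t)} satisfies
#' \code{applyTransform(applyTransform(m, t), invertTransform(t)) == m} up to
#' numerical tolerance. \code{composeTransforms(a, b)} applies \code{b} first,
#' then \code{a}.
#'
#' @param transform,a,b \linkS4class{SimilarityTransform} objects.
#' @export
invertTransform <- function(transform) {
  if (transform@scale == 0) stop("zero scale is not invertible")
  Rt <- t(transform@rotation)
  SimilarityTransform(scale = 1 / transform@scale, rotation = Rt,
                      translation = as.numeric(-(Rt %*% transform@translation) / transform@scale))
}

#' @rdname invertTransform
#' @export
composeTransforms <- function(a, b) {
  SimilarityTransform(scale = a@scale * b@scale,
                      rotation = a@rotation %*% b@rotation,
                      translation = as.numeric(a@scale * a@rotation %*% b@translation + a@translation))
}

# Umeyama closed-form similarity alignment of matched point sets (moving -> fixed)
umeyamaSimilarity <- function(moving, fixed) {
  mu_m <- colMeans(moving); mu_f <- colMeans(fixed)
  X <- sweep(moving, 2, mu_m); Y <- sweep(fixed, 2, mu_f)
  n <- nrow(moving)
  S <- crossprod(Y, X) / n            # 3x3 covariance
  sv <- svd(S)
  D <- diag(3)
  if (det(sv$u %*% t(sv$v)) < 0) D[3, 3] <- -1
  R <- sv$u %*% D %*% t(sv$v)
  varX <- sum(X^2) / n
  s <- sum(diag(D) * sv$d) / varX
  t <- mu_f - s * as.numeric(R %*% mu_m)
  SimilarityTransform(scale = s, rotation = R, translation = t)
}

#' Similarity registration (scaled iterative closest point)
#'
#' Registers \code{moving} onto \code{reference} with a rigid + isotropic
#' scale transform. Correspondences are nearest points on the reference
#' surface (point-to-triangle); each iteration solves the closed-form
#' similarity Procrustes problem (Umeyama). Initialization aligns centroids
#' and matches maximum radial extents.
#'
#' @param moving,reference \linkS4class{TriangleMesh} objects.
#' @param maxIter maximum ICP iterations (default 50).
#' @param tol relative misfit-change stopping tolerance (default 1e-7).
#' @param nSamples number of moving vertices used per iteration (subsampled
#'   deterministically when the mesh is larger).
#' @return A \linkS4class{SimilarityTransform} with attributes
#'   \code{"converged"} (logical) and \code{"misfit"} (final RMS
#'   point-to-surface distance).
#' @export
registerSimilarity <- function(moving, reference, maxIter = 50, tol = 1e-7,
                               nSamples = 1000) {
  for (m in list(moving, reference)) {
    if (nrow(m@vertices) < 4) stop("degenerate mesh: need >= 4 vertices")
    if (abs(det(stats::cov(m@vertices))) < .Machine$double.xmin &&
        qr(sweep(m@vertices, 2, colMeans(m@vertices)))$rank < 3)
      stop("degenerate mesh: vertices are coplanar")
  }
  mv <- moving@vertices
  if (nrow(mv) > nSamples) {
    sel <- round(seq(1, nrow(mv), length.out = nSamples))
    mv <- mv[sel, , drop = FALSE]
  }
  # init: centroid alignment + radial-extent scale ratio + principal-axes
  # rotation (four det=+1 sign candidates, best by point-to-surface misfit)
  cm <- colMeans(moving@vertices); cr <- colMeans(reference@vertices)
  rm_ <- max(sqrt(rowSums(sweep(moving@vertices, 2, cm)^2)))
  rr <- max(sqrt(rowSums(sweep(reference@vertices, 2, cr)^2)))
  s0 <- rr / rm_
  em <- eigen(stats::cov(moving@vertices), symmetric = TRUE)$vectors
  er <- eigen(stats::cov(reference@vertices), symmetric = TRUE)$vectors
  cand <- list(diag(3), diag(c(1, -1, -1)), diag(c(-1, 1, -1)), diag(c(-1, -1, 1)))
  trans <- NULL
  bestInit <- Inf
  probe <- mv[round(seq(1, nrow(mv), length.out = min(200, nrow(mv)))), , drop = FALSE]
  for (S in cand) {
    R0 <- er %*% S %*% t(em)
    if (det(R0) < 0) R0 <- er %*% (S %*% diag(c(1, 1, -1))) %*% t(em)
    tcand <- SimilarityTransform(scale = s0, rotation = R0,
                                 translation = cr - s0 * as.numeric(R0 %*% cm))
    mis <- mean(cpp_point_mesh_closest(transformPoints(probe, tcand),
                                       reference@vertices, reference@faces)$distance)
    # earlier candidates win ties (keeps the identity for self-registration
    # of symmetric shapes, where flipped inits are equally good)
    if (mis < bestInit - 1e-9 * rr) { bestInit <- mis; trans <- tcand }
  }
  refV <- reference@vertices
  refF <- reference@faces
  prev <- Inf
  converged <- FALSE
  misfit <- NA_real_
  for (it in seq_len(maxIter)) {
    cur <- transformPoints(mv, trans)
    cp <- cpp_point_mesh_closest(cur, refV, refF)
    misfit <- sqrt(mean(cp$distance^2))
    if (misfit <= 1e-10 * rr ||
        (is.finite(prev) && abs(prev - misfit) <= tol * max(prev, .Machine$double.eps))) {
      converged <- TRUE
      break
    }
    prev <- misfit
    trans <- umeyamaSimilarity(mv, cp$point)
  }
  if (!converged && maxIter > 0)
    warning("registration did not converge within ", maxIter,
            " iterations; returning best-so-far")
  attr(trans, "converged") <- converged
  attr(trans, "misfit") <- misfit
  trans
}

#' Normalize a mesh pair into the unit sphere
#'
#' Centers on the mean of the bone vertices and scales by the maximum radial
#' distance over all vertices of both surfaces, so the pair lies within the
#' unit sphere (maximum radius exactly 1).
#'
#' @param pair a \linkS4class{TriangleMeshPair}.
#' @return list with elements \code{pair} (normalized, frame "normalized")
#'   and \code{transform} (maps the original frame to the normalized frame).
#' @export
normalizeUnitSphere <- function(pair) {
  vb <- pair@bone@vertices; vc <- pair@cartilage@vertices
  if (nrow(vb) == 0 || nrow(vc) == 0) stop("empty mesh in pair")
  ctr <- colMeans(vb)
  rmax <- sqrt(max(rowSums(sweep(vb, 2, ctr)^2),
                   rowSums(sweep(vc, 2, ctr)^2)))
  if (rmax <= 0) stop("zero-extent mesh")
  trans <- SimilarityTransform(scale = 1 / rmax, rotation = diag(3),
                               translation = -ctr / rmax)
  out <- TriangleMeshPair(applyTransform(pair@bone, trans),
                          applyTransform(pair@cartilage, trans),
                          frameId = "normalized")
  list(pair = out, transform = trans)
}

#' Signed distance from points to a watertight mesh
#'
#' Unsigned distance is the exact nearest point-to-triangle distance
#' (uniform-grid accelerated); the sign is negative inside, decided by the
#' generalized winding number (>= 0.5 means inside). The exact solid-angle
#' sum is used for small workloads, and a Barnes-Hut dipole approximation of
#' the winding number for large ones.
#'
#' @param mesh a watertight, outward-oriented \linkS4class{TriangleMesh}.
#' @param points n x 3 coordinate matrix.
#' @param exactWinding logical or NA; NA (default) switches to the fast
#'   approximation when \code{n * nFaces} exceeds 2e7.
#' @return numeric vector of signed distances (negative inside).
#' @export
signedDistance <- function(mesh, points, exactWinding = NA) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("points must be n x 3")
  oe <- openEdgeCount(mesh)
  if (oe > 0)
    stop("mesh is not watertight: ", oe, " open edges")
  d <- cpp_point_mesh_closest(points, mesh@vertices, mesh@faces)$distance
  if (is.na(exactWinding))
    exactWinding <- (as.double(nrow(points)) * nrow(mesh@faces)) <= 2e7
  w <- if (exactWinding)
    cpp_winding_exact(points, mesh@vertices, mesh@faces)
  else
    cpp_winding_fast(points, mesh@vertices, mesh@faces, 2.0)
  ifelse(w >= 0.5, -d, d)
}

#' Unsigned point-to-surface distances
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param points n x 3 matrix.
#' @return numeric vector of unsigned nearest point-to-triangle distances.
#' @export
surfaceDistance <- function(mesh, points) {
  cpp_point_mesh_closest(as.matrix(points), mesh@vertices, mesh@faces)$distance
}

#' Average symmetric surface distance (ASSD)
#'
#' Mean of unsigned point-to-surface distances from the vertices of each
#' mesh to the other surface, both directions pooled weighted by vertex
#' counts: \code{(sum d(a -> B) + sum d(b -> A)) / (Na + Nb)}. Symmetric by
#' construction; zero for identical surfaces.
#'
#' @param a,b \linkS4class{TriangleMesh} objects (same units).
#' @return scalar ASSD in vertex units.
#' @export
assd <- function(a, b) {
  if (nrow(a@vertices) == 0 || nrow(b@vertices) == 0) stop("empty mesh")
  dab <- cpp_point_mesh_closest(a@vertices, b@vertices, b@faces)$distance
  dba <- cpp_point_mesh_closest(b@vertices, a@vertices, a@faces)$distance
  (sum(dab) + sum(dba)) / (length(dab) + length(dba))
}

#' Extract the zero (or other) level set of an SDF grid
#'
#' Triangulates the level set of the sampled field using marching tetrahedra
#' on the conforming Kuhn 6-tetrahedron cube decomposition (the same
#' linear-interpolation accuracy class as marching cubes; vertices lie within
#' one grid spacing of the true level set for smooth fields). Output faces
#' are oriented with normals pointing toward positive field values
#' (outward for an SDF with the inside-negative convention).
#'
#' @param grid an \linkS4class{SDFGrid}.
#' @param level iso level (default 0).
#' @return a welded \linkS4class{TriangleMesh}.
#' @export
extractSurface <- function(grid, level = 0) {
  v <- grid@values
  if (all(v >= level) || all(v <= level))
    stop("EmptySurface: grid contains no sign change about the level")
  res <- cpp_marching_tetra(as.numeric(v), grid@resolution,
                            grid@extent[1], grid@extent[2], level)
  TriangleMesh(res$vertices, res$faces)
}

#' Evaluate a mesh's SDF on a regular grid
#'
#' @param mesh watertight \linkS4class{TriangleMesh}.
#' @param resolution samples per axis.
#' @param extent cube bounds (default unit cube [-1, 1]^3).
#' @return an \linkS4class{SDFGrid}.
#' @export
meshToSDFGrid <- function(mesh, resolution = 64, extent = c(-1, 1)) {
  ax <- seq(extent[1], extent[2], length.out = resolution)
  pts <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  s <- signedDistance(mesh, pts)
  SDFGrid(s, resolution, extent)
}
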