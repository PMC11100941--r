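# Brute-force geometric oracles, independently implemented in plain R:
# point-to-triangle distance via plane projection + segment distances, and
# the generalized winding number as a direct solid-angle sum.

oracleTriDist <- function(p, a, b, c) {
  # distance to the plane-clipped triangle: project, test barycentrics,
  # otherwise min over the three edge segments
  n <- pracmaCross(b - a, c - a)
  nn <- sqrt(sum(n^2))
  segDist <- function(p, u, v) {
    d <- v - u
    t <- sum((p - u) * d) / sum(d * d)
    t <- min(max(t, 0), 1)
    sqrt(sum((p - (u + t * d))^2))
  }
  if (nn > 0) {
    n <- n / nn
    proj <- p - sum((p - a) * n) * n
    # barycentric coordinates of proj
    v0 <- b - a; v1 <- c - a; v2 <- proj - a
    d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
    d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
    den <- d00 * d11 - d01 * d01
    v <- (d11 * d20 - d01 * d21) / den
    w <- (d00 * d21 - d01 * d20) / den
    if (v >= 0 && w >= 0 && v + w <= 1)
      return(abs(sum((p - a) * n)))
  }
  min(segDist(p, a, b), segDist(p, b, c), segDist(p, c, a))
}

pracmaCross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

oracleMeshDist <- function(p, mesh) {
  v <- meshVertices(mesh); f <- meshFaces(mesh)
  min(vapply(seq_len(nrow(f)), function(t)
    oracleTriDist(p, v[f[t, 1], ], v[f[t, 2], ], v[f[t, 3], ]), numeric(1)))
}

oracleWinding <- function(p, mesh) {
  v <- meshVertices(mesh); f <- meshFaces(mesh)
  s <- 0
  for (t in seq_len(nrow(f))) {
    a <- v[f[t, 1], ] - p; b <- v[f[t, 2], ] - p; cc <- v[f[t, 3], ] - p
    la <- sqrt(sum(a^2)); lb <- sqrt(sum(b^2)); lc <- sqrt(sum(cc^2))
    det <- sum(a * pracmaCross(b, cc))
    den <- la * lb * lc + sum(a * b) * lc + sum(b * cc) * la + sum(cc * a) * lb
    s <- s + 2 * atan2(det, den)
  }
  s / (4 * pi)
}

oracleSignedDistance <- function(p, mesh) {
  d <- oracleMeshDist(p, mesh)
  if (oracleWinding(p, mesh) >= 0.5) -d else d
}

oracleAssd <- function(a, b) {
  da <- vapply(seq_len(nVertices(a)), function(i)
    oracleMeshDist(meshVertices(a)[i, ], b), numeric(1))
  db <- vapply(seq_len(nVertices(b)), function(i)
    oracleMeshDist(meshVertices(b)[i, ], a), numeric(1))
  (sum(da) + sum(db)) / (length(da) + length(db))
}

rotationMatrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

rotationAngleDeg <- function(R1, R2) {
  tr <- sum(diag(t(R1) %*% R2))
  acos(min(1, max(-1, (tr - 1) / 2))) * 180 / pi
}
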