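# Internal neural-network primitives: initializers, dense layers, 2D
# transpose convolutions (kernel 4, stride 2, pad 1) expressed as 16 gather/
# scatter matrix products, bilinear plane sampling, and AdamW. Everything is
# plain matrix algebra so gradients are exact and finite-difference testable.

.deconvMapCache <- new.env(parent = emptyenv())

# index maps for transpose conv k4 s2 p1 at one kernel offset (kx, ky in 0:3):
# output (0-based) o = 2*i + k - 1. Linear ids are x-fastest.
deconvMap <- function(H, kx, ky) {
  key <- paste(H, kx, ky)
  m <- .deconvMapCache[[key]]
  if (!is.null(m)) return(m)
  ixs <- 0:(H - 1)
  vx <- ixs[2 * ixs + kx - 1 >= 0 & 2 * ixs + kx - 1 <= 2 * H - 1]
  vy <- ixs[2 * ixs + ky - 1 >= 0 & 2 * ixs + ky - 1 <= 2 * H - 1]
  if (length(vx) == 0 || length(vy) == 0) {
    m <- list(inIdx = integer(0), outIdx = integer(0))
  } else {
    gi <- rep(vx, times = length(vy))
    gj <- rep(vy, each = length(vx))
    m <- list(inIdx = gi + H * gj + 1L,
              outIdx = (2L * gi + kx - 1L) + 2L * H * (2L * gj + ky - 1L) + 1L)
  }
  .deconvMapCache[[key]] <- m
  m
}

# weights: list(K = list of 16 (Cin x Cout) matrices indexed kx*4+ky+1, b)
deconvForward <- function(inMat, H, w) {
  Cout <- length(w$b)
  out <- matrix(0, 4 * H * H, Cout)
  for (kx in 0:3) for (ky in 0:3) {
    m <- deconvMap(H, kx, ky)
    if (length(m$inIdx) == 0) next
    out[m$outIdx, ] <- out[m$outIdx, ] +
      inMat[m$inIdx, , drop = FALSE] %*% w$K[[kx * 4 + ky + 1]]
  }
  sweep(out, 2, w$b, "+")
}

deconvBackward <- function(dOut, inMat, H, w) {
  Cin <- ncol(inMat)
  dIn <- matrix(0, H * H, Cin)
  dK <- vector("list", 16)
  for (kx in 0:3) for (ky in 0:3) {
    id <- kx * 4 + ky + 1
    m <- deconvMap(H, kx, ky)
    if (length(m$inIdx) == 0) {
      dK[[id]] <- matrix(0, Cin, ncol(dOut))
      next
    }
    go <- dOut[m$outIdx, , drop = FALSE]
    dIn[m$inIdx, ] <- dIn[m$inIdx, ] + go %*% t(w$K[[id]])
    dK[[id]] <- crossprod(inMat[m$inIdx, , drop = FALSE], go)
  }
  list(dIn = dIn, grad = list(K = dK, b = colSums(dOut)))
}

# bilinear read from a plane stored as (R^2 x F), corner-aligned over [-1,1]^2
# (node 0 at -1, node R-1 at +1), x-fastest linear ids. Returns features and
# the gather cache needed for the backward scatter.
planeSample <- function(plane, R, u, v) {
  g <- function(t) pmin(pmax((t + 1) / 2 * (R - 1), 0), R - 1)
  u <- g(u); v <- g(v)
  i0 <- pmin(floor(u), R - 2); j0 <- pmin(floor(v), R - 2)
  fu <- u - i0; fv <- v - j0
  n00 <- i0 + R * j0 + 1
  n10 <- n00 + 1
  n01 <- n00 + R
  n11 <- n01 + 1
  w00 <- (1 - fu) * (1 - fv); w10 <- fu * (1 - fv)
  w01 <- (1 - fu) * fv;       w11 <- fu * fv
  feat <- plane[n00, , drop = FALSE] * w00 + plane[n10, , drop = FALSE] * w10 +
          plane[n01, , drop = FALSE] * w01 + plane[n11, , drop = FALSE] * w11
  list(feat = feat,
       cache = list(n = cbind(n00, n10, n01, n11), w = cbind(w00, w10, w01, w11)))
}

planeScatter <- function(dFeat, cache, R) {
  dP <- matrix(0, R * R, ncol(dFeat))
  for (k in 1:4) {
    contrib <- dFeat * cache$w[, k]
    acc <- rowsum(contrib, cache$n[, k])
    rows <- as.integer(rownames(acc))
    dP[rows, ] <- dP[rows, ] + acc
  }
  dP
}

relu <- function(x) { x[x < 0] <- 0; x }

# initializers (R's RNG; call set.seed upstream)
initGlorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}
initHe <- function(nin, nout) matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
initSiren <- function(nin, nout, omega, first = FALSE) {
  lim <- if (first) 1 / nin else sqrt(6 / nin) / omega
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

# ---- AdamW on nested weight lists -----------------------------------------

treeZero <- function(w) {
  if (is.list(w)) lapply(w, treeZero) else array(0, dim = dim(w) %||% length(w))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adamInit <- function(w) list(m = treeZero(w), v = treeZero(w), t = 0L)

# one AdamW step over a nested list of arrays; weight decay is decoupled.
adamStep <- function(w, g, state, lr, weightDecay = 0, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  step <- function(w, g, m, v) {
    if (is.list(w)) {
      out <- list(w = w, m = m, v = v)
      for (nm in seq_along(w)) {
        r <- step(w[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$w[[nm]] <- r$w; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      out
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g * g
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      w <- w - lr * (mhat / (sqrt(vhat) + eps) + weightDecay * w)
      list(w = w, m = m, v = v)
    }
  }
  r <- step(w, g, state$m, state$v)
  list(w = r$w, state = list(m = r$m, v = r$v, t = t))
}

treeAdd <- function(a, b) {
  if (is.list(a)) mapply(treeAdd, a, b, SIMPLIFY = FALSE) else a + b
}
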