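#' @title Shape decoder architectures
#' @name decoders
#' @description Three autodecoder families mapping (latent z, coordinate x)
#'   to two signed distances, one per tissue: the triplanar hybrid
#'   explicit-implicit decoder, a deep implicit MLP, and a modulated
#'   periodic-activation (MPA) decoder. All outputs pass a tanh scaled by the
#'   clamp bound delta so the decoder range matches the clamped target range.
NULL

#' Construct a hybrid explicit-implicit (triplanar) decoder
#'
#' A dense layer expands the global latent to a 2 x 2 x baseChannels tensor;
#' \code{nDeconv} stride-2 transpose convolutions (kernel 4, pad 1, ReLU
#' between layers) grow it to a \code{planeRes x planeRes x 3*planeFeatures}
#' map split into three orthogonal feature planes (xy, xz, yz). A query point
#' is projected onto each plane, features are read bilinearly and summed into
#' a local latent, which is concatenated with the coordinate and decoded by a
#' 3-layer ReLU MLP with a 2-channel tanh output. Full-scale defaults:
#' latent 512, 5 deconvs to 64 x 64 x 384, trunk width 512, delta 1.
#'
#' @param latentLen global latent length.
#' @param nDeconv number of transpose-convolution layers; plane resolution is
#'   \code{2 * 2^nDeconv}.
#' @param channels channel width of the CNN (all layers; the final layer has
#'   \code{3 * planeFeatures} outputs).
#' @param planeFeatures features per orthogonal plane.
#' @param trunkWidth width of the implicit MLP trunk.
#' @param delta clamp bound scaling the tanh output.
#' @param seed RNG seed for weight initialization.
#' @return a \linkS4class{HybridDecoder}.
#' @export
hybridDecoder <- function(latentLen = 512L, nDeconv = 5L, channels = 512L,
                          planeFeatures = 128L, trunkWidth = 512L, delta = 1,
                          seed = 1L) {
  set.seed(seed)
  C0 <- as.integer(channels)
  cfg <- list(latentLen = as.integer(latentLen), nDeconv = as.integer(nDeconv),
              channels = C0, planeFeatures = as.integer(planeFeatures),
              trunkWidth = as.integer(trunkWidth),
              planeRes = as.integer(2 * 2^nDeconv))
  chans <- c(C0, rep(C0, nDeconv - 1), 3L * cfg$planeFeatures)
  w <- list(dense = list(W = initGlorot(latentLen, 4L * C0), b = numeric(4L * C0)),
            deconv = lapply(seq_len(nDeconv), function(l) {
              cin <- chans[l]; cout <- chans[l + 1]
              list(K = lapply(1:16, function(k) initHe(cin, cout) / 4),
                   b = numeric(cout))
            }),
            trunk = list(
              list(W = initHe(cfg$planeFeatures + 3L, trunkWidth), b = numeric(trunkWidth)),
              list(W = initHe(trunkWidth, trunkWidth), b = numeric(trunkWidth)),
              list(W = initHe(trunkWidth, trunkWidth), b = numeric(trunkWidth))),
            head = list(W = initGlorot(trunkWidth, 2L), b = numeric(2L)))
  new("HybridDecoder", config = cfg, weights = w,
      latentLen = as.integer(latentLen), delta = delta)
}

#' Construct the implicit MLP decoder
#'
#' Two independent 8-layer ReLU trunks of equal width (one per tissue); the
#' input is \code{[x, z]} and is concatenated again into layer 4's input
#' (skip connection). Each trunk ends in a scalar tanh output scaled by
#' delta. Full-scale defaults: width 512, latent 512, delta 0.1.
#'
#' @inheritParams hybridDecoder
#' @param width trunk width.
#' @return an \linkS4class{MLPDecoder}.
#' @export
mlpDecoder <- function(latentLen = 512L, width = 512L, delta = 0.1, seed = 1L) {
  set.seed(seed)
  nin <- latentLen + 3L
  mkTrunk <- function() {
    layers <- vector("list", 8)
    layers[[1]] <- list(W = initHe(nin, width), b = numeric(width))
    for (l in 2:8) {
      fanin <- if (l == 4) width + nin else width
      layers[[l]] <- list(W = initHe(fanin, width), b = numeric(width))
    }
    list(layers = layers, head = list(W = initGlorot(width, 1L), b = numeric(1)))
  }
  cfg <- list(latentLen = as.integer(latentLen), width = as.integer(width),
              depth = 8L, skipLayer = 4L)
  new("MLPDecoder", config = cfg,
      weights = list(bone = mkTrunk(), cartilage = mkTrunk()),
      latentLen = as.integer(latentLen), delta = delta)
}

#' Construct the modulated periodic-activation (MPA) decoder
#'
#' A "synthesizer" MLP with sinusoidal activations runs on the coordinate x;
#' a "modulator" ReLU MLP runs on the latent z with z concatenated into every
#' layer's input. Layer i's output is the elementwise product of the
#' synthesizer activation and the modulator activation; the final modulated
#' state feeds a 2-channel tanh head. Frequency scale omega0 = 30 on the
#' first synthesizer layer, 1 thereafter. Full-scale defaults: depth 8,
#' width 512, delta 0.1.
#'
#' @inheritParams mlpDecoder
#' @param depth number of synthesizer/modulator layers.
#' @param omega0 first-layer sinusoidal frequency scale.
#' @return an \linkS4class{MPADecoder}.
#' @export
mpaDecoder <- function(latentLen = 512L, width = 512L, depth = 8L, delta = 0.1,
                       omega0 = 30, seed = 1L) {
  set.seed(seed)
  synth <- vector("list", depth)
  synth[[1]] <- list(W = initSiren(3L, width, omega0, first = TRUE), b = numeric(width))
  for (l in 2:depth)
    synth[[l]] <- list(W = initSiren(width, width, 1), b = numeric(width))
  modl <- vector("list", depth)
  modl[[1]] <- list(W = initHe(latentLen, width), b = numeric(width))
  for (l in 2:depth)
    modl[[l]] <- list(W = initHe(width + latentLen, width), b = numeric(width))
  cfg <- list(latentLen = as.integer(latentLen), width = as.integer(width),
              depth = as.integer(depth), omega0 = omega0)
  new("MPADecoder", config = cfg,
      weights = list(synth = synth, mod = modl,
                     head = list(W = initGlorot(width, 2L), b = numeric(2))),
      latentLen = as.integer(latentLen), delta = delta)
}

# ---- paramCount ------------------------------------------------------------

#' Count trainable parameters of a decoder
#'
#' Exact closed-form count of weight and bias scalars (latent codebooks are
#' excluded). The implicit-MLP architecture at full scale has 4,733,954
#' parameters (4.7 M at one decimal).
#'
#' @param decoder a \linkS4class{ShapeDecoder}.
#' @return integer parameter count.
#' @export
setGeneric("paramCount", function(decoder) standardGeneric("paramCount"))

#' @rdname paramCount
#' @export
setMethod("paramCount", "HybridDecoder", function(decoder) {
  cfg <- decoder@config
  L <- cfg$latentLen; C <- cfg$channels; Fp <- cfg$planeFeatures
  Tw <- cfg$trunkWidth
  chans <- c(C, rep(C, cfg$nDeconv - 1), 3 * Fp)
  deconvs <- sum(vapply(seq_len(cfg$nDeconv), function(l)
    16 * chans[l] * chans[l + 1] + chans[l + 1], numeric(1)))
  dense <- L * 4 * C + 4 * C
  trunk <- (Fp + 3) * Tw + Tw + 2 * (Tw^2 + Tw)
  head <- Tw * 2 + 2
  as.integer(dense + deconvs + trunk + head)
})

#' @rdname paramCount
#' @export
setMethod("paramCount", "MLPDecoder", function(decoder) {
  cfg <- decoder@config
  L <- cfg$latentLen; W <- cfg$width
  nin <- L + 3
  one <- nin * W + W + 2 * (W^2 + W) + (W + nin) * W + W + 4 * (W^2 + W) + W + 1
  as.integer(2 * one)
})

#' @rdname paramCount
#' @export
setMethod("paramCount", "MPADecoder", function(decoder) {
  cfg <- decoder@config
  L <- cfg$latentLen; W <- cfg$width; D <- cfg$depth
  synth <- 3 * W + W + (D - 1) * (W^2 + W)
  modl <- L * W + W + (D - 1) * ((W + L) * W + W)
  as.integer(synth + modl + W * 2 + 2)
})

# ---- forward passes --------------------------------------------------------

#' Decode signed distances for a batch of coordinates
#'
#' Deterministic pure function of (weights, z, x). Coordinates outside
#' \code{[-1, 1]^3} are clamped to the boundary with a warning for the
#' hybrid decoder (reconstruction grids may touch corners).
#'
#' @param decoder a \linkS4class{ShapeDecoder}.
#' @param z latent vector of length \code{decoderLatentLen(decoder)}.
#' @param x n x 3 coordinate matrix.
#' @param grad if TRUE also return the cache needed by the backward pass.
#' @return n x 2 matrix (columns bone, cartilage), or \code{list(out, cache)}
#'   when \code{grad = TRUE}.
#' @export
setGeneric("decoderForward", function(decoder, z, x, grad = FALSE)
  standardGeneric("decoderForward"))

# CNN part of the hybrid decoder: z -> three feature planes
hybridPlanes <- function(decoder, z, grad = FALSE) {
  cfg <- decoder@config; w <- decoder@weights
  d0 <- as.numeric(z %*% w$dense$W) + w$dense$b
  H <- 2L
  cur <- matrix(d0, nrow = 4, ncol = cfg$channels)
  cache <- list(inputs = list(), pre = list())
  for (l in seq_len(cfg$nDeconv)) {
    if (grad) cache$inputs[[l]] <- cur
    pre <- deconvForward(cur, H, w$deconv[[l]])
    H <- 2L * H
    if (l < cfg$nDeconv) {
      if (grad) cache$pre[[l]] <- pre
      cur <- relu(pre)
    } else cur <- pre
  }
  Fp <- cfg$planeFeatures
  planes <- lapply(1:3, function(p) cur[, ((p - 1) * Fp + 1):(p * Fp), drop = FALSE])
  if (grad) list(planes = planes, cache = cache) else list(planes = planes)
}

#' @rdname decoderForward
#' @export
setMethod("decoderForward", "HybridDecoder", function(decoder, z, x, grad = FALSE) {
  cfg <- decoder@config; w <- decoder@weights
  x <- as.matrix(x)
  if (length(z) != cfg$latentLen) stop("latent length mismatch")
  if (any(abs(x) > 1)) {
    warning("coordinates outside [-1,1]^3 clamped to boundary")
    x <- pmin(pmax(x, -1), 1)
  }
  cp <- hybridPlanes(decoder, z, grad)
  R <- cfg$planeRes
  axes <- list(c(1, 2), c(1, 3), c(2, 3))   # xy, xz, yz
  reads <- lapply(1:3, function(p)
    planeSample(cp$planes[[p]], R, x[, axes[[p]][1]], x[, axes[[p]][2]]))
  localZ <- reads[[1]]$feat + reads[[2]]$feat + reads[[3]]$feat
  X1 <- cbind(localZ, x)
  pre1 <- sweep(X1 %*% w$trunk[[1]]$W, 2, w$trunk[[1]]$b, "+"); a1 <- relu(pre1)
  pre2 <- sweep(a1 %*% w$trunk[[2]]$W, 2, w$trunk[[2]]$b, "+"); a2 <- relu(pre2)
  pre3 <- sweep(a2 %*% w$trunk[[3]]$W, 2, w$trunk[[3]]$b, "+"); a3 <- relu(pre3)
  preH <- sweep(a3 %*% w$head$W, 2, w$head$b, "+")
  th <- tanh(preH)
  out <- decoder@delta * th
  colnames(out) <- c("bone", "cartilage")
  if (!grad) return(out)
  list(out = out,
       cache = list(cnn = cp$cache, reads = reads, X1 = X1,
                    pre = list(pre1, pre2, pre3), act = list(a1, a2, a3),
                    th = th, x = x, z = as.numeric(z)))
})

# backward for the hybrid decoder: returns weight grads + dz
hybridBackward <- function(decoder, cache, dOut) {
  cfg <- decoder@config; w <- decoder@weights
  dPreH <- dOut * decoder@delta * (1 - cache$th^2)
  gHead <- list(W = crossprod(cache$act[[3]], dPreH), b = colSums(dPreH))
  dA3 <- dPreH %*% t(w$head$W)
  dPre3 <- dA3 * (cache$pre[[3]] > 0)
  gT3 <- list(W = crossprod(cache$act[[2]], dPre3), b = colSums(dPre3))
  dA2 <- dPre3 %*% t(w$trunk[[3]]$W)
  dPre2 <- dA2 * (cache$pre[[2]] > 0)
  gT2 <- list(W = crossprod(cache$act[[1]], dPre2), b = colSums(dPre2))
  dA1 <- dPre2 %*% t(w$trunk[[2]]$W)
  dPre1 <- dA1 * (cache$pre[[1]] > 0)
  gT1 <- list(W = crossprod(cache$X1, dPre1), b = colSums(dPre1))
  dX1 <- dPre1 %*% t(w$trunk[[1]]$W)
  Fp <- cfg$planeFeatures
  dLocalZ <- dX1[, seq_len(Fp), drop = FALSE]
  R <- cfg$planeRes
  dPlanes <- lapply(1:3, function(p) planeScatter(dLocalZ, cache$reads[[p]]$cache, R))
  # back through the CNN
  dCur <- cbind(dPlanes[[1]], dPlanes[[2]], dPlanes[[3]])
  gDeconv <- vector("list", cfg$nDeconv)
  H <- cfg$planeRes / 2L
  for (l in rev(seq_len(cfg$nDeconv))) {
    if (l < cfg$nDeconv) dCur <- dCur * (cache$cnn$pre[[l]] > 0)
    bk <- deconvBackward(dCur, cache$cnn$inputs[[l]], H, w$deconv[[l]])
    gDeconv[[l]] <- bk$grad
    dCur <- bk$dIn
    H <- H / 2L
  }
  dDense <- as.numeric(dCur)   # 4 x C0 flattened, matches dense output layout
  gDense <- list(W = outer(cache$z, dDense), b = dDense)
  list(grads = list(dense = gDense, deconv = gDeconv,
                    trunk = list(gT1, gT2, gT3), head = gHead),
       dz = as.numeric(w$dense$W %*% dDense))
}

mlpTrunkForward <- function(trunk, X0, skipLayer, grad) {
  pres <- list(); acts <- list()
  h <- X0
  for (l in seq_along(trunk$layers)) {
    inp <- if (l == skipLayer) cbind(h, X0) else h
    if (grad) acts[[l]] <- inp
    pre <- sweep(inp %*% trunk$layers[[l]]$W, 2, trunk$layers[[l]]$b, "+")
    if (grad) pres[[l]] <- pre
    h <- relu(pre)
  }
  preH <- sweep(h %*% trunk$head$W, 2, trunk$head$b, "+")
  list(pre = preH, pres = pres, acts = acts, hLast = h)
}

#' @rdname decoderForward
#' @export
setMethod("decoderForward", "MLPDecoder", function(decoder, z, x, grad = FALSE) {
  cfg <- decoder@config
  if (length(z) != cfg$latentLen) stop("latent length mismatch")
  x <- as.matrix(x)
  X0 <- cbind(x, matrix(z, nrow(x), length(z), byrow = TRUE))
  fb <- mlpTrunkForward(decoder@weights$bone, X0, cfg$skipLayer, grad)
  fc <- mlpTrunkForward(decoder@weights$cartilage, X0, cfg$skipLayer, grad)
  thB <- tanh(fb$pre); thC <- tanh(fc$pre)
  out <- decoder@delta * cbind(thB, thC)
  colnames(out) <- c("bone", "cartilage")
  if (!grad) return(out)
  list(out = out, cache = list(bone = fb, cartilage = fc, X0 = X0,
                               th = cbind(thB, thC)))
})

mlpTrunkBackward <- function(trunk, cache, X0, skipLayer, dPreH) {
  gHead <- list(W = crossprod(cache$hLast, dPreH), b = colSums(dPreH))
  dH <- dPreH %*% t(trunk$head$W)
  nL <- length(trunk$layers)
  gL <- vector("list", nL)
  dX0 <- matrix(0, nrow(X0), ncol(X0))
  for (l in rev(seq_len(nL))) {
    dPre <- dH * (cache$pres[[l]] > 0)
    gL[[l]] <- list(W = crossprod(cache$acts[[l]], dPre), b = colSums(dPre))
    dInp <- dPre %*% t(trunk$layers[[l]]$W)
    if (l == skipLayer) {
      wmain <- ncol(dInp) - ncol(X0)
      dH <- dInp[, seq_len(wmain), drop = FALSE]
      dX0 <- dX0 + dInp[, wmain + seq_len(ncol(X0)), drop = FALSE]
    } else dH <- dInp
  }
  dX0 <- dX0 + dH   # layer-1 input is X0 itself
  list(grads = list(layers = gL, head = gHead), dX0 = dX0)
}

mlpBackward <- function(decoder, cache, dOut) {
  cfg <- decoder@config
  dPreB <- dOut[, 1, drop = FALSE] * decoder@delta * (1 - cache$th[, 1]^2)
  dPreC <- dOut[, 2, drop = FALSE] * decoder@delta * (1 - cache$th[, 2]^2)
  bb <- mlpTrunkBackward(decoder@weights$bone, cache$bone, cache$X0,
                         cfg$skipLayer, dPreB)
  bc <- mlpTrunkBackward(decoder@weights$cartilage, cache$cartilage, cache$X0,
                         cfg$skipLayer, dPreC)
  dX0 <- bb$dX0 + bc$dX0
  dz <- colSums(dX0[, 3 + seq_len(cfg$latentLen), drop = FALSE])
  list(grads = list(bone = bb$grads, cartilage = bc$grads), dz = dz)
}

#' @rdname decoderForward
#' @export
setMethod("decoderForward", "MPADecoder", function(decoder, z, x, grad = FALSE) {
  cfg <- decoder@config; w <- decoder@weights
  if (length(z) != cfg$latentLen) stop("latent length mismatch")
  x <- as.matrix(x)
  D <- cfg$depth
  # modulator depends on z only: row vectors broadcast across the batch
  mPre <- list(); mAct <- list()
  mh <- NULL
  for (l in seq_len(D)) {
    inp <- if (l == 1) matrix(z, 1) else cbind(mh, matrix(z, 1))
    pre <- inp %*% w$mod[[l]]$W + w$mod[[l]]$b
    mPre[[l]] <- pre
    mh <- relu(pre)
    mAct[[l]] <- mh
  }
  sPre <- list(); sSin <- list(); hList <- list()
  h <- x
  for (l in seq_len(D)) {
    om <- if (l == 1) cfg$omega0 else 1
    pre <- sweep(h %*% w$synth[[l]]$W, 2, w$synth[[l]]$b, "+")
    s <- sin(om * pre)
    if (grad) { sPre[[l]] <- pre; sSin[[l]] <- s }
    h <- sweep(s, 2, as.numeric(mAct[[l]]), "*")
    if (grad) hList[[l]] <- h
  }
  preH <- sweep(h %*% w$head$W, 2, w$head$b, "+")
  th <- tanh(preH)
  out <- decoder@delta * th
  colnames(out) <- c("bone", "cartilage")
  if (!grad) return(out)
  list(out = out, cache = list(mPre = mPre, mAct = mAct, sPre = sPre,
                               sSin = sSin, h = hList, x = x, z = z, th = th))
})

mpaBackward <- function(decoder, cache, dOut) {
  cfg <- decoder@config; w <- decoder@weights
  D <- cfg$depth
  dPreH <- dOut * decoder@delta * (1 - cache$th^2)
  gHead <- list(W = crossprod(cache$h[[D]], dPreH), b = colSums(dPreH))
  dH <- dPreH %*% t(w$head$W)
  gSynth <- vector("list", D)
  dMAct <- vector("list", D)   # accumulated grad on each modulator activation
  for (l in rev(seq_len(D))) {
    om <- if (l == 1) cfg$omega0 else 1
    m <- as.numeric(cache$mAct[[l]])
    dS <- sweep(dH, 2, m, "*")
    dMAct[[l]] <- colSums(dH * cache$sSin[[l]])
    dPre <- dS * om * cos(om * cache$sPre[[l]])
    hin <- if (l == 1) cache$x else cache$h[[l - 1]]
    gSynth[[l]] <- list(W = crossprod(hin, dPre), b = colSums(dPre))
    if (l > 1) dH <- dPre %*% t(w$synth[[l]]$W)
  }
  # modulator chain backward (row-vector algebra)
  gMod <- vector("list", D)
  dz <- numeric(cfg$latentLen)
  dMh <- NULL
  for (l in rev(seq_len(D))) {
    dAct <- matrix(dMAct[[l]], 1)
    if (!is.null(dMh)) dAct <- dAct + dMh
    dPre <- dAct * (cache$mPre[[l]] > 0)
    inp <- if (l == 1) matrix(cache$z, 1) else cbind(cache$mAct[[l - 1]], matrix(cache$z, 1))
    gMod[[l]] <- list(W = crossprod(inp, dPre), b = as.numeric(dPre))
    dInp <- dPre %*% t(w$mod[[l]]$W)
    if (l == 1) {
      dz <- dz + as.numeric(dInp)
    } else {
      wmain <- cfg$width
      dMh <- dInp[, seq_len(wmain), drop = FALSE]
      dz <- dz + as.numeric(dInp[, wmain + seq_len(cfg$latentLen)])
    }
  }
  list(grads = list(synth = gSynth, mod = gMod, head = gHead), dz = dz)
}

# dispatch helper used by training/fitting code
decoderBackward <- function(decoder, cache, dOut) {
  if (is(decoder, "HybridDecoder")) hybridBackward(decoder, cache, dOut)
  else if (is(decoder, "MLPDecoder")) mlpBackward(decoder, cache, dOut)
  else mpaBackward(decoder, cache, dOut)
}
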