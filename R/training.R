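#' @title Autodecoder training: losses, schedules, optimization
#' @name training
NULL

#' Training schedules
#'
#' Bundles the four schedules used during autodecoder training, at the study
#' conditions by default:
#' \itemize{
#'   \item curriculum weight lambda: smooth exponential ramp from 0 to
#'     \code{lambdaMax = 0.2} over the first 1800 epochs
#'     (\code{lambda(e) = lambdaMax * (exp(k e/ramp) - 1)/(exp(k) - 1)},
#'     k = 5), constant afterwards;
#'   \item latent-regularization weight: linear warmup over the first 100
#'     epochs multiplied by a cyclic anneal beta with 5 cycles over the
#'     2000-epoch run, \code{beta(t) = 2t/T} for \code{t < T/2}, else 1;
#'   \item two learning-rate schedules \code{lr = lr0 * f^(e/i)} with a
#'     continuous exponent: network preset (5e-3, 1/1.05, 16.67) and latent
#'     preset (1e-4, 0.1, 1000).
#' }
#'
#' @param lambdaMax curriculum ceiling.
#' @param rampEpochs curriculum ramp length.
#' @param warmupEpochs linear warmup length for the regularization weight.
#' @param nCycles anneal cycles over the run.
#' @param totalEpochs planned training length (cycle length = total/nCycles).
#' @param lrNet,lrLatent lists with fields \code{lr0}, \code{f}, \code{i}.
#' @param sigma latent-regularization scale (per-component penalty z_i^2/sigma^2).
#' @return named list of class "trainingSchedules".
#' @export
trainingSchedules <- function(lambdaMax = 0.2, rampEpochs = 1800L,
                              warmupEpochs = 100L, nCycles = 5L,
                              totalEpochs = 2000L,
                              lrNet = list(lr0 = 5e-3, f = 1 / 1.05, i = 16.67),
                              lrLatent = list(lr0 = 1e-4, f = 0.1, i = 1000),
                              sigma = 100) {
  structure(list(lambdaMax = lambdaMax, rampEpochs = rampEpochs,
                 warmupEpochs = warmupEpochs, nCycles = nCycles,
                 totalEpochs = totalEpochs, cycleLen = totalEpochs / nCycles,
                 lrNet = lrNet, lrLatent = lrLatent, sigma = sigma,
                 k = 5),
            class = "trainingSchedules")
}

#' Curriculum weight lambda at an epoch
#'
#' Exponential ramp from exactly 0 at epoch 0 to exactly \code{lambdaMax} at
#' \code{rampEpochs}, constant afterwards.
#' @param e epoch (0-based).
#' @param sched a \code{\link{trainingSchedules}} object.
#' @export
curriculumLambda <- function(e, sched = trainingSchedules()) {
  if (any(e < 0)) stop("negative epoch")
  frac <- pmin(e, sched$rampEpochs) / sched$rampEpochs
  sched$lambdaMax * (exp(sched$k * frac) - 1) / (exp(sched$k) - 1)
}

#' Cyclic anneal weight beta
#'
#' \code{beta(t) = 2 t / T} for \code{0 <= t < T/2}, 1 for
#' \code{T/2 <= t < T}; periodic with the cycle length.
#' @param t epoch within the cycle (or absolute epoch; reduced mod T).
#' @param cycleLen cycle length T.
#' @export
annealBeta <- function(t, cycleLen) {
  tc <- t %% cycleLen
  ifelse(tc < cycleLen / 2, 2 * tc / cycleLen, 1)
}

#' Learning rate at an epoch: lr0 * f^(e/i), continuous exponent
#' @param e epoch.
#' @param preset list with lr0, f, i.
#' @export
lrAt <- function(e, preset) preset$lr0 * preset$f^(e / preset$i)

#' Evaluate all schedules at an epoch
#'
#' @param sched a \code{\link{trainingSchedules}}.
#' @param e epoch (0-based).
#' @return list with \code{lambda}, \code{wReg} (warmup x cyclic beta),
#'   \code{lrNet}, \code{lrLatent}.
#' @export
scheduleEval <- function(sched, e) {
  if (any(e < 0)) stop("negative epoch")
  list(lambda = curriculumLambda(e, sched),
       wReg = pmin(e / sched$warmupEpochs, 1) * annealBeta(e, sched$cycleLen),
       lrNet = lrAt(e, sched$lrNet),
       lrLatent = lrAt(e, sched$lrLatent))
}

#' Curriculum-weighted clamped L1 reconstruction loss
#'
#' Mean over points of \code{w * |clamp(sPred) - clamp(sTrue)|} with the
#' hard-sample weight \code{w = 1 + lambda * sign(sTrue) * sign(sTrue -
#' sPred)}: predictions on the wrong side of the truth relative to the
#' surface get up-weighted, easy ones down-weighted; \code{lambda = 0}
#' recovers plain clamped L1. Clamping is at \code{|s| = delta}.
#'
#' @param sPred,sTrue numeric vectors of equal length.
#' @param lambda curriculum weight in [0, 1].
#' @param delta clamp bound.
#' @return scalar loss (with attribute "weights" when \code{details = TRUE}).
#' @param details return per-point weights as an attribute.
#' @export
reconLoss <- function(sPred, sTrue, lambda = 0, delta = 0.1, details = FALSE) {
  if (length(sPred) != length(sTrue)) stop("prediction/target length mismatch")
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  cp <- pmin(pmax(sPred, -delta), delta)
  ct <- pmin(pmax(sTrue, -delta), delta)
  w <- 1 + lambda * sign(sTrue) * sign(sTrue - sPred)
  loss <- mean(w * abs(cp - ct))
  if (details) attr(loss, "weights") <- w
  loss
}

# gradient of reconLoss wrt sPred (weights treated as constants; zero outside
# the clamp interval)
reconLossGrad <- function(sPred, sTrue, lambda, delta) {
  cp <- pmin(pmax(sPred, -delta), delta)
  ct <- pmin(pmax(sTrue, -delta), delta)
  w <- 1 + lambda * sign(sTrue) * sign(sTrue - sPred)
  g <- w * sign(cp - ct)
  g[abs(sPred) > delta] <- 0
  g / length(sPred)
}

#' Latent regularization: sum_i z_i^2 / sigma^2
#' @param z latent vector.
#' @param sigma regularization scale.
#' @export
latentReg <- function(z, sigma = 100) {
  if (sigma <= 0) stop("sigma must be positive")
  sum(z^2) / sigma^2
}

#' Initialize a latent codebook z ~ N(0, 0.01^2)
#'
#' @param shapeIds character identifiers.
#' @param latentLen latent length.
#' @param sdInit initialization standard deviation (0.01).
#' @param seed RNG seed.
#' @export
initCodebook <- function(shapeIds, latentLen, sdInit = 0.01, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  LatentCodebook(matrix(rnorm(length(shapeIds) * latentLen, sd = sdInit),
                        length(shapeIds), latentLen), shapeIds)
}

#' Train a shape autodecoder on SDF sample sets
#'
#' Joint optimization of decoder weights and per-shape latent codes
#' (autodecoder). Each epoch iterates the shapes in shuffled order; per shape
#' one sign-balanced batch is drawn from each surface's sample set, both
#' decoder heads are supervised on both batches (each point stores s against
#' both meshes), and one AdamW step is taken for the network (weight decay
#' 1e-4) and for that shape's latent (no weight decay; latents carry their
#' own explicit regularization, weighted by the warmup x cyclic-anneal
#' schedule).
#'
#' @param dataset named list, one element per shape, each a list with
#'   \code{bone} and \code{cartilage} \linkS4class{SDFSampleSet}s (as
#'   returned by \code{\link{sampleTrainingPoints}}).
#' @param decoder an initialized \linkS4class{ShapeDecoder}; its
#'   \code{delta} sets the clamp bound for loss and targets.
#' @param sched a \code{\link{trainingSchedules}}.
#' @param epochs number of epochs to run.
#' @param batch a \code{\link{batchSpec}}.
#' @param seed RNG seed (batch draws, shuffling, codebook init).
#' @param weightDecay AdamW decoupled weight decay on network weights.
#' @param verbose print a line every \code{verbose} epochs (0 = quiet).
#' @return list with \code{decoder} (trained weights), \code{codebook},
#'   and \code{trace} (data.frame: epoch, loss, reconLoss, regLoss, lambda,
#'   wReg, lrNet, lrLatent).
#' @export
trainNSM <- function(dataset, decoder, sched = trainingSchedules(),
                     epochs = sched$totalEpochs, batch = batchSpec(),
                     seed = 1L, weightDecay = 1e-4, verbose = 0) {
  if (length(dataset) < 2) stop("need at least 2 shapes for autodecoding")
  set.seed(seed)
  shapeIds <- names(dataset)
  if (is.null(shapeIds)) shapeIds <- paste0("shape", seq_along(dataset))
  L <- decoder@latentLen
  codebook <- initCodebook(shapeIds, L, 0.01)
  Z <- codebook@latents
  netState <- adamInit(decoder@weights)
  latState <- lapply(shapeIds, function(i) list(m = numeric(L), v = numeric(L), t = 0L))
  delta <- decoder@delta
  trace <- vector("list", epochs)
  for (e in seq_len(epochs) - 1L) {
    sc <- scheduleEval(sched, e)
    order_ <- sample.int(length(dataset))
    eRecon <- 0; eReg <- 0
    for (k in order_) {
      bB <- drawBatch(dataset[[k]]$bone, batch)
      bC <- drawBatch(dataset[[k]]$cartilage, batch)
      pts <- rbind(bB@coords, bC@coords)
      sB <- c(bB@sBone, bC@sBone)
      sC <- c(bB@sCartilage, bC@sCartilage)
      z <- Z[k, ]
      fw <- decoderForward(decoder, z, pts, grad = TRUE)
      lossB <- reconLoss(fw$out[, 1], sB, sc$lambda, delta)
      lossC <- reconLoss(fw$out[, 2], sC, sc$lambda, delta)
      reg <- latentReg(z, sched$sigma)
      total <- lossB + lossC + sc$wReg * reg
      if (!is.finite(total))
        stop(sprintf("NaN/Inf loss at epoch %d, shape %s (lambda %.4g, lrNet %.4g)",
                     e, shapeIds[k], sc$lambda, sc$lrNet))
      dOut <- cbind(reconLossGrad(fw$out[, 1], sB, sc$lambda, delta),
                    reconLossGrad(fw$out[, 2], sC, sc$lambda, delta))
      bk <- decoderBackward(decoder, fw$cache, dOut)
      up <- adamStep(decoder@weights, bk$grads, netState, sc$lrNet, weightDecay)
      decoder@weights <- up$w
      netState <- up$state
      dz <- bk$dz + sc$wReg * 2 * z / sched$sigma^2
      lu <- adamStep(Z[k, ], dz, latState[[k]], sc$lrLatent, 0)
      Z[k, ] <- lu$w
      latState[[k]] <- lu$state
      eRecon <- eRecon + lossB + lossC
      eReg <- eReg + reg
    }
    n <- length(dataset)
    trace[[e + 1]] <- data.frame(epoch = e, loss = (eRecon + sc$wReg * eReg) / n,
                                 reconLoss = eRecon / n, regLoss = eReg / n,
                                 lambda = sc$lambda, wReg = sc$wReg,
                                 lrNet = sc$lrNet, lrLatent = sc$lrLatent)
    if (verbose > 0 && (e %% verbose == 0))
      message(sprintf("epoch %d: recon %.5f (lambda %.3f, wReg %.3f)",
                      e, eRecon / n, sc$lambda, sc$wReg))
  }
  list(decoder = decoder, codebook = LatentCodebook(Z, shapeIds),
       trace = do.call(rbind, trace))
}
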