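#' @title Clinical staging heads on shape latents
#' @name clinical
#' @description Label schema and binning, ordinal consistent-rank-logits
#'   (CORAL) loss and prediction, latent-space classifiers (grid-searched
#'   MLP and logistic regression), evaluation metrics, and latent
#'   interpolation/traversal for interpretation.
NULL

.moaksRegions <- c("anterior-medial", "anterior-lateral", "medial-central",
                   "lateral-central", "medial-posterior", "lateral-posterior")

#' The six femoral MOAKS regions
#' @export
moaksRegions <- function() .moaksRegions

#' Derive analysis labels from raw clinical grades
#'
#' Applies the task binning rules: osteoarthritis (OA) diagnosis is
#' Kellgren-Lawrence (KL) grade >= 2; MOAKS osteophyte grades are binned to
#' three levels with raw 2/3 merged into level 2; MOAKS cartilage thinning
#' is binarized at the 10%-of-region threshold (raw grades 2/3 positive);
#' MOAKS cartilage hole is binarized as any hole (raw >= 1).
#'
#' @param record data.frame (or one-row list) with columns \code{kl} (0-4)
#'   and optionally, per MOAKS region suffix, \code{osteophyte.<region>},
#'   \code{thinning.<region>}, \code{hole.<region>} raw grades (0-3).
#' @return the input with derived columns \code{oa},
#'   \code{osteophyteBinned.<region>}, \code{thinningBinary.<region>},
#'   \code{holeBinary.<region>}.
#' @export
binLabels <- function(record) {
  record <- as.data.frame(record)
  if (!"kl" %in% names(record)) stop("missing field: kl")
  chk <- function(x, lo, hi, nm) {
    bad <- !is.na(x) & (x < lo | x > hi | x != round(x))
    if (any(bad)) stop("out-of-range grade in field: ", nm)
    x
  }
  chk(record$kl, 0, 4, "kl")
  record$oa <- as.integer(record$kl >= 2)
  for (r in .moaksRegions) {
    oc <- paste0("osteophyte.", r)
    if (oc %in% names(record)) {
      chk(record[[oc]], 0, 3, oc)
      record[[paste0("osteophyteBinned.", r)]] <- pmin(record[[oc]], 2L)
    }
    tc <- paste0("thinning.", r)
    if (tc %in% names(record)) {
      chk(record[[tc]], 0, 3, tc)
      record[[paste0("thinningBinary.", r)]] <- as.integer(record[[tc]] >= 2)
    }
    hc <- paste0("hole.", r)
    if (hc %in% names(record)) {
      chk(record[[hc]], 0, 3, hc)
      record[[paste0("holeBinary.", r)]] <- as.integer(record[[hc]] >= 1)
    }
  }
  record
}

#' Consistent-rank-logits (CORAL) ordinal loss and prediction
#'
#' For K ordered grades, a shared-weight head emits K-1 threshold logits;
#' the loss is the sum of binary cross-entropies of sigmoid(logit_k) against
#' the cumulative targets 1[grade > k]. The predicted grade counts the
#' thresholds passed: \code{sum(sigmoid(logit_k) > 0.5)}. The shared-weight
#' construction guarantees non-increasing cumulative probabilities when the
#' biases are ordered decreasingly; predictions are monotone-consistent by
#' the counting rule regardless.
#'
#' @param logits numeric vector (or matrix, rows = samples) of K-1 logits.
#' @param grade integer grade(s) in 0..K-1.
#' @return \code{coralLoss}: mean loss over samples; \code{coralPredict}:
#'   integer grades.
#' @export
coralLoss <- function(logits, grade) {
  logits <- rbind(logits)
  K <- ncol(logits) + 1L
  if (any(grade < 0 | grade > K - 1)) stop("grade outside 0..K-1")
  targets <- outer(grade, seq_len(K - 1) - 1, ">") * 1
  # numerically stable BCE-with-logits
  l <- pmax(logits, 0) - logits * targets + log1p(exp(-abs(logits)))
  mean(rowSums(l))
}

#' @rdname coralLoss
#' @export
coralPredict <- function(logits) {
  logits <- rbind(logits)
  as.integer(rowSums(stats::plogis(logits) > 0.5))
}

# gradient of coralLoss wrt logits (per sample, divided by n)
coralLossGrad <- function(logits, grade) {
  logits <- rbind(logits)
  K <- ncol(logits) + 1L
  targets <- outer(grade, seq_len(K - 1) - 1, ">") * 1
  (stats::plogis(logits) - targets) / nrow(logits)
}

# ---- metrics ---------------------------------------------------------------

#' Quadratic-weighted Cohen's kappa
#'
#' Weights \code{(i - j)^2 / (K - 1)^2}; 1 for perfect agreement, 0 when
#' observed weighted disagreement equals chance expectation (e.g. any
#' constant predictor).
#'
#' @param pred,obs integer vectors of grades on the same 0-based scale.
#' @param nLevels number of grade levels K (inferred from data if NULL).
#' @export
quadraticKappa <- function(pred, obs, nLevels = NULL) {
  K <- nLevels %||% (max(c(pred, obs)) + 1L)
  conf <- table(factor(pred, levels = 0:(K - 1)), factor(obs, levels = 0:(K - 1)))
  n <- sum(conf)
  w <- outer(0:(K - 1), 0:(K - 1), function(i, j) (i - j)^2 / (K - 1)^2)
  expected <- outer(rowSums(conf), colSums(conf)) / n
  denom <- sum(w * expected)
  if (denom == 0) return(NA_real_)
  1 - sum(w * conf) / denom
}

#' Area under the precision-recall curve (step-wise)
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 labels.
#' @export
prAUC <- function(scores, labels) {
  if (length(unique(labels)) < 2) return(NA_real_)
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  tp <- cumsum(lab)
  fp <- cumsum(1 - lab)
  prec <- tp / (tp + fp)
  rec <- tp / sum(lab)
  # step-wise integration over recall increments (AP-style)
  sum(prec * diff(c(0, rec)))
}

#' F1 score at a threshold
#' @param scores numeric scores.
#' @param labels binary 0/1 labels.
#' @param threshold decision threshold on the scores.
#' @export
f1Score <- function(scores, labels, threshold = 0.5) {
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  if (2 * tp + fp + fn == 0) return(NA_real_)
  2 * tp / (2 * tp + fp + fn)
}

#' Evaluation metrics for a prediction task
#'
#' Ordinal tasks: quadratic-weighted kappa and accuracy. Binary tasks:
#' AUROC (trapezoidal, via pROC), AUPRC, accuracy and F1 at a threshold.
#' The F1/accuracy threshold defaults to 0.5; it may be tuned on a
#' validation set and passed in, or (reproducing a reported-results
#' convention only when explicitly requested) optimized on the evaluated
#' set with \code{optimizeThresholdOnTest = TRUE}.
#'
#' @param predictions grades (ordinal task) or scores in [0,1] (binary).
#' @param labels observed grades or binary labels.
#' @param task "ordinal" or "binary".
#' @param nLevels number of ordinal levels.
#' @param threshold binary decision threshold.
#' @param optimizeThresholdOnTest explicitly opt in to picking the
#'   F1-maximizing threshold on the evaluated data.
#' @return named list of metrics (single-class binary inputs yield NA for
#'   AUROC/AUPRC).
#' @export
classifierMetrics <- function(predictions, labels, task = c("binary", "ordinal"),
                              nLevels = NULL, threshold = 0.5,
                              optimizeThresholdOnTest = FALSE) {
  task <- match.arg(task)
  if (length(predictions) != length(labels) || length(labels) == 0)
    stop("predictions and labels must be non-empty and aligned")
  if (task == "ordinal") {
    list(kappa = quadraticKappa(predictions, labels, nLevels),
         accuracy = mean(predictions == labels))
  } else {
    auroc <- if (length(unique(labels)) < 2) NA_real_ else
      as.numeric(pROC::auc(pROC::roc(labels, predictions, quiet = TRUE,
                                     direction = "<")))
    if (optimizeThresholdOnTest && length(unique(labels)) == 2) {
      cand <- sort(unique(predictions))
      f1s <- vapply(cand, function(t) f1Score(predictions, labels, t) %||% 0,
                    numeric(1))
      f1s[is.na(f1s)] <- 0
      threshold <- cand[which.max(f1s)]
    }
    list(auroc = auroc,
         auprc = prAUC(predictions, labels),
         accuracy = mean(as.integer(predictions > threshold) == labels),
         f1 = f1Score(predictions, labels, threshold),
         threshold = threshold)
  }
}

# ---- classifier heads ------------------------------------------------------

#' Classifier search specification
#'
#' @param headType "mlp" or "logistic".
#' @param depth,width,dropout,lr,batchSize candidate grids (the full study
#'   grid by default; pass smaller grids for desk-scale runs).
#' @param epochs training epochs per grid candidate.
#' @export
classifierSpec <- function(headType = c("mlp", "logistic"),
                           depth = c(2L, 3L), width = c(64L, 128L, 256L),
                           dropout = c(0.2, 0.4), lr = c(1e-3, 1e-4, 1e-5),
                           batchSize = c(64L, 128L, 256L, 512L),
                           epochs = 200L) {
  structure(list(headType = match.arg(headType), depth = depth, width = width,
                 dropout = dropout, lr = lr, batchSize = batchSize,
                 epochs = as.integer(epochs)), class = "classifierSpec")
}

# small MLP classifier with dropout; loss = "bce" (1 output) or "coral"
# (K-1 outputs). Returns weights and a predict function on logits scale.
trainMLPHead <- function(X, y, depth, width, dropout, lr, batchSize, epochs,
                         loss = c("bce", "coral"), nLevels = 2L) {
  loss <- match.arg(loss)
  nOut <- if (loss == "bce") 1L else nLevels - 1L
  nin <- ncol(X)
  layers <- list()
  prev <- nin
  for (l in seq_len(depth)) {
    layers[[l]] <- list(W = initHe(prev, width), b = numeric(width))
    prev <- width
  }
  head <- if (loss == "coral")
    list(W = initGlorot(prev, 1L), b = sort(rnorm(nOut, sd = 0.1), decreasing = TRUE))
  else list(W = initGlorot(prev, nOut), b = numeric(nOut))
  w <- list(layers = layers, head = head)
  state <- adamInit(w)
  n <- nrow(X)
  forward <- function(w, X, drop = NULL) {
    h <- X
    caches <- list()
    for (l in seq_along(w$layers)) {
      pre <- sweep(h %*% w$layers[[l]]$W, 2, w$layers[[l]]$b, "+")
      a <- relu(pre)
      if (!is.null(drop)) {
        mask <- matrix(runif(length(a)) > dropout, nrow(a), ncol(a)) / (1 - dropout)
        a <- a * mask
        caches[[l]] <- list(inp = h, pre = pre, mask = mask)
      } else caches[[l]] <- list(inp = h, pre = pre, mask = NULL)
      h <- a
    }
    logits <- if (!is.null(w$head$W)) {
      base <- h %*% w$head$W
      if (length(w$head$b) > 1 && ncol(base) == 1)
        sweep(matrix(base, nrow(h), length(w$head$b)), 2, w$head$b, "+")
      else sweep(base, 2, w$head$b, "+")
    }
    list(logits = logits, h = h, caches = caches)
  }
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    for (start in seq(1, n, by = batchSize)) {
      sel <- idx[start:min(start + batchSize - 1, n)]
      Xb <- X[sel, , drop = FALSE]
      yb <- y[sel]
      fw <- forward(w, Xb, drop = TRUE)
      if (loss == "bce") {
        p <- stats::plogis(fw$logits[, 1])
        dLogits <- matrix((p - yb) / length(sel), ncol = 1)
      } else {
        dFull <- coralLossGrad(fw$logits, yb)     # n x (K-1)
        dLogits <- matrix(rowSums(dFull), ncol = 1)  # shared weight column
        dBias <- colSums(dFull)
      }
      gHead <- list(W = crossprod(fw$h, dLogits),
                    b = if (loss == "coral") dBias else colSums(dLogits))
      dH <- dLogits %*% t(w$head$W)
      gL <- vector("list", length(w$layers))
      for (l in rev(seq_along(w$layers))) {
        ch <- fw$caches[[l]]
        dA <- if (is.null(ch$mask)) dH else dH * ch$mask
        dPre <- dA * (ch$pre > 0)
        gL[[l]] <- list(W = crossprod(ch$inp, dPre), b = colSums(dPre))
        dH <- dPre %*% t(w$layers[[l]]$W)
      }
      up <- adamStep(w, list(layers = gL, head = gHead), state, lr, 1e-4)
      w <- up$w
      state <- up$state
    }
  }
  list(weights = w, forward = function(Xnew) forward(w, Xnew, drop = NULL)$logits,
       loss = loss, nLevels = nLevels)
}

#' Train a latent-space classifier with grid search
#'
#' Trains either a grid-searched MLP head or a logistic regression on latent
#' codes. Binary tasks use binary cross-entropy; ordinal tasks use the
#' consistent-rank-logits loss. The grid winner is chosen on the validation
#' split by quadratic kappa (ordinal), AUROC (balanced binary) or AUPRC
#' (imbalanced binary, prevalence < 25%).
#'
#' @param latents numeric matrix (rows = shapes).
#' @param labels integer labels (binary 0/1 or ordinal 0..K-1).
#' @param task "binary" or "ordinal".
#' @param spec a \code{\link{classifierSpec}}.
#' @param valFraction held-out fraction used for grid selection.
#' @param seed RNG seed (split, init, batching).
#' @param nLevels ordinal level count (inferred if NULL).
#' @return list with \code{predict} (function latents -> scores/grades),
#'   \code{scoreFun} (raw score function), \code{config} (winning config),
#'   \code{validation} (metrics of the winner), \code{direction} (for
#'   logistic heads, the unit coefficient vector).
#' @export
trainClassifier <- function(latents, labels, task = c("binary", "ordinal"),
                            spec = classifierSpec(), valFraction = 0.25,
                            seed = 1L, nLevels = NULL) {
  task <- match.arg(task)
  set.seed(seed)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("need >= 2 classes in the labels")
  K <- nLevels %||% (max(labels) + 1L)
  n <- nrow(latents)
  # stratified validation split
  val <- unlist(lapply(split(seq_len(n), labels), function(ix)
    ix[seq_len(max(1, round(length(ix) * valFraction)))]))
  tr <- setdiff(seq_len(n), val)
  if (length(unique(labels[tr])) < 2) stop("single-class training split")
  Xtr <- latents[tr, , drop = FALSE]; ytr <- labels[tr]
  Xv <- latents[val, , drop = FALSE]; yv <- labels[val]
  prevalence <- mean(labels)
  valMetric <- function(scores) {
    if (task == "ordinal") quadraticKappa(coralPredict(scores), yv, K)
    else if (prevalence < 0.25) prAUC(scores, yv)
    else {
      if (length(unique(yv)) < 2) return(NA_real_)
      as.numeric(pROC::auc(pROC::roc(yv, scores, quiet = TRUE, direction = "<")))
    }
  }
  if (spec$headType == "logistic") {
    if (task == "ordinal") stop("logistic head supports binary tasks only")
    df <- data.frame(y = ytr, Xtr)
    fit <- suppressWarnings(glm(y ~ ., data = df, family = binomial()))
    beta <- coef(fit)[-1]
    beta[is.na(beta)] <- 0
    scoreFun <- function(Xn) as.numeric(stats::plogis(cbind(1, Xn) %*% c(coef(fit)[1], beta)))
    sv <- scoreFun(Xv)
    return(list(predict = scoreFun, scoreFun = scoreFun,
                config = list(headType = "logistic"),
                validation = classifierMetrics(sv, yv, "binary"),
                direction = beta / sqrt(sum(beta^2)),
                intercept = unname(coef(fit)[1])))
  }
  grid <- expand.grid(depth = spec$depth, width = spec$width,
                      dropout = spec$dropout, lr = spec$lr,
                      batchSize = spec$batchSize)
  best <- NULL
  for (gi in seq_len(nrow(grid))) {
    g <- grid[gi, ]
    set.seed(seed + gi)
    head <- trainMLPHead(Xtr, ytr, g$depth, g$width, g$dropout, g$lr,
                         min(g$batchSize, length(tr)), spec$epochs,
                         loss = if (task == "ordinal") "coral" else "bce",
                         nLevels = K)
    sv <- if (task == "ordinal") head$forward(Xv) else
      stats::plogis(head$forward(Xv)[, 1])
    m <- valMetric(sv)
    if (is.null(best) || (!is.na(m) && m > best$metric)) {
      best <- list(metric = m, head = head, config = as.list(g))
    }
  }
  scoreFun <- if (task == "ordinal") function(Xn) best$head$forward(Xn)
  else function(Xn) stats::plogis(best$head$forward(Xn)[, 1])
  predictFun <- if (task == "ordinal") function(Xn) coralPredict(scoreFun(Xn))
  else scoreFun
  sv <- scoreFun(Xv)
  valReport <- if (task == "ordinal")
    classifierMetrics(coralPredict(sv), yv, "ordinal", nLevels = K)
  else classifierMetrics(sv, yv, "binary")
  list(predict = predictFun, scoreFun = scoreFun, config = best$config,
       validation = valReport, gridMetric = best$metric)
}

# ---- interpretation --------------------------------------------------------

#' Linear latent interpolation
#'
#' \code{z(alpha) = (1 - alpha) zA + alpha zB} on an even alpha grid
#' including both endpoints.
#'
#' @param zA,zB latent vectors of equal length.
#' @param nSteps number of latents returned (>= 2).
#' @return matrix with nSteps rows from zA to zB.
#' @export
interpolateLatents <- function(zA, zB, nSteps = 10) {
  if (length(zA) != length(zB)) stop("latent length mismatch")
  alpha <- seq(0, 1, length.out = nSteps)
  outer(1 - alpha, zA) + outer(alpha, zB)
}

#' Traverse latent space along a classifier direction
#'
#' \code{z(c) = z + c * direction} for each step coefficient; the direction
#' is unit-normalized (e.g. logistic-regression coefficients), so the
#' classifier's probability is strictly monotone along the traversal.
#'
#' @param z starting latent.
#' @param direction coefficient vector (nonzero).
#' @param steps numeric vector of signed step coefficients.
#' @return matrix with one latent per step.
#' @export
traverseClassifier <- function(z, direction, steps = seq(-2, 2, length.out = 9)) {
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("zero direction vector")
  d <- direction / nrm
  t(vapply(steps, function(s) z + s * d, numeric(length(z))))
}
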