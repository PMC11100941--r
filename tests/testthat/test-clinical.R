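# Clinical heads: binning, CORAL, metrics, classifiers, interpretation.

test_that("label binning applies the diagnostic thresholds exactly", {
  reg <- moaksRegions()[1]
  rec <- data.frame(kl = 0:4)
  out <- binLabels(rec)
  expect_identical(out$oa, c(0L, 0L, 1L, 1L, 1L))    # OA iff KL >= 2
  rec2 <- data.frame(kl = rep(2, 4))
  rec2[[paste0("osteophyte.", reg)]] <- 0:3
  rec2[[paste0("thinning.", reg)]] <- 0:3
  rec2[[paste0("hole.", reg)]] <- 0:3
  out2 <- binLabels(rec2)
  expect_identical(out2[[paste0("osteophyteBinned.", reg)]], c(0L, 1L, 2L, 2L))
  expect_identical(out2[[paste0("thinningBinary.", reg)]], c(0L, 0L, 1L, 1L))
  expect_identical(out2[[paste0("holeBinary.", reg)]], c(0L, 1L, 1L, 1L))
  bad <- data.frame(kl = 7)
  expect_error(binLabels(bad), "kl")
  bad2 <- data.frame(kl = 1)
  bad2[[paste0("hole.", reg)]] <- 5
  expect_error(binLabels(bad2), "hole")
})

test_that("CORAL predictions follow the count-over-threshold rule exactly", {
  # strongly negative logits: grade 0, vanishing loss
  lg <- rep(-20, 4)
  expect_identical(coralPredict(lg), 0L)
  expect_lt(coralLoss(lg, 0), 1e-6)
  # sigmoids (0.9, 0.8, 0.4, 0.1) -> two thresholds passed
  expect_identical(coralPredict(qlogis(c(0.9, 0.8, 0.4, 0.1))), 2L)
  # perfect cumulative targets recover every grade 0..K-1
  K <- 5
  for (g in 0:(K - 1)) {
    lg <- ifelse(seq_len(K - 1) - 1 < g, 8, -8)
    expect_identical(coralPredict(lg), g)
    expect_lt(coralLoss(lg, g), 0.01)
  }
  expect_error(coralLoss(lg, 7), "grade")
  # cumulative probabilities are non-increasing for ordered biases
  set.seed(2)
  w <- rnorm(6)
  x <- matrix(rnorm(30), 5)
  biases <- sort(rnorm(4), decreasing = TRUE)
  logits <- sweep(matrix(x %*% w, 5, 4), 2, biases, "+")
  probs <- plogis(logits)
  expect_true(all(apply(probs, 1, function(p) all(diff(p) <= 1e-12))))
})

test_that("quadratic kappa matches a by-hand confusion-matrix computation", {
  # 3x3 confusion matrix worked through the definition independently
  pred <- c(rep(0, 10), rep(1, 12), rep(2, 8), rep(0, 3), rep(2, 5), rep(1, 2))
  obs  <- c(rep(0, 10), rep(1, 12), rep(2, 8), rep(1, 3), rep(1, 5), rep(2, 2))
  K <- 3
  conf <- table(factor(pred, levels = 0:2), factor(obs, levels = 0:2))
  w <- outer(0:2, 0:2, function(i, j) (i - j)^2 / (K - 1)^2)
  n <- sum(conf)
  expManual <- outer(rowSums(conf), colSums(conf)) / n
  kManual <- 1 - sum(w * conf) / sum(w * expManual)
  expect_equal(quadraticKappa(pred, obs, 3), kManual)
  # perfect prediction and constant predictor
  expect_equal(quadraticKappa(obs, obs, 3), 1)
  expect_equal(quadraticKappa(rep(1L, 30), sample(0:2, 30, replace = TRUE), 3), 0)
  # swapped 2-class indexing leaves kappa unchanged
  p2 <- rep(c(0L, 1L), 15); o2 <- c(rep(c(0L, 1L), 12), rep(c(1L, 0L), 3))
  expect_equal(quadraticKappa(p2, o2, 2), quadraticKappa(1L - p2, 1L - o2, 2))
})

test_that("AUROC/AUPRC/F1 reproduce hand-computed small cases", {
  scores <- c(0.9, 0.8, 0.7, 0.3, 0.2)
  labels <- c(1, 1, 0, 1, 0)
  m <- classifierMetrics(scores, labels, "binary", threshold = 0.5)
  # AUROC by counting concordant pairs: pairs (pos, neg) with s_pos > s_neg
  conc <- mean(outer(scores[labels == 1], scores[labels == 0], ">"))
  expect_equal(m$auroc, conc)
  # AP-style AUPRC: sum of precision at each recall step
  expect_equal(m$auprc, (1 / 1 + 2 / 2 + 3 / 4) / 3)
  expect_equal(m$f1, 2 * 2 / (2 * 2 + 1 + 1))      # tp=2, fp=1, fn=1 at 0.5
  perfect <- classifierMetrics(labels, labels, "binary")
  expect_equal(perfect$auroc, 1)
  expect_true(is.na(classifierMetrics(c(0.2, 0.8), c(1, 1), "binary")$auroc))
  ord <- classifierMetrics(c(0, 1, 2), c(0, 1, 2), "ordinal", nLevels = 3)
  expect_equal(ord$kappa, 1)
  expect_equal(ord$accuracy, 1)
})

test_that("logistic heads separate a sign-separable latent construction", {
  set.seed(14)
  n <- 400
  Z <- matrix(rnorm(n * 4), n, 4)
  y <- as.integer(Z[, 1] > 0)
  head <- trainClassifier(Z, y, "binary",
                          classifierSpec(headType = "logistic"), seed = 3)
  expect_gt(head$validation$auroc, 0.99)
  expect_equal(unname(abs(head$direction[1])), max(abs(head$direction)))
  # shuffled labels carry no signal
  head0 <- trainClassifier(Z, sample(y), "binary",
                           classifierSpec(headType = "logistic"), seed = 3)
  expect_lt(abs(head0$validation$auroc - 0.5), 0.12)
})

test_that("grid-searched MLP heads learn binary and ordinal synthetic tasks deterministically", {
  set.seed(15)
  n <- 300
  Z <- matrix(rnorm(n * 3), n, 3)
  spec <- classifierSpec(headType = "mlp", depth = 2L, width = 16L,
                         dropout = 0.2, lr = c(1e-2, 1e-3), batchSize = 64L,
                         epochs = 60L)
  y <- as.integer(Z[, 2] > 0)
  h1 <- trainClassifier(Z, y, "binary", spec, seed = 5)
  expect_gt(h1$validation$auroc, 0.95)
  h2 <- trainClassifier(Z, y, "binary", spec, seed = 5)
  expect_identical(h1$config, h2$config)
  expect_equal(h1$scoreFun(Z[1:5, ]), h2$scoreFun(Z[1:5, ]))
  # ordinal task: grade = binned first coordinate
  g <- pmin(3L, pmax(0L, as.integer(floor(Z[, 1] + 2) - 0.0)))
  h3 <- trainClassifier(Z, g, "ordinal", spec, seed = 5, nLevels = 4L)
  expect_gt(h3$validation$kappa, 0.6)
  expect_error(trainClassifier(Z, rep(1L, n), "binary", spec), "2 classes")
})

test_that("latent interpolation and classifier traversal behave linearly", {
  set.seed(16)
  za <- rnorm(8); zb <- rnorm(8)
  Z <- interpolateLatents(za, zb, 5)
  expect_equal(Z[1, ], za)
  expect_equal(Z[5, ], zb)
  expect_equal(Z[3, ], (za + zb) / 2)
  # probability along a logistic head's own direction is strictly monotone
  n <- 200
  X <- matrix(rnorm(n * 4), n, 4)
  y <- as.integer(X %*% c(1, -2, 0.5, 0) + rnorm(n, sd = 0.3) > 0)
  head <- trainClassifier(X, y, "binary", classifierSpec(headType = "logistic"),
                          seed = 2)
  steps <- seq(-1, 1, length.out = 9)
  traj <- traverseClassifier(rnorm(4), head$direction, steps)
  p <- head$scoreFun(traj)
  # strictly monotone up to double saturation of the sigmoid at the ends
  expect_true(all(diff(p) >= 0))
  expect_gt(p[9], p[1])
  mid <- p > 1e-12 & p < 1 - 1e-12
  expect_true(all(diff(p[mid]) > 0))
  expect_error(traverseClassifier(rnorm(4), numeric(4)), "zero direction")
})
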