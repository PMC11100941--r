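# Shared fixtures, built once per test session and cached.

.fixtureEnv <- new.env(parent = emptyenv())

suiteFixture <- function() {
  if (is.null(.fixtureEnv$suite)) .fixtureEnv$suite <- makeFixtureSuite(42L)
  .fixtureEnv$suite
}

# The scaled-down training study shared between the learning/reconstruction
# tests and the acceptance suite: hybrid decoder (latent 32, plane
# resolution 16), 10 synthetic shape pairs, 300 epochs, grid 64 at
# reconstruction time. Schedule horizons scale with the run (curriculum ramp
# 90% of epochs, warmup 5%, 5 anneal cycles), mirroring the full-scale
# proportions.
scaledStudyConfig <- function() {
  list(latentLen = 32L, nDeconv = 3L, channels = 64L, planeFeatures = 32L,
       trunkWidth = 64L, epochs = 300L, nSamplePoints = 30000L,
       batchPoints = 2048L, gridResolution = 64L, seed = 42L)
}

scaledModel <- function() {
  if (!is.null(.fixtureEnv$scaled)) return(.fixtureEnv$scaled)
  cfg <- scaledStudyConfig()
  suite <- suiteFixture()
  normalized <- lapply(suite$population, function(s) normalizeUnitSphere(s$pair))
  dataset <- setNames(lapply(seq_along(suite$population), function(i)
    sampleTrainingPoints(normalized[[i]]$pair,
                         samplingConfig(nTotal = cfg$nSamplePoints),
                         shapeId = suite$population[[i]]$shapeId)),
    vapply(suite$population, `[[`, "", "shapeId"))
  dec <- hybridDecoder(latentLen = cfg$latentLen, nDeconv = cfg$nDeconv,
                       channels = cfg$channels, planeFeatures = cfg$planeFeatures,
                       trunkWidth = cfg$trunkWidth, delta = 1, seed = cfg$seed)
  sched <- trainingSchedules(rampEpochs = round(0.9 * cfg$epochs),
                             warmupEpochs = round(0.05 * cfg$epochs),
                             nCycles = 5L, totalEpochs = cfg$epochs)
  set.seed(cfg$seed)
  fit <- trainNSM(dataset, dec, sched, epochs = cfg$epochs,
                  batch = batchSpec(cfg$batchPoints), seed = cfg$seed)
  .fixtureEnv$scaled <- list(fit = fit, normalized = normalized,
                             suite = suite, cfg = cfg)
  .fixtureEnv$scaled
}
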