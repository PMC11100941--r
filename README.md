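# NeuralSDF

Neural shape models of paired anatomic surfaces — a femoral bone and its
overlying cartilage — represented as signed distance functions (SDFs) and
decoded from a single shape-level latent vector. The package is aimed at
researchers in musculoskeletal imaging and anatomic shape analysis who want
a complete, inspectable SDF-autodecoder pipeline in R: mesh geometry and
registration, SDF sampling, decoder training, test-time latent fitting and
surface reconstruction, cartilage-thickness biomarkers, and latent-space
clinical staging — all exercisable end-to-end on a built-in synthetic knee
generator.

## The model

A decoder `f_theta(z, x) -> (s_bone, s_cartilage)` maps a latent vector `z`
and a 3D coordinate `x` to signed distances from both surfaces (negative
inside). Training is an **autodecoder**: each training shape owns a free
latent, optimized jointly with the decoder weights under a
curriculum-weighted clamped-L1 reconstruction loss

    L = mean( w * | clamp_d(s_hat) - clamp_d(s) | ),
    w = 1 + lambda * sign(s) * sign(s - s_hat)

plus a per-component latent penalty `sum_i z_i^2 / sigma^2` (sigma = 100)
whose weight follows a linear warmup times a cyclic anneal
(`beta(t) = 2t/T` for `t < T/2`, else 1; five cycles). Three decoder
families are provided: a triplanar **hybrid explicit–implicit** decoder (a
CNN expands `z` into three orthogonal feature planes; points read local
latents by bilinear interpolation, decoded by a small MLP), a deep
**implicit MLP** (two 8-layer width-512 trunks, skip connection into layer
4; 4,733,954 parameters at full scale — 4.7 M), and a **modulated
periodic-activation** decoder (sinusoidal synthesizer on `x`, ReLU
modulator on `z`, layerwise elementwise products). New shapes are fitted by
freezing the weights and optimizing a fresh latent against 20,000 surface
samples; surfaces are recovered by marching the decoded SDF grid and
inverting the registration transform.

## Worked example

Generate a synthetic diseased knee shape, measure its regional cartilage
thickness biomarkers, and inspect the planted labels:

```r
library(NeuralSDF)

dec <- mlpDecoder()        # full-scale implicit MLP
paramCount(dec)
#> [1] 4733954

suite <- makeFixtureSuite(42)
pair <- suite$population[[5]]$pair     # severity-4 sample
pair
#> TriangleMeshPair [frame 'canonical']
#>   bone:      642 vertices, 1280 faces
#>   cartilage: 1538 vertices, 3072 faces

reg <- assignRegions(pairBone(pair), regionAtlas())
tm  <- computeThickness(pair, regions = reg)
regionalMeans(tm, shapeId = "synth005")
#>    shapeId trochlea medial-central lateral-central medial-posterior lateral-posterior
#> 1 synth005     1.77           1.57            1.88             1.24              1.93

suite$population[[5]]$labels[, c("kl", "oa")]
#>   kl oa
#> 1  4  1
```

The depressed regional means reflect the planted thinning patches and
cartilage holes of a severe-disease sample (base thickness 2 mm); the
KL-like grade and OA label derive deterministically from the same planted
features.

Training and reconstruction at desk scale:

```r
dataset <- setNames(lapply(suite$population, function(s)
  sampleTrainingPoints(normalizeUnitSphere(s$pair)$pair,
                       samplingConfig(nTotal = 30000L),
                       shapeId = s$shapeId)),
  sapply(suite$population, `[[`, "shapeId"))
dec  <- hybridDecoder(latentLen = 32, nDeconv = 3, channels = 64,
                      planeFeatures = 32, trunkWidth = 64, delta = 1)
fit  <- trainNSM(dataset, dec,
                 trainingSchedules(rampEpochs = 270, warmupEpochs = 15,
                                   totalEpochs = 300),
                 epochs = 300, batch = batchSpec(2048L), seed = 1)
z    <- codebookLatents(fit$codebook)[1, ]
rec  <- reconstructPair(fit$decoder, z, resolution = 64)
assd(pairBone(rec), pairBone(normalizeUnitSphere(suite$population[[1]]$pair)$pair))
```

On this run the final epoch's reconstruction loss is about 5% of the first
epoch's, and the fitted-latent bone reconstruction lands within a fraction
of the marching-grid spacing of the target (ASSD ≈ 0.006 in normalized
units vs spacing 0.032).

A thin command-line wrapper over these functions is installed at
`inst/scripts/nsm-cli.R` (subcommands `synth-generate`, `mask2mesh`,
`sample-points`, `train`, `fit`, `reconstruct`, `eval-recon`, `biomarkers`,
`eval-biomarkers`, `train-classifier`, `evaluate`, `interpolate`).

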