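#' @title Pipeline interface: mask conversion and command-line dispatch
#' @name interface
NULL

#' Convert a binary segmentation mask to a surface mesh
#'
#' Level-set extraction at 0.5 on the (optionally Gaussian-smoothed) binary
#' volume, with the NIfTI affine applied so the mesh lands in scanner
#' millimeter coordinates. Left-side shapes can be mirrored to right via
#' \code{flipLR}.
#'
#' @param mask a 3D 0/1 array, or a path to a NIfTI file (requires the
#'   RNifti package).
#' @param smoothSigma Gaussian pre-smoothing in voxels (0 disables).
#' @param affine optional 4x4 voxel-to-world matrix (taken from the NIfTI
#'   header when a path is given; identity otherwise).
#' @param flipLR mirror the first axis (left to right knees).
#' @return a \linkS4class{TriangleMesh} in world coordinates.
#' @export
maskToMesh <- function(mask, smoothSigma = 0.5, affine = NULL, flipLR = FALSE) {
  if (is.character(mask)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI masks requires the RNifti package")
    img <- RNifti::readNifti(mask)
    if (is.null(affine)) affine <- structure(RNifti::xform(img), class = NULL)
    mask <- as.array(img)
  }
  vol <- (mask != 0) * 1
  if (flipLR) vol <- vol[dim(vol)[1]:1, , , drop = FALSE]
  if (smoothSigma > 0) vol <- gaussianSmooth3D(vol, smoothSigma)
  dims <- dim(vol)
  n <- max(dims)
  # pad into a cube (marching kernel expects a cubic grid), border of zeros
  cube <- array(0, rep(n + 2, 3))
  cube[1 + seq_len(dims[1]), 1 + seq_len(dims[2]), 1 + seq_len(dims[3])] <- vol
  ext <- c(0, n + 1)
  res <- cpp_marching_tetra(as.numeric(-cube + 0.5), n + 2L, ext[1], ext[2], 0)
  v <- res$vertices - 1     # back to voxel indices (0-based)
  if (!is.null(affine)) {
    v <- cbind(v, 1) %*% t(affine)
    v <- v[, 1:3, drop = FALSE]
  }
  m <- TriangleMesh(v, res$faces)
  if (meshVolume(m) < 0) m <- TriangleMesh(m@vertices, m@faces[, c(1, 3, 2)])
  m
}

# separable 3D Gaussian smoothing, truncated at 3 sigma
gaussianSmooth3D <- function(vol, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  sm1 <- function(x) {
    # pad-replicate convolution along the first axis of a 3D array
    d <- dim(x)
    out <- array(0, d)
    for (o in -r:r) {
      idx <- pmin(pmax(seq_len(d[1]) + o, 1), d[1])
      out <- out + k[o + r + 1] * x[idx, , , drop = FALSE]
    }
    out
  }
  x <- sm1(vol)
  x <- aperm(sm1(aperm(x, c(2, 1, 3))), c(2, 1, 3))
  aperm(sm1(aperm(x, c(3, 2, 1))), c(3, 2, 1))
}

#' Command-line entry point
#'
#' Thin subcommand dispatcher over the package's exported functions, used by
#' the installed script \code{inst/scripts/nsm-cli.R}. Subcommands:
#' \code{synth-generate}, \code{mask2mesh}, \code{sample-points},
#' \code{train}, \code{fit}, \code{reconstruct}, \code{eval-recon},
#' \code{biomarkers}, \code{eval-biomarkers}, \code{train-classifier},
#' \code{evaluate}, \code{interpolate}. Every run writes its resolved
#' configuration as JSON next to its outputs so it can be rerun exactly.
#'
#' @param args character vector of command-line arguments (subcommand first).
#' @return integer exit status (0 on success), invisibly.
#' @export
nsmCli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: nsm-cli.R <command> [--key value ...]",
    "commands: synth-generate mask2mesh sample-points train fit reconstruct",
    "          eval-recon biomarkers eval-biomarkers train-classifier",
    "          evaluate interpolate", sep = "\n")
  if (length(args) == 0) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- parseCliOpts(args[-1])
  out <- opts$out %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(opts$seed %||% 1)
  logFile <- file.path(out, paste0(cmd, ".log"))
  logLine <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                               "\n", file = logFile, append = TRUE, sep = "")
  echoConfig <- function(cfg) jsonlite::write_json(
    c(list(command = cmd, seed = seed), cfg),
    file.path(out, paste0(cmd, "-config.json")), auto_unbox = TRUE,
    digits = NA, force = TRUE)
  status <- tryCatch({
    switch(cmd,
      "synth-generate" = {
        n <- as.integer(opts$n %||% 10)
        pop <- generatePopulation(synthConfig(seed = seed, n = n))
        labs <- do.call(rbind, lapply(pop, `[[`, "labels"))
        write.csv(labs, file.path(out, "labels.csv"), row.names = FALSE)
        for (s in pop) {
          writeMesh(s$pair@bone, file.path(out, paste0(s$shapeId, "_bone.ply")))
          writeMesh(s$pair@cartilage,
                    file.path(out, paste0(s$shapeId, "_cartilage.ply")),
                    )
          write.csv(data.frame(thickness = s$thicknessTruth,
                               region5 = s$regions5, region6 = s$regions6),
                    file.path(out, paste0(s$shapeId, "_truth.csv")),
                    row.names = FALSE)
        }
        echoConfig(list(n = n))
        logLine("wrote ", n, " synthetic shape pairs")
        0L
      },
      "mask2mesh" = {
        m <- maskToMesh(reqOpt(opts, "mask"),
                        smoothSigma = as.numeric(opts$smooth %||% 0.5),
                        flipLR = isTRUE(opts$fliplr == "true"))
        writeMesh(m, file.path(out, opts$name %||% "mask-mesh.ply"))
        echoConfig(list(mask = opts$mask))
        0L
      },
      "sample-points" = {
        pair <- readPairOpts(opts)
        nm <- normalizeUnitSphere(pair)
        cfg <- samplingConfig(nTotal = as.integer(opts$n %||% 500000))
        ss <- sampleTrainingPoints(nm$pair, cfg, seed = seed,
                                   shapeId = opts$name %||% "shape")
        writeSampleSet(ss$bone, file.path(out, "samples_bone.bin"))
        writeSampleSet(ss$cartilage, file.path(out, "samples_cartilage.bin"))
        echoConfig(cfg)
        0L
      },
      "train" = {
        dataDir <- reqOpt(opts, "data")
        ids <- sub("_bone.ply$", "",
                   basename(Sys.glob(file.path(dataDir, "*_bone.ply"))))
        cfgS <- samplingConfig(nTotal = as.integer(opts$npoints %||% 30000))
        dataset <- setNames(lapply(ids, function(id) {
          pair <- TriangleMeshPair(
            readMesh(file.path(dataDir, paste0(id, "_bone.ply"))),
            readMesh(file.path(dataDir, paste0(id, "_cartilage.ply"))))
          sampleTrainingPoints(normalizeUnitSphere(pair)$pair, cfgS,
                               shapeId = id)
        }), ids)
        dec <- hybridDecoder(latentLen = as.integer(opts$latent %||% 32),
                             nDeconv = as.integer(opts$ndeconv %||% 3),
                             channels = 64L, planeFeatures = 32L,
                             trunkWidth = 64L, seed = seed)
        fit <- trainNSM(dataset, dec,
                        epochs = as.integer(opts$epochs %||% 300),
                        batch = batchSpec(as.integer(opts$batch %||% 2048)),
                        seed = seed)
        saveDecoder(fit$decoder, file.path(out, "decoder.bin"),
                    extra = list(epochs = nrow(fit$trace), seed = seed))
        write.csv(fit$trace, file.path(out, "training-log.csv"), row.names = FALSE)
        write.csv(data.frame(shapeId = codebookShapeIds(fit$codebook),
                             codebookLatents(fit$codebook)),
                  file.path(out, "codebook.csv"), row.names = FALSE)
        echoConfig(list(nShapes = length(ids)))
        0L
      },
      "fit" = {
        dec <- loadDecoder(reqOpt(opts, "model"))
        pair <- readPairOpts(opts)
        fit <- fitLatent(dec, pair,
                         fitConfig(epochs = as.integer(opts$epochs %||% 300),
                                   nSurfacePoints = as.integer(opts$npoints %||% 4000)),
                         seed = seed)
        jsonlite::write_json(list(z = fit$z, bestLoss = fit$bestLoss,
                                  scale = fit$transform@scale,
                                  rotation = as.numeric(fit$transform@rotation),
                                  translation = fit$transform@translation),
                             file.path(out, "latent.json"), digits = NA)
        echoConfig(list(model = opts$model))
        0L
      },
      "reconstruct" = {
        dec <- loadDecoder(reqOpt(opts, "model"))
        lat <- jsonlite::read_json(reqOpt(opts, "latent"), simplifyVector = TRUE)
        tr <- SimilarityTransform(lat$scale, matrix(lat$rotation, 3, 3),
                                  lat$translation)
        rec <- reconstructPair(dec, lat$z, tr,
                               resolution = as.integer(opts$grid %||% 64))
        writeMesh(rec@bone, file.path(out, "recon_bone.ply"))
        writeMesh(rec@cartilage, file.path(out, "recon_cartilage.ply"))
        echoConfig(list(model = opts$model, latent = opts$latent))
        0L
      },
      "eval-recon" = {
        a <- readPairOpts(opts)
        b <- TriangleMeshPair(readMesh(reqOpt(opts, "bone2")),
                              readMesh(reqOpt(opts, "cartilage2")))
        res <- data.frame(surface = c("bone", "cartilage"),
                          assd = c(assd(a@bone, b@bone),
                                   assd(a@cartilage, b@cartilage)))
        write.csv(res, file.path(out, "assd.csv"), row.names = FALSE)
        echoConfig(list())
        0L
      },
      "biomarkers" = {
        pair <- readPairOpts(opts)
        reg <- assignRegions(pair@bone, regionAtlas())
        tm <- computeThickness(pair, regions = reg)
        write.csv(regionalMeans(tm, shapeId = opts$name %||% "shape"),
                  file.path(out, "biomarkers.csv"), row.names = FALSE)
        writeMesh(pair@bone, file.path(out, "bone_thickness.ply"),
                  vertexScalar = list(thickness = tm$thickness))
        echoConfig(list())
        0L
      },
      "eval-biomarkers" = {
        ref <- read.csv(reqOpt(opts, "reference"), check.names = FALSE)
        rec <- read.csv(reqOpt(opts, "reconstructed"), check.names = FALSE)
        err <- biomarkerErrors(ref, rec)
        write.csv(data.frame(region = names(err$rmse), rmse = err$rmse,
                             sdd = err$sdd),
                  file.path(out, "biomarker-errors.csv"), row.names = FALSE)
        echoConfig(list())
        0L
      },
      "train-classifier" = {
        lat <- read.csv(reqOpt(opts, "latents"))
        labs <- read.csv(reqOpt(opts, "labels"))
        task <- opts$task %||% "binary"
        X <- as.matrix(lat[, -1])
        y <- labs[[reqOpt(opts, "column")]][match(lat[[1]], labs$shapeId)]
        head <- trainClassifier(X, y, task,
                                classifierSpec(headType = opts$head %||% "logistic",
                                               depth = 2L, width = 64L,
                                               dropout = 0.2, lr = 1e-3,
                                               batchSize = 64L),
                                seed = seed)
        jsonlite::write_json(head$validation, file.path(out, "validation.json"),
                             auto_unbox = TRUE, digits = NA)
        echoConfig(list(task = task))
        0L
      },
      "evaluate" = {
        pred <- read.csv(reqOpt(opts, "predictions"))
        m <- classifierMetrics(pred$prediction, pred$label,
                               task = opts$task %||% "binary")
        jsonlite::write_json(m, file.path(out, "metrics.json"),
                             auto_unbox = TRUE, digits = NA)
        echoConfig(list())
        0L
      },
      "interpolate" = {
        za <- as.numeric(strsplit(reqOpt(opts, "za"), ",")[[1]])
        zb <- as.numeric(strsplit(reqOpt(opts, "zb"), ",")[[1]])
        Z <- interpolateLatents(za, zb, as.integer(opts$steps %||% 5))
        write.csv(Z, file.path(out, "latents.csv"), row.names = FALSE)
        echoConfig(list(steps = nrow(Z)))
        0L
      },
      { message("unknown command: ", cmd, "\n", usage); 1L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parseCliOpts <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    if (startsWith(args[i], "--")) {
      key <- sub("^--", "", args[i])
      if (i + 1 <= length(args) && !startsWith(args[i + 1], "--")) {
        opts[[key]] <- args[i + 1]
        i <- i + 2
      } else {
        opts[[key]] <- "true"
        i <- i + 1
      }
    } else stop("unknown argument: ", args[i])
  }
  opts
}

reqOpt <- function(opts, key) {
  if (is.null(opts[[key]])) stop("missing required option --", key)
  opts[[key]]
}

readPairOpts <- function(opts) {
  TriangleMeshPair(readMesh(reqOpt(opts, "bone")),
                   readMesh(reqOpt(opts, "cartilage")))
}

#' Save / load decoder checkpoints
#'
#' Weights are flattened to a little-endian float64 stream with a JSON
#' manifest (class, config, delta, weight shapes) at \code{<path>.json}.
#'
#' @param decoder a \linkS4class{ShapeDecoder}.
#' @param path binary output path.
#' @param extra extra manifest fields (seed, epoch, notes).
#' @export
saveDecoder <- function(decoder, path, extra = list()) {
  shapes <- list()
  flat <- numeric(0)
  walk <- function(w, prefix) {
    if (is.list(w)) {
      nms <- names(w) %||% seq_along(w)
      for (k in seq_along(w)) walk(w[[k]], paste0(prefix, "/", nms[k]))
    } else {
      shapes[[prefix]] <<- dim(w) %||% length(w)
      flat <<- c(flat, as.numeric(w))
    }
  }
  walk(decoder@weights, "")
  con <- file(path, "wb")
  writeBin(flat, con, size = 8, endian = "little")
  close(con)
  jsonlite::write_json(c(list(class = class(decoder), config = decoder@config,
                              delta = decoder@delta,
                              latentLen = decoder@latentLen, shapes = shapes),
                         extra),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveDecoder
#' @export
loadDecoder <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  cfg <- meta$config
  dec <- switch(meta$class,
    HybridDecoder = hybridDecoder(cfg$latentLen, cfg$nDeconv, cfg$channels,
                                  cfg$planeFeatures, cfg$trunkWidth,
                                  meta$delta),
    MLPDecoder = mlpDecoder(cfg$latentLen, cfg$width, meta$delta),
    MPADecoder = mpaDecoder(cfg$latentLen, cfg$width, cfg$depth, meta$delta,
                            cfg$omega0),
    stop("unknown decoder class in manifest"))
  con <- file(path, "rb")
  flat <- readBin(con, "numeric", n = file.info(path)$size / 8, size = 8,
                  endian = "little")
  close(con)
  pos <- 0
  fill <- function(w) {
    if (is.list(w)) return(lapply(w, fill))
    n <- length(w)
    out <- flat[(pos + 1):(pos + n)]
    pos <<- pos + n
    if (!is.null(dim(w))) dim(out) <- dim(w)
    out
  }
  dec@weights <- fill(dec@weights)
  if (pos != length(flat)) stop("checkpoint size mismatch")
  dec
}
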