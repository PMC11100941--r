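#' @title Core S4 classes
#' @name NeuralSDF-classes
#' @description S4 containers for triangle meshes, mesh pairs, similarity
#'   transforms, SDF grids, SDF training samples and latent codebooks.
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Triangle surface mesh
#'
#' A triangulated surface with an \code{n x 3} vertex matrix (columns x, y, z)
#' and an \code{m x 3} integer face matrix of 1-based vertex indices. Faces
#' are assumed consistently oriented with outward normals (signed volume > 0)
#' whenever the mesh is used for signed-distance queries.
#'
#' @slot vertices numeric matrix, one row per vertex.
#' @slot faces integer matrix, one row per triangle.
#' @export
setClass("TriangleMesh",
  representation(vertices = "matrix", faces = "matrix"),
  validity = function(object) {
    v <- object@vertices; f <- object@faces
    if (ncol(v) != 3) return("vertices must have 3 columns")
    if (nrow(f) > 0 && ncol(f) != 3) return("faces must have 3 columns")
    if (any(!is.finite(v))) return("vertex coordinates must be finite")
    if (nrow(f) > 0) {
      if (any(f < 1) || any(f > nrow(v))) return("face indices out of range")
      if (any(f != round(f))) return("face indices must be integral")
    }
    TRUE
  })

#' @param vertices numeric matrix (n x 3) of vertex coordinates.
#' @param faces matrix (m x 3) of 1-based vertex indices.
#' @return A \linkS4class{TriangleMesh}.
#' @rdname TriangleMesh-class
#' @export
TriangleMesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(vertices) <- "double"
  storage.mode(faces) <- "integer"
  new("TriangleMesh", vertices = vertices, faces = faces)
}

#' Paired bone and cartilage meshes in one coordinate frame
#'
#' @slot bone,cartilage \linkS4class{TriangleMesh} objects sharing a frame.
#' @slot frameId label of the coordinate frame (e.g. "native", "normalized").
#' @export
setClass("TriangleMeshPair",
  representation(bone = "TriangleMesh", cartilage = "TriangleMesh",
                 frameId = "character"))

#' @param bone,cartilage \linkS4class{TriangleMesh} objects.
#' @param frameId character frame label.
#' @rdname TriangleMeshPair-class
#' @export
TriangleMeshPair <- function(bone, cartilage, frameId = "native") {
  new("TriangleMeshPair", bone = bone, cartilage = cartilage, frameId = frameId)
}

#' Similarity transform (rigid + isotropic scale)
#'
#' Maps x to \code{scale * rotation \%*\% x + translation}.
#'
#' @slot scale positive scalar.
#' @slot rotation 3 x 3 rotation matrix, det = +1.
#' @slot translation length-3 numeric.
#' @export
setClass("SimilarityTransform",
  representation(scale = "numeric", rotation = "matrix", translation = "numeric"),
  validity = function(object) {
    if (length(object@scale) != 1 || object@scale <= 0) return("scale must be a positive scalar")
    R <- object@rotation
    if (!all(dim(R) == c(3, 3))) return("rotation must be 3x3")
    if (max(abs(crossprod(R) - diag(3))) > 1e-6) return("rotation must be orthonormal")
    if (abs(det(R) - 1) > 1e-6) return("rotation must have det +1")
    if (length(object@translation) != 3) return("translation must have length 3")
    TRUE
  })

#' @param scale positive scalar.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 numeric.
#' @rdname SimilarityTransform-class
#' @export
SimilarityTransform <- function(scale = 1, rotation = diag(3), translation = c(0, 0, 0)) {
  new("SimilarityTransform", scale = as.numeric(scale), rotation = rotation,
      translation = as.numeric(translation))
}

#' Identity similarity transform
#' @return A \linkS4class{SimilarityTransform} with scale 1, identity rotation,
#'   zero translation.
#' @export
identityTransform <- function() SimilarityTransform()

#' Signed-distance grid
#'
#' Signed distances sampled on a regular grid over an axis-aligned cube
#' \code{[extent[1], extent[2]]^3}; \code{values} is a
#' \code{resolution^3} array, x index fastest. Node spacing is
#' \code{diff(extent) / (resolution - 1)}.
#'
#' @slot resolution integer samples per axis.
#' @slot extent numeric length-2 cube bounds.
#' @slot values numeric array of signed distances.
#' @export
setClass("SDFGrid",
  representation(resolution = "integer", extent = "numeric", values = "array"),
  validity = function(object) {
    if (object@resolution < 2) return("resolution must be >= 2")
    if (length(object@extent) != 2 || diff(object@extent) <= 0)
      return("extent must be increasing length-2 bounds")
    if (length(object@values) != object@resolution^3)
      return("values length must equal resolution^3")
    if (any(!is.finite(object@values))) return("grid values must be finite")
    TRUE
  })

#' @param values numeric vector/array of length resolution^3 (x fastest).
#' @param resolution samples per axis.
#' @param extent cube bounds, default the unit cube [-1, 1]^3.
#' @rdname SDFGrid-class
#' @export
SDFGrid <- function(values, resolution, extent = c(-1, 1)) {
  new("SDFGrid", resolution = as.integer(resolution), extent = as.numeric(extent),
      values = array(as.numeric(values), dim = rep(as.integer(resolution), 3)))
}

#' SDF training samples for one shape/surface
#'
#' Point coordinates in the normalized frame with signed distances stored
#' against both surfaces of the pair (the surface the set was sampled around
#' is \code{surfaceId}), plus a provenance tag per point:
#' 1 = surface-perturbed small sigma, 2 = surface-perturbed large sigma,
#' 3 = uniform in the cube.
#'
#' @slot shapeId shape identifier.
#' @slot surfaceId "bone" or "cartilage".
#' @slot coords n x 3 point matrix.
#' @slot sBone,sCartilage signed distances of each point to either mesh.
#' @slot provenance integer tag per point.
#' @export
setClass("SDFSampleSet",
  representation(shapeId = "character", surfaceId = "character",
                 coords = "matrix", sBone = "numeric", sCartilage = "numeric",
                 provenance = "integer"),
  validity = function(object) {
    n <- nrow(object@coords)
    if (length(object@sBone) != n || length(object@sCartilage) != n ||
        length(object@provenance) != n)
      return("coords, distances and provenance must agree in length")
    if (!object@surfaceId %in% c("bone", "cartilage"))
      return("surfaceId must be 'bone' or 'cartilage'")
    TRUE
  })

#' @param shapeId,surfaceId identifiers.
#' @param coords n x 3 matrix of points.
#' @param sBone,sCartilage per-point signed distances to the two meshes.
#' @param provenance integer per-point tag (1, 2 or 3).
#' @rdname SDFSampleSet-class
#' @export
SDFSampleSet <- function(shapeId, surfaceId, coords, sBone, sCartilage, provenance) {
  new("SDFSampleSet", shapeId = as.character(shapeId),
      surfaceId = as.character(surfaceId), coords = as.matrix(coords),
      sBone = as.numeric(sBone), sCartilage = as.numeric(sCartilage),
      provenance = as.integer(provenance))
}

#' Latent codebook: one trainable latent vector per training shape
#'
#' @slot latents numeric matrix, one row per shape.
#' @slot shapeIds character row labels.
#' @export
setClass("LatentCodebook",
  representation(latents = "matrix", shapeIds = "character"),
  validity = function(object) {
    if (nrow(object@latents) != length(object@shapeIds))
      return("one shapeId per latent row required")
    if (any(!is.finite(object@latents))) return("latents must be finite")
    TRUE
  })

#' @param latents numeric matrix of latent codes (rows = shapes).
#' @param shapeIds character identifiers, one per row.
#' @rdname LatentCodebook-class
#' @export
LatentCodebook <- function(latents, shapeIds) {
  latents <- as.matrix(latents)
  rownames(latents) <- shapeIds
  new("LatentCodebook", latents = latents, shapeIds = as.character(shapeIds))
}

#' Shape decoder base class
#'
#' Virtual parent of the three decoder families. All decoders map a latent
#' vector z plus 3D coordinates to two signed distances (bone, cartilage),
#' bounded to \code{[-delta, delta]} by a scaled tanh output, where delta is
#' the clamp bound used during training.
#'
#' @slot config named list of architecture hyperparameters.
#' @slot weights named list of weight arrays.
#' @slot latentLen latent vector length.
#' @slot delta clamp bound (tanh output scale).
#' @export
setClass("ShapeDecoder",
  representation(config = "list", weights = "list",
                 latentLen = "integer", delta = "numeric", "VIRTUAL"))

#' @rdname ShapeDecoder-class
#' @export
setClass("HybridDecoder", contains = "ShapeDecoder")
#' @rdname ShapeDecoder-class
#' @export
setClass("MLPDecoder", contains = "ShapeDecoder")
#' @rdname ShapeDecoder-class
#' @export
setClass("MPADecoder", contains = "ShapeDecoder")

# ---- show methods ----------------------------------------------------------

setMethod("show", "TriangleMesh", function(object) {
  cat(sprintf("TriangleMesh: %d vertices, %d faces\n",
              nrow(object@vertices), nrow(object@faces)))
})

setMethod("show", "TriangleMeshPair", function(object) {
  cat(sprintf("TriangleMeshPair [frame '%s']\n  bone:      %d vertices, %d faces\n  cartilage: %d vertices, %d faces\n",
              object@frameId,
              nrow(object@bone@vertices), nrow(object@bone@faces),
              nrow(object@cartilage@vertices), nrow(object@cartilage@faces)))
})

setMethod("show", "SimilarityTransform", function(object) {
  cat(sprintf("SimilarityTransform: scale %.6g, translation (%.4g, %.4g, %.4g)\n",
              object@scale, object@translation[1], object@translation[2],
              object@translation[3]))
})

setMethod("show", "SDFGrid", function(object) {
  cat(sprintf("SDFGrid: %d^3 nodes over [%g, %g]^3 (spacing %.5g)\n",
              object@resolution, object@extent[1], object@extent[2],
              diff(object@extent) / (object@resolution - 1)))
})

setMethod("show", "SDFSampleSet", function(object) {
  tab <- tabulate(object@provenance, 3)
  cat(sprintf("SDFSampleSet '%s' (%s): %d points [perturbed-small %d, perturbed-large %d, uniform %d]\n",
              object@shapeId, object@surfaceId, nrow(object@coords),
              tab[1], tab[2], tab[3]))
})

setMethod("show", "LatentCodebook", function(object) {
  cat(sprintf("LatentCodebook: %d shapes x latent length %d\n",
              nrow(object@latents), ncol(object@latents)))
})

setMethod("show", "ShapeDecoder", function(object) {
  cat(sprintf("%s: latent length %d, clamp delta %g, %s parameters\n",
              class(object), object@latentLen, object@delta,
              format(paramCount(object), big.mark = ",")))
})

# ---- accessors -------------------------------------------------------------

#' Mesh accessors
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @return \code{meshVertices}/\code{meshFaces} return the raw matrices;
#'   \code{nVertices}/\code{nFaces} the counts; \code{meshArea} the total
#'   surface area; \code{meshVolume} the signed enclosed volume (positive for
#'   outward orientation).
#' @export
meshVertices <- function(mesh) mesh@vertices

#' @rdname meshVertices
#' @export
meshFaces <- function(mesh) mesh@faces

#' @rdname meshVertices
#' @export
nVertices <- function(mesh) nrow(mesh@vertices)

#' @rdname meshVertices
#' @export
nFaces <- function(mesh) nrow(mesh@faces)

#' @rdname meshVertices
#' @export
meshArea <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' @rdname meshVertices
#' @export
meshVolume <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  p1 <- v[f[, 1], , drop = FALSE]; p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) +
      p1[, 2] * (p2[, 3] * p3[, 1] - p2[, 1] * p3[, 3]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

#' Count edges not shared by exactly two faces
#'
#' Zero for a watertight (closed 2-manifold) mesh.
#' @param mesh a \linkS4class{TriangleMesh}.
#' @return integer count of open (boundary or non-manifold) edges.
#' @export
openEdgeCount <- function(mesh) {
  f <- mesh@faces
  if (nrow(f) == 0) return(0L)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  sum(tab != 2)
}

#' @rdname openEdgeCount
#' @export
isWatertight <- function(mesh) openEdgeCount(mesh) == 0L

#' Area-weighted outward vertex normals
#'
#' Face normals weighted by face area and accumulated per vertex, then
#' normalized; follows the stored face orientation.
#' @param mesh a \linkS4class{TriangleMesh}.
#' @return n x 3 matrix of unit normals.
#' @export
vertexNormals <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])  # 2*area-weighted
  idx <- c(f[, 1], f[, 2], f[, 3])
  acc <- rowsum(rbind(fn, fn, fn), idx)
  nrm <- matrix(0, nrow(v), 3)
  nrm[as.integer(rownames(acc)), ] <- acc
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm / len
}

#' Pair accessors
#' @param pair a \linkS4class{TriangleMeshPair}.
#' @export
pairBone <- function(pair) pair@bone

#' @rdname pairBone
#' @export
pairCartilage <- function(pair) pair@cartilage

#' @rdname pairBone
#' @export
pairFrameId <- function(pair) pair@frameId

#' Grid accessors
#' @param grid an \linkS4class{SDFGrid}.
#' @export
gridValues <- function(grid) grid@values

#' @rdname gridValues
#' @export
gridResolution <- function(grid) grid@resolution

#' @rdname gridValues
#' @export
gridExtent <- function(grid) grid@extent

#' @rdname gridValues
#' @export
gridSpacing <- function(grid) diff(grid@extent) / (grid@resolution - 1)

#' Sample-set accessors
#' @param x an \linkS4class{SDFSampleSet}.
#' @param surface which stored distances: "own" (the sampled surface),
#'   "bone" or "cartilage".
#' @export
sampleCoords <- function(x) x@coords

#' @rdname sampleCoords
#' @export
sampleDistances <- function(x, surface = c("own", "bone", "cartilage")) {
  surface <- match.arg(surface)
  if (surface == "own") surface <- x@surfaceId
  if (surface == "bone") x@sBone else x@sCartilage
}

#' @rdname sampleCoords
#' @export
sampleProvenance <- function(x) x@provenance

#' Codebook accessors
#' @param codebook a \linkS4class{LatentCodebook}.
#' @param shapeId optional shape identifier to extract one latent.
#' @export
codebookLatents <- function(codebook, shapeId = NULL) {
  if (is.null(shapeId)) return(codebook@latents)
  codebook@latents[match(shapeId, codebook@shapeIds), ]
}

#' @rdname codebookLatents
#' @export
codebookShapeIds <- function(codebook) codebook@shapeIds

#' Decoder accessors
#' @param decoder a \linkS4class{ShapeDecoder}.
#' @export
decoderConfig <- function(decoder) decoder@config

#' @rdname decoderConfig
#' @export
decoderWeights <- function(decoder) decoder@weights

#' @rdname decoderConfig
#' @export
decoderLatentLen <- function(decoder) decoder@latentLen

#' @rdname decoderConfig
#' @export
decoderDelta <- function(decoder) decoder@delta
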