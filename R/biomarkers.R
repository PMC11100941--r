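#' @title Cartilage thickness biomarkers
#' @name biomarkers
#' @description Per-vertex cartilage thickness over the bone surface by
#'   normal ray casting, angular-sector region assignment, regional mean
#'   thickness biomarkers, and RMSE/SDD agreement statistics between
#'   reference and reconstructed shapes.
NULL

.regionNames <- c("trochlea", "medial-central", "lateral-central",
                  "medial-posterior", "lateral-posterior")

#' Region names of the five-subregion thickness atlas
#' @export
regionNames <- function() .regionNames

#' Angular-sector region atlas
#'
#' Parameterizes the five femoral cartilage subregions for shapes in the
#' canonical pose used by the synthetic generator: the cartilage cap is
#' centered on \code{capAxis} (+z), the anterior direction is +x and the
#' medial side is y > 0. Sectors over the cap azimuth phi = atan2(y, x):
#' anterior (|phi| <= anteriorHalfWidth) is the trochlea, merged across
#' sides; central and posterior sectors split medial/lateral by sign(y).
#'
#' @param capAxis unit vector of the cartilage cap center.
#' @param capAngle cap polar half-angle (radians): vertices with polar angle
#'   beyond it are labeled "none".
#' @param anteriorHalfWidth azimuthal half-width of the trochlear sector.
#' @param centralEnd azimuth where central sectors end and posterior begin.
#' @export
regionAtlas <- function(capAxis = c(0, 0, 1), capAngle = 75 * pi / 180,
                        anteriorHalfWidth = 60 * pi / 180,
                        centralEnd = 120 * pi / 180) {
  structure(list(capAxis = capAxis / sqrt(sum(capAxis^2)), capAngle = capAngle,
                 anteriorHalfWidth = anteriorHalfWidth, centralEnd = centralEnd),
            class = "regionAtlas")
}

#' Per-vertex cartilage thickness by normal ray casting
#'
#' For each bone vertex a ray is cast along the outward vertex normal; when
#' it pierces the closed cartilage surface an even number (>= 2) of times
#' within \code{maxThickness}, the thickness is the distance between the
#' first and second intersections (entry to exit), otherwise 0. Degenerate
#' vertex normals are rebuilt by area-weighted face-normal averaging (the
#' default normal computation already does this).
#'
#' @param pair a \linkS4class{TriangleMeshPair} in a shared frame; the bone
#'   must be watertight.
#' @param maxThickness maximum plausible thickness (same units as vertices;
#'   10 mm by default).
#' @param regions optional per-vertex region labels to attach.
#' @return list of class "ThicknessMap": \code{thickness} (per bone vertex)
#'   and \code{region} (character labels, "none" where unassigned).
#' @export
computeThickness <- function(pair, maxThickness = 10, regions = NULL) {
  bone <- pair@bone
  if (nrow(pair@cartilage@faces) == 0) {
    th <- numeric(nVertices(bone))
  } else {
    nrm <- vertexNormals(bone)
    th <- cpp_ray_thickness(bone@vertices, nrm, pair@cartilage@vertices,
                            pair@cartilage@faces, maxThickness)
  }
  if (is.null(regions)) regions <- rep("none", nVertices(bone))
  structure(list(thickness = th, region = regions), class = "ThicknessMap")
}

#' Assign bone vertices to cartilage subregions
#'
#' Every vertex inside the atlas cap gets exactly one of the five region
#' labels; vertices outside the cap get "none". Labels partition by angular
#' sector (anterior/central/posterior) x side (medial/lateral) with the
#' anterior band merged across sides as "trochlea". Mirroring a shape about
#' the sagittal (y = 0) plane swaps medial and lateral labels.
#'
#' @param bone a \linkS4class{TriangleMesh} in the canonical pose (synthetic
#'   shapes are generated in it; for arbitrary real meshes supply per-vertex
#'   labels via \code{labels} instead).
#' @param atlas a \code{\link{regionAtlas}}; required unless labels given.
#' @param labels optional externally supplied per-vertex label vector.
#' @return character vector of per-vertex labels.
#' @export
assignRegions <- function(bone, atlas = NULL, labels = NULL) {
  if (!is.null(labels)) {
    if (length(labels) != nVertices(bone)) stop("label length mismatch")
    return(as.character(labels))
  }
  if (is.null(atlas)) stop("need either a region atlas or a per-vertex label file")
  v <- bone@vertices
  ctr <- colMeans(v)
  d <- sweep(v, 2, ctr)
  d <- d / sqrt(rowSums(d^2))
  polar <- acos(pmin(pmax(d %*% atlas$capAxis, -1), 1))
  phi <- atan2(d[, 2], d[, 1])          # azimuth about +z from +x (anterior)
  side <- ifelse(d[, 2] > 0, "medial", "lateral")
  lab <- rep("none", nrow(v))
  inCap <- polar <= atlas$capAngle
  aphi <- abs(phi)
  lab[inCap & aphi <= atlas$anteriorHalfWidth] <- "trochlea"
  cen <- inCap & aphi > atlas$anteriorHalfWidth & aphi <= atlas$centralEnd
  pos <- inCap & aphi > atlas$centralEnd
  lab[cen] <- paste0(side[cen], "-central")
  lab[pos] <- paste0(side[pos], "-posterior")
  lab
}

#' Regional mean-thickness biomarkers
#'
#' Arithmetic mean of per-vertex thickness over each region's vertices,
#' including zero-thickness vertices inside the region (full-thickness holes
#' pull the mean down); empty regions are reported as NA rather than 0.
#'
#' @param map a ThicknessMap from \code{\link{computeThickness}} (with
#'   region labels attached or supplied via \code{regions}).
#' @param regions optional label vector overriding the map's.
#' @param shapeId identifier for the output row.
#' @param includeZeros include zero-thickness vertices in the mean
#'   (default TRUE, the biomarker's hole-sensitivity convention).
#' @return one-row data.frame: shapeId plus one column per region.
#' @export
regionalMeans <- function(map, regions = NULL, shapeId = "shape",
                          includeZeros = TRUE) {
  lab <- regions %||% map$region
  out <- lapply(.regionNames, function(r) {
    sel <- lab == r
    if (!includeZeros) sel <- sel & map$thickness > 0
    if (!any(sel)) NA_real_ else mean(map$thickness[sel])
  })
  names(out) <- .regionNames
  cbind(data.frame(shapeId = shapeId, stringsAsFactors = FALSE),
        as.data.frame(out, check.names = FALSE))
}

#' RMSE and SDD between reference and reconstructed biomarker tables
#'
#' Per region, over matched shapes, with differences d = reconstructed -
#' reference: RMSE = sqrt(mean d^2) and SDD = population standard deviation
#' of d (removes systematic bias; RMSE^2 = mean(d)^2 + SDD^2). The "Average"
#' column is the mean over the five regions.
#'
#' @param reference,reconstructed data.frames as stacked rows of
#'   \code{\link{regionalMeans}} output, matched via shapeId.
#' @return list with \code{rmse} and \code{sdd}, each a named numeric with
#'   the five regions plus "Average".
#' @export
biomarkerErrors <- function(reference, reconstructed) {
  if (!setequal(reference$shapeId, reconstructed$shapeId))
    stop("shapeId sets differ between tables")
  reconstructed <- reconstructed[match(reference$shapeId, reconstructed$shapeId), ]
  rmse <- sdd <- setNames(numeric(length(.regionNames)), .regionNames)
  for (r in .regionNames) {
    d <- reconstructed[[r]] - reference[[r]]
    d <- d[is.finite(d)]
    rmse[r] <- sqrt(mean(d^2))
    sdd[r] <- sqrt(mean((d - mean(d))^2))
  }
  list(rmse = c(rmse, Average = mean(rmse)),
       sdd = c(sdd, Average = mean(sdd)))
}
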