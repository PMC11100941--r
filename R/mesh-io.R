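#' @title Mesh and array I/O
#' @name mesh-io
#' @description Readers/writers for PLY (ascii and binary little-endian),
#'   OBJ and STL surface files, plus portable binary containers with JSON
#'   sidecars for SDF grids and sample sets.
NULL

#' Read a triangle mesh from PLY, OBJ or STL
#'
#' The format is taken from the file extension (.ply, .obj, .stl). PLY
#' supports ascii and binary_little_endian with float/double vertex
#' properties; faces must be triangles. STL supports ascii and binary.
#'
#' @param path file path.
#' @return a \linkS4class{TriangleMesh}.
#' @export
readMesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = readPLY(path),
         obj = readOBJ(path),
         stl = readSTL(path),
         stop("unsupported mesh format: .", ext))
}

#' Write a triangle mesh to PLY, OBJ or STL
#'
#' @param mesh a \linkS4class{TriangleMesh}.
#' @param path output path; the extension selects the format.
#' @param binary use the binary variant where the format has one (PLY, STL).
#' @param vertexScalar optional named list of per-vertex numeric properties
#'   written as extra float properties (PLY only), e.g. a thickness map.
#' @return invisibly, \code{path}.
#' @export
writeMesh <- function(mesh, path, binary = FALSE, vertexScalar = NULL) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ply = writePLY(mesh, path, binary, vertexScalar),
         obj = writeOBJ(mesh, path),
         stl = writeSTL(mesh, path, binary),
         stop("unsupported mesh format: .", ext))
  invisible(path)
}

readPLY <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("unexpected end of PLY header")
    header <- c(header, line)
    if (trimws(line) == "end_header") break
  }
  fmtLine <- grep("^format", header, value = TRUE)[1]
  fmt <- strsplit(trimws(fmtLine), "\\s+")[[1]][2]
  elLines <- grep("^element", header)
  nVert <- nFace <- 0
  vertProps <- character(0)
  curEl <- ""
  for (ln in header) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tok[1] == "element") {
      curEl <- tok[2]
      if (curEl == "vertex") nVert <- as.integer(tok[3])
      if (curEl == "face") nFace <- as.integer(tok[3])
    } else if (tok[1] == "property" && curEl == "vertex") {
      vertProps <- c(vertProps, tok[length(tok)])
    }
  }
  np <- length(vertProps)
  if (fmt == "ascii") {
    dat <- scan(con, what = numeric(), n = nVert * np, quiet = TRUE)
    vm <- matrix(dat, ncol = np, byrow = TRUE)
    faces <- matrix(0L, nFace, 3)
    for (i in seq_len(nFace)) {
      row <- scan(con, what = integer(), nlines = 1, quiet = TRUE)
      if (row[1] != 3) stop("non-triangular face in PLY")
      faces[i, ] <- row[2:4] + 1L
    }
  } else if (fmt == "binary_little_endian") {
    # vertex properties assumed float32
    vm <- matrix(readBin(con, "numeric", n = nVert * np, size = 4,
                         endian = "little"), ncol = np, byrow = TRUE)
    faces <- matrix(0L, nFace, 3)
    for (i in seq_len(nFace)) {
      cnt <- readBin(con, "integer", n = 1, size = 1, signed = FALSE)
      if (cnt != 3) stop("non-triangular face in PLY")
      faces[i, ] <- readBin(con, "integer", n = 3, size = 4,
                            endian = "little") + 1L
    }
  } else stop("unsupported PLY format: ", fmt)
  ix <- match(c("x", "y", "z"), vertProps)
  mesh <- TriangleMesh(vm[, ix, drop = FALSE], faces)
  extra <- setdiff(vertProps, c("x", "y", "z"))
  if (length(extra)) {
    vs <- lapply(extra, function(p) vm[, match(p, vertProps)])
    names(vs) <- extra
    attr(mesh, "vertexScalar") <- vs
  }
  mesh
}

writePLY <- function(mesh, path, binary = FALSE, vertexScalar = NULL) {
  v <- mesh@vertices; f <- mesh@faces
  props <- c("x", "y", "z", names(vertexScalar))
  hdr <- c("ply",
           sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", nrow(v)),
           sprintf("property float %s", props),
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  vm <- v
  if (!is.null(vertexScalar))
    vm <- cbind(vm, do.call(cbind, vertexScalar))
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    writeBin(as.numeric(t(vm)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3), con)
      writeBin(as.integer(f[i, ] - 1L), con, size = 4, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(apply(format(vm, trim = TRUE, digits = 9), 1, paste, collapse = " "), con)
    writeLines(paste(3, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  }
  invisible(path)
}

readOBJ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  v <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  f <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"), function(x) {
    if (length(x) != 3) stop("non-triangular face in OBJ")
    as.integer(sub("/.*", "", x))
  }))
  TriangleMesh(v, f)
}

writeOBJ <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh@vertices; f <- mesh@faces
  writeLines(paste("v", format(v[, 1], trim = TRUE, digits = 9),
                   format(v[, 2], trim = TRUE, digits = 9),
                   format(v[, 3], trim = TRUE, digits = 9)), con)
  writeLines(paste("f", f[, 1], f[, 2], f[, 3]), con)
  invisible(path)
}

readSTL <- function(path) {
  # detect binary: 80-byte header then uint32 facet count matching file size
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  head80 <- readBin(con, "raw", n = 80)
  isBinary <- FALSE
  if (sz >= 84) {
    n <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    if (!is.na(n) && sz == 84 + 50 * as.double(n)) isBinary <- TRUE
  }
  if (isBinary) {
    nTri <- n
    tri <- matrix(0, nTri * 3, 3)
    for (i in seq_len(nTri)) {
      dat <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
      readBin(con, "raw", n = 2)
      tri[(3 * i - 2):(3 * i), ] <- matrix(dat[4:12], 3, 3, byrow = TRUE)
    }
  } else {
    close(con)
    on.exit()
    lines <- trimws(readLines(path, warn = FALSE))
    vl <- lines[startsWith(lines, "vertex")]
    tri <- do.call(rbind, lapply(strsplit(vl, "\\s+"),
                                 function(x) as.numeric(x[2:4])))
  }
  weldVertices(tri)
}

writeSTL <- function(mesh, path, binary = FALSE) {
  v <- mesh@vertices; f <- mesh@faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
               a[, 3] * b[, 1] - a[, 1] * b[, 3],
               a[, 1] * b[, 2] - a[, 2] * b[, 1])
  len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
  nrm <- nrm / len
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(nrm[i, ], t(v[f[i, ], ]))), con, size = 4,
               endian = "little")
      writeBin(raw(2), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf("facet normal %g %g %g", nrm[i, 1], nrm[i, 2], nrm[i, 3]), con)
      writeLines("  outer loop", con)
      for (k in 1:3)
        writeLines(sprintf("    vertex %g %g %g", v[f[i, k], 1], v[f[i, k], 2],
                           v[f[i, k], 3]), con)
      writeLines("  endloop", con)
      writeLines("endfacet", con)
    }
    writeLines("endsolid mesh", con)
  }
  invisible(path)
}

# merge exactly-coincident vertices of a triangle soup (3 rows per facet)
weldVertices <- function(tri) {
  key <- paste(tri[, 1], tri[, 2], tri[, 3])
  uk <- !duplicated(key)
  ids <- match(key, key[uk])
  TriangleMesh(tri[uk, , drop = FALSE],
               matrix(ids, ncol = 3, byrow = TRUE))
}

#' Persist an SDF grid as a binary array with a JSON sidecar
#'
#' Values are written as little-endian float32 (\code{<path>}), and
#' resolution/extent metadata as JSON (\code{<path>.json}).
#'
#' @param grid an \linkS4class{SDFGrid}.
#' @param path output path for the binary array.
#' @export
writeSDFGrid <- function(grid, path) {
  con <- file(path, "wb")
  writeBin(as.numeric(grid@values), con, size = 4, endian = "little")
  close(con)
  jsonlite::write_json(list(resolution = grid@resolution, extent = grid@extent,
                            dtype = "float32", order = "x-fastest"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSDFGrid
#' @export
readSDFGrid <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  vals <- readBin(con, "numeric", n = meta$resolution^3, size = 4, endian = "little")
  close(con)
  SDFGrid(vals, meta$resolution, meta$extent)
}

#' Persist / load an SDF sample set (float32 + JSON sidecar)
#'
#' @param samples an \linkS4class{SDFSampleSet}.
#' @param path binary output path; metadata goes to \code{<path>.json}.
#' @export
writeSampleSet <- function(samples, path) {
  con <- file(path, "wb")
  writeBin(as.numeric(t(samples@coords)), con, size = 4, endian = "little")
  writeBin(as.numeric(samples@sBone), con, size = 4, endian = "little")
  writeBin(as.numeric(samples@sCartilage), con, size = 4, endian = "little")
  writeBin(as.integer(samples@provenance), con, size = 1)
  close(con)
  jsonlite::write_json(list(shapeId = samples@shapeId, surfaceId = samples@surfaceId,
                            n = nrow(samples@coords), layout = "xyz*n,sBone,sCart,prov",
                            dtype = "float32/uint8"),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeSampleSet
#' @export
readSampleSet <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- meta$n
  con <- file(path, "rb")
  co <- matrix(readBin(con, "numeric", n = 3 * n, size = 4, endian = "little"),
               ncol = 3, byrow = TRUE)
  sb <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  sc <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  pv <- readBin(con, "integer", n = n, size = 1, signed = FALSE)
  close(con)
  SDFSampleSet(meta$shapeId, meta$surfaceId, co, sb, sc, pv)
}
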