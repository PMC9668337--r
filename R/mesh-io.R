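# Surface mesh readers/writers: FreeSurfer binary triangle format, OFF,
# PLY (ascii and binary little-endian). All on-disk index conventions are
# 0-based and converted to the package's 1-based convention on read.

FS_TRIANGLE_MAGIC <- c(255L, 255L, 254L)

.detectFormat <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 3L, size = 1L, signed = FALSE)
  if (length(magic) == 3L && all(magic == FS_TRIANGLE_MAGIC))
    return("freesurfer")
  head <- rawToChar(as.raw(magic))
  rest <- readBin(con, "raw", n = 16L)
  head <- paste0(head, rawToChar(rest[rest != as.raw(0)]))
  if (grepl("^ply", head, ignore.case = TRUE)) return("ply")
  if (grepl("^\\s*OFF", head)) return("off")
  stop("cannot detect mesh format of '", path, "'")
}

#' Read a triangle surface mesh
#'
#' Reads FreeSurfer binary triangle surfaces, OFF, or PLY (ascii or
#' binary little-endian) files. Faces must be triangles.
#'
#' @param path path to the surface file.
#' @param format one of "auto", "freesurfer", "off", "ply".
#' @return A \linkS4class{TriangleMesh} with 1-based face indices.
#' @seealso \code{\link{writeSurface}}, \code{\link{validateMesh}}
#' @export
readSurface <- function(path, format = c("auto", "freesurfer", "off", "ply")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- .detectFormat(path)
  mesh <- switch(format,
    freesurfer = .readFreeSurfer(path),
    off = .readOFF(path),
    ply = .readPLY(path))
  mesh@metadata$source <- path
  mesh@metadata$format <- format
  validObject(mesh)
  mesh
}

.readFreeSurfer <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 3L, size = 1L, signed = FALSE)
  if (!all(magic == FS_TRIANGLE_MAGIC))
    stop("not a FreeSurfer binary triangle surface: ", path)
  # creation comment is terminated by "\n\n"
  prev <- as.raw(0)
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0L) stop("truncated FreeSurfer surface: ", path)
    if (b == as.raw(10) && prev == as.raw(10)) break
    prev <- b
  }
  nv <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "big")
  if (is.na(nv) || is.na(nf) || nv <= 0L || nf <= 0L)
    stop("corrupt FreeSurfer surface header: ", path)
  v <- readBin(con, "numeric", n = 3L * nv, size = 4L, endian = "big")
  f <- readBin(con, "integer", n = 3L * nf, size = 4L, endian = "big")
  if (length(v) < 3L * nv || length(f) < 3L * nf)
    stop("truncated FreeSurfer surface: ", path)
  TriangleMesh(matrix(v, ncol = 3L, byrow = TRUE),
               matrix(f, ncol = 3L, byrow = TRUE) + 1L)
}

.readOFF <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines) || !grepl("^OFF", lines[[1]]))
    stop("not an OFF file: ", path)
  toks <- scan(text = paste(c(sub("^OFF", "", lines[[1]]), lines[-1]),
                            collapse = "\n"),
               what = numeric(), quiet = TRUE)
  nv <- as.integer(toks[1]); nf <- as.integer(toks[2])
  pos <- 4L  # skip edge count
  if (length(toks) < 3L + 3L * nv) stop("truncated OFF file: ", path)
  v <- matrix(toks[pos:(pos + 3L * nv - 1L)], ncol = 3L, byrow = TRUE)
  pos <- pos + 3L * nv
  faces <- matrix(NA_integer_, nf, 3L)
  for (i in seq_len(nf)) {
    if (pos > length(toks)) stop("truncated OFF face list: ", path)
    cnt <- as.integer(toks[pos])
    if (cnt != 3L)
      stop("non-triangular face (", cnt, " vertices) in OFF file: ", path)
    faces[i, ] <- as.integer(toks[(pos + 1L):(pos + 3L)])
    pos <- pos + 1L + cnt
  }
  TriangleMesh(v, faces + 1L)
}

.readPLY <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readHeaderLine <- function() {
    out <- raw(0)
    repeat {
      b <- readBin(con, "raw", n = 1L)
      if (length(b) == 0L) stop("truncated PLY header: ", path)
      if (b == as.raw(10)) break
      out <- c(out, b)
    }
    trimws(rawToChar(out[out != as.raw(13)]))
  }
  if (readHeaderLine() != "ply") stop("not a PLY file: ", path)
  fmt <- NULL; nv <- NULL; nf <- NULL
  elem <- NULL
  vprops <- character(0)
  faceIndexType <- "int32"; faceCountType <- "uint8"
  repeat {
    ln <- readHeaderLine()
    if (ln == "end_header") break
    t <- strsplit(ln, "\\s+")[[1]]
    if (t[1] == "format") fmt <- t[2]
    else if (t[1] == "element") {
      elem <- t[2]
      if (elem == "vertex") nv <- as.integer(t[3])
      if (elem == "face") nf <- as.integer(t[3])
    } else if (t[1] == "property" && identical(elem, "vertex")) {
      if (t[2] == "list") stop("list property on vertices unsupported")
      vprops <- c(vprops, t[3])
    } else if (t[1] == "property" && identical(elem, "face")) {
      if (t[2] != "list") stop("face element must use a list property")
      faceCountType <- t[3]; faceIndexType <- t[4]
    }
  }
  if (is.null(fmt) || is.null(nv) || is.null(nf))
    stop("incomplete PLY header: ", path)
  if (!all(c("x", "y", "z") %in% vprops))
    stop("PLY vertex element lacks x/y/z properties: ", path)
  ixyz <- match(c("x", "y", "z"), vprops)
  np <- length(vprops)
  if (fmt == "ascii") {
    toks <- scan(con, what = numeric(), quiet = TRUE)
    v <- matrix(toks[seq_len(np * nv)], ncol = np, byrow = TRUE)[, ixyz,
                                                                drop = FALSE]
    pos <- np * nv + 1L
    faces <- matrix(NA_integer_, nf, 3L)
    for (i in seq_len(nf)) {
      cnt <- as.integer(toks[pos])
      if (cnt != 3L) stop("non-triangular face in PLY file: ", path)
      faces[i, ] <- as.integer(toks[(pos + 1L):(pos + 3L)])
      pos <- pos + 1L + cnt
    }
  } else if (fmt == "binary_little_endian") {
    readType <- function(type, n) {
      switch(type,
        float = , float32 = readBin(con, "numeric", n, size = 4L,
                                    endian = "little"),
        double = , float64 = readBin(con, "numeric", n, size = 8L,
                                     endian = "little"),
        uchar = , uint8 = readBin(con, "integer", n, size = 1L,
                                  signed = FALSE, endian = "little"),
        char = , int8 = readBin(con, "integer", n, size = 1L,
                                endian = "little"),
        short = , int16 = readBin(con, "integer", n, size = 2L,
                                  endian = "little"),
        ushort = , uint16 = readBin(con, "integer", n, size = 2L,
                                    signed = FALSE, endian = "little"),
        int = , int32 = , uint = , uint32 = readBin(con, "integer", n,
                                                    size = 4L,
                                                    endian = "little"),
        stop("unsupported PLY type: ", type))
    }
    # vertex properties are assumed homogeneous float32 (the common case)
    vall <- readType("float32", np * nv)
    v <- matrix(vall, ncol = np, byrow = TRUE)[, ixyz, drop = FALSE]
    faces <- matrix(NA_integer_, nf, 3L)
    for (i in seq_len(nf)) {
      cnt <- readType(faceCountType, 1L)
      if (cnt != 3L) stop("non-triangular face in PLY file: ", path)
      faces[i, ] <- readType(faceIndexType, 3L)
    }
  } else stop("unsupported PLY format: ", fmt)
  TriangleMesh(v, faces + 1L)
}

#' Write a triangle surface mesh
#'
#' @param mesh a valid \linkS4class{TriangleMesh} with at least one face.
#' @param path output path.
#' @param format one of "off", "ply", "ply_binary", "freesurfer"; "auto"
#'   picks from the file extension (.off, .ply, anything else FreeSurfer).
#' @return The path, invisibly.
#' @seealso \code{\link{readSurface}}
#' @export
writeSurface <- function(mesh, path,
                         format = c("auto", "off", "ply", "ply_binary",
                                    "freesurfer")) {
  format <- match.arg(format)
  validObject(mesh)
  if (nFaces(mesh) == 0L || nVertices(mesh) == 0L)
    stop("refusing to write an empty mesh")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "off") "off" else if (ext == "ply") "ply"
              else "freesurfer"
  }
  switch(format,
    off = .writeOFF(mesh, path),
    ply = .writePLY(mesh, path, binary = FALSE),
    ply_binary = .writePLY(mesh, path, binary = TRUE),
    freesurfer = .writeFreeSurfer(mesh, path))
  invisible(path)
}

.writeOFF <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nVertices(mesh), nFaces(mesh)), con)
  writeLines(apply(mesh@vertices, 1L,
                   function(r) paste(format(r, digits = 17), collapse = " ")),
             con)
  writeLines(paste("3", mesh@faces[, 1] - 1L, mesh@faces[, 2] - 1L,
                   mesh@faces[, 3] - 1L), con)
}

.writePLY <- function(mesh, path, binary = FALSE) {
  nv <- nVertices(mesh); nf <- nFaces(mesh)
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else
             "format ascii 1.0",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(as.numeric(t(mesh@vertices)), con, size = 4L,
             endian = "little")
    f0 <- mesh@faces - 1L
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f0[i, ]), con, size = 4L, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(apply(mesh@vertices, 1L,
                     function(r) paste(format(r, digits = 9),
                                       collapse = " ")), con)
    writeLines(paste("3", mesh@faces[, 1] - 1L, mesh@faces[, 2] - 1L,
                     mesh@faces[, 3] - 1L), con)
  }
}

.writeFreeSurfer <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(FS_TRIANGLE_MAGIC), con)
  writeBin(charToRaw("created by shapeAsym\n\n"), con)
  writeBin(as.integer(nVertices(mesh)), con, size = 4L, endian = "big")
  writeBin(as.integer(nFaces(mesh)), con, size = 4L, endian = "big")
  writeBin(as.numeric(t(mesh@vertices)), con, size = 4L, endian = "big")
  writeBin(as.integer(t(mesh@faces - 1L)), con, size = 4L, endian = "big")
}

# ---- topology ----

.edgeKeys <- function(faces) {
  # directed edges per face: (1->2, 2->3, 3->1)
  from <- c(faces[, 1], faces[, 2], faces[, 3])
  to   <- c(faces[, 2], faces[, 3], faces[, 1])
  list(from = from, to = to,
       key = paste(pmin(from, to), pmax(from, to)))
}

#' @describeIn validateMesh checks closedness (every edge shared by exactly
#'   two faces), edge-manifoldness, global orientation consistency, and the
#'   genus from the Euler characteristic.
setMethod("validateMesh", "TriangleMesh", function(mesh) {
  f <- mesh@faces
  e <- .edgeKeys(f)
  cnt <- table(e$key)
  boundary <- names(cnt)[cnt == 1L]
  nonmanifold <- names(cnt)[cnt > 2L]
  closed <- length(boundary) == 0L && length(nonmanifold) == 0L
  manifold <- length(nonmanifold) == 0L
  # orientation: for a consistently wound closed mesh every undirected edge
  # appears exactly once in each direction
  dirKey <- paste(e$from, e$to)
  oriented <- closed && !anyDuplicated(dirKey)
  nE <- length(cnt)
  chi <- nVertices(mesh) - nE + nrow(f)
  genus <- if (closed && manifold) as.integer((2L - chi) / 2L) else NA_integer_
  parse2 <- function(keys) {
    if (!length(keys)) return(matrix(integer(0), 0, 2))
    do.call(rbind, lapply(strsplit(keys, " "), as.integer))
  }
  list(closed = closed, manifold = manifold, oriented = oriented,
       genus = genus, euler = chi,
       boundary_edges = parse2(boundary),
       nonmanifold_edges = parse2(nonmanifold))
})

#' Repair face orientation
#'
#' Makes the winding of all faces globally consistent by propagating
#' orientation across shared edges, then flips the whole mesh if its
#' signed volume is negative, so that normals point outward. Emits a
#' warning when any face had to be flipped.
#'
#' @param mesh a closed manifold \linkS4class{TriangleMesh}.
#' @return The repaired mesh.
#' @export
repairOrientation <- function(mesh) {
  f <- mesh@faces
  nf <- nrow(f)
  if (nf == 0L) return(mesh)
  # fast path: winding already globally consistent
  ek <- .edgeKeys(f)
  if (!anyDuplicated(paste(ek$from, ek$to))) {
    if (.signedVolume(mesh) < 0) {
      mesh@faces <- f[, c(1L, 3L, 2L)]
      warning("repairOrientation: flipped all ", nf,
              " faces (inward normals)")
    }
    return(mesh)
  }
  e <- ek
  faceOfEdge <- rep(seq_len(nf), 3L)
  byKey <- split(seq_along(e$key), e$key)
  flipped <- rep(FALSE, nf)
  visited <- rep(FALSE, nf)
  nflip <- 0L
  for (seed in seq_len(nf)) {
    if (visited[seed]) next
    queue <- seed; visited[seed] <- TRUE
    while (length(queue)) {
      fi <- queue[[1]]; queue <- queue[-1]
      slots <- c(fi, fi + nf, fi + 2L * nf)
      for (s in slots) {
        mates <- byKey[[e$key[s]]]
        mates <- mates[faceOfEdge[mates] != fi]
        for (m in mates) {
          fj <- faceOfEdge[m]
          if (visited[fj]) next
          # consistent winding <=> the shared edge runs in opposite
          # directions on the two faces (after applying flips)
          efrom_s <- if (flipped[fi]) e$to[s] else e$from[s]
          flipped[fj] <- efrom_s == e$from[m]
          if (flipped[fj]) nflip <- nflip + 1L
          visited[fj] <- TRUE
          queue <- c(queue, fj)
        }
      }
    }
  }
  if (any(flipped)) {
    f[flipped, ] <- f[flipped, c(1L, 3L, 2L)]
    mesh@faces <- f
  }
  vol <- .signedVolume(mesh)
  if (vol < 0) {
    mesh@faces <- mesh@faces[, c(1L, 3L, 2L)]
    nflip <- nf
  }
  if (nflip > 0L)
    warning("repairOrientation: flipped ", nflip, " face(s)")
  mesh
}

.signedVolume <- function(mesh) {
  v <- mesh@vertices; f <- mesh@faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}
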