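# PLY and STL mesh interchange, ASCII and binary dialects.  Units are
# millimetres throughout.  Writers emit a minimal conforming subset
# (triangular faces; PLY vertices at double precision so round trips are
# lossless, binary STL at the format's fixed float32); readers accept that
# subset and fail loudly, naming the file, on anything malformed.

#' Write a mesh as PLY
#'
#' @param mesh a `grip_mesh`.
#' @param path output file path.
#' @param binary write `binary_little_endian` (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path, binary = TRUE) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           sprintf("element vertex %d", nv),
           "property double x", "property double y", "property double z",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(as.numeric(t(mesh$vertices)), con, size = 8, endian = "little")
    f0 <- t(mesh$faces) - 1L
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f0[, i]), con, size = 4, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(apply(mesh$vertices, 1, function(v)
      paste(formatC(v, format = "g", digits = 17), collapse = " ")), con)
    writeLines(apply(mesh$faces - 1L, 1, function(f)
      paste(c(3L, f), collapse = " ")), con)
  }
  invisible(path)
}

#' Read a PLY mesh
#'
#' @param path file path.
#' @return A [grip_mesh()].
#' @export
read_ply <- function(path) {
  fail <- function(what) stop(sprintf("format error in PLY file '%s': %s", path, what))
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, 1)
    if (length(line) == 0) fail("unterminated header")
    hdr <- c(hdr, line)
    if (line == "end_header") break
    if (length(hdr) > 100) fail("header too long")
  }
  if (hdr[1] != "ply") fail("missing 'ply' magic")
  fmt <- grep("^format ", hdr, value = TRUE)
  if (length(fmt) != 1) fail("missing format line")
  binary <- grepl("binary_little_endian", fmt)
  if (!binary && !grepl("ascii", fmt)) fail("unsupported format dialect")
  nv <- suppressWarnings(as.integer(sub("element vertex ", "",
                                        grep("^element vertex ", hdr, value = TRUE))))
  nf <- suppressWarnings(as.integer(sub("element face ", "",
                                        grep("^element face ", hdr, value = TRUE))))
  if (length(nv) != 1 || is.na(nv) || length(nf) != 1 || is.na(nf))
    fail("missing element counts")
  vsize <- if (any(grepl("^property double", hdr))) 8L else 4L
  if (binary) {
    verts <- readBin(con, numeric(), n = 3 * nv, size = vsize, endian = "little")
    if (length(verts) != 3 * nv) fail("truncated vertex data")
    V <- matrix(verts, ncol = 3, byrow = TRUE)
    F_ <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- readBin(con, integer(), 1, size = 1, signed = FALSE)
      if (length(cnt) == 0 || cnt != 3) fail(sprintf("face %d is not a triangle", i))
      idx <- readBin(con, integer(), 3, size = 4, endian = "little")
      if (length(idx) != 3) fail(sprintf("truncated face %d", i))
      F_[i, ] <- idx + 1L
    }
  } else {
    txt <- readLines(con)
    if (length(txt) < nv + nf) fail("truncated body")
    V <- do.call(rbind, lapply(txt[seq_len(nv)], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3])))
    if (any(is.na(V))) fail("non-numeric vertex line")
    F_ <- do.call(rbind, lapply(txt[nv + seq_len(nf)], function(l) {
      x <- as.integer(strsplit(trimws(l), "\\s+")[[1]])
      if (is.na(x[1]) || x[1] != 3) fail("non-triangular face")
      x[2:4] + 1L
    }))
  }
  grip_mesh(V, F_)
}

face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  n / pmax(len, 1e-30)
}

#' Write a mesh as STL
#'
#' @param mesh a `grip_mesh`.
#' @param path output file path.
#' @param binary write binary STL (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  nrm <- face_normals(mesh)
  f <- mesh$faces; v <- mesh$vertices
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw(formatC("gripangle binary STL", width = 80, flag = "-")), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(nrm[i, ], t(v[f[i, ], ]))), con, size = 4,
               endian = "little")
      writeBin(as.raw(c(0, 0)), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid gripangle", con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf("  facet normal %g %g %g", nrm[i, 1], nrm[i, 2], nrm[i, 3]), con)
      writeLines("    outer loop", con)
      for (k in 1:3) {
        p <- v[f[i, k], ]
        writeLines(sprintf("      vertex %.17g %.17g %.17g", p[1], p[2], p[3]), con)
      }
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines("endsolid gripangle", con)
  }
  invisible(path)
}

#' Read an STL mesh
#'
#' Duplicate vertices shared by neighbouring facets are merged exactly, so a
#' watertight mesh survives an STL round trip.
#'
#' @param path file path.
#' @return A [grip_mesh()].
#' @export
read_stl <- function(path) {
  fail <- function(what) stop(sprintf("format error in STL file '%s': %s", path, what))
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  head5 <- rawToChar(readBin(con, raw(), 5))
  seek(con, 0)
  tris <- NULL
  if (identical(head5, "solid") && {
    txt <- tryCatch(suppressWarnings(readLines(path, warn = FALSE)),
                    error = function(e) NULL)
    !is.null(txt) && any(grepl("facet normal", txt))
  }) {
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (length(vl) == 0 || length(vl) %% 3 != 0) fail("vertex count not a multiple of 3")
    tris <- do.call(rbind, lapply(vl, function(l) {
      x <- as.numeric(strsplit(trimws(l), "\\s+")[[1]][2:4])
      if (any(is.na(x))) fail("non-numeric vertex line")
      x
    }))
  } else {
    readBin(con, raw(), 80)
    nf <- readBin(con, integer(), 1, size = 4, endian = "little")
    if (is.na(nf) || nf <= 0 || 84 + nf * 50 != sz) fail("bad triangle count/size")
    tris <- matrix(0, nf * 3, 3)
    for (i in seq_len(nf)) {
      vals <- readBin(con, numeric(), 12, size = 4, endian = "little")
      if (length(vals) != 12) fail(sprintf("truncated facet %d", i))
      readBin(con, raw(), 2)
      tris[(i - 1) * 3 + 1:3, ] <- matrix(vals[4:12], 3, byrow = TRUE)
    }
  }
  key <- apply(tris, 1, paste, collapse = ",")
  uk <- unique(key)
  V <- tris[match(uk, key), , drop = FALSE]
  F_ <- matrix(match(key, uk), ncol = 3, byrow = TRUE)
  grip_mesh(V, F_)
}
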