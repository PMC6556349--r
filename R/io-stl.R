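# STL exchange. STL carries no units; this package reads and writes STL in
# millimetres throughout, converting to cm^2 / cm^3 only at reporting time.

float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4, endian = "little"),
          "numeric", size = 4, n = length(x), endian = "little")
}

# per-triangle unit normals from (already float32-quantized) vertices
stl_normals <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  e1 <- vertices[triangles[, 2], , drop = FALSE] - a
  e2 <- vertices[triangles[, 3], , drop = FALSE] - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

#' Write a triangle mesh to STL
#'
#' Emits a canonical file: vertices are quantized to 32-bit floats before
#' facet normals are computed from them, so `write -> read -> write`
#' reproduces the first file byte for byte.
#'
#' @param mesh A [triangle_mesh()].
#' @param path Output file path.
#' @param binary Write the binary dialect (default) or ASCII.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, binary = TRUE) {
  if (!inherits(mesh, "laa_mesh")) stop("`mesh` must be a laa_mesh", call. = FALSE)
  nt <- nrow(mesh$triangles)
  if (nt == 0L) stop("refusing to write an empty mesh", call. = FALSE)
  v <- matrix(float32(mesh$vertices), ncol = 3)
  tr <- mesh$triangles
  nrm <- matrix(float32(stl_normals(v, tr)), ncol = 3)
  # 12 floats per facet: normal, v1, v2, v3
  facets <- t(cbind(nrm, v[tr[, 1], , drop = FALSE], v[tr[, 2], , drop = FALSE],
                    v[tr[, 3], , drop = FALSE]))
  if (binary) {
    hdr <- charToRaw(formatC("laa3d binary STL", width = -80))
    fl <- writeBin(as.numeric(facets), raw(), size = 4, endian = "little")
    recs <- rbind(matrix(fl, nrow = 48L), matrix(as.raw(0), nrow = 2L, ncol = nt))
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(hdr, con)
    writeBin(as.integer(nt), con, size = 4, endian = "little")
    writeBin(as.vector(recs), con)
  } else {
    num <- function(x) sprintf("%.9g", x)
    lines <- character(2 + 7 * nt)
    lines[1] <- "solid laa3d"
    for (t in seq_len(nt)) {
      b <- 1 + (t - 1) * 7
      f <- facets[, t]
      lines[b + 1] <- paste("facet normal", num(f[1]), num(f[2]), num(f[3]))
      lines[b + 2] <- "  outer loop"
      lines[b + 3] <- paste("    vertex", num(f[4]), num(f[5]), num(f[6]))
      lines[b + 4] <- paste("    vertex", num(f[7]), num(f[8]), num(f[9]))
      lines[b + 5] <- paste("    vertex", num(f[10]), num(f[11]), num(f[12]))
      lines[b + 6] <- "  endloop"
      lines[b + 7] <- "endfacet"
    }
    lines[length(lines)] <- "endsolid laa3d"
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read an STL file (binary or ASCII)
#'
#' Facet vertices duplicated across triangles are merged by exact coordinate
#' match, in order of first appearance.
#'
#' @param path Path to an STL file.
#' @return A [triangle_mesh()].
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("cannot read STL: no such file ", path, call. = FALSE)
  sz <- file.size(path)
  head_raw <- readBin(path, raw(), n = min(sz, 1024))
  printable <- head_raw >= as.raw(0x20) & head_raw < as.raw(0x7f) |
    head_raw %in% as.raw(c(9L, 10L, 13L))
  head_txt <- rawToChar(head_raw[printable])
  ascii <- grepl("^\\s*solid", head_txt, useBytes = TRUE) &&
    grepl("facet", head_txt, useBytes = TRUE)
  pts <- if (ascii) read_stl_ascii(path) else read_stl_binary(path, sz)
  if (nrow(pts) == 0L || nrow(pts) %% 3L != 0L)
    stop("not a valid STL file: ", path, call. = FALSE)
  key <- paste(sprintf("%a", pts[, 1]), sprintf("%a", pts[, 2]),
               sprintf("%a", pts[, 3]))
  vid <- match(key, key)                       # first-occurrence id per point
  keep <- !duplicated(vid)
  verts <- pts[keep, , drop = FALSE]
  vid <- match(vid, which(keep))               # compact 1..n in appearance order
  tris <- matrix(vid, ncol = 3, byrow = TRUE)
  triangle_mesh(verts, tris)
}

read_stl_binary <- function(path, sz) {
  if (sz < 84) stop("not a valid STL file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, raw(), n = 80))
  nt <- readBin(con, "integer", size = 4, endian = "little")
  if (nt < 1 || sz != 84 + 50 * as.numeric(nt))
    stop("not a valid STL file: ", path, call. = FALSE)
  body <- readBin(con, raw(), n = 50 * nt)
  recs <- matrix(body, nrow = 50L)
  fl <- readBin(as.vector(recs[1:48, , drop = FALSE]), "numeric", size = 4,
                n = 12L * nt, endian = "little")
  f <- matrix(fl, nrow = 12L)
  pts <- matrix(0, nrow = 3L * nt, ncol = 3L)
  pts[seq(1, 3 * nt, by = 3), ] <- t(f[4:6, , drop = FALSE])
  pts[seq(2, 3 * nt, by = 3), ] <- t(f[7:9, , drop = FALSE])
  pts[seq(3, 3 * nt, by = 3), ] <- t(f[10:12, , drop = FALSE])
  pts
}

read_stl_ascii <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE)
  at <- which(toks == "vertex")
  if (!length(at) || max(at) + 3 > length(toks))
    stop("not a valid STL file: ", path, call. = FALSE)
  xyz <- suppressWarnings(vapply(1:3, function(o) as.numeric(toks[at + o]),
                                 numeric(length(at))))
  xyz <- matrix(xyz, ncol = 3)
  if (any(!is.finite(xyz))) stop("not a valid STL file: ", path, call. = FALSE)
  xyz
}
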