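# Fixture builders shared across test files. Everything is generated in code
# at test time; no binary fixtures are stored.

# digitized solid sphere mask on a voxel-centre grid
sphere_mask <- function(radius = 15, spacing = c(0.419, 0.419, 1), pad = 2,
                        center = c(0, 0, 0)) {
  half <- radius + pad
  ax <- lapply(1:3, function(d) seq(-half + spacing[d] / 2, half, by = spacing[d]))
  nx <- length(ax[[1]]); ny <- length(ax[[2]]); nz <- length(ax[[3]])
  dx2 <- (ax[[1]] - center[1])^2
  dy2 <- (ax[[2]] - center[2])^2
  dz2 <- (ax[[3]] - center[3])^2
  ind <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius^2
  binary_mask(array(ind, dim = c(nx, ny, nz)), spacing = spacing,
              origin = c(ax[[1]][1], ax[[2]][1], ax[[3]][1]))
}

# independent breadth-first flood fill (R reference for component selection)
bfs_flood <- function(mask, seed_ijk) {
  dims <- dim(mask)
  visited <- array(FALSE, dims)
  queue <- list(seed_ijk)
  visited[seed_ijk[1], seed_ijk[2], seed_ijk[3]] <- TRUE
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    for (r in seq_len(nrow(offs))) {
      nb <- cur + offs[r, ]
      if (any(nb < 1) || any(nb > dims)) next
      if (mask[nb[1], nb[2], nb[3]] && !visited[nb[1], nb[2], nb[3]]) {
        visited[nb[1], nb[2], nb[3]] <- TRUE
        queue[[length(queue) + 1]] <- nb
      }
    }
  }
  visited
}

# brute-force Otsu: exhaustive search over all histogram cut points
otsu_brute <- function(x, bins = 256) {
  edges <- seq(min(x), max(x), length.out = bins + 1)
  idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = bins)
  mids <- (edges[-1] + edges[-(bins + 1)]) / 2
  best <- -Inf; best_t <- NA
  for (t in 1:(bins - 1)) {
    w1 <- sum(counts[1:t]); w2 <- sum(counts) - w1
    if (w1 == 0 || w2 == 0) next
    mu1 <- sum(counts[1:t] * mids[1:t]) / w1
    mu2 <- sum(counts[(t + 1):bins] * mids[(t + 1):bins]) / w2
    v <- w1 * w2 * (mu1 - mu2)^2
    if (v > best) { best <- v; best_t <- edges[t + 1] }
  }
  best_t
}

# --- minimal DICOM writer (explicit VR little endian) for reader tests ----

dcm_el <- function(group, elem, vr, value) {
  raw_val <- switch(vr,
    US = writeBin(as.integer(value), raw(), size = 2, endian = "little"),
    IS = ,
    DS = {
      s <- paste(format(value, trim = TRUE, scientific = FALSE), collapse = "\\")
      if (nchar(s) %% 2 == 1) s <- paste0(s, " ")
      charToRaw(s)
    },
    UI = {
      v <- charToRaw(value)
      if (length(v) %% 2 == 1) v <- c(v, as.raw(0))
      v
    },
    OW = value)
  hdr <- writeBin(as.integer(c(group, elem)), raw(), size = 2, endian = "little")
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(hdr, charToRaw(vr), as.raw(c(0, 0)),
      writeBin(length(raw_val), raw(), size = 4, endian = "little"), raw_val)
  } else {
    c(hdr, charToRaw(vr),
      writeBin(length(raw_val), raw(), size = 2, endian = "little"), raw_val)
  }
}

# write one single-frame CT-like slice; pixels is a rows x cols integer matrix
write_dicom_slice <- function(path, pixels, ipp, pixel_spacing = c(0.5, 0.5),
                              iop = c(1, 0, 0, 0, 1, 0)) {
  rows <- nrow(pixels); cols <- ncol(pixels)
  # pixel data in row-major order
  pix <- writeBin(as.integer(t(pixels)), raw(), size = 2, endian = "little")
  body <- c(
    dcm_el(0x0020, 0x0032, "DS", ipp),
    dcm_el(0x0020, 0x0037, "DS", iop),
    dcm_el(0x0028, 0x0010, "US", rows),
    dcm_el(0x0028, 0x0011, "US", cols),
    dcm_el(0x0028, 0x0030, "DS", pixel_spacing),
    dcm_el(0x0028, 0x0100, "US", 16),
    dcm_el(0x0028, 0x0103, "US", 0),
    dcm_el(0x7FE0, 0x0010, "OW", pix))
  meta <- dcm_el(0x0002, 0x0010, "UI", "1.2.840.10008.1.2.1")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(rep(as.raw(0), 128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, body), con)
  invisible(path)
}

# write a whole synthetic series into a directory; returns the array written
write_dicom_series <- function(dir, nx = 16, ny = 12, nz = 5,
                               spacing = c(0.7, 0.5, 2), origin = c(1, 2, 3)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  arr <- array(sample.int(1000, nx * ny * nz, replace = TRUE) - 1L,
               dim = c(nx, ny, nz))
  for (k in seq_len(nz)) {
    # file content is rows x cols = ny x nx
    write_dicom_slice(file.path(dir, sprintf("slice%02d.dcm", k)),
                      pixels = t(arr[, , k]),
                      ipp = c(origin[1], origin[2], origin[3] + (k - 1) * spacing[3]),
                      pixel_spacing = c(spacing[2], spacing[1]))
  }
  arr
}
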