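# Minimal DICOM series reader: single-frame uncompressed slices, explicit or
# implicit VR little endian, axis-aligned orientation. No R DICOM package is
# depended on; only the handful of tags the geometry needs is parsed.

dicom_tag <- function(group, elem) sprintf("%04x,%04x", group, elem)

# parse one DICOM file into the tags we care about
parse_dicom_file <- function(path) {
  buf <- readBin(path, raw(), n = file.size(path))
  if (length(buf) < 140 || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM file: ", path, call. = FALSE)
  pos <- 133L
  u16 <- function(at) readBin(buf[at + 0:1], "integer", size = 2, signed = FALSE,
                              endian = "little")
  u32 <- function(at) readBin(buf[at + 0:3], "integer", size = 4, endian = "little")
  long_vrs <- c("OB", "OW", "OF", "SQ", "UT", "UN")
  tags <- new.env(parent = emptyenv())
  read_element <- function(pos, explicit) {
    g <- u16(pos); e <- u16(pos + 2L)
    if (explicit) {
      vr <- rawToChar(buf[pos + 4:5])
      if (vr %in% long_vrs) {
        len <- u32(pos + 8L); val_at <- pos + 12L
      } else {
        len <- u16(pos + 6L); val_at <- pos + 8L
      }
    } else {
      vr <- NA_character_
      len <- u32(pos + 4L); val_at <- pos + 8L
    }
    if (len < 0 || len == 0xFFFFFFFF)
      stop("unsupported DICOM encoding (undefined length) in ", path, call. = FALSE)
    list(group = g, elem = e, vr = vr, len = len, val_at = val_at,
         next_pos = val_at + len)
  }
  # file meta information group (0002,...) is always explicit VR
  transfer_syntax <- "1.2.840.10008.1.2.1"
  while (pos + 8L <= length(buf)) {
    el <- read_element(pos, explicit = TRUE)
    if (el$group != 2L) break
    if (el$elem == 0x0010) {
      v <- buf[el$val_at + seq_len(el$len) - 1L]
      transfer_syntax <- trimws(rawToChar(v[v != as.raw(0)]))
    }
    pos <- el$next_pos
  }
  explicit <- transfer_syntax != "1.2.840.10008.1.2"
  if (!(transfer_syntax %in% c("1.2.840.10008.1.2", "1.2.840.10008.1.2.1")))
    stop("unsupported DICOM transfer syntax ", transfer_syntax, " in ", path,
         call. = FALSE)
  repeat {
    if (pos + 8L > length(buf)) break
    el <- read_element(pos, explicit)
    key <- dicom_tag(el$group, el$elem)
    raw_val <- buf[el$val_at + seq_len(el$len) - 1L]
    assign(key, list(vr = el$vr, raw = raw_val), envir = tags)
    pos <- el$next_pos
    if (el$group == 0x7FE0 && el$elem == 0x0010) break
  }
  get_tag <- function(g, e) {
    k <- dicom_tag(g, e)
    if (exists(k, envir = tags)) get(k, envir = tags) else NULL
  }
  as_us <- function(v) if (is.null(v)) NULL else
    readBin(v$raw, "integer", size = 2, signed = FALSE, endian = "little")
  as_ds <- function(v) if (is.null(v)) NULL else
    as.numeric(strsplit(trimws(rawToChar(v$raw)), "\\\\")[[1]])
  rows <- as_us(get_tag(0x0028, 0x0010))
  cols <- as_us(get_tag(0x0028, 0x0011))
  bits <- as_us(get_tag(0x0028, 0x0100)) %||% 16L
  pixrep <- as_us(get_tag(0x0028, 0x0103)) %||% 0L
  px <- get_tag(0x7FE0, 0x0010)
  if (is.null(rows) || is.null(cols) || is.null(px))
    stop("corrupt DICOM file (missing image tags): ", path, call. = FALSE)
  if (bits != 16L)
    stop("unsupported DICOM bit depth ", bits, " in ", path, call. = FALSE)
  n_px <- as.integer(rows) * as.integer(cols)
  if (length(px$raw) < 2L * n_px)
    stop("corrupt DICOM pixel data in ", path, call. = FALSE)
  pix <- readBin(px$raw, "integer", size = 2, n = n_px, signed = (pixrep == 1L),
                 endian = "little")
  slope <- (as_ds(get_tag(0x0028, 0x1053)) %||% 1)[1]
  intercept <- (as_ds(get_tag(0x0028, 0x1052)) %||% 0)[1]
  list(rows = as.integer(rows), cols = as.integer(cols),
       pixel_spacing = as_ds(get_tag(0x0028, 0x0030)),
       ipp = as_ds(get_tag(0x0020, 0x0032)),
       iop = as_ds(get_tag(0x0020, 0x0037)) %||% c(1, 0, 0, 0, 1, 0),
       # pixel data is row-major: fill a cols x rows matrix -> [column, row]
       data = matrix(pix * slope + intercept, nrow = as.integer(cols)))
}

read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (!length(files)) stop("no DICOM files found in ", dir, call. = FALSE)
  slices <- lapply(sort(files), parse_dicom_file)
  rows <- unique(vapply(slices, `[[`, integer(1), "rows"))
  cols <- unique(vapply(slices, `[[`, integer(1), "cols"))
  if (length(rows) != 1L || length(cols) != 1L)
    stop("DICOM geometry error: slice dimensions differ within series ", dir,
         call. = FALSE)
  iop <- slices[[1]]$iop
  ax <- function(v) {
    i <- which.max(abs(v))
    if (abs(abs(v[i]) - 1) > 1e-4 || sum(abs(v[-i])) > 1e-4)
      stop("DICOM geometry error: non-axis-aligned series rejected (", dir, ")",
           call. = FALSE)
    i * sign(v[i])
  }
  if (abs(ax(iop[1:3])) == abs(ax(iop[4:6])))
    stop("DICOM geometry error: degenerate orientation in ", dir, call. = FALSE)
  if (!isTRUE(all.equal(iop, c(1, 0, 0, 0, 1, 0), tolerance = 1e-4)))
    stop("DICOM geometry error: only identity orientation is supported (", dir, ")",
         call. = FALSE)
  ipp <- t(vapply(slices, function(s) {
    if (is.null(s$ipp) || length(s$ipp) != 3)
      stop("DICOM geometry error: missing ImagePositionPatient in ", dir,
           call. = FALSE)
    s$ipp
  }, numeric(3)))
  ord <- order(ipp[, 3])
  slices <- slices[ord]
  ipp <- ipp[ord, , drop = FALSE]
  ps <- slices[[1]]$pixel_spacing
  if (is.null(ps) || length(ps) != 2)
    stop("DICOM geometry error: missing PixelSpacing in ", dir, call. = FALSE)
  if (nrow(ipp) > 1) {
    dz <- diff(ipp[, 3])
    if (any(dz <= 0) || (max(dz) - min(dz)) > 1e-3)
      stop("DICOM geometry error: inconsistent slice spacing in ", dir, call. = FALSE)
    zsp <- mean(dz)
  } else {
    zsp <- 1
  }
  data <- array(0, dim = c(cols, rows, length(slices)))
  for (k in seq_along(slices)) data[, , k] <- slices[[k]]$data
  # PixelSpacing = (row spacing, column spacing) = (y, x) in our axis order
  image_volume(data, spacing = c(ps[2], ps[1], zsp), origin = ipp[1, ])
}
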