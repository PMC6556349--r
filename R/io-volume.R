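#' Read a 3D image volume
#'
#' Accepts a single NIfTI file (`.nii` / `.nii.gz`) or a directory holding an
#' uncompressed single-frame DICOM series (one slice per file, little-endian,
#' axis-aligned). Spacing and origin are taken from the file metadata;
#' intensities are returned unmodified (DICOM rescale slope/intercept applied
#' when present).
#'
#' @param path File (NIfTI) or directory (DICOM series).
#' @param format_hint `"auto"` (default), `"nifti"` or `"dicom"`.
#' @return An [image_volume()].
#' @export
read_volume <- function(path, format_hint = c("auto", "nifti", "dicom")) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) stop("cannot read volume: no such path ", path, call. = FALSE)
  fmt <- format_hint
  if (fmt == "auto") fmt <- if (dir.exists(path)) "dicom" else "nifti"
  if (fmt == "dicom") return(read_dicom_series(path))
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim = dim(img)[1:3])
  spacing <- RNifti::pixdim(img)[1:3]
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (inherits(xf, "try-error")) c(0, 0, 0) else as.numeric(xf[1:3, 4])
  image_volume(data, spacing = spacing, origin = origin)
}

#' Write a volume as NIfTI
#'
#' @param volume An [image_volume()].
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (!inherits(volume, "laa_volume")) stop("`volume` must be a laa_volume", call. = FALSE)
  mat <- diag(4)
  diag(mat)[1:3] <- volume$spacing
  mat[1:3, 4] <- volume$origin
  img <- RNifti::asNifti(volume$data, pixdim = volume$spacing)
  img <- RNifti::`sform<-`(img, structure(mat, code = 2L))
  img <- RNifti::`qform<-`(img, structure(mat, code = 2L))
  img <- RNifti::`pixdim<-`(img, volume$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a landmark table
#'
#' Comma-separated file with header `name,role,x,y,z`; coordinates in world
#' millimetres, roles validated against the set used by the pipeline.
#'
#' @param path CSV file path.
#' @return A [landmark_set()] tibble.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("cannot read landmarks: no such file ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "role", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("landmark file must have header columns name,role,x,y,z", call. = FALSE)
  landmark_set(df$name, df$role, df$x, df$y, df$z)
}

#' Write a landmark table
#'
#' @param landmarks A [landmark_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  write.csv(as.data.frame(landmarks[, c("name", "role", "x", "y", "z")]),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
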