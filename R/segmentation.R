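#' Automatic intensity threshold (Otsu)
#'
#' Initial blood-pool threshold computed by maximizing the between-class
#' variance of the 256-bin intensity histogram (Otsu's criterion). The
#' returned value lies strictly between the minimum and maximum intensity and
#' can be overridden downstream, modelling the operator's interactive
#' adjustment.
#'
#' @param volume An [image_volume()].
#' @param bins Number of histogram bins (default 256).
#' @return Scalar intensity threshold.
#' @export
auto_threshold <- function(volume, bins = 256L) {
  x <- as.numeric(volume$data)
  rng <- range(x)
  if (diff(rng) == 0) stop("no contrast: volume is constant", call. = FALSE)
  edges <- seq(rng[1], rng[2], length.out = bins + 1L)
  idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = bins)
  p <- counts / sum(counts)
  mids <- (edges[-1] + edges[-(bins + 1L)]) / 2
  w1 <- cumsum(p)
  m1 <- cumsum(p * mids)
  mt <- m1[bins]
  valid <- w1 > 0 & w1 < 1
  sb2 <- rep(-Inf, bins)
  sb2[valid] <- (mt * w1[valid] - m1[valid])^2 / (w1[valid] * (1 - w1[valid]))
  t_best <- which.max(sb2[-bins])          # cut between bin t and t+1
  edges[t_best + 1L]
}

#' Apply an intensity threshold
#'
#' Voxels with intensity greater than or equal to the threshold become
#' foreground. `override`, when given, replaces `threshold` (the operator's
#' interactive adjustment).
#'
#' @param volume An [image_volume()].
#' @param threshold Scalar intensity threshold.
#' @param override Optional scalar replacing `threshold`.
#' @return A [binary_mask()]; an all-false mask is allowed at this stage.
#' @export
apply_threshold <- function(volume, threshold, override = NULL) {
  thr <- override %||% threshold
  if (!is.finite(thr)) stop("threshold must be finite", call. = FALSE)
  binary_mask(volume$data >= thr, spacing = volume$spacing, origin = volume$origin)
}

#' Keep the connected component containing a seed point
#'
#' Retains only the 26-connected foreground component that contains the voxel
#' nearest to the world-coordinate seed, isolating the left-atrial blood pool
#' from other enhancing structures.
#'
#' @param mask A [binary_mask()].
#' @param seed World point (mm), length 3.
#' @return A [binary_mask()] restricted to one component.
#' @export
select_component <- function(mask, seed) {
  dims <- dim(mask$data)
  ijk <- world_to_voxel(seed, mask$spacing, mask$origin, dims)
  if (is.null(ijk)) stop("seed lies outside the volume bounds", call. = FALSE)
  if (!mask$data[ijk[1], ijk[2], ijk[3]])
    stop("seed outside segmented blood pool", call. = FALSE)
  lin0 <- (ijk[1] - 1L) + dims[1] * ((ijk[2] - 1L) + dims[2] * (ijk[3] - 1L))
  keep <- cpp_flood26(as.logical(mask$data), as.integer(dims), lin0)
  binary_mask(array(keep, dim = dims), spacing = mask$spacing, origin = mask$origin)
}

#' Mask volume by voxel counting
#'
#' The voxel-counting volume definition: number of foreground voxels times
#' the voxel size, reported in cm^3.
#'
#' @param mask A non-empty [binary_mask()].
#' @return Volume in cm^3.
#' @export
mask_voxel_volume <- function(mask) {
  n <- sum(mask$data)
  if (n == 0) stop("mask is empty", call. = FALSE)
  n * prod(mask$spacing) / 1000
}
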