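#' Image volume with world geometry
#'
#' A scalar 3D grid in scanner (world) coordinates. Voxel `(i, j, k)`
#' (1-based in R) has its centre at `origin + (c(i, j, k) - 1) * spacing`;
#' all geometry in the package is expressed in millimetres.
#'
#' @param data Numeric 3D array of intensities (arbitrary units / HU).
#' @param spacing Numeric length-3, voxel spacing in mm (all > 0).
#' @param origin Numeric length-3, world position (mm) of the centre of the
#'   first voxel.
#' @param phase_label Optional scalar, percentage of the RR interval this
#'   frame was reconstructed at.
#' @return An object of class `laa_volume`.
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0), phase_label = NULL) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array", call. = FALSE)
  if (any(dim(data) < 2L)) stop("each image axis needs at least 2 voxels", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)", call. = FALSE)
  if (any(!is.finite(data))) stop("intensities must be finite", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin,
                 phase_label = phase_label),
            class = "laa_volume")
}

#' @export
print.laa_volume <- function(x, ...) {
  cat("<laa_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels @ (", paste(format(x$spacing, digits = 4), collapse = ", "),
      ") mm", sep = "")
  if (!is.null(x$phase_label)) cat(", phase ", x$phase_label, "%", sep = "")
  cat("\n  intensity range [", format(min(x$data), digits = 4), ", ",
      format(max(x$data), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Ordered multi-phase image stack
#'
#' @param volumes List of [image_volume()] objects, one per cardiac phase.
#' @param phase_percents Strictly increasing phase positions, percent of the
#'   RR interval, each in `[0, 100)`.
#' @return An object of class `laa_phase_stack`.
#' @export
phase_stack <- function(volumes, phase_percents) {
  if (!is.list(volumes) || !all(vapply(volumes, inherits, logical(1), "laa_volume")))
    stop("`volumes` must be a list of laa_volume objects", call. = FALSE)
  phase_percents <- as.numeric(phase_percents)
  if (length(volumes) != length(phase_percents))
    stop("`volumes` and `phase_percents` lengths differ", call. = FALSE)
  if (any(phase_percents < 0 | phase_percents >= 100) ||
      any(diff(phase_percents) <= 0))
    stop("`phase_percents` must be strictly increasing within [0, 100)", call. = FALSE)
  structure(list(volumes = volumes, phase_percents = phase_percents),
            class = "laa_phase_stack")
}

#' @export
print.laa_phase_stack <- function(x, ...) {
  cat("<laa_phase_stack> ", length(x$volumes), " phases at ",
      paste(x$phase_percents, collapse = ", "), "% RR\n", sep = "")
  invisible(x)
}

#' Triangle surface mesh in world millimetres
#'
#' @param vertices Numeric matrix `n x 3` of vertex positions (mm).
#' @param triangles Integer matrix `m x 3` of 1-based vertex indices.
#' @param allow_slivers Accept triangles whose area underflows to exactly
#'   zero (distinct but numerically collinear vertices). Used internally
#'   when splitting triangles along cutting planes can create such slivers;
#'   user-supplied meshes are validated strictly.
#' @return An object of class `laa_mesh`.
#' @export
triangle_mesh <- function(vertices, triangles, allow_slivers = FALSE) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  triangles <- matrix(as.integer(triangles), ncol = 3)
  if (nrow(triangles) < 1L) stop("mesh has no triangles", call. = FALSE)
  if (any(!is.finite(vertices))) stop("vertex coordinates must be finite", call. = FALSE)
  if (any(triangles < 1L) || any(triangles > nrow(vertices)))
    stop("triangle indices out of range", call. = FALSE)
  if (!allow_slivers) {
    a <- vertices[triangles[, 1], , drop = FALSE]
    e1 <- vertices[triangles[, 2], , drop = FALSE] - a
    e2 <- vertices[triangles[, 3], , drop = FALSE] - a
    cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
    cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
    cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    if (any(cx == 0 & cy == 0 & cz == 0))
      stop("mesh contains degenerate (zero-area) triangles", call. = FALSE)
  }
  structure(list(vertices = vertices, triangles = triangles), class = "laa_mesh")
}

#' @export
print.laa_mesh <- function(x, ...) {
  nb <- nrow(mesh_boundary_edges(x))
  cat("<laa_mesh> ", nrow(x$vertices), " vertices, ", nrow(x$triangles),
      " triangles", if (nb == 0) ", watertight" else
        paste0(", ", nb, " boundary edges"), "\n", sep = "")
  invisible(x)
}

#' Named landmark points in world millimetres
#'
#' Landmarks replace the interactive point-picking of the manual workflow:
#' `ostium_cut` points define the ostium cutting plane, `laa_seed` marks a
#' point inside the appendage, `la_seed` a point inside the atrial body.
#'
#' @param name Character vector of point names.
#' @param role Character vector, each one of `"ostium_cut"`, `"laa_seed"`,
#'   `"la_seed"`.
#' @param x,y,z Numeric world coordinates (mm).
#' @return A tibble with class `laa_landmarks`.
#' @export
landmark_set <- function(name, role, x, y, z) {
  allowed <- c("ostium_cut", "laa_seed", "la_seed")
  role <- as.character(role)
  bad <- setdiff(unique(role), allowed)
  if (length(bad))
    stop("unknown landmark role(s) ", paste(bad, collapse = ", "),
         "; allowed roles: ", paste(allowed, collapse = ", "), call. = FALSE)
  out <- tibble::tibble(name = as.character(name), role = role,
                        x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  if (any(!is.finite(out$x) | !is.finite(out$y) | !is.finite(out$z)))
    stop("landmark coordinates must be finite", call. = FALSE)
  class(out) <- c("laa_landmarks", class(out))
  out
}

#' Extract landmark coordinates for one role
#'
#' @param landmarks A [landmark_set()].
#' @param role One of the allowed landmark roles.
#' @return Numeric matrix, one point per row (mm).
#' @export
landmark_points <- function(landmarks, role) {
  m <- as.matrix(landmarks[landmarks$role == role, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

#' Binary segmentation mask
#'
#' @param data Logical 3D array.
#' @param spacing,origin World geometry inherited from the source volume.
#' @return An object of class `laa_mask`.
#' @export
binary_mask <- function(data, spacing, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array", call. = FALSE)
  storage.mode(data) <- "logical"
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "laa_mask")
}

#' @export
print.laa_mask <- function(x, ...) {
  cat("<laa_mask> ", paste(dim(x$data), collapse = " x "), " voxels, ",
      sum(x$data), " foreground\n", sep = "")
  invisible(x)
}

# world point -> nearest voxel index (1-based ijk); NULL if out of bounds
world_to_voxel <- function(point, spacing, origin, dims) {
  ijk <- round((as.numeric(point) - origin) / spacing) + 1
  if (any(ijk < 1) || any(ijk > dims)) return(NULL)
  as.integer(ijk)
}
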