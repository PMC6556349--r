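# Surface generation and mesh processing. Isosurfaces are extracted with a
# tetrahedral-decomposition variant of marching cubes (6-simplex Kuhn
# decomposition per grid cube, iso-level 0.5 on the {0,1} mask), which yields
# watertight, consistently oriented meshes without case tables.

#' Extract the closed isosurface of a binary mask
#'
#' The mask is padded by one background voxel on every side so the surface
#' closes, then contoured at level 0.5; vertices are mapped to world
#' millimetres. Optional Laplacian smoothing can be applied (off by default:
#' smoothing biases volume; the induced volume change is recorded in the
#' `smoothing_volume_change` attribute when used).
#'
#' @param mask A non-empty [binary_mask()].
#' @param smoothing_iterations Number of Laplacian smoothing passes.
#' @return A watertight [triangle_mesh()].
#' @export
extract_surface <- function(mask, smoothing_iterations = 0L) {
  dims <- dim(mask$data)
  if (sum(mask$data) == 0) stop("mask is empty", call. = FALSE)
  padded <- array(0, dim = dims + 2L)
  padded[2:(dims[1] + 1L), 2:(dims[2] + 1L), 2:(dims[3] + 1L)] <- mask$data
  res <- cpp_march_tets(as.numeric(padded), as.integer(dims + 2L),
                        as.numeric(mask$origin - mask$spacing),
                        as.numeric(mask$spacing), 0.5)
  mesh <- triangle_mesh(res$vertices, res$triangles)
  if (smoothing_iterations > 0L) {
    v0 <- mesh_volume(mesh)
    mesh <- laplacian_smooth(mesh, smoothing_iterations)
    attr(mesh, "smoothing_volume_change") <- mesh_volume(mesh) - v0
  }
  mesh
}

laplacian_smooth <- function(mesh, iterations, lambda = 0.5) {
  tr <- mesh$triangles
  e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  v <- mesh$vertices
  deg <- tabulate(e[, 1], nbins = nrow(v))
  for (it in seq_len(iterations)) {
    nb_sum <- rowsum(v[e[, 2], , drop = FALSE], e[, 1])
    v <- v + lambda * (nb_sum / deg - v)
  }
  triangle_mesh(v, tr)
}

# all undirected edges (sorted vertex pairs), one row per triangle edge
mesh_edge_table <- function(mesh) {
  tr <- mesh$triangles
  e <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

#' Boundary edges of a mesh
#'
#' @param mesh A [triangle_mesh()].
#' @return Integer matrix of undirected edges used by exactly one triangle
#'   (zero rows for a watertight mesh).
#' @export
mesh_boundary_edges <- function(mesh) {
  e <- mesh_edge_table(mesh)
  key <- (e[, 1] - 1) * nrow(mesh$vertices) + e[, 2]  # < 2^53 for any real mesh
  r <- rle(sort(key))
  open <- r$values[r$lengths == 1L]
  e[key %in% open, , drop = FALSE]
}

#' Is a mesh watertight?
#'
#' Every edge must be shared by exactly two triangles.
#'
#' @param mesh A [triangle_mesh()].
#' @return Logical scalar.
#' @export
mesh_is_watertight <- function(mesh) {
  e <- mesh_edge_table(mesh)
  r <- rle(sort((e[, 1] - 1) * nrow(mesh$vertices) + e[, 2]))
  all(r$lengths == 2L)
}

#' Mesh surface area
#'
#' @param mesh A [triangle_mesh()].
#' @return Total triangle area in mm^2.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices
  tr <- mesh$triangles
  a <- v[tr[, 1], , drop = FALSE]
  e1 <- v[tr[, 2], , drop = FALSE] - a
  e2 <- v[tr[, 3], , drop = FALSE] - a
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Enclosed volume of a watertight mesh
#'
#' Signed volume by the divergence theorem (sum of signed tetrahedra spanned
#' with the origin); the absolute value is returned in cm^3. This is the
#' mesh-based volume definition, used as an independent cross-check of the
#' voxel-counting volume.
#'
#' @param mesh A watertight, consistently oriented [triangle_mesh()].
#' @return Volume in cm^3.
#' @export
mesh_volume <- function(mesh) {
  be <- mesh_boundary_edges(mesh)
  if (nrow(be) > 0)
    stop("mesh is not watertight: ", nrow(be), " open edge(s)", call. = FALSE)
  v <- mesh$vertices
  tr <- mesh$triangles
  a <- v[tr[, 1], , drop = FALSE]
  b <- v[tr[, 2], , drop = FALSE]
  d <- v[tr[, 3], , drop = FALSE]
  det <- a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
         a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
         a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])
  abs(sum(det)) / 6 / 1000
}

#' Plane-based crop specification
#'
#' Programmatic stand-in for the manual crop of the appendage from the
#' atrial surface: a cutting plane plus a seed marking the side to keep.
#'
#' @param point Point on the plane (mm).
#' @param normal Plane normal (normalized internally).
#' @param keep_seed World point on the side of the plane to keep; must be
#'   farther than 1e-6 mm from the plane.
#' @return An object of class `laa_crop_spec`.
#' @export
crop_spec <- function(point, normal, keep_seed) {
  normal <- unit(as.numeric(normal))
  point <- as.numeric(point)
  keep_seed <- as.numeric(keep_seed)
  if (abs(sum((keep_seed - point) * normal)) <= 1e-6)
    stop("keep_seed lies on the cutting plane", call. = FALSE)
  structure(list(point = point, normal = normal, keep_seed = keep_seed),
            class = "laa_crop_spec")
}

# signed distances with deterministic symbolic perturbation: values within
# tol of the plane are pushed to the positive side so crop and intersection
# agree point-for-point and no vertex sits exactly on the plane
plane_signed_dist <- function(vertices, point, normal) {
  s <- as.numeric((vertices - matrix(point, nrow(vertices), 3, byrow = TRUE)) %*% normal)
  tol <- 1e-9 * max(1, max(abs(vertices)))
  s[abs(s) < tol] <- tol
  s
}

# canonical interpolation of the plane crossing on edge (i, j): computed from
# the lower vertex id so both traversal directions give identical points
edge_plane_point <- function(vertices, s, i, j) {
  if (i > j) { tmp <- i; i <- j; j <- tmp }
  t <- s[i] / (s[i] - s[j])
  vertices[i, ] + t * (vertices[j, ] - vertices[i, ])
}

#' Crop a mesh with a cutting plane
#'
#' Triangles on the keep side are retained, triangles crossing the plane are
#' split along it, and the connected open submesh containing the vertex
#' nearest `spec$keep_seed` is returned; its boundary lies on the plane.
#'
#' @param mesh A [triangle_mesh()].
#' @param spec A [crop_spec()].
#' @return An open [triangle_mesh()].
#' @export
crop_mesh <- function(mesh, spec) {
  v <- mesh$vertices
  tr <- mesh$triangles
  n <- spec$normal
  if (sum((spec$keep_seed - spec$point) * n) < 0) n <- -n
  s <- plane_signed_dist(v, spec$point, n)
  pos <- s > 0
  npos <- pos[tr[, 1]] + pos[tr[, 2]] + pos[tr[, 3]]
  if (all(npos == 3L) || all(npos == 0L))
    stop("cutting plane does not intersect the mesh", call. = FALSE)
  keep_full <- tr[npos == 3L, , drop = FALSE]
  crossing <- which(npos == 1L | npos == 2L)

  new_v <- list()
  new_key <- character(0)
  get_cut_vertex <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    at <- match(key, new_key)
    if (!is.na(at)) return(nrow(v) + at)
    new_v[[length(new_v) + 1L]] <<- edge_plane_point(v, s, i, j)
    new_key[length(new_key) + 1L] <<- key
    nrow(v) + length(new_v)
  }
  clipped <- list()
  for (t in crossing) {
    ids <- tr[t, ]
    out_poly <- integer(0)
    for (k in 1:3) {
      a <- ids[k]; b <- ids[if (k == 3) 1 else k + 1]
      if (pos[a]) out_poly <- c(out_poly, a)
      if (xor(pos[a], pos[b])) out_poly <- c(out_poly, get_cut_vertex(a, b))
    }
    if (length(out_poly) == 3L) {
      clipped[[length(clipped) + 1L]] <- out_poly
    } else if (length(out_poly) == 4L) {
      clipped[[length(clipped) + 1L]] <- out_poly[c(1, 2, 3)]
      clipped[[length(clipped) + 1L]] <- out_poly[c(1, 3, 4)]
    }
  }
  all_v <- rbind(v, do.call(rbind, new_v))
  all_t <- rbind(keep_full, do.call(rbind, clipped))
  if (nrow(all_t) == 0L) stop("keep side of the cut is empty", call. = FALSE)

  labels <- cpp_mesh_components(nrow(all_v), all_t)
  used <- sort(unique(as.integer(all_t)))
  d2 <- rowSums((all_v[used, , drop = FALSE] -
                 matrix(spec$keep_seed, length(used), 3, byrow = TRUE))^2)
  lab_keep <- labels[used[which.min(d2)]]
  all_t <- all_t[labels[all_t[, 1]] == lab_keep, , drop = FALSE]
  compact_mesh(all_v, all_t)
}

# merge bit-identical vertices, drop collapsed triangles and unreferenced
# vertices, renumber
compact_mesh <- function(vertices, triangles) {
  key <- paste(sprintf("%a", vertices[, 1]), sprintf("%a", vertices[, 2]),
               sprintf("%a", vertices[, 3]))
  vid <- match(key, key)
  triangles <- matrix(vid[triangles], ncol = 3)
  collapsed <- triangles[, 1] == triangles[, 2] |
               triangles[, 2] == triangles[, 3] |
               triangles[, 1] == triangles[, 3]
  triangles <- triangles[!collapsed, , drop = FALSE]
  used <- sort(unique(as.integer(triangles)))
  remap <- integer(nrow(vertices))
  remap[used] <- seq_along(used)
  triangle_mesh(vertices[used, , drop = FALSE],
                matrix(remap[triangles], ncol = 3), allow_slivers = TRUE)
}

#' Icosphere test mesh
#'
#' Subdivided icosahedron projected onto a sphere; a standard analytic
#' fixture for volumetry and contour checks.
#'
#' @param radius Sphere radius in mm.
#' @param subdivisions Number of 4-fold subdivision passes.
#' @param center Sphere centre (mm).
#' @return A watertight [triangle_mesh()].
#' @export
mesh_icosphere <- function(radius = 10, subdivisions = 3L, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  v <- v / sqrt(rowSums(v^2))
  for (s in seq_len(subdivisions)) {
    mid_env <- new.env(parent = emptyenv())
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_env[[key]])) return(mid_env[[key]])
      p <- unit(v[a, ] + v[b, ])
      v <<- rbind(v, p)
      mid_env[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; cc <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[4 * t - 3, ] <- c(a, ab, ca)
      nf[4 * t - 2, ] <- c(b, bc, ab)
      nf[4 * t - 1, ] <- c(cc, ca, bc)
      nf[4 * t, ] <- c(ab, bc, ca)
    }
    f <- nf
  }
  v <- v * radius
  v <- v + matrix(center, nrow(v), 3, byrow = TRUE)
  triangle_mesh(v, f)
}

#' Axis-aligned cube test mesh
#'
#' @param side Edge length in mm.
#' @param corner Minimum corner (mm).
#' @return A watertight 12-triangle [triangle_mesh()].
#' @export
mesh_cube <- function(side = 10, corner = c(0, 0, 0)) {
  b <- as.matrix(expand.grid(x = c(0, 1), y = c(0, 1), z = c(0, 1)))
  v <- b * side + matrix(corner, 8, 3, byrow = TRUE)
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),   # z = 0 (normal -z)
    c(5, 6, 7), c(6, 8, 7),   # z = 1 (normal +z)
    c(1, 2, 5), c(2, 6, 5),   # y = 0
    c(3, 7, 4), c(4, 7, 8),   # y = 1
    c(1, 5, 3), c(3, 5, 7),   # x = 0
    c(2, 4, 6), c(4, 8, 6))   # x = 1
  triangle_mesh(v, f)
}
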