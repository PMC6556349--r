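# Ostium morphometry: cutting-plane definition, mesh-plane intersection
# contour, ostium area, surface capping, and volumetry by voxelization of the
# closed model at the source CT resolution. Internal units are mm / mm^2 /
# mm^3; reported areas and volumes are cm^2 / cm^3.

#' Cutting plane
#'
#' @param point Point on the plane (mm).
#' @param normal Plane normal; normalized internally.
#' @param source_landmarks Optional matrix of the fitting points.
#' @return An object of class `laa_plane`.
#' @export
cutting_plane <- function(point, normal, source_landmarks = NULL) {
  structure(list(point = as.numeric(point), normal = unit(as.numeric(normal)),
                 source_landmarks = source_landmarks),
            class = "laa_plane")
}

#' Fit the ostium cutting plane to landmarks
#'
#' Three points give the exact plane through them; more than three give the
#' total-least-squares plane (smallest principal direction of the centred
#' points). With `mesh` supplied, the normal is oriented to point away from
#' the appendage apex side, taken as the side holding the mesh vertex
#' farthest from the plane.
#'
#' @param landmarks A [landmark_set()] (its `ostium_cut` points are used) or
#'   a numeric matrix with one point per row.
#' @param mesh Optional [triangle_mesh()] used only to orient the normal.
#' @return A [cutting_plane()].
#' @export
fit_plane <- function(landmarks, mesh = NULL) {
  pts <- if (inherits(landmarks, "laa_landmarks"))
    landmark_points(landmarks, "ostium_cut") else matrix(as.numeric(landmarks), ncol = 3)
  if (nrow(pts) < 3) stop("plane fitting needs at least 3 points", call. = FALSE)
  ctr <- colMeans(pts)
  x <- sweep(pts, 2, ctr)
  scale <- max(1, max(abs(x)))
  if (nrow(pts) == 3) {
    n <- cross3(x[2, ] - x[1, ], x[3, ] - x[1, ])
    if (vnorm(n) < 1e-9 * scale^2) stop("landmarks are collinear", call. = FALSE)
    n <- unit(n)
  } else {
    sv <- svd(x)
    if (sv$d[2] < 1e-9 * scale) stop("landmarks are collinear", call. = FALSE)
    n <- sv$v[, 3]
  }
  if (!is.null(mesh)) {
    s <- as.numeric((mesh$vertices - matrix(ctr, nrow(mesh$vertices), 3,
                                            byrow = TRUE)) %*% n)
    if (s[which.max(abs(s))] > 0) n <- -n   # point away from the apex side
  }
  cutting_plane(ctr, n, source_landmarks = pts)
}

#' Ostium contour
#'
#' Ordered closed planar polyline (first point implicitly follows the last),
#' counterclockwise about the plane normal.
#'
#' @param points Numeric matrix, one 3D point (mm) per row, no repeated
#'   closing point.
#' @param plane The [cutting_plane()] the points lie on.
#' @return An object of class `laa_contour`.
#' @export
ostium_contour <- function(points, plane) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) < 3) stop("a contour needs at least 3 points", call. = FALSE)
  d <- abs(as.numeric((points - matrix(plane$point, nrow(points), 3,
                                       byrow = TRUE)) %*% plane$normal))
  if (max(d) > 1e-6)
    stop("contour points do not lie on the plane (max deviation ",
         format(max(d)), " mm)", call. = FALSE)
  structure(list(points = points, plane = plane), class = "laa_contour")
}

#' @export
print.laa_contour <- function(x, ...) {
  cat("<laa_contour> ", nrow(x$points), " points, area ",
      format(contour_area(x), digits = 4), " cm^2\n", sep = "")
  invisible(x)
}

# 2D coordinates of points in the plane's orthonormal frame
contour_2d <- function(points, plane) {
  fr <- plane_frame(plane$normal)
  rel <- points - matrix(plane$point, nrow(points), 3, byrow = TRUE)
  cbind(as.numeric(rel %*% fr$u), as.numeric(rel %*% fr$v))
}

shoelace <- function(p2) {
  n <- nrow(p2)
  i2 <- c(2:n, 1)
  sum(p2[, 1] * p2[i2, 2] - p2[i2, 1] * p2[, 2]) / 2
}

#' Intersect a mesh with a cutting plane
#'
#' All closed intersection loops are traced by walking triangle-plane
#' segments across shared edges. The loop with the largest enclosed planar
#' area is returned, or, when `anchor` is given, the loop whose centroid is
#' nearest the anchor; points are ordered counterclockwise about the plane
#' normal.
#'
#' @param mesh A [triangle_mesh()], closed across the plane.
#' @param plane A [cutting_plane()].
#' @param anchor Optional world point selecting among multiple loops.
#' @return An [ostium_contour()].
#' @export
intersect_mesh_plane <- function(mesh, plane, anchor = NULL) {
  v <- mesh$vertices
  tr <- mesh$triangles
  s <- plane_signed_dist(v, plane$point, plane$normal)
  pos <- s > 0
  npos <- pos[tr[, 1]] + pos[tr[, 2]] + pos[tr[, 3]]
  crossing <- which(npos == 1L | npos == 2L)
  if (length(crossing) == 0L)
    stop("plane does not intersect the mesh", call. = FALSE)
  # one segment per crossing triangle, endpoints keyed by the crossed edge
  seg_a <- character(length(crossing))
  seg_b <- character(length(crossing))
  pt_env <- new.env(parent = emptyenv())
  for (q in seq_along(crossing)) {
    ids <- tr[crossing[q], ]
    keys <- character(0)
    for (k in 1:3) {
      a <- ids[k]; b <- ids[if (k == 3) 1 else k + 1]
      if (xor(pos[a], pos[b])) {
        key <- paste(min(a, b), max(a, b))
        if (is.null(pt_env[[key]])) pt_env[[key]] <- edge_plane_point(v, s, a, b)
        keys <- c(keys, key)
      }
    }
    seg_a[q] <- keys[1]; seg_b[q] <- keys[2]
  }
  # chain segments into loops via endpoint adjacency
  ends <- c(seg_a, seg_b)
  cnt <- table(ends)
  if (any(cnt != 2))
    stop("mesh not closed across plane: open intersection chain", call. = FALSE)
  nseg <- length(seg_a)
  used <- logical(nseg)
  by_end <- split(rep(seq_len(nseg), 2), ends)
  loops <- list()
  for (start in seq_len(nseg)) {
    if (used[start]) next
    used[start] <- TRUE
    loop_keys <- c(seg_a[start])
    cur_key <- seg_b[start]
    repeat {
      loop_keys <- c(loop_keys, cur_key)
      nxt <- by_end[[cur_key]]
      nxt <- nxt[!used[nxt]]
      if (length(nxt) == 0) break
      nxt <- nxt[1]
      used[nxt] <- TRUE
      cur_key <- if (seg_a[nxt] == cur_key) seg_b[nxt] else seg_a[nxt]
    }
    if (loop_keys[length(loop_keys)] == loop_keys[1])
      loop_keys <- loop_keys[-length(loop_keys)]
    loops[[length(loops) + 1L]] <- loop_keys
  }
  loop_pts <- lapply(loops, function(keys)
    do.call(rbind, lapply(keys, function(k) pt_env[[k]])))
  areas <- vapply(loop_pts, function(p) abs(shoelace(contour_2d(p, plane))),
                  numeric(1))
  pick <- if (is.null(anchor)) {
    which.max(areas)
  } else {
    cents <- t(vapply(loop_pts, colMeans, numeric(3)))
    which.min(rowSums((cents - matrix(as.numeric(anchor), nrow(cents), 3,
                                      byrow = TRUE))^2))
  }
  pts <- loop_pts[[pick]]
  if (shoelace(contour_2d(pts, plane)) < 0) pts <- pts[nrow(pts):1, ]
  ostium_contour(pts, plane)
}

#' Planar contour area
#'
#' Points are projected onto the plane's orthonormal 2D frame and the
#' shoelace formula is applied; the absolute value is reported in cm^2.
#'
#' @param contour An [ostium_contour()].
#' @return Area in cm^2.
#' @export
contour_area <- function(contour) {
  if (nrow(contour$points) < 3) stop("contour needs at least 3 points", call. = FALSE)
  abs(shoelace(contour_2d(contour$points, contour$plane))) / 100
}

#' Close an open appendage surface across the ostium
#'
#' The single boundary loop of the open mesh, which must coincide with the
#' ostium contour, is capped: a triangle fan from the contour's planar
#' centroid when the contour is star-shaped about it, otherwise an
#' ear-clipping triangulation. The result is watertight with outward
#' orientation consistent with the input surface.
#'
#' @param open_mesh Open [triangle_mesh()] with exactly one boundary loop.
#' @param contour The [ostium_contour()] along that boundary.
#' @return An object of class `laa_closed_model` with elements `mesh`,
#'   `ostium`, `cap_triangles` and `cap_method`.
#' @export
close_surface <- function(open_mesh, contour) {
  cycle <- boundary_cycles(open_mesh)
  if (length(cycle) != 1L)
    stop("open mesh has ", length(cycle), " boundary loops; expected exactly 1",
         call. = FALSE)
  cycle <- cycle[[1]]
  bv <- open_mesh$vertices[cycle, , drop = FALSE]
  # boundary must coincide with the contour point-for-point
  cp <- contour$points
  if (nrow(bv) != nrow(cp))
    stop("contour mismatch: boundary has ", nrow(bv), " points, contour ",
         nrow(cp), call. = FALSE)
  nn <- vapply(seq_len(nrow(bv)), function(i)
    min(rowSums((cp - matrix(bv[i, ], nrow(cp), 3, byrow = TRUE))^2)), numeric(1))
  if (max(sqrt(nn)) > 1e-6)
    stop("contour mismatch: boundary deviates ", format(max(sqrt(nn))),
         " mm from contour", call. = FALSE)

  # polygon traversed opposite to the mesh boundary direction, so cap
  # triangles use boundary edges in reverse and watertightness follows
  poly_idx <- rev(cycle)
  p2 <- contour_2d(open_mesh$vertices[poly_idx, , drop = FALSE], contour$plane)
  c2 <- colMeans(p2)
  n <- length(poly_idx)
  i2 <- c(2:n, 1)
  fan_signs <- (p2[, 1] - c2[1]) * (p2[i2, 2] - c2[2]) -
               (p2[i2, 1] - c2[1]) * (p2[, 2] - c2[2])
  total <- shoelace(p2)
  if (all(sign(fan_signs) == sign(total))) {
    centroid3 <- colMeans(open_mesh$vertices[poly_idx, , drop = FALSE])
    cid <- nrow(open_mesh$vertices) + 1L
    cap <- cbind(rep(cid, n), poly_idx, poly_idx[i2])
    verts <- rbind(open_mesh$vertices, centroid3)
    method <- "centroid_fan"
  } else {
    cap_local <- ear_clip(p2)
    cap <- cbind(poly_idx[cap_local[, 1]], poly_idx[cap_local[, 2]],
                 poly_idx[cap_local[, 3]])
    verts <- open_mesh$vertices
    method <- "ear_clipping"
  }
  mesh <- triangle_mesh(verts, rbind(open_mesh$triangles, cap),
                        allow_slivers = TRUE)
  if (!mesh_is_watertight(mesh))
    stop("capping failed to produce a watertight surface", call. = FALSE)
  structure(list(mesh = mesh, ostium = contour,
                 cap_triangles = nrow(open_mesh$triangles) + seq_len(nrow(cap)),
                 cap_method = method),
            class = "laa_closed_model")
}

#' @export
print.laa_closed_model <- function(x, ...) {
  cat("<laa_closed_model> ", nrow(x$mesh$triangles), " triangles (",
      length(x$cap_triangles), " cap, ", x$cap_method, "), volume ",
      format(mesh_volume(x$mesh), digits = 4), " cm^3, ostium ",
      format(contour_area(x$ostium), digits = 4), " cm^2\n", sep = "")
  invisible(x)
}

# ordered directed boundary cycles (each a vector of vertex ids, following
# the triangles' traversal direction)
boundary_cycles <- function(mesh) {
  tr <- mesh$triangles
  de <- rbind(tr[, 1:2], tr[, 2:3], tr[, c(3, 1)])
  nv <- nrow(mesh$vertices)
  key <- (pmin(de[, 1], de[, 2]) - 1) * nv + pmax(de[, 1], de[, 2])
  r <- rle(sort(key))
  open <- r$values[r$lengths == 1L]
  bd <- de[key %in% open, , drop = FALSE]
  if (nrow(bd) == 0) return(list())
  nxt <- integer(nv)
  nxt[bd[, 1]] <- bd[, 2]
  seen <- logical(nv)
  cycles <- list()
  for (srt in bd[, 1]) {
    if (seen[srt]) next
    cyc <- integer(0)
    cur <- srt
    repeat {
      cyc <- c(cyc, cur)
      seen[cur] <- TRUE
      cur <- nxt[cur]
      if (cur == srt || cur == 0L || seen[cur] && cur != srt) break
    }
    cycles[[length(cycles) + 1L]] <- cyc
  }
  cycles
}

# ear-clipping triangulation of a simple polygon given as an n x 2 matrix;
# returns index triples into the polygon, wound like the polygon itself.
# Near-degenerate ears (collinear boundary runs) are deferred unless no
# well-shaped ear remains, so sliver triangles are only emitted when the
# polygon forces them.
ear_clip <- function(p2) {
  n <- nrow(p2)
  orient <- sign(shoelace(p2))
  idx <- seq_len(n)
  tris <- matrix(0L, nrow = n - 2, ncol = 3)
  nt <- 0L
  sliver <- 1e-9    # twice the ear area, mm^2
  while (length(idx) > 3L) {
    m <- length(idx)
    fallback <- 0L
    chosen <- 0L
    for (k in seq_len(m)) {
      ia <- idx[if (k == 1) m else k - 1]
      ib <- idx[k]
      ic <- idx[if (k == m) 1 else k + 1]
      a <- p2[ia, ]; b <- p2[ib, ]; cc <- p2[ic, ]
      cr <- (b[1] - a[1]) * (cc[2] - a[2]) - (cc[1] - a[1]) * (b[2] - a[2])
      if (cr * orient <= 0) next                       # reflex corner
      others <- setdiff(idx, c(ia, ib, ic))
      if (length(others)) {
        inside <- point_in_tri(p2[others, , drop = FALSE], a, b, cc)
        if (any(inside)) next
      }
      if (abs(cr) > sliver) { chosen <- k; break }
      if (fallback == 0L) fallback <- k
    }
    if (chosen == 0L) chosen <- fallback
    if (chosen == 0L) stop("ear clipping failed: polygon may self-intersect",
                           call. = FALSE)
    ia <- idx[if (chosen == 1) m else chosen - 1]
    ib <- idx[chosen]
    ic <- idx[if (chosen == m) 1 else chosen + 1]
    nt <- nt + 1L
    tris[nt, ] <- c(ia, ib, ic)
    idx <- idx[idx != ib]
  }
  nt <- nt + 1L
  tris[nt, ] <- idx
  tris[seq_len(nt), , drop = FALSE]
}

point_in_tri <- function(p, a, b, cc) {
  w1 <- (b[1] - a[1]) * (p[, 2] - a[2]) - (b[2] - a[2]) * (p[, 1] - a[1])
  w2 <- (cc[1] - b[1]) * (p[, 2] - b[2]) - (cc[2] - b[2]) * (p[, 1] - b[1])
  w3 <- (a[1] - cc[1]) * (p[, 2] - cc[2]) - (a[2] - cc[2]) * (p[, 1] - cc[1])
  (w1 >= 0 & w2 >= 0 & w3 >= 0) | (w1 <= 0 & w2 <= 0 & w3 <= 0)
}

#' Voxelization-based volume of a closed appendage model
#'
#' The watertight model is rasterized on a voxel grid aligned to its bounding
#' box (half-voxel margin) at the requested spacing, normally the resolution
#' of the source CT. A voxel centre is inside when a +z ray from it crosses
#' the surface an odd number of times; rays grazing an edge or vertex are
#' retried with a deterministic jitter schedule. Volume is the inside-voxel
#' count times the voxel size.
#'
#' @param model A `laa_closed_model` or watertight [triangle_mesh()].
#' @param spacing Length-3 voxel spacing in mm (pass the source CT spacing).
#' @return List with `volume_cm3`, `mask` (a [binary_mask()] on the model
#'   grid) and `count`.
#' @export
voxelize_volume <- function(model, spacing) {
  mesh <- if (inherits(model, "laa_closed_model")) model$mesh else model
  be <- mesh_boundary_edges(mesh)
  if (nrow(be) > 0)
    stop("model is not watertight: ", nrow(be), " open edge(s)", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0))
    stop("`spacing` must be 3 positive values (mm)", call. = FALSE)
  bb_min <- apply(mesh$vertices, 2, min)
  bb_max <- apply(mesh$vertices, 2, max)
  ndim <- pmax(2L, as.integer(floor((bb_max - bb_min) / spacing)) + 2L)
  c0 <- bb_min - spacing / 2
  res <- cpp_voxelize(mesh$vertices, mesh$triangles, c0, spacing, ndim)
  count <- res$count
  if (count < 10)
    warning("fewer than 10 interior voxels at this spacing; ",
            "volume estimate is unreliable", call. = FALSE)
  list(volume_cm3 = count * prod(spacing) / 1000,
       mask = binary_mask(array(res$mask, dim = ndim), spacing = spacing,
                          origin = c0),
       count = count)
}

#' Slice-stack (Simpson) volume
#'
#' The classical 2D reference measurement: each manually traced planar
#' contour area is multiplied by the slice thickness and the slabs are
#' summed.
#'
#' @param areas Planar contour areas per slice, cm^2.
#' @param slice_thickness Slice thickness in mm.
#' @return Volume in cm^3.
#' @export
simpson_volume <- function(areas, slice_thickness) {
  areas <- as.numeric(areas)
  if (length(areas) < 1) stop("at least one slice is required", call. = FALSE)
  if (any(!is.finite(areas)) || any(areas < 0))
    stop("slice areas must be finite and non-negative", call. = FALSE)
  if (slice_thickness <= 0) stop("slice thickness must be positive", call. = FALSE)
  sum(areas) * slice_thickness / 10
}
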