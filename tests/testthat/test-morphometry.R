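test_that("plane fitting is exact for 3 points and coplanar sets", {
  pl <- fit_plane(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
  expect_equal(abs(pl$normal), c(0, 0, 1))
  pts <- rbind(c(3, 0, 0), c(0, 3, 0), c(0, 0, 3), c(1, 1, 1))
  pl2 <- fit_plane(pts)
  expect_equal(abs(pl2$normal), rep(1 / sqrt(3), 3))
  resid <- (pts - matrix(pl2$point, 4, 3, byrow = TRUE)) %*% pl2$normal
  expect_lt(max(abs(resid)), 1e-9)
  expect_error(fit_plane(rbind(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2))), "collinear")
  expect_error(fit_plane(rbind(c(0, 0, 0), c(1, 1, 1))), "at least 3")
})

test_that("total-least-squares plane matches the eigen oracle on noisy points", {
  set.seed(17)
  n_true <- unit(c(2, -1, 3))
  fr <- laa3d:::plane_frame(n_true)
  uv <- matrix(runif(40, -10, 10), ncol = 2)
  pts <- t(vapply(seq_len(20), function(i)
    uv[i, 1] * fr$u + uv[i, 2] * fr$v + rnorm(3, sd = 0.1), numeric(3)))
  pl <- fit_plane(pts)
  # independent oracle: smallest eigenvector of the covariance matrix
  ev <- eigen(cov(pts))$vectors[, 3]
  expect_lt(acos(min(abs(sum(pl$normal * ev)), 1)) * 180 / pi, 1e-3)
  expect_lt(acos(abs(sum(pl$normal * n_true))) * 180 / pi, 2)
})

test_that("plane normal orients away from the apex side when a mesh is given", {
  ico <- mesh_icosphere(10, 2, center = c(0, 0, 8))
  pl <- fit_plane(rbind(c(1, 0, 0), c(0, 1, 0), c(-1, -1, 0)), mesh = ico)
  expect_equal(pl$normal, c(0, 0, -1))   # mesh sits at z > 0
})

test_that("sphere cross-section contour has the Pythagorean radius", {
  ico <- mesh_icosphere(10, 4)
  ct <- intersect_mesh_plane(ico, cutting_plane(c(0, 0, 6), c(0, 0, 1)))
  r <- sqrt(rowSums(ct$points[, 1:2, drop = FALSE]^2))
  expect_lt(max(abs(r - 8)) / 8, 0.005)
  expect_lt(max(abs(ct$points[, 3] - 6)), 1e-6)
  a_true <- pi * 64 / 100
  expect_lt(abs(contour_area(ct) - a_true) / a_true, 0.01)
  expect_error(intersect_mesh_plane(ico, cutting_plane(c(0, 0, 20), c(0, 0, 1))),
               "does not intersect")
})

test_that("contour points run counterclockwise about the plane normal", {
  ico <- mesh_icosphere(10, 3)
  pl <- cutting_plane(c(0, 0, 2), c(0, 0, 1))
  ct <- intersect_mesh_plane(ico, pl)
  p2 <- laa3d:::contour_2d(ct$points, pl)
  expect_gt(laa3d:::shoelace(p2), 0)
})

test_that("loop selection prefers the largest area unless anchored", {
  big <- mesh_icosphere(10, 3)
  small <- mesh_icosphere(5, 3, center = c(30, 0, 0))
  both <- triangle_mesh(rbind(big$vertices, small$vertices),
                        rbind(big$triangles, small$triangles + nrow(big$vertices)))
  pl <- cutting_plane(c(0, 0, 0), c(0, 0, 1))
  ct <- intersect_mesh_plane(both, pl)
  expect_lt(abs(contour_area(ct) - pi), 0.03)           # big loop, ~3.14 cm^2
  ct2 <- intersect_mesh_plane(both, pl, anchor = c(30, 0, 0))
  expect_lt(abs(contour_area(ct2) - pi * 25 / 100), 0.02)
  # an open surface whose boundary crosses the plane is rejected
  hemi <- crop_mesh(big, crop_spec(c(0, 0, -3), c(0, 0, 1), c(0, 0, 9)))
  expect_error(intersect_mesh_plane(hemi, cutting_plane(c(0, 0, 0), c(1, 0, 0))),
               "not closed across plane")
})

test_that("contour area matches closed forms", {
  pl <- cutting_plane(c(0, 0, 0), c(0, 0, 1))
  sq <- ostium_contour(rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), c(0, 10, 0)), pl)
  expect_equal(contour_area(sq), 1)
  th <- 2 * pi * (0:359) / 360
  ngon <- ostium_contour(cbind(10 * cos(th), 10 * sin(th), 0), pl)
  expect_lt(abs(contour_area(ngon) - pi) / pi, 1e-4)
  th2 <- 2 * pi * (0:719) / 720
  ell <- ostium_contour(cbind(15 * cos(th2), 8 * sin(th2), 0), pl)
  expect_lt(abs(contour_area(ell) - pi * 15 * 8 / 100) / (pi * 1.2), 0.001)
  expect_error(ostium_contour(rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0)), pl),
               "do not lie on the plane")
})

test_that("contour area is invariant under rigid motion of mesh and plane", {
  ico <- mesh_icosphere(10, 3)
  pl <- cutting_plane(c(0, 0, 4), c(0, 0, 1))
  a0 <- contour_area(intersect_mesh_plane(ico, pl))
  ang <- c(0.4, -1.1, 0.7)
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])), c(0, sin(ang[1]), cos(ang[1])))
  Ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0), c(-sin(ang[2]), 0, cos(ang[2])))
  Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0), c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  Q <- Rx %*% Ry %*% Rz
  shift <- c(3, -7, 11)
  ico2 <- triangle_mesh(ico$vertices %*% t(Q) +
                          matrix(shift, nrow(ico$vertices), 3, byrow = TRUE),
                        ico$triangles)
  pl2 <- cutting_plane(as.numeric(Q %*% c(0, 0, 4)) + shift, as.numeric(Q %*% c(0, 0, 1)))
  a1 <- contour_area(intersect_mesh_plane(ico2, pl2))
  expect_lt(abs(a1 - a0) / a0, 1e-9)
})

test_that("capping a hemisphere restores the analytic half-sphere volume", {
  ico <- mesh_icosphere(10, 3)
  pl <- cutting_plane(c(0, 0, 0), c(0, 0, 1))
  up <- crop_mesh(ico, crop_spec(c(0, 0, 0), c(0, 0, 1), c(0, 0, 9)))
  ct <- intersect_mesh_plane(ico, pl)
  model <- close_surface(up, ct)
  expect_true(mesh_is_watertight(model$mesh))
  expect_identical(model$cap_method, "centroid_fan")
  v_true <- 0.5 * 4 / 3 * pi
  expect_lt(abs(mesh_volume(model$mesh) - v_true) / v_true, 0.01)
  # the cap is the contour polygon: identical areas
  cap <- model$mesh$triangles[model$cap_triangles, , drop = FALSE]
  cap_area <- mesh_area(triangle_mesh(model$mesh$vertices, cap)) / 100
  expect_lt(abs(cap_area - contour_area(ct)) / contour_area(ct), 1e-6)
  # cap triangles are coplanar with the cutting plane
  cap_z <- model$mesh$vertices[unique(as.integer(cap)), 3]
  expect_lt(max(abs(cap_z)), 1e-6)
  # mismatched contour is refused
  ct_wrong <- intersect_mesh_plane(ico, cutting_plane(c(0, 0, 1), c(0, 0, 1)))
  expect_error(close_surface(up, ct_wrong), "contour mismatch")
})

test_that("non-star-shaped contours are capped by ear clipping", {
  # crescent prism: analytic volume = polygon area x height
  th_out <- seq(-110, 110, length.out = 25) * pi / 180
  th_in <- rev(th_out)
  poly <- rbind(cbind(20 * cos(th_out), 20 * sin(th_out)),
                cbind(6 + 13 * cos(th_in), 13 * sin(th_in)))
  n <- nrow(poly)
  h <- 20
  area_mm2 <- abs(laa3d:::shoelace(poly))
  bot <- cbind(poly, 0)
  top <- cbind(poly, h)
  verts <- rbind(bot, top)
  i2 <- c(2:n, 1)
  wall <- rbind(cbind(seq_len(n), i2, n + i2),
                cbind(seq_len(n), n + i2, n + seq_len(n)))
  # top cap as a ladder strip between the two arcs (independent triangulation)
  m <- n / 2
  out_idx <- n + seq_len(m)
  in_idx <- n + n:(m + 1)
  strip <- NULL
  for (k in seq_len(m - 1)) {
    strip <- rbind(strip,
                   c(out_idx[k], out_idx[k + 1], in_idx[k + 1]),
                   c(out_idx[k], in_idx[k + 1], in_idx[k]))
  }
  open_mesh <- triangle_mesh(verts, rbind(wall, strip))
  expect_identical(length(laa3d:::boundary_cycles(open_mesh)), 1L)

  pl <- cutting_plane(c(0, 0, 0), c(0, 0, 1))
  ct <- ostium_contour(bot, pl)
  model <- close_surface(open_mesh, ct)
  expect_identical(model$cap_method, "ear_clipping")
  expect_true(mesh_is_watertight(model$mesh))
  v_true <- area_mm2 * h / 1000
  expect_lt(abs(mesh_volume(model$mesh) - v_true) / v_true, 1e-9)
  # cross-method: voxelization of the same model agrees
  vx <- voxelize_volume(model, c(0.419, 0.419, 1))
  expect_lt(abs(vx$volume_cm3 - v_true) / v_true, 0.03)
})

test_that("voxelization reproduces the aligned cube exactly", {
  vx <- voxelize_volume(mesh_cube(10), c(1, 1, 1))
  expect_identical(vx$count, 1000)
  expect_equal(vx$volume_cm3, 1)
  up <- crop_mesh(mesh_icosphere(10, 2), crop_spec(c(0, 0, 0), c(0, 0, 1), c(0, 0, 9)))
  expect_error(voxelize_volume(up, c(1, 1, 1)), "not watertight")
})

test_that("voxelization and mesh volume agree on the icosphere at CT spacing", {
  ico <- mesh_icosphere(15, 4)
  vx <- voxelize_volume(ico, c(0.419, 0.419, 1))
  v_true <- 4 / 3 * pi * 15^3 / 1000
  expect_lt(abs(vx$volume_cm3 - v_true) / v_true, 0.015)
  vm <- mesh_volume(ico)
  expect_lt(abs(vx$volume_cm3 - vm) / vm, 0.02)
})

test_that("voxelization error contracts when the spacing is halved", {
  ico <- mesh_icosphere(15, 3)
  vm <- mesh_volume(ico)
  e1 <- abs(voxelize_volume(ico, c(3.352, 3.352, 8))$volume_cm3 - vm)
  e2 <- abs(voxelize_volume(ico, c(0.838, 0.838, 2))$volume_cm3 - vm)
  expect_lt(e2, e1)
})

test_that("degenerate resolution warns but still returns a volume", {
  ico <- mesh_icosphere(5, 3)
  expect_warning(vx <- voxelize_volume(ico, c(10, 10, 10)), "fewer than 10")
  expect_true(vx$volume_cm3 >= 0)
})

test_that("Simpson slice-stack volume matches its closed forms", {
  expect_equal(simpson_volume(1.0, 10), 1)
  expect_equal(simpson_volume(rep(0, 5), 1), 0)
  expect_error(simpson_volume(c(1, -0.1), 1), "non-negative")
  z <- seq(-14.5, 14.5, by = 1)
  areas <- pi * (15^2 - z^2) / 100
  v_true <- 4 / 3 * pi * 15^3 / 1000
  expect_lt(abs(simpson_volume(areas, 1) - v_true) / v_true, 0.01)
})

test_that("Simpson volume of a convex solid converges to the mesh volume", {
  v_true <- 4 / 3 * pi * 15^3 / 1000
  err <- vapply(c(2, 1, 0.5), function(h) {
    z <- seq(-15 + h / 2, 15, by = h)
    abs(simpson_volume(pi * pmax(15^2 - z^2, 0) / 100, h) - v_true)
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})
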