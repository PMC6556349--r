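# Dynamic digital phantom: a bright blood-pool solid (static left-atrial
# sphere joined through a cylindrical neck to a lobed ellipsoidal appendage)
# on a dark background, rendered at CT-like resolution over a cardiac cycle.
# The appendage is scaled per phase about a fixed point on the ostium plane,
# so the true appendage volume scales exactly with s(t)^3 and the ostium
# cross-section with s(t)^2; ground truth therefore needs one oversampled
# integration at s = 1.

#' Phantom specification
#'
#' Defaults render a phantom whose diastolic ostium area (~3.8 cm^2) and
#' appendage volume (~10 cm^3) sit in the range reported for patients
#' scheduled for appendage closure, at CT-native resolution
#' (0.419 x 0.419 x 1 mm) with 10 cardiac phases and a contraction profile
#' whose true ejection fraction is `1 - 0.87^3` (about 34%).
#'
#' @param la_radius Left-atrial body radius, mm.
#' @param laa_semiaxes Appendage ellipsoid semiaxes `(a, b, c)`, mm; `a` runs
#'   along the appendage axis (+x).
#' @param neck_radius Ostium neck cylinder radius, mm (must not exceed
#'   `min(b, c)`).
#' @param n_lobes Number of cosine lobes sculpted into the ellipsoid.
#' @param lobe_amplitude Approximate radial lobe amplitude, mm.
#' @param blood_intensity,background_intensity Rendered intensities (HU-like).
#' @param noise_sd Additive Gaussian noise standard deviation; blood contrast
#'   must exceed `background + 3 * noise_sd`.
#' @param spacing Voxel spacing, mm.
#' @param n_phases Number of cardiac phases (>= 2).
#' @param scale_profile Per-phase appendage scale factors `s(t)`, all > 0.
#' @param seed RNG seed for the noise.
#' @param margin Field-of-view margin beyond the solid, mm.
#' @param truth_oversample Linear oversampling factor of the ground-truth
#'   integration grid relative to `spacing`.
#' @param fov Optional list with `xlim`, `ylim`, `zlim` (mm) overriding the
#'   derived field of view.
#' @return An object of class `laa_phantom_spec`.
#' @export
phantom_spec <- function(la_radius = 22, laa_semiaxes = c(20, 13, 11),
                         neck_radius = 11, n_lobes = 3, lobe_amplitude = 1.5,
                         blood_intensity = 300, background_intensity = 0,
                         noise_sd = 15, spacing = c(0.419, 0.419, 1),
                         n_phases = 10,
                         scale_profile = c(1, 0.98, 0.93, 0.89, 0.87,
                                           0.89, 0.93, 0.96, 0.99, 1),
                         seed = 1L, margin = 4, truth_oversample = 10,
                         fov = NULL) {
  stopifnot(la_radius > 0, all(laa_semiaxes > 0), neck_radius > 0,
            lobe_amplitude >= 0, n_lobes >= 0, all(spacing > 0),
            n_phases >= 2, margin > 0, truth_oversample >= 1)
  if (length(scale_profile) != n_phases)
    stop("`scale_profile` must have one factor per phase", call. = FALSE)
  if (any(scale_profile <= 0)) stop("scale factors must be positive", call. = FALSE)
  if (blood_intensity <= background_intensity + 3 * noise_sd)
    stop("intensity separation too small: need blood > background + 3*noise_sd",
         call. = FALSE)
  if (neck_radius > min(laa_semiaxes[2:3]))
    stop("neck_radius must not exceed the transverse ellipsoid semiaxes",
         call. = FALSE)
  geom <- list(
    cyl_x0 = la_radius - 6,
    cyl_x1 = la_radius + 6,
    ostium_x = la_radius + 2,                       # ostium plane location
    ell_cx = la_radius + 6 + 0.55 * laa_semiaxes[1] # ellipsoid centre on +x
  )
  # ellipsoid cross-section at the ostium plane must stay inside the neck so
  # the true ostium area is the analytic disc
  fr <- (geom$ostium_x - geom$ell_cx) / laa_semiaxes[1]
  if (abs(fr) < 1 &&
      (laa_semiaxes[2] + lobe_amplitude) * sqrt(1 - fr^2) >= neck_radius)
    warning("ellipsoid bulges past the neck at the ostium plane; ",
            "analytic ostium-area truth will be biased", call. = FALSE)
  spec <- structure(
    list(la_radius = la_radius, laa_semiaxes = laa_semiaxes,
         neck_radius = neck_radius, n_lobes = n_lobes,
         lobe_amplitude = lobe_amplitude, blood_intensity = blood_intensity,
         background_intensity = background_intensity, noise_sd = noise_sd,
         spacing = as.numeric(spacing), n_phases = as.integer(n_phases),
         scale_profile = as.numeric(scale_profile), seed = as.integer(seed),
         margin = margin, truth_oversample = truth_oversample, geom = geom),
    class = "laa_phantom_spec")
  ext <- phantom_extent(spec)
  spec$fov <- fov %||% ext
  for (ax in c("xlim", "ylim", "zlim")) {
    if (spec$fov[[ax]][1] > ext[[ax]][1] + 1e-9 ||
        spec$fov[[ax]][2] < ext[[ax]][2] - 1e-9)
      stop("appendage overlapping volume boundary: enlarge field of view",
           call. = FALSE)
  }
  spec
}

# solid bounding box plus margin, covering every phase
phantom_extent <- function(spec) {
  g <- spec$geom
  smax <- max(spec$scale_profile)
  a <- spec$laa_semiaxes[1]
  amp <- spec$lobe_amplitude
  half_yz <- max(spec$la_radius, spec$neck_radius,
                 max(spec$laa_semiaxes[2:3]) + amp) * max(1, smax) + spec$margin
  xmax <- g$ostium_x + (g$ell_cx + a + amp - g$ostium_x) * smax + spec$margin
  list(xlim = c(-spec$la_radius - spec$margin, xmax),
       ylim = c(-half_yz, half_yz), zlim = c(-half_yz, half_yz))
}

phantom_params <- function(spec, s) {
  g <- spec$geom
  c(spec$la_radius, g$cyl_x0, g$cyl_x1, spec$neck_radius, g$ell_cx,
    spec$laa_semiaxes, spec$n_lobes, spec$lobe_amplitude, s, g$ostium_x)
}

phantom_axes <- function(spec) {
  f <- spec$fov
  mk <- function(lim, sp) seq(lim[1] + sp / 2, lim[2], by = sp)
  list(x = mk(f$xlim, spec$spacing[1]),
       y = mk(f$ylim, spec$spacing[2]),
       z = mk(f$zlim, spec$spacing[3]))
}

#' Render one phantom phase
#'
#' Voxel intensity is `blood_intensity` where the voxel centre lies inside
#' the implicit solid at this phase's scale factor, else
#' `background_intensity`; Gaussian noise with the spec's seed (offset by the
#' phase index) is added on top. Ground truth accompanies the volume.
#'
#' @param spec A [phantom_spec()].
#' @param phase_index 1-based phase number.
#' @return List with `volume` (an [image_volume()]) and `truth`
#'   (see [phantom_truth()]).
#' @export
make_static_phantom <- function(spec, phase_index = 1L) {
  if (phase_index < 1 || phase_index > spec$n_phases)
    stop("phase_index out of range", call. = FALSE)
  list(volume = make_static_phantom_volume(spec, phase_index),
       truth = phantom_truth(spec))
}

#' Ground truth of the phantom
#'
#' The base appendage volume (everything distal to the ostium plane at scale
#' 1) is integrated on a grid oversampled `truth_oversample`-fold relative to
#' the rendering spacing; per-phase volumes follow exactly as `s(t)^3` times
#' the base volume and ostium areas as `pi * neck_radius^2 * s(t)^2`. This
#' oversampled indicator integration is independent of the segmentation,
#' surface and voxelization code it validates.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `laa_phantom_truth`: per-phase `volumes_cm3`
#'   and `ostium_areas_cm2`, `ef`, the ostium `plane`, and a [landmark_set()]
#'   with the ostium cut points and seeds.
#' @export
phantom_truth <- function(spec) {
  g <- spec$geom
  amp <- spec$lobe_amplitude
  step <- spec$spacing / spec$truth_oversample
  xmax <- g$ell_cx + spec$laa_semiaxes[1] + amp + 1
  half <- max(spec$neck_radius, max(spec$laa_semiaxes[2:3]) + amp) + 1
  xs <- seq(g$ostium_x + step[1] / 2, xmax, by = step[1])
  ys <- seq(-half + step[2] / 2, half, by = step[2])
  zs <- seq(-half + step[3] / 2, half, by = step[3])
  n_in <- cpp_phantom_count(xs, ys, zs, phantom_params(spec, 1))
  v_base <- n_in * prod(step) / 1000                       # cm^3 at s = 1
  s <- spec$scale_profile
  volumes <- v_base * s^3
  areas <- pi * spec$neck_radius^2 * s^2 / 100             # cm^2
  lm <- landmark_set(
    name = c("cut1", "cut2", "cut3", "cut4", "laa", "la"),
    role = c(rep("ostium_cut", 4), "laa_seed", "la_seed"),
    x = c(rep(g$ostium_x, 4), g$ostium_x + 2, 0),
    y = c(spec$neck_radius, 0, -spec$neck_radius, 0, 0, 0),
    z = c(0, spec$neck_radius, 0, -spec$neck_radius, 0, 0))
  structure(list(volumes_cm3 = volumes, ostium_areas_cm2 = areas,
                 ef = 1 - (min(s) / max(s))^3,
                 phase_percents = 100 * (seq_len(spec$n_phases) - 1) / spec$n_phases,
                 plane = cutting_plane(c(g$ostium_x, 0, 0), c(1, 0, 0)),
                 landmarks = lm, base_volume_cm3 = v_base, spec = spec),
            class = "laa_phantom_truth")
}

#' @export
print.laa_phantom_truth <- function(x, ...) {
  cat("<laa_phantom_truth> EF ", format(100 * x$ef, digits = 4), "%, volumes ",
      format(min(x$volumes_cm3), digits = 4), "-",
      format(max(x$volumes_cm3), digits = 4), " cm^3 over ",
      length(x$volumes_cm3), " phases\n", sep = "")
  invisible(x)
}

#' Render the full dynamic phantom series
#'
#' One volume per cardiac phase with the scale profile applied to the
#' appendage only (the atrial body stays static), phases at
#' `100 * k / n_phases` percent of the RR interval.
#'
#' @param spec A [phantom_spec()].
#' @return List with `stack` (a [phase_stack()]) and `truth`
#'   (see [phantom_truth()]).
#' @export
make_dynamic_series <- function(spec) {
  truth <- phantom_truth(spec)
  vols <- lapply(seq_len(spec$n_phases), function(k)
    make_static_phantom_volume(spec, k))
  list(stack = phase_stack(vols, truth$phase_percents), truth = truth)
}

# rendering only (no truth recomputation)
make_static_phantom_volume <- function(spec, phase_index) {
  ax <- phantom_axes(spec)
  s <- spec$scale_profile[phase_index]
  ind <- cpp_phantom_grid(ax$x, ax$y, ax$z, phantom_params(spec, s))
  dims <- c(length(ax$x), length(ax$y), length(ax$z))
  data <- array(spec$background_intensity +
                  as.numeric(ind) * (spec$blood_intensity - spec$background_intensity),
                dim = dims)
  if (spec$noise_sd > 0)
    data <- data + with_seed(spec$seed + phase_index,
                             array(rnorm(prod(dims), sd = spec$noise_sd), dim = dims))
  image_volume(data, spacing = spec$spacing,
               origin = c(ax$x[1], ax$y[1], ax$z[1]),
               phase_label = 100 * (phase_index - 1) / spec$n_phases)
}
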