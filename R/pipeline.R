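# End-to-end per-case pipeline: per phase, segment -> component-select ->
# surface -> crop -> ostium cut -> close -> voxelize; then aggregate the
# volume-time curve into the function report. Threshold and landmarks chosen
# for the first phase are reused for the others unless overridden, mirroring
# the interactive workflow where adjustment is usually needed only for the
# first frame.

#' Case configuration
#'
#' @param input A [phase_stack()], a single [image_volume()], or a character
#'   vector of per-phase volume paths (read with [read_volume()]).
#' @param landmarks A [landmark_set()] or path to a landmark CSV; must hold
#'   `ostium_cut` points and one `laa_seed`.
#' @param phase_percents Phase positions when `input` is paths; inferred
#'   otherwise.
#' @param threshold Optional intensity threshold overriding the automatic
#'   one.
#' @param spacing Optional length-3 spacing (mm) for the volumetry grid;
#'   defaults to the source CT spacing.
#' @param crop_margin_mm Distance (mm) the preliminary crop plane is shifted
#'   from the ostium plane into the atrium.
#' @param body Optional [body_metrics()] for BSA normalization.
#' @param out_dir Optional directory for intermediate STL meshes and the JSON
#'   report.
#' @return An object of class `laa_case_config`.
#' @export
case_config <- function(input, landmarks, phase_percents = NULL,
                        threshold = NULL, spacing = NULL, crop_margin_mm = 3,
                        body = NULL, out_dir = NULL) {
  if (is.character(landmarks)) landmarks <- read_landmarks(landmarks)
  if (nrow(landmarks[landmarks$role == "ostium_cut", ]) < 3)
    stop("landmarks must include at least 3 ostium_cut points", call. = FALSE)
  if (sum(landmarks$role == "laa_seed") != 1)
    stop("landmarks must include exactly one laa_seed", call. = FALSE)
  if (crop_margin_mm <= 0) stop("crop_margin_mm must be positive", call. = FALSE)
  structure(list(input = input, landmarks = landmarks,
                 phase_percents = phase_percents, threshold = threshold,
                 spacing = spacing, crop_margin_mm = crop_margin_mm,
                 body = body, out_dir = out_dir),
            class = "laa_case_config")
}

load_case_stack <- function(config) {
  input <- config$input
  if (inherits(input, "laa_phase_stack")) return(input)
  if (inherits(input, "laa_volume"))
    return(phase_stack(list(input), input$phase_label %||% 0))
  if (is.character(input)) {
    vols <- lapply(input, read_volume)
    pp <- config$phase_percents %||% (100 * (seq_along(vols) - 1) / length(vols))
    return(phase_stack(vols, pp))
  }
  stop("unsupported case input", call. = FALSE)
}

#' Run the full 3D analysis for one case
#'
#' Per phase: threshold segmentation of the blood pool, connected-component
#' selection from the appendage seed, isosurface extraction, plane-based
#' preliminary crop, ostium plane fit, mesh-plane intersection for the ostium
#' contour, surface capping, and voxelization volumetry at the CT spacing.
#' The per-phase series then yields the ejection fraction; measurements are
#' BSA-normalized when body metrics are supplied. Any stage failure is
#' reported with its phase index and stage name.
#'
#' @param config A [case_config()].
#' @return An object of class `laa_case_report`: `phases` (a tibble with
#'   ostium area and both volume definitions per phase), `series` (a
#'   [phase_series()]), `func` (a `laa_function`, `NULL` with a flag for a
#'   single-phase case), `normalized`, and `decisions` (the log of every
#'   operator-replaceable choice).
#' @export
run_case <- function(config) {
  stack <- load_case_stack(config)
  lm <- config$landmarks
  laa_seed <- as.numeric(landmark_points(lm, "laa_seed")[1, ])
  n_phase <- length(stack$volumes)
  stage <- function(phase, name, expr) {
    tryCatch(expr, error = function(e)
      stop("phase ", phase, " [", name, "]: ", conditionMessage(e), call. = FALSE))
  }
  threshold <- config$threshold
  threshold_source <- if (is.null(threshold)) "auto (Otsu)" else "override"
  rows <- vector("list", n_phase)
  decisions <- list(threshold_source = threshold_source,
                    crop_margin_mm = config$crop_margin_mm,
                    cap_method = character(n_phase),
                    loop_count = integer(n_phase))
  for (p in seq_len(n_phase)) {
    vol <- stack$volumes[[p]]
    if (is.null(threshold))
      threshold <- stage(p, "auto_threshold", auto_threshold(vol))
    mask <- stage(p, "apply_threshold", apply_threshold(vol, threshold))
    comp <- stage(p, "select_component", select_component(mask, laa_seed))
    mesh <- stage(p, "extract_surface", extract_surface(comp))
    plane <- stage(p, "fit_plane", fit_plane(lm, mesh))
    n_laa <- plane$normal
    if (sum((laa_seed - plane$point) * n_laa) < 0) n_laa <- -n_laa
    crop1 <- stage(p, "crop_mesh", crop_mesh(mesh, crop_spec(
      plane$point - config$crop_margin_mm * n_laa, plane$normal, laa_seed)))
    contour <- stage(p, "intersect_mesh_plane",
                     intersect_mesh_plane(crop1, plane, anchor = laa_seed))
    open_laa <- stage(p, "ostium_cut", crop_mesh(crop1, crop_spec(
      plane$point, plane$normal, laa_seed)))
    model <- stage(p, "close_surface", close_surface(open_laa, contour))
    vox <- stage(p, "voxelize_volume",
                 voxelize_volume(model, config$spacing %||% vol$spacing))
    decisions$cap_method[p] <- model$cap_method
    decisions$loop_count[p] <- 1L
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_stl(mesh, file.path(config$out_dir, sprintf("phase%02d_la.stl", p)))
      write_stl(model$mesh,
                file.path(config$out_dir, sprintf("phase%02d_laa_closed.stl", p)))
    }
    rows[[p]] <- tibble::tibble(
      phase_percent = stack$phase_percents[p],
      ostium_area_cm2 = contour_area(contour),
      volume_cm3 = vox$volume_cm3,
      mesh_volume_cm3 = mesh_volume(model$mesh),
      threshold = threshold)
  }
  phases <- do.call(rbind, rows)
  series <- phase_series(phases$phase_percent, phases$volume_cm3,
                         phases$ostium_area_cm2)
  func <- NULL
  ef_omitted <- n_phase < 2
  if (!ef_omitted) func <- ejection_fraction(series)
  normalized <- NULL
  if (!is.null(config$body)) {
    di <- if (is.null(func)) 1L else func$diastolic_index
    si <- if (is.null(func)) 1L else func$systolic_index
    normalized <- tibble::tibble(
      parameter = c("diastolic_ostium_area_cm2_m2", "systolic_ostium_area_cm2_m2",
                    "diastolic_volume_cm3_m2", "systolic_volume_cm3_m2"),
      value = normalize_by_bsa(
        c(phases$ostium_area_cm2[di], phases$ostium_area_cm2[si],
          phases$volume_cm3[di], phases$volume_cm3[si]), config$body))
  }
  report <- structure(list(phases = phases, series = series, func = func,
                           ef_omitted = ef_omitted, normalized = normalized,
                           decisions = decisions),
                      class = "laa_case_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_case_report(report, file.path(config$out_dir, "report.json"))
  }
  report
}

#' @export
print.laa_case_report <- function(x, ...) {
  cat("<laa_case_report> ", nrow(x$phases), " phase(s)\n", sep = "")
  print(x$phases)
  if (!is.null(x$func)) print(x$func)
  else cat("single-phase case: ejection fraction omitted\n")
  invisible(x)
}

#' Write a case report as JSON
#'
#' @param report A `laa_case_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_case_report <- function(report, path) {
  payload <- list(
    schema = "laa3d-case-report/1",
    phases = report$phases,
    ef_omitted = report$ef_omitted,
    decisions = report$decisions)
  if (!is.null(report$func)) payload$func <- glance(report$func)
  if (!is.null(report$normalized)) payload$normalized <- report$normalized
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
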