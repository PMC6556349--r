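# Phase-resolved LAA function (volume-time curve, ejection fraction) and the
# method-agreement statistics used for validation: within-subject coefficient
# of variation, Bland-Altman bias with 95% limits of agreement, paired t-test.

#' Phase series of LAA measurements
#'
#' @param phase_percent Strictly increasing phase positions, percent of the
#'   RR interval, each in `[0, 100)`.
#' @param volume_cm3 LAA volume per phase, cm^3 (all > 0).
#' @param ostium_area_cm2 Optional ostium area per phase, cm^2.
#' @return A tibble with class `laa_phase_series`.
#' @export
phase_series <- function(phase_percent, volume_cm3, ostium_area_cm2 = NULL) {
  phase_percent <- as.numeric(phase_percent)
  volume_cm3 <- as.numeric(volume_cm3)
  if (length(phase_percent) != length(volume_cm3))
    stop("`phase_percent` and `volume_cm3` lengths differ", call. = FALSE)
  if (any(phase_percent < 0 | phase_percent >= 100) ||
      (length(phase_percent) > 1 && any(diff(phase_percent) <= 0)))
    stop("`phase_percent` must be strictly increasing within [0, 100)", call. = FALSE)
  if (any(!is.finite(volume_cm3)) || any(volume_cm3 <= 0))
    stop("volumes must be finite and positive", call. = FALSE)
  out <- tibble::tibble(phase_percent = phase_percent, volume_cm3 = volume_cm3)
  if (!is.null(ostium_area_cm2)) {
    if (length(ostium_area_cm2) != length(volume_cm3))
      stop("`ostium_area_cm2` length differs", call. = FALSE)
    out$ostium_area_cm2 <- as.numeric(ostium_area_cm2)
  }
  class(out) <- c("laa_phase_series", class(out))
  out
}

#' LAA ejection fraction from the volume-time curve
#'
#' The diastolic phase is the volume maximum and the systolic phase the
#' minimum (first occurrence on ties); the ejection fraction is
#' `(Vmax - Vmin) / Vmax`.
#'
#' @param series A [phase_series()] or data frame with columns
#'   `phase_percent` and `volume_cm3`.
#' @return An object of class `laa_function` with elements `ef` (fraction),
#'   `ef_percent`, `diastolic_index` / `systolic_index` (1-based positions in
#'   the series), `diastolic_volume` / `systolic_volume` (cm^3),
#'   `diastolic_phase` / `systolic_phase` (% RR) and the input `series`.
#' @export
ejection_fraction <- function(series) {
  if (!is.data.frame(series))
    stop("`series` must be a data frame (see phase_series())", call. = FALSE)
  if (!all(c("phase_percent", "volume_cm3") %in% names(series)))
    stop("`series` needs columns phase_percent and volume_cm3", call. = FALSE)
  v <- series$volume_cm3
  if (length(v) < 2) stop("at least 2 phases are required", call. = FALSE)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("volumes must be finite and positive", call. = FALSE)
  di <- which.max(v)
  si <- which.min(v)
  ef <- (v[di] - v[si]) / v[di]
  structure(list(ef = ef, ef_percent = 100 * ef,
                 diastolic_index = di, systolic_index = si,
                 diastolic_volume = v[di], systolic_volume = v[si],
                 diastolic_phase = series$phase_percent[di],
                 systolic_phase = series$phase_percent[si],
                 series = series),
            class = "laa_function")
}

#' @export
print.laa_function <- function(x, ...) {
  cat("<laa_function> EF ", format(x$ef_percent, digits = 3), "% (V ",
      format(x$diastolic_volume, digits = 4), " -> ",
      format(x$systolic_volume, digits = 4), " cm^3; diastole at ",
      x$diastolic_phase, "% RR, systole at ", x$systolic_phase, "% RR)\n",
      sep = "")
  invisible(x)
}

#' @rdname ejection_fraction
#' @param x A `laa_function` object.
#' @param ... Unused.
#' @method tidy laa_function
#' @export
tidy.laa_function <- function(x, ...) {
  out <- tibble::as_tibble(x$series)
  out$is_diastole <- seq_len(nrow(out)) == x$diastolic_index
  out$is_systole <- seq_len(nrow(out)) == x$systolic_index
  out
}

#' @rdname ejection_fraction
#' @method glance laa_function
#' @export
glance.laa_function <- function(x, ...) {
  tibble::tibble(ef = x$ef, ef_percent = x$ef_percent,
                 diastolic_volume_cm3 = x$diastolic_volume,
                 systolic_volume_cm3 = x$systolic_volume,
                 diastolic_phase_percent = x$diastolic_phase,
                 systolic_phase_percent = x$systolic_phase,
                 n_phases = nrow(x$series))
}

#' Body metrics and body surface area (Mosteller)
#'
#' BSA by the Mosteller formula `sqrt(height_cm * weight_kg / 3600)` (m^2).
#'
#' @param height_cm Height in cm (> 0).
#' @param weight_kg Weight in kg (> 0).
#' @return List with `height`, `weight` and `bsa` (class `laa_body`).
#' @export
body_metrics <- function(height_cm, weight_kg) {
  if (height_cm <= 0 || weight_kg <= 0)
    stop("height and weight must be positive", call. = FALSE)
  structure(list(height = height_cm, weight = weight_kg,
                 bsa = sqrt(height_cm * weight_kg / 3600)),
            class = "laa_body")
}

#' Normalize a measurement by body surface area
#'
#' @param value Measurement (cm^2 or cm^3).
#' @param body A [body_metrics()] object.
#' @return `value / bsa` (cm^2/m^2 or cm^3/m^2).
#' @export
normalize_by_bsa <- function(value, body) {
  if (!inherits(body, "laa_body")) stop("`body` must come from body_metrics()", call. = FALSE)
  value / body$bsa
}

#' Paired measurement table for agreement analysis
#'
#' @param m1,m2 Paired measurements of one parameter (same units) by two
#'   observers or two methods.
#' @param subject Optional subject identifiers.
#' @return A tibble with class `laa_agreement_table`.
#' @export
agreement_table <- function(m1, m2, subject = NULL) {
  m1 <- as.numeric(m1); m2 <- as.numeric(m2)
  if (length(m1) != length(m2)) stop("`m1` and `m2` lengths differ", call. = FALSE)
  if (length(m1) < 2) stop("at least 2 paired measurements are required", call. = FALSE)
  if (any(!is.finite(m1)) || any(!is.finite(m2)))
    stop("measurements must be finite", call. = FALSE)
  out <- tibble::tibble(subject = subject %||% seq_along(m1), m1 = m1, m2 = m2)
  class(out) <- c("laa_agreement_table", class(out))
  out
}

as_agreement <- function(table) {
  if (!is.data.frame(table) || !all(c("m1", "m2") %in% names(table)))
    stop("agreement data needs columns m1 and m2 (see agreement_table())",
         call. = FALSE)
  if (nrow(table) < 2) stop("at least 2 paired measurements are required", call. = FALSE)
  table
}

#' Within-subject coefficient of variation for two raters
#'
#' `CoV = 100 * sqrt(mean(d_i^2 / 2)) / grand mean`, with `d_i = m1_i - m2_i`
#' and the grand mean taken over all `2n` values: the root-mean-square
#' within-subject CoV, the standard reproducibility companion to
#' Bland-Altman bias and limits. The `definition` column records this
#' convention.
#'
#' @param table An [agreement_table()] or data frame with columns `m1`, `m2`.
#' @return One-row tibble with `cov_percent`, `n` and `definition`.
#' @export
coefficient_of_variation <- function(table) {
  table <- as_agreement(table)
  d <- table$m1 - table$m2
  gm <- mean(c(table$m1, table$m2))
  if (gm <= 0) stop("grand mean must be positive for a CoV", call. = FALSE)
  tibble::tibble(cov_percent = 100 * sqrt(mean(d^2 / 2)) / gm,
                 n = nrow(table),
                 definition = "within-subject RMS, two raters")
}

#' Bland-Altman bias and 95% limits of agreement
#'
#' Bias is the mean paired difference `m1 - m2`; the limits are
#' `bias +/- 1.96 * SD(d)` (sample SD). `interval` renders the open-ended
#' "]lower; upper[" style used in reproducibility tables.
#'
#' @param table An [agreement_table()] or data frame with columns `m1`, `m2`.
#' @return One-row tibble with class `laa_bland_altman`: `bias`, `loa_lower`,
#'   `loa_upper`, `sd_diff`, `n` and `interval`; the paired data used are
#'   attached as the `"data"` attribute for plotting.
#' @export
bland_altman <- function(table) {
  table <- as_agreement(table)
  d <- table$m1 - table$m2
  bias <- mean(d)
  s <- sd(d)
  out <- tibble::tibble(bias = bias,
                        loa_lower = bias - 1.96 * s,
                        loa_upper = bias + 1.96 * s,
                        sd_diff = s, n = nrow(table),
                        interval = sprintf("]%.2f; %.2f[", bias - 1.96 * s,
                                           bias + 1.96 * s))
  attr(out, "data") <- tibble::tibble(mean = (table$m1 + table$m2) / 2, diff = d)
  class(out) <- c("laa_bland_altman", class(out))
  out
}

#' Paired t-test for agreement between methods
#'
#' `t = mean(d) / (SD(d) / sqrt(n))` with `n - 1` degrees of freedom and a
#' two-sided p-value. When every paired difference is zero the statistic is
#' defined as 0 with p = 1.
#'
#' @param table An [agreement_table()] or data frame with columns `m1`, `m2`.
#' @return One-row tibble with `t`, `df`, `p_value`, `mean_diff` and `n`.
#' @export
paired_t_test <- function(table) {
  table <- as_agreement(table)
  d <- table$m1 - table$m2
  n <- length(d)
  if (all(d == 0))
    return(tibble::tibble(t = 0, df = n - 1, p_value = 1, mean_diff = 0, n = n))
  s <- sd(d)
  if (s == 0) stop("paired differences are constant but non-zero; t undefined",
                   call. = FALSE)
  t_stat <- mean(d) / (s / sqrt(n))
  tibble::tibble(t = t_stat, df = n - 1,
                 p_value = 2 * pt(-abs(t_stat), df = n - 1),
                 mean_diff = mean(d), n = n)
}
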