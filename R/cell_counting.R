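#' Construct a counting design for epifluorescence cell counts
#'
#' Describes how microbial cells detached from one individual end up in the
#' microscope fields that are actually counted: the individual is shaken in
#' `detachment_volume_ml` of solution, `stained_volume_ml` of it is
#' DAPI-stained and filtered onto a membrane of `effective_filter_area_mm2`,
#' and `n_fields` camera fields of `field_area_mm2` each are photographed
#' and counted. The filter and field areas depend on the filtration holder
#' and the camera/objective combination; the defaults describe a 25-mm
#' membrane holder with a 400x field and are calibration inputs, not
#' measurements.
#'
#' @param detachment_volume_ml volume the individual is shaken in (default
#'   5 mL).
#' @param stained_volume_ml stained and filtered volume (default 1 mL; must
#'   not exceed the detachment volume).
#' @param effective_filter_area_mm2 area of the filter actually carrying
#'   cells (default 244 mm2).
#' @param field_area_mm2 area of one photographed field (default 0.1 mm2;
#'   must not exceed the filter area).
#' @param n_fields number of fields counted per sample (default 3).
#' @return a list of class `counting_design`.
#' @export
counting_design <- function(detachment_volume_ml = 5, stained_volume_ml = 1,
                            effective_filter_area_mm2 = 244,
                            field_area_mm2 = 0.1, n_fields = 3) {
  .assert_scalar(detachment_volume_ml, "detachment_volume_ml", lower = 0,
                 strict_lower = TRUE)
  .assert_scalar(stained_volume_ml, "stained_volume_ml", lower = 0,
                 strict_lower = TRUE)
  .assert_scalar(effective_filter_area_mm2, "effective_filter_area_mm2",
                 lower = 0, strict_lower = TRUE)
  .assert_scalar(field_area_mm2, "field_area_mm2", lower = 0,
                 strict_lower = TRUE)
  .assert_scalar(n_fields, "n_fields", lower = 1, integer = TRUE)
  if (stained_volume_ml > detachment_volume_ml) {
    stop("stained_volume_ml cannot exceed detachment_volume_ml",
         call. = FALSE)
  }
  if (field_area_mm2 > effective_filter_area_mm2) {
    stop("field_area_mm2 cannot exceed effective_filter_area_mm2",
         call. = FALSE)
  }
  structure(list(detachment_volume_ml = detachment_volume_ml,
                 stained_volume_ml = stained_volume_ml,
                 effective_filter_area_mm2 = effective_filter_area_mm2,
                 field_area_mm2 = field_area_mm2,
                 n_fields = n_fields),
            class = "counting_design")
}

#' Count fluorescent cells in a micrograph
#'
#' Automated spot counting for well-separated DAPI-stained cells: the image
#' is globally thresholded with Otsu's method, the binary mask is labelled
#' into connected components, and components of at least `min_spot_px`
#' pixels are counted as cells. A uniform image has no meaningful threshold
#' and returns 0 with a warning. Touching cells are not deblended.
#'
#' @param image a `cell_count_image` (see [simulate_dapi_image()],
#'   [read_cell_image()]) or a plain numeric matrix of intensities.
#' @param min_spot_px minimum component area in pixels (default 4);
#'   suppresses single-pixel noise.
#' @return integer cell count.
#' @export
count_cells_in_image <- function(image, min_spot_px = 4) {
  px <- if (inherits(image, "cell_count_image")) image$pixels else image
  if (!is.matrix(px) || !is.numeric(px)) {
    stop("image must be a cell_count_image or numeric matrix", call. = FALSE)
  }
  if (any(px < 0)) stop("negative intensities", call. = FALSE)
  .assert_scalar(min_spot_px, "min_spot_px", lower = 1, integer = TRUE)
  rng <- range(px)
  if (diff(rng) == 0) {
    warning("uniform image: threshold undefined, returning 0 cells")
    return(0L)
  }
  norm <- (px - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  mask <- EBImage::Image(norm > thr)
  lab <- EBImage::bwlabel(mask)
  areas <- tabulate(as.integer(lab))
  sum(areas >= min_spot_px)
}

#' Scale mean field counts to cells per individual
#'
#' Inverts the counting design: the mean count per field is scaled up by
#' the filter-to-field area ratio (cells on the whole filter) and by the
#' detachment-to-stained volume ratio (cells in the whole detachment
#' solution, i.e. on the whole individual).
#'
#' @param field_counts integer cell counts of the photographed fields.
#' @param design a [counting_design()].
#' @return estimated number of cells on the individual (real).
#' @export
#' @examples
#' cells_per_individual(c(95, 100, 105), counting_design())
cells_per_individual <- function(field_counts, design = counting_design()) {
  if (!inherits(design, "counting_design")) {
    stop("design must be a counting_design()", call. = FALSE)
  }
  if (length(field_counts) < 1L || any(field_counts < 0)) {
    stop("field_counts must be at least one non-negative count",
         call. = FALSE)
  }
  mean(field_counts) *
    (design$effective_filter_area_mm2 / design$field_area_mm2) *
    (design$detachment_volume_ml / design$stained_volume_ml)
}

#' Linear regression of microbial load on insect body weight
#'
#' Larger insects expose more surface and carry more microbial cells; this
#' fits the relationship as ordinary least squares of load (cells) on
#' fresh body weight (mg) on the raw scale, with a t-based 95% confidence
#' interval for the slope. Set `log_log = TRUE` to fit
#' `log10(load) ~ log10(weight)` instead (both variables must then be
#' positive).
#'
#' @param weights_mg insect fresh weights in mg (positive; at least 3
#'   points, not all equal).
#' @param loads_cells per-individual cell loads (same length).
#' @param log_log fit on the log10-log10 scale instead of the raw scale.
#' @return an object of class `weight_load_fit`: list with `intercept`,
#'   `slope`, `r_squared`, `ci95` (slope confidence bounds), `n`,
#'   `log_log`, and the underlying `lm` fit.
#' @export
fit_weight_model <- function(weights_mg, loads_cells, log_log = FALSE) {
  if (length(weights_mg) != length(loads_cells)) {
    stop("weights and loads must have the same length", call. = FALSE)
  }
  if (length(weights_mg) < 3L) stop("need at least 3 points", call. = FALSE)
  if (any(weights_mg <= 0)) stop("weights must be positive", call. = FALSE)
  if (stats::sd(weights_mg) == 0) {
    stop("all weights equal: slope not identifiable", call. = FALSE)
  }
  df <- if (log_log) {
    if (any(loads_cells <= 0)) {
      stop("log-log fit requires positive loads", call. = FALSE)
    }
    data.frame(w = log10(weights_mg), l = log10(loads_cells))
  } else {
    data.frame(w = weights_mg, l = loads_cells)
  }
  fit <- stats::lm(l ~ w, data = df)
  ci <- stats::confint(fit, "w", level = 0.95)
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 r_squared = summary(fit)$r.squared,
                 ci95 = c(lower = ci[1], upper = ci[2]),
                 n = length(weights_mg), log_log = log_log, fit = fit),
            class = "weight_load_fit")
}

#' @export
print.weight_load_fit <- function(x, ...) {
  cat(sprintf(
    "Load-weight regression (%s scale, n = %d)\n  load = %.4g %+.4g x weight,  r^2 = %.3f\n  slope 95%% CI: [%.4g, %.4g]\n",
    if (x$log_log) "log10-log10" else "raw", x$n, x$intercept, x$slope,
    x$r_squared, x$ci95[["lower"]], x$ci95[["upper"]]))
  invisible(x)
}

#' Write or read a cell-count image as 16-bit grayscale TIFF
#'
#' Intensities are clamped to \[0, 1\] on write. Ground-truth planted
#' centers, if any, are not stored in the file.
#'
#' @param image a `cell_count_image` or numeric matrix with values in
#'   \[0, 1\].
#' @param path file path (`.tif`/`.tiff`).
#' @return `path` invisibly (write); a `cell_count_image` (read).
#' @export
write_cell_image <- function(image, path) {
  px <- if (inherits(image, "cell_count_image")) image$pixels else image
  px <- pmin(pmax(px, 0), 1)
  tiff::writeTIFF(px, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_cell_image
#' @param pixel_size_um physical pixel size to attach on read (default
#'   0.25 um, a 400x magnification).
#' @export
read_cell_image <- function(path, pixel_size_um = 0.25) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  structure(list(pixels = px, pixel_size_um = pixel_size_um,
                 planted_centers = NULL),
            class = "cell_count_image")
}
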