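# Radiochromic-film dose QA: net optical density to dose via a calibration
# curve, and lateral homogeneity scoring over a region of interest.

#' Film calibration curve
#'
#' A set of (net optical density, dose) nodes, strictly increasing in both
#' coordinates, as measured for the film batch and beam quality in use.
#'
#' @param net_od Net optical densities of the calibration films.
#' @param dose Corresponding doses in Gy.
#' @return Object of class `"calibration_curve"`.
#' @export
calibration_curve <- function(net_od, dose) {
  stopifnot(length(net_od) == length(dose), length(net_od) >= 2L,
            is.finite(net_od), is.finite(dose))
  if (any(diff(net_od) <= 0) || any(diff(dose) <= 0))
    stop("calibration curve must be strictly increasing in both coordinates",
         call. = FALSE)
  structure(list(net_od = as.numeric(net_od), dose = as.numeric(dose)),
            class = "calibration_curve")
}

#' Read a calibration curve from a two-column CSV
#'
#' @param path CSV with columns `net_od` and `dose` (header required).
#' @return A [calibration_curve()] object.
#' @export
read_calibration_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("net_od", "dose") %in% names(d)))
  calibration_curve(d$net_od, d$dose)
}

#' Convert net optical density to dose
#'
#' Monotone interpolation through the calibration nodes: piecewise linear by
#' default, or a monotone Hyman-filtered cubic spline. Calibration nodes map
#' exactly to their doses. Optical densities outside the calibrated range are
#' clamped to the first/last node with a warning.
#'
#' @param net_od Numeric matrix (or vector) of net optical densities.
#' @param curve A [calibration_curve()] object.
#' @param method `"linear"` or `"spline"`.
#' @return Dose raster (same shape as `net_od`), in Gy.
#' @examples
#' cc <- calibration_curve(c(0, 1), c(0, 10))
#' od_to_dose(0.5, cc)  # 5 Gy
#' @export
od_to_dose <- function(net_od, curve, method = c("linear", "spline")) {
  method <- match.arg(method)
  stopifnot(inherits(curve, "calibration_curve"))
  rng <- range(curve$net_od)
  out_of_range <- sum(net_od < rng[1] | net_od > rng[2], na.rm = TRUE)
  if (out_of_range > 0)
    warning(out_of_range, " OD value(s) outside the calibrated range [",
            format(rng[1]), ", ", format(rng[2]), "]: clamped")
  x <- pmin(pmax(net_od, rng[1]), rng[2])
  dose <- if (method == "linear") {
    stats::approx(curve$net_od, curve$dose, xout = as.vector(x),
                  rule = 2)$y
  } else {
    f <- stats::splinefun(curve$net_od, curve$dose, method = "hyman")
    f(as.vector(x))
  }
  if (is.matrix(net_od)) dose <- matrix(dose, nrow(net_od), ncol(net_od))
  dose
}

#' Lateral dose homogeneity over a region of interest
#'
#' The homogeneity index is the percentile-clipped min/max dose ratio within
#' the ROI: `H = 100 x D_low / D_high`, with `D_low`/`D_high` the
#' `clip_percentiles` doses (default the 2nd and 98th percentile, robust
#' against scanner dust and film edge artifacts). A perfectly flat field
#' scores 100; the acceptance threshold used for slice irradiation plates is
#' 95.
#'
#' @param dose Dose raster (Gy).
#' @param roi Logical mask of the region of interest; `NULL` uses the whole
#'   raster. Must be non-empty.
#' @param clip_percentiles Lower and upper clip percentiles (0-100).
#' @return Object of class `"dose_homogeneity"`: list with `homogeneity`
#'   (percent), `d_low`, `d_high`, `d_min`, `d_max`, `d_mean` (Gy, within
#'   the ROI after clipping) and `n_pixels`.
#' @examples
#' homogeneity(matrix(10, 32, 32))$homogeneity  # 100
#' @export
homogeneity <- function(dose, roi = NULL, clip_percentiles = c(2, 98)) {
  assert_raster(dose)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(dose), ncol(dose))
  assert_same_shape(dose, roi)
  stopifnot(length(clip_percentiles) == 2L,
            clip_percentiles[1] < clip_percentiles[2],
            clip_percentiles[1] >= 0, clip_percentiles[2] <= 100)
  v <- dose[roi]
  if (length(v) == 0L) stop("empty ROI", call. = FALSE)
  q <- stats::quantile(v, clip_percentiles / 100, names = FALSE)
  if (q[2] <= 0)
    stop("upper-percentile dose is not positive: homogeneity undefined",
         call. = FALSE)
  inside <- v[v >= q[1] & v <= q[2]]
  structure(list(homogeneity = 100 * q[1] / q[2],
                 d_low = q[1], d_high = q[2],
                 d_min = min(inside), d_max = max(inside),
                 d_mean = mean(inside), n_pixels = length(v)),
            class = "dose_homogeneity")
}

#' @export
print.dose_homogeneity <- function(x, ...) {
  cat(sprintf("Dose homogeneity: %.1f%% (D_low %.3f Gy / D_high %.3f Gy, %d px)\n",
              x$homogeneity, x$d_low, x$d_high, x$n_pixels))
  invisible(x)
}
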