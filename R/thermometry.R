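#' Photoacoustic intensity increment
#'
#' `alpha = (p0(T) - p0(T0)) / p0(T0)`: the relative amplitude increase of
#' the photoacoustic signal against its reference at the start temperature.
#' With a linear Grueneisen model and fixed fluence this is proportional to
#' the temperature increment.
#'
#' @param p0_T amplitudes at the current temperature (vector over AOPs).
#' @param p0_T0 reference amplitudes at `T0`; must exceed `noise_floor`.
#' @param noise_floor amplitudes at or below this are unreliable; the
#'   corresponding entries are returned as `NA` with a warning (the points
#'   should be dropped from the observable set).
#' @return Vector of dimensionless increments, `NA` where the reference was
#'   at or below the floor.
#' @export
alpha_increment <- function(p0_T, p0_T0, noise_floor = 0) {
  if (length(p0_T0) == 1) p0_T0 <- rep(p0_T0, length(p0_T))
  stopifnot(length(p0_T) == length(p0_T0))
  bad <- p0_T0 <= noise_floor
  if (any(bad))
    warning(sum(bad), " point(s) have reference amplitude at/below the noise floor; excluded")
  out <- (p0_T - p0_T0) / p0_T0
  out[bad] <- NA_real_
  out
}

#' Thermometry calibration model
#'
#' Stores the composite observation gain `slope_coeff = B / (A + B*T0)`
#' (1/K): the slope of `alpha` against temperature increment. Only this
#' composite enters the pipeline; A and B separately matter only to forward
#' simulation.
#'
#' @param slope_coeff observation gain (1/K), > 0.
#' @param T0 reference temperature (deg C).
#' @param fit_r correlation coefficient of the calibration fit (when fitted).
#' @param source `"fit"` or `"configured"`.
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(slope_coeff, T0, fit_r = NA_real_,
                              source = c("configured", "fit")) {
  source <- match.arg(source)
  stopifnot(slope_coeff > 0)
  if (source == "fit" && is.na(fit_r))
    stop("fit_r must be reported for a fitted calibration")
  structure(list(slope_coeff = slope_coeff, T0 = T0, fit_r = fit_r,
                 source = source),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model: gain %.4g 1/K at T0 = %.1f C (%s%s)>\n",
              x$slope_coeff, x$T0, x$source,
              if (is.na(x$fit_r)) "" else sprintf(", r = %.4f", x$fit_r)))
  invisible(x)
}

#' Composite gain implied by a Grueneisen model
#'
#' @param gm a [grueneisen_model()].
#' @param T0 reference temperature (deg C).
#' @return `B / (A + B*T0)` (1/K).
#' @export
calibrate_gain <- function(gm, T0) gm$B / (gm$A + gm$B * T0)

#' Temperature increments from photoacoustic increments
#'
#' `deltaT = alpha / slope_coeff` (the inverse observation gain), valid in
#' the linear (biologically viable) temperature range; a warning is issued
#' when the implied temperature leaves 30-45 deg C.
#'
#' @param alpha_vec increments from [alpha_increment()].
#' @param cal a [calibration_model()].
#' @return Temperature increments relative to `cal$T0` (K).
#' @export
delta_T <- function(alpha_vec, cal) {
  dT <- alpha_vec / cal$slope_coeff
  rng <- range(cal$T0 + dT, na.rm = TRUE)
  if (rng[1] < 30 || rng[2] > 45)
    warning("implied temperature outside the 30-45 C linearity range")
  dT
}

#' Water-bath calibration of the observation gain
#'
#' Fits `alpha` against `T - T0` by least squares over a stepped bath sweep
#' (the reference amplitudes are those measured at the temperature nearest
#' `T0`). The slope is the composite gain `B/(A + B*T0)`.
#'
#' @param temps bath temperatures (deg C), >= 3 distinct values.
#' @param pa_amplitudes matrix (length(temps) x n_points) or vector of mean
#'   PA amplitudes per bath step; must be positive.
#' @param T0 reference temperature (deg C); typically the final bath step.
#' @return A [calibration_model()] with `source = "fit"` and `fit_r`.
#' @export
calibrate <- function(temps, pa_amplitudes, T0) {
  amps <- if (is.matrix(pa_amplitudes)) pa_amplitudes
          else matrix(pa_amplitudes, ncol = 1)
  if (length(unique(temps)) < 3)
    stop("calibration needs at least 3 distinct temperatures")
  stopifnot(length(temps) == nrow(amps), all(amps > 0))
  iref <- which.min(abs(temps - T0))
  a <- sweep(amps, 2, amps[iref, ], "/") - 1
  x <- rep(temps - temps[iref], ncol(a))
  y <- as.vector(a)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0)
    stop("degenerate calibration design: non-positive or undefined slope")
  calibration_model(slope, T0 = temps[iref], fit_r = stats::cor(x, y),
                    source = "fit")
}

#' Select observable points from a reconstructed pressure field
#'
#' TOPs (theoretically observable points) are the voxels whose initial
#' pressure reaches `threshold_frac` of the field maximum — the points with
#' a significant photoacoustic effect, which under matching illumination are
#' exactly the significant heat-source points. AOPs (actually observable
#' points) restrict the TOPs to the aperture's view: in 2-D imaging mode the
#' voxels within half a slab width of the imaging plane.
#'
#' @param p0_field a `pressure_field` on the full grid (3-D `p0`).
#' @param threshold_frac fraction of the maximum (default 0.05, the same 5%
#'   threshold used to delimit the beam spot).
#' @param roips linear indices of the region of interest (default: all grid
#'   voxels).
#' @param plane_y imaging-plane y index (1-based) or `NULL` for full view
#'   (all TOPs observable).
#' @param slab_halfwidth half slab thickness in voxels around `plane_y`.
#' @return A [point_sets()] object.
#' @export
select_tops <- function(p0_field, threshold_frac = 0.05, roips = NULL,
                        plane_y = NULL, slab_halfwidth = 1L) {
  stopifnot(length(dim(p0_field$p0)) == 3)
  dims <- dim(p0_field$p0)
  if (is.null(roips)) roips <- seq_len(prod(dims))
  thr <- threshold_frac * max(p0_field$p0)
  sel <- which(p0_field$p0 >= thr & p0_field$p0 > 0)
  tops <- intersect(roips, sel)
  if (length(tops) == 0)
    stop(sprintf("empty TOP selection: max p0 = %.3g, threshold = %.3g",
                 max(p0_field$p0), thr))
  if (is.null(plane_y)) {
    aops <- tops
  } else {
    yidx <- arrayInd(tops, dims)[, 2]
    aops <- tops[abs(yidx - plane_y) <= slab_halfwidth]
    if (length(aops) == 0)
      stop("no TOPs within the imaging aperture's view")
  }
  point_sets(sort(roips), sort(tops), sort(aops), dims)
}

#' Observation matrix
#'
#' Assembles the sparse observation matrix
#' `H = [gain * I(MxM) | 0(Mx(N-M)) | 0(MxW)]`
#' (columns ordered as the stacked state `[deltaT at ROIPs; S at TOPs]`):
#' row `m` reads the temperature increment at the m'th AOP with the
#' calibrated gain, so `H x` is in alpha units; the heat-source block is
#' never read (the source cannot be observed directly).
#'
#' @param points a [point_sets()].
#' @param cal a [calibration_model()].
#' @return An object of class `observation_matrix` with sparse `H` and
#'   counts `M`, `N`, `W`.
#' @export
build_H <- function(points, cal) {
  N <- points$N; W <- points$W; M <- points$M
  roi_pos <- integer(max(points$roips))
  roi_pos[points$roips] <- seq_len(N)
  cols <- roi_pos[points$aops]
  if (any(cols == 0)) stop("AOPs are not consistent with the ROI ordering")
  H <- Matrix::sparseMatrix(i = seq_len(M), j = cols,
                            x = rep(cal$slope_coeff, M),
                            dims = c(M, N + W))
  structure(list(H = H, M = M, N = N, W = W, gain = cal$slope_coeff,
                 points = points),
            class = "observation_matrix")
}

#' @export
print.observation_matrix <- function(x, ...) {
  cat(sprintf("<observation_matrix: %d x %d (M=%d, N=%d, W=%d), gain %.4g>\n",
              x$M, x$N + x$W, x$M, x$N, x$W, x$gain))
  invisible(x)
}
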