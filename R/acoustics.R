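#' Temperature-dependent Grueneisen model
#'
#' The thermoelastic efficiency `Gamma(T) = A + B*T` (T in deg C), assumed
#' spatially uniform within a tissue type. `Gamma` must stay positive over
#' the operating range 30-45 deg C.
#'
#' @param A dimensionless intercept.
#' @param B slope (1/K).
#' @return An object of class `grueneisen_model`.
#' @export
grueneisen_model <- function(A, B) {
  if (min(A + B * c(30, 45)) <= 0)
    stop("Gamma = A + B*T must be positive over 30-45 deg C")
  structure(list(A = A, B = B), class = "grueneisen_model")
}

#' Grueneisen model of a tissue-property set
#'
#' @param props a [tissue_properties()] object.
#' @return A [grueneisen_model()] using the stored `grueneisen_A`/`_B`.
#' @export
grueneisen_of <- function(props) {
  grueneisen_model(props$grueneisen_A, props$grueneisen_B)
}

#' Initial photoacoustic pressure
#'
#' `p0(r) = Gamma(T(r)) * Phi(r) * mu_a(r)` in relative units. Accepts either
#' a fluence field (multiplied by `mu_a` internally) or a precomputed heat
#' source `S = mu_a * Phi`.
#'
#' @param field a `fluence_field` or `heat_source_field`.
#' @param grid the matching `voxel_grid`.
#' @param T_field absolute temperature (deg C): a scalar or grid-shaped array.
#' @param gm a [grueneisen_model()].
#' @return An object of class `pressure_field` with array `p0`.
#' @export
initial_pressure <- function(field, grid, T_field, gm) {
  S <- if (inherits(field, "heat_source_field")) field$S
       else grid_property(grid, "mu_a") * field$phi
  gam <- gm$A + gm$B * T_field
  if (any(gam <= 0)) stop("Gamma non-positive at some temperature")
  structure(list(p0 = gam * S, dims = grid$dims, dl = grid$dl),
            class = "pressure_field")
}

#' @export
print.pressure_field <- function(x, ...) {
  cat(sprintf("<pressure_field %s, max %.4g (relative)>\n",
              paste(dim(x$p0), collapse = " x "), max(x$p0)))
  invisible(x)
}

#' Linear transducer array geometry
#'
#' A 1-D array of point-like elements along x, placed a standoff above the
#' tissue surface (negative z) in the imaging plane `y = y_plane`.
#'
#' @param n_elements element count (default 128).
#' @param pitch element spacing (m).
#' @param center_frequency center frequency (Hz, default 5.5 MHz).
#' @param sampling_rate RF sampling rate (Hz); must exceed twice the upper
#'   band edge.
#' @param bandwidth fractional bandwidth for optional band-limiting.
#' @param x_center lateral center of the aperture (m).
#' @param y_plane imaging-plane coordinate (m).
#' @param standoff distance above the tissue surface (m).
#' @return An object of class `transducer_array` with `positions`
#'   (`n_elements` x 3 matrix, m).
#' @export
transducer_array <- function(n_elements = 128, pitch = 0.3e-3,
                             center_frequency = 5.5e6, sampling_rate = 40e6,
                             bandwidth = 0.6, x_center = 0, y_plane = 0,
                             standoff = 5e-3) {
  upper_edge <- center_frequency * (1 + bandwidth / 2)
  if (sampling_rate <= 2 * upper_edge)
    stop("sampling_rate must exceed twice the upper band edge")
  xs <- (seq_len(n_elements) - (n_elements + 1) / 2) * pitch + x_center
  positions <- cbind(x = xs, y = rep(y_plane, n_elements),
                     z = rep(-standoff, n_elements))
  normals <- cbind(rep(0, n_elements), rep(0, n_elements), rep(1, n_elements))
  structure(list(n_elements = n_elements, pitch = pitch,
                 center_frequency = center_frequency,
                 sampling_rate = sampling_rate, bandwidth = bandwidth,
                 positions = positions, normals = normals, planar = TRUE),
            class = "transducer_array")
}

#' Full-view ring aperture
#'
#' A synthetic circular aperture of point detectors surrounding the imaging
#' plane — the full-view reference geometry against which the limited-view
#' linear array is compared. Elements lie on a circle of radius `radius`
#' around `center` in the plane `y = y_plane`, aimed at the center.
#'
#' @param radius ring radius (m); must enclose the object.
#' @param center `(x, z)` coordinates of the ring center (m).
#' @param n_elements element count.
#' @param pitch nominal element size used for solid-angle weighting (m).
#' @inheritParams transducer_array
#' @return A `transducer_array` (non-planar).
#' @export
ring_array <- function(radius, center = c(0, 6e-3), n_elements = 256,
                       pitch = 0.3e-3, center_frequency = 5.5e6,
                       sampling_rate = 40e6, bandwidth = 0.6, y_plane = 0) {
  th <- (seq_len(n_elements) - 1) / n_elements * 2 * pi
  positions <- cbind(center[1] + radius * cos(th), rep(y_plane, n_elements),
                     center[2] + radius * sin(th))
  normals <- cbind(-cos(th), rep(0, n_elements), -sin(th))
  structure(list(n_elements = n_elements, pitch = pitch,
                 center_frequency = center_frequency,
                 sampling_rate = sampling_rate, bandwidth = bandwidth,
                 positions = positions, normals = normals, planar = FALSE),
            class = "transducer_array")
}

#' Full-view spherical aperture
#'
#' Point detectors on a sphere enclosing the object (Fibonacci lattice),
#' aimed at the center — the closed measurement surface for which universal
#' back-projection is an exact inversion. Used as the noise-free round-trip
#' reference.
#'
#' @param radius sphere radius (m); must enclose the object.
#' @param center `(x, y, z)` sphere center (m).
#' @param n_elements element count.
#' @inheritParams transducer_array
#' @return A `transducer_array` (non-planar).
#' @export
sphere_array <- function(radius, center = c(0, 0, 6e-3), n_elements = 1024,
                         pitch = 0.3e-3, center_frequency = 5.5e6,
                         sampling_rate = 40e6, bandwidth = 0.6) {
  i <- seq_len(n_elements) - 0.5
  phi_g <- pi * (3 - sqrt(5)) * i          # golden-angle longitude
  cos_t <- 1 - 2 * i / n_elements
  sin_t <- sqrt(pmax(0, 1 - cos_t^2))
  dirs <- cbind(sin_t * cos(phi_g), sin_t * sin(phi_g), cos_t)
  positions <- sweep(radius * dirs, 2, center, "+")
  structure(list(n_elements = n_elements, pitch = pitch,
                 center_frequency = center_frequency,
                 sampling_rate = sampling_rate, bandwidth = bandwidth,
                 positions = positions, normals = -dirs, planar = FALSE),
            class = "transducer_array")
}

#' @export
print.transducer_array <- function(x, ...) {
  cat(sprintf("<transducer_array: %d elements, pitch %.3g mm, fc %.3g MHz, fs %.3g MHz>\n",
              x$n_elements, x$pitch * 1e3, x$center_frequency / 1e6,
              x$sampling_rate / 1e6))
  invisible(x)
}

#' Channel-noise specification
#'
#' @param channel_snr_db additive white Gaussian noise level per channel,
#'   as signal RMS / noise RMS in dB (`Inf` = none).
#' @param pulse_jitter_frac fractional standard deviation of per-frame pulse
#'   energy (multiplies the whole frame).
#' @param seed RNG seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(channel_snr_db = Inf, pulse_jitter_frac = 0, seed = 1L) {
  stopifnot(pulse_jitter_frac >= 0)
  structure(list(channel_snr_db = channel_snr_db,
                 pulse_jitter_frac = pulse_jitter_frac,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Photoacoustic forward projection
#'
#' Analytic delay-and-sum solution of the photoacoustic wave equation for
#' point-like detectors in a homogeneous medium: every source voxel is
#' treated as a uniform sphere of equal volume, whose exact emitted field is
#' the bipolar N-wave `p(t) = p0 (r - vs t)/(2 r)` supported on
#' `|r - vs t| <= a`; element traces are superpositions of these ramps, so
#' they carry the time-derivative character and `1/r` far-field decay of the
#' photoacoustic Green's function without numerical differentiation.
#' Optional band-limiting around the center frequency and seeded channel
#' noise / pulse-energy jitter.
#'
#' @param p0 a `pressure_field` on the full grid.
#' @param array a [transducer_array()]; the grid must lie in front of the
#'   array plane (all voxel z above element z).
#' @param vs speed of sound (m/s), single value.
#' @param noise a [noise_spec()] or `NULL`.
#' @param bandlimit apply a Gaussian band-pass around `center_frequency`.
#' @param grid_origin_xy lateral placement: coordinates of the grid's
#'   (x=0, y=0) corner in array coordinates. Default centers the grid under
#'   the aperture.
#' @param impulse_sigma Gaussian temporal impulse response of the detection
#'   chain, in samples (0 disables).
#' @return An object of class `rf_data`: `samples` (n_samples x n_elements),
#'   `dt_sample`, `t0 = 0`.
#' @export
forward_project <- function(p0, array, vs, noise = NULL, bandlimit = FALSE,
                            grid_origin_xy = NULL, impulse_sigma = 2) {
  dims <- p0$dims; dl <- p0$dl
  if (is.null(grid_origin_xy))
    grid_origin_xy <- c(-dims[1] * dl / 2, -dims[2] * dl / 2)
  if (isTRUE(array$planar) && min(array$positions[, 3]) >= 0)
    stop("grid extends behind the array plane")
  nz_idx <- which(p0$p0 != 0)
  if (length(nz_idx) == 0) {
    nt <- 16L
    return(structure(list(samples = matrix(0, nt, array$n_elements),
                          dt_sample = 1 / array$sampling_rate, t0 = 0),
                     class = "rf_data"))
  }
  ijk <- arrayInd(nz_idx, dims)
  vx <- (ijk[, 1] - 0.5) * dl + grid_origin_xy[1]
  vy <- (ijk[, 2] - 0.5) * dl + grid_origin_xy[2]
  vz <- (ijk[, 3] - 0.5) * dl

  dt <- 1 / array$sampling_rate
  # generous time base: all element-voxel delays plus margin
  corner_x <- grid_origin_xy[1] + c(0, dims[1] * dl)
  corner_y <- grid_origin_xy[2] + c(0, dims[2] * dl)
  corner_z <- c(0, dims[3] * dl)
  rmax <- 0
  for (ex in range(array$positions[, 1]))
    for (ey in range(array$positions[, 2]))
      for (ez in range(array$positions[, 3]))
        rmax <- max(rmax, sqrt(max((corner_x - ex)^2) + max((corner_y - ey)^2) +
                               max((corner_z - ez)^2)))
  nt <- as.integer(ceiling(rmax / vs / dt)) + 8L
  a_eff <- dl * (3 / (4 * pi))^(1 / 3)  # equal-volume sphere radius
  samples <- pa_forward_cpp(vx, vy, vz, p0$p0[nz_idx], array$positions,
                            vs, dt, nt, a_eff)
  if (impulse_sigma > 0) {
    # finite temporal impulse response of the detection chain (samples);
    # also rounds the ramp corners so the back-projection derivative is
    # well resolved
    kw <- ceiling(4 * impulse_sigma)
    kern <- stats::dnorm(seq(-kw, kw), 0, impulse_sigma)
    kern <- kern / sum(kern)
    samples <- apply(samples, 2, function(s) {
      out <- stats::filter(s, kern, sides = 2)
      out[is.na(out)] <- 0
      as.numeric(out)
    })
  }

  if (bandlimit) samples <- bandpass_gaussian(samples, dt, array)
  if (!is.null(noise)) {
    samples <- withr::with_seed(noise$seed, {
      s <- samples
      if (noise$pulse_jitter_frac > 0)
        s <- s * (1 + noise$pulse_jitter_frac * stats::rnorm(1))
      if (is.finite(noise$channel_snr_db)) {
        sig_rms <- sqrt(mean(s^2))
        s + stats::rnorm(length(s),
                         sd = sig_rms / 10^(noise$channel_snr_db / 20))
      } else s
    })
  }
  structure(list(samples = samples, dt_sample = dt, t0 = 0),
            class = "rf_data")
}

#' @export
print.rf_data <- function(x, ...) {
  cat(sprintf("<rf_data: %d samples x %d elements, fs %.3g MHz>\n",
              nrow(x$samples), ncol(x$samples), 1e-6 / x$dt_sample))
  invisible(x)
}

# Gaussian band-pass around the array center frequency (zero-phase, FFT).
bandpass_gaussian <- function(samples, dt, array) {
  nt <- nrow(samples)
  f <- (seq_len(nt) - 1) / (nt * dt)
  f <- pmin(f, 1 / dt - f)
  fc <- array$center_frequency
  sigma <- array$bandwidth * fc / 2.355
  H <- exp(-(f - fc)^2 / (2 * sigma^2))
  Re(stats::mvfft(stats::mvfft(samples) * H, inverse = TRUE)) / nt
}

#' Deconvolution of detected RF traces
#'
#' Approximates the ideal pressure traces from band-limited detected signals.
#' `"identity"` (default) passes traces through unchanged; `"equalize"`
#' divides the trace spectra by the array's Gaussian band-pass response with
#' Wiener regularization, flattening the in-band spectrum. The exact filters
#' a given detection chain applies are system-specific, so this stays
#' minimal. Equalization is not idempotent; applying it twice over-whitens
#' and a warning is issued if the input is already marked equalized.
#'
#' @param rf an `rf_data`.
#' @param array the [transducer_array()].
#' @param mode `"identity"` or `"equalize"`.
#' @param reg Wiener regularization (fraction of peak response).
#' @return An `rf_data` with processed samples.
#' @export
estimate_deconvolution <- function(rf, array, mode = c("identity", "equalize"),
                                   reg = 0.05) {
  mode <- match.arg(mode)
  if (mode == "identity") return(rf)
  if (isTRUE(attr(rf, "equalized")))
    warning("traces already equalized; repeating is not idempotent")
  nt <- nrow(rf$samples)
  f <- (seq_len(nt) - 1) / (nt * rf$dt_sample)
  f <- pmin(f, 1 / rf$dt_sample - f)
  fc <- array$center_frequency
  sigma <- array$bandwidth * fc / 2.355
  H <- exp(-(f - fc)^2 / (2 * sigma^2))
  W <- H / (H^2 + reg^2)
  out <- rf
  out$samples <- Re(stats::mvfft(stats::mvfft(rf$samples) * W,
                                 inverse = TRUE)) / nt
  attr(out, "equalized") <- TRUE
  out
}

#' Universal back-projection reconstruction
#'
#' Reconstructs the initial pressure from RF channel data by back-projecting
#' the filtered term `b(d, t) = p'(d, t) - t dp'(d, t)/dt` evaluated at the
#' voxel-element time of flight `t = |r - d|/vs`, weighted by the solid angle
#' each (point-like) element subtends as seen from the voxel and normalized
#' by the total subtended angle per voxel.
#'
#' @param rf an `rf_data`.
#' @param array the [transducer_array()] that recorded it.
#' @param vs speed of sound (m/s).
#' @param grid the `voxel_grid` defining the reconstruction voxels.
#' @param plane_y optional y index (1-based): reconstruct only the imaging
#'   plane slice, returning a 2-D (x, z) field. `NULL` reconstructs the full
#'   grid.
#' @param grid_origin_xy as in [forward_project()]; must match the forward
#'   model.
#' @return A `pressure_field` whose `p0` is a 2-D matrix (plane mode) or 3-D
#'   array, with attribute `plane_y`.
#' @export
ubp_reconstruct <- function(rf, array, vs, grid, plane_y = NULL,
                            grid_origin_xy = NULL) {
  dims <- grid$dims; dl <- grid$dl
  if (is.null(grid_origin_xy))
    grid_origin_xy <- c(-dims[1] * dl / 2, -dims[2] * dl / 2)
  nt <- nrow(rf$samples)
  tvec <- rf$t0 + (seq_len(nt) - 1) * rf$dt_sample
  dpdt <- apply(rf$samples, 2, function(s)
    c(0, diff(s, lag = 2) / (2 * rf$dt_sample), 0))
  b <- rf$samples - tvec * dpdt

  ys <- if (is.null(plane_y)) seq_len(dims[2]) else plane_y
  xs <- (seq_len(dims[1]) - 0.5) * dl + grid_origin_xy[1]
  zs <- (seq_len(dims[3]) - 0.5) * dl
  out <- array(0, dim = c(dims[1], length(ys), dims[3]))
  elem_area <- array$pitch^2
  t_max <- tvec[nt]
  dropped <- FALSE

  xz_x <- matrix(xs, dims[1], dims[3])
  xz_z <- matrix(zs, dims[1], dims[3], byrow = TRUE)
  for (yi in seq_along(ys)) {
    yc <- (ys[yi] - 0.5) * dl + grid_origin_xy[2]
    num <- matrix(0, dims[1], dims[3])
    den <- matrix(0, dims[1], dims[3])
    for (e in seq_len(array$n_elements)) {
      pe <- array$positions[e, ]
      r <- sqrt((xz_x - pe[1])^2 + (yc - pe[2])^2 + (xz_z - pe[3])^2)
      tt <- r / vs
      ok <- tt <= t_max
      if (!all(ok)) dropped <- TRUE
      # linear interpolation of b at the time of flight
      fi <- (tt - rf$t0) / rf$dt_sample + 1
      i0 <- pmax(1L, pmin(nt - 1L, as.integer(floor(fi))))
      frac <- pmin(1, pmax(0, fi - i0))
      bv <- (1 - frac) * b[i0, e] + frac * b[i0 + 1L, e]
      nv <- array$normals[e, ]
      cos_th <- abs((xz_x - pe[1]) * nv[1] + (yc - pe[2]) * nv[2] +
                    (xz_z - pe[3]) * nv[3]) / r
      dOmega <- elem_area * cos_th / r^2
      num <- num + ifelse(ok, bv * dOmega, 0)
      den <- den + ifelse(ok, dOmega, 0)
    }
    out[, yi, ] <- ifelse(den > 0, 2 * num / den, 0)
  }
  if (dropped)
    warning("some element/voxel delays exceed the RF time base; those contributions were dropped")
  p0 <- if (is.null(plane_y)) out else array(out[, 1, ], dim = dims[c(1, 3)])
  structure(list(p0 = p0, dims = dims, dl = dl, plane_y = plane_y),
            class = "pressure_field")
}
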