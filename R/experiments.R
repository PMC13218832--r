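#' Spot profile and FWHM analysis
#'
#' Thresholds a 2-D intensity image at a fraction of its maximum (rejecting
#' artifacts and low-level noise), takes the intensity-weighted centroid of
#' the supra-threshold region as the spot center, extracts horizontal and
#' vertical profiles through the center, and measures their full width at
#' half maximum by linear interpolation at the half-max crossings.
#'
#' @param image 2-D numeric matrix of intensities, not all zero.
#' @param boundary_threshold_frac spot-boundary threshold as a fraction of
#'   the maximum (default 0.05).
#' @param pixel_size physical pixel edge (m); FWHM values are returned in
#'   these units.
#' @return An object of class `profile_analysis`: `center` (fractional pixel
#'   coordinates), `fwhm_h`, `fwhm_v`, the two profiles, and the threshold.
#' @export
fit_spot <- function(image, boundary_threshold_frac = 0.05, pixel_size = 1) {
  if (all(image <= 0)) stop("all-zero image: no spot to fit")
  thr <- boundary_threshold_frac * max(image)
  mask <- image >= thr
  idx <- which(mask, arr.ind = TRUE)
  w <- image[mask]
  center <- c(sum(idx[, 1] * w), sum(idx[, 2] * w)) / sum(w)
  ci <- pmin(pmax(round(center), 1), dim(image))
  prof_h <- image[, ci[2]]
  prof_v <- image[ci[1], ]
  structure(list(center = center, center_pixel = ci,
                 fwhm_h = fwhm_interp(prof_h) * pixel_size,
                 fwhm_v = fwhm_interp(prof_v) * pixel_size,
                 profile_h = prof_h, profile_v = prof_v,
                 boundary_threshold_frac = boundary_threshold_frac,
                 pixel_size = pixel_size),
            class = "profile_analysis")
}

#' @export
print.profile_analysis <- function(x, ...) {
  cat(sprintf("<profile_analysis: center (%.2f, %.2f), FWHM h %.4g, v %.4g>\n",
              x$center[1], x$center[2], x$fwhm_h, x$fwhm_v))
  invisible(x)
}

# FWHM of a 1-D profile by linear interpolation at the half-max crossings
# on either side of the peak, in index units.
fwhm_interp <- function(p) {
  pk <- which.max(p)
  half <- p[pk] / 2
  left <- NA_real_
  for (i in seq(pk, 2)) if (p[i - 1] < half) {
    left <- (i - 1) + (half - p[i - 1]) / (p[i] - p[i - 1]); break
  }
  right <- NA_real_
  for (i in seq(pk, length(p) - 1)) if (p[i + 1] < half) {
    right <- i + (p[i] - half) / (p[i] - p[i + 1]); break
  }
  if (is.na(left) || is.na(right))
    stop("profile does not fall below half maximum on both sides")
  right - left
}

#' Decimate a voxel grid
#'
#' Coarsens a grid by an integer factor per axis (majority region label per
#' block). Used to run the fusion filter on a reduced region of interest;
#' [restrict_field()] and [interp_weights()] are the matching restriction and
#' injection maps.
#'
#' @param grid a `voxel_grid` whose dimensions are divisible by `factor`.
#' @param factor integer decimation factor (>= 1).
#' @return A `voxel_grid` with `dl * factor` voxels.
#' @export
decimate_grid <- function(grid, factor) {
  factor <- as.integer(factor)
  if (factor == 1L) return(grid)
  if (any(grid$dims %% factor != 0))
    stop("grid dimensions must be divisible by the decimation factor")
  cd <- grid$dims %/% factor
  counts <- list()
  for (lb in names(grid$props))
    counts[[lb]] <- restrict_field((grid$labels == as.integer(lb)) * 1,
                                   factor, mean)
  stacked <- simplify2array(counts)
  clabs <- array(as.integer(names(grid$props)[apply(stacked, c(1, 2, 3),
                                                    which.max)]), dim = cd)
  new_voxel_grid(cd, grid$dl * factor, clabs, grid$props)
}

#' Block-restrict a fine field to a decimated grid
#'
#' @param a numeric array on the fine grid.
#' @param factor decimation factor.
#' @param fun block aggregator (default `mean`, which conserves volumetric
#'   densities).
#' @return Array on the coarse grid.
#' @export
restrict_field <- function(a, factor, fun = mean) {
  d <- dim(a); cd <- d %/% factor
  out <- array(0, cd)
  if (identical(fun, mean)) {
    for (i in 0:(factor - 1)) for (j in 0:(factor - 1))
      for (k in 0:(factor - 1))
        out <- out + a[seq(1 + i, factor * cd[1], factor),
                       seq(1 + j, factor * cd[2], factor),
                       seq(1 + k, factor * cd[3], factor)]
    return(out / factor^3)
  }
  for (ci in seq_len(cd[1])) for (cj in seq_len(cd[2]))
    for (ck in seq_len(cd[3]))
      out[ci, cj, ck] <- fun(a[(ci - 1) * factor + 1:factor,
                               (cj - 1) * factor + 1:factor,
                               (ck - 1) * factor + 1:factor])
  out
}

#' Trilinear injection weights for a fine-grid point
#'
#' Weights over coarse-grid voxel centers that interpolate a field to the
#' physical position of a fine-grid voxel center (a virtual thermocouple
#' location).
#'
#' @param p_fine 1-based fine-grid index `(i, j, k)`.
#' @param fine_dl fine voxel edge (m).
#' @param coarse_dims,coarse_dl coarse grid geometry.
#' @return Sparse weight vector of length `prod(coarse_dims)`.
#' @export
interp_weights <- function(p_fine, fine_dl, coarse_dims, coarse_dl) {
  pos <- (p_fine - 0.5) * fine_dl
  fc <- pos / coarse_dl + 0.5
  i0 <- pmin(pmax(as.integer(floor(fc)), 1L), coarse_dims - 1L)
  fr <- pmin(pmax(fc - i0, 0), 1)
  w <- numeric(prod(coarse_dims))
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    ii <- i0 + c(a, b, cc)
    lin <- ii[1] + coarse_dims[1] * (ii[2] - 1) +
      coarse_dims[1] * coarse_dims[2] * (ii[3] - 1)
    w[lin] <- w[lin] + prod(ifelse(c(a, b, cc) == 1, fr, 1 - fr))
  }
  w
}

#' Default configuration for the depth-attenuation experiment
#'
#' Cover depths 0 and 2-8 mm in 1 mm steps under a 3 mm, 808 nm beam;
#' depth 0 is the normalization reference and the 2-8 mm range enters the
#' log-linear fit.
#'
#' @param n_photons photon packets per depth.
#' @return Nested configuration list.
#' @export
depth_attenuation_config <- function(n_photons = 1e6) {
  list(depths_mm = c(0, 2:8),
       dl_mm = 0.25,
       lateral_extent_mm = 12,
       beam = list(profile = "gaussian", diameter_mm = 3,
                   energy_j = 1e-3),
       n_photons = n_photons,
       boundary_threshold_frac = 0.05)
}

#' Depth-wise optical energy attenuation experiment
#'
#' For each cover depth, builds the absorber-plane phantom, runs seeded
#' Monte-Carlo transport, integrates the absorbed energy over the absorber
#' plane, and normalizes to the zero-depth reference. Fits log relative
#' energy against depth (2-8 mm points) and analyses the lateral deposition
#' profile at each depth (spot center and FWHM at the 5% boundary
#' threshold).
#'
#' @param config list from [depth_attenuation_config()] (possibly modified).
#' @param seed master RNG seed; per-depth runs derive distinct streams.
#' @return List: `table` (depth_mm, relative_energy, log_energy, fwhm_mm),
#'   `fit` (slope_per_mm, r_squared), `profiles` (per-depth
#'   [fit_spot()] results), `monotone` flag.
#' @export
run_depth_attenuation <- function(config = depth_attenuation_config(), seed = 1) {
  depths <- config$depths_mm * 1e-3
  dl <- config$dl_mm * 1e-3
  beam <- beam_spec(config$beam$profile, config$beam$diameter_mm * 1e-3,
                    config$beam$energy_j, mode = "pulsed")
  energies <- numeric(length(depths))
  profiles <- vector("list", length(depths))
  for (i in seq_along(depths)) {
    g <- build_absorber_plane_phantom(
      depths[i], dl = dl,
      lateral_extent = rep(config$lateral_extent_mm * 1e-3, 2))
    mc <- mc_fluence(g, beam, n_photons = config$n_photons,
                     seed = (seed * 1000 + i) %% .Machine$integer.max)
    energies[i] <- absorber_plane_energy(mc, g)
    # lateral deposition image: absorbed energy in the absorber's top layer
    z0 <- g$absorber_z0 + 1L
    img <- grid_property(g, "mu_a")[, , z0] * mc$fluence$phi[, , z0]
    profiles[[i]] <- fit_spot(img, config$boundary_threshold_frac,
                              pixel_size = dl)
  }
  i0 <- which(depths == 0)
  if (length(i0) != 1) stop("config must include depth 0 as the reference")
  rel <- energies / energies[i0]
  tab <- data.frame(depth_mm = config$depths_mm,
                    relative_energy = rel,
                    log_energy = log(rel),
                    fwhm_mm = vapply(profiles, function(p) p$fwhm_h * 1e3,
                                     numeric(1)))
  fitrows <- which(config$depths_mm > 0)
  fit <- stats::lm(log_energy ~ depth_mm, data = tab[fitrows, ])
  monotone <- !is.unsorted(rev(rel[order(config$depths_mm)]))
  if (!monotone)
    warning("relative energy is not monotone non-increasing with depth")
  list(table = tab,
       fit = list(slope_per_mm = unname(stats::coef(fit)[2]),
                  r_squared = summary(fit)$r.squared),
       profiles = profiles, monotone = monotone, config = config, seed = seed)
}

#' Default configuration for the heat-source reconstruction experiment
#'
#' @param n_photons Monte-Carlo packets for the fluence solution.
#' @param view `"limited"` (128-element linear array) or `"full"`
#'   (synthetic ring aperture).
#' @return Nested configuration list.
#' @export
heat_source_recon_config <- function(n_photons = 5e5, view = "limited") {
  list(phantom = list(tumor_diameter_mm = 5, tumor_depth_mm = 3.2,
                      dl_mm = 0.25, extent_mm = c(16, 16, 12)),
       beam = list(profile = "gaussian", diameter_mm = 3, energy_j = 1e-3),
       n_photons = n_photons,
       array = list(n_elements = 128, pitch_mm = 0.3,
                    center_frequency_hz = 5.5e6, sampling_rate_hz = 40e6,
                    standoff_mm = 1),
       view = view,
       noise = list(channel_snr_db = 40),
       region_pad_mm = 2,
       normalization = "fit",
       T0 = 36)
}

#' Heat-source reconstruction discrepancy experiment
#'
#' Digital-twin version of the preoperative heat-source estimation check:
#' the simulated heat source `S = mu_a Phi` of the sphere phantom is the
#' truth; the initial pressure at the reference temperature is forward
#' projected to the array, reconstructed by universal back-projection, and
#' the lateral intensity profiles of reconstruction and truth are compared
#' over the target region (tumor bounding box plus a margin — spatial
#' registration is identity in the twin; the arbitrary-unit reconstruction
#' amplitude is registered to the simulated profile by a least-squares
#' normalization fit). Reported is the relative difference of the two
#' trapezoidal envelope-profile integrals.
#'
#' @param config list from [heat_source_recon_config()].
#' @param seed master RNG seed.
#' @return List: `integral_discrepancy` (fraction), `profile_table`
#'   (x_mm, source, reconstruction, both normalized), `region` (index
#'   ranges), plus the reconstruction.
#' @export
run_heat_source_recon <- function(config = heat_source_recon_config(),
                                  seed = 1) {
  ph <- config$phantom
  dl <- ph$dl_mm * 1e-3
  g <- build_tumor_phantom(ph$tumor_diameter_mm * 1e-3,
                           ph$tumor_depth_mm * 1e-3, dl = dl,
                           extent = ph$extent_mm * 1e-3)
  beam <- beam_spec(config$beam$profile, config$beam$diameter_mm * 1e-3,
                    config$beam$energy_j, mode = "pulsed")
  mc <- mc_fluence(g, beam, n_photons = config$n_photons,
                   seed = (seed * 1000 + 1) %% .Machine$integer.max)
  S <- heat_source(g, mc$fluence)
  gm <- grueneisen_of(g$props[["1"]])
  p0 <- initial_pressure(S, g, config$T0, gm)
  vs <- g$props[["1"]]$vs
  yc <- g$dims[2] %/% 2
  full <- config$view == "full"
  arr <- if (full) {
    # exact-inversion reference: closed spherical aperture, full band
    half <- g$dims * dl / 2
    sphere_array(radius = sqrt(sum(half^2)) + 2e-3,
                 center = c(0, 0, half[3]), n_elements = 2048,
                 sampling_rate = config$array$sampling_rate_hz)
  } else {
    transducer_array(n_elements = config$array$n_elements,
                     pitch = config$array$pitch_mm * 1e-3,
                     center_frequency = config$array$center_frequency_hz,
                     sampling_rate = config$array$sampling_rate_hz,
                     standoff = config$array$standoff_mm * 1e-3)
  }
  rf <- forward_project(p0, arr, vs, bandlimit = !full,
                        noise = noise_spec(config$noise$channel_snr_db,
                                           seed = (seed * 1000 + 2) %%
                                             .Machine$integer.max))
  rec <- ubp_reconstruct(rf, arr, vs, g, plane_y = yc)

  tmask <- g$labels[, yc, ] == 2L
  if (!any(tmask)) stop("empty target region: no tumor voxels in the plane")
  pad <- as.integer(round(config$region_pad_mm * 1e-3 / dl))
  xr <- pmax(1, pmin(g$dims[1], range(which(rowSums(tmask) > 0)) + c(-pad, pad)))
  zr <- pmax(1, pmin(g$dims[3], range(which(colSums(tmask) > 0)) + c(-pad, pad)))
  Spl <- S$S[, yc, ]
  pr_s <- apply(Spl[xr[1]:xr[2], zr[1]:zr[2]], 1, max)
  pr_s <- pr_s / max(pr_s)
  pr_r <- apply(abs(rec$p0)[xr[1]:xr[2], zr[1]:zr[2]], 1, max)
  # the reconstruction is in arbitrary units. "fit": register its amplitude
  # to the simulated profile by least squares (normalization fitting) before
  # comparing the trapezoidal envelope integrals; "max": normalize each
  # profile to unit maximum (sensitive to limited-view shoulder loss)
  pr_r <- if (identical(config$normalization, "max")) pr_r / max(pr_r)
          else pr_r * sum(pr_s * pr_r) / sum(pr_r^2)
  i_s <- sum((pr_s[-1] + pr_s[-length(pr_s)]) / 2)
  i_r <- sum((pr_r[-1] + pr_r[-length(pr_r)]) / 2)
  list(integral_discrepancy = abs(i_r - i_s) / i_s,
       profile_table = data.frame(
         x_mm = ((xr[1]:xr[2]) - 0.5) * dl * 1e3,
         source = pr_s, reconstruction = pr_r),
       region = list(x = xr, z = zr), reconstruction = rec,
       config = config, seed = seed)
}

#' Default configuration for the photothermal-therapy twin
#'
#' The study conditions of the simulated treatment: a 5 mm black-agarose
#' sphere 3.2 mm deep in muscle tissue, heated by a 3 mm continuous beam
#' from 36 deg C into the mild-therapy window, observed by pulsed
#' photoacoustic frames with 0.5% pulse-energy jitter, after a 30-to-36 deg C
#' water-bath calibration sweep in 0.5 deg C steps.
#'
#' @param n_photons_truth,n_photons_model Monte-Carlo packets for the truth
#'   and model fluence solutions (separate seeds: the model's optical solve
#'   is an independent, noisier estimate).
#' @param decimate fusion-ROI decimation factor (1 = fuse on the simulation
#'   grid).
#' @return Nested configuration list.
#' @export
ptt_twin_config <- function(n_photons_truth = 5e5, n_photons_model = 5e5,
                            decimate = 1) {
  list(phantom = list(tumor_diameter_mm = 5, tumor_depth_mm = 3.2,
                      dl_mm = 0.75, extent_mm = c(12, 12, 10.5)),
       beam = list(profile = "gaussian", diameter_mm = 3,
                   cw_power_w = 0.3, pulse_energy_j = 1e-3),
       T0 = 36, T_max = 45,
       duration_s = 120,
       frame_every = 1,
       n_static_frames = 50,
       pulse_jitter_frac = 0.005,
       calibration = list(T_start = 30, T_end = 36, T_step = 0.5,
                          n_repeats = 10),
       top_threshold_frac = 0.05,
       slab_halfwidth = 1,
       source_bias = 1.05,
       n_photons_truth = n_photons_truth,
       n_photons_model = n_photons_model,
       decimate = decimate,
       kalman = list(Q_dT_transient = 1e-3, Q_dT_steady = 1e-4,
                     transient_s = 30, Q_S = 0, P_init_dT = 1e-4,
                     P_init_S_frac = 0.05))
}

#' Simulated photothermal-therapy twin with Kalman fusion
#'
#' Runs the full treatment twin: truth bioheat simulation of the heated
#' sphere phantom on the fine grid; synthetic photoacoustic observations at
#' the actually-observable points each frame (Grueneisen model with seeded
#' pulse-energy jitter); water-bath calibration of the observation gain;
#' and the predict/update fusion filter on the (optionally decimated)
#' region of interest. The model's heat source is its own Monte-Carlo
#' estimate scaled by a deliberate calibration bias, split into adjustable
#' source states at the significant-source points (TOPs) and a known input
#' for the sub-threshold remainder. Errors are evaluated at the four
#' validation thermocouples (tumor top, tumor core, adjacent tissue,
#' lateral margin).
#'
#' The run stops with a report if the truth temperature exceeds the
#' mild-therapy ceiling.
#'
#' @param config list from [ptt_twin_config()].
#' @param seed master RNG seed; all noise streams derive from it.
#' @return List: `trajectories` (long data frame: time_s, point, truth,
#'   model_only, fused, pa_only), `summary` (per-point maximum absolute
#'   errors), `calibration`, `R_hat`, `points`, `window_violation`,
#'   `diagnostics` (innovations, covariance trace).
#' @export
run_ptt_twin <- function(config = ptt_twin_config(), seed = 1) {
  ph <- config$phantom
  dl <- ph$dl_mm * 1e-3
  g <- build_tumor_phantom(ph$tumor_diameter_mm * 1e-3,
                           ph$tumor_depth_mm * 1e-3, dl = dl,
                           extent = ph$extent_mm * 1e-3)
  T0 <- config$T0
  sub_seed <- function(k) (seed * 1000 + k) %% .Machine$integer.max

  ## --- optics: truth and model fluence solutions (matching illumination) ---
  beam_cw <- beam_spec(config$beam$profile, config$beam$diameter_mm * 1e-3,
                       config$beam$cw_power_w, mode = "continuous")
  mc_truth <- mc_fluence(g, beam_cw, n_photons = config$n_photons_truth,
                         seed = sub_seed(1))
  S_true <- heat_source(g, mc_truth$fluence)$S
  mc_model <- mc_fluence(g, beam_cw, n_photons = config$n_photons_model,
                         seed = sub_seed(2))
  S_model <- heat_source(g, mc_model$fluence)$S * config$source_bias

  ## --- fusion ROI (optionally decimated) and point sets ---
  dec <- as.integer(config$decimate)
  cg <- decimate_grid(g, dec)
  cd <- cg$dims
  S_model_c <- if (dec > 1) restrict_field(S_model, dec) else S_model
  gm <- grueneisen_of(g$props[["1"]])
  # pulsed-mode pressure pattern for point selection (matching illumination:
  # the same fluence solution rescaled to pulse energy)
  p0_model <- initial_pressure(
    structure(list(S = S_model_c, dims = cd, dl = cg$dl),
              class = "heat_source_field"), cg, T0, gm)
  ps <- select_tops(p0_model, config$top_threshold_frac,
                    plane_y = cd[2] %/% 2,
                    slab_halfwidth = config$slab_halfwidth)

  ## --- clocks and state-space model ---
  dt <- 0.9 * cfl_max_dt(g)
  n_steps <- ceiling(config$duration_s / dt)
  clock <- sim_clock(dt)
  model <- build_state_space(cg, ps, clock, bc = "dirichlet")

  ## --- truth simulation, recording thermocouples and AOP frames ---
  pts <- default_sampling_points(g)
  frames <- seq(config$frame_every, n_steps, config$frame_every)
  aop_fine <- lapply(seq_len(ps$M), function(m) {
    ijk <- arrayInd(ps$aops[m], cd)
    as.matrix(expand.grid((ijk[1] - 1) * dec + 1:dec,
                          (ijk[2] - 1) * dec + 1:dec,
                          (ijk[3] - 1) * dec + 1:dec))
  })
  stn <- thermal_stencil(g, "dirichlet")
  Tf <- array(T0, g$dims)
  truth_trace <- matrix(NA_real_, n_steps, length(pts))
  T_aop <- matrix(NA_real_, length(frames), ps$M)
  window_violation <- FALSE
  fi <- 0L
  for (k in seq_len(n_steps)) {
    Tf <- step_heat(Tf, S_true, g, clock, "dirichlet", T0, stn)
    truth_trace[k, ] <- vapply(pts, function(p)
      Tf[p$position[1], p$position[2], p$position[3]], numeric(1))
    if (k %% config$frame_every == 0) {
      fi <- fi + 1L
      T_aop[fi, ] <- vapply(aop_fine, function(ch) mean(Tf[ch]), numeric(1))
    }
    if (max(Tf) > config$T_max) {
      warning(sprintf("therapy window violated at t = %.1f s (T > %.1f C); run stopped",
                      k * dt, config$T_max))
      window_violation <- TRUE
      n_steps <- k
      truth_trace <- truth_trace[seq_len(k), , drop = FALSE]
      keep <- frames <= k
      frames <- frames[keep]; T_aop <- T_aop[seq_along(frames), , drop = FALSE]
      break
    }
  }

  ## --- synthetic water-bath calibration sweep (strictly before heating) ---
  calcfg <- config$calibration
  bath_T <- seq(calcfg$T_start, calcfg$T_end, calcfg$T_step)
  # truth pressure pattern at the AOPs: the truth heat source scaled to
  # pulsed mode; absolute scale cancels in alpha
  p0_ref_aop <- vapply(aop_fine, function(ch) mean(S_true[ch]), numeric(1)) *
    (gm$A + gm$B * T0)
  jit <- config$pulse_jitter_frac
  n_rep <- if (is.null(calcfg$n_repeats)) 1L else calcfg$n_repeats
  cal_amp <- withr::with_seed(sub_seed(3), {
    sweep_gam <- gm$A + gm$B * bath_T
    # each bath step averages n_repeats pulse acquisitions
    jit_step <- stats::rnorm(length(bath_T)) * jit / sqrt(n_rep)
    outer(sweep_gam / (gm$A + gm$B * T0), p0_ref_aop) * (1 + jit_step)
  })
  cal <- calibrate(bath_T, cal_amp, T0 = calcfg$T_end)

  ## --- static frames before heating: reference amplitudes and R ---
  static_amp <- withr::with_seed(sub_seed(4),
    outer(1 + stats::rnorm(config$n_static_frames) * jit, p0_ref_aop))
  ref_amp <- colMeans(static_amp)
  alpha_static <- sweep(static_amp, 2, ref_amp, "/") - 1
  R_hat <- estimate_R(alpha_static)

  ## --- per-frame observations during heating ---
  alpha_frames <- withr::with_seed(sub_seed(5), {
    eps <- stats::rnorm(length(frames)) * jit
    amp <- (gm$A + gm$B * T_aop) *
      outer(rep(1, length(frames)), p0_ref_aop / (gm$A + gm$B * T0)) *
      (1 + eps)
    sweep(amp, 2, ref_amp, "/") - 1
  })

  ## --- state-space heat-source split: states on TOPs, input below ---
  roi_pos <- integer(prod(cd)); roi_pos[ps$roips] <- seq_len(ps$N)
  S0 <- S_model_c[ps$tops]
  S_sub <- S_model_c; S_sub[ps$tops] <- 0
  rho_cp <- grid_property(cg, "rho") * grid_property(cg, "cp")
  input <- c(as.numeric((dt * S_sub / rho_cp)[ps$roips]), numeric(ps$W))

  ## --- thermocouple read-out weights on the fusion state ---
  Wrec <- t(vapply(pts, function(p)
    c(interp_weights(p$position, dl, cd, cg$dl), numeric(ps$W)),
    numeric(ps$N + ps$W)))

  kcfg <- config$kalman
  # process-noise schedule: the transient range while the source estimate
  # settles after the laser-power step, the steady range thereafter
  k_transient <- ceiling(kcfg$transient_s / dt)
  Q_sched <- function(step) {
    qdT <- if (step <= k_transient) kcfg$Q_dT_transient else kcfg$Q_dT_steady
    c(rep(qdT, ps$N), rep(kcfg$Q_S, ps$W))
  }
  cfg_k <- kalman_config(
    Qkf = Q_sched,
    R = mean(R_hat),
    P_init_dT = kcfg$P_init_dT,
    P_init_S = (kcfg$P_init_S_frac * max(S_model_c))^2)
  H <- build_H(ps, cal)

  fus <- run_fusion(model, H, alpha_frames, frames, S0 = S0, cfg = cfg_k,
                    n_steps = n_steps, input = input, record_weights = Wrec)

  ## --- model-only propagation (no observations, no covariance) ---
  x <- numeric(ps$N + ps$W); x[ps$N + seq_len(ps$W)] <- S0
  model_trace <- matrix(NA_real_, n_steps, length(pts))
  for (k in seq_len(n_steps)) {
    x <- as.numeric(model$F %*% x) + input
    model_trace[k, ] <- as.numeric(Wrec %*% x)
  }

  ## --- assemble trajectories and error summary (at frame times) ---
  labels <- vapply(pts, function(p) p$label, character(1))
  pa_dT <- alpha_frames / cal$slope_coeff
  aop_of_pt <- vapply(seq_along(pts), function(i) {
    cijk <- pmin(pmax((pts[[i]]$position - 1L) %/% dec + 1L, 1L), cd)
    lin <- cijk[1] + cd[1] * (cijk[2] - 1) + cd[1] * cd[2] * (cijk[3] - 1)
    m <- match(lin, ps$aops)
    if (is.na(m)) NA_integer_ else m
  }, integer(1))

  nf <- length(frames)
  traj <- do.call(rbind, lapply(seq_along(pts), function(i) {
    data.frame(time_s = frames * dt, point = rep(labels[i], nf),
               truth = truth_trace[frames, i],
               model_only = T0 + model_trace[frames, i],
               fused = T0 + fus$trace[frames, i],
               pa_only = if (!is.na(aop_of_pt[i]) && nf > 0)
                 T0 + pa_dT[, aop_of_pt[i]] else rep(NA_real_, nf))
  }))
  err <- function(est) tapply(abs(est - traj$truth), traj$point, max)
  summary <- if (nf == 0) {
    list(max_fused_error = NA_real_, max_model_error = NA_real_,
         max_pa_error = NA_real_, per_point_fused = NULL,
         per_point_model = NULL)
  } else list(
    max_fused_error = max(abs(traj$fused - traj$truth)),
    max_model_error = max(abs(traj$model_only - traj$truth)),
    max_pa_error = max(abs(traj$pa_only - traj$truth), na.rm = TRUE),
    per_point_fused = err(traj$fused),
    per_point_model = err(traj$model_only))
  list(trajectories = traj, summary = summary, calibration = cal,
       R_hat = R_hat, points = ps, sampling_points = pts,
       window_violation = window_violation,
       diagnostics = list(innovations = fus$innovations,
                          P_trace = fus$P_trace),
       config = config, seed = seed)
}
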