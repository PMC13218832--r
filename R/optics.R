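#' Laser beam specification
#'
#' Describes the surface illumination. Both the pulsed (photoacoustic) and
#' continuous (heating) beams are represented by the same object; under the
#' matching-illumination condition they share one spatial profile and differ
#' only in `mode` and `power_or_energy`, so a single fluence solution serves
#' both after rescaling (see [scale_fluence()]).
#'
#' @param profile `"gaussian"` or `"flattop"`.
#' @param diameter beam diameter (m). For a Gaussian profile this is by
#'   default the 1/e^2 intensity diameter; set `width_convention = "fwhm"` to
#'   interpret it as the FWHM instead. For a flat-top it is the disc diameter.
#' @param power_or_energy beam power (W, `mode = "continuous"`) or pulse
#'   energy (J, `mode = "pulsed"`).
#' @param mode `"continuous"` or `"pulsed"`.
#' @param wavelength wavelength (m); metadata only.
#' @param center lateral beam-center coordinates `(x, y)` on the surface (m),
#'   or `NULL` for the grid center at solve time.
#' @param width_convention `"e2"` or `"fwhm"` (Gaussian profile only).
#' @return An object of class `beam_spec`.
#' @export
beam_spec <- function(profile = c("gaussian", "flattop"), diameter,
                      power_or_energy, mode = c("continuous", "pulsed"),
                      wavelength = 808e-9, center = NULL,
                      width_convention = c("e2", "fwhm")) {
  profile <- match.arg(profile)
  mode <- match.arg(mode)
  width_convention <- match.arg(width_convention)
  stopifnot(diameter > 0, power_or_energy > 0)
  structure(list(profile = profile, diameter = diameter,
                 power_or_energy = power_or_energy, mode = mode,
                 wavelength = wavelength, center = center,
                 width_convention = width_convention),
            class = "beam_spec")
}

# 1/e^2 intensity radius. FWHM of exp(-2 r^2 / w0^2) is w0 sqrt(2 ln 2).
beam_radius_e2 <- function(beam) {
  if (beam$profile == "gaussian" && beam$width_convention == "fwhm")
    beam$diameter / sqrt(2 * log(2))
  else beam$diameter / 2
}

new_fluence_field <- function(phi, beam, grid, n_photons = NA_integer_,
                              seed = NA_integer_) {
  stopifnot(all(is.finite(phi)), all(phi >= -1e-12))
  phi[phi < 0] <- 0
  structure(list(phi = phi, beam = beam, dims = grid$dims, dl = grid$dl,
                 n_photons = n_photons, seed = seed),
            class = "fluence_field")
}

#' @export
print.fluence_field <- function(x, ...) {
  unit <- if (x$beam$mode == "pulsed") "J/m^2" else "W/m^2"
  cat(sprintf("<fluence_field %d x %d x %d, max %.4g %s>\n",
              x$dims[1], x$dims[2], x$dims[3], max(x$phi), unit))
  invisible(x)
}

#' Monte-Carlo fluence solution
#'
#' Voxel Monte-Carlo photon transport with Henyey-Greenstein scattering,
#' continuous absorption weighting and a track-length fluence estimator.
#' Boundaries are refractive-index matched (photons leaving the grid are
#' lost). The returned fluence is normalized so that
#' `sum(mu_a * phi * dl^3) = absorbed_fraction * power_or_energy`.
#'
#' @param grid a `voxel_grid`.
#' @param beam a [beam_spec()]; launched at normal incidence on the top
#'   surface (z = 0).
#' @param n_photons number of photon packets (default 1e6).
#' @param seed RNG seed; mandatory for reproducibility. Two runs with the
#'   same seed are bit-identical.
#' @return An object of class `mc_result` with fields `fluence`
#'   (a `fluence_field`), `absorbed_fraction`, `escaped_fraction`
#'   (top/lateral exits), `transmitted_fraction` (bottom exits) and
#'   `lost_fraction` (roulette remainder).
#' @export
mc_fluence <- function(grid, beam, n_photons = 1e6, seed) {
  stopifnot(n_photons >= 1)
  if (missing(seed)) stop("a seed is required for mc_fluence()")
  mu_a <- grid_property(grid, "mu_a")
  mu_s <- grid_property(grid, "mu_s")
  g <- grid_property(grid, "g")
  cen <- beam$center
  if (is.null(cen)) cen <- c(grid$dims[1], grid$dims[2]) * grid$dl / 2
  prof <- if (beam$profile == "gaussian") 0L else 1L
  res <- withr::with_seed(as.integer(seed),
    mc_transport_cpp(grid$dims, grid$dl, as.numeric(mu_a), as.numeric(mu_s),
                     as.numeric(g), prof, beam_radius_e2(beam),
                     cen[1], cen[2], as.integer(n_photons)))
  vol <- grid$dl^3
  phi <- array(res$track_length * beam$power_or_energy / (n_photons * vol),
               dim = grid$dims)
  structure(list(fluence = new_fluence_field(phi, beam, grid,
                                             n_photons = n_photons,
                                             seed = as.integer(seed)),
                 absorbed_fraction = res$absorbed,
                 escaped_fraction = res$escaped,
                 transmitted_fraction = res$transmitted,
                 lost_fraction = res$lost),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf(paste0("<mc_result: %.0f photons, absorbed %.4f, escaped %.4f,",
                     " transmitted %.4f>\n"),
              x$fluence$n_photons, x$absorbed_fraction, x$escaped_fraction,
              x$transmitted_fraction))
  invisible(x)
}

#' Rescale a fluence field to a different beam power or energy
#'
#' Under the matching-illumination condition the pulsed and continuous beams
#' deposit energy with the same spatial pattern, so one transport solution is
#' reused for both by linear rescaling.
#'
#' @param fluence a `fluence_field`.
#' @param power_or_energy new beam power (W) or pulse energy (J).
#' @param mode `"continuous"` or `"pulsed"` for the rescaled field.
#' @return A `fluence_field` with rescaled `phi`.
#' @export
scale_fluence <- function(fluence, power_or_energy, mode = fluence$beam$mode) {
  fac <- power_or_energy / fluence$beam$power_or_energy
  fluence$phi <- fluence$phi * fac
  fluence$beam$power_or_energy <- power_or_energy
  fluence$beam$mode <- mode
  fluence
}

#' Steady-state diffusion-approximation fluence
#'
#' Solves the steady-state optical diffusion equation
#' `-div(D grad Phi) + mu_a Phi = L` with `D = 1/(3 (mu_a + mu_s'))` by a
#' 7-point finite-difference scheme with Dirichlet `Phi = 0` on the outer
#' boundary. The collimated beam is mapped to an isotropic equivalent source
#' one transport mean free path below the surface, spread over the lateral
#' beam profile. Intended as a fast alternative in scattering-dominated
#' media; [mc_fluence()] is the reference solver.
#'
#' @param grid a `voxel_grid`.
#' @param beam a [beam_spec()].
#' @param source optional explicit per-voxel source array `L` (W/m^3),
#'   overriding the beam mapping (used for Green's-function checks).
#' @return A `fluence_field`.
#' @export
diffusion_fluence <- function(grid, beam = NULL, source = NULL) {
  mu_a <- grid_property(grid, "mu_a")
  mu_sp <- grid_property(grid, "mu_s_reduced")
  mu_t <- mu_a + mu_sp
  if (any(mu_t <= 0)) stop("diffusion coefficient undefined where mu_a + mu_s' = 0")
  if (max(mu_a) == 0)
    warning("zero absorption everywhere: solution fixed only by boundary loss")
  if (stats::median(mu_sp) < 10 * stats::median(mu_a))
    warning("mu_s' is not >> mu_a: diffusion approximation may be inaccurate")
  D <- 1 / (3 * mu_t)
  dims <- grid$dims; dl <- grid$dl
  n <- prod(dims)

  if (is.null(source)) {
    if (is.null(beam)) stop("either a beam or an explicit source is required")
    cen <- beam$center
    if (is.null(cen)) cen <- c(dims[1], dims[2]) * dl / 2
    ltr <- 1 / mu_t[ceiling(dims[1] / 2), ceiling(dims[2] / 2), 1]
    iz <- min(dims[3], max(1L, as.integer(ceiling(ltr / dl))))
    cx <- voxel_centers(grid, 1); cy <- voxel_centers(grid, 2)
    r2 <- outer((cx - cen[1])^2, (cy - cen[2])^2, `+`)
    w0 <- beam_radius_e2(beam)
    lateral <- if (beam$profile == "gaussian") exp(-2 * r2 / w0^2)
               else (r2 <= w0^2) * 1.0
    lateral <- lateral / sum(lateral)
    source <- array(0, dim = dims)
    source[, , iz] <- lateral * beam$power_or_energy / dl^3
  }

  idx <- array(seq_len(n), dim = dims)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  diag_acc <- as.numeric(mu_a)
  shifts <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))
  Dv <- D
  for (s in shifts) {
    src <- list(seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3]))
    dst <- lapply(1:3, function(a) src[[a]] + s[a])
    keep <- lapply(1:3, function(a) dst[[a]] >= 1 & dst[[a]] <= dims[a])
    ii <- idx[src[[1]][keep[[1]]], src[[2]][keep[[2]]], src[[3]][keep[[3]]], drop = FALSE]
    jj <- idx[dst[[1]][keep[[1]]], dst[[2]][keep[[2]]], dst[[3]][keep[[3]]], drop = FALSE]
    Dface <- 2 * Dv[ii] * Dv[jj] / (Dv[ii] + Dv[jj]) / dl^2
    rows <- c(rows, as.integer(ii)); cols <- c(cols, as.integer(jj))
    vals <- c(vals, -Dface)
    dacc <- numeric(n); dacc[as.integer(ii)] <- Dface
    diag_acc <- diag_acc + dacc
    # Dirichlet Phi = 0 just outside: boundary faces couple to a zero ghost
    bnd <- setdiff(seq_len(n), as.integer(ii))
    dbnd <- numeric(n); dbnd[bnd] <- Dv[bnd] / dl^2
    diag_acc <- diag_acc + dbnd
  }
  A <- Matrix::sparseMatrix(i = c(rows, seq_len(n)), j = c(cols, seq_len(n)),
                            x = c(vals, diag_acc), dims = c(n, n))
  # the operator is symmetric positive definite: solve by sparse Cholesky
  A <- Matrix::forceSymmetric(A)
  phi <- tryCatch(as.numeric(Matrix::solve(A, as.numeric(source))),
                  error = function(e) stop("diffusion system is ill-posed: ",
                                           conditionMessage(e)))
  phi[phi < 0] <- 0
  bm <- if (is.null(beam)) beam_spec("flattop", diameter = dl,
                                     power_or_energy = sum(source) * dl^3,
                                     mode = "continuous") else beam
  new_fluence_field(array(phi, dim = dims), bm, grid)
}

#' Photothermal heat source
#'
#' `S(r) = mu_a(r) * Phi(r)`: the volumetric power (or energy) density
#' deposited by the beam.
#'
#' @param grid a `voxel_grid`.
#' @param fluence a `fluence_field` on the same grid.
#' @return An object of class `heat_source_field` with array `S` (W/m^3 for a
#'   continuous beam, J/m^3 for a pulsed one).
#' @export
heat_source <- function(grid, fluence) {
  if (!identical(as.integer(fluence$dims), grid$dims) ||
      !isTRUE(all.equal(fluence$dl, grid$dl)))
    stop("fluence field and grid geometries do not match")
  S <- grid_property(grid, "mu_a") * fluence$phi
  structure(list(S = S, dims = grid$dims, dl = grid$dl,
                 mode = fluence$beam$mode),
            class = "heat_source_field")
}

#' @export
print.heat_source_field <- function(x, ...) {
  unit <- if (identical(x$mode, "pulsed")) "J/m^3" else "W/m^3"
  cat(sprintf("<heat_source_field %d x %d x %d, max %.4g %s>\n",
              x$dims[1], x$dims[2], x$dims[3], max(x$S), unit))
  invisible(x)
}

#' Absorbed energy in the absorber-plane region
#'
#' Fraction of the input beam energy absorbed inside the absorber slab of a
#' phantom from [build_absorber_plane_phantom()].
#'
#' @param result an `mc_result`.
#' @param grid the absorber-plane `voxel_grid` the result was computed on.
#' @return Dimensionless absorbed fraction in the absorber region.
#' @export
absorber_plane_energy <- function(result, grid) {
  if (is.null(grid$absorber_z0)) stop("grid has no absorber plane region")
  mask <- grid$labels == 2L
  mu_a <- grid_property(grid, "mu_a")
  sum(mu_a[mask] * result$fluence$phi[mask]) * grid$dl^3 /
    result$fluence$beam$power_or_energy
}

#' Depth-wise relative energy at the absorber plane
#'
#' Absorbed energy integrated over the absorber plane, normalized to the same
#' quantity with the absorber at zero depth. Values lie in (0, 1] and decay
#' with cover depth.
#'
#' @param result an `mc_result` for a covered absorber-plane phantom.
#' @param grid the matching `voxel_grid`.
#' @param reference_energy the unnormalized [absorber_plane_energy()] of the
#'   zero-cover-depth phantom.
#' @return Relative energy (dimensionless).
#' @export
depth_energy_integral <- function(result, grid, reference_energy) {
  stopifnot(reference_energy > 0)
  absorber_plane_energy(result, grid) / reference_energy
}
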