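#' Per-region tissue properties
#'
#' Bundles the optical, thermal and acoustic constants of one tissue type.
#' Optical coefficients are in 1/m, thermal constants in SI units, and the
#' Grueneisen parameter is the affine model `Gamma(T) = A + B*T` with `T` in
#' degrees Celsius.
#'
#' @param mu_a absorption coefficient (1/m), >= 0.
#' @param mu_s scattering coefficient (1/m), >= 0.
#' @param g scattering anisotropy factor, in `[0, 1)`.
#' @param rho density (kg/m^3), > 0.
#' @param cp specific heat capacity (J/(kg K)), > 0.
#' @param kv thermal conductivity (W/(m K)), > 0.
#' @param vs speed of sound (m/s), > 0.
#' @param grueneisen_A Grueneisen intercept (dimensionless).
#' @param grueneisen_B Grueneisen slope (1/K).
#' @param name optional label used in printing.
#' @return An object of class `tissue_properties`.
#' @seealso [tissue_preset()] for ready-made parameter sets,
#'   [mu_s_reduced()] for the reduced scattering coefficient.
#' @export
tissue_properties <- function(mu_a, mu_s, g, rho, cp, kv, vs,
                              grueneisen_A = 0.12, grueneisen_B = 0.0,
                              name = "custom") {
  stopifnot(mu_a >= 0, mu_s >= 0, g >= 0, g < 1,
            rho > 0, cp > 0, kv > 0, vs > 0)
  structure(list(mu_a = mu_a, mu_s = mu_s, g = g, rho = rho, cp = cp,
                 kv = kv, vs = vs, grueneisen_A = grueneisen_A,
                 grueneisen_B = grueneisen_B, name = name),
            class = "tissue_properties")
}

#' @export
print.tissue_properties <- function(x, ...) {
  cat(sprintf("<tissue_properties: %s>\n", x$name))
  cat(sprintf("  mu_a %.3g 1/m, mu_s %.3g 1/m (g %.2f, mu_s' %.3g 1/m)\n",
              x$mu_a, x$mu_s, x$g, mu_s_reduced(x)))
  cat(sprintf("  rho %.4g kg/m^3, cp %.4g J/(kg K), kv %.3g W/(m K), vs %.4g m/s\n",
              x$rho, x$cp, x$kv, x$vs))
  cat(sprintf("  Grueneisen A %.4g, B %.4g 1/K\n", x$grueneisen_A, x$grueneisen_B))
  invisible(x)
}

#' Reduced scattering coefficient
#'
#' `mu_s' = (1 - g) * mu_s`, computed on demand from the stored coefficients.
#'
#' @param props a [tissue_properties()] object.
#' @return Reduced scattering coefficient (1/m).
#' @export
mu_s_reduced <- function(props) (1 - props$g) * props$mu_s

#' Named tissue-property presets
#'
#' Literature-style soft-tissue parameter sets at 808 nm. `"chicken_breast_808"`
#' is the default background muscle tissue; `"black_agarose"` is the strongly
#' absorbing ink-loaded gel used both for absorber planes and simulated tumors
#' (its absorption is 200x the muscle preset, so a slab of it intercepts
#' essentially all remaining light); `"water_gel"` is a transparent agarose
#' coupling layer. The Grueneisen slope/intercept of the tissue presets are
#' chosen so that the composite thermometry gain `B/(A + B*T0)` at
#' `T0 = 36` degrees C equals 0.0354 (see [calibrate_gain()]).
#'
#' All values are overridable: the returned object is an ordinary
#' [tissue_properties()] and individual fields can be replaced via [modify_props()].
#'
#' @param name one of `"chicken_breast_808"`, `"black_agarose"`, `"water_gel"`.
#' @return A [tissue_properties()] object.
#' @export
tissue_preset <- function(name = c("chicken_breast_808", "black_agarose",
                                   "water_gel")) {
  name <- match.arg(name)
  # Gamma(36 C) = 0.25 with relative slope 0.0354 1/K at 36 C
  B <- 0.0354 * 0.25
  A <- 0.25 - B * 36
  switch(name,
    chicken_breast_808 = tissue_properties(
      mu_a = 10, mu_s = 6000, g = 0.9, rho = 1050, cp = 3600, kv = 0.5,
      vs = 1540, grueneisen_A = A, grueneisen_B = B, name = name),
    black_agarose = tissue_properties(
      mu_a = 2000, mu_s = 100, g = 0.9, rho = 1000, cp = 4180, kv = 0.6,
      vs = 1500, grueneisen_A = A, grueneisen_B = B, name = name),
    water_gel = tissue_properties(
      mu_a = 0.2, mu_s = 100, g = 0.9, rho = 1000, cp = 4180, kv = 0.6,
      vs = 1500, grueneisen_A = A, grueneisen_B = B, name = name))
}

#' Modify fields of a tissue-property set
#'
#' @param props a [tissue_properties()] object.
#' @param ... named fields to replace, e.g. `mu_a = 500`.
#' @return The modified [tissue_properties()] object (revalidated).
#' @export
modify_props <- function(props, ...) {
  repl <- list(...)
  bad <- setdiff(names(repl), setdiff(names(props), "name"))
  if (length(bad)) stop("unknown tissue property field(s): ",
                        paste(bad, collapse = ", "))
  for (nm in names(repl)) props[[nm]] <- repl[[nm]]
  do.call(tissue_properties, props)
}

new_voxel_grid <- function(dims, dl, labels, props, origin = c(0, 0, 0)) {
  stopifnot(dl > 0, length(dims) == 3, all(dims >= 1),
            identical(dim(labels), as.integer(dims)))
  labs <- sort(unique(as.vector(labels)))
  if (!all(as.character(labs) %in% names(props)))
    stop("every region label must map to a tissue_properties entry")
  structure(list(dims = as.integer(dims), dl = dl, origin = origin,
                 labels = labels, props = props),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid %d x %d x %d, dl = %.3g mm (%.3g x %.3g x %.3g mm)>\n",
              x$dims[1], x$dims[2], x$dims[3], x$dl * 1e3,
              x$dims[1] * x$dl * 1e3, x$dims[2] * x$dl * 1e3,
              x$dims[3] * x$dl * 1e3))
  tab <- table(x$labels)
  for (lb in names(tab))
    cat(sprintf("  region %s (%s): %d voxels\n", lb,
                x$props[[lb]]$name, tab[[lb]]))
  invisible(x)
}

#' Per-voxel property map
#'
#' Expands a named scalar tissue property to a full array over the grid by
#' region label.
#'
#' @param grid a `voxel_grid`.
#' @param field property name, e.g. `"mu_a"`, `"kv"`; `"mu_s_reduced"` is
#'   accepted and computed on demand.
#' @return Numeric array of the grid's dimensions.
#' @export
grid_property <- function(grid, field) {
  labs <- names(grid$props)
  vals <- vapply(grid$props, function(p) {
    if (field == "mu_s_reduced") mu_s_reduced(p) else p[[field]]
  }, numeric(1))
  lookup <- stats::setNames(vals, labs)
  array(lookup[as.character(grid$labels)], dim = grid$dims)
}

#' Voxel-center coordinates along one axis
#'
#' Centers follow the voxel-center convention: voxel index `i` (0-based) spans
#' `[i*dl, (i+1)*dl)` with center `(i + 0.5)*dl` plus the grid origin.
#'
#' @param grid a `voxel_grid`.
#' @param axis 1 (x), 2 (y) or 3 (z = depth).
#' @return Numeric vector of voxel-center coordinates (m).
#' @export
voxel_centers <- function(grid, axis) {
  (seq_len(grid$dims[axis]) - 0.5) * grid$dl + grid$origin[axis]
}

#' Layered slab phantom
#'
#' Stacks horizontal tissue layers along the depth axis z. Physical layer
#' thicknesses are rounded to the nearest whole number of voxels (minimum 1).
#'
#' @param layer_thicknesses layer thicknesses (m), top first.
#' @param layer_props list of [tissue_properties()], one per layer.
#' @param dl voxel edge length (m).
#' @param lateral_extent lateral size in x and y (m); rounded to voxels.
#' @return A `voxel_grid` with region label `i` for layer `i`.
#' @export
build_layered_phantom <- function(layer_thicknesses, layer_props, dl,
                                  lateral_extent = c(12e-3, 12e-3)) {
  stopifnot(length(layer_thicknesses) == length(layer_props), dl > 0)
  bad <- which(layer_thicknesses <= 0)
  if (length(bad)) stop("layer ", bad[1], " has non-positive thickness")
  nvox <- pmax(1L, as.integer(round(layer_thicknesses / dl)))
  nx <- max(1L, as.integer(round(lateral_extent[1] / dl)))
  ny <- max(1L, as.integer(round(lateral_extent[2] / dl)))
  nz <- sum(nvox)
  lab_z <- rep(seq_along(nvox), nvox)
  labels <- array(rep(lab_z, each = nx * ny), dim = c(nx, ny, nz))
  props <- stats::setNames(layer_props, as.character(seq_along(layer_props)))
  new_voxel_grid(c(nx, ny, nz), dl, labels, props)
}

#' Spherical-tumor phantom
#'
#' Embeds a spherical absorbing tumor in homogeneous background tissue. The
#' sphere is laterally centered; its top is at `tumor_depth` below the
#' illuminated surface, so the center sits at `tumor_depth + diameter/2`.
#' Voxels whose centers fall within the sphere radius are labelled tumor.
#'
#' @param tumor_diameter sphere diameter (m), > 0.
#' @param tumor_depth depth of the sphere's top below the surface (m).
#' @param background,tumor [tissue_properties()] for the two regions.
#' @param dl voxel edge length (m).
#' @param extent domain size `(x, y, z)` (m).
#' @return A `voxel_grid`; label 1 = background, 2 = tumor.
#' @export
build_tumor_phantom <- function(tumor_diameter, tumor_depth,
                                background = tissue_preset("chicken_breast_808"),
                                tumor = tissue_preset("black_agarose"),
                                dl = 0.25e-3,
                                extent = c(16e-3, 16e-3, 14e-3)) {
  if (tumor_diameter <= 0) stop("tumor diameter must be positive")
  dims <- pmax(1L, as.integer(round(extent / dl)))
  rad <- tumor_diameter / 2
  cen <- c(dims[1] * dl / 2, dims[2] * dl / 2, tumor_depth + rad)
  if (tumor_depth < 0 ||
      cen[3] + rad > dims[3] * dl ||
      cen[1] - rad < 0 || cen[1] + rad > dims[1] * dl ||
      cen[2] - rad < 0 || cen[2] + rad > dims[2] * dl)
    stop("tumor sphere does not fit inside the requested extent")
  cx <- (seq_len(dims[1]) - 0.5) * dl
  cy <- (seq_len(dims[2]) - 0.5) * dl
  cz <- (seq_len(dims[3]) - 0.5) * dl
  d2 <- outer(outer((cx - cen[1])^2, (cy - cen[2])^2, `+`), (cz - cen[3])^2, `+`)
  labels <- array(1L, dim = dims)
  labels[d2 <= rad^2] <- 2L
  grid <- new_voxel_grid(dims, dl, labels,
                         list(`1` = background, `2` = tumor))
  grid$tumor_center <- cen
  grid$tumor_radius <- rad
  grid
}

#' Absorber-plane phantom
#'
#' A cover layer of scattering tissue over a strongly absorbing flat slab: the
#' geometry of the depth-wise energy-integration measurement, in which the
#' absorber intercepts essentially all light reaching its depth.
#'
#' @param cover_depth thickness of the cover tissue (m), >= 0 (0 puts the
#'   absorber at the surface — the normalization reference).
#' @param cover,absorber [tissue_properties()] for the two regions.
#' @param dl voxel edge length (m).
#' @param absorber_thickness slab thickness (m).
#' @param lateral_extent lateral size (m).
#' @return A `voxel_grid`; label 1 = cover (absent if `cover_depth` rounds to
#'   0), label 2 = absorber. The absorber's first z index (0-based) is stored
#'   as `$absorber_z0`.
#' @export
build_absorber_plane_phantom <- function(cover_depth,
                                         cover = tissue_preset("chicken_breast_808"),
                                         absorber = tissue_preset("black_agarose"),
                                         dl = 0.25e-3,
                                         absorber_thickness = 2e-3,
                                         lateral_extent = c(12e-3, 12e-3)) {
  if (cover_depth < 0) stop("cover_depth must be non-negative")
  n_cover <- as.integer(round(cover_depth / dl))
  n_abs <- max(1L, as.integer(round(absorber_thickness / dl)))
  nx <- max(1L, as.integer(round(lateral_extent[1] / dl)))
  ny <- max(1L, as.integer(round(lateral_extent[2] / dl)))
  nz <- n_cover + n_abs
  lab_z <- c(rep(1L, n_cover), rep(2L, n_abs))
  labels <- array(rep(lab_z, each = nx * ny), dim = c(nx, ny, nz))
  props <- list(`1` = cover, `2` = absorber)
  if (n_cover == 0) props <- props["2"]
  grid <- new_voxel_grid(c(nx, ny, nz), dl, labels, props)
  grid$absorber_z0 <- n_cover
  grid
}

#' Virtual thermocouple placement
#'
#' @param position 1-based grid index `(i, j, k)`.
#' @param label one of `"tumor_top"`, `"tumor_core"`, `"adjacent_tissue"`,
#'   `"lateral_margin"`, `"custom"`.
#' @param sensor_noise_sd additive temperature-reading noise (K).
#' @return An object of class `sampling_point`.
#' @export
sampling_point <- function(position, label = "custom", sensor_noise_sd = 0) {
  label <- match.arg(label, c("tumor_top", "tumor_core", "adjacent_tissue",
                              "lateral_margin", "custom"))
  stopifnot(length(position) == 3, all(position >= 1), sensor_noise_sd >= 0)
  structure(list(position = as.integer(position), label = label,
                 sensor_noise_sd = sensor_noise_sd),
            class = "sampling_point")
}

#' Standard validation thermocouples for a tumor phantom
#'
#' Mirrors the four-point validation layout: tumor upper surface (within the
#' imaging plane), tumor core, adjacent background tissue below the tumor, and
#' the lateral tumor margin outside the imaging plane.
#'
#' @param grid a tumor phantom from [build_tumor_phantom()].
#' @return A list of four [sampling_point()]s.
#' @export
default_sampling_points <- function(grid) {
  if (is.null(grid$tumor_center)) stop("grid is not a tumor phantom")
  dl <- grid$dl
  ci <- pmin(pmax(1L, as.integer(ceiling(grid$tumor_center / dl))), grid$dims)
  rad_vox <- grid$tumor_radius / dl
  top <- c(ci[1], ci[2], max(1L, as.integer(ceiling((grid$tumor_center[3] - grid$tumor_radius) / dl)) + 1L))
  core <- ci
  below <- c(ci[1], ci[2],
             min(grid$dims[3], as.integer(ceiling((grid$tumor_center[3] + grid$tumor_radius) / dl)) + 3L))
  lateral <- c(ci[1], min(grid$dims[2], ci[2] + as.integer(ceiling(rad_vox)) + 1L), ci[3])
  list(sampling_point(top, "tumor_top"),
       sampling_point(core, "tumor_core"),
       sampling_point(below, "adjacent_tissue"),
       sampling_point(lateral, "lateral_margin"))
}
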