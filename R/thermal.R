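#' Simulation clock
#'
#' @param dt time step (s), > 0.
#' @param n current step index (0-based).
#' @return An object of class `sim_clock`.
#' @export
sim_clock <- function(dt, n = 0L) {
  stopifnot(dt > 0, n >= 0)
  structure(list(dt = dt, n = as.integer(n)), class = "sim_clock")
}

#' Explicit-scheme stability bound
#'
#' Maximum stable time step of the explicit Euler bioheat scheme,
#' `dt <= dl^2 rho cp / (6 kv)`, taken as the minimum over voxels (the most
#' diffusive voxel limits the grid).
#'
#' @param grid a `voxel_grid`.
#' @return Maximum stable `dt` (s).
#' @export
cfl_max_dt <- function(grid) {
  rho_cp <- grid_property(grid, "rho") * grid_property(grid, "cp")
  kv <- grid_property(grid, "kv")
  min(grid$dl^2 * rho_cp / (6 * kv))
}

# Face conductivities (harmonic mean across each voxel face) plus the
# boundary closure folded into a per-voxel loss term. Precomputing this once
# makes repeated stepping cheap and guarantees that the stepping stencil and
# the sparse transition matrix are assembled from identical coefficients.
thermal_stencil <- function(grid, bc = "dirichlet") {
  # bc: one condition for all outer faces, or one per axis (x, y, z)
  bc <- match.arg(bc, c("dirichlet", "adiabatic"), several.ok = TRUE)
  if (length(bc) == 1) bc <- rep(bc, 3)
  if (length(bc) != 3) stop("bc must have length 1 or 3")
  kv <- grid_property(grid, "kv")
  d <- grid$dims
  hmean <- function(a, b) 2 * a * b / (a + b)
  kx <- hmean(kv[-d[1], , , drop = FALSE], kv[-1, , , drop = FALSE])
  ky <- hmean(kv[, -d[2], , drop = FALSE], kv[, -1, , drop = FALSE])
  kz <- hmean(kv[, , -d[3], drop = FALSE], kv[, , -1, drop = FALSE])
  bloss <- array(0, dim = d)
  # ghost voxel at ambient just outside each Dirichlet face
  if (bc[1] == "dirichlet") {
    bloss[1, , ] <- bloss[1, , ] + kv[1, , ]
    bloss[d[1], , ] <- bloss[d[1], , ] + kv[d[1], , ]
  }
  if (bc[2] == "dirichlet") {
    bloss[, 1, ] <- bloss[, 1, ] + kv[, 1, ]
    bloss[, d[2], ] <- bloss[, d[2], ] + kv[, d[2], ]
  }
  if (bc[3] == "dirichlet") {
    bloss[, , 1] <- bloss[, , 1] + kv[, , 1]
    bloss[, , d[3]] <- bloss[, , d[3]] + kv[, , d[3]]
  }
  list(kx = kx, ky = ky, kz = kz, bloss = bloss, bc = bc,
       rho_cp = grid_property(grid, "rho") * grid_property(grid, "cp"),
       dl = grid$dl, dims = d)
}

# div(k grad T) / dl^2 with the ambient offset already removed (operates on
# delta-T relative to ambient; Dirichlet closure pulls towards 0).
apply_laplacian <- function(dT, st) {
  d <- st$dims
  out <- -st$bloss * dT
  fx <- st$kx * (dT[-1, , , drop = FALSE] - dT[-d[1], , , drop = FALSE])
  out[-d[1], , ] <- out[-d[1], , , drop = FALSE] + fx
  out[-1, , ] <- out[-1, , , drop = FALSE] - fx
  fy <- st$ky * (dT[, -1, , drop = FALSE] - dT[, -d[2], , drop = FALSE])
  out[, -d[2], ] <- out[, -d[2], , drop = FALSE] + fy
  out[, -1, ] <- out[, -1, , drop = FALSE] - fy
  fz <- st$kz * (dT[, , -1, drop = FALSE] - dT[, , -d[3], drop = FALSE])
  out[, , -d[3]] <- out[, , -d[3], drop = FALSE] + fz
  out[, , -1] <- out[, , -1, drop = FALSE] - fz
  out / st$dl^2
}

#' One explicit Euler bioheat step
#'
#' Advances the temperature field by one step of the explicit
#' finite-difference scheme
#' `T(n+1) = T(n) + dt * (div(kv grad T)/ (rho cp) + S/(rho cp))`
#' with a 7-point Laplacian. Heterogeneous conductivity uses harmonic-mean
#' face values. Boundary conditions: `"dirichlet"` clamps a ghost layer at
#' `T_ambient` (constant-temperature bath), `"adiabatic"` imposes zero flux.
#'
#' @param T_field numeric array of absolute temperatures (deg C), grid-shaped.
#' @param S a `heat_source_field` (continuous mode, W/m^3) or a grid-shaped
#'   array, or `NULL` for no source.
#' @param grid a `voxel_grid`.
#' @param clock a [sim_clock()]; `clock$dt` must respect [cfl_max_dt()].
#' @param bc `"dirichlet"` or `"adiabatic"`, either one value for all outer
#'   faces or a length-3 vector giving the condition per axis (x, y, z).
#' @param T_ambient ambient/bath temperature for the Dirichlet closure (deg C).
#' @param stencil optional precomputed internal stencil (from repeated runs);
#'   must match `grid` and `bc`.
#' @param enforce_cfl reject `dt` above the stability bound (default). Only
#'   disable to demonstrate instability.
#' @return The advanced temperature array.
#' @export
step_heat <- function(T_field, S, grid, clock, bc = "dirichlet",
                      T_ambient = 36, stencil = NULL, enforce_cfl = TRUE) {
  if (enforce_cfl && clock$dt > cfl_max_dt(grid) * (1 + 1e-12))
    stop(sprintf("dt = %.4g s exceeds the stability bound %.4g s",
                 clock$dt, cfl_max_dt(grid)))
  if (is.null(stencil)) stencil <- thermal_stencil(grid, bc)
  dT <- T_field - T_ambient
  Sarr <- if (is.null(S)) 0 else if (inherits(S, "heat_source_field")) S$S else S
  dT <- dT + clock$dt * (apply_laplacian(dT, stencil) + Sarr) / stencil$rho_cp
  dT + T_ambient
}

#' Run the bioheat solver for many steps
#'
#' @inheritParams step_heat
#' @param n_steps number of steps.
#' @param record list of [sampling_point()]s whose temperatures are recorded
#'   each step, or `NULL`.
#' @param callback optional `function(step, T_field)` called after each step.
#' @return A list with `T_field` (final array), `time` (s) and `trace`
#'   (matrix steps x points, if `record` was given).
#' @export
run_heat <- function(T_field, S, grid, clock, n_steps, bc = "dirichlet",
                     T_ambient = 36, record = NULL, callback = NULL) {
  stencil <- thermal_stencil(grid, bc)
  trace <- if (!is.null(record))
    matrix(NA_real_, nrow = n_steps, ncol = length(record)) else NULL
  for (k in seq_len(n_steps)) {
    T_field <- step_heat(T_field, S, grid, clock, bc, T_ambient, stencil)
    if (!is.null(record))
      trace[k, ] <- vapply(record, function(p)
        T_field[p$position[1], p$position[2], p$position[3]], numeric(1))
    if (!is.null(callback)) callback(k, T_field)
  }
  list(T_field = T_field, time = n_steps * clock$dt, trace = trace)
}

#' Ordered state-space point sets
#'
#' The region-of-interest points (ROIPs), heat-source points (TOPs) and
#' observable points (AOPs) as linear grid indices (column-major, 1-based,
#' strictly increasing — the fixed state ordering). `aops` must be a subset
#' of `tops`, and `tops` of `roips`.
#'
#' @param roips,tops,aops integer linear voxel indices.
#' @param dims grid dimensions the indices refer to.
#' @return An object of class `point_sets` with counts `N`, `W`, `M`.
#' @export
point_sets <- function(roips, tops, aops, dims) {
  roips <- as.integer(roips); tops <- as.integer(tops); aops <- as.integer(aops)
  if (is.unsorted(roips, strictly = TRUE) || is.unsorted(tops, strictly = TRUE) ||
      is.unsorted(aops, strictly = TRUE))
    stop("point sets must be strictly increasing linear indices")
  if (!all(tops %in% roips)) stop("tops must be a subset of roips")
  if (!all(aops %in% tops)) stop("aops must be a subset of tops")
  if (max(roips) > prod(dims) || min(roips) < 1)
    stop("roips outside grid bounds")
  structure(list(roips = roips, tops = tops, aops = aops,
                 dims = as.integer(dims),
                 N = length(roips), W = length(tops), M = length(aops)),
            class = "point_sets")
}

#' @export
print.point_sets <- function(x, ...) {
  cat(sprintf("<point_sets: N = %d ROIPs, W = %d TOPs, M = %d AOPs>\n",
              x$N, x$W, x$M))
  invisible(x)
}

#' State-space transition matrix for the bioheat model
#'
#' Assembles the sparse block transition matrix
#' `F = [[FT, FST], [0, FS]]` over the stacked state
#' `x = [deltaT at ROIPs; S at TOPs]`:
#' `FT` is the explicit Euler heat-conduction propagator (interior rows have
#' center `1 - 6 kv dt/(rho cp dl^2)` and neighbor weight
#' `kv dt/(rho cp dl^2)` for homogeneous tissue; heterogeneous faces use
#' harmonic means, boundary rows fold the chosen closure into the diagonal),
#' `FST` places `dt/(rho cp)` at each heat-source point, and `FS` is the
#' identity (constant-power source). Applying `F` reproduces [step_heat()] on
#' the ROI restriction exactly.
#'
#' ROI points that are a strict subset of the grid are closed like a grid
#' boundary: a missing neighbor is treated per `bc`.
#'
#' @param grid a `voxel_grid`.
#' @param points a [point_sets()] on the same grid.
#' @param clock a [sim_clock()]; `dt` must respect [cfl_max_dt()].
#' @param bc `"dirichlet"` or `"adiabatic"`.
#' @return An object of class `state_space_model` with sparse `F` and the
#'   block index ranges.
#' @export
build_state_space <- function(grid, points, clock, bc = "dirichlet") {
  if (!identical(points$dims, grid$dims))
    stop("point set ordering is inconsistent with the grid")
  if (clock$dt > cfl_max_dt(grid) * (1 + 1e-12))
    stop("dt exceeds the stability bound for this grid")
  st <- thermal_stencil(grid, bc)
  d <- grid$dims
  N <- points$N; W <- points$W
  roi_pos <- integer(prod(d)); roi_pos[points$roips] <- seq_len(N)

  ijk <- arrayInd(points$roips, d)
  rho_cp <- st$rho_cp[points$roips]
  coef <- clock$dt / (rho_cp * grid$dl^2)

  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  diag_val <- rep(1, N) - clock$dt * st$bloss[points$roips] / (rho_cp * grid$dl^2)

  face_k <- function(axis, side, sub) {
    # conductivity of the face between voxel sub and its neighbor on `side`
    arr <- switch(axis, st$kx, st$ky, st$kz)
    s2 <- sub
    if (side < 0) s2[, axis] <- s2[, axis] - 1
    arr[s2]
  }
  for (axis in 1:3) for (side in c(-1, 1)) {
    nb <- ijk
    nb[, axis] <- nb[, axis] + side
    inside <- nb[, axis] >= 1 & nb[, axis] <= d[axis]
    kf <- numeric(N)
    kf[inside] <- face_k(axis, side, ijk[inside, , drop = FALSE])
    nb_lin <- integer(N)
    nb_lin[inside] <- nb[inside, 1] + d[1] * (nb[inside, 2] - 1) +
      d[1] * d[2] * (nb[inside, 3] - 1)
    in_roi <- inside & roi_pos[pmax(nb_lin, 1L)] > 0 & nb_lin >= 1
    # neighbor inside grid but outside ROI: close like a boundary face
    ext <- inside & !in_roi
    if (st$bc[axis] == "dirichlet")
      diag_val[ext] <- diag_val[ext] - coef[ext] * kf[ext]
    diag_val[in_roi] <- diag_val[in_roi] - coef[in_roi] * kf[in_roi]
    rows <- c(rows, which(in_roi))
    cols <- c(cols, roi_pos[nb_lin[in_roi]])
    vals <- c(vals, coef[in_roi] * kf[in_roi])
  }
  rows <- c(rows, seq_len(N)); cols <- c(cols, seq_len(N))
  vals <- c(vals, diag_val)

  # FST: dt/(rho cp) at (ROI row of each TOP, TOP column); FS = I
  top_roi_row <- roi_pos[points$tops]
  rows <- c(rows, top_roi_row, N + seq_len(W))
  cols <- c(cols, N + seq_len(W), N + seq_len(W))
  vals <- c(vals, clock$dt / st$rho_cp[points$tops], rep(1, W))

  Fm <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                             dims = c(N + W, N + W))
  structure(list(F = Fm, points = points, dt = clock$dt, bc = bc,
                 N = N, W = W), class = "state_space_model")
}

#' @export
print.state_space_model <- function(x, ...) {
  cat(sprintf("<state_space_model: N = %d, W = %d, dt = %.4g s, bc = %s, %d nonzeros>\n",
              x$N, x$W, x$dt, x$bc, length(x$F@x)))
  invisible(x)
}
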