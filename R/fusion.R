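#' Kalman filter configuration
#'
#' Process noise `Qkf` (per model step) is diagonal; typical values are
#' 1e-5 to 1e-4 in near-steady conditions and 1e-3 to 1e-2 during a heating
#' transient (in squared state units per step). Measurement noise `R` is the
#' variance of the alpha observations, ideally estimated from static frames
#' via [estimate_R()]. `P_init` sets the initial covariance: small on the
#' temperature block (the run starts at a known bath temperature) and large
#' on the heat-source block (source intensity is the quantity the filter
#' must converge).
#'
#' @param Qkf scalar or length-(N+W) diagonal of process-noise variances, or
#'   a schedule `function(step)` returning either (used to switch between
#'   the transient and steady ranges as the commanded laser power settles).
#' @param R scalar or per-AOP vector of measurement-noise variances, > 0
#'   (floored at 1e-12 to avoid singular updates).
#' @param P_init_dT initial variance of each temperature state (K^2).
#' @param P_init_S initial variance of each source state ((W/m^3)^2, scaled).
#' @return An object of class `kalman_config`.
#' @export
kalman_config <- function(Qkf = 1e-4, R = 1e-4, P_init_dT = 1e-4,
                          P_init_S = 1e6) {
  stopifnot(is.function(Qkf) || all(Qkf >= 0), all(R > 0),
            P_init_dT >= 0, P_init_S >= 0)
  R <- pmax(R, 1e-12)
  structure(list(Qkf = Qkf, R = R, P_init_dT = P_init_dT,
                 P_init_S = P_init_S),
            class = "kalman_config")
}

#' Initialize the filter covariance
#'
#' @param model a `state_space_model`.
#' @param cfg a [kalman_config()].
#' @return An object of class `kalman_state` holding the dense covariance
#'   `P` (updated in place by the predict/update steps) and the last gain.
#' @export
kalman_init <- function(model, cfg) {
  n <- model$N + model$W
  P <- diag(c(rep(cfg$P_init_dT, model$N), rep(cfg$P_init_S, model$W)),
            nrow = n)
  structure(list(P = P, K = NULL), class = "kalman_state")
}

#' Kalman prediction step
#'
#' Propagates state and covariance through the bioheat transition matrix:
#' `x <- F x`, `P <- F P F' + Qkf`.
#'
#' @param x numeric state vector, length N+W.
#' @param model a `state_space_model`.
#' @param ks a `kalman_state`.
#' @param cfg a [kalman_config()].
#' @param input optional known exogenous input added after the transition
#'   (length N+W): deterministic heat deposition outside the source states,
#'   e.g. the sub-threshold part of a simulated heat source.
#' @param step current model step (1-based), used when `cfg$Qkf` is a
#'   schedule function of the step.
#' @return List `(x, ks)`.
#' @export
kalman_predict <- function(x, model, ks, cfg, input = NULL, step = NA) {
  n <- model$N + model$W
  if (length(x) != n || nrow(ks$P) != n)
    stop("state/covariance dimensions do not match the model")
  x <- as.numeric(model$F %*% x)
  if (!is.null(input)) x <- x + input
  # F P F' is symmetric given symmetric P; roundoff asymmetry is removed at
  # the next measurement update, so no per-step symmetrization is needed.
  q <- cfg$Qkf
  if (is.function(q)) {
    if (is.na(step)) stop("a step index is required for a scheduled Qkf")
    q <- q(step)
  }
  if (length(q) == 1) q <- rep(q, n)
  ks$P <- sp_fpft(model$F, ks$P, q)
  list(x = x, ks = ks)
}

#' Kalman measurement update
#'
#' Uses the photoacoustic increments `alpha` directly as the measurement
#' (the observation matrix carries the calibration gain, so `H x` is in
#' alpha units): `x <- x + K (alpha - H x)` with
#' `K = P H' (H P H' + R)^-1`, `P <- (I - K H) P`.
#'
#' @param x state vector.
#' @param ks a `kalman_state`.
#' @param alpha_obs observed increments, length M.
#' @param H an `observation_matrix`.
#' @param cfg a [kalman_config()].
#' @return List `(x, ks, innovation)`.
#' @export
kalman_update <- function(x, ks, alpha_obs, H, cfg) {
  if (length(alpha_obs) != H$M) stop("alpha_obs must have length M")
  Hm <- H$H
  # one nonzero per row (gain * indicator): P H' is a scaled column subset
  nz_per_row <- Matrix::rowSums(Hm != 0)
  if (all(nz_per_row == 1)) {
    ji <- Matrix::summary(Hm)
    ord <- order(ji$i)
    cols <- ji$j[ord]; vals <- ji$x[ord]
    PHt <- sweep(ks$P[, cols, drop = FALSE], 2, vals, "*")
    S <- sweep(PHt[cols, , drop = FALSE], 1, vals, "*")
  } else {
    PHt <- as.matrix(ks$P %*% Matrix::t(Hm))
    S <- as.matrix(Hm %*% PHt)
  }
  rvec <- if (length(cfg$R) == 1) rep(cfg$R, H$M) else cfg$R
  diag(S) <- diag(S) + rvec
  rc <- rcond(S)
  if (!is.finite(rc) || rc < 1e-14)
    stop(sprintf("innovation covariance numerically singular (rcond = %.3g)", rc))
  innov <- as.numeric(alpha_obs - Hm %*% x)
  K <- PHt %*% solve(S)
  x <- x + as.numeric(K %*% innov)
  P <- ks$P - K %*% t(PHt)
  ks$P <- (P + t(P)) / 2
  ks$K <- K
  list(x = x, ks = ks, innovation = innov)
}

#' Measurement-noise variance from static frames
#'
#' Sample variance of the alpha observations over repeated frames acquired
#' in a static, non-heating state — the fluctuation level of the sensor.
#' Zero variances (identical frames) are floored at 1e-12.
#'
#' @param static_alpha matrix (frames x AOPs) of increments.
#' @return Per-AOP variance vector.
#' @export
estimate_R <- function(static_alpha) {
  static_alpha <- as.matrix(static_alpha)
  if (nrow(static_alpha) < 2)
    stop("at least 2 static frames are required to estimate R")
  v <- apply(static_alpha, 2, stats::var)
  if (any(v == 0))
    message("zero-variance channel(s); applying floor 1e-12")
  pmax(v, 1e-12)
}

#' Predict/update fusion loop
#'
#' Runs the Kalman filter over a heating schedule: every model step performs
#' a prediction through the bioheat transition matrix; at steps listed in
#' `frame_steps` the matching row of `alpha_frames` is assimilated.
#' Observation timestamps must be model steps; non-integer frame times are
#' associated with the nearest step with a warning.
#'
#' @param model a `state_space_model` for the fusion ROI.
#' @param H an `observation_matrix` consistent with `model`.
#' @param alpha_frames matrix (n_frames x M) of observed increments.
#' @param frame_steps model-step index (1-based) of each frame.
#' @param x0 initial state (defaults to zeros with `S0` in the source block).
#' @param S0 initial heat-source estimate at TOPs (state units), used when
#'   `x0` is `NULL`.
#' @param cfg a [kalman_config()].
#' @param n_steps total model steps to run.
#' @param record_rows state indices whose trajectories are recorded each step.
#' @param input optional known exogenous input (see [kalman_predict()]).
#' @param record_weights optional matrix (n_points x (N+W)): each row is a
#'   linear functional of the state recorded per step (e.g. interpolation
#'   weights of a virtual thermocouple); overrides `record_rows`.
#' @return List: `trace` (n_steps x length(record_rows)), `x` (final state),
#'   `innovations` (n_frames x M), `P_trace` (trace of P per step),
#'   `ks` (final `kalman_state`).
#' @export
run_fusion <- function(model, H, alpha_frames, frame_steps, x0 = NULL,
                       S0 = NULL, cfg = kalman_config(), n_steps,
                       record_rows = integer(0), input = NULL,
                       record_weights = NULL) {
  n <- model$N + model$W
  if (is.null(x0)) {
    x0 <- numeric(n)
    if (!is.null(S0)) {
      stopifnot(length(S0) == model$W)
      x0[model$N + seq_len(model$W)] <- S0
    }
  }
  if (any(frame_steps != round(frame_steps))) {
    warning("non-integer frame steps; associating with the nearest model step")
    frame_steps <- round(frame_steps)
  }
  frame_of_step <- integer(n_steps)
  frame_of_step[pmin(pmax(frame_steps, 1), n_steps)] <- seq_along(frame_steps)
  ks <- kalman_init(model, cfg)
  x <- x0
  n_rec <- if (!is.null(record_weights)) nrow(record_weights)
           else length(record_rows)
  trace <- matrix(NA_real_, n_steps, n_rec)
  P_trace <- numeric(n_steps)
  innovations <- matrix(NA_real_, nrow(alpha_frames), ncol(alpha_frames))
  for (k in seq_len(n_steps)) {
    st <- kalman_predict(x, model, ks, cfg, input, step = k)
    x <- st$x; ks <- st$ks
    f <- frame_of_step[k]
    if (f > 0) {
      up <- kalman_update(x, ks, alpha_frames[f, ], H, cfg)
      x <- up$x; ks <- up$ks
      innovations[f, ] <- up$innovation
    }
    if (!is.null(record_weights)) trace[k, ] <- as.numeric(record_weights %*% x)
    else if (length(record_rows)) trace[k, ] <- x[record_rows]
    P_trace[k] <- sum(diag(ks$P))
  }
  list(trace = trace, x = x, innovations = innovations,
       P_trace = P_trace, ks = ks)
}
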