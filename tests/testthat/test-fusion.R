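make_scalar_model <- function(f = 0.9, dt = 0.1) {
  # single ROI point, no source states: F = [f]
  Fm <- Matrix::sparseMatrix(i = 1, j = 1, x = f, dims = c(1, 1))
  structure(list(F = Fm, N = 1L, W = 0L, dt = dt, bc = "dirichlet"),
            class = "state_space_model")
}

small_thermal_model <- function() {
  g <- uniform_grid(dims = c(4, 4, 4))
  clock <- sim_clock(0.9 * cfl_max_dt(g))
  n <- prod(g$dims)
  tops <- c(22L, 43L)
  ps <- point_sets(seq_len(n), tops, tops[1], g$dims)
  list(model = build_state_space(g, ps, clock, bc = "adiabatic"), ps = ps)
}

test_that("prediction propagates state and covariance", {
  sm <- small_thermal_model()
  cfg <- kalman_config(Qkf = 0, R = 1e-4, P_init_dT = 0, P_init_S = 0)
  ks <- kalman_init(sm$model, cfg)
  st <- kalman_predict(numeric(sm$ps$N + sm$ps$W), sm$model, ks, cfg)
  expect_true(all(st$x == 0))            # zero state, zero source stays zero
  expect_true(all(st$ks$P == 0))         # Q = 0, P = 0 stays zero
  # trace growth is bounded by trace(Q) for the contractive heat propagator
  cfg2 <- kalman_config(Qkf = 1e-5, R = 1e-4, P_init_dT = 1e-3, P_init_S = 0)
  ks2 <- kalman_init(sm$model, cfg2)
  tr0 <- sum(diag(ks2$P))
  st2 <- kalman_predict(numeric(sm$ps$N + sm$ps$W), sm$model, ks2, cfg2)
  n_states <- sm$ps$N + sm$ps$W
  expect_lte(sum(diag(st2$ks$P)), tr0 + n_states * 1e-5 + 1e-12)
  expect_error(kalman_predict(numeric(3), sm$model, ks, cfg), "dimension")
})

test_that("scalar update matches the hand-computed Kalman formulas", {
  model <- make_scalar_model(f = 0.95)
  cfg <- kalman_config(Qkf = 1e-3, R = 4e-4, P_init_dT = 0.5, P_init_S = 0)
  ps <- point_sets(1, 1, 1, c(1, 1, 1))
  # observation matrix with gain h over the single state plus its source slot
  h <- 0.0354
  H <- build_H(ps, calibration_model(h, 36))
  # build_H appends the source column; strip to scalar system by W = 0 model
  Hs <- structure(list(H = Matrix::sparseMatrix(i = 1, j = 1, x = h,
                                                dims = c(1, 1)),
                       M = 1L, N = 1L, W = 0L, gain = h),
                  class = "observation_matrix")
  x <- 2; P <- 0.5
  ks <- structure(list(P = matrix(P, 1, 1), K = NULL), class = "kalman_state")
  z <- 0.1
  for (i in 1:5) {
    ref <- scalar_kalman_step(x, P, 0.95, 1e-3, h, 4e-4, z)
    st <- kalman_predict(x, model, ks, cfg)
    up <- kalman_update(st$x, st$ks, z, Hs, cfg)
    expect_equal(up$x, ref$x, tolerance = 1e-12)
    expect_equal(up$ks$P[1, 1], ref$P, tolerance = 1e-12)
    x <- up$x; ks <- up$ks; P <- ref$P
  }
})

test_that("update obeys the R -> 0 and R -> Inf limits", {
  sm <- small_thermal_model()
  n <- sm$ps$N + sm$ps$W
  H <- build_H(sm$ps, calibration_model(0.0354, 36))
  x0 <- withr::with_seed(5, stats::rnorm(n))
  alpha <- 0.25
  # huge R: the model is trusted, state barely moves
  cfg_inf <- kalman_config(Qkf = 0, R = 1e12, P_init_dT = 1, P_init_S = 1)
  ks <- kalman_init(sm$model, cfg_inf)
  up <- kalman_update(x0, ks, alpha, H, cfg_inf)
  expect_lt(max(abs(up$x - x0)), 1e-9)
  # tiny R: the observed component is matched exactly (alpha / gain)
  cfg_0 <- kalman_config(Qkf = 0, R = 1e-14, P_init_dT = 1, P_init_S = 1)
  ks0 <- kalman_init(sm$model, cfg_0)
  up0 <- kalman_update(x0, ks0, alpha, H, cfg_0)
  aop_state <- match(sm$ps$aops, sm$ps$roips)
  expect_equal(up0$x[aop_state], alpha / 0.0354, tolerance = 1e-4)
})

test_that("measurement-noise estimation recovers the injected variance", {
  # alpha jitter of sd 0.01 -> R about 1e-4 at 100 frames
  a <- withr::with_seed(31, matrix(stats::rnorm(100 * 3, 0, 0.01), 100, 3))
  Rhat <- estimate_R(a)
  expect_true(all(abs(Rhat / 1e-4 - 1) < 0.5))
  # independence from the mean level (alpha is already relative)
  Rhat2 <- estimate_R(a + 5)
  expect_equal(Rhat2, Rhat, tolerance = 1e-10)
  expect_error(estimate_R(a[1, , drop = FALSE]), "2 static frames")
  expect_message(Rf <- estimate_R(matrix(1, 5, 2)), "floor")
  expect_equal(unname(Rf), rep(1e-12, 2))
})

test_that("covariance stays symmetric positive semidefinite over 1000 steps", {
  sm <- small_thermal_model()
  n <- sm$ps$N + sm$ps$W
  H <- build_H(sm$ps, calibration_model(0.0354, 36))
  cfg <- kalman_config(Qkf = 1e-4, R = 1e-4, P_init_dT = 1e-2, P_init_S = 1)
  ks <- kalman_init(sm$model, cfg)
  x <- numeric(n)
  alpha <- withr::with_seed(7, stats::rnorm(1000, 0, 0.01))
  for (k in seq_len(1000)) {
    st <- kalman_predict(x, sm$model, ks, cfg)
    x <- st$x; ks <- st$ks
    if (k %% 5 == 0) {
      up <- kalman_update(x, ks, alpha[k], H, cfg)
      x <- up$x; ks <- up$ks
    }
  }
  expect_equal(ks$P, t(ks$P), tolerance = 1e-10)
  ev <- eigen(ks$P, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * sum(diag(ks$P)))
})

test_that("innovations are white on a well-specified model", {
  # scalar stationary system observed every step
  model <- make_scalar_model(f = 0.9)
  h <- 1
  Hs <- structure(list(H = Matrix::sparseMatrix(i = 1, j = 1, x = h,
                                                dims = c(1, 1)),
                       M = 1L, N = 1L, W = 0L, gain = h),
                  class = "observation_matrix")
  q <- 1e-4; r <- 1e-4
  cfg <- kalman_config(Qkf = q, R = r, P_init_dT = 1e-2, P_init_S = 0)
  withr::with_seed(13, {
    x_true <- 0; x <- 0
    ks <- structure(list(P = matrix(1e-2, 1, 1), K = NULL),
                    class = "kalman_state")
    innov <- numeric(200)
    for (k in 1:200) {
      x_true <- 0.9 * x_true + stats::rnorm(1, 0, sqrt(q))
      z <- h * x_true + stats::rnorm(1, 0, sqrt(r))
      st <- kalman_predict(x, model, ks, cfg)
      up <- kalman_update(st$x, st$ks, z, Hs, cfg)
      innov[k] <- up$innovation
      x <- up$x; ks <- up$ks
    }
    rho1 <- stats::cor(innov[-1], innov[-200])
    expect_lt(abs(rho1), 0.2)
  })
})

test_that("run_fusion associates off-step observations with a warning", {
  sm <- small_thermal_model()
  H <- build_H(sm$ps, calibration_model(0.0354, 36))
  cfg <- kalman_config(Qkf = 1e-5, R = 1e-4)
  expect_warning(
    run_fusion(sm$model, H, matrix(0.01, 2, 1), frame_steps = c(2.4, 7.6),
               cfg = cfg, n_steps = 10, record_rows = 1L),
    "nearest")
})
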