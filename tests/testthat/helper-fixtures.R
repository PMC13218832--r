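# Small fixtures shared across test files. Everything is built in code.

absorbing_props <- function(mu_a = 100, mu_s = 0, g = 0) {
  modify_props(tissue_preset("chicken_breast_808"),
               mu_a = mu_a, mu_s = mu_s, g = g)
}

tiny_tumor_grid <- function(dl = 0.5e-3, extent = c(8e-3, 8e-3, 8e-3),
                            diameter = 3e-3, depth = 2e-3, ...) {
  build_tumor_phantom(diameter, depth, dl = dl, extent = extent, ...)
}

# uniform single-region grid with convenient thermal numbers
uniform_grid <- function(dims = c(6, 6, 6), dl = 0.5e-3,
                         props = tissue_properties(
                           mu_a = 10, mu_s = 1000, g = 0.9, rho = 1000,
                           cp = 4000, kv = 0.5, vs = 1500)) {
  build_layered_phantom(dims[3] * dl, list(props), dl,
                        lateral_extent = dims[1:2] * dl)
}

# analytic 1-D scalar Kalman filter step for cross-checking
scalar_kalman_step <- function(x, P, f, q, h, r, z) {
  xp <- f * x
  Pp <- f * P * f + q
  K <- Pp * h / (h * Pp * h + r)
  list(x = xp + K * (z - h * xp), P = (1 - K * h) * Pp, K = K)
}
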