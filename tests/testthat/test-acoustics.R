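test_that("Grueneisen model validates positivity over the operating range", {
  expect_error(grueneisen_model(A = 0.1, B = -0.01), "positive")
  gm <- grueneisen_model(A = -0.0686, B = 0.00885)
  expect_gt(gm$A + gm$B * 30, 0)
  # composite gain of the shipped preset reproduces the calibrated value
  gmp <- grueneisen_of(tissue_preset("chicken_breast_808"))
  expect_equal(calibrate_gain(gmp, 36), 0.0354, tolerance = 1e-12)
})

test_that("initial pressure is Gamma(T) * mu_a * Phi", {
  g <- tiny_tumor_grid()
  phi <- array(1000, g$dims)
  ff <- structure(list(phi = phi, dims = g$dims, dl = g$dl,
                       beam = beam_spec("flattop", 1e-3, 1, "pulsed")),
                  class = "fluence_field")
  gm <- grueneisen_of(g$props[["1"]])
  # temperature-independent when B = 0
  gm0 <- grueneisen_model(A = 0.2, B = 0)
  p36 <- initial_pressure(ff, g, 36, gm0)
  p40 <- initial_pressure(ff, g, 40, gm0)
  expect_equal(p36$p0, p40$p0)
  # voxelwise ratio between two uniform temperatures
  pa <- initial_pressure(ff, g, 36, gm)
  pb <- initial_pressure(ff, g, 37, gm)
  mask <- pa$p0 > 0
  expect_equal(unique(round(pb$p0[mask] / pa$p0[mask], 12)),
               round((gm$A + 37 * gm$B) / (gm$A + 36 * gm$B), 12))
  # zero where mu_a is zero
  clear <- modify_props(tissue_preset("chicken_breast_808"), mu_a = 0)
  g2 <- build_layered_phantom(c(2e-3, 2e-3), list(clear, tissue_preset("black_agarose")),
                              dl = 0.5e-3, lateral_extent = c(4e-3, 4e-3))
  S2 <- heat_source(g2, structure(list(phi = array(1, g2$dims), dims = g2$dims,
                                       dl = g2$dl, beam = ff$beam),
                                  class = "fluence_field"))
  p2 <- initial_pressure(S2, g2, 36, gm)
  expect_true(all(p2$p0[g2$labels == 1L] == 0))
})

test_that("traces carry time-of-flight, linearity and array-shift structure", {
  g <- build_layered_phantom(10e-3, list(tissue_preset("chicken_breast_808")),
                             dl = 0.25e-3, lateral_extent = c(10e-3, 10e-3))
  arr <- transducer_array(n_elements = 32, standoff = 5e-3)
  vs <- 1540
  pf <- structure(list(p0 = array(0, g$dims), dims = g$dims, dl = g$dl),
                  class = "pressure_field")
  pf$p0[20, 20, 24] <- 1
  rf <- forward_project(pf, arr, vs)
  # support of the central element's trace is centred at r/vs
  e <- 16
  pe <- arr$positions[e, ]
  vox <- c(((20 - 0.5) * g$dl - 10e-3 / 2), ((20 - 0.5) * g$dl - 10e-3 / 2),
           (24 - 0.5) * g$dl)
  r <- sqrt(sum((vox - pe)^2))
  tt <- (which(abs(rf$samples[, e]) > 0.5 * max(abs(rf$samples[, e]))) - 1) *
    rf$dt_sample
  expect_lt(abs(mean(tt) - r / vs), 3 * g$dl / vs)
  # doubling p0 doubles every sample
  pf2 <- pf; pf2$p0 <- 2 * pf$p0
  rf2 <- forward_project(pf2, arr, vs)
  expect_equal(rf2$samples, 2 * rf$samples, tolerance = 1e-12)
  # moving the array farther by delta shifts supports by delta/vs
  arr2 <- transducer_array(n_elements = 32, standoff = 7e-3)
  rf3 <- forward_project(pf, arr2, vs)
  t1 <- which.max(abs(rf$samples[, e]))
  t2 <- which.max(abs(rf3$samples[, e]))
  shift_expect <- (sqrt(sum((vox - arr2$positions[e, ])^2)) - r) / vs
  expect_lt(abs((t2 - t1) * rf$dt_sample - shift_expect), 3 * g$dl / vs)
})

test_that("a uniform sphere source radiates an N-shaped bipolar pulse", {
  g <- build_tumor_phantom(4e-3, 3e-3, dl = 0.25e-3,
                           extent = c(12e-3, 12e-3, 10e-3))
  pf <- structure(list(p0 = array(0, g$dims), dims = g$dims, dl = g$dl),
                  class = "pressure_field")
  pf$p0[g$labels == 2L] <- 1
  arr <- transducer_array(n_elements = 1, standoff = 6e-3)
  vs <- 1540
  rf <- forward_project(pf, arr, vs)
  s <- rf$samples[, 1]
  pk <- which.max(s); tr <- which.min(s)
  expect_lt(pk, tr)  # compression then rarefaction
  expect_gt(max(s), 0); expect_lt(min(s), 0)
  # zero crossing at the shell through the sphere center
  r_center <- sqrt(sum((c(0, 0, g$tumor_center[3]) - arr$positions[1, ])^2))
  crossing <- pk + which(s[pk:tr] <= 0)[1] - 1
  expect_lt(abs((crossing - 1) * rf$dt_sample - r_center / vs),
            4 * g$dl / vs)
})

test_that("back-projection localizes sources and preserves amplitude ratios", {
  g <- build_layered_phantom(12e-3, list(tissue_preset("chicken_breast_808")),
                             dl = 0.25e-3, lateral_extent = c(12e-3, 12e-3))
  vs <- 1540
  pf <- structure(list(p0 = array(0, g$dims), dims = g$dims, dl = g$dl),
                  class = "pressure_field")
  pf$p0[24, 24, 20] <- 1
  arr <- transducer_array(standoff = 5e-3)
  rec <- ubp_reconstruct(forward_project(pf, arr, vs), arr, vs, g, plane_y = 24)
  pk <- which(abs(rec$p0) == max(abs(rec$p0)), arr.ind = TRUE)
  expect_lte(max(abs(pk - c(24, 20))), 1)

  # zero RF -> zero image
  rf0 <- forward_project(structure(list(p0 = array(0, g$dims), dims = g$dims,
                                        dl = g$dl), class = "pressure_field"),
                         arr, vs)
  rec0 <- ubp_reconstruct(rf0, arr, vs, g, plane_y = 24)
  expect_true(all(rec0$p0 == 0))

  # 2:1 two-point amplitude ratio under a full-view ring
  pf$p0[, , ] <- 0
  pf$p0[18, 24, 18] <- 2
  pf$p0[30, 24, 26] <- 1
  ring <- ring_array(radius = 12e-3, center = c(0, 6e-3), n_elements = 128)
  rec2 <- ubp_reconstruct(forward_project(pf, ring, vs), ring, vs, g,
                          plane_y = 24)
  a1 <- max(abs(rec2$p0[14:22, 14:22]))
  a2 <- max(abs(rec2$p0[26:34, 22:30]))
  expect_lt(abs(a1 / a2 - 2) / 2, 0.05)
})

test_that("limited-view reconstruction concentrates on the surface facing the probe", {
  g <- build_tumor_phantom(5e-3, 3.2e-3, dl = 0.25e-3,
                           extent = c(16e-3, 16e-3, 12e-3))
  beam <- beam_spec("gaussian", 3e-3, 1e-3, mode = "pulsed")
  mc <- mc_fluence(g, beam, n_photons = 1e5, seed = 11)
  gm <- grueneisen_of(g$props[["1"]])
  p0 <- initial_pressure(heat_source(g, mc$fluence), g, 36, gm)
  arr <- transducer_array(standoff = 1e-3)
  yc <- g$dims[2] %/% 2
  rec <- ubp_reconstruct(forward_project(p0, arr, 1540, bandlimit = TRUE),
                         arr, 1540, g, plane_y = yc)
  w <- abs(rec$p0)^2
  zc <- sum(w * matrix(voxel_centers(g, 3), g$dims[1], g$dims[3],
                       byrow = TRUE)) / sum(w)
  expect_lt(zc, g$tumor_center[3])  # energy centroid above the sphere center
})

test_that("deconvolution modes behave as documented", {
  g <- build_layered_phantom(10e-3, list(tissue_preset("chicken_breast_808")),
                             dl = 0.25e-3, lateral_extent = c(8e-3, 8e-3))
  pf <- structure(list(p0 = array(0, g$dims), dims = g$dims, dl = g$dl),
                  class = "pressure_field")
  pf$p0[16, 16, 20] <- 1
  arr <- transducer_array(n_elements = 8, standoff = 5e-3)
  rf_full <- forward_project(pf, arr, 1540, bandlimit = FALSE)
  rf <- forward_project(pf, arr, 1540, bandlimit = TRUE)
  expect_identical(estimate_deconvolution(rf, arr, "identity"), rf)
  eq <- estimate_deconvolution(rf, arr, "equalize")
  # equalization restores the pre-band-limit in-band spectral shape: the
  # ratio to the unlimited trace is flatter after equalization
  spec_of <- function(x) abs(stats::fft(x))
  f <- (seq_len(nrow(rf$samples)) - 1) / (nrow(rf$samples) * rf$dt_sample)
  band <- which(f > 4.5e6 & f < 6.5e6)
  ref <- spec_of(rf_full$samples[, 4])[band]
  flatness <- function(s) {
    ratio <- s[band] / ref
    stats::sd(ratio) / mean(ratio)
  }
  expect_lt(flatness(spec_of(eq$samples[, 4])),
            flatness(spec_of(rf$samples[, 4])))
  expect_warning(estimate_deconvolution(eq, arr, "equalize"), "idempotent")
})
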