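test_that("absorption-only depth profile follows Beer-Lambert", {
  g <- build_layered_phantom(8e-3, list(absorbing_props(mu_a = 300)),
                             dl = 0.5e-3, lateral_extent = c(6e-3, 6e-3))
  beam <- beam_spec("flattop", 0.2e-3, 1, mode = "continuous")
  mc <- mc_fluence(g, beam, n_photons = 1e5, seed = 42)
  absorbed <- apply(heat_source(g, mc$fluence)$S, 3, sum) * g$dl^3
  z <- voxel_centers(g, 3)
  # exact per-slab absorption of a collimated beam
  expected <- exp(-300 * (z - g$dl / 2)) - exp(-300 * (z + g$dl / 2))
  first <- which(z < 3 / 300)  # first three mean free paths
  expect_lt(max(abs(absorbed[first] / expected[first] - 1)), 0.02)
})

test_that("energy bookkeeping: fractions sum to one", {
  g <- build_absorber_plane_phantom(2e-3, dl = 0.5e-3,
                                    lateral_extent = c(8e-3, 8e-3))
  beam <- beam_spec("gaussian", 3e-3, 1e-3, mode = "pulsed")
  mc <- mc_fluence(g, beam, n_photons = 5e4, seed = 7)
  total <- mc$absorbed_fraction + mc$escaped_fraction +
    mc$transmitted_fraction + mc$lost_fraction
  expect_lt(abs(total - 1), 0.01)
  # absorbed energy equals sum(mu_a * phi * V) by construction; check against
  # the beam energy bookkeeping
  S <- heat_source(g, mc$fluence)
  expect_equal(sum(S$S) * g$dl^3,
               mc$absorbed_fraction * beam$power_or_energy,
               tolerance = 1e-12)
})

test_that("transparent and non-absorbing media behave correctly", {
  clear <- modify_props(tissue_preset("chicken_breast_808"), mu_a = 0, mu_s = 0)
  g <- build_layered_phantom(4e-3, list(clear), dl = 0.5e-3,
                             lateral_extent = c(6e-3, 6e-3))
  beam <- beam_spec("flattop", 1e-3, 1, mode = "continuous")
  mc <- mc_fluence(g, beam, n_photons = 1e4, seed = 3)
  expect_equal(mc$absorbed_fraction, 0)
  expect_equal(mc$transmitted_fraction, 1)

  scat <- modify_props(tissue_preset("chicken_breast_808"), mu_a = 0)
  g2 <- build_layered_phantom(4e-3, list(scat), dl = 0.5e-3,
                              lateral_extent = c(6e-3, 6e-3))
  mc2 <- mc_fluence(g2, beam, n_photons = 1e4, seed = 3)
  expect_equal(mc2$absorbed_fraction, 0)
  expect_gt(max(mc2$fluence$phi), 0)  # track-length fluence still defined
})

test_that("same seed gives bit-identical fluence, different seed differs", {
  g <- build_absorber_plane_phantom(2e-3, dl = 0.5e-3,
                                    lateral_extent = c(6e-3, 6e-3))
  beam <- beam_spec("gaussian", 3e-3, 1e-3, mode = "pulsed")
  a <- mc_fluence(g, beam, n_photons = 2e4, seed = 11)
  b <- mc_fluence(g, beam, n_photons = 2e4, seed = 11)
  c <- mc_fluence(g, beam, n_photons = 2e4, seed = 12)
  expect_identical(a$fluence$phi, b$fluence$phi)
  expect_false(identical(a$fluence$phi, c$fluence$phi))
})

test_that("fluence is linear in beam power for both solvers", {
  g <- build_absorber_plane_phantom(2e-3, dl = 0.5e-3,
                                    lateral_extent = c(6e-3, 6e-3))
  b1 <- beam_spec("gaussian", 3e-3, 1, mode = "continuous")
  b2 <- beam_spec("gaussian", 3e-3, 3, mode = "continuous")
  m1 <- mc_fluence(g, b1, n_photons = 2e4, seed = 5)
  m2 <- mc_fluence(g, b2, n_photons = 2e4, seed = 5)
  expect_equal(3 * m1$fluence$phi, m2$fluence$phi, tolerance = 1e-12)
  d1 <- diffusion_fluence(g, b1)
  d2 <- diffusion_fluence(g, b2)
  expect_equal(3 * d1$phi, d2$phi, tolerance = 1e-8)
  # scale_fluence reuses one solution for both illumination modes
  expect_equal(scale_fluence(m1$fluence, 3)$phi, m2$fluence$phi,
               tolerance = 1e-12)
})

test_that("MC standard error shrinks like 1/sqrt(n_photons)", {
  g <- build_absorber_plane_phantom(1e-3, dl = 0.5e-3,
                                    lateral_extent = c(4e-3, 4e-3))
  beam <- beam_spec("gaussian", 2e-3, 1e-3, mode = "pulsed")
  en <- function(n, seeds) vapply(seeds, function(s)
    absorber_plane_energy(mc_fluence(g, beam, n_photons = n, seed = s), g),
    numeric(1))
  s1 <- stats::sd(en(2000, 1:16))
  s2 <- stats::sd(en(8000, 101:116))
  # quadrupling the photons should roughly halve the spread; the bound is
  # generous because each sd is itself estimated from 16 replicates
  expect_lt(s2 / s1, 0.75)
})

test_that("diffusion solution matches the point-source Green's function", {
  # short diffusion length relative to the domain keeps the Dirichlet
  # boundary out of the fitted window
  props <- tissue_properties(mu_a = 50, mu_s = 20000, g = 0.9, rho = 1000,
                             cp = 4000, kv = 0.5, vs = 1500)
  g <- build_layered_phantom(16e-3, list(props), dl = 0.4e-3,
                             lateral_extent = c(16e-3, 16e-3))
  src <- array(0, g$dims)
  cen <- (g$dims + 1) / 2
  src[cen[1], cen[2], cen[3]] <- 1 / g$dl^3
  ff <- diffusion_fluence(g, source = src)
  mu_eff <- sqrt(3 * 50 * (50 + 2000))
  # radial log-slope along the x axis, away from source and boundary
  ix <- (cen[1] + 4):(cen[1] + 11)
  r <- (ix - cen[1]) * g$dl
  phi_r <- ff$phi[ix, cen[2], cen[3]]
  slope <- stats::coef(stats::lm(log(phi_r * r) ~ r))[2]
  expect_lt(abs(-slope / mu_eff - 1), 0.05)
})

test_that("diffusion agrees with Monte Carlo in a scattering slab", {
  g <- build_layered_phantom(8e-3, list(tissue_preset("chicken_breast_808")),
                             dl = 0.5e-3, lateral_extent = c(12e-3, 12e-3))
  beam <- beam_spec("gaussian", 3e-3, 1, mode = "continuous")
  mc <- mc_fluence(g, beam, n_photons = 2e5, seed = 9)
  df <- diffusion_fluence(g, beam)
  # depth profiles beyond one transport mean free path
  ltr <- 1 / (10 + 600)
  zi <- which(voxel_centers(g, 3) > ltr)
  pm <- apply(mc$fluence$phi, 3, sum)[zi]
  pd <- apply(df$phi, 3, sum)[zi]
  expect_gt(stats::cor(pm, pd), 0.95)
})

test_that("heat source is the pointwise product mu_a * phi", {
  g <- build_absorber_plane_phantom(1e-3, dl = 0.5e-3,
                                    lateral_extent = c(4e-3, 4e-3))
  phi <- array(1000, g$dims)
  ff <- structure(list(phi = phi, dims = g$dims, dl = g$dl,
                       beam = beam_spec("flattop", 1e-3, 1, "continuous")),
                  class = "fluence_field")
  S <- heat_source(g, ff)
  mu_a <- grid_property(g, "mu_a")
  expect_equal(S$S, mu_a * 1000)
  expect_true(all(S$S[mu_a == 0] == 0))
  # mismatched grid rejected
  g2 <- build_absorber_plane_phantom(2e-3, dl = 0.5e-3,
                                     lateral_extent = c(4e-3, 4e-3))
  expect_error(heat_source(g2, ff), "match")
})

test_that("depth energy integral is 1 at depth zero and decays", {
  beam <- beam_spec("gaussian", 3e-3, 1e-3, mode = "pulsed")
  g0 <- build_absorber_plane_phantom(0, dl = 0.5e-3,
                                     lateral_extent = c(8e-3, 8e-3))
  ref <- absorber_plane_energy(mc_fluence(g0, beam, 5e4, seed = 1), g0)
  expect_equal(depth_energy_integral(mc_fluence(g0, beam, 5e4, seed = 1),
                                     g0, ref), 1)
  g3 <- build_absorber_plane_phantom(3e-3, dl = 0.5e-3,
                                     lateral_extent = c(8e-3, 8e-3))
  rel3 <- depth_energy_integral(mc_fluence(g3, beam, 5e4, seed = 2), g3, ref)
  expect_gt(rel3, 0); expect_lt(rel3, 1)
  g5 <- build_absorber_plane_phantom(5e-3, dl = 0.5e-3,
                                     lateral_extent = c(8e-3, 8e-3))
  rel5 <- depth_energy_integral(mc_fluence(g5, beam, 5e4, seed = 3), g5, ref)
  expect_lt(rel5, rel3)
  # no absorber region -> rejected
  g_plain <- build_layered_phantom(4e-3, list(tissue_preset("chicken_breast_808")),
                                   dl = 0.5e-3)
  mc <- mc_fluence(g_plain, beam, 1e4, seed = 4)
  expect_error(absorber_plane_energy(mc, g_plain), "absorber")
})
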