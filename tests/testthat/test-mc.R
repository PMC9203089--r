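test_that("photon weight is conserved to 1e-6 and runs are bit-reproducible", {
  mp <- mc_default_map()
  expect_true(all(abs(colSums(mp$tallies) - 1) < 1e-6))
  expect_true(all(mp$values >= 0))
  mp2 <- simulate_reflectance(build_default_skin(),
                              adapter_geometry(edge_offset = 0),
                              spectral_grid(c(474, 554, 635)),
                              n_photons = 2e4, seed = 7)
  expect_identical(mp$values, mp2$values)
  expect_identical(mp$tallies, mp2$tallies)
})

test_that("a lossless semi-infinite medium returns all launched weight", {
  m <- layered_skin(list(skin_layer("med", Inf, 0, 2, g = 0, n = 1)))
  geo <- adapter_geometry(spot_radius = 0.5, edge_offset = 0,
                          acceptance_half_angle = 89, incidence_angle = 0)
  mp <- simulate_reflectance(m, geo, spectral_grid(550), n_photons = 5e4,
                             seed = 9, max_steps = 1e4)
  expect_equal(unname(mp$tallies["reflected", 1]), 1, tolerance = 1e-9)
  expect_equal(unname(mp$tallies["absorbed", 1]), 0, tolerance = 1e-12)
})

test_that("azimuthally averaged reflectance decays with radius beyond the beam", {
  m <- layered_skin(list(skin_layer("med", Inf, 0.01, 10, g = 0.9, n = 1)))
  geo <- adapter_geometry(spot_radius = 0.1, edge_offset = 0,
                          acceptance_half_angle = 89, incidence_angle = 0)
  mp <- memo("mc_oracle_map",
             simulate_reflectance(m, geo, spectral_grid(550),
                                  n_photons = 2e5, seed = 3))
  pr <- biliphone:::radial_profile(mp)
  sel <- pr$r_mid > 0.5 & pr$r_mid < 9
  p <- pr$reflectance[sel]
  smooth <- stats::filter(p, rep(1 / 3, 3))
  smooth <- smooth[!is.na(smooth)]
  expect_true(all(diff(smooth) < 0))
})

test_that("MC radial profile agrees with the diffusion oracle at low absorption", {
  m <- layered_skin(list(skin_layer("med", Inf, 0.01, 10, g = 0.9, n = 1)))
  geo <- adapter_geometry(spot_radius = 0.1, edge_offset = 0,
                          acceptance_half_angle = 89, incidence_angle = 0)
  mp <- memo("mc_oracle_map",
             simulate_reflectance(m, geo, spectral_grid(550),
                                  n_photons = 2e5, seed = 3))
  pr <- biliphone:::radial_profile(mp)
  sel <- pr$r_mid >= 2 & pr$r_mid <= 6
  oracle <- as.numeric(diffusion_reflectance(m, pr$r_mid[sel], 550))
  expect_true(all(abs(pr$reflectance[sel] / oracle - 1) < 0.15))
})

test_that("reducing the edge offset never decreases collected weight", {
  skin <- build_default_skin()
  grid <- spectral_grid(c(474, 554, 635))
  map0 <- mc_default_map()
  map16 <- memo("mc_offset16_map",
                simulate_reflectance(skin, adapter_geometry(edge_offset = 1.6),
                                     grid, n_photons = 2e4, seed = 7))
  tot0 <- apply(map0$values, 3, sum)
  tot16 <- apply(map16$values, 3, sum)
  expect_true(all(tot0 > tot16))
})

test_that("channel totals order blue < green < red for pigmented skin", {
  ch <- integrate_channels(mc_default_map())
  expect_lt(ch$totals["blue"], ch$totals["green"])
  expect_lt(ch$totals["green"], ch$totals["red"])
})

test_that("invalid simulation inputs are rejected", {
  skin <- build_default_skin()
  geo <- adapter_geometry()
  expect_error(simulate_reflectance(skin, geo, spectral_grid(550),
                                    n_photons = 0), "invalid-parameter")
})
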