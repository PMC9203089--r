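# assemble a reflectance_map by hand so channel integration can be tested
# against known spectral content
fake_map <- function(values, wavelengths) {
  structure(list(values = values, wavelengths = wavelengths, bin_mm = 0.25,
                 radial = matrix(0, 4, length(wavelengths)),
                 radial_bin_mm = 0.25,
                 tallies = matrix(0, 4, length(wavelengths)),
                 geometry = adapter_geometry(), n_photons = 1, seed = 1),
            class = "reflectance_map")
}

test_that("a one-point band returns the input map unchanged", {
  v <- array(runif(4 * 5), dim = c(4, 5, 1))
  mp <- fake_map(v, 474)
  blue_only <- channel_bank(data.frame(name = "blue", center = 474,
                                       halfwidth = 10))
  ch <- integrate_channels(mp, blue_only)[["maps"]]
  expect_equal(ch$blue, v[, , 1])
})

test_that("a spectrally constant map integrates to the constant in every channel", {
  wl <- seq(400, 700, 10)
  v <- array(0.5, dim = c(3, 3, length(wl)))
  ch <- integrate_channels(fake_map(v, wl))
  expect_equal(unname(ch$totals), rep(0.5 * 9, 3))
})

test_that("in-band averaging uses uniform weights over in-band samples only", {
  wl <- c(464, 474, 484, 554, 635)
  v <- array(0, dim = c(1, 1, 5))
  v[1, 1, ] <- c(1, 2, 9, 5, 7)
  ch <- integrate_channels(fake_map(v, wl))
  expect_equal(unname(ch$totals["blue"]), 4)   # mean(1, 2, 9)
  expect_equal(unname(ch$totals["green"]), 5)
  expect_equal(unname(ch$totals["red"]), 7)
})

test_that("bands outside the grid raise an unsupported-band error", {
  mp <- fake_map(array(1, dim = c(2, 2, 1)), 550)
  expect_error(integrate_channels(mp), "unsupported-band")
})

test_that("identical geometries compare with exactly zero percent increase", {
  skin <- build_default_skin()
  g <- adapter_geometry(edge_offset = 0)
  cmp <- compare_geometries(skin, g, g, grid = spectral_grid(c(474, 554, 635)),
                            n_photons = 5e3, seed = 5)
  expect_equal(unname(cmp$percent_increase), rep(0, 3))
  expect_equal(unname(cmp$percent_increase_relative), rep(0, 3))
  # both increase measures are plain arithmetic on the stored totals
  expect_equal(cmp$percent_increase, 100 * (cmp$totals_B - cmp$totals_A))
  expect_equal(cmp$percent_increase_relative,
               100 * (cmp$totals_B - cmp$totals_A) / cmp$totals_A)
})

test_that("geometries differing beyond edge_offset are rejected", {
  skin <- build_default_skin()
  expect_error(compare_geometries(skin, adapter_geometry(spot_radius = 1),
                                  adapter_geometry(spot_radius = 2)),
               "edge_offset")
})
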