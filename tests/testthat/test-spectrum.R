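dip <- extended_dipole(0.34, 0.7)

test_that("stick spectra separate polarization channels and wall weights", {
  s_par <- make_sites(rbind(c(0, 0, 0), c(0, 0, 1.2)),
                      rbind(c(0, 0, 1), c(0, 0, 1)))
  sticks <- stick_spectrum(diagonalize(build_hamiltonian(s_par, e0 = 0,
                                                         dipole = dip)))
  expect_equal(sum(sticks$perpendicular), 0, tolerance = 1e-12)
  expect_equal(sum(sticks$parallel > 1e-12), 1)  # one bright stick

  s_perp <- make_sites(rbind(c(0, 0, 0), c(0, 0, 1.2)),
                       rbind(c(1, 0, 0), c(1, 0, 0)))
  sticks_p <- stick_spectrum(diagonalize(build_hamiltonian(s_perp, e0 = 0,
                                                           dipole = dip)))
  expect_equal(sum(sticks_p$parallel), 0, tolerance = 1e-12)

  iw <- small_tube(length = 4, radius = 3.2, wall = "IW")
  ow <- small_tube(length = 4, radius = 5.7, wall = "OW")
  dw <- assemble_double_wall(iw, ow)
  sticks_dw <- stick_spectrum(diagonalize(build_hamiltonian(dw)))
  expect_equal(sticks_dw$weight_IW + sticks_dw$weight_OW,
               rep(1, nrow(sticks_dw)), tolerance = 1e-9)
})

test_that("broadening preserves area and reproduces lineshape widths", {
  sticks <- tibble::tibble(energy = 17000, parallel = 2, perpendicular = 0,
                           total = 2, weight_IW = 1)
  for (shape in c("lorentzian", "gaussian")) {
    sp <- broaden_spectrum(sticks, fwhm = 120, lineshape = shape,
                           n_grid = 6000)
    pk <- peak_metrics(sp, "parallel")
    expect_equal(pk$peaks$energy[1], 17000, tolerance = 0.5)
    expect_equal(pk$peaks$fwhm[1], 120, tolerance = 2)
    # trapezoid quadrature oracle for area conservation; the Lorentzian's
    # power-law wings need a wide grid to hold the total weight
    margin <- if (shape == "gaussian") 10 else 500
    wide <- seq(17000 - margin * 120, 17000 + margin * 120, length.out = 40000)
    spw <- suppressWarnings(broaden_spectrum(sticks, fwhm = 120,
                                             lineshape = shape, grid = wide))
    area <- sum(diff(spw$energy) * (head(spw$total, -1) + tail(spw$total, -1)) / 2)
    expect_equal(area, 2, tolerance = 0.001)
  }

  # linearity: two equal sticks double the area
  st2 <- tibble::tibble(energy = c(16900, 17100), parallel = c(2, 2),
                        perpendicular = 0, total = parallel, weight_IW = 1)
  sp1 <- broaden_spectrum(sticks, fwhm = 120, lineshape = "gaussian", n_grid = 6000)
  sp2 <- broaden_spectrum(st2, fwhm = 120, lineshape = "gaussian", n_grid = 6000)
  a1 <- sum(diff(sp1$energy) * (head(sp1$total, -1) + tail(sp1$total, -1)) / 2)
  a2 <- sum(diff(sp2$energy) * (head(sp2$total, -1) + tail(sp2$total, -1)) / 2)
  expect_equal(a2 / a1, 2, tolerance = 1e-3)

  expect_error(broaden_spectrum(sticks, fwhm = 0), "> 0")
  expect_warning(broaden_spectrum(sticks, fwhm = 120,
                                  grid = seq(16950, 17050, 1)),
                 "grid")
})

test_that("polarization closure holds pointwise through broadening", {
  tube <- small_tube(length = 6)
  sp <- broaden_spectrum(stick_spectrum(diagonalize(build_hamiltonian(tube))),
                         fwhm = 150)
  expect_equal(sp$total, sp$parallel + sp$perpendicular, tolerance = 1e-12)
  expect_true(all(sp$total >= 0))
  expect_equal(sp$wavelength, 1e7 / sp$energy)
  # single wall: the wall channel is the total
  expect_equal(sp$IW, sp$total, tolerance = 1e-9)
})

test_that("ensemble averaging reduces to the single-structure spectrum", {
  tube <- small_tube(length = 5)
  ens0 <- generate_ensemble(tube, NULL, NULL, n_snapshots = 1, seed = 1)
  sp0 <- ensemble_average_spectrum(ens0, fwhm = 150)
  single <- broaden_spectrum(stick_spectrum(diagonalize(build_hamiltonian(tube))),
                             fwhm = 150, grid = sp0$energy)
  expect_equal(sp0$total, single$total, tolerance = 1e-10)

  ens3 <- generate_ensemble(tube, NULL, NULL, n_snapshots = 3, seed = 1)
  sp3 <- ensemble_average_spectrum(ens3, fwhm = 150)
  expect_equal(sp3$total, sp0$total, tolerance = 1e-10)
})

test_that("disorder broadens the ensemble-averaged J-band", {
  tube <- small_tube(length = 5)
  grid <- NULL
  sp0 <- ensemble_average_spectrum(
    generate_ensemble(tube, NULL, NULL, 1, seed = 1), fwhm = 100)
  dd <- diagonal_disorder(mean = c(IW = 0), sigma = c(IW = 250))
  spd <- ensemble_average_spectrum(
    generate_ensemble(tube, NULL, dd, 12, seed = 1), fwhm = 100,
    grid = sp0$energy)
  f0 <- peak_metrics(sp0, "parallel")$peaks$fwhm[1]
  fd <- peak_metrics(spd, "parallel")$peaks$fwhm[1]
  expect_gt(fd, f0)
})

test_that("peak metrics find constructed peaks, splittings and ratios", {
  grid <- seq(16000, 18500, 0.5)
  lor <- function(e0, w) (w / (2 * pi)) / ((grid - e0)^2 + (w / 2)^2)
  lor2 <- lor
  spectrum <- tibble::tibble(
    energy = grid, wavelength = 1e7 / grid,
    parallel = 2 * lor(17000, 100) + 1 * lor(17300, 100),
    perpendicular = 0, total = parallel)
  pm <- peak_metrics(spectrum, "parallel")
  expect_equal(nrow(pm$peaks), 2)
  expect_equal(pm$splitting, 300, tolerance = 0.5)

  # area ratio on a well-separated pair (overlapping wings bias windowed
  # band areas, so the ratio check uses narrow, distant lines)
  sep <- tibble::tibble(
    energy = grid, wavelength = 1e7 / grid,
    parallel = 2 * lor2(17000, 60) + 1 * lor2(17800, 60),
    perpendicular = 0, total = parallel)
  pms <- peak_metrics(sep, "parallel")
  expect_equal(pms$splitting, 800, tolerance = 0.5)
  expect_equal(pms$ratio, 2, tolerance = 0.05)

  single <- tibble::tibble(energy = grid, wavelength = 1e7 / grid,
                           parallel = lor(17000, 100), perpendicular = 0,
                           total = parallel)
  ps <- peak_metrics(single, "parallel")
  expect_true(is.na(ps$splitting))

  flat <- tibble::tibble(energy = grid, wavelength = 1e7 / grid,
                         parallel = 0, perpendicular = 0, total = 0)
  expect_warning(pf <- peak_metrics(flat, "parallel"), "No peaks")
  expect_equal(nrow(pf$peaks), 0)
})

test_that("spectrum TSV writer emits all channels", {
  tube <- small_tube(length = 4)
  sp <- broaden_spectrum(stick_spectrum(diagonalize(build_hamiltonian(tube))),
                         fwhm = 150)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum_tsv(sp, f, normalize = "max")
  back <- read.table(f, header = TRUE, sep = "\t", check.names = FALSE)
  expect_named(back, c("energy_cm-1", "wavelength_nm", "total", "parallel",
                       "perpendicular", "IW"))
  expect_equal(max(back$total), 1)
})
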