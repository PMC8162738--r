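test_that("pair maps bin distances and axis-symmetric angles", {
  two <- make_sites(rbind(c(0, 0, 0), c(1, 0, 0)),
                    rbind(c(0, 0, 1), c(0, 0, 1)))
  pm <- pair_angle_distance_map(two, r_max = 3, per_wall = FALSE)
  expect_equal(nrow(pm), 1)
  expect_equal(pm$r, 1.025)          # centre of the 0.05 nm bin holding 1.0
  expect_equal(pm$phi, 1)            # centre of the first 2-degree bin
  expect_equal(pm$density, 1)

  # antiparallel dipoles count as parallel under the axis convention
  anti <- make_sites(rbind(c(0, 0, 0), c(1, 0, 0)),
                     rbind(c(0, 0, 1), c(0, 0, -1)))
  pma <- pair_angle_distance_map(anti, r_max = 3, per_wall = FALSE)
  expect_equal(pma$phi, 1)

  far <- make_sites(rbind(c(0, 0, 0), c(9, 0, 0)),
                    rbind(c(0, 0, 1), c(0, 0, 1)))
  expect_warning(pmf <- pair_angle_distance_map(far, r_max = 3), "empty")
  expect_equal(nrow(pmf), 0)
})

test_that("pair maps are invariant to site order and rigid motions", {
  tube <- small_tube(length = 5)
  pm <- pair_angle_distance_map(tube, r_max = 2.5)
  perm <- tube[sample(nrow(tube)), ]
  pm_perm <- pair_angle_distance_map(perm, r_max = 2.5)
  expect_equal(dplyr::arrange(tibble::as_tibble(pm), wall, r, phi),
               dplyr::arrange(tibble::as_tibble(pm_perm), wall, r, phi))

  th <- 0.6
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- tube
  xyz <- as.matrix(tube[, c("x", "y", "z")]) %*% t(R)
  dxyz <- as.matrix(tube[, c("dx", "dy", "dz")]) %*% t(R)
  rot$x <- xyz[, 1] + 5; rot$y <- xyz[, 2]; rot$z <- xyz[, 3] - 2
  rot$dx <- dxyz[, 1]; rot$dy <- dxyz[, 2]; rot$dz <- dxyz[, 3]
  pm_rot <- pair_angle_distance_map(rot, r_max = 2.5)
  expect_equal(dplyr::arrange(tibble::as_tibble(pm_rot), wall, r, phi)$density,
               dplyr::arrange(tibble::as_tibble(pm), wall, r, phi)$density,
               tolerance = 1e-12)

  # bins sum to one whenever pairs exist
  sums <- as.numeric(tapply(pm$density, pm$wall, sum))
  expect_equal(sums, rep(1, length(sums)), tolerance = 1e-9)
})

test_that("jitter smears the pair map but keeps the ideal peak neighbourhood", {
  tube <- small_tube(length = 6)
  pm_ideal <- pair_angle_distance_map(tube, r_max = 2, per_wall = FALSE)
  jit <- jitter_structure(tube, structural_jitter(0.05, 5), seed = 21)
  pm_jit <- pair_angle_distance_map(jit, r_max = 2, per_wall = FALSE)
  expect_gt(nrow(pm_jit), nrow(pm_ideal))  # smeared over more bins
  top <- pm_ideal[which.max(pm_ideal$density), ]
  near <- pm_jit[abs(pm_jit$r - top$r) <= 0.1 & abs(pm_jit$phi - top$phi) <= 6, ]
  expect_gt(sum(near$density), 0.5 * top$density * 0.2)
})

test_that("rolling-angle scans are deterministic tables", {
  cell <- default_unit_cell()
  one <- scan_rolling_angle(cell, 30, tube_length = 8)
  expect_equal(nrow(one), 1)
  rep2 <- scan_rolling_angle(cell, c(30, 30), tube_length = 8)
  expect_equal(rep2[1, ], rep2[2, ])
  expect_error(scan_rolling_angle(cell, numeric(0)), "at least one")
})

test_that("outer-wall expansion opens a monotone density splitting", {
  cell <- default_unit_cell()
  sc <- scan_density_splitting(cell, c(1, 1.016, 1.032), tube_length = 10,
                               target = NULL)
  expect_equal(sc$splitting[1], 0, tolerance = 12)  # near-zero at equal cells
  expect_true(all(diff(sc$splitting) > 0))

  sc_t <- scan_density_splitting(cell, c(1, 1.016, 1.032), tube_length = 10,
                                 target = mean(range(sc$splitting)))
  expect_true(is.finite(attr(sc_t, "factor_for_target")))
  expect_error(scan_density_splitting(cell, c(1, 1.016), tube_length = 10,
                                      target = 1e5), "not bracketed")
})

test_that("coupling-sum histograms contrast ideal and disordered packings", {
  tube <- small_tube(length = 5)
  dip <- extended_dipole(0.34, 0.7)
  ens <- generate_ensemble(tube, structural_jitter(), NULL,
                           n_snapshots = 8, seed = 13)
  res <- coupling_sum_histogram(ens, dipole = dip)
  s <- res$summary
  expect_gt(s$sd[s$kind == "disordered"], s$sd[s$kind == "ideal"])
  # structural disorder weakens the mean (less negative)
  expect_gt(s$mean[s$kind == "disordered"], s$mean[s$kind == "ideal"])

  # dimer sanity: without disorder every pooled value is the dimer coupling
  dimer <- make_sites(rbind(c(0, 0, 0), c(0, 0, 1.2)),
                      rbind(c(0, 0, 1), c(0, 0, 1)))
  ens0 <- generate_ensemble(dimer, NULL, NULL, n_snapshots = 3, seed = 1)
  r0 <- coupling_sum_histogram(ens0, dipole = dip)
  J <- coupling_extended_dipole(c(0, 0, 0), c(0, 0, 1.2),
                                c(0, 0, 1), c(0, 0, 1), dip)
  expect_true(all(abs(r0$values$coupling_sum - J) < 1e-9))
  expect_equal(r0$summary$sd, c(0, 0), tolerance = 1e-9)
})

test_that("autoplot methods return ggplot objects", {
  tube <- small_tube(length = 4)
  sp <- broaden_spectrum(stick_spectrum(diagonalize(build_hamiltonian(tube))),
                         fwhm = 150)
  expect_s3_class(ggplot2::autoplot(sp), "ggplot")
  expect_s3_class(ggplot2::autoplot(pair_angle_distance_map(tube)), "ggplot")
  expect_s3_class(ggplot2::autoplot(tube), "ggplot")
})
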