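test_that("Hamiltonian assembly: diagonal shifts, symmetry, cutoff", {
  dip <- extended_dipole(1, 0.7)
  s2 <- make_sites(rbind(c(0, 0, 0), c(1, 0, 0)),
                   rbind(c(0, 0, 1), c(0, 0, 1)))
  J <- coupling_extended_dipole(c(0, 0, 0), c(1, 0, 0),
                                c(0, 0, 1), c(0, 0, 1), dip)
  ham <- build_hamiltonian(s2, e0 = 0, dipole = dip)
  expect_equal(ham$H, rbind(c(0, J), c(J, 0)))

  ham_s <- build_hamiltonian(s2, e0 = 100, shifts = c(10, -10), dipole = dip)
  expect_equal(diag(ham_s$H), c(110, 90))
  expect_error(build_hamiltonian(s2, shifts = c(1, NaN), dipole = dip),
               "finite")
  expect_error(build_hamiltonian(s2, shifts = 1, dipole = dip), "per site")

  # zero cutoff leaves a diagonal matrix
  ham0 <- build_hamiltonian(s2, e0 = 5, dipole = dip, cutoff = 0)
  expect_equal(ham0$H, diag(c(5, 5)))

  st <- random_structure(60, seed = 9)
  H <- build_hamiltonian(st, dipole = extended_dipole(0.34, 0.7))$H
  expect_identical(H, t(H))
  expect_equal(sum(H[upper.tri(H)] != 0), choose(60, 2))
})

test_that("diagonalization reproduces dimer and ring closed forms", {
  # dimer: eigenvalues -|J|, +|J|
  J <- -600
  ham <- exciton_hamiltonian(rbind(c(0, J), c(J, 0)))
  st <- diagonalize(ham)
  expect_equal(st$energies, c(-abs(J), abs(J)))

  # 3-site ring with equal couplings: {2J, -J, -J}
  J <- 150
  H3 <- matrix(J, 3, 3); diag(H3) <- 0
  st3 <- diagonalize(exciton_hamiltonian(H3))
  expect_equal(st3$energies, c(-J, -J, 2 * J))

  # trace conservation
  expect_equal(sum(st3$energies), 0, tolerance = 1e-10)

  expect_error(diagonalize(exciton_hamiltonian(rbind(c(0, 1), c(2, 0)))),
               "symmetric")
})

test_that("random symmetric matrices match an independent decomposition", {
  set.seed(31)
  A <- matrix(stats::rnorm(50 * 50), 50)
  H <- (A + t(A)) / 2 * 100
  st <- diagonalize(exciton_hamiltonian(H))
  # independent route: singular values of the positive-shifted matrix
  shift <- max(abs(H)) * 60
  sv <- svd(H + diag(shift, 50))$d
  expect_equal(st$energies, sort(sv - shift), tolerance = 1e-9)
  # orthonormality
  G <- crossprod(st$coefficients)
  expect_equal(G, diag(50), tolerance = 1e-10)
})

test_that("collective dipoles obey the oscillator-strength sum rule", {
  dip <- extended_dipole(0.34, 0.7)
  st <- random_structure(200, seed = 17)
  states <- diagonalize(build_hamiltonian(st, dipole = dip))
  expect_equal(sum(states$osc_strength), 200 * dip$mu^2, tolerance = 1e-8)
  expect_equal(sum(states$energies), sum(diag(build_hamiltonian(st, dipole = dip)$H)),
               tolerance = 1e-8)

  # parallel dimer: the symmetric state carries all the strength
  s2 <- make_sites(rbind(c(0, 0, 0), c(0, 0, 1.2)),
                   rbind(c(0, 0, 1), c(0, 0, 1)))
  d2 <- diagonalize(build_hamiltonian(s2, e0 = 0, dipole = dip))
  expect_equal(sort(d2$osc_strength), c(0, 2 * dip$mu^2), tolerance = 1e-10)
  # J-type pair: the bright state is the lower one
  expect_gt(d2$osc_strength[1], d2$osc_strength[2])

  # single site
  s1 <- make_sites(c(0, 0, 0), c(1, 0, 0))
  d1 <- diagonalize(build_hamiltonian(s1, e0 = 0, dipole = dip))
  expect_equal(collective_dipoles(d1)[1, ], c(dip$mu, 0, 0))
})

test_that("per-site coupling sums match hand-countable cases", {
  J <- -321
  ham <- exciton_hamiltonian(rbind(c(0, J), c(J, 0)))
  expect_equal(coupling_sum_per_site(ham)$coupling_sum, c(J, J))

  H3 <- matrix(J, 3, 3); diag(H3) <- 7   # diagonal must be ignored
  expect_equal(coupling_sum_per_site(exciton_hamiltonian(H3))$coupling_sum,
               rep(2 * J, 3))
})

test_that("bandwidth and delocalization follow their definitions", {
  J <- -500
  d <- diagonalize(exciton_hamiltonian(rbind(c(0, J), c(J, 0))))
  expect_equal(exciton_bandwidth(d), 2 * abs(J))
  expect_equal(exciton_bandwidth(diagonalize(exciton_hamiltonian(diag(c(1, 1, 1))))), 0)

  # zero-disorder ring of parallel dipoles: the bright state is uniform and
  # delocalized over all N sites
  n <- 24
  phi <- 2 * pi * (seq_len(n) - 1) / n
  ring <- make_sites(cbind(3 * cos(phi), 3 * sin(phi), 0),
                     cbind(rep(0, n), rep(0, n), rep(1, n)))
  states <- diagonalize(build_hamiltonian(ring, e0 = 0,
                                          dipole = extended_dipole(0.34, 0.7)))
  bright <- which.max(states$osc_strength)
  expect_equal(states$ipr_size[bright], n, tolerance = 1e-6)
  dl <- delocalization_size(states, window = range(states$energies))
  expect_equal(dl$weighted_size, n, tolerance = 1e-4)

  # a fully localized state has size 1
  iso <- diagonalize(exciton_hamiltonian(diag(c(0, 1000))))
  expect_equal(iso$ipr_size, c(1, 1))
})

test_that("tidy and glance summarise states consistently", {
  tube <- small_tube(length = 5)
  states <- diagonalize(build_hamiltonian(tube))
  td <- tidy(states)
  expect_equal(nrow(td), nrow(tube))
  expect_equal(td$osc_strength, td$osc_parallel + td$osc_perpendicular,
               tolerance = 1e-10)
  expect_equal(td$weight_IW, rep(1, nrow(td)), tolerance = 1e-9)
  gl <- glance(states)
  expect_equal(gl$bandwidth, exciton_bandwidth(states))
  expect_equal(gl$n_sites, nrow(tube))
})
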