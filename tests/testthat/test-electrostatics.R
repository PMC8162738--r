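test_that("Coulomb interaction energy matches the closed form", {
  k <- k_coulomb_cm1_nm()
  expect_equal(coulomb_interaction_energy(c(0, 0, 0), 1, c(1, 0, 0), 1), k)
  expect_equal(coulomb_interaction_energy(c(0, 0, 0), 1, c(1, 0, 0), -1), -k)
  expect_equal(coulomb_interaction_energy(rbind(c(0, 0, 0), c(0, 1, 0)),
                                          c(0, 0), c(1, 0, 0), 1), 0)
  expect_error(coulomb_interaction_energy(c(0, 0, 0), 1, c(0.05, 0, 0), 1),
               "guard")

  # rigid rotation + translation invariance
  set.seed(5)
  A <- matrix(stats::runif(9, 0, 2), 3); qa <- stats::rnorm(3)
  B <- matrix(stats::runif(9, 3, 5), 3); qb <- stats::rnorm(3)
  e1 <- coulomb_interaction_energy(A, qa, B, qb)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  shift <- c(1, -2, 3)
  e2 <- coulomb_interaction_energy(sweep(A %*% t(R), 2, shift, "+"), qa,
                                   sweep(B %*% t(R), 2, shift, "+"), qb)
  expect_equal(e2, e1, tolerance = 1e-9)
})

test_that("cluster carving keeps whole molecules inside the radius", {
  central <- synthetic_chromophore(molecule = 1L)
  near <- synthetic_water(c(2.9, 0, 0), molecule = 2L)
  far <- synthetic_water(c(3.1, 0, 0), molecule = 3L)
  snap <- dplyr::bind_rows(central, near, far)
  cl <- carve_cluster(snap, central = 1, radius = 3.0)
  expect_setequal(unique(cl$environment$molecule), 2L)
  expect_false(1L %in% cl$environment$molecule)
  expect_error(carve_cluster(snap, central = 99), "not present")

  # empty environment gives a zero shift
  lone <- carve_cluster(central, central = 1, radius = 3)
  expect_equal(solvent_shift(lone$central, lone$environment)$shift, 0)
})

test_that("induced dipoles solve the self-consistent field equations", {
  # one site in the field of one unit charge at 1 nm: p = alpha E, u = -k alpha E^2 / 2
  alpha <- 0.0015
  sol <- solve_induced_dipoles(rbind(c(0, 0, 1)), alpha, rbind(c(0, 0, 0)), 1)
  expect_equal(sol$p[1, ], c(0, 0, alpha))
  expect_equal(sol$energy, -0.5 * k_coulomb_cm1_nm() * alpha)
  expect_true(sol$converged)

  # zero polarizability: zero induction energy
  sol0 <- solve_induced_dipoles(rbind(c(0, 0, 1)), 0, rbind(c(0, 0, 0)), 1)
  expect_equal(sol0$energy, 0)

  # two coupled sites against the direct 6x6 linear solve
  pol <- rbind(c(0, 0, 1), c(0.4, 0.2, 1.6))
  alpha <- c(0.0012, 0.0018)
  perm <- rbind(c(0, 0, 0), c(1, 1, 0.5)); q <- c(0.8, -0.5)
  sol2 <- solve_induced_dipoles(pol, alpha, perm, q, tol = 1e-13)
  E0 <- excitube:::charge_field(perm, q, pol)
  rvec <- pol[1, ] - pol[2, ]; r <- sqrt(sum(rvec^2)); rhat <- rvec / r
  T12 <- (3 * outer(rhat, rhat) - diag(3)) / r^3
  A <- diag(6)
  A[1:3, 4:6] <- -alpha[1] * T12
  A[4:6, 1:3] <- -alpha[2] * T12
  p_direct <- solve(A, c(alpha[1] * E0[1, ], alpha[2] * E0[2, ]))
  expect_lt(max(abs(as.vector(t(sol2$p)) - p_direct)), 1e-10)

  # damped iterations reach the same fixed point from a different damping
  sol2b <- solve_induced_dipoles(pol, alpha, perm, q, damping = 0.3,
                                 tol = 1e-13)
  expect_equal(sol2$p, sol2b$p, tolerance = 1e-9)
  expect_equal(sol2$energy, sol2b$energy, tolerance = 1e-8)

  # inside the catastrophe radius the self-consistent equations have no
  # stable solution: the guard warns, then the iteration reports failure
  expect_warning(
    expect_error(
      solve_induced_dipoles(rbind(c(0, 0, 0), c(0, 0, 0.12)),
                            c(0.0015, 0.0015), rbind(c(2, 0, 0)), 1),
      "converge"),
    "catastrophe")
})

test_that("solvent shift is the excited-ground interaction-energy difference", {
  # identical state charges: zero shift by definition
  atoms <- tibble::tibble(name = "A", x = 0, y = 0, z = 0,
                          q_ground = 0.3, q_excited = 0.3, alpha = 0)
  same <- charge_model(atoms)
  env <- synthetic_water(c(1.5, 0, 0), molecule = 2L)
  expect_equal(solvent_shift(same, env)$shift, 0)

  # +-0.1 e dumbbell whose excited state flips sign, one external charge:
  # shift = -2 x ground electrostatic energy (hand-summed Coulomb terms)
  k <- k_coulomb_cm1_nm()
  dumb <- charge_model(tibble::tibble(
    name = c("P", "M"), x = c(0, 0), y = c(0, 0), z = c(0.35, -0.35),
    q_ground = c(0.1, -0.1), q_excited = c(-0.1, 0.1), alpha = c(0, 0)))
  ext <- charge_model(tibble::tibble(name = "Q", x = 2, y = 0, z = 0,
                                     q_ground = 0.5, q_excited = 0.5,
                                     alpha = 0), molecule = 2L)
  e_g <- k * (0.1 * 0.5 / sqrt(4 + 0.35^2) - 0.1 * 0.5 / sqrt(4 + 0.35^2))
  res <- solvent_shift(dumb, ext)
  expect_equal(res$shift, -2 * res$e_ground, tolerance = 1e-10)
  expect_equal(res$e_ground, e_g, tolerance = 1e-10)

  # off-axis external charge: nonzero energies, still shift = -2 E_g
  ext2 <- charge_model(tibble::tibble(name = "Q", x = 1.2, y = 0.3, z = 0.9,
                                      q_ground = 0.5, q_excited = 0.5,
                                      alpha = 0), molecule = 2L)
  res2 <- solvent_shift(dumb, ext2)
  expect_gt(abs(res2$e_ground), 0)
  expect_equal(res2$shift, -2 * res2$e_ground, tolerance = 1e-10)
})

test_that("pure electrostatic shifts are additive over environment subsets", {
  central <- synthetic_chromophore(alpha = 0)
  w1 <- synthetic_water(c(1.6, 0, 0), molecule = 2L)
  w1$alpha <- 0
  ion <- charge_model(tibble::tibble(name = "NA+", x = 0, y = -1.8, z = 0.4,
                                     q_ground = 1, q_excited = 1, alpha = 0),
                      molecule = 3L, source = "ion")
  env <- dplyr::bind_rows(w1, ion)
  full <- solvent_shift(central, env, polarizable = FALSE)$shift
  water_only <- solvent_shift(central, env, sources = "water",
                              polarizable = FALSE)$shift
  ion_only <- solvent_shift(central, env, sources = "ion",
                            polarizable = FALSE)$shift
  expect_equal(full, water_only + ion_only, tolerance = 1e-10)
})

test_that("shift statistics recover Gaussian parameters per wall", {
  set.seed(12)
  shifts <- tibble::tibble(
    shift = c(stats::rnorm(1e4, 350, 213), stats::rnorm(1e4, 350, 231)),
    wall = rep(c("IW", "OW"), each = 1e4))
  st <- shift_statistics(shifts)
  expect_equal(st$mean[st$wall == "IW"], 350, tolerance = 5 / 350 * 350)
  expect_lt(abs(st$mean[st$wall == "IW"] - 350), 5)
  expect_lt(abs(st$sigma[st$wall == "IW"] - 213), 4)
  expect_lt(abs(st$sigma[st$wall == "OW"] - 231), 4)

  const <- tibble::tibble(shift = rep(42, 50), wall = "IW")
  stc <- shift_statistics(const)
  expect_equal(stc$sigma, 0)
  expect_error(shift_statistics(tibble::tibble(shift = 1:5, wall = "IW")),
               "at least")
})

test_that("the synthetic solvated cluster feeds the full shift pipeline", {
  snap <- synthetic_solvated_cluster(n_water = 25, n_ions = 2, seed = 3)
  cl <- carve_cluster(snap, central = 1, radius = 3)
  res <- solvent_shift(cl$central, cl$environment)
  expect_true(is.finite(res$shift))
  # induction always stabilizes each state
  expect_true(all(res$components$induction <= 0))
  # reproducible under the same seed
  snap2 <- synthetic_solvated_cluster(n_water = 25, n_ions = 2, seed = 3)
  expect_identical(as.data.frame(snap), as.data.frame(snap2))
})
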