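# Synthetic stand-ins for the quantum-chemically derived C8S3 atomic charge
# model, which is not redistributed with the package.  The generators below
# produce physically plausible inputs for exercising and testing the
# microelectrostatics machinery; they are calibration fixtures, not the
# published charge sets.

#' Synthetic chromophore charge model
#'
#' A linear polymethine-bridge-like chromophore: `n_atoms` sites spaced
#' along an axis, with alternating ground-state partial charges and an
#' excited state that shifts charge from one end of the bridge to the other
#' (a crude but characteristic pi-pi* redistribution).  Totals of the ground
#' and excited sets are equal by construction.
#'
#' @param n_atoms Number of atoms along the bridge (>= 2).
#' @param length Bridge length, nm.
#' @param centre Length-3 centre position, nm.
#' @param axis Length-3 direction of the bridge (normalized internally).
#' @param dq Magnitude of the ground-state charge alternation, e.
#' @param dq_excited Magnitude of the end-to-end charge transfer upon
#'   excitation, e.
#' @param alpha Per-atom polarizability volume, nm^3.
#' @param molecule,source Passed to [charge_model()].
#' @return A `charge_model`.
#' @export
synthetic_chromophore <- function(n_atoms = 7, length = 0.7,
                                  centre = c(0, 0, 0), axis = c(0, 0, 1),
                                  dq = 0.15, dq_excited = 0.1,
                                  alpha = 0.0012, molecule = 1L,
                                  source = "aggregate") {
  n_atoms <- as.integer(n_atoms)
  if (n_atoms < 2L) abort("`n_atoms` must be >= 2.")
  axis <- axis / sqrt(sum(axis^2))
  t <- seq(-0.5, 0.5, length.out = n_atoms) * length
  pos <- outer(t, axis) + matrix(centre, n_atoms, 3, byrow = TRUE)
  q_g <- dq * (-1)^(seq_len(n_atoms))
  q_g <- q_g - mean(q_g)                       # neutral chromophore
  # excitation moves dq_excited from the tail half to the head half
  w <- t / (max(t) - min(t))                   # -0.5 .. 0.5 along the bridge
  q_e <- q_g + dq_excited * (w / sum(w[w > 0]))
  charge_model(
    tibble(name = paste0("C", seq_len(n_atoms)),
           x = pos[, 1], y = pos[, 2], z = pos[, 3],
           q_ground = q_g, q_excited = q_e, alpha = alpha),
    molecule = molecule, source = source
  )
}

#' Synthetic three-site water model
#'
#' Rigid three-point water (O and two H) with SPC-like partial charges and a
#' molecular polarizability placed on the oxygen.  Ground and excited sets
#' are identical (the solvent is never excited).
#'
#' @param centre Oxygen position, nm.
#' @param rng_angles Optional length-2 numeric (polar, azimuth in radians)
#'   orienting the molecule; random orientation requires drawing these
#'   outside and passing them in.
#' @param molecule Molecule id.
#' @return A `charge_model` with `source = "water"`.
#' @export
synthetic_water <- function(centre, rng_angles = c(0, 0), molecule = 1L) {
  doh <- 0.09572; ang <- deg2rad(104.52)
  h1 <- c(sin(ang / 2), 0, cos(ang / 2)) * doh
  h2 <- c(-sin(ang / 2), 0, cos(ang / 2)) * doh
  rot <- rotation_zy(rng_angles[1], rng_angles[2])
  h1 <- as.numeric(rot %*% h1); h2 <- as.numeric(rot %*% h2)
  q <- c(-0.82, 0.41, 0.41)
  charge_model(
    tibble(name = c("OW", "HW1", "HW2"),
           x = centre[1] + c(0, h1[1], h2[1]),
           y = centre[2] + c(0, h1[2], h2[2]),
           z = centre[3] + c(0, h1[3], h2[3]),
           q_ground = q, q_excited = q,
           alpha = c(0.00145, 0, 0)),
    molecule = molecule, source = "water"
  )
}

rotation_zy <- function(a, b) {
  Rz <- rbind(c(cos(b), -sin(b), 0), c(sin(b), cos(b), 0), c(0, 0, 1))
  Ry <- rbind(c(cos(a), 0, sin(a)), c(0, 1, 0), c(-sin(a), 0, cos(a)))
  Rz %*% Ry
}

#' Synthetic solvated cluster around a central chromophore
#'
#' Builds a central synthetic chromophore surrounded by a shell of water
#' molecules and monovalent counterions placed uniformly at random between
#' `r_min` and `radius`, emulating the carved clusters used for
#' microelectrostatic solvent-shift calculations.
#'
#' @param n_water,n_ions Number of solvent molecules / Na+-like ions.
#' @param radius Cluster radius, nm.
#' @param r_min Exclusion radius around the central molecule, nm.
#' @param seed Integer seed.
#' @param ion_alpha Ion polarizability volume, nm^3.
#' @return A single tibble containing the central molecule (`molecule == 1`)
#'   plus the environment molecules; feed to [carve_cluster()] /
#'   [solvent_shift()].
#' @export
synthetic_solvated_cluster <- function(n_water = 40, n_ions = 2, radius = 3,
                                       r_min = 0.45, seed = 1,
                                       ion_alpha = 0.00018) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  central <- synthetic_chromophore(molecule = 1L)
  placed <- matrix(numeric(0), 0, 3)
  shell_point <- function() {
    # uniform in the shell, rejecting overlaps with already-placed molecules
    repeat {
      p <- runif(3, -radius, radius)
      r <- sqrt(sum(p^2))
      if (r < r_min || r > radius) next
      if (nrow(placed) && min(sqrt(rowSums(sweep(placed, 2, p)^2))) < 0.28) next
      placed <<- rbind(placed, p)
      return(p)
    }
  }
  mols <- list(central)
  id <- 1L
  for (w in seq_len(n_water)) {
    id <- id + 1L
    mols[[length(mols) + 1L]] <-
      synthetic_water(shell_point(), rng_angles = runif(2, 0, 2 * pi),
                      molecule = id)
  }
  for (i in seq_len(n_ions)) {
    id <- id + 1L
    p <- shell_point()
    mols[[length(mols) + 1L]] <- charge_model(
      tibble(name = "NA+", x = p[1], y = p[2], z = p[3],
             q_ground = 1, q_excited = 1, alpha = ion_alpha),
      molecule = id, source = "ion"
    )
  }
  bind_rows(mols)
}
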