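#' Atomic point-charge model of a molecule
#'
#' A classical description for microelectrostatics: atoms carry positions,
#' ground- and excited-state point charges, and isotropic polarizability
#' volumes.  Ground and excited charge sets must carry the same total
#' molecular charge (the excitation moves charge around, it does not ionize).
#'
#' @param atoms A data frame with columns `name`, `x`, `y`, `z` (nm),
#'   `q_ground`, `q_excited` (e), `alpha` (nm^3, >= 0).
#' @param molecule Optional molecule id label.
#' @param source Source tag (`"aggregate"`, `"water"`, `"ion"`, ...), used
#'   for environment decomposition.
#' @return A `charge_model` tibble.
#' @export
charge_model <- function(atoms, molecule = 1L, source = "aggregate") {
  atoms <- as_tibble(atoms)
  req <- c("x", "y", "z", "q_ground", "q_excited", "alpha")
  if (!all(req %in% names(atoms))) {
    abort(paste0("`atoms` needs columns: ", paste(req, collapse = ", "), "."))
  }
  if (!"name" %in% names(atoms)) atoms$name <- paste0("A", seq_len(nrow(atoms)))
  if (any(atoms$alpha < 0)) abort("Polarizabilities must be >= 0.")
  if (abs(sum(atoms$q_ground) - sum(atoms$q_excited)) > 1e-6) {
    abort("Ground and excited charges must sum to the same total charge (tol 1e-6 e).")
  }
  atoms$molecule <- molecule
  atoms$source <- source
  structure(atoms[c("molecule", "source", "name", req)],
            class = c("charge_model", class(tibble())))
}

centre_of_geometry <- function(m) {
  c(mean(m$x), mean(m$y), mean(m$z))
}

#' Carve a finite cluster around a central molecule
#'
#' Selects from a multi-molecule snapshot the whole molecules whose centre
#' of geometry lies within `radius` of the central molecule's centre of
#' geometry; the central molecule itself is excluded from the environment.
#'
#' @param snapshot A `charge_model`-style tibble containing several
#'   molecules (distinct `molecule` ids).
#' @param central Molecule id of the central chromophore.
#' @param radius Carve radius, nm (default 3).
#' @return A list with `central` and `environment` (both `charge_model`
#'   tibbles; the environment may have zero rows).
#' @export
carve_cluster <- function(snapshot, central, radius = 3) {
  if (radius <= 0) abort("`radius` must be > 0 nm.")
  snapshot <- as_tibble(snapshot)
  if (!central %in% snapshot$molecule) {
    abort(sprintf("Central molecule id '%s' not present in the snapshot.",
                  format(central)))
  }
  cen <- snapshot[snapshot$molecule == central, ]
  cog0 <- centre_of_geometry(cen)
  keep <- snapshot %>%
    filter(.data$molecule != central) %>%
    group_by(.data$molecule) %>%
    filter(sqrt((mean(.data$x) - cog0[1])^2 + (mean(.data$y) - cog0[2])^2 +
                  (mean(.data$z) - cog0[3])^2) <= radius) %>%
    ungroup()
  list(central = cen, environment = keep)
}

#' Coulomb interaction energy between two charge sets
#'
#' \eqn{E = k \sum_{a \in A} \sum_{b \in B} q_a q_b / r_{ab}} (cross terms
#' only, no intra-set energy), in cm^-1.
#'
#' @param pos_a,pos_b Matrices (n x 3), nm.
#' @param q_a,q_b Charge vectors, e.
#' @param guard Minimum allowed inter-set distance, nm.
#' @return Energy, cm^-1.
#' @export
coulomb_interaction_energy <- function(pos_a, q_a, pos_b, q_b,
                                       guard = ENDPOINT_GUARD_NM) {
  pos_a <- rbind(pos_a); pos_b <- rbind(pos_b)
  if (nrow(pos_a) == 0L || nrow(pos_b) == 0L) return(0)
  d2 <- outer(rowSums(pos_a^2), rowSums(pos_b^2), "+") - 2 * tcrossprod(pos_a, pos_b)
  d2[d2 < 0] <- 0
  r <- sqrt(d2)
  if (min(r) < guard) {
    bad <- which(r == min(r), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "Atoms %d (set A) and %d (set B) are %.4f nm apart (< %.2f nm guard).",
      bad[1], bad[2], min(r), guard))
  }
  k_coulomb_cm1_nm() * sum(outer(q_a, q_b) / r)
}

# Field (in e / nm^2, i.e. energy = -k p.E) of point charges at positions
# `pos_q` with charges `q`, evaluated at points `at`.  Contributions between
# members of the same exclusion group (same molecule) are omitted, as is any
# self term (r = 0).
charge_field <- function(pos_q, q, at, group_q = NULL, group_at = NULL) {
  if (nrow(rbind(pos_q)) == 0L) return(matrix(0, nrow(rbind(at)), 3))
  pos_q <- rbind(pos_q); at <- rbind(at)
  r2 <- outer(at[, 1], pos_q[, 1], "-")^2 +
    outer(at[, 2], pos_q[, 2], "-")^2 +
    outer(at[, 3], pos_q[, 3], "-")^2
  mask <- r2 < 1e-12
  if (!is.null(group_q) && !is.null(group_at)) {
    mask <- mask | outer(group_at, group_q, "==")
  }
  r2[mask] <- Inf
  E <- matrix(0, nrow(at), 3)
  for (ax in 1:3) {
    dd <- outer(at[, ax], pos_q[, ax], "-")        # at x q
    E[, ax] <- (dd / r2^1.5) %*% q
  }
  E
}

# Field at each polarizable site from all other induced dipoles P (n x 3);
# same-molecule (same `group`) dipole-dipole interactions are excluded.
dipole_field <- function(pos, P, group = NULL) {
  n <- nrow(pos)
  E <- matrix(0, n, 3)
  if (n < 2L) return(E)
  dx <- outer(pos[, 1], pos[, 1], "-")
  dy <- outer(pos[, 2], pos[, 2], "-")
  dz <- outer(pos[, 3], pos[, 3], "-")
  r2 <- dx^2 + dy^2 + dz^2
  diag(r2) <- Inf
  if (!is.null(group)) r2[outer(group, group, "==")] <- Inf
  r5 <- r2^2.5; r3 <- r2^1.5
  # E_i = sum_j [3 (p_j . r_ij) r_ij / r^5 - p_j / r^3], r_ij = pos_i - pos_j
  pr <- dx * rep(P[, 1], each = n) + dy * rep(P[, 2], each = n) +
    dz * rep(P[, 3], each = n)
  E[, 1] <- rowSums(3 * pr * dx / r5) - (1 / r3) %*% P[, 1]
  E[, 2] <- rowSums(3 * pr * dy / r5) - (1 / r3) %*% P[, 2]
  E[, 3] <- rowSums(3 * pr * dz / r5) - (1 / r3) %*% P[, 3]
  E
}

#' Solve for self-consistent induced dipoles
#'
#' Damped Jacobi iteration of \eqn{p_i = \alpha_i E_i}, where \eqn{E_i} is
#' the field of all permanent charges plus all other induced dipoles.  The
#' induction energy is \eqn{-\tfrac12 k \sum_i p_i \cdot E^0_i} with
#' \eqn{E^0} the permanent-charge field only.  Pairs of polarizable sites
#' closer than \eqn{(4\alpha_i\alpha_j)^{1/6}} trigger a
#' polarization-catastrophe warning.
#'
#' @param pol_pos Polarizable site positions (n x 3, nm).
#' @param alpha Isotropic polarizability volumes (nm^3).
#' @param perm_pos,perm_q Permanent charge positions / values generating the
#'   external field.
#' @param damping Jacobi mixing factor in (0, 1]; default 0.5.
#' @param tol Convergence tolerance on the largest dipole change, e nm.
#' @param max_iter Iteration cap.
#' @param group_pol,group_perm Optional molecule ids for the polarizable
#'   sites and permanent charges: interactions within one molecule
#'   (polarizing one's own atoms) are excluded, as in standard polarizable
#'   embedding schemes.
#' @return A list with `p` (n x 3 induced dipoles, e nm), `energy`
#'   (induction energy, cm^-1), `iterations`, `converged`.
#' @export
solve_induced_dipoles <- function(pol_pos, alpha, perm_pos, perm_q,
                                  damping = 0.5, tol = 1e-8, max_iter = 200,
                                  group_pol = NULL, group_perm = NULL) {
  pol_pos <- rbind(pol_pos)
  n <- nrow(pol_pos)
  if (any(alpha < 0)) abort("Polarizabilities must be >= 0.")
  if (n == 0L) {
    return(list(p = matrix(0, 0, 3), energy = 0, iterations = 0L,
                converged = TRUE))
  }
  if (n > 1L) {
    d2 <- outer(rowSums(pol_pos^2), rowSums(pol_pos^2), "+") -
      2 * tcrossprod(pol_pos)
    diag(d2) <- Inf
    crit <- (4 * outer(alpha, alpha))^(1 / 6)
    if (any(d2 < crit^2 & crit > 0)) {
      warn("Polarizable sites closer than (4 a_i a_j)^(1/6): risk of polarization catastrophe.")
    }
  }
  E0 <- charge_field(perm_pos, perm_q, pol_pos, group_q = group_perm,
                     group_at = group_pol)
  P <- alpha * E0
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Pnew <- alpha * (E0 + dipole_field(pol_pos, P, group = group_pol))
    P1 <- (1 - damping) * P + damping * Pnew
    delta <- max(sqrt(rowSums((P1 - P)^2)))
    P <- P1
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    abort(sprintf(
      "Induced dipoles did not converge in %d iterations (last change %.2e e nm); try a smaller `damping`.",
      max_iter, delta))
  }
  list(p = P, energy = -0.5 * k_coulomb_cm1_nm() * sum(P * E0),
       iterations = it, converged = converged)
}

#' Environment-induced excitation-energy shift of a central molecule
#'
#' Performs two classical interaction-energy evaluations against the same
#' ground-state environment: one with the central molecule's excited-state
#' charges (\eqn{E_e}) and one with its ground-state charges (\eqn{E_g}).
#' Each evaluation is the central--environment Coulomb energy plus the
#' induction energy of the environment's polarizable atoms responding
#' self-consistently to all permanent charges.  The solvent shift is
#' \deqn{\Delta\varepsilon = E_e - E_g.}
#'
#' @param central A `charge_model` for the central molecule.
#' @param environment A `charge_model` tibble of surrounding molecules
#'   (ground-state charges are used; may be empty).
#' @param sources Optional character vector restricting the environment to
#'   molecules with these `source` tags (e.g. `"aggregate"` to discard the
#'   solvent contribution); `NULL` keeps everything.
#' @param polarizable If `FALSE`, skip induction (pure electrostatics).
#' @param ... Passed to [solve_induced_dipoles()].
#' @return A list with `shift` (cm^-1), `e_excited`, `e_ground`, and the
#'   electrostatic/induction components of each.
#' @export
solvent_shift <- function(central, environment, sources = NULL,
                          polarizable = TRUE, ...) {
  env <- as_tibble(environment)
  if (!is.null(sources) && nrow(env)) env <- env[env$source %in% sources, ]
  if (nrow(env) == 0L) {
    zero <- list(shift = 0, e_excited = 0, e_ground = 0,
                 components = tibble(state = c("ground", "excited"),
                                     electrostatic = 0, induction = 0))
    return(zero)
  }
  cen_pos <- cbind(central$x, central$y, central$z)
  env_pos <- cbind(env$x, env$y, env$z)
  eval_state <- function(q_central) {
    elec <- coulomb_interaction_energy(cen_pos, q_central, env_pos, env$q_ground)
    ind <- 0
    if (polarizable && any(env$alpha > 0)) {
      # permanent field: central charges plus environment ground charges;
      # a molecule never polarizes its own atoms
      perm_pos <- rbind(cen_pos, env_pos)
      perm_q <- c(q_central, env$q_ground)
      gp <- c(rep(-1L, nrow(cen_pos)), as.integer(factor(env$molecule)))
      sol <- solve_induced_dipoles(env_pos, env$alpha, perm_pos, perm_q,
                                   group_pol = gp[-seq_len(nrow(cen_pos))],
                                   group_perm = gp, ...)
      ind <- sol$energy
    }
    c(elec = elec, ind = ind)
  }
  g <- eval_state(central$q_ground)
  e <- eval_state(central$q_excited)
  list(
    shift = unname(sum(e) - sum(g)),
    e_excited = unname(sum(e)),
    e_ground = unname(sum(g)),
    components = tibble(state = c("ground", "excited"),
                        electrostatic = c(g[["elec"]], e[["elec"]]),
                        induction = c(g[["ind"]], e[["ind"]]))
  )
}

#' Per-wall Gaussian statistics of solvent shifts
#'
#' Maximum-likelihood Gaussian fit (sample mean; ML standard deviation) of
#' per-molecule shifts, per wall.  The fitted parameters feed directly into
#' [diagonal_disorder()].
#'
#' @param shifts A data frame with columns `shift` (cm^-1) and `wall`.
#' @param min_n Minimum number of shifts per wall required for a fit.
#' @return A tibble with `wall`, `n`, `mean`, `sigma`, and the
#'   root-mean-square residual `fit_rms` between the fitted normal density
#'   and a histogram density estimate.
#' @export
shift_statistics <- function(shifts, min_n = 10) {
  shifts <- as_tibble(shifts)
  if (!all(c("shift", "wall") %in% names(shifts))) {
    abort("`shifts` needs columns `shift` and `wall`.")
  }
  counts <- table(shifts$wall)
  if (any(counts < min_n)) {
    abort(sprintf("Each wall needs at least %d shifts for a Gaussian fit.",
                  min_n))
  }
  shifts %>%
    group_by(.data$wall) %>%
    summarise(
      n = dplyr::n(),
      mean = mean(.data$shift),
      sigma = sqrt(mean((.data$shift - mean(.data$shift))^2)),
      fit_rms = gaussian_fit_rms(.data$shift),
      .groups = "drop"
    )
}

gaussian_fit_rms <- function(x) {
  m <- mean(x); s <- sqrt(mean((x - m)^2))
  if (s == 0) return(0)
  h <- graphics::hist(x, breaks = "FD", plot = FALSE)
  sqrt(mean((h$density - dnorm(h$mids, m, s))^2))
}
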