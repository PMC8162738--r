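#' Frenkel exciton Hamiltonian of a tube structure
#'
#' One-exciton tight-binding Hamiltonian in the site basis: diagonal entries
#' are site excitation energies \eqn{\varepsilon_n = E_0 + \Delta\varepsilon_n}
#' (gas-phase monomer energy plus an environment shift), off-diagonal entries
#' are extended-dipole resonance couplings \eqn{J_{nm}}.
#'
#' @param structure A `tube_structure`.
#' @param e0 Gas-phase monomer excitation energy, cm^-1.
#' @param shifts Per-site energy shifts (cm^-1): a numeric vector of length
#'   `nrow(structure)`, or `NULL` for zeros.
#' @param dipole An [extended_dipole()].
#' @param screening Relative screening constant for the couplings.
#' @param cutoff Centre-to-centre coupling cutoff, nm (`NULL` = all pairs).
#' @param periodic Use the screw-periodic axial boundary recorded by
#'   [build_tube()] with `axial = "periodic"`: every site is additionally
#'   coupled to the periodic images of all sites, giving bulk (edge-free)
#'   band positions for ideal tubes.
#' @return An `exciton_hamiltonian`: list with the symmetric matrix `H`
#'   (cm^-1), `wall` labels, `e0`, and the site `structure`.
#' @export
build_hamiltonian <- function(structure, e0 = E0_MONOMER_CM1, shifts = NULL,
                              dipole = default_extended_dipole(),
                              screening = 1, cutoff = NULL,
                              periodic = FALSE) {
  n <- nrow(structure)
  if (is.null(shifts)) shifts <- numeric(n)
  if (length(shifts) != n) abort("`shifts` must have one entry per site.")
  if (!all(is.finite(shifts))) abort("`shifts` must be finite.")
  screw <- NULL
  if (periodic) {
    screw <- attr(structure, "screw")
    if (is.null(screw)) {
      abort("`periodic = TRUE` needs a structure built with `build_tube(axial = \"periodic\")`.")
    }
  }
  H <- coupling_matrix(structure, dipole, screening = screening,
                       cutoff = cutoff, screw = screw)
  diag(H) <- e0 + shifts
  structure(list(H = H, wall = structure$wall, e0 = e0,
                 structure = structure, dipole = dipole),
            class = "exciton_hamiltonian")
}

#' Construct an exciton Hamiltonian from an explicit coupling matrix
#'
#' Lower-level companion to [build_hamiltonian()] for hand-specified
#' couplings (model systems: dimers, rings, chains).
#'
#' @param H Symmetric numeric matrix, cm^-1 (diagonal = site energies).
#' @param structure Site tibble with `dx`, `dy`, `dz` and `wall` (defaults
#'   to z-polarized single-wall sites).
#' @param e0 Reference monomer energy stored as metadata, cm^-1.
#' @param dipole An [extended_dipole()] giving the monomer dipole magnitude.
#' @return An `exciton_hamiltonian`.
#' @export
exciton_hamiltonian <- function(H, structure = NULL, e0 = 0,
                                dipole = default_extended_dipole()) {
  H <- as.matrix(H)
  if (nrow(H) != ncol(H)) abort("`H` must be square.")
  if (!all(is.finite(H))) abort("`H` must be finite.")
  if (max(abs(H - t(H))) > 1e-8 * max(1, max(abs(H)))) {
    abort("`H` must be symmetric.")
  }
  n <- nrow(H)
  if (is.null(structure)) {
    structure <- tibble(site = seq_len(n), x = seq_len(n), y = 0, z = 0,
                        dx = 0, dy = 0, dz = 1, wall = "IW")
  }
  if (nrow(structure) != n) abort("`structure` must have one row per site.")
  structure(list(H = H, wall = structure$wall, e0 = e0,
                 structure = structure, dipole = dipole),
            class = "exciton_hamiltonian")
}

#' @export
print.exciton_hamiltonian <- function(x, ...) {
  cat(sprintf("<exciton_hamiltonian> N = %d sites, E0 = %.0f cm^-1\n",
              nrow(x$H), x$e0))
  cs <- coupling_sum_per_site(x)
  s <- tapply(cs$coupling_sum, cs$wall, mean)
  cat("  mean per-site coupling sum (cm^-1):",
      paste(sprintf("%s %.0f", names(s), s), collapse = ", "), "\n")
  invisible(x)
}

#' Diagonalize an exciton Hamiltonian
#'
#' Full dense symmetric eigendecomposition.  Eigenvalues are returned in
#' ascending order with orthonormal eigenvectors; each state's collective
#' transition dipole is \eqn{\vec\mu_k = \sum_n c_{kn}\,\mu\,\hat d_n}.
#'
#' @param ham An `exciton_hamiltonian`.
#' @return An `exciton_states` object: `energies` (cm^-1, ascending),
#'   `coefficients` (N x N; column k is state k), `mu` (N_states x 3
#'   collective dipoles, e nm), `osc_strength` (\eqn{|\mu_k|^2}), `wall`
#'   site labels, `wall_weight` (states x walls matrix), `ipr_size`
#'   (per-state delocalization size \eqn{1/\sum_n c_{kn}^4}).
#' @export
diagonalize <- function(ham) {
  H <- ham$H
  if (!is.matrix(H) || nrow(H) != ncol(H)) abort("Hamiltonian must be square.")
  if (!all(is.finite(H))) abort("Hamiltonian must be finite.")
  if (max(abs(H - t(H))) > 1e-8 * max(1, max(abs(H)))) {
    abort("Hamiltonian must be symmetric.")
  }
  eig <- eigen((H + t(H)) / 2, symmetric = TRUE)
  ord <- order(eig$values)
  energies <- eig$values[ord]
  C <- eig$vectors[, ord, drop = FALSE]
  st <- ham$structure
  axes <- cbind(st$dx, st$dy, st$dz)
  mu_site <- ham$dipole$mu * axes                 # N x 3
  mu_k <- crossprod(C, mu_site)                   # states x 3
  walls <- sort(unique(ham$wall))
  wall_weight <- vapply(walls,
                        function(w) colSums(C[ham$wall == w, , drop = FALSE]^2),
                        numeric(ncol(C)))
  wall_weight <- matrix(wall_weight, ncol = length(walls),
                        dimnames = list(NULL, walls))
  structure(list(
    energies = energies,
    coefficients = C,
    mu = mu_k,
    osc_strength = rowSums(mu_k^2),
    wall = ham$wall,
    wall_weight = wall_weight,
    ipr_size = 1 / colSums(C^4),
    e0 = ham$e0,
    mu_monomer = ham$dipole$mu
  ), class = "exciton_states")
}

#' @export
print.exciton_states <- function(x, ...) {
  cat(sprintf("<exciton_states> %d states, band %.0f..%.0f cm^-1 (W = %.0f)\n",
              length(x$energies), min(x$energies), max(x$energies),
              exciton_bandwidth(x)))
  invisible(x)
}

#' @describeIn diagonalize Tidy per-state summary: energy, oscillator
#'   strength, polarization components, wall weights, delocalization size.
#' @param x An `exciton_states` object.
#' @param ... Unused.
#' @export
tidy.exciton_states <- function(x, ...) {
  out <- tibble(
    state = seq_along(x$energies),
    energy = x$energies,
    osc_strength = x$osc_strength,
    osc_parallel = x$mu[, 3]^2,
    osc_perpendicular = x$mu[, 1]^2 + x$mu[, 2]^2,
    deloc_size = x$ipr_size
  )
  for (w in colnames(x$wall_weight)) {
    out[[paste0("weight_", w)]] <- x$wall_weight[, w]
  }
  out
}

#' @describeIn diagonalize One-row summary: N, bandwidth, total oscillator
#'   strength, trace.
#' @export
glance.exciton_states <- function(x, ...) {
  tibble(
    n_sites = nrow(x$coefficients),
    n_states = length(x$energies),
    bandwidth = exciton_bandwidth(x),
    total_osc_strength = sum(x$osc_strength),
    trace = sum(x$energies)
  )
}

#' Collective transition dipoles of exciton states
#'
#' @param states An `exciton_states` object.
#' @return A numeric matrix (states x 3), e nm.
#' @export
collective_dipoles <- function(states) states$mu

#' Per-site sum of excitonic couplings
#'
#' Row sums of the off-diagonal Hamiltonian, \eqn{\sum_{j\neq i} J_{ij}}:
#' the sign and magnitude diagnose J- versus H-aggregate character and the
#' approximate exciton shift of the parallel band per wall.
#'
#' @param ham An `exciton_hamiltonian`.
#' @return A tibble with `site`, `wall`, `coupling_sum` (cm^-1).
#' @export
coupling_sum_per_site <- function(ham) {
  J <- ham$H
  diag(J) <- 0
  tibble(site = seq_len(nrow(J)), wall = ham$wall,
         coupling_sum = rowSums(J))
}

#' Exciton band width
#'
#' @param states An `exciton_states` object.
#' @return `max(E_k) - min(E_k)` in cm^-1.
#' @export
exciton_bandwidth <- function(states) {
  if (length(states$energies) < 1L) abort("No states.")
  max(states$energies) - min(states$energies)
}

#' Exciton delocalization size
#'
#' Inverse-participation-ratio size per state,
#' \eqn{N_k = 1/\sum_n c_{kn}^4} (a uniform state over N sites gives N, a
#' fully localized state gives 1), summarised as the oscillator-strength
#' weighted average over a low-energy band window.
#'
#' @param states An `exciton_states` object.
#' @param window Energy window (cm^-1, length 2) selecting the states to
#'   average over.  Default: from the lowest state up to the energy of the
#'   brightest state of the lowest band plus `band_halfwidth`.
#' @param band_halfwidth Half-width (cm^-1) used to form the default window
#'   around the brightest low-energy state (default 300).
#' @return A list with `per_state` (tibble: state, energy, size, weight) and
#'   `weighted_size` (scalar).
#' @export
delocalization_size <- function(states, window = NULL, band_halfwidth = 300) {
  sizes <- states$ipr_size
  if (is.null(window)) {
    bright <- which.max(states$osc_strength)
    window <- c(min(states$energies) - 1e-9,
                states$energies[bright] + band_halfwidth)
  }
  sel <- states$energies >= window[1] & states$energies <= window[2]
  if (!any(sel)) abort("No states inside the requested window.")
  w <- states$osc_strength[sel]
  wsize <- if (sum(w) > 0) sum(w * sizes[sel]) / sum(w) else mean(sizes[sel])
  list(
    per_state = tibble(state = which(sel), energy = states$energies[sel],
                       size = sizes[sel], weight = w),
    weighted_size = wsize
  )
}

#' Write a Hamiltonian as a TSV matrix
#'
#' Dense tab-separated export (suitable for small N).
#'
#' @param ham An `exciton_hamiltonian`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hamiltonian_tsv <- function(ham, path) {
  write.table(ham$H, path, sep = "\t", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
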