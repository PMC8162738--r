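#' Pair angle-distance map
#'
#' Two-dimensional histogram over all unordered site pairs of the
#' centre-to-centre distance \eqn{r_{ij}} and the angle between the two
#' transition-dipole axes, \eqn{\phi_{ij} = \arccos|\hat d_i \cdot \hat
#' d_j|} (axis convention: dipoles enter the couplings quadratically, so
#' antiparallel pairs count as parallel and \eqn{\phi \in [0, 90]} degrees).
#' Counts are normalized to the number of binned pairs.  Computed per wall
#' and for the whole structure.
#'
#' @param structure A `tube_structure`.
#' @param r_max Maximum pair distance, nm (default 3).
#' @param dr,dphi Bin widths: nm (default 0.05) and degrees (default 2).
#' @param per_wall Also compute per-wall maps (pairs within one wall).
#' @return A `pair_map`: tibble with bin centres `r`, `phi`, normalized
#'   `density`, and `wall` (`"all"` plus one level per wall when
#'   `per_wall`); empty bins are omitted.
#' @export
pair_angle_distance_map <- function(structure, r_max = 3, dr = 0.05,
                                    dphi = 2, per_wall = TRUE) {
  if (r_max <= 0) abort("`r_max` must be > 0 nm.")
  pairs <- pair_table(structure, r_max)
  if (nrow(pairs) == 0L) {
    warn("No site pairs within `r_max`; empty map.")
    return(structure(tibble(r = numeric(), phi = numeric(),
                            density = numeric(), wall = character()),
                     r_max = r_max, dr = dr, dphi = dphi,
                     class = c("pair_map", class(tibble()))))
  }
  bin_map <- function(df, label) {
    df %>%
      mutate(rb = (floor(.data$r / dr) + 0.5) * dr,
             pb = (floor(.data$phi / dphi) + 0.5) * dphi) %>%
      dplyr::count(.data$rb, .data$pb, name = "n") %>%
      mutate(density = .data$n / sum(.data$n), wall = label) %>%
      select(r = "rb", phi = "pb", "density", "wall")
  }
  out <- bin_map(pairs, "all")
  if (per_wall) {
    for (w in unique(structure$wall)) {
      ww <- pairs[pairs$wall_i == w & pairs$wall_j == w, ]
      if (nrow(ww)) out <- bind_rows(out, bin_map(ww, w))
    }
  }
  structure(out, r_max = r_max, dr = dr, dphi = dphi,
            class = c("pair_map", class(tibble())))
}

# All unordered pairs with r <= r_max: distance, axis angle, wall labels.
pair_table <- function(structure, r_max) {
  pos <- cbind(structure$x, structure$y, structure$z)
  ax <- cbind(structure$dx, structure$dy, structure$dz)
  n <- nrow(pos)
  if (n < 2L) return(tibble(r = numeric(), phi = numeric(),
                            wall_i = character(), wall_j = character()))
  d2 <- outer(rowSums(pos^2), rowSums(pos^2), "+") - 2 * tcrossprod(pos)
  d2[d2 < 0] <- 0
  idx <- which(upper.tri(d2) & d2 <= r_max^2, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(tibble(r = numeric(), phi = numeric(),
                                     wall_i = character(), wall_j = character()))
  cosang <- abs(rowSums(ax[idx[, 1], , drop = FALSE] * ax[idx[, 2], , drop = FALSE]))
  cosang <- pmin(cosang, 1)
  tibble(r = sqrt(d2[idx]), phi = rad2deg(acos(cosang)),
         wall_i = structure$wall[idx[, 1]], wall_j = structure$wall[idx[, 2]])
}

#' Scan the rolling angle
#'
#' Builds an ideal single-walled tube for each rolling angle, diagonalizes
#' its Hamiltonian, and tabulates the parallel and perpendicular peak
#' positions (of the broadened spectrum) and the parallel/perpendicular
#' oscillator-strength ratio.  The parallel peak of a cylindrical aggregate
#' is essentially rolling-angle independent while the perpendicular band
#' moves strongly, which is what makes this scan a structure-selection tool.
#'
#' @param cell A [unit_cell()].
#' @param thetas Rolling angles to scan, degrees.
#' @param radius,tube_length Tube geometry, nm.
#' @param dipole An [extended_dipole()].
#' @param e0 Monomer energy, cm^-1.
#' @param fwhm Homogeneous FWHM for peak finding, cm^-1.
#' @return A tibble: `theta` (requested), `theta_snapped`, `n_sites`,
#'   `parallel_peak`, `perpendicular_peak` (cm^-1), `osc_ratio`
#'   (parallel / perpendicular total oscillator strength).
#' @export
scan_rolling_angle <- function(cell, thetas, radius = 3.2, tube_length = 15,
                               dipole = default_extended_dipole(),
                               e0 = E0_MONOMER_CM1, fwhm = 150) {
  if (!length(thetas)) abort("Provide at least one rolling angle.")
  purrr::map_dfr(thetas, function(th) {
    tube <- build_tube(cell, radius, th, tube_length, axial = "periodic",
                       quiet = TRUE)
    states <- diagonalize(build_hamiltonian(tube, e0 = e0, dipole = dipole,
                                            periodic = TRUE))
    sp <- broaden_spectrum(stick_spectrum(states), fwhm = fwhm)
    pk_par <- peak_metrics(sp, "parallel")
    pk_per <- peak_metrics(sp, "perpendicular")
    sticks <- stick_spectrum(states)
    tibble(
      theta = th,
      theta_snapped = attr(tube, "rolling")[[1]]$theta,
      n_sites = nrow(tube),
      parallel_peak = if (nrow(pk_par$peaks)) pk_par$peaks$energy[1] else NA_real_,
      perpendicular_peak = if (nrow(pk_per$peaks)) pk_per$peaks$energy[which.max(pk_per$peaks$height)] else NA_real_,
      osc_ratio = sum(sticks$parallel) / sum(sticks$perpendicular)
    )
  })
}

#' Scan the outer-wall packing density
#'
#' Expands the outer-wall in-plane lattice constants by each `factor`
#' (inner wall fixed) and records the resulting splitting between the
#' inner- and outer-wall parallel absorption peaks.  Because the parallel
#' peak position is radius-independent, each wall is computed as a separate
#' single-walled tube.  An inverse lookup interpolates the factor that
#' reproduces a target splitting.
#'
#' @param cell Inner-wall [unit_cell()].
#' @param factors Outer-wall lattice expansion factors (> 0), e.g.
#'   `seq(1, 1.05, 0.01)`.
#' @param r_iw,r_ow Wall radii, nm.
#' @param tube_length Tube length, nm.
#' @param dipole,e0,fwhm As in [scan_rolling_angle()].
#' @param theta Rolling angle, degrees.
#' @param target Optional target splitting (cm^-1) for the inverse lookup.
#' @return A tibble `factor`, `iw_peak`, `ow_peak`, `splitting` (cm^-1),
#'   with attribute `factor_for_target` when `target` is given (error if
#'   the scanned factors do not bracket it).
#' @export
scan_density_splitting <- function(cell, factors, r_iw = 3.2, r_ow = 5.7,
                                   tube_length = 15, theta = 30,
                                   dipole = default_extended_dipole(),
                                   e0 = E0_MONOMER_CM1, fwhm = 150,
                                   target = NULL) {
  if (any(factors <= 0)) abort("`factors` must be > 0.")
  wall_peak <- function(c_wall, r, wall) {
    tube <- build_tube(c_wall, r, theta, tube_length, wall = wall,
                       axial = "periodic", quiet = TRUE)
    states <- diagonalize(build_hamiltonian(tube, e0 = e0, dipole = dipole,
                                            periodic = TRUE))
    sp <- broaden_spectrum(stick_spectrum(states), fwhm = fwhm)
    pk <- peak_metrics(sp, "parallel")
    pk$peaks$energy[1]
  }
  iw_peak <- wall_peak(cell, r_iw, "IW")
  out <- purrr::map_dfr(factors, function(f) {
    ow_peak <- wall_peak(scale_unit_cell(cell, f), r_ow, "OW")
    tibble(factor = f, iw_peak = iw_peak, ow_peak = ow_peak,
           splitting = ow_peak - iw_peak)
  })
  if (!is.null(target)) {
    if (target < min(out$splitting) || target > max(out$splitting)) {
      abort(sprintf(
        "Target splitting %.0f cm^-1 is not bracketed by the scanned factors (range %.0f..%.0f cm^-1).",
        target, min(out$splitting), max(out$splitting)))
    }
    attr(out, "factor_for_target") <-
      approx(out$splitting, out$factor, xout = target)$y
  }
  out
}

#' Coupling-sum histograms across a disorder ensemble
#'
#' Pools the per-site coupling sums \eqn{\sum_{j\neq i} J_{ij}} over all
#' snapshots of an ensemble and compares them per wall with the ideal
#' (base) structure: structural disorder broadens the distribution and
#' makes the mean less negative.
#'
#' @param ensemble A `snapshot_ensemble`.
#' @param dipole An [extended_dipole()].
#' @param screening,cutoff Passed to the Hamiltonian build.
#' @return A list with `values` (tibble: `wall`, `kind` ideal/disordered,
#'   `coupling_sum`) and `summary` (per wall and kind: mean, sd, n).
#' @export
coupling_sum_histogram <- function(ensemble, dipole = default_extended_dipole(),
                                   screening = 1, cutoff = NULL) {
  stopifnot(inherits(ensemble, "snapshot_ensemble"))
  cs_of <- function(st) {
    ham <- build_hamiltonian(st, e0 = 0, dipole = dipole,
                             screening = screening, cutoff = cutoff)
    coupling_sum_per_site(ham)
  }
  ideal <- cs_of(ensemble$base) %>% mutate(kind = "ideal")
  dis <- purrr::map_dfr(ensemble$snapshots, cs_of) %>% mutate(kind = "disordered")
  values <- bind_rows(ideal, dis)
  summary <- values %>%
    group_by(.data$wall, .data$kind) %>%
    summarise(mean = mean(.data$coupling_sum), sd = sd(.data$coupling_sum),
              n = dplyr::n(), .groups = "drop")
  list(values = values, summary = summary)
}
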