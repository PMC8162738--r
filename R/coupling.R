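#' Extended-dipole excitonic coupling between two sites
#'
#' Each transition dipole is replaced by two opposite charges \eqn{\pm q}
#' separated by \eqn{l} along the dipole axis; the resonance coupling is the
#' four-term Coulomb sum over the charge end points,
#' \deqn{J_{ij} = \frac{k\,q^2}{s}\left[\frac{1}{r_{++}} + \frac{1}{r_{--}}
#'   - \frac{1}{r_{+-}} - \frac{1}{r_{-+}}\right],}
#' with \eqn{k} the Coulomb constant ([k_coulomb_cm1_nm()]) and \eqn{s} an
#' optional relative screening constant.  Side-by-side parallel dipoles give
#' \eqn{J > 0} (H-type), head-to-tail dipoles \eqn{J < 0} (J-type).
#'
#' @param pos_i,pos_j Site positions, numeric length-3 (nm).
#' @param axis_i,axis_j Dipole unit vectors.
#' @param dipole An [extended_dipole()].
#' @param screening Relative screening constant (default 1, vacuum).
#' @return Coupling in cm^-1.
#' @export
#' @examples
#' # H-type side-by-side pair, 1 nm apart
#' coupling_extended_dipole(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1), c(0, 0, 1),
#'                          extended_dipole(1, 0.7))
coupling_extended_dipole <- function(pos_i, pos_j, axis_i, axis_j, dipole,
                                     screening = 1) {
  stopifnot(inherits(dipole, "extended_dipole"))
  h <- dipole$l / 2
  pi_p <- pos_i + h * axis_i; pi_m <- pos_i - h * axis_i
  pj_p <- pos_j + h * axis_j; pj_m <- pos_j - h * axis_j
  d <- function(a, b) sqrt(sum((a - b)^2))
  r <- c(d(pi_p, pj_p), d(pi_m, pj_m), d(pi_p, pj_m), d(pi_m, pj_p))
  if (any(r < ENDPOINT_GUARD_NM)) {
    abort(sprintf(
      "Charge end points of the two molecules approach within %.3f nm (< %.1f nm guard): unphysical overlap.",
      min(r), ENDPOINT_GUARD_NM))
  }
  (k_coulomb_cm1_nm() / screening) * dipole$q^2 *
    (1 / r[1] + 1 / r[2] - 1 / r[3] - 1 / r[4])
}

#' Point-dipole excitonic coupling
#'
#' Far-field limit of the extended-dipole interaction: the standard
#' dipole--dipole kernel
#' \deqn{J_{ij} = \frac{k\,\mu^2}{s\,r^3}\left[\hat d_i\cdot\hat d_j
#'   - 3(\hat d_i\cdot\hat r)(\hat d_j\cdot\hat r)\right].}
#'
#' @inheritParams coupling_extended_dipole
#' @param mu Transition dipole magnitude, e nm.
#' @return Coupling in cm^-1.
#' @export
coupling_point_dipole <- function(pos_i, pos_j, axis_i, axis_j, mu,
                                  screening = 1) {
  rvec <- pos_j - pos_i
  r <- sqrt(sum(rvec^2))
  if (r == 0) abort("Coincident sites: point-dipole coupling undefined.")
  rhat <- rvec / r
  (k_coulomb_cm1_nm() / screening) * mu^2 *
    (sum(axis_i * axis_j) - 3 * sum(axis_i * rhat) * sum(axis_j * rhat)) / r^3
}

# Dense pairwise extended-dipole coupling matrix (cm^-1), vectorised over all
# site pairs; J[n, n] = 0.  `cutoff` (nm, centre-to-centre) zeroes couplings
# beyond it; NULL keeps all pairs.  With `screw` (list Lz, dphi) the matrix
# additionally sums couplings to the screw-periodic images of every site
# (k = -k_images..k_images, k != 0), including a site's own images (added to
# the diagonal as for the symmetric supercell state of an infinite tube).
coupling_matrix <- function(structure, dipole, screening = 1, cutoff = NULL,
                            screw = NULL, k_images = 2L) {
  n <- nrow(structure)
  ends <- site_charge_positions(structure, dipole)
  cross_d <- function(a, b) {
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
    d2[d2 < 0] <- 0
    sqrt(d2)
  }
  kq2 <- (k_coulomb_cm1_nm() / screening) * dipole$q^2
  pos <- cbind(structure$x, structure$y, structure$z)
  block <- function(e2, p2, self_excluded) {
    rpp <- cross_d(ends$plus, e2$plus)
    rmm <- cross_d(ends$minus, e2$minus)
    rpm <- cross_d(ends$plus, e2$minus)
    rmp <- cross_d(ends$minus, e2$plus)
    rmin <- pmin(rpp, rmm, rpm, rmp)
    chk <- if (self_excluded) !diag(TRUE, n) else matrix(TRUE, n, n)
    if (any(chk) && min(rmin[chk]) < ENDPOINT_GUARD_NM) {
      bad <- which(chk & rmin < ENDPOINT_GUARD_NM, arr.ind = TRUE)[1, ]
      abort(sprintf(
        "Charge end points of sites %d and %d approach within %.3f nm (< %.1f nm guard).",
        bad[1], bad[2], min(rmin[chk]), ENDPOINT_GUARD_NM))
    }
    Jb <- kq2 * (1 / rpp + 1 / rmm - 1 / rpm - 1 / rmp)
    if (self_excluded) diag(Jb) <- 0
    if (!is.null(cutoff) && is.finite(cutoff)) {
      Jb[cross_d(pos, p2) > cutoff] <- 0
    }
    Jb
  }
  J <- block(ends, pos, self_excluded = TRUE)
  if (!is.null(screw)) {
    for (k in setdiff(seq(-k_images, k_images), 0L)) {
      a <- k * screw$dphi
      rot <- function(m) cbind(cos(a) * m[, 1] - sin(a) * m[, 2],
                               sin(a) * m[, 1] + cos(a) * m[, 2],
                               m[, 3])
      shift <- c(0, 0, k * screw$Lz)
      e2 <- list(plus = sweep(rot(ends$plus), 2, shift, "+"),
                 minus = sweep(rot(ends$minus), 2, shift, "+"))
      p2 <- sweep(rot(pos), 2, shift, "+")
      J <- J + block(e2, p2, self_excluded = FALSE)
    }
  }
  # exact symmetry against round-off
  (J + t(J)) / 2
}
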