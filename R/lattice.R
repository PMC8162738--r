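#' Build a finite planar herringbone lattice
#'
#' Tiles `n1 x n2` unit cells of `cell` and places both basis molecules in
#' each, producing `2 * n1 * n2` sites.  Planar coordinates live in the
#' lattice plane (nm); the plane normal is the local `z` used for the
#' out-of-plane dipole tilt.
#'
#' @param cell A [unit_cell()].
#' @param n1,n2 Number of cells along `a1` and `a2` (integers >= 1).
#' @return A tibble with one row per site: cell indices `i`, `j`, basis index
#'   `basis`, planar position `u1`, `u2` (nm), and the planar dipole unit
#'   vector `d1`, `d2`, `dn` (in-plane components and out-of-plane component).
#' @export
#' @examples
#' nrow(build_planar_lattice(default_unit_cell(), 3, 3))  # 18
build_planar_lattice <- function(cell, n1, n2) {
  stopifnot(inherits(cell, "unit_cell"))
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (is.na(n1) || is.na(n2) || n1 < 1L || n2 < 1L) {
    abort("`n1` and `n2` must be integers >= 1.")
  }
  grid <- tidyr::expand_grid(i = seq_len(n1) - 1L, j = seq_len(n2) - 1L,
                             basis = seq_len(nrow(cell$basis)))
  planar_sites(cell, grid)
}

# Place sites for arbitrary integer cell indices.  The in-plane dipole angle
# is measured from a1; tilt rotates the dipole out of the lattice plane.
planar_sites <- function(cell, grid) {
  b <- cell$basis[grid$basis, ]
  phi_a1 <- atan2(cell$a1[2], cell$a1[1])
  ang <- deg2rad(b$angle) + phi_a1      # absolute in-plane angle
  tlt <- deg2rad(b$tilt)
  tibble(
    i = grid$i, j = grid$j, basis = grid$basis,
    u1 = (grid$i + b$frac1) * cell$a1[1] + (grid$j + b$frac2) * cell$a2[1],
    u2 = (grid$i + b$frac1) * cell$a1[2] + (grid$j + b$frac2) * cell$a2[2],
    d1 = cos(tlt) * cos(ang),
    d2 = cos(tlt) * sin(ang),
    dn = sin(tlt)
  )
}

#' Snap a rolling vector onto the lattice
#'
#' Wrapping a periodic lattice seamlessly onto a cylinder requires the
#' circumference vector to be an integer combination of lattice translations
#' (as for a carbon-nanotube chiral vector).  Given a requested radius and
#' rolling angle, this finds the integer combination `m1*a1 + m2*a2` closest
#' to the requested circumference vector and adjusts the tube radius and
#' rolling angle to it, leaving the lattice itself unstrained.
#'
#' @param cell A [unit_cell()].
#' @param radius Requested tube radius, nm.
#' @param theta Requested rolling angle, degrees in `[0, 90)`: the angle
#'   between `a1` and the circumferential direction.
#' @param max_strain Error if the relative circumference (radius) adjustment
#'   exceeds this (default 0.02; the lattice itself is never strained, and
#'   experimental radii carry ~15\% uncertainty).
#' @return A list with `m1`, `m2`, `radius` (snapped, nm), `theta` (snapped,
#'   degrees), `circumference` (nm), and `strain` (relative vector mismatch).
#' @export
commensurate_rolling <- function(cell, radius, theta, max_strain = 0.02) {
  stopifnot(inherits(cell, "unit_cell"))
  if (!is.numeric(radius) || radius <= 0) abort("`radius` must be > 0 nm.")
  if (!is.numeric(theta) || theta < 0 || theta >= 90) {
    abort("`theta` must lie in [0, 90) degrees.")
  }
  phi_a1 <- atan2(cell$a1[2], cell$a1[1])
  target_len <- 2 * pi * radius
  target <- target_len * c(cos(phi_a1 + deg2rad(theta)),
                           sin(phi_a1 + deg2rad(theta)))
  A <- cbind(cell$a1, cell$a2)
  m0 <- solve(A, target)
  cand <- tidyr::expand_grid(m1 = round(m0[1]) + (-10:10),
                             m2 = round(m0[2]) + (-10:10))
  w1 <- cand$m1 * cell$a1[1] + cand$m2 * cell$a2[1]
  w2 <- cand$m1 * cell$a1[2] + cand$m2 * cell$a2[2]
  wlen <- sqrt(w1^2 + w2^2)
  dtheta <- abs(((atan2(w2, w1) - atan2(target[2], target[1]) + pi) %% (2 * pi)) - pi)
  ok <- wlen > 0 & dtheta <= deg2rad(4)
  if (!any(ok)) {
    abort("No commensurate rolling vector within 4 degrees of the requested angle; adjust the rolling angle.")
  }
  # among directions close to the requested one, match the circumference;
  # small angular deviations only break ties
  miss <- abs(wlen - target_len) / target_len + 1e-3 * dtheta
  miss[!ok] <- Inf
  best <- which.min(miss)
  strain <- abs(wlen[best] - target_len) / target_len
  if (strain > max_strain) {
    abort(sprintf(
      "Nearest commensurate circumference deviates by %.2f%% (> %.2f%% allowed); adjust radius or rolling angle.",
      100 * strain, 100 * max_strain))
  }
  theta_new <- rad2deg(atan2(w2[best], w1[best]) - phi_a1)
  list(m1 = cand$m1[best], m2 = cand$m2[best],
       radius = wlen[best] / (2 * pi), theta = theta_new,
       circumference = wlen[best], strain = strain)
}

#' Roll planar sites onto a cylinder
#'
#' Maps the planar coordinate along the rolling (circumferential) direction
#' to azimuth by arc length, \eqn{\phi = u / r}, and the transverse planar
#' coordinate to the axial coordinate `z`.  Dipoles are rotated rigidly with
#' the local tangent frame: writing the planar dipole in (circumferential,
#' axial, plane-normal) components \eqn{(d_c, d_t, d_n)}, the Cartesian
#' dipole at azimuth \eqn{\phi} is
#' \deqn{d = d_c(-\sin\phi, \cos\phi, 0) + d_t(0, 0, 1) + d_n(\cos\phi, \sin\phi, 0),}
#' i.e. the out-of-plane component points along the outward cylinder normal.
#' The tube axis is `+z` through the origin and azimuth is measured from
#' `+x`; sites occupy the half-open azimuthal interval `[0, 360)` degrees
#' (no duplicated seam row) and open axial ends `[0, tube_length]`.
#'
#' @param planar A planar site tibble from [build_planar_lattice()].
#' @param cell The [unit_cell()] the sites came from (used to snap the
#'   rolling vector; see [commensurate_rolling()]).
#' @param radius,theta Requested tube radius (nm) and rolling angle
#'   (degrees); snapped to the nearest commensurate rolling vector.
#' @param tube_length Axial length to retain, nm.
#' @param wall Wall label for all sites, `"IW"` or `"OW"`.
#' @param quiet Suppress the commensuration message.
#' @param half_open_z Clip the axial interval half-open `[0, tube_length)`
#'   (used for periodic supercells so the wrap row is not duplicated).
#' @return A `tube_structure`: a tibble with columns `site`, `x`, `y`, `z`
#'   (nm), dipole unit vector `dx`, `dy`, `dz`, `wall`, and provenance
#'   `i`, `j`, `basis`; attributes `wall_radii` (named, nm) and `rolling`
#'   (the snapped rolling description).
#' @export
roll_to_cylinder <- function(planar, cell, radius, theta, tube_length,
                             wall = "IW", quiet = FALSE, half_open_z = FALSE) {
  stopifnot(inherits(cell, "unit_cell"))
  if (!is.numeric(tube_length) || tube_length <= 0) {
    abort("`tube_length` must be > 0 nm.")
  }
  wall <- match.arg(wall, c("IW", "OW"))
  roll <- commensurate_rolling(cell, radius, theta)
  if (!quiet && roll$strain > 1e-9) {
    inform(sprintf(
      "Rolling vector snapped to (%d, %d): radius %.4f nm, theta %.3f deg (mismatch %.3f%%).",
      roll$m1, roll$m2, roll$radius, roll$theta, 100 * roll$strain))
  }
  phi_a1 <- atan2(cell$a1[2], cell$a1[1])
  th <- phi_a1 + deg2rad(roll$theta)
  chat <- c(cos(th), sin(th))        # circumferential direction in plane
  that <- c(-sin(th), cos(th))       # axial direction in plane
  u <- planar$u1 * chat[1] + planar$u2 * chat[2]
  v <- planar$u1 * that[1] + planar$u2 * that[2]
  C <- roll$circumference
  z_hi <- if (half_open_z) tube_length - 1e-9 else tube_length + 1e-9
  keep <- u >= -1e-9 & u < C - 1e-9 & v >= -1e-9 & v <= z_hi
  if (!any(keep)) {
    abort("No sites fall inside one circumference and the requested length; the planar lattice extent is insufficient.")
  }
  p <- planar[keep, ]
  u <- u[keep]; v <- v[keep]
  dc <- p$d1 * chat[1] + p$d2 * chat[2]
  dt <- p$d1 * that[1] + p$d2 * that[2]
  dn <- p$dn
  phi <- u / roll$radius
  out <- tibble(
    site = seq_len(nrow(p)),
    x = roll$radius * cos(phi),
    y = roll$radius * sin(phi),
    z = v,
    dx = -dc * sin(phi) + dn * cos(phi),
    dy =  dc * cos(phi) + dn * sin(phi),
    dz =  dt,
    wall = wall,
    i = p$i, j = p$j, basis = p$basis
  )
  new_tube_structure(out, wall_radii = setNames(roll$radius, wall),
                     rolling = list(roll))
}

new_tube_structure <- function(df, wall_radii, rolling = NULL) {
  structure(df,
            wall_radii = wall_radii,
            rolling = rolling,
            class = c("tube_structure", class(tibble())))
}

#' @export
print.tube_structure <- function(x, ...) {
  wr <- attr(x, "wall_radii")
  cat(sprintf("<tube_structure> %d sites | walls: %s\n", nrow(x),
              paste(sprintf("%s r = %.3f nm (%d sites)", names(wr), wr,
                            vapply(names(wr), function(w) sum(x$wall == w), 1L)),
                    collapse = ", ")))
  NextMethod()
}

#' Wall radii of a tube structure
#'
#' @param structure A `tube_structure`.
#' @return Named numeric vector of wall radii, nm.
#' @export
wall_radii <- function(structure) attr(structure, "wall_radii")

#' Build a single-walled cylindrical aggregate
#'
#' Convenience wrapper: generates a planar lattice large enough to cover one
#' circumference and the requested length, then rolls it with
#' [roll_to_cylinder()].
#'
#' @inheritParams roll_to_cylinder
#' @param cell A [unit_cell()].
#' @param axial Axial boundary treatment.  `"open"` (default): a finite tube
#'   with open ends, clipped to `[0, tube_length]`.  `"periodic"`: a
#'   screw-symmetric supercell for ideal-tube band analysis -- the axial
#'   extent is snapped to a lattice translation vector `T` (nearest to
#'   `tube_length` along the axis) and the structure records the screw
#'   operation (axial period plus twist angle) so that
#'   [build_hamiltonian()] with `periodic = TRUE` couples every site to the
#'   full infinite-tube environment, removing open-end effects from band
#'   positions.
#' @return A `tube_structure`.
#' @export
#' @examples
#' tube <- build_tube(default_unit_cell(), radius = 3.2, theta = 30,
#'                    tube_length = 10, quiet = TRUE)
#' range(sqrt(tube$x^2 + tube$y^2))  # all equal the snapped radius
build_tube <- function(cell, radius, theta, tube_length, wall = "IW",
                       axial = c("open", "periodic"), quiet = FALSE) {
  stopifnot(inherits(cell, "unit_cell"))
  axial <- match.arg(axial)
  roll <- commensurate_rolling(cell, radius, theta)
  phi_a1 <- atan2(cell$a1[2], cell$a1[1])
  th <- phi_a1 + deg2rad(roll$theta)
  screw <- NULL
  if (axial == "periodic") {
    # lattice translation closest to tube_length along the tube axis; its
    # circumferential component becomes a twist of the periodic image
    that_plane <- c(-sin(th), cos(th))
    A <- cbind(cell$a1, cell$a2)
    m0 <- solve(A, tube_length * that_plane)
    cand <- tidyr::expand_grid(p = round(m0[1]) + (-6:6),
                               q = round(m0[2]) + (-6:6))
    T1 <- cand$p * cell$a1[1] + cand$q * cell$a2[1]
    T2 <- cand$p * cell$a1[2] + cand$q * cell$a2[2]
    t_ax <- T1 * that_plane[1] + T2 * that_plane[2]
    t_ci <- T1 * cos(th) + T2 * sin(th)
    ok <- t_ax > 0.5 * tube_length
    if (!any(ok)) abort("No axial lattice translation near `tube_length`.")
    score <- (t_ax - tube_length)^2 + t_ci^2
    score[!ok] <- Inf
    best <- which.min(score)
    tube_length <- t_ax[best]
    screw <- list(Lz = t_ax[best],
                  dphi = t_ci[best] / roll$radius)
  }
  # corners of the (u, v) region to cover, mapped back to cell indices
  corners <- rbind(c(0, 0), c(roll$circumference, 0),
                   c(0, tube_length), c(roll$circumference, tube_length))
  R <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  xy <- corners %*% t(R)  # plane coordinates of the region corners
  A <- cbind(cell$a1, cell$a2)
  ij <- t(solve(A, t(xy)))
  i_rng <- floor(min(ij[, 1])) - 2L; i_max <- ceiling(max(ij[, 1])) + 2L
  j_rng <- floor(min(ij[, 2])) - 2L; j_max <- ceiling(max(ij[, 2])) + 2L
  grid <- tidyr::expand_grid(i = i_rng:i_max, j = j_rng:j_max,
                             basis = seq_len(nrow(cell$basis)))
  planar <- planar_sites(cell, grid)
  out <- roll_to_cylinder(planar, cell, radius, theta, tube_length,
                          wall = wall, quiet = quiet,
                          half_open_z = !is.null(screw))
  attr(out, "screw") <- screw
  out
}

#' Assemble a double-walled tube from two coaxial walls
#'
#' Concatenates an inner- and outer-wall structure (shared axis convention),
#' keeping wall labels.  The wall-to-wall distance is reported; distances
#' outside the 2.3--2.7 nm band that supports stable double-walled packing
#' trigger a warning.
#'
#' @param iw,ow `tube_structure` objects with walls labelled `IW` and `OW`.
#' @return A combined `tube_structure`; the wall-to-wall distance (nm) is
#'   stored in attribute `wall_gap`.
#' @export
assemble_double_wall <- function(iw, ow) {
  if (nrow(iw) == 0L || nrow(ow) == 0L) abort("Both walls must contain sites.")
  r_iw <- unname(wall_radii(iw)["IW"])
  r_ow <- unname(wall_radii(ow)["OW"])
  if (is.na(r_iw) || is.na(r_ow)) {
    abort("`iw` must be labelled IW and `ow` OW (see `build_tube(wall = )`).")
  }
  if (r_ow <= r_iw) abort("Outer-wall radius must exceed inner-wall radius.")
  gap <- r_ow - r_iw
  if (gap < 2.3 || gap > 2.7) {
    warn(sprintf(
      "Wall-to-wall distance %.2f nm lies outside the 2.3-2.7 nm band of stable double-walled packings.",
      gap))
  }
  ow2 <- ow
  ow2$site <- ow2$site + max(iw$site)
  out <- bind_rows(as_tibble(iw), as_tibble(ow2))
  out <- new_tube_structure(out, wall_radii = c(IW = r_iw, OW = r_ow),
                            rolling = c(attr(iw, "rolling"), attr(ow, "rolling")))
  attr(out, "wall_gap") <- gap
  out
}

#' Charge end points of a site's extended dipole
#'
#' Places the \eqn{+q} charge at `position + (l/2) * dipole_axis` and the
#' \eqn{-q} charge at `position - (l/2) * dipole_axis`.
#'
#' @param structure A `tube_structure` (or any tibble with `x,y,z,dx,dy,dz`).
#' @param dipole An [extended_dipole()].
#' @return A list of two matrices `plus` and `minus` (n x 3, nm).
#' @export
site_charge_positions <- function(structure, dipole) {
  stopifnot(inherits(dipole, "extended_dipole"))
  pos <- cbind(structure$x, structure$y, structure$z)
  ax <- cbind(structure$dx, structure$dy, structure$dz)
  h <- dipole$l / 2
  list(plus = pos + h * ax, minus = pos - h * ax)
}
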