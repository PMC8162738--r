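# In-code fixtures shared across the suite.

# Square two-molecule cell with trivially checkable geometry.
square_cell <- function(angle = c(0, 0), tilt = c(0, 0),
                        frac = rbind(c(0, 0), c(0.5, 0.5))) {
  unit_cell(a1 = c(1, 0), a2 = c(0, 1),
            basis = tibble::tibble(frac1 = frac[, 1], frac2 = frac[, 2],
                                   angle = angle, tilt = tilt))
}

# Hand-placed site table (not rolled): positions + unit dipole axes.
make_sites <- function(pos, axes, wall = "IW") {
  pos <- unname(rbind(pos)); axes <- unname(rbind(axes))
  nrm <- sqrt(rowSums(axes^2))
  axes <- axes / nrm
  excitube:::new_tube_structure(
    tibble::tibble(site = seq_len(nrow(pos)),
                   x = pos[, 1], y = pos[, 2], z = pos[, 3],
                   dx = axes[, 1], dy = axes[, 2], dz = axes[, 3],
                   wall = wall,
                   i = NA_integer_, j = NA_integer_, basis = NA_integer_),
    wall_radii = stats::setNames(mean(sqrt(pos[, 1]^2 + pos[, 2]^2)),
                                 wall[1]))
}

# Independent four-term Coulomb oracle for the extended-dipole coupling.
oracle_extended_dipole <- function(pos_i, pos_j, axis_i, axis_j, q, l,
                                   screening = 1) {
  k <- 1.439964548 * 8065.543937
  h <- l / 2
  pp <- sqrt(sum((pos_i + h * axis_i - pos_j - h * axis_j)^2))
  mm <- sqrt(sum((pos_i - h * axis_i - pos_j + h * axis_j)^2))
  pm <- sqrt(sum((pos_i + h * axis_i - pos_j + h * axis_j)^2))
  mp <- sqrt(sum((pos_i - h * axis_i - pos_j - h * axis_j)^2))
  (k / screening) * q^2 * (1 / pp + 1 / mm - 1 / pm - 1 / mp)
}

random_unit_vectors <- function(n) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

# Random site cloud with a minimum separation, for sum-rule checks.
random_structure <- function(n, box = 40, min_sep = 1.2, seed = 1) {
  set.seed(seed)
  pos <- matrix(numeric(0), 0, 3)
  while (nrow(pos) < n) {
    cand <- stats::runif(3, 0, box)
    if (!nrow(pos) || min(sqrt(rowSums(sweep(pos, 2, cand)^2))) >= min_sep) {
      pos <- rbind(pos, cand)
    }
  }
  make_sites(pos, random_unit_vectors(n))
}

# Small ideal tube reused by several files.
small_tube <- function(length = 8, theta = 30, radius = 3.2, wall = "IW",
                       axial = "open") {
  build_tube(default_unit_cell(), radius, theta, length, wall = wall,
             axial = axial, quiet = TRUE)
}
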