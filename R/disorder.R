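#' Gaussian diagonal (energetic) disorder model
#'
#' Per-wall Gaussian distributions of site-energy shifts, as delivered by
#' microelectrostatic calculations on solvated aggregates: both walls have
#' nearly identical mean shifts around +350 cm^-1, with standard deviations
#' of 213 cm^-1 (inner wall) and 231 cm^-1 (outer wall) quantifying the
#' energetic disorder.  Those values are the package defaults.
#'
#' @param mean Named numeric: mean shift per wall, cm^-1.
#' @param sigma Named numeric: standard deviation per wall, cm^-1 (>= 0).
#' @return A `diagonal_disorder` object.
#' @export
diagonal_disorder <- function(mean = c(IW = 350, OW = 350),
                              sigma = c(IW = 213, OW = 231)) {
  if (any(sigma < 0)) abort("`sigma` must be >= 0.")
  if (is.null(names(mean)) || is.null(names(sigma))) {
    abort("`mean` and `sigma` must be named by wall.")
  }
  structure(list(mean = mean, sigma = sigma), class = "diagonal_disorder")
}

#' Structural jitter model (molecular-dynamics surrogate)
#'
#' Independent Gaussian positional displacements (`sigma_pos` per Cartesian
#' axis, nm) and small random rotations of the dipole axes (rotation angle
#' `|N(0, sigma_orient)|` degrees about a uniformly random axis) emulate the
#' packing disorder an equilibrated aggregate acquires in solution.  Jitter
#' is i.i.d. per site; spatial correlations are not modelled.
#'
#' The defaults are calibrated so the surrogate reproduces the qualitative
#' signature of solution-phase packing disorder in these aggregates: the
#' per-site coupling-sum distribution broadens and its mean becomes less
#' negative, blue-shifting the J-band.  Positional jitter alone does the
#' opposite (couplings grow on average because \eqn{1/r^3} is convex), so
#' the default disorder is orientation-dominated.
#'
#' @param sigma_pos Positional standard deviation per axis, nm (>= 0).
#' @param sigma_orient Orientational standard deviation, degrees (>= 0).
#' @return A `structural_jitter` object.
#' @export
structural_jitter <- function(sigma_pos = 0.02, sigma_orient = 20) {
  if (sigma_pos < 0 || sigma_orient < 0) {
    abort("Jitter standard deviations must be >= 0.")
  }
  structure(list(sigma_pos = sigma_pos, sigma_orient = sigma_orient),
            class = "structural_jitter")
}

#' Draw per-site diagonal energy shifts
#'
#' I.i.d. Gaussian draws with each wall's mean and standard deviation;
#' reproducible under a fixed seed.
#'
#' @param structure A `tube_structure` (only `wall` is used).
#' @param model A [diagonal_disorder()].
#' @param seed Optional integer seed (local to this call).
#' @return Numeric vector of shifts (cm^-1), one per site.
#' @export
sample_diagonal_shifts <- function(structure, model = diagonal_disorder(),
                                   seed = NULL) {
  stopifnot(inherits(model, "diagonal_disorder"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  walls <- structure$wall
  unknown <- setdiff(unique(walls), names(model$mean))
  if (length(unknown)) {
    abort(paste0("No disorder parameters for wall(s): ",
                 paste(unknown, collapse = ", ")))
  }
  rnorm(length(walls), mean = model$mean[walls], sd = model$sigma[walls])
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Apply structural jitter to a tube structure
#'
#' Displaces positions by isotropic Gaussian noise and rotates each dipole
#' axis by a small random rotation; dipole unit norms and wall labels are
#' preserved.
#'
#' @param structure A `tube_structure`.
#' @param model A [structural_jitter()].
#' @param seed Optional integer seed (local to this call).
#' @param dipole Optional [extended_dipole()]; when given, sites whose charge
#'   end points would overlap another molecule's (within the 0.1 nm guard)
#'   are re-jittered up to `max_resample` times, then an error is raised.
#' @param max_resample Resampling attempts per overlap check (default 10).
#' @return A jittered `tube_structure`.
#' @export
jitter_structure <- function(structure, model = structural_jitter(),
                             seed = NULL, dipole = NULL, max_resample = 10) {
  stopifnot(inherits(model, "structural_jitter"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  out <- jitter_once(structure, model)
  if (!is.null(dipole)) {
    for (attempt in seq_len(max_resample + 1L)) {
      bad <- overlapping_sites(out, dipole)
      if (!length(bad)) break
      if (attempt > max_resample) {
        abort(sprintf(
          "Jitter left %d site(s) with overlapping charge end points after %d resampling attempts; reduce `sigma_pos`.",
          length(bad), max_resample))
      }
      redo <- jitter_once(structure[bad, , drop = FALSE], model)
      out[bad, c("x", "y", "z", "dx", "dy", "dz")] <-
        redo[, c("x", "y", "z", "dx", "dy", "dz")]
    }
  }
  out
}

jitter_once <- function(structure, model) {
  n <- nrow(structure)
  out <- structure
  if (model$sigma_pos > 0) {
    out$x <- out$x + rnorm(n, sd = model$sigma_pos)
    out$y <- out$y + rnorm(n, sd = model$sigma_pos)
    out$z <- out$z + rnorm(n, sd = model$sigma_pos)
  }
  if (model$sigma_orient > 0) {
    ax <- cbind(out$dx, out$dy, out$dz)
    ax <- rotate_axes_small(ax, deg2rad(model$sigma_orient))
    out$dx <- ax[, 1]; out$dy <- ax[, 2]; out$dz <- ax[, 3]
  }
  out
}

# Indices of sites whose dipole end points fall within the overlap guard of
# another molecule's end points.
overlapping_sites <- function(structure, dipole) {
  n <- nrow(structure)
  if (n < 2L) return(integer(0))
  ends <- site_charge_positions(structure, dipole)
  pts <- rbind(ends$plus, ends$minus)       # 2n x 3; row k maps to site (k-1) %% n + 1
  d2 <- outer(rowSums(pts^2), rowSums(pts^2), "+") - 2 * tcrossprod(pts)
  site_of <- rep(seq_len(n), 2L)
  same <- outer(site_of, site_of, "==")
  hit <- which(!same & d2 < ENDPOINT_GUARD_NM^2, arr.ind = TRUE)
  unique(site_of[hit[, 1]])
}

# Rotate each row of `ax` (unit vectors) about a uniformly random axis by an
# angle |N(0, sigma_rad)| (Rodrigues' formula, vectorised).
rotate_axes_small <- function(ax, sigma_rad) {
  n <- nrow(ax)
  u <- matrix(rnorm(3 * n), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  th <- abs(rnorm(n, sd = sigma_rad))
  ct <- cos(th); st <- sin(th)
  dotp <- rowSums(u * ax)
  crossp <- cbind(u[, 2] * ax[, 3] - u[, 3] * ax[, 2],
                  u[, 3] * ax[, 1] - u[, 1] * ax[, 3],
                  u[, 1] * ax[, 2] - u[, 2] * ax[, 1])
  out <- ax * ct + crossp * st + u * (dotp * (1 - ct))
  out / sqrt(rowSums(out^2))
}

#' Generate a disorder ensemble (snapshot surrogate)
#'
#' Produces `n_snapshots` independent realizations of a base structure:
#' each snapshot is the base structure under [jitter_structure()] (giving
#' off-diagonal, i.e. coupling, disorder) together with a fresh draw of
#' diagonal energy shifts.  Snapshot seeds are derived deterministically
#' from `seed`, so a fixed master seed reproduces the ensemble bitwise.
#'
#' @param structure Base `tube_structure`.
#' @param jitter A [structural_jitter()] (or `NULL` for none).
#' @param diagonal A [diagonal_disorder()] (or `NULL` for none).
#' @param n_snapshots Number of realizations (>= 1).
#' @param seed Master integer seed.
#' @return A `snapshot_ensemble`: list with `snapshots` (list of
#'   `tube_structure`), `shifts` (list of numeric vectors), `base`, and the
#'   models used.
#' @export
generate_ensemble <- function(structure, jitter = structural_jitter(),
                              diagonal = diagonal_disorder(),
                              n_snapshots = 20, seed = 1) {
  n_snapshots <- as.integer(n_snapshots)
  if (is.na(n_snapshots) || n_snapshots < 1L) abort("`n_snapshots` must be >= 1.")
  sub_seeds <- derive_seeds(seed, n_snapshots)
  snaps <- vector("list", n_snapshots)
  shifts <- vector("list", n_snapshots)
  for (s in seq_len(n_snapshots)) {
    snaps[[s]] <- if (is.null(jitter)) structure else {
      jitter_structure(structure, jitter, seed = sub_seeds[s])
    }
    shifts[[s]] <- if (is.null(diagonal)) numeric(nrow(structure)) else {
      sample_diagonal_shifts(structure, diagonal, seed = sub_seeds[s] + 1L)
    }
  }
  structure(list(snapshots = snaps, shifts = shifts, base = structure,
                 jitter = jitter, diagonal = diagonal, seed = seed),
            class = "snapshot_ensemble")
}

# Deterministic 32-bit sub-seed stream from a master seed.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  sample.int(.Machine$integer.max - 2L, n)
}

#' @export
print.snapshot_ensemble <- function(x, ...) {
  cat(sprintf("<snapshot_ensemble> %d snapshots of %d sites (seed %s)\n",
              length(x$snapshots), nrow(x$base), format(x$seed)))
  invisible(x)
}
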