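#' Stick spectrum of exciton states
#'
#' One stick per state at its eigenenergy.  The parallel intensity is the
#' squared axial component of the collective transition dipole,
#' \eqn{\mu_{k,z}^2} (the tube axis is `z`); the perpendicular intensity is
#' \eqn{\mu_{k,x}^2 + \mu_{k,y}^2}.  Wall weights
#' \eqn{w_{k,\mathrm{wall}} = \sum_{n\in\mathrm{wall}} c_{kn}^2} (summing to
#' 1 per state) attribute each stick to the inner/outer wall.
#'
#' @param states An `exciton_states` object.
#' @return A tibble with `energy` (cm^-1), `parallel`, `perpendicular`,
#'   `total` intensities (e^2 nm^2) and one `weight_<wall>` column per wall.
#' @export
stick_spectrum <- function(states) {
  out <- tibble(
    energy = states$energies,
    parallel = states$mu[, 3]^2,
    perpendicular = states$mu[, 1]^2 + states$mu[, 2]^2
  )
  out$total <- out$parallel + out$perpendicular
  for (w in colnames(states$wall_weight)) {
    out[[paste0("weight_", w)]] <- states$wall_weight[, w]
  }
  out
}

#' Broaden a stick spectrum into an absorption spectrum
#'
#' Convolves each stick with a normalized lineshape (Lorentzian by default,
#' Gaussian optional) of full width at half maximum `fwhm`; the integrated
#' area of every channel equals the corresponding total stick weight.
#' Homogeneous broadening is phenomenological here: `fwhm` is a free
#' parameter, optionally different for parallel and perpendicular channels.
#'
#' @param sticks A stick tibble from [stick_spectrum()].
#' @param fwhm Full width at half maximum, cm^-1 (> 0).  A single value, or
#'   a named vector `c(parallel = , perpendicular = )`.
#' @param lineshape `"lorentzian"` or `"gaussian"`.
#' @param grid Energy grid (cm^-1); default covers the sticks +- 5 widths
#'   with `n_grid` points.
#' @param n_grid Number of default grid points.
#' @return An `absorption_spectrum` tibble: `energy`, `wavelength`
#'   (nm, \eqn{10^7/E}), `total`, `parallel`, `perpendicular`, and per-wall
#'   intensity columns; `total = parallel + perpendicular` pointwise.
#' @export
broaden_spectrum <- function(sticks, fwhm = 150, lineshape = c("lorentzian", "gaussian"),
                             grid = NULL, n_grid = 2000) {
  lineshape <- match.arg(lineshape)
  if (any(fwhm <= 0)) abort("`fwhm` must be > 0.")
  fw <- c(parallel = unname(if ("parallel" %in% names(fwhm)) fwhm[["parallel"]] else fwhm[[1]]),
          perpendicular = unname(if ("perpendicular" %in% names(fwhm)) fwhm[["perpendicular"]] else fwhm[[1]]))
  wmax <- max(fw)
  if (is.null(grid)) {
    grid <- seq(min(sticks$energy) - 5 * wmax, max(sticks$energy) + 5 * wmax,
                length.out = n_grid)
  } else if (min(grid) > min(sticks$energy) - 5 * wmax ||
             max(grid) < max(sticks$energy) + 5 * wmax) {
    warn("Energy grid does not cover the sticks +- 5 widths; line wings will be clipped.")
  }
  shape <- function(E0, w) {
    if (lineshape == "lorentzian") {
      (w / (2 * pi)) / ((grid - E0)^2 + (w / 2)^2)
    } else {
      s <- w / (2 * sqrt(2 * log(2)))
      dnorm(grid, mean = E0, sd = s)
    }
  }
  # lineshape matrix per channel width: grid x sticks
  conv <- function(weights, w) {
    out <- numeric(length(grid))
    for (k in seq_len(nrow(sticks))) {
      if (weights[k] != 0) out <- out + weights[k] * shape(sticks$energy[k], w)
    }
    out
  }
  par_ch <- conv(sticks$parallel, fw[["parallel"]])
  per_ch <- conv(sticks$perpendicular, fw[["perpendicular"]])
  out <- tibble(energy = grid, wavelength = 1e7 / grid,
                total = par_ch + per_ch, parallel = par_ch,
                perpendicular = per_ch)
  wall_cols <- grep("^weight_", names(sticks), value = TRUE)
  for (wc in wall_cols) {
    wname <- sub("^weight_", "", wc)
    out[[wname]] <- conv(sticks$parallel * sticks[[wc]], fw[["parallel"]]) +
      conv(sticks$perpendicular * sticks[[wc]], fw[["perpendicular"]])
  }
  structure(out, fwhm = fw, lineshape = lineshape, n_snapshots = 1L,
            class = c("absorption_spectrum", class(tibble())))
}

#' Disorder-averaged absorption spectrum
#'
#' Builds the exciton Hamiltonian of every snapshot in an ensemble (each
#' with its own structural realization and diagonal energy shifts),
#' diagonalizes it, broadens the resulting sticks on a common energy grid,
#' and averages the spectra.  All channels (polarization, per wall) are
#' averaged consistently.
#'
#' @param ensemble A `snapshot_ensemble` from [generate_ensemble()].
#' @param e0 Gas-phase monomer energy, cm^-1.
#' @param dipole An [extended_dipole()].
#' @param fwhm,lineshape,grid,n_grid Passed to [broaden_spectrum()].
#' @param screening,cutoff Passed to [build_hamiltonian()].
#' @return An `absorption_spectrum` (average over snapshots).
#' @export
ensemble_average_spectrum <- function(ensemble, e0 = E0_MONOMER_CM1,
                                      dipole = default_extended_dipole(),
                                      fwhm = 150,
                                      lineshape = "lorentzian",
                                      grid = NULL, n_grid = 2000,
                                      screening = 1, cutoff = NULL) {
  stopifnot(inherits(ensemble, "snapshot_ensemble"))
  n_snap <- length(ensemble$snapshots)
  if (is.null(grid)) {
    # common grid from the base structure's sticks, padded generously for
    # disorder-induced shifts
    base_ham <- build_hamiltonian(ensemble$base, e0 = e0, dipole = dipole,
                                  screening = screening, cutoff = cutoff)
    st0 <- stick_spectrum(diagonalize(base_ham))
    wmax <- max(fwhm)
    pad <- 5 * wmax + 6 * max(c(0, ensemble$diagonal$sigma)) + 0.15 * diff(range(st0$energy))
    grid <- seq(min(st0$energy) - pad, max(st0$energy) + pad,
                length.out = n_grid)
  }
  acc <- NULL
  for (s in seq_len(n_snap)) {
    ham <- build_hamiltonian(ensemble$snapshots[[s]], e0 = e0,
                             shifts = ensemble$shifts[[s]], dipole = dipole,
                             screening = screening, cutoff = cutoff)
    sp <- broaden_spectrum(stick_spectrum(diagonalize(ham)), fwhm = fwhm,
                           lineshape = lineshape, grid = grid)
    if (is.null(acc)) {
      acc <- sp
    } else {
      num <- setdiff(names(sp), c("energy", "wavelength"))
      for (cn in num) acc[[cn]] <- acc[[cn]] + sp[[cn]]
    }
  }
  num <- setdiff(names(acc), c("energy", "wavelength"))
  for (cn in num) acc[[cn]] <- acc[[cn]] / n_snap
  attr(acc, "n_snapshots") <- n_snap
  acc
}

#' Peak metrics of an absorption spectrum
#'
#' Locates local maxima of a chosen channel (quadratically refined on the
#' three points around each grid maximum), their heights and FWHM, the
#' splitting between the two lowest-energy peaks, and the ratio of their
#' integrated band areas over windows of +-`window_fwhm` x FWHM around each
#' peak.
#'
#' @param spectrum An `absorption_spectrum`.
#' @param channel Channel to analyse (default `"parallel"`).
#' @param min_rel_height Ignore maxima below this fraction of the channel
#'   maximum (default 0.02).
#' @param window_fwhm Half-width of the area-integration window in units of
#'   the peak FWHM (default 1.5).
#' @return A list with `peaks` (tibble: energy, height, fwhm, area),
#'   `splitting` (cm^-1 between the two lowest-energy peaks, `NA` if fewer
#'   than two), and `ratio` (area of lowest / second-lowest peak, `NA` if
#'   fewer than two).
#' @export
peak_metrics <- function(spectrum, channel = "parallel",
                         min_rel_height = 0.02, window_fwhm = 1.5) {
  yy <- spectrum[[channel]]
  xx <- spectrum$energy
  ord <- order(xx)
  xx <- xx[ord]; yy <- yy[ord]
  n <- length(xx)
  if (n < 3L || max(yy) <= 0) {
    warn("No peaks found in the requested channel.")
    return(list(peaks = tibble(energy = numeric(), height = numeric(),
                               fwhm = numeric(), area = numeric()),
                splitting = NA_real_, ratio = NA_real_))
  }
  idx <- which(yy[2:(n - 1)] > yy[1:(n - 2)] & yy[2:(n - 1)] >= yy[3:n]) + 1L
  idx <- idx[yy[idx] >= min_rel_height * max(yy)]
  if (!length(idx)) {
    warn("No peaks found in the requested channel.")
    return(list(peaks = tibble(energy = numeric(), height = numeric(),
                               fwhm = numeric(), area = numeric()),
                splitting = NA_real_, ratio = NA_real_))
  }
  refine <- function(k) {
    x3 <- xx[(k - 1):(k + 1)]; y3 <- yy[(k - 1):(k + 1)]
    d <- (y3[1] - 2 * y3[2] + y3[3])
    if (d >= 0) return(c(x3[2], y3[2]))
    delta <- 0.5 * (y3[1] - y3[3]) / d
    xpk <- x3[2] + delta * (x3[3] - x3[2])
    ypk <- y3[2] - 0.25 * (y3[1] - y3[3]) * delta
    c(xpk, ypk)
  }
  pk <- t(vapply(idx, refine, numeric(2)))
  fwhm <- vapply(seq_along(idx), function(m) {
    half <- pk[m, 2] / 2
    k <- idx[m]
    lo <- k; while (lo > 1L && yy[lo] > half) lo <- lo - 1L
    hi <- k; while (hi < n && yy[hi] > half) hi <- hi + 1L
    xl <- if (lo == k) xx[1] else approx(yy[c(lo, lo + 1L)], xx[c(lo, lo + 1L)], half)$y
    xr <- if (hi == k) xx[n] else approx(yy[c(hi - 1L, hi)], xx[c(hi - 1L, hi)], half)$y
    xr - xl
  }, numeric(1))
  area <- vapply(seq_along(idx), function(m) {
    wlo <- pk[m, 1] - window_fwhm * fwhm[m]
    whi <- pk[m, 1] + window_fwhm * fwhm[m]
    sel <- xx >= wlo & xx <= whi
    if (sum(sel) < 2L) return(0)
    sum(diff(xx[sel]) * (head(yy[sel], -1) + tail(yy[sel], -1)) / 2)
  }, numeric(1))
  peaks <- tibble(energy = pk[, 1], height = pk[, 2], fwhm = fwhm,
                  area = area) %>% arrange(.data$energy)
  splitting <- if (nrow(peaks) >= 2L) peaks$energy[2] - peaks$energy[1] else NA_real_
  ratio <- if (nrow(peaks) >= 2L) peaks$area[1] / peaks$area[2] else NA_real_
  list(peaks = peaks, splitting = splitting, ratio = ratio)
}

#' Write a spectrum as TSV
#'
#' Columns: `energy_cm-1`, `wavelength_nm`, `total`, `parallel`,
#' `perpendicular`, and one column per wall.
#'
#' @param spectrum An `absorption_spectrum`.
#' @param path Output file.
#' @param normalize `"none"` (default raw intensities) or `"max"` (peak of
#'   the total channel scaled to 1; all channels share the scale).
#' @return `path`, invisibly.
#' @export
write_spectrum_tsv <- function(spectrum, path, normalize = c("none", "max")) {
  normalize <- match.arg(normalize)
  out <- as_tibble(spectrum)
  num <- setdiff(names(out), c("energy", "wavelength"))
  if (normalize == "max" && max(out$total) > 0) {
    sc <- max(out$total)
    for (cn in num) out[[cn]] <- out[[cn]] / sc
  }
  names(out)[names(out) == "energy"] <- "energy_cm-1"
  names(out)[names(out) == "wavelength"] <- "wavelength_nm"
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
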