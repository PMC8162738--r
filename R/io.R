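#' Write a tube structure as XYZ
#'
#' One pseudo-atom per chromophore site (element by wall: `I` for IW, `O`
#' for OW), coordinates in nm.  With `endpoints = TRUE` two extra
#' pseudo-atoms (`P`/`M`) mark the extended-dipole charge end points.
#'
#' @param structure A `tube_structure`.
#' @param path Output file.
#' @param endpoints Also write charge end points (needs `dipole`).
#' @param dipole An [extended_dipole()], required when `endpoints`.
#' @param comment Second-line comment.
#' @return `path`, invisibly.
#' @export
write_structure_xyz <- function(structure, path, endpoints = FALSE,
                                dipole = NULL, comment = "excitube sites (nm)") {
  el <- ifelse(structure$wall == "IW", "I", "O")
  lines <- sprintf("%s %12.6f %12.6f %12.6f", el, structure$x, structure$y,
                   structure$z)
  if (endpoints) {
    if (is.null(dipole)) abort("`dipole` is required when `endpoints = TRUE`.")
    ends <- site_charge_positions(structure, dipole)
    lines <- c(lines,
               sprintf("P %12.6f %12.6f %12.6f", ends$plus[, 1],
                       ends$plus[, 2], ends$plus[, 3]),
               sprintf("M %12.6f %12.6f %12.6f", ends$minus[, 1],
                       ends$minus[, 2], ends$minus[, 3]))
  }
  writeLines(c(length(lines), comment, lines), path)
  invisible(path)
}

#' Write a tube structure as PDB
#'
#' Sites are written as HETATM pseudo-atoms (one per chromophore), the wall
#' label in the chain ID (`I`/`O`), coordinates in Angstrom (PDB
#' convention; internal nm are multiplied by 10).
#'
#' @param structure A `tube_structure`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_structure_pdb <- function(structure, path) {
  chain <- ifelse(structure$wall == "IW", "I", "O")
  serial <- seq_len(nrow(structure)) %% 100000L
  resno <- seq_len(nrow(structure)) %% 10000L
  lines <- sprintf(
    "HETATM%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    serial, "DYE", "CHR", chain, resno,
    structure$x * 10, structure$y * 10, structure$z * 10, 1, 0, "C")
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# --- snapshot readers ------------------------------------------------------

# Returns a tibble: molecule (residue id), resname, name, x, y, z in nm.
read_coordinates <- function(file, format = c("auto", "pdb", "gro", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(file))
    format <- switch(ext, pdb = "pdb", gro = "gro", xyz = "xyz",
                     abort(sprintf("Cannot infer format from extension '.%s'.", ext)))
  }
  switch(format,
         pdb = read_coords_pdb(file),
         gro = read_coords_gro(file),
         xyz = read_coords_xyz(file))
}

read_coords_pdb <- function(file) {
  pdb <- bio3d::read.pdb(file)
  a <- pdb$atom
  tibble(molecule = a$resno, resname = trimws(a$resid),
         name = trimws(a$elety),
         x = a$x / 10, y = a$y / 10, z = a$z / 10)  # Angstrom -> nm
}

# GROMACS .gro fixed-format: resno(5) resname(5) atom(5) atomno(5) x y z
# (%8.3f each, nm).  Velocities, if present, are ignored.
read_coords_gro <- function(file) {
  lines <- readLines(file)
  if (length(lines) < 3L) abort("Malformed GRO file: fewer than 3 lines.")
  natoms <- as.integer(trimws(lines[2]))
  if (is.na(natoms) || length(lines) < 2L + natoms) {
    abort("Malformed GRO file: atom count does not match content.")
  }
  body <- lines[3:(2 + natoms)]
  tibble(
    molecule = as.integer(substr(body, 1, 5)),
    resname = trimws(substr(body, 6, 10)),
    name = trimws(substr(body, 11, 15)),
    x = as.numeric(substr(body, 21, 28)),
    y = as.numeric(substr(body, 29, 36)),
    z = as.numeric(substr(body, 37, 44))
  )
}

# XYZ (single frame): atoms get names from column 1; molecules must be
# identified via `atoms_per_molecule` since XYZ has no residue field.
read_coords_xyz <- function(file, atoms_per_molecule = NULL) {
  lines <- readLines(file)
  natoms <- as.integer(trimws(lines[1]))
  body <- lines[3:(2 + natoms)]
  parts <- strsplit(trimws(body), "\\s+")
  out <- tibble(
    molecule = NA_integer_,
    resname = "MOL",
    name = vapply(parts, `[[`, "", 1),
    x = as.numeric(vapply(parts, `[[`, "", 2)),
    y = as.numeric(vapply(parts, `[[`, "", 3)),
    z = as.numeric(vapply(parts, `[[`, "", 4))
  )
  if (!is.null(atoms_per_molecule)) {
    out$molecule <- rep(seq_len(ceiling(natoms / atoms_per_molecule)),
                        each = atoms_per_molecule)[seq_len(natoms)]
  } else {
    out$molecule <- seq_len(natoms)
  }
  out
}

#' Read multi-frame XYZ as a list of coordinate tables
#'
#' @param file Multi-frame XYZ file.
#' @param atoms_per_molecule Number of atoms per molecule (assigns molecule
#'   ids block-wise).
#' @return A list of coordinate tibbles, one per frame.
#' @export
read_xyz_frames <- function(file, atoms_per_molecule = NULL) {
  lines <- readLines(file)
  frames <- list()
  k <- 1L
  while (k <= length(lines) && nzchar(trimws(lines[k]))) {
    natoms <- as.integer(trimws(lines[k]))
    if (is.na(natoms)) abort("Malformed XYZ: expected an atom count line.")
    if (k + 1L + natoms > length(lines)) {
      abort("Malformed XYZ: truncated frame.")
    }
    tmp <- tempfile(fileext = ".xyz")
    writeLines(lines[k:(k + 1L + natoms)], tmp)
    frames[[length(frames) + 1L]] <- read_coords_xyz(tmp, atoms_per_molecule)
    unlink(tmp)
    k <- k + 2L + natoms
  }
  if (!length(frames)) abort("No frames found.")
  frames
}

#' Build a tube structure from a coordinate snapshot
#'
#' Reduces an externally produced snapshot (PDB, GRO or XYZ) to one
#' chromophore site per molecule using an atom mapping that names the two
#' atoms spanning the transition-dipole axis (for a cyanine, the ends of
#' the polymethine bridge): the site position is the midpoint of the two
#' mapped atoms, the dipole axis their normalized difference.  Wall labels
#' are assigned by a radial threshold (distance from the `z` axis).
#'
#' @param file Coordinate file, or a coordinate tibble from
#'   [read_xyz_frames()].
#' @param mapping A data frame with columns `resname`, `head`, `tail`
#'   naming the two bridge-end atoms per residue type; residues without a
#'   mapping row are skipped (solvent, ions).
#' @param wall_threshold Radial threshold (nm): sites farther from the axis
#'   are labelled `OW`, closer ones `IW`.
#' @param format Forwarded to the reader (`"auto"` by default).
#' @return A `tube_structure` (wall radii estimated as per-wall mean radius).
#' @export
read_structure_snapshot <- function(file, mapping, wall_threshold = 4.8,
                                    format = "auto") {
  coords <- if (is.data.frame(file)) as_tibble(file) else {
    read_coordinates(file, format)
  }
  mapping <- as_tibble(mapping)
  if (!all(c("resname", "head", "tail") %in% names(mapping))) {
    abort("`mapping` needs columns `resname`, `head`, `tail`.")
  }
  coords <- coords[coords$resname %in% mapping$resname, ]
  if (nrow(coords) == 0L) abort("No mapped residues in the snapshot.")
  sites <- coords %>%
    group_by(.data$molecule, .data$resname) %>%
    dplyr::group_modify(function(g, key) {
      m <- mapping[mapping$resname == key$resname[1], ][1, ]
      h <- g[g$name == m$head, ]
      t <- g[g$name == m$tail, ]
      if (nrow(h) != 1L || nrow(t) != 1L) {
        abort(sprintf("Residue %s (%s): mapped atoms '%s'/'%s' not found exactly once.",
                      format(key$molecule[1]), key$resname[1], m$head, m$tail))
      }
      d <- c(t$x - h$x, t$y - h$y, t$z - h$z)
      dn <- sqrt(sum(d^2))
      if (dn < 1e-9) {
        abort(sprintf("Residue %s: mapped end-point atoms coincide.",
                      format(key$molecule[1])))
      }
      tibble(x = (h$x + t$x) / 2, y = (h$y + t$y) / 2, z = (h$z + t$z) / 2,
             dx = d[1] / dn, dy = d[2] / dn, dz = d[3] / dn)
    }) %>%
    ungroup()
  rad <- sqrt(sites$x^2 + sites$y^2)
  wall <- ifelse(rad > wall_threshold, "OW", "IW")
  out <- tibble(site = seq_len(nrow(sites)),
                x = sites$x, y = sites$y, z = sites$z,
                dx = sites$dx, dy = sites$dy, dz = sites$dz,
                wall = wall, i = NA_integer_, j = NA_integer_,
                basis = NA_integer_)
  wr <- tapply(rad, wall, mean)
  new_tube_structure(out, wall_radii = setNames(as.numeric(wr), names(wr)))
}

# --- configuration ---------------------------------------------------------

#' Default configuration
#'
#' Nested list with every tunable of the workflow: `unit_cell` (lattice
#' vectors, basis), `walls` (radii, rolling angle, length, outer-wall
#' lattice expansion), `extended_dipole` (q, l), `monomer` (gas-phase
#' energy), `disorder` (jitter and per-wall diagonal parameters),
#' `broadening`, and `scan` settings.  [read_config()] merges a YAML file
#' over these defaults.
#'
#' @return A named list.
#' @export
default_config <- function() {
  cell <- default_unit_cell()
  dip <- default_extended_dipole()
  list(
    unit_cell = list(
      a1 = cell$a1, a2 = cell$a2,
      basis = lapply(seq_len(2), function(b) as.list(cell$basis[b, ]))
    ),
    walls = list(r_iw = 3.2, r_ow = 5.7, theta = 30, tube_length = 15,
                 ow_scale = 1.024),
    extended_dipole = list(q = dip$q, l = dip$l),
    monomer = list(e0 = E0_MONOMER_CM1),
    disorder = list(
      sigma_pos = 0.05, sigma_orient = 5,
      diagonal = list(mean_iw = 350, mean_ow = 350,
                      sigma_iw = 213, sigma_ow = 231),
      n_snapshots = 20
    ),
    broadening = list(fwhm = 150, lineshape = "lorentzian"),
    scan = list(thetas = c(20, 30, 40, 55), factors = seq(1, 1.05, 0.005)),
    seed = 1
  )
}

#' Read a YAML configuration file
#'
#' Keys present in the file override [default_config()]; everything else
#' keeps its default.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return A configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  modify_deep(cfg, user)
}

modify_deep <- function(base, user) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(base[[k]]) && !is.null(names(user[[k]]))) {
      base[[k]] <- modify_deep(base[[k]], user[[k]])
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Objects from a configuration
#'
#' @param cfg A configuration list from [read_config()].
#' @return `config_unit_cell()`: the [unit_cell()]; `config_dipole()`: the
#'   [extended_dipole()].
#' @export
config_unit_cell <- function(cfg) {
  basis <- bind_rows(lapply(cfg$unit_cell$basis, as_tibble))
  unit_cell(unlist(cfg$unit_cell$a1), unlist(cfg$unit_cell$a2), basis)
}

#' @rdname config_unit_cell
#' @export
config_dipole <- function(cfg) {
  extended_dipole(cfg$extended_dipole$q, cfg$extended_dipole$l)
}

#' Write a configuration as YAML
#'
#' @param cfg Configuration list.
#' @param path Output file (or `stdout()`).
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Read an atomic charge model from tabular text
#'
#' Whitespace- or tab-separated columns `name`, `x`, `y`, `z` (nm),
#' `q_ground`, `q_excited` (e), `alpha` (nm^3), with a header line.
#'
#' @param path Input file.
#' @param molecule,source Passed to [charge_model()].
#' @return A `charge_model`.
#' @export
read_charge_model <- function(path, molecule = 1L, source = "aggregate") {
  df <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  charge_model(df, molecule = molecule, source = source)
}

#' Write an atomic charge model as tabular text
#'
#' @param model A `charge_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_charge_model <- function(model, path) {
  write.table(as_tibble(model)[c("name", "x", "y", "z", "q_ground",
                                 "q_excited", "alpha")],
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
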