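# Unit system: lengths in nm, charges in elementary charges (e), energies in
# wavenumbers (cm^-1), transition dipoles in e*nm, polarizability volumes in
# nm^3.  With these units every Coulombic energy is k * q1 * q2 / r with a
# single constant k = e^2 / (4 pi eps0 h c), derived from CODATA-2018 values:
#   e^2/(4 pi eps0) = 1.439964548 eV nm      (Coulomb constant times e^2)
#   1 eV            = 8065.543937 cm^-1
#   k               = 1.439964548 * 8065.543937 = 11614.0 cm^-1 nm e^-2

#' Coulomb constant in spectroscopic units
#'
#' Energy of two unit elementary charges 1 nm apart, in wavenumbers:
#' \eqn{k = e^2/(4\pi\varepsilon_0 h c) \approx 1.1614\times 10^4}
#' cm\eqn{^{-1}} nm e\eqn{^{-2}}.
#'
#' @return A length-one numeric.
#' @export
#' @examples
#' k_coulomb_cm1_nm()
k_coulomb_cm1_nm <- function() {
  1.439964548 * 8065.543937
}

# Gas-phase excitation energy of a single C8S3 chromophore (cm^-1); the
# absolute spectral position is anchored to this value.
E0_MONOMER_CM1 <- 19498

# Hard floor on the distance between extended-dipole charge end points of
# different molecules (nm): closer approaches are unphysical overlap.
ENDPOINT_GUARD_NM <- 0.1

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
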