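#' Physical constants used throughout the package
#'
#' `kB_kJmolK` is the Boltzmann constant in kJ/(mol K); `coulomb_kJmolAng`
#' is the Coulomb constant e^2/(4 pi eps0) in kJ A/(mol e^2), so that the
#' potential of a unit point charge at distance r Angstrom in a medium of
#' relative permittivity eps is `coulomb_kJmolAng / (eps * r)` kJ/mol/e.
#'
#' @format Named numeric scalars.
#' @name constants
NULL

#' @rdname constants
#' @export
kB_kJmolK <- 0.0083144621

#' @rdname constants
#' @export
coulomb_kJmolAng <- 1389.35457644382
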