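#' Force-field parameter set for the TIS energy function
#'
#' Returns the complete, editable set of force-field constants used by
#' [evaluateEnergy()] and the propagators. Every constant of the energy
#' function lives here; pass a modified copy to change the model. The
#' defaults are a self-consistent desk-scale calibration chosen to give
#' stable dynamics and correct qualitative behaviour for the small test
#' systems shipped with the package; they are \emph{not} the published
#' transferable-parameter calibration fitted to nucleotide-dimer, hairpin
#' and pseudoknot thermodynamics, which is distributed with its original
#' simulation code.
#'
#' Units: energies kcal/mol, lengths nm, angles rad, temperatures Celsius.
#'
#' @param ... name-value overrides of individual defaults.
#' @return A named list of parameters with class `tisParams`.
#' @examples
#' p <- tisParams(epsHb = 5)
#' p$epsHb
#' @export
tisParams <- function(...) {
  p <- list(
    ## bonded terms
    kBond = 100,          # kcal/mol/nm^2, U = kBond (r - r0)^2
    kAngle = 10,          # kcal/mol, U = kAngle (cos th - cos th0)^2
    ## excluded volume (purely repulsive, WCA-like shifted LJ)
    epsEv = 0.4,          # kcal/mol
    ## hydrogen bonds: U = -eps * exp(-krHb (r-r0)^2 - kthHb sum(dth^2))
    epsHb = 8.0,          # per registered/native secondary base pair
    epsHbNonnative = 5.5, # per dynamically formed non-native pair
    epsHbTertiary = 6.0,  # per registered tertiary H-bond
    krHb = 40,            # nm^-2, radial width of the well
    kthHb = 1.0,          # rad^-2, angular modulation (secondary pairs)
    hbR0 = 0.50,          # nm, generic base-base pair distance
    hbTheta0 = 1.85,      # rad, generic sugar-base-base flank angles
    hbCapture = 0.35,     # nm, pair is an active candidate if |r - r0| < capture
    hbMinSep = 4,         # min residue separation |i-j| for secondary pairs
    ## stacking: U = -eps * exp(-krSt (r - r0)^2)
    epsSt = 3.0,          # per consecutive-nucleotide stack
    epsStTertiary = 2.5,  # per registered tertiary stack
    krSt = 60,            # nm^-2
    stR0 = 0.46,          # nm, generic base-base stacking distance
    ## electrostatics
    eleCutoff = 3.0,      # nm, truncated-and-shifted minimum-image Coulomb
    ## geometry / bead properties
    radii = c(P = 0.21, S = 0.29, A = 0.14, G = 0.14, C = 0.13, U = 0.13,
              MG = 0.23, K = 0.33, CL = 0.35),   # nm
    masses = c(P = 94.97, S = 99.11, A = 134.1, G = 150.1, C = 110.1,
               U = 111.1, MG = 24.31, K = 39.10, CL = 35.45),  # amu
    ## dynamics
    viscosity = 8.9e-4,   # Pa s, water
    contactEnergyKT = 1   # an interaction is "formed" when E < -contactEnergyKT * kB T
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  class(p) <- "tisParams"
  p
}

#' @export
print.tisParams <- function(x, ...) {
  cat("TIS force-field parameter set (", length(unclass(x)), " entries)\n", sep = "")
  str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Write or read a parameter set as JSON
#'
#' @param params a `tisParams` list.
#' @param path file path.
#' @return `readTisParams` returns a `tisParams` list.
#' @export
writeTisParams <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeTisParams
#' @export
readTisParams <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(tisParams, raw)
}
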