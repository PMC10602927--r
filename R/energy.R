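#' @include AllClasses.R params.R topology.R
#' @useDynLib tisfold, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## flatten system + registry + params into the list consumed by the C++ core
.packSystem <- function(system, registry, params = tisParams(),
                        temperatureC = 37) {
  n <- nNucleotides(system)
  bidx <- beadIndices(n)
  nb <- nBeads(system)
  nIon <- nrow(system@ionCoords)
  cst <- tisConstants()
  sq <- rnaSequence(system)
  comp <- outer(sq, sq, FUN = Vectorize(isComplementary))
  sp <- registry@secondaryPairs
  st <- registry@stacks
  thb <- registry@tertiaryHB
  list(
    n = nb + nIon,
    box = system@boxEdge,
    charge = c(system@beadCharge, system@ionCharge),
    radius = c(system@beadRadius, system@ionRadius),
    bondI = as.integer(registry@bonds$i - 1L),
    bondJ = as.integer(registry@bonds$j - 1L),
    bondR0 = registry@bonds$r0,
    angI = as.integer(registry@angles$i - 1L),
    angJ = as.integer(registry@angles$j - 1L),
    angK = as.integer(registry@angles$k - 1L),
    angTh0 = registry@angles$theta0,
    baseIdx = as.integer(bidx[, "B"] - 1L),
    sugarIdx = as.integer(bidx[, "S"] - 1L),
    comp = as.integer(t(comp)),
    natResI = as.integer(sp$resI - 1L),
    natResJ = as.integer(sp$resJ - 1L),
    natR0 = as.numeric(sp$r0),
    natTh1 = as.numeric(sp$theta1),
    natTh2 = as.numeric(sp$theta2),
    natEps = rep(params$epsHb, nrow(sp)),
    thbI = as.integer(thb$i - 1L),
    thbJ = as.integer(thb$j - 1L),
    thbR0 = as.numeric(thb$r0),
    thbEps = rep(params$epsHbTertiary, nrow(thb)),
    stI = as.integer(st$i - 1L),
    stJ = as.integer(st$j - 1L),
    stTert = as.integer(st$tertiary),
    stR0 = as.numeric(st$r0),
    stEps = ifelse(st$tertiary, params$epsStTertiary, params$epsSt),
    kBond = params$kBond, kAngle = params$kAngle, epsEv = params$epsEv,
    epsHbNonnative = params$epsHbNonnative,
    krHb = params$krHb, kthHb = params$kthHb, hbR0 = params$hbR0,
    hbTheta0 = params$hbTheta0, hbCapture = params$hbCapture,
    hbMinSep = as.integer(params$hbMinSep), krSt = params$krSt,
    eleCutoff = params$eleCutoff,
    coulPref = cst$coulomb / waterDielectric(temperatureC),
    kT = cst$kB * (temperatureC + 273.15)
  )
}

.termMask <- function(terms) {
  all6 <- c("bond", "angle", "ev", "hb", "st", "ele")
  if (is.null(terms)) return(rep(TRUE, 6))
  stopifnot(all(terms %in% all6))
  all6 %in% terms
}

#' Evaluate the TIS energy of a configuration
#'
#' Computes \eqn{U_{TIS} = U_{bond} + U_{angle} + U_{EV} + U_{HB} + U_{ST}
#' + U_{ele}} for a coarse-grained system: harmonic bonds and angles about
#' their natural values, purely repulsive excluded volume between all
#' non-bonded site pairs, attractive wells for hydrogen bonds and stacks,
#' and truncated-and-shifted minimum-image Coulomb electrostatics with the
#' temperature-dependent water dielectric. Hydrogen-bond eligibility is
#' dynamic: any canonical or wobble base combination at sufficient
#' sequence separation becomes an active candidate when its base beads
#' enter the well's capture range, with each base restricted to at most
#' one secondary partner (strongest wins; ties go to the lower residue
#' index); registered tertiary hydrogen bonds and stacks are always
#' evaluated.
#'
#' @param system a [CGSystem-class].
#' @param registry an [InteractionRegistry-class].
#' @param coords optional (nBeads + nIons) x 3 coordinate matrix overriding
#'   the system's coordinates (nm).
#' @param params a [tisParams()] list.
#' @param temperatureC temperature, Celsius.
#' @param terms optional character subset of
#'   c("bond","angle","ev","hb","st","ele") to evaluate.
#' @return An [EnergyBreakdown-class].
#' @examples
#' hp <- makeHairpin(4, 4)
#' evaluateEnergy(hp$system, hp$registry)
#' @export
evaluateEnergy <- function(system, registry, coords = NULL,
                           params = tisParams(), temperatureC = 37,
                           terms = NULL) {
  s <- .packSystem(system, registry, params, temperatureC)
  if (is.null(coords)) coords <- rbind(system@beadCoords, system@ionCoords)
  out <- .cg_energy_cpp(coords, s, .termMask(terms), FALSE)
  pairs <- data.frame(resI = out$pairsResI, resJ = out$pairsResJ,
                      energy = out$pairsE, native = out$pairsNative == 1)
  reg <- rbind(
    if (length(out$thbE)) data.frame(kind = "hb", id = seq_along(out$thbE),
                                     energy = out$thbE),
    if (length(out$stE)) data.frame(kind = "stack", id = seq_along(out$stE),
                                    energy = out$stE))
  if (is.null(reg)) reg <- data.frame(kind = character(), id = integer(),
                                      energy = numeric())
  new("EnergyBreakdown", terms = out$terms, total = out$total,
      pairs = pairs, registry = reg)
}

#' Forces of the TIS energy function
#'
#' Analytic negative gradient of [evaluateEnergy()], kcal/mol/nm.
#'
#' @inheritParams evaluateEnergy
#' @return Numeric matrix (nSites x 3).
#' @export
cgForces <- function(system, registry, coords = NULL, params = tisParams(),
                     temperatureC = 37, terms = NULL) {
  s <- .packSystem(system, registry, params, temperatureC)
  if (is.null(coords)) coords <- rbind(system@beadCoords, system@ionCoords)
  .cg_energy_cpp(coords, s, .termMask(terms), TRUE)$forces
}

#' Unscreened-by-cutoff Coulomb pair energy in water
#'
#' Energy of two point charges at separation r in implicit water,
#' \eqn{U = q_1 q_2 e^2 / (4\pi\epsilon_0 \epsilon(T) r)}, in kcal/mol. At
#' r equal to the Bjerrum length the magnitude for unit opposite charges
#' equals the thermal energy k_B T.
#'
#' @param r separation, nm.
#' @param q1,q2 charges in units of e.
#' @param temperatureC temperature, Celsius.
#' @return Energy in kcal/mol.
#' @export
coulombPairEnergy <- function(r, q1 = 1, q2 = -1, temperatureC = 37) {
  stopifnot(all(r > 0))
  tisConstants()$coulomb * q1 * q2 / (waterDielectric(temperatureC) * r)
}
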