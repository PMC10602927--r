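#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Coarse-grained RNA system with explicit ions
#'
#' Three-interaction-site representation of one RNA chain: a phosphate (P),
#' sugar (S) and base (B) bead per nucleotide, except the 5'-terminal
#' nucleotide which has no phosphate, plus explicit Mg2+, K+ and Cl- ions
#' in a cubic periodic box. Coordinates are in nm; charges in units of the
#' elementary charge (P = -1, Mg2+ = +2, K+ = +1, Cl- = -1).
#'
#' @slot sequence character vector of nucleotide letters (A/C/G/U).
#' @slot beadCoords numeric matrix (nBeads x 3), nm.
#' @slot beadResidue integer, residue index (1-based) of each bead.
#' @slot beadType character, "P", "S" or "B" per bead.
#' @slot beadCharge,beadRadius numeric per bead (e, nm).
#' @slot ionCoords numeric matrix (nIons x 3), nm.
#' @slot ionSpecies character, "MG", "K" or "CL".
#' @slot ionCharge,ionRadius numeric per ion (e, nm).
#' @slot boxEdge numeric(1), cubic box edge in nm; `Inf` for an open system.
#' @slot numberingOffset integer(1), residue number of the first nucleotide.
#' @export
setClass("CGSystem", representation(
  sequence = "character",
  beadCoords = "matrix",
  beadResidue = "integer",
  beadType = "character",
  beadCharge = "numeric",
  beadRadius = "numeric",
  ionCoords = "matrix",
  ionSpecies = "character",
  ionCharge = "numeric",
  ionRadius = "numeric",
  boxEdge = "numeric",
  numberingOffset = "integer"
))

setValidity("CGSystem", function(object) {
  msgs <- character()
  n <- length(object@sequence)
  nb <- nrow(object@beadCoords)
  if (!all(object@sequence %in% c("A", "C", "G", "U")))
    msgs <- c(msgs, "sequence letters must be A/C/G/U")
  if (nb != 3L * n - 1L)
    msgs <- c(msgs, sprintf("expected %d beads (3N-1) for %d nt, got %d",
                            3L * n - 1L, n, nb))
  if (length(object@beadResidue) != nb || length(object@beadType) != nb ||
      length(object@beadCharge) != nb || length(object@beadRadius) != nb)
    msgs <- c(msgs, "per-bead slots must have one entry per bead")
  if (!all(object@beadType %in% c("P", "S", "B")))
    msgs <- c(msgs, "bead types must be P/S/B")
  if (any(object@beadType[object@beadResidue == 1L] == "P"))
    msgs <- c(msgs, "5'-terminal nucleotide must not carry a phosphate bead")
  if (!all(is.finite(object@beadCoords)))
    msgs <- c(msgs, "bead coordinates must be finite")
  if (nrow(object@ionCoords) != length(object@ionSpecies) ||
      length(object@ionSpecies) != length(object@ionCharge) ||
      length(object@ionCharge) != length(object@ionRadius))
    msgs <- c(msgs, "per-ion slots must have one entry per ion")
  if (nrow(object@ionCoords) && !all(is.finite(object@ionCoords)))
    msgs <- c(msgs, "ion coordinates must be finite")
  if (length(object@boxEdge) != 1L || object@boxEdge <= 0)
    msgs <- c(msgs, "boxEdge must be a single positive number (Inf for open)")
  if (is.finite(object@boxEdge)) {
    if (any(object@beadCoords < 0) || any(object@beadCoords > object@boxEdge) ||
        (nrow(object@ionCoords) &&
         (any(object@ionCoords < 0) || any(object@ionCoords > object@boxEdge))))
      msgs <- c(msgs, "coordinates must be wrapped into [0, boxEdge]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Registry of native and bonded interactions
#'
#' Holds the bonded topology (bonds, angles with natural values), the
#' native secondary base pairs grouped into helices, registered tertiary
#' hydrogen bonds and stacks, the consecutive-nucleotide stack list, named
#' tertiary-element groupings (e.g. a triple helix, a tetraloop/receptor
#' contact or a guanosine-binding site), labelled strand segments used to
#' name mispaired helices, and the list of crystallographic Mg2+-binding
#' nucleotides.
#'
#' Interaction tables use bead indices into the companion [CGSystem-class]
#' and carry natural distances/angles (Go-style, measured from the native
#' frame) plus well depths. Element groups are named lists of interaction
#' ids; helix groups are disjoint over secondary pairs, while element
#' groups may share interactions.
#'
#' @slot bonds data.frame(i, j, r0).
#' @slot angles data.frame(i, j, k, theta0).
#' @slot secondaryPairs data.frame(resI, resJ, helix, r0, theta1, theta2).
#' @slot tertiaryHB data.frame(i, j, r0, label).
#' @slot stacks data.frame(i, j, r0, tertiary, label).
#' @slot elements named list; each entry is a list with integer vectors
#'   `pairs` (rows of secondaryPairs), `hb` (rows of tertiaryHB) and
#'   `stacks` (rows of stacks).
#' @slot segments named list of integer residue vectors.
#' @slot mgSites integer, residue indices of crystal Mg2+ sites.
#' @export
setClass("InteractionRegistry", representation(
  bonds = "data.frame",
  angles = "data.frame",
  secondaryPairs = "data.frame",
  tertiaryHB = "data.frame",
  stacks = "data.frame",
  elements = "list",
  segments = "list",
  mgSites = "integer"
))

setValidity("InteractionRegistry", function(object) {
  msgs <- character()
  need <- function(df, cols, nm) {
    if (!all(cols %in% names(df)))
      msgs <<- c(msgs, paste0(nm, " must have columns ", paste(cols, collapse = ",")))
  }
  need(object@bonds, c("i", "j", "r0"), "bonds")
  need(object@angles, c("i", "j", "k", "theta0"), "angles")
  need(object@secondaryPairs, c("resI", "resJ", "helix", "r0"), "secondaryPairs")
  need(object@tertiaryHB, c("i", "j", "r0"), "tertiaryHB")
  need(object@stacks, c("i", "j", "r0", "tertiary"), "stacks")
  sp <- object@secondaryPairs
  if (nrow(sp)) {
    key <- paste(pmin(sp$resI, sp$resJ), pmax(sp$resI, sp$resJ))
    if (anyDuplicated(key))
      msgs <- c(msgs, "helix groups must be disjoint sets of base pairs")
  }
  if (length(msgs)) msgs else TRUE
})

#' Simulation protocol
#'
#' Bundles everything that defines a run: thermodynamic state, box, ion
#' concentrations, friction, the integration step and the save schedule.
#' Ion counts are derived as `round(concentration * boxVolume * N_A)` with
#' the Cl- count set by charge neutrality.
#'
#' @slot temperatureC temperature, Celsius.
#' @slot boxEdge cubic box edge, nm.
#' @slot cMg,cK ion concentrations, mM.
#' @slot viscosity solvent viscosity, Pa s.
#' @slot frictionScale fraction of `viscosity` actually applied (1 = full;
#'   0.01 reproduces the low-friction equilibrium-sampling protocol).
#' @slot dt integration time step, ps.
#' @slot saveInterval save a frame every this many steps.
#' @slot nSteps total number of steps (must be a multiple of saveInterval).
#' @slot maxDisp per-step displacement safety threshold, nm.
#' @slot seed integer random seed.
#' @export
setClass("SimulationProtocol", representation(
  temperatureC = "numeric", boxEdge = "numeric",
  cMg = "numeric", cK = "numeric",
  viscosity = "numeric", frictionScale = "numeric",
  dt = "numeric", saveInterval = "integer", nSteps = "integer",
  maxDisp = "numeric", seed = "integer"
))

setValidity("SimulationProtocol", function(object) {
  msgs <- character()
  if (object@nSteps %% object@saveInterval != 0L)
    msgs <- c(msgs, "saveInterval must divide nSteps")
  if (object@dt <= 0) msgs <- c(msgs, "dt must be positive")
  if (object@cMg < 0 || object@cK < 0) msgs <- c(msgs, "concentrations must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Time-ordered trajectory of a coarse-grained system
#'
#' Frames hold RNA bead coordinates followed by ion coordinates
#' (nm, wrapped into the box). Frame 0 is the supplied initial condition;
#' times are in ms, strictly increasing and uniformly spaced.
#'
#' @slot frames numeric array (nFrames x nSites x 3), nm.
#' @slot times numeric, frame times in ms.
#' @slot nRnaBeads integer, number of RNA beads (leading rows of a frame).
#' @slot boxEdge numeric, nm.
#' @slot protocol the [SimulationProtocol-class] that produced it (or NULL
#'   placeholder protocol for synthetic trajectories).
#' @slot stepOffset integer, absolute step index of frame 0 (for restarts).
#' @slot finalVelocities numeric matrix or NULL (Langevin restarts).
#' @slot nRejected integer, count of safety-halved steps.
#' @export
setClass("Trajectory", representation(
  frames = "array", times = "numeric", nRnaBeads = "integer",
  boxEdge = "numeric", protocol = "ANY", stepOffset = "numeric",
  finalVelocities = "ANY", nRejected = "integer"
))

setValidity("Trajectory", function(object) {
  msgs <- character()
  if (length(dim(object@frames)) != 3L || dim(object@frames)[3] != 3L)
    msgs <- c(msgs, "frames must be an (nFrames x nSites x 3) array")
  if (dim(object@frames)[1] != length(object@times))
    msgs <- c(msgs, "one time per frame required")
  dt <- diff(object@times)
  if (length(dt) && (any(dt <= 0) || diff(range(dt)) > 1e-9 * max(dt)))
    msgs <- c(msgs, "frame times must be strictly increasing and uniform")
  if (length(msgs)) msgs else TRUE
})

#' Energy breakdown of a configuration
#'
#' Per-term totals of the TIS energy function, with the hydrogen-bond and
#' stacking terms split into secondary and tertiary parts, and
#' per-interaction energies for every registry entry and every dynamically
#' formed base pair.
#'
#' @slot terms named numeric: bond, angle, ev, hbSecondary, hbTertiary,
#'   stSecondary, stTertiary, ele (kcal/mol).
#' @slot total numeric, sum of terms.
#' @slot pairs data.frame of currently active base pairs
#'   (resI, resJ, energy, native).
#' @slot registry data.frame of per-registered-interaction energies
#'   (kind, id, energy).
#' @export
setClass("EnergyBreakdown", representation(
  terms = "numeric", total = "numeric",
  pairs = "data.frame", registry = "data.frame"
))

#' Multi-exponential collapse fit
#'
#' Result of fitting an ensemble-averaged radius-of-gyration decay with a
#' sum of n exponential phases whose amplitudes are constrained to sum to
#' one: \deqn{R_g(t) = R_{gU} - (R_{gU} - R_{gF}) \sum_i \Phi_i (1 -
#' e^{-t/\tau_i}).}
#'
#' @slot rgU,rgF unfolded and folded plateau Rg, nm.
#' @slot phi amplitudes, sum to 1.
#' @slot tau time constants in ms, sorted ascending.
#' @slot nPhases integer.
#' @slot rss residual sum of squares.
#' @slot aic Akaike information criterion.
#' @slot ci matrix of approximate 95% confidence half-widths (or NA).
#' @slot nObs number of fitted points.
#' @export
setClass("KineticFit", representation(
  rgU = "numeric", rgF = "numeric", phi = "numeric", tau = "numeric",
  nPhases = "integer", rss = "numeric", aic = "numeric",
  ci = "ANY", nObs = "integer"
))

setValidity("KineticFit", function(object) {
  msgs <- character()
  if (abs(sum(object@phi) - 1) > 1e-8)
    msgs <- c(msgs, "amplitudes must sum to 1")
  if (any(object@tau <= 0) || is.unsorted(object@tau))
    msgs <- c(msgs, "time constants must be positive and sorted ascending")
  if (object@rgU <= object@rgF)
    msgs <- c(msgs, "rgU must exceed rgF")
  if (length(msgs)) msgs else TRUE
})
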