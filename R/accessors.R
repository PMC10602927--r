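#' @include AllClasses.R
NULL

#' Accessors for coarse-grained systems and trajectories
#'
#' `nNucleotides` and `nBeads` count residues and RNA beads; `beadCoords`
#' and `ionCoords` return coordinate matrices (nm); `rnaSequence` the
#' nucleotide letters; `residueNumbers` the author numbering
#' (offset-based); `boxEdge` the periodic box edge; `totalCharge` the net
#' charge of RNA plus ions (e); `nFrames` and `frameCoords` access
#' trajectory frames; `frameTimes` the frame times in ms.
#'
#' @param x a [CGSystem-class] or [Trajectory-class].
#' @param i frame index (1-based).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nNucleotides", function(x) standardGeneric("nNucleotides"))
#' @rdname accessors
#' @export
setMethod("nNucleotides", "CGSystem", function(x) length(x@sequence))

#' @rdname accessors
#' @export
setGeneric("nBeads", function(x) standardGeneric("nBeads"))
#' @rdname accessors
#' @export
setMethod("nBeads", "CGSystem", function(x) nrow(x@beadCoords))

#' @rdname accessors
#' @export
setGeneric("beadCoords", function(x) standardGeneric("beadCoords"))
#' @rdname accessors
#' @export
setMethod("beadCoords", "CGSystem", function(x) x@beadCoords)

#' @rdname accessors
#' @export
setGeneric("ionCoords", function(x) standardGeneric("ionCoords"))
#' @rdname accessors
#' @export
setMethod("ionCoords", "CGSystem", function(x) x@ionCoords)

#' @rdname accessors
#' @export
setGeneric("rnaSequence", function(x) standardGeneric("rnaSequence"))
#' @rdname accessors
#' @export
setMethod("rnaSequence", "CGSystem", function(x) x@sequence)

#' @rdname accessors
#' @export
setGeneric("residueNumbers", function(x) standardGeneric("residueNumbers"))
#' @rdname accessors
#' @export
setMethod("residueNumbers", "CGSystem", function(x)
  seq_along(x@sequence) + x@numberingOffset - 1L)

#' @rdname accessors
#' @export
setGeneric("boxEdge", function(x) standardGeneric("boxEdge"))
#' @rdname accessors
#' @export
setMethod("boxEdge", "CGSystem", function(x) x@boxEdge)
#' @rdname accessors
#' @export
setMethod("boxEdge", "Trajectory", function(x) x@boxEdge)

#' @rdname accessors
#' @export
setGeneric("totalCharge", function(x) standardGeneric("totalCharge"))
#' @rdname accessors
#' @export
setMethod("totalCharge", "CGSystem", function(x)
  sum(x@beadCharge) + sum(x@ionCharge))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@frames)[1])

#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setMethod("frameTimes", "Trajectory", function(x) x@times)

#' @rdname accessors
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))
#' @rdname accessors
#' @export
setMethod("frameCoords", "Trajectory", function(x, i) {
  stopifnot(i >= 1, i <= dim(x@frames)[1])
  matrix(x@frames[i, , ], ncol = 3L)
})

setMethod("show", "CGSystem", function(object) {
  cat("CGSystem:", length(object@sequence), "nt,",
      nrow(object@beadCoords), "beads,",
      nrow(object@ionCoords), "ions",
      sprintf("(%d Mg2+, %d K+, %d Cl-)",
              sum(object@ionSpecies == "MG"),
              sum(object@ionSpecies == "K"),
              sum(object@ionSpecies == "CL")), "\n")
  cat("  box edge:", object@boxEdge, "nm; numbering",
      object@numberingOffset, "..",
      object@numberingOffset + length(object@sequence) - 1L, "\n")
  cat("  net charge:", totalCharge(object), "e\n")
})

setMethod("show", "InteractionRegistry", function(object) {
  cat("InteractionRegistry:", nrow(object@secondaryPairs), "secondary pairs in",
      length(unique(object@secondaryPairs$helix)), "helices;",
      nrow(object@tertiaryHB), "tertiary H-bonds;",
      nrow(object@stacks), "stacks;",
      length(object@elements), "elements;",
      length(object@segments), "segments\n")
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", dim(object@frames)[1], "frames x",
      dim(object@frames)[2], "sites;",
      "t =", min(object@times), "..", max(object@times), "ms\n")
})

setMethod("show", "EnergyBreakdown", function(object) {
  cat("TIS energy breakdown (kcal/mol):\n")
  print(round(object@terms, 4))
  cat("  total:", round(object@total, 4), "\n")
})

setMethod("show", "KineticFit", function(object) {
  cat(sprintf("KineticFit: %d phases, RgU = %.3f nm, RgF = %.3f nm\n",
              object@nPhases, object@rgU, object@rgF))
  for (i in seq_len(object@nPhases))
    cat(sprintf("  phase %d: Phi = %.3f, tau = %.4g ms\n",
                i, object@phi[i], object@tau[i]))
  cat(sprintf("  RSS = %.4g, AIC = %.4g (n = %d)\n",
              object@rss, object@aic, object@nObs))
})
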