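## Programmatic fixtures shared across test files.

## A "ladder" system: designated base pairs are placed facing each other at
## the generic hydrogen-bond distance with sensible flank angles; all other
## residues are parked far away on a line so they form nothing.
## pairs: data.frame(resI, resJ); registryPairs: the pairs registered as
## native (with helix label); formedPairs: the pairs realized in the
## returned coordinates.
buildLadder <- function(sequence, registryPairs, formedPairs,
                        segments = list(), params = tisParams()) {
  n <- length(sequence)
  bidx <- beadIndices(n)
  coords <- matrix(NA_real_, 3 * n - 1, 3)
  placed <- rep(FALSE, n)
  z <- 0
  for (k in seq_len(nrow(formedPairs))) {
    i <- formedPairs$resI[k]; j <- formedPairs$resJ[k]
    coords[bidx[i, "B"], ] <- c(0, 0.3, z)
    coords[bidx[i, "S"], ] <- c(-0.4, 0.55, z)
    coords[bidx[j, "B"], ] <- c(0, -0.3, z)
    coords[bidx[j, "S"], ] <- c(-0.4, -0.55, z)
    placed[c(i, j)] <- TRUE
    z <- z + 0.55
  }
  far <- 8
  for (r in which(!placed)) {
    coords[bidx[r, "S"], ] <- c(far, 0, 0)
    coords[bidx[r, "B"], ] <- c(far + 0.4, 0, 0)
    far <- far + 2.5
  }
  for (r in 2:n)
    coords[bidx[r, "P"], ] <-
      (coords[bidx[r - 1, "S"], ] + coords[bidx[r, "S"], ]) / 2 +
      c(0, 0, 0.12)
  system <- newCGSystemForTest(sequence, coords, params)
  ## natural values for registered pairs measured from an idealized
  ## reference in which the *registered* pairs are the formed ones
  refCoords <- coords
  registry <- buildRegistry(system, refCoords, pairs = registryPairs,
                            segments = segments)
  ## use generic well geometry for the registered pairs so that formation
  ## is judged by the same criterion whether or not they are realized here
  if (nrow(registry@secondaryPairs)) {
    registry@secondaryPairs$r0 <- params$hbR0
    registry@secondaryPairs$theta1 <- params$hbTheta0
    registry@secondaryPairs$theta2 <- params$hbTheta0
  }
  list(system = system, registry = registry, coords = coords)
}

## thin wrapper because newCGSystem is internal
newCGSystemForTest <- function(sequence, coords, params = tisParams()) {
  tisfold:::newCGSystem(sequence, coords, boxEdge = Inf, params = params)
}

## ladder geometry tuned so a formed pair sits at the generic well bottom
ladderParams <- function() {
  ## B-B distance in buildLadder is 0.6 nm; generic hbR0 default is 0.50,
  ## so override to match the fixture geometry
  tisParams(hbR0 = 0.6, hbTheta0 = 2.13)
}

## Minimal single-chain RNA PDB text (coordinates in Angstrom).
## residues: list of lists(resno, resid, atoms = data.frame(name, x, y, z))
writePDBFixture <- function(residues, path) {
  lines <- character()
  serial <- 1L
  for (res in residues) {
    for (a in seq_len(nrow(res$atoms))) {
      at <- res$atoms[a, ]
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        serial, at$name, res$resid, res$resno, at$x, at$y, at$z,
        substr(at$name, 1, 1)))
      serial <- serial + 1L
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

## a clean 4-nt GCGC chain along z: P, C4' and three base atoms per residue
toyPDBResidues <- function() {
  res <- list()
  base3 <- function(x0, y0, z0)
    data.frame(name = c("N1", "C2", "N3"),
               x = x0 + c(0, 1.2, 2.4), y = y0 + c(0, 0.8, 0), z = z0)
  for (r in 1:4) {
    z <- (r - 1) * 6
    atoms <- rbind(
      if (r > 1) data.frame(name = "P", x = 0, y = 0, z = z) else NULL,
      data.frame(name = "C4'", x = 2, y = 1, z = z + 1),
      base3(4, 0, z + 2))
    res[[r]] <- list(resno = r + 11L, resid = c("G", "C", "G", "C")[r],
                     atoms = atoms)
  }
  res
}

## a trajectory of n identical frames holding the system's coordinates
staticTrajectory <- function(system, nFrames = 3, dtMs = 0.1) {
  X <- rbind(beadCoords(system), system@ionCoords)
  fr <- array(NA_real_, c(nFrames, nrow(X), 3))
  for (f in seq_len(nFrames)) fr[f, , ] <- X
  proto <- simulationProtocol(nSteps = max(1L, nFrames - 1L),
                              saveInterval = 1L, dt = dtMs * 1e9)
  new("Trajectory", frames = fr, times = (seq_len(nFrames) - 1) * dtMs,
      nRnaBeads = nBeads(system), boxEdge = system@boxEdge,
      protocol = proto, stepOffset = 0, finalVelocities = NULL,
      nRejected = 0L)
}

## quick whole-suite default parameter set
.p <- tisParams()
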