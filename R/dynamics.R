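#' @include AllClasses.R energy.R
NULL

#' Define a simulation protocol
#'
#' Two protocols cover a folding study: low-friction underdamped Langevin
#' sampling of the Mg2+-free unfolded ensemble (frictionScale = 0.01), and
#' Brownian dynamics at full water viscosity after a Mg2+ jump. Ion counts
#' follow from concentration times box volume; Cl- enforces neutrality.
#'
#' @param temperatureC temperature, Celsius (default 37).
#' @param boxEdge cubic box edge, nm (default 35).
#' @param cMg,cK Mg2+ and K+ concentrations, mM (defaults 5 and 12).
#' @param viscosity solvent viscosity, Pa s (default water, 8.9e-4).
#' @param frictionScale fraction of `viscosity` applied (default 1).
#' @param dt time step, ps (default 0.2).
#' @param saveInterval steps between saved frames.
#' @param nSteps total steps (multiple of saveInterval).
#' @param maxDisp per-step displacement safety threshold, nm (default 0.3);
#'   a step moving any site farther is redrawn at half the step size.
#' @param seed integer random seed.
#' @return A [SimulationProtocol-class].
#' @export
simulationProtocol <- function(temperatureC = 37, boxEdge = 35, cMg = 5,
                               cK = 12, viscosity = 8.9e-4,
                               frictionScale = 1, dt = 0.2,
                               saveInterval = 1000L, nSteps = 100000L,
                               maxDisp = 0.3, seed = 1L) {
  new("SimulationProtocol", temperatureC = temperatureC, boxEdge = boxEdge,
      cMg = cMg, cK = cK, viscosity = viscosity,
      frictionScale = frictionScale, dt = dt,
      saveInterval = as.integer(saveInterval), nSteps = as.integer(nSteps),
      maxDisp = maxDisp, seed = as.integer(seed))
}

#' Ion counts implied by a protocol
#'
#' `count = round(concentration * boxVolume * N_A)` for Mg2+ and K+; the
#' Cl- count is set by charge neutrality against the RNA phosphates. If
#' the concentration-derived cations cannot neutralize the RNA (tiny
#' boxes), additional neutralizing K+ counterions are added.
#'
#' @param protocol a [SimulationProtocol-class].
#' @param nPhosphates number of P beads (charge -1 each).
#' @return Named integer vector (MG, K, CL).
#' @examples
#' ionCounts(simulationProtocol(boxEdge = 35, cMg = 5, cK = 12), 195)
#' @export
ionCounts <- function(protocol, nPhosphates = 0L) {
  v <- protocol@boxEdge^3                       # nm^3
  f <- tisConstants()$perNm3PerMolar * 1e-3     # counts per mM per nm^3
  nMg <- round(protocol@cMg * v * f)
  nK <- round(protocol@cK * v * f)
  nCl <- 2 * nMg + nK - nPhosphates
  if (nCl < 0) { nK <- nK - nCl; nCl <- 0 }
  c(MG = as.integer(nMg), K = as.integer(nK), CL = as.integer(nCl))
}

#' Insert ions into a system
#'
#' Places the protocol's Mg2+, K+ and Cl- ions (see [ionCounts()]) at
#' uniform random non-overlapping positions in the box. Overlap means
#' closer than the sum of excluded-volume radii to any existing site.
#' RNA coordinates are untouched, so calling this on the final frame of a
#' Mg2+-free equilibrium run realizes the concentration-jump protocol.
#'
#' @param system a [CGSystem-class] (existing ions are replaced).
#' @param protocol a [SimulationProtocol-class].
#' @param seed integer seed for placement.
#' @param maxTries placement attempts per ion before giving up.
#' @param params a [tisParams()] list (ion radii).
#' @return The system with ions added; net charge is zero.
#' @export
placeIons <- function(system, protocol, seed = protocol@seed,
                      maxTries = 2000L, params = tisParams()) {
  nP <- sum(system@beadType == "P")
  cnt <- ionCounts(protocol, nP)
  species <- rep(c("MG", "K", "CL"), cnt)
  chg <- rep(c(2, 1, -1), cnt)
  rad <- unname(params$radii[species])
  L <- protocol@boxEdge
  sys <- system
  sys@boxEdge <- L
  sys@beadCoords <- system@beadCoords -
    L * floor(system@beadCoords / L)
  nIon <- length(species)
  pos <- matrix(NA_real_, nIon, 3)
  occ <- sys@beadCoords
  occR <- sys@beadRadius
  set.seed(seed)
  for (k in seq_len(nIon)) {
    ok <- FALSE
    for (t in seq_len(maxTries)) {
      p <- runif(3, 0, L)
      d <- sweep(occ, 2, p)
      d <- d - L * round(d / L)
      if (all(sqrt(rowSums(d^2)) >= 0.8 * (occR + rad[k]))) { ok <- TRUE; break }
    }
    if (!ok) stop("ion insertion failed after ", maxTries,
                  " tries (box too crowded)")
    pos[k, ] <- p
    occ <- rbind(occ, p)
    occR <- c(occR, rad[k])
  }
  sys@ionCoords <- pos
  sys@ionSpecies <- species
  sys@ionCharge <- chg
  sys@ionRadius <- rad
  validObject(sys)
  if (abs(totalCharge(sys)) > 1e-9)
    stop("charge neutrality violated after ion placement")
  sys
}

## per-site Stokes friction (amu/ps) and masses (amu)
.siteFriction <- function(system, protocol, params) {
  rad <- c(system@beadRadius, system@ionRadius)
  gammaSI <- 6 * pi * protocol@viscosity * protocol@frictionScale *
    rad * 1e-9                      # kg/s
  gammaSI * 6.02214076e14           # amu/ps
}

.siteMasses <- function(system, params) {
  key <- ifelse(system@beadType == "B", system@sequence[system@beadResidue],
                system@beadType)
  unname(params$masses[c(key, system@ionSpecies)])
}

.makeTrajectory <- function(frames, protocol, nRna, stepOffset,
                            finalVel = NULL, nRejected = 0L) {
  nf <- dim(frames)[1]
  idx <- stepOffset + (seq_len(nf) - 1L) * protocol@saveInterval
  new("Trajectory", frames = frames, times = idx * protocol@dt * 1e-9,
      nRnaBeads = as.integer(nRna), boxEdge = protocol@boxEdge,
      protocol = protocol, stepOffset = stepOffset,
      finalVelocities = finalVel, nRejected = as.integer(nRejected))
}

#' Underdamped Langevin equilibrium sampling
#'
#' Samples configurations at the target temperature with the BAOAB
#' integrator and a friction coefficient reduced to `frictionScale` of the
#' solvent value (1% in the sampling protocol), which accelerates
#' configurational diffusion without changing the sampled distribution.
#' Used to prepare the Mg2+-free unfolded ensemble whose saved frames
#' serve as independent initial conditions for folding runs (see
#' [selectSeparatedFrames()]).
#'
#' @param system a [CGSystem-class]; must contain no Mg2+ ions.
#' @param registry an [InteractionRegistry-class].
#' @param protocol a [SimulationProtocol-class] (cMg must be 0).
#' @param params a [tisParams()] list.
#' @param velocities optional initial velocity matrix (nm/ps); default
#'   Maxwell-Boltzmann draw.
#' @param stepOffset absolute step index of the initial frame (restarts).
#' @param energyAbort abort if |U| exceeds this many kcal/mol (divergence).
#' @return A [Trajectory-class] (with final velocities for restarting).
#' @export
runLangevinEquilibrium <- function(system, registry, protocol,
                                   params = tisParams(), velocities = NULL,
                                   stepOffset = 0, energyAbort = 1e8) {
  if (protocol@cMg != 0 || any(system@ionSpecies == "MG"))
    stop("equilibrium preparation runs at [Mg2+] = 0")
  s <- .packSystem(system, registry, params, protocol@temperatureC)
  coords <- rbind(system@beadCoords, system@ionCoords)
  mass <- .siteMasses(system, params)
  gam <- .siteFriction(system, protocol, params)
  if (is.null(velocities)) {
    set.seed(protocol@seed + 211L)
    kTint <- tisConstants()$kB * (protocol@temperatureC + 273.15) * 4.184
    velocities <- matrix(rnorm(3 * s$n, 0, sqrt(kTint / mass)), s$n, 3)
  }
  out <- .cg_langevin_cpp(coords, velocities, s, mass, gam, protocol@dt,
                          protocol@nSteps, protocol@saveInterval,
                          protocol@seed, stepOffset)
  traj <- .makeTrajectory(out$frames, protocol, nBeads(system), stepOffset,
                          finalVel = out$finalVel)
  Uend <- evaluateEnergy(system, registry,
                         coords = frameCoords(traj, nFrames(traj)),
                         params = params,
                         temperatureC = protocol@temperatureC)@total
  if (!is.finite(Uend) || abs(Uend) > energyAbort)
    stop("energy divergence: |U| = ", Uend, " kcal/mol at final frame")
  traj
}

#' Brownian-dynamics propagation (folding runs)
#'
#' Overdamped Ermak-McCammon propagation without hydrodynamic
#' interactions; each site diffuses with its Stokes-Einstein coefficient
#' \eqn{D_i = k_B T / (6\pi\eta a_i)} at the protocol viscosity. The run
#' terminates when `stopCondition` (evaluated on each saved frame) returns
#' TRUE, or after `nSteps`. Steps displacing any site beyond the safety
#' threshold are redrawn at half step size and counted.
#'
#' @param system a [CGSystem-class] holding the initial frame (typically an
#'   equilibrium frame with Mg2+ freshly added by [placeIons()]).
#' @param registry an [InteractionRegistry-class].
#' @param protocol a [SimulationProtocol-class].
#' @param stopCondition NULL, or function(coords, time) -> logical applied
#'   to each saved frame.
#' @param params a [tisParams()] list.
#' @param stepOffset absolute step index of the initial frame.
#' @return A [Trajectory-class].
#' @export
runBrownianFolding <- function(system, registry, protocol,
                               stopCondition = NULL, params = tisParams(),
                               stepOffset = 0) {
  s <- .packSystem(system, registry, params, protocol@temperatureC)
  coords <- rbind(system@beadCoords, system@ionCoords)
  kTint <- s$kT * 4.184
  D <- kTint / .siteFriction(system, protocol, params)  # nm^2/ps
  nChunks <- protocol@nSteps %/% protocol@saveInterval
  nSites <- s$n
  framesList <- vector("list", nChunks + 1L)
  framesList[[1]] <- coords
  nRej <- 0L
  used <- 0L
  for (ch in seq_len(nChunks)) {
    out <- .cg_bd_cpp(coords, s, D, protocol@dt, protocol@saveInterval,
                      protocol@saveInterval, protocol@seed,
                      stepOffset + used, protocol@maxDisp)
    coords <- matrix(out$frames[2, , ], nSites, 3)
    nRej <- nRej + out$nRejected
    used <- used + protocol@saveInterval
    framesList[[ch + 1L]] <- coords
    t_ms <- (stepOffset + used) * protocol@dt * 1e-9
    if (!is.null(stopCondition) && isTRUE(stopCondition(coords, t_ms))) {
      framesList <- framesList[seq_len(ch + 1L)]
      break
    }
  }
  nf <- length(framesList)
  frames <- array(NA_real_, c(nf, nSites, 3))
  for (f in seq_len(nf)) frames[f, , ] <- framesList[[f]]
  .makeTrajectory(frames, protocol, nBeads(system), stepOffset,
                  nRejected = nRej)
}

#' Re-image a wrapped chain into a connected molecule
#'
#' Coordinates saved under periodic boundaries are wrapped into the box,
#' which can split a molecule across faces. This places each bead at its
#' minimum image relative to the previous bead along the chain, restoring
#' a connected conformation for RMSD/Rg analysis (the potential itself is
#' minimum-image and unaffected by wrapping).
#'
#' @param coords coordinate matrix (chain beads in chain order first).
#' @param box box edge, nm.
#' @param nChain number of chain beads (default all rows).
#' @return Re-imaged coordinate matrix.
#' @export
unwrapChain <- function(coords, box, nChain = nrow(coords)) {
  if (!is.finite(box)) return(coords)
  out <- coords
  for (i in 2:nChain) {
    d <- out[i, ] - out[i - 1L, ]
    out[i, ] <- out[i, ] - box * round(d / box)
  }
  out
}

#' Select well-separated frames as folding initial conditions
#'
#' Greedy filter keeping frames whose RNA-bead RMSD (after optimal
#' superposition) to every previously kept frame is at least `minRmsd`,
#' guaranteeing initial structures well separated in configuration space.
#'
#' @param traj a [Trajectory-class].
#' @param minRmsd minimum pairwise RMSD, nm (default 1.5).
#' @return Integer vector of kept frame indices.
#' @export
selectSeparatedFrames <- function(traj, minRmsd = 1.5) {
  nb <- traj@nRnaBeads
  kept <- integer()
  for (f in seq_len(nFrames(traj))) {
    x <- frameCoords(traj, f)[seq_len(nb), , drop = FALSE]
    ok <- all(vapply(kept, function(g)
      rmsdToNative(x, frameCoords(traj, g)[seq_len(nb), , drop = FALSE]) >=
        minRmsd, TRUE))
    if (ok) kept <- c(kept, f)
  }
  kept
}

#' Mean squared displacement with multiple time origins
#'
#' Standard sliding-origin MSD estimator; for a freely diffusing particle
#' MSD(lag) = 6 D lag. Only meaningful for trajectories propagated without
#' wrapping (open box).
#'
#' @param trajs a [Trajectory-class] or list of them (replicas).
#' @param maxLag maximum lag in frames.
#' @param sites site indices to include (default all).
#' @return data.frame(lag (ms), msd (nm^2)).
#' @export
msdCurve <- function(trajs, maxLag = NULL, sites = NULL) {
  if (is(trajs, "Trajectory")) trajs <- list(trajs)
  t0 <- frameTimes(trajs[[1]])
  dtF <- t0[2] - t0[1]
  nf <- length(t0)
  if (is.null(maxLag)) maxLag <- nf %/% 4
  acc <- numeric(maxLag); cnt <- numeric(maxLag)
  for (tr in trajs) {
    A <- tr@frames
    if (is.null(sites)) sites <- seq_len(dim(A)[2])
    for (lag in seq_len(maxLag)) {
      d <- A[(1 + lag):nf, sites, , drop = FALSE] -
        A[1:(nf - lag), sites, , drop = FALSE]
      acc[lag] <- acc[lag] + sum(d^2)
      cnt[lag] <- cnt[lag] + (nf - lag) * length(sites)
    }
  }
  data.frame(lag = seq_len(maxLag) * dtF, msd = acc / cnt)
}

#' Write or read a trajectory as plain text
#'
#' Long-format CSV (frame, site, x, y, z) with a one-line JSON header
#' comment carrying times and box metadata.
#'
#' @param traj a [Trajectory-class].
#' @param path file path.
#' @return `readTrajectoryCSV` returns a [Trajectory-class] (protocol slot
#'   is a placeholder).
#' @export
writeTrajectoryCSV <- function(traj, path) {
  hdr <- jsonlite::toJSON(list(times = traj@times,
                               box = as.character(traj@boxEdge),
                               nRnaBeads = traj@nRnaBeads), digits = NA)
  con <- file(path, "w")
  writeLines(paste0("# ", hdr), con)
  nf <- nFrames(traj); ns <- dim(traj@frames)[2]
  df <- data.frame(frame = rep(seq_len(nf), each = ns),
                   site = rep(seq_len(ns), nf),
                   x = as.vector(aperm(traj@frames, c(2, 1, 3))[, , 1]),
                   y = as.vector(aperm(traj@frames, c(2, 1, 3))[, , 2]),
                   z = as.vector(aperm(traj@frames, c(2, 1, 3))[, , 3]))
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname writeTrajectoryCSV
#' @export
readTrajectoryCSV <- function(path) {
  lines1 <- readLines(path, n = 1)
  meta <- jsonlite::fromJSON(sub("^# ", "", lines1))
  df <- utils::read.csv(path, comment.char = "#")
  nf <- max(df$frame); ns <- max(df$site)
  frames <- array(NA_real_, c(nf, ns, 3))
  for (f in seq_len(nf)) {
    sub <- df[df$frame == f, ]
    frames[f, sub$site, ] <- as.matrix(sub[, c("x", "y", "z")])
  }
  times <- as.numeric(meta$times)
  box <- as.numeric(meta$box)
  proto <- simulationProtocol(saveInterval = 1L, nSteps = max(1L, nf - 1L),
                              boxEdge = if (is.finite(box)) box else 35)
  new("Trajectory", frames = frames, times = times,
      nRnaBeads = as.integer(meta$nRnaBeads),
      boxEdge = box, protocol = proto,
      stepOffset = 0, finalVelocities = NULL, nRejected = 0L)
}
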