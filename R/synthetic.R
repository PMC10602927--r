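#' @include AllClasses.R topology.R dynamics.R
NULL

#' Construct a toy RNA hairpin system
#'
#' Builds a stem-loop of `nStem` base pairs (alternating G/C) and an
#' A-loop of `nLoop` nucleotides with idealized helical native
#' coordinates: paired bases face each other across the helix axis, sugars
#' and phosphates wind outside, and the loop bridges the two strands on a
#' semicircular arc. The interaction registry is Go-style (natural values
#' measured from the native frame) with the stem helix as the only
#' secondary element, one synthetic tertiary contact ("tert", a
#' cross-stem sugar-sugar hydrogen bond) for element-fraction tests, and
#' labelled segments stem5/loop/stem3.
#'
#' @param nStem stem length in base pairs (>= 2).
#' @param nLoop loop length in nucleotides (>= 3).
#' @param boxEdge box edge, nm (default Inf = open).
#' @param params a [tisParams()] list.
#' @return list(system, registry, native) where native is the bead
#'   coordinate matrix (nm).
#' @examples
#' hp <- makeHairpin(4, 4)
#' nBeads(hp$system)  # 35
#' @export
makeHairpin <- function(nStem = 4L, nLoop = 4L, boxEdge = Inf,
                        params = tisParams()) {
  stopifnot(nStem >= 2, nLoop >= 3)
  n <- 2L * nStem + nLoop
  stem1 <- rep(c("G", "C"), length.out = nStem)
  ## reverse complement of stem1 so that pair (k, n+1-k) is canonical
  stem2 <- rev(chartr("GC", "CG", stem1))
  sq <- c(stem1, rep("A", nLoop), stem2)
  rise <- 0.30; twist <- 35 * pi / 180
  rB <- 0.30; rS <- 0.70; delta <- 20 * pi / 180
  bidx <- beadIndices(n)
  S <- matrix(NA_real_, n, 3); B <- matrix(NA_real_, n, 3)
  pol <- function(r, a, z) c(r * cos(a), r * sin(a), z)
  for (k in seq_len(nStem)) {
    a <- (k - 1) * twist; z <- (k - 1) * rise
    B[k, ] <- pol(rB, a, z)
    S[k, ] <- pol(rS, a - delta, z)
    m <- n + 1L - k
    B[m, ] <- pol(rB, a + pi, z)
    S[m, ] <- pol(rS, a + pi + delta, z)
  }
  ## loop: semicircular arc between the two top-stem sugars
  a1 <- S[nStem, ]; a2 <- S[n + 1L - nStem, ]
  mid <- (a1 + a2) / 2
  u <- (a2 - a1) / sqrt(sum((a2 - a1)^2))
  Rh <- sqrt(sum((a2 - a1)^2)) / 2
  for (l in seq_len(nLoop)) {
    al <- pi * l / (nLoop + 1)
    r <- nStem + l
    S[r, ] <- mid - cos(al) * Rh * u + sin(al) * Rh * c(0, 0, 1)
    dir <- S[r, ] - mid
    dir <- dir / sqrt(sum(dir^2))
    B[r, ] <- S[r, ] + 0.40 * dir
  }
  coords <- matrix(NA_real_, 3L * n - 1L, 3)
  for (r in seq_len(n)) {
    coords[bidx[r, "S"], ] <- S[r, ]
    coords[bidx[r, "B"], ] <- B[r, ]
    if (r > 1L) {
      p <- (S[r - 1L, ] + S[r, ]) / 2
      rad <- sqrt(sum(p[1:2]^2))
      if (rad > 1e-6) p[1:2] <- p[1:2] * (rad + 0.30) / rad
      coords[bidx[r, "P"], ] <- p
    }
  }
  if (is.finite(boxEdge))
    coords <- sweep(coords, 2, colMeans(coords)) + boxEdge / 2
  system <- newCGSystem(sq, coords, boxEdge = boxEdge, params = params)
  pairs <- data.frame(resI = seq_len(nStem), resJ = n - seq_len(nStem) + 1L,
                      helix = "stem")
  ## native contact network (tertiary hydrogen bonds read off the native
  ## frame, as the full model reads them off the crystal structure):
  ## bead pairs >= 2 nt apart within 1.1 nm, excluding the stem's
  ## secondary base pairs. The designated "tert" element is the
  ## cross-stem sugar-sugar contact of residues 2 and n-1.
  thb <- data.frame(i = bidx[2L, "S"], j = bidx[n - 1L, "S"],
                    label = "tert")
  secKey <- paste(pmin(pairs$resI, pairs$resJ), pmax(pairs$resI, pairs$resJ))
  sys0 <- newCGSystem(sq, coords, boxEdge = boxEdge, params = params)
  for (bi in seq_len(3L * n - 2L)) for (bj in (bi + 1L):(3L * n - 1L)) {
    ri <- sys0@beadResidue[bi]; rj <- sys0@beadResidue[bj]
    if (abs(rj - ri) < 2L) next
    if (sys0@beadType[bi] == "B" && sys0@beadType[bj] == "B" &&
        paste(min(ri, rj), max(ri, rj)) %in% secKey) next
    if (bi == bidx[2L, "S"] && bj == bidx[n - 1L, "S"]) next
    d <- sqrt(sum((coords[bi, ] - coords[bj, ])^2))
    if (d < 1.1)
      thb <- rbind(thb, data.frame(i = bi, j = bj,
                                   label = sprintf("go%d-%d", bi, bj)))
  }
  elements <- list(stem = list(pairs = seq_len(nStem)),
                   tert = list(hb = 1L))
  segments <- list(stem5 = seq_len(nStem),
                   loop = nStem + seq_len(nLoop),
                   stem3 = (nStem + nLoop + 1L):n)
  registry <- buildRegistry(system, beadCoords(system), pairs = pairs,
                            tertiaryHB = thb, elements = elements,
                            segments = segments)
  list(system = system, registry = registry, native = beadCoords(system))
}

#' Synthetic multi-exponential Rg(t) ensembles
#'
#' Generates per-trajectory Rg(t) curves from [collapseModel()] plus
#' i.i.d. Gaussian per-frame noise, emulating the dispersion of
#' single-trajectory collapse curves around the ensemble decay. The
#' generating parameters are attached as attributes for recovery tests.
#'
#' @param fitParams list(rgU, rgF, phi, tau); amplitudes must sum to 1.
#' @param nTraj number of trajectories.
#' @param noiseSigma per-frame Gaussian sd, nm (>= 0).
#' @param tGrid time grid, ms; default 0 plus 199 log-spaced points from
#'   1e-3 to 30 ms.
#' @param seed integer seed.
#' @return Matrix (nTraj x length(tGrid)) with attributes `time` and
#'   `truth`.
#' @export
makeRgEnsemble <- function(fitParams = list(rgU = 7.8, rgF = 3.0,
                                            phi = c(0.76, 0.11, 0.13),
                                            tau = c(0.15, 1.6, 33)),
                           nTraj = 95L, noiseSigma = 0.3, tGrid = NULL,
                           seed = 1L) {
  stopifnot(noiseSigma >= 0)
  if (abs(sum(fitParams$phi) - 1) > 1e-8)
    stop("amplitudes must sum to 1")
  if (is.null(tGrid))
    tGrid <- c(0, 10^seq(-3, log10(30), length.out = 199))
  base <- collapseModel(tGrid, fitParams$rgU, fitParams$rgF,
                        fitParams$phi, fitParams$tau)
  set.seed(seed)
  curves <- matrix(rep(base, each = nTraj), nTraj, length(tGrid)) +
    matrix(rnorm(nTraj * length(tGrid), 0, noiseSigma), nTraj)
  attr(curves, "time") <- tGrid
  attr(curves, "truth") <- fitParams
  curves
}

#' Synthetic ion-binding trajectories with known first-passage times
#'
#' Builds a minimal two-nucleotide system with one Mg2+ ion and, per
#' trajectory, coordinate frames in which the ion sits far from the
#' phosphate until its drawn binding time and inside the contact shell
#' afterwards, so the shell criterion recovers the drawn times at frame
#' resolution. Contact-formation times (binding time plus a drawn lag)
#' are returned in the ground-truth table for concurrency analyses.
#'
#' @param nTraj number of trajectories.
#' @param frameDt frame spacing, ms (> 0).
#' @param tMax trajectory duration, ms.
#' @param fptSampler function(n) drawing binding first-passage times (ms).
#' @param contactLag function(n) drawing contact-minus-binding lags (ms).
#' @param r0,dr contact-shell parameters, nm.
#' @param seed integer seed.
#' @return list(trajs, system, truth = data.frame(tauDraw, tauIon,
#'   tauContact)); `tauIon` is the drawn time rounded up to the frame
#'   grid (NA when beyond tMax).
#' @export
makeIonEventTrajs <- function(nTraj = 50L, frameDt = 0.01, tMax = 5,
                              fptSampler = function(n) rexp(n, 2),
                              contactLag = function(n) runif(n, 0, 0.1),
                              r0 = 0.44, dr = 0.15, seed = 1L) {
  stopifnot(frameDt > 0, tMax > 0)
  set.seed(seed)
  draws <- fptSampler(nTraj)
  lags <- contactLag(nTraj)
  params <- tisParams()
  coords <- rbind(c(0.2, 0, 0), c(0.6, 0, 0),    # res1 S, B
                  c(0, 0, 0), c(0.2, 0.4, 0), c(0.6, 0.4, 0)) # res2 P,S,B
  system <- newCGSystem(c("G", "C"), coords, boxEdge = Inf, params = params)
  system@ionCoords <- matrix(c(3, 0, 0), 1, 3)
  system@ionSpecies <- "MG"
  system@ionCharge <- 2
  system@ionRadius <- unname(params$radii["MG"])
  times <- seq(0, tMax, by = frameDt)
  nf <- length(times)
  proto <- simulationProtocol(boxEdge = 35, saveInterval = 1L,
                              nSteps = nf - 1L, dt = frameDt * 1e9)
  trajs <- vector("list", nTraj)
  tauIon <- rep(NA_real_, nTraj)
  for (k in seq_len(nTraj)) {
    bindFrame <- which(times >= draws[k])[1]
    if (!is.na(bindFrame)) tauIon[k] <- times[bindFrame]
    fr <- array(NA_real_, c(nf, 6, 3))
    for (f in seq_len(nf)) {
      ion <- if (!is.na(bindFrame) && f >= bindFrame) c(r0, 0, 0)
             else c(3 + 0.001 * f, 0, 0)
      fr[f, , ] <- rbind(coords, ion)
    }
    trajs[[k]] <- new("Trajectory", frames = fr, times = times,
                      nRnaBeads = 5L, boxEdge = Inf, protocol = proto,
                      stepOffset = 0, finalVelocities = NULL,
                      nRejected = 0L)
  }
  list(trajs = trajs, system = system,
       truth = data.frame(tauDraw = draws, tauIon = tauIon,
                          tauContact = tauIon + lags))
}

#' Labelled synthetic conformational ensembles
#'
#' Emulates the three structural ensembles a folding study compares:
#' "Native" (small-jitter copies of the native frame), "Misfold" (the
#' native frame with the 3'-half of the chain rigidly displaced — a
#' native-like but topologically distinct state), and "Unfolded"
#' (affinely expanded conformers with larger jitter). Labels are the list
#' names; generation is deterministic given the seed.
#'
#' @param native native bead coordinate matrix.
#' @param residue residue index per bead.
#' @param nPerState frames per ensemble.
#' @param jitter native-state Gaussian jitter sd, nm.
#' @param displacement misfold rigid displacement, nm.
#' @param expandFactor unfolded-state affine expansion factor.
#' @param seed integer seed.
#' @return Named list of frame lists (Unfolded, Native, Misfold).
#' @export
makeConformerEnsemble <- function(native, residue, nPerState = 20L,
                                  jitter = 0.03, displacement = 1.5,
                                  expandFactor = 2.5, seed = 1L) {
  stopifnot(nPerState >= 1, expandFactor > 1, displacement > 10 * jitter)
  set.seed(seed)
  nb <- nrow(native)
  half <- residue > stats::median(residue)
  jit <- function(X, s) X + matrix(rnorm(3 * nb, 0, s), nb, 3)
  ctr <- colMeans(native)
  list(
    Unfolded = lapply(seq_len(nPerState), function(i)
      jit(sweep(native, 2, ctr) * expandFactor +
            matrix(ctr, nb, 3, byrow = TRUE), 5 * jitter)),
    Native = lapply(seq_len(nPerState), function(i) jit(native, jitter)),
    Misfold = lapply(seq_len(nPerState), function(i) {
      X <- native
      X[half, 1] <- X[half, 1] + displacement
      jit(X, jitter)
    }))
}
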