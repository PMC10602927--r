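#' @include AllClasses.R constants.R
NULL

.minImageDist <- function(a, B, box) {
  d <- sweep(B, 2, a)
  if (is.finite(box)) d <- d - box * round(d / box)
  sqrt(rowSums(d^2))
}

#' Count condensed ions in a frame
#'
#' An ion is condensed when its minimum-image distance to any phosphate
#' bead is below the cutoff; the default cutoff is the Bjerrum length, at
#' which thermal energy balances the Coulomb attraction between a cation
#' and an anion, putting Mg2+ and K+ on equal footing. Each ion is counted
#' at most once however many phosphates it neighbours.
#'
#' @param coords full site coordinate matrix (beads then ions); NULL to
#'   use the system's coordinates.
#' @param system a [CGSystem-class] (supplies bead types/ion species).
#' @param species ion species to count ("MG", "K" or "CL").
#' @param cutoff distance cutoff, nm (default [bjerrumLength()] at
#'   `temperatureC`).
#' @param temperatureC temperature used for the default cutoff.
#' @return Integer count.
#' @export
condensedIonCount <- function(coords = NULL, system, species = "MG",
                              cutoff = NULL, temperatureC = 37) {
  if (is.null(cutoff)) cutoff <- bjerrumLength(temperatureC)
  stopifnot(cutoff > 0, species %in% c("MG", "K", "CL"))
  if (is.null(coords)) coords <- rbind(system@beadCoords, system@ionCoords)
  nb <- nBeads(system)
  pIdx <- which(system@beadType == "P")
  ionRows <- nb + which(system@ionSpecies == species)
  if (!length(ionRows) || !length(pIdx)) return(0L)
  P <- coords[pIdx, , drop = FALSE]
  sum(vapply(ionRows, function(r)
    min(.minImageDist(coords[r, ], P, system@boxEdge)) < cutoff, TRUE))
}

#' Per-frame condensed-ion counts along a trajectory
#'
#' @param traj a [Trajectory-class].
#' @inheritParams condensedIonCount
#' @return data.frame(time, count).
#' @export
condensedIonSeries <- function(traj, system, species = "MG", cutoff = NULL,
                               temperatureC = 37) {
  counts <- vapply(seq_len(nFrames(traj)), function(f)
    condensedIonCount(frameCoords(traj, f), system, species, cutoff,
                      temperatureC), 0L)
  data.frame(time = frameTimes(traj), count = counts)
}

#' Volume of the phosphate contact shell
#'
#' \eqn{V = (4\pi/3)[(r_0+\Delta r)^3 - (r_0-\Delta r)^3]}, the thin
#' spherical shell around a phosphate within which a Mg2+ is in contact;
#' r0 is the sum of the phosphate and Mg2+ excluded-volume radii and
#' delta r a tolerance margin.
#'
#' @param r0 shell centre radius, nm (default 0.44).
#' @param dr tolerance margin, nm (default 0.15); must satisfy r0 > dr > 0.
#' @return Shell volume in nm^3 (0.7581 at the defaults).
#' @export
contactShellVolume <- function(r0 = 0.44, dr = 0.15) {
  stopifnot(r0 > dr, dr > 0)
  4 * pi / 3 * ((r0 + dr)^3 - (r0 - dr)^3)
}

#' Contact Mg2+ concentration at a nucleotide
#'
#' Time-averaged number of Mg2+ ions in the contact shell of the
#' nucleotide's phosphate, divided by the shell volume and converted to
#' mol/L. A single permanently bound ion corresponds to about 2.19 M at
#' the default shell (r0 = 0.44 nm, dr = 0.15 nm).
#'
#' @param traj a [Trajectory-class] (or a list of frame matrices).
#' @param system a [CGSystem-class].
#' @param residue nucleotide index (1-based along the chain).
#' @param r0,dr shell parameters, nm.
#' @return c* in mol/L.
#' @export
contactConcentration <- function(traj, system, residue, r0 = 0.44,
                                 dr = 0.15) {
  stopifnot(r0 > dr, dr > 0)
  frames <- if (is(traj, "Trajectory"))
    lapply(seq_len(nFrames(traj)), function(f) frameCoords(traj, f))
  else traj
  pIdx <- beadIndices(nNucleotides(system))[residue, "P"]
  if (is.na(pIdx)) stop("residue ", residue, " has no phosphate bead")
  nb <- nBeads(system)
  mgRows <- nb + which(system@ionSpecies == "MG")
  cnt <- vapply(frames, function(X) {
    if (!length(mgRows)) return(0)
    d <- .minImageDist(X[pIdx, ], X[mgRows, , drop = FALSE], system@boxEdge)
    sum(d > r0 - dr & d < r0 + dr)
  }, 0)
  mean(cnt) / contactShellVolume(r0, dr) * tisConstants()$molarPerPerNm3
}

#' Mg2+ binding kinetics at a phosphate site
#'
#' First passage time of Mg2+ coordination: the first frame time at which
#' any Mg2+ enters the contact shell of the site's phosphate (same shell
#' criterion as [contactConcentration()]; resolved at the save-frame
#' interval, no interpolation). The binding rate is the inverse of the
#' mean first passage time over trajectories; censored trajectories (no
#' entry within the run) are excluded with a warning.
#'
#' @param trajs a [Trajectory-class] or list of them.
#' @param system a [CGSystem-class].
#' @param residue nucleotide index.
#' @param r0,dr shell parameters, nm.
#' @return list(mfpt (ms), kb (1/ms), fpt = per-trajectory times,
#'   nCensored).
#' @export
bindingKinetics <- function(trajs, system, residue, r0 = 0.44, dr = 0.15) {
  if (is(trajs, "Trajectory")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1)
  pIdx <- beadIndices(nNucleotides(system))[residue, "P"]
  if (is.na(pIdx)) stop("residue ", residue, " has no phosphate bead")
  nb <- nBeads(system)
  mgRows <- nb + which(system@ionSpecies == "MG")
  fpt <- vapply(trajs, function(tr) {
    tt <- frameTimes(tr)
    for (f in seq_len(nFrames(tr))) {
      X <- frameCoords(tr, f)
      d <- .minImageDist(X[pIdx, ], X[mgRows, , drop = FALSE],
                         system@boxEdge)
      if (any(d > r0 - dr & d < r0 + dr)) return(tt[f] - tt[1])
    }
    NA_real_
  }, 0)
  nc <- sum(is.na(fpt))
  if (nc == length(fpt)) {
    warning("all trajectories censored: MFPT undefined")
    return(list(mfpt = NA_real_, kb = NA_real_, fpt = fpt, nCensored = nc))
  }
  if (nc > 0) warning(nc, " censored trajectories excluded from MFPT")
  mfpt <- mean(fpt, na.rm = TRUE)
  list(mfpt = mfpt, kb = 1 / mfpt, fpt = fpt, nCensored = nc)
}

#' Concurrency of ion binding and contact formation
#'
#' Pairs, per trajectory, the first passage time of Mg2+ binding at a site
#' with the first passage time of a tertiary-contact formation. Events
#' within `window` of each other are concurrent (strongly correlated); the
#' Pearson correlation is computed over all pairs; and contact-precedes-
#' binding violations (contact strictly earlier than binding) are counted
#' to support the necessity test: if the contact never precedes binding,
#' binding is a necessary condition for formation.
#'
#' @param tauIon per-trajectory ion-binding first passage times (ms).
#' @param tauContact per-trajectory contact-formation times (ms).
#' @param window concurrency window, ms (> 0; default 0.2).
#' @return list(fraction, rho, precedenceViolations, table).
#' @export
bindingContactConcurrency <- function(tauIon, tauContact, window = 0.2) {
  stopifnot(window > 0, length(tauIon) == length(tauContact))
  ok <- !is.na(tauIon) & !is.na(tauContact)
  ti <- tauIon[ok]; tc <- tauContact[ok]
  frac <- mean(abs(tc - ti) < window)
  rho <- if (length(ti) >= 2) stats::cor(ti, tc) else {
    warning("fewer than 2 complete pairs: correlation undefined")
    NA_real_
  }
  list(fraction = frac, rho = rho,
       precedenceViolations = sum(tc < ti),
       table = data.frame(tauIon = ti, tauContact = tc,
                          concurrent = abs(tc - ti) < window))
}
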