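#' @include AllClasses.R energy.R
NULL

#' Radius of gyration
#'
#' Equal-mass Rg over RNA beads: \eqn{R_g = \sqrt{\langle |x - \bar x|^2
#' \rangle}}. For a [Trajectory-class], one value per frame (ions
#' excluded).
#'
#' @param x coordinate matrix (nBeads x 3, nm) or a [Trajectory-class].
#' @return Numeric scalar or per-frame vector (nm).
#' @export
radiusOfGyration <- function(x) {
  if (is(x, "Trajectory")) {
    nb <- x@nRnaBeads
    return(vapply(seq_len(nFrames(x)), function(f)
      radiusOfGyration(frameCoords(x, f)[seq_len(nb), , drop = FALSE]), 0))
  }
  stopifnot(is.matrix(x), nrow(x) >= 1)
  ctr <- colMeans(x)
  sqrt(mean(rowSums(sweep(x, 2, ctr)^2)))
}

#' Ensemble Rg mean and coefficient of variation
#'
#' Averages per-trajectory Rg(t) curves on a common time grid and reports
#' the coefficient of variation C.V.(t) = sd/mean across trajectories, the
#' dispersion measure revealing pathway heterogeneity.
#'
#' @param curves numeric matrix (nTraj x nTimes) of Rg values, or a list
#'   of [Trajectory-class] objects on identical time grids.
#' @param times time grid (ms); taken from the trajectories if omitted.
#' @return data.frame(time, mean, sd, cv).
#' @export
ensembleRg <- function(curves, times = NULL) {
  if (is.list(curves) && length(curves) && is(curves[[1]], "Trajectory")) {
    tg <- lapply(curves, frameTimes)
    if (!all(vapply(tg, function(t) isTRUE(all.equal(t, tg[[1]])), TRUE)))
      stop("trajectories are on mismatched time grids")
    times <- tg[[1]]
    curves <- do.call(rbind, lapply(curves, radiusOfGyration))
  }
  stopifnot(is.matrix(curves), nrow(curves) >= 2)
  if (is.null(times)) times <- seq_len(ncol(curves))
  if (length(times) != ncol(curves))
    stop("time grid length does not match curves")
  m <- colMeans(curves)
  s <- apply(curves, 2, sd)
  data.frame(time = times, mean = m, sd = s, cv = s / m)
}

#' Multi-exponential collapse model
#'
#' \deqn{R_g(t) = R_{gU} - (R_{gU} - R_{gF}) \sum_i \Phi_i (1 -
#' e^{-t/\tau_i})} with amplitudes summing to 1, so the curve runs from
#' the unfolded plateau at t = 0 to the folded plateau as t grows beyond
#' the slowest phase.
#'
#' @param t times (ms).
#' @param rgU,rgF plateau Rg values (nm), rgU > rgF.
#' @param phi amplitudes (must sum to 1).
#' @param tau time constants (ms), same length as phi.
#' @return Rg values (nm).
#' @export
collapseModel <- function(t, rgU, rgF, phi, tau) {
  stopifnot(length(phi) == length(tau), abs(sum(phi) - 1) < 1e-8)
  decay <- sapply(seq_along(phi), function(i) phi[i] * (1 - exp(-t / tau[i])))
  if (is.null(dim(decay))) decay <- matrix(decay, nrow = 1)
  rgU - (rgU - rgF) * rowSums(decay)
}

## theta = (rgU, log dR, a_1..a_{n-1}, log tau_1..n); phi = softmax(a, 0)
.cfUnpack <- function(theta, n) {
  rgU <- theta[1]
  rgF <- rgU - exp(theta[2])
  a <- c(theta[2 + seq_len(n - 1)], 0)
  phi <- exp(a) / sum(exp(a))
  tau <- exp(theta[(n + 2):(2 * n + 1)])
  list(rgU = rgU, rgF = rgF, phi = phi, tau = tau)
}

#' Fit the constrained multi-exponential collapse model
#'
#' Nonlinear least squares for [collapseModel()] under the constraints
#' \eqn{\sum_i \Phi_i = 1}, \eqn{\tau_i > 0} and \eqn{R_{gU} > R_{gF}}
#' (enforced by a softmax/log reparameterization), minimized with
#' multi-start BFGS. Phases are reported sorted by ascending time
#' constant. The AIC allows the two-versus-three phase comparison: fit
#' with `nPhases = 2` and `3` and compare `@aic`.
#'
#' @param time time grid (ms), length >= 4*nPhases.
#' @param rg ensemble-mean Rg values (nm).
#' @param nPhases number of exponential phases (>= 1).
#' @param nStarts number of randomized starts.
#' @param seed seed for start jitter.
#' @param tauMaxFactor upper bound on time constants as a multiple of the
#'   last observation time (default 1.5). A decay truncated at T cannot
#'   identify time constants beyond T; leaving them unbounded lets the
#'   slowest phase drift arbitrarily and drag the plateau and amplitudes
#'   with it, so the fit reports at most a lower-bound time constant for
#'   the slowest phase (set `Inf` to disable).
#' @return A [KineticFit-class].
#' @examples
#' t <- c(0, 10^seq(-3, log10(30), length.out = 120))
#' y <- collapseModel(t, 7.8, 3.0, c(0.76, 0.11, 0.13), c(0.15, 1.6, 33))
#' fitCollapse(t, y, 3)
#' @export
fitCollapse <- function(time, rg, nPhases = 3L, nStarts = 8L, seed = 1L,
                        tauMaxFactor = 1.5) {
  n <- as.integer(nPhases)
  if (n < 1) stop("nPhases must be >= 1")
  stopifnot(length(time) == length(rg), all(time >= 0))
  if (length(time) < 4 * n)
    stop("need at least ", 4 * n, " points for ", n, " phases")
  obj <- function(theta) {
    p <- .cfUnpack(theta, n)
    sum((rg - collapseModel(time, p$rgU, p$rgF, p$phi, p$tau))^2)
  }
  tpos <- sort(unique(time[time > 0]))
  ltRange <- log(range(tpos))
  base <- c(max(rg), log(max(1e-3, max(rg) - min(rg))), rep(0, n - 1),
            seq(ltRange[1] + 0.15 * diff(ltRange),
                ltRange[2] - 0.05 * diff(ltRange), length.out = n))
  lower <- c(-Inf, -Inf, rep(-Inf, n - 1),
             rep(log(min(tpos)) - 3, n))
  upper <- c(Inf, Inf, rep(Inf, n - 1),
             rep(log(max(time) * tauMaxFactor), n))
  set.seed(seed)
  best <- NULL
  for (s in seq_len(nStarts)) {
    th0 <- base + if (s == 1) 0 else rnorm(length(base), 0, 0.4)
    th0 <- pmin(pmax(th0, lower + 1e-6), upper - 1e-6)
    fit <- tryCatch(
      stats::optim(th0, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = 5000, factr = 1e3,
                                  ndeps = rep(1e-7, length(th0)))),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  ## polish the winner to tight tolerance
  for (rep in 1:3) {
    fit <- tryCatch(
      stats::optim(best$par, obj, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(maxit = 5000, factr = 1,
                                  ndeps = rep(1e-7, length(best$par)))),
      error = function(e) NULL)
    if (!is.null(fit) && fit$value < best$value) best <- fit else break
  }
  if (is.null(best)) stop("collapse fit did not converge")
  p <- .cfUnpack(best$par, n)
  ord <- order(p$tau)
  rss <- best$value
  nObs <- length(time)
  k <- 2 * n + 1
  aic <- nObs * log(rss / nObs) + 2 * (k + 1)
  ## approximate CIs from the numerical Hessian in transformed coordinates,
  ## mapped through the log/softmax scales (delta method on tau only)
  ci <- tryCatch({
    H <- stats::optimHess(best$par, obj)
    sig2 <- rss / max(1, nObs - k)
    V <- 2 * sig2 * solve(H)
    se <- sqrt(pmax(0, diag(V)))
    tauSe <- p$tau * se[(n + 2):(2 * n + 1)]   # d tau / d log tau = tau
    m <- cbind(tau = 1.96 * tauSe[ord])
    rownames(m) <- paste0("phase", seq_len(n))
    m
  }, error = function(e) NULL)
  new("KineticFit", rgU = p$rgU, rgF = p$rgF, phi = p$phi[ord],
      tau = p$tau[ord], nPhases = n, rss = rss, aic = aic, ci = ci,
      nObs = as.integer(nObs))
}

#' Predict from a collapse fit
#' @param fit a [KineticFit-class].
#' @param time times (ms).
#' @return Fitted Rg values (nm).
#' @export
predictCollapse <- function(fit, time) {
  collapseModel(time, fit@rgU, fit@rgF, fit@phi, fit@tau)
}

#' Intramolecular distance distribution P(r)
#'
#' Normalized histogram of all intra-RNA bead pair distances pooled over
#' the supplied frames; the real-space counterpart of a small-angle
#' scattering profile, \eqn{\int P(r) dr = 1}.
#'
#' @param frames a coordinate matrix, a list of them, or a
#'   [Trajectory-class].
#' @param binWidth bin width, nm.
#' @param rMax histogram upper edge (default: data maximum).
#' @return data.frame(r = bin midpoints (nm), density).
#' @export
distanceDistribution <- function(frames, binWidth = 0.1, rMax = NULL) {
  stopifnot(binWidth > 0)
  if (is(frames, "Trajectory")) {
    nb <- frames@nRnaBeads
    frames <- lapply(seq_len(nFrames(frames)), function(f)
      frameCoords(frames, f)[seq_len(nb), , drop = FALSE])
  }
  if (is.matrix(frames)) frames <- list(frames)
  if (!length(frames)) stop("empty frame set")
  d <- unlist(lapply(frames, function(x) as.vector(dist(x))))
  if (is.null(rMax)) rMax <- max(d) + binWidth
  breaks <- seq(0, rMax + binWidth, by = binWidth)
  h <- hist(d, breaks = breaks, plot = FALSE)
  data.frame(r = h$mids, density = h$density)
}

#' Optimal-superposition RMSD to a reference
#'
#' Root-mean-square deviation after optimal rigid superposition (Kabsch
#' SVD rotation + translation), nm.
#'
#' @param frame,native coordinate matrices with equal row counts.
#' @return RMSD in nm.
#' @export
rmsdToNative <- function(frame, native) {
  if (!is.matrix(frame) || !is.matrix(native) ||
      nrow(frame) != nrow(native))
    stop("bead-count mismatch between frame and reference")
  x <- sweep(frame, 2, colMeans(frame))
  y <- sweep(native, 2, colMeans(native))
  s <- svd(crossprod(y, x))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  sqrt(mean(rowSums((x %*% t(R) - y)^2)))
}

#' Folding and compactness classifiers
#'
#' A conformation is folded when its superposition RMSD to the native
#' structure is below `cutoff` (default 0.6 nm, at which all secondary and
#' tertiary interactions are correctly formed); compact when its Rg is at
#' most `cutoff` (default 3.5 nm for the full-length ribozyme; pass the
#' appropriate scale for smaller systems).
#'
#' @param frame coordinate matrix (RNA beads).
#' @param native native reference matrix.
#' @param cutoff decision threshold (nm).
#' @return Logical.
#' @export
classifyFolded <- function(frame, native, cutoff = 0.6) {
  rmsdToNative(frame, native) < cutoff
}

#' @rdname classifyFolded
#' @export
classifyCompact <- function(frame, cutoff = 3.5) {
  radiusOfGyration(frame) <= cutoff
}

#' Structural overlap with the native state
#'
#' Order parameter \eqn{\chi \in [0, 1]}: the fraction of bead pairs
#' separated by at least `minSep` nucleotides whose distance lies within
#' `tolerance` of its native value. 1 for the native state, near 0 for
#' conformations with no native similarity.
#'
#' @param frame,native coordinate matrices (RNA beads).
#' @param residue residue index of each bead.
#' @param tolerance distance agreement tolerance, nm (> 0, default 0.2).
#' @param minSep minimum nucleotide separation (default 2).
#' @return chi in [0, 1].
#' @export
structuralOverlap <- function(frame, native, residue, tolerance = 0.2,
                              minSep = 2L) {
  stopifnot(tolerance > 0, nrow(frame) == nrow(native),
            length(residue) == nrow(frame))
  sep <- abs(outer(residue, residue, "-"))
  use <- upper.tri(sep) & sep >= minSep
  df <- as.matrix(dist(frame))[use]
  dn <- as.matrix(dist(native))[use]
  mean(abs(df - dn) < tolerance)
}

## resolve an element name: explicit registry element, or a helix label
.elementRows <- function(registry, element) {
  if (element %in% names(registry@elements)) {
    e <- registry@elements[[element]]
    return(list(pairs = as.integer(e$pairs %||% integer()),
                hb = as.integer(e$hb %||% integer()),
                stacks = as.integer(e$stacks %||% integer())))
  }
  hp <- which(registry@secondaryPairs$helix == element)
  if (length(hp))
    return(list(pairs = hp, hb = integer(), stacks = integer()))
  stop("unknown element: ", element)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fraction of an element's interactions currently formed
#'
#' An interaction is formed when its hydrogen-bond or stacking energy is
#' below \eqn{-k_B T} (threshold scalable via `params$contactEnergyKT`).
#' `element` may name a registered tertiary element or a helix label from
#' the secondary-pair table.
#'
#' @param coords full coordinate matrix (beads + ions) or NULL to use the
#'   system's coordinates.
#' @param system a [CGSystem-class].
#' @param registry an [InteractionRegistry-class].
#' @param element element or helix name.
#' @param params a [tisParams()] list.
#' @param temperatureC temperature, Celsius.
#' @return Fraction in [0, 1].
#' @export
elementFormationFraction <- function(coords, system, registry, element,
                                     params = tisParams(),
                                     temperatureC = 37) {
  rows <- .elementRows(registry, element)
  eb <- evaluateEnergy(system, registry, coords = coords, params = params,
                       temperatureC = temperatureC)
  thr <- -params$contactEnergyKT * tisConstants()$kB * (temperatureC + 273.15)
  formed <- 0L; total <- 0L
  sp <- registry@secondaryPairs
  for (k in rows$pairs) {
    total <- total + 1L
    hit <- eb@pairs$native & eb@pairs$resI == sp$resI[k] &
      eb@pairs$resJ == sp$resJ[k] & eb@pairs$energy < thr
    if (any(hit)) formed <- formed + 1L
  }
  reg <- eb@registry
  for (k in rows$hb) {
    total <- total + 1L
    if (reg$energy[reg$kind == "hb"][k] < thr) formed <- formed + 1L
  }
  for (k in rows$stacks) {
    total <- total + 1L
    if (reg$energy[reg$kind == "stack"][k] < thr) formed <- formed + 1L
  }
  if (total == 0L) stop("element '", element, "' has no interactions")
  formed / total
}

#' Scan a conformation for mispaired (non-native) helices
#'
#' Finds maximal runs of at least `minConsecutive` consecutive formed
#' non-native base pairs — the mispaired helices that arise while strands
#' search for their native partners and act as energetic traps. Runs are
#' labelled by the registry's strand segments when both strands fall
#' inside labelled segments, else "unlabeled".
#'
#' @inheritParams elementFormationFraction
#' @param minConsecutive minimum run length (default 4, >= 2).
#' @return data.frame(label, length, startI, startJ); zero rows if none.
#' @export
mispairedHelixScan <- function(coords, system, registry,
                               minConsecutive = 4L, params = tisParams(),
                               temperatureC = 37) {
  stopifnot(minConsecutive >= 2)
  eb <- evaluateEnergy(system, registry, coords = coords, params = params,
                       temperatureC = temperatureC)
  thr <- -params$contactEnergyKT * tisConstants()$kB * (temperatureC + 273.15)
  pp <- eb@pairs[!eb@pairs$native & eb@pairs$energy < thr, , drop = FALSE]
  empty <- data.frame(label = character(), length = integer(),
                      startI = integer(), startJ = integer())
  if (!nrow(pp)) return(empty)
  key <- paste(pp$resI, pp$resJ)
  runs <- list()
  for (k in seq_len(nrow(pp))) {
    i <- pp$resI[k]; j <- pp$resJ[k]
    if (paste(i - 1L, j + 1L) %in% key) next   # not a run start
    L <- 0L
    while (paste(i + L, j - L) %in% key) L <- L + 1L
    if (L >= minConsecutive)
      runs[[length(runs) + 1L]] <- c(i, j, L)
  }
  if (!length(runs)) return(empty)
  segLabel <- function(res) {
    for (nm in names(registry@segments))
      if (all(res %in% registry@segments[[nm]])) return(nm)
    NA_character_
  }
  out <- lapply(runs, function(r) {
    i <- r[1]; j <- r[2]; L <- r[3]
    s1 <- segLabel(i:(i + L - 1L)); s2 <- segLabel((j - L + 1L):j)
    lab <- if (is.na(s1) || is.na(s2)) "unlabeled" else paste0(s1, "-", s2)
    data.frame(label = lab, length = L, startI = i, startJ = j)
  })
  do.call(rbind, out)
}

#' First-passage statistics and kinetic partitioning
#'
#' From a per-trajectory event table, computes the cumulative fractions
#' \eqn{\Phi^F(t)} (reached the folded state by t) and \eqn{\Phi^M(t)}
#' (reached the trapped state), and an outcome census: folded rapidly
#' (\eqn{\tau_F \le} `rapidCutoff`), folded slowly (later but within the
#' cap), trapped, other. Trajectories with no event are right-censored at
#' the duration cap.
#'
#' @param events data.frame with columns `tauF` and `tauM` (ms; NA =
#'   censored / event not reached).
#' @param cap duration cap, ms (default 30).
#' @param rapidCutoff rapid-folding threshold, ms (default 5).
#' @return list(phiF, phiM = functions of t; census = named counts;
#'   outcomes = per-trajectory labels).
#' @export
firstPassageAnalysis <- function(events, cap = 30, rapidCutoff = 5) {
  stopifnot(nrow(events) >= 1, all(c("tauF", "tauM") %in% names(events)))
  n <- nrow(events)
  tf <- events$tauF; tm <- events$tauM
  if (any(tf < 0 | tm < 0, na.rm = TRUE)) stop("negative first-passage time")
  phiF <- function(t) vapply(t, function(u) sum(!is.na(tf) & tf <= u) / n, 0)
  phiM <- function(t) vapply(t, function(u) sum(!is.na(tm) & tm <= u) / n, 0)
  outcomes <- ifelse(!is.na(tf) & tf <= rapidCutoff, "folded rapidly",
              ifelse(!is.na(tf) & tf <= cap, "folded slowly",
              ifelse(!is.na(tm) & tm <= cap, "trapped", "other")))
  census <- table(factor(outcomes, levels = c("folded rapidly",
                                              "folded slowly", "trapped",
                                              "other")))
  list(phiF = phiF, phiM = phiM, census = census, outcomes = outcomes)
}
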