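#' @include AllClasses.R topology.R
NULL

#' DRID conformational descriptor
#'
#' Distribution of Reciprocal Interatomic Distances: for each centroid
#' bead, the first three moments of the set of reciprocal distances to all
#' other beads (excluding the centroid's own and adjacent nucleotides) —
#' the mean mu, the square root of the second central moment nu, and the
#' (signed) cube root of the third central moment xi. The concatenated
#' (mu, nu, xi) triplets form a rigid-motion-invariant feature vector;
#' `dridDistance` is the root-mean-square difference of two feature
#' vectors.
#'
#' @param coords RNA bead coordinate matrix (nm).
#' @param residue residue index of each bead.
#' @param centroids bead indices used as centroids (default: all sugar
#'   beads).
#' @param excludeAdjacent exclude beads of the same and adjacent
#'   nucleotides from each centroid's distance set (default TRUE).
#' @return Numeric feature vector of length 3 * length(centroids).
#' @export
dridFeatures <- function(coords, residue, centroids = NULL,
                         excludeAdjacent = TRUE) {
  stopifnot(nrow(coords) >= 3, length(residue) == nrow(coords))
  if (is.null(centroids)) stop("centroid selection must be nonempty")
  out <- numeric(0)
  for (c0 in centroids) {
    keep <- seq_len(nrow(coords)) != c0
    if (excludeAdjacent)
      keep <- keep & abs(residue - residue[c0]) > 1L
    d <- sqrt(rowSums(sweep(coords[keep, , drop = FALSE], 2,
                            coords[c0, ])^2))
    if (any(d < 1e-9)) stop("coincident beads in DRID computation")
    r <- 1 / d
    mu <- mean(r)
    m2 <- mean((r - mu)^2)
    m3 <- mean((r - mu)^3)
    out <- c(out, mu, sqrt(m2), sign(m3) * abs(m3)^(1 / 3))
  }
  out
}

#' @rdname dridFeatures
#' @param a,b feature vectors of equal length.
#' @export
dridDistance <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  sqrt(mean((a - b)^2))
}

#' Cluster the compact conformational ensemble
#'
#' Implements the compact-state clustering protocol: filter frames to
#' those with Rg at most `rgCutoff`, reduce to floor(n / subsampleFactor)
#' frames by seeded random selection, featurize with DRID (centroids =
#' sugar beads), and cluster by Ward's method. The number of clusters is
#' chosen at the largest gap in the dendrogram merge heights unless `k` is
#' given; cluster representatives are medoids.
#'
#' @param frames list of RNA bead coordinate matrices.
#' @param system a [CGSystem-class].
#' @param rgCutoff compactness cutoff, nm (default 3.5).
#' @param subsampleFactor random-selection reduction factor (>= 1).
#' @param seed selection seed.
#' @param k number of clusters (NULL: largest merge-height gap).
#' @return list(labels, representatives (frame indices into the retained
#'   set), retained (indices into `frames`), hclust, k).
#' @export
clusterCompactEnsemble <- function(frames, system, rgCutoff = 3.5,
                                   subsampleFactor = 1L, seed = 1L,
                                   k = NULL) {
  stopifnot(rgCutoff > 0, subsampleFactor >= 1)
  rg <- vapply(frames, radiusOfGyration, 0)
  compact <- which(rg <= rgCutoff)
  if (!length(compact)) stop("no compact frames (Rg <= ", rgCutoff, " nm)")
  nKeep <- subsampleCount(length(compact), subsampleFactor)
  set.seed(seed)
  retained <- sort(sample(compact, nKeep))
  bidx <- beadIndices(nNucleotides(system))
  centroids <- bidx[, "S"]
  res <- system@beadResidue
  feats <- t(vapply(retained, function(i)
    dridFeatures(frames[[i]], res, centroids), numeric(3 * length(centroids))))
  ## dridDistance = euclidean / sqrt(p)
  D <- stats::dist(feats) / sqrt(ncol(feats))
  hc <- stats::hclust(D, method = "ward.D2")
  if (is.null(k)) {
    h <- hc$height
    k <- if (length(h) >= 2) {
      gaps <- diff(h)
      length(h) - which.max(gaps) + 1L
    } else length(retained)
    k <- max(1L, min(k, length(retained)))
  }
  labels <- stats::cutree(hc, k = k)
  Dm <- as.matrix(D)
  reps <- vapply(seq_len(k), function(cl) {
    idx <- which(labels == cl)
    idx[which.min(colSums(Dm[idx, idx, drop = FALSE]))]
  }, 0L)
  list(labels = labels, representatives = reps, retained = retained,
       hclust = hc, k = k)
}

#' Deterministic subsample size
#'
#' Number of structures retained when reducing a set of `n` by random
#' selection with reduction factor `factor`: floor(n / factor).
#'
#' @param n set size.
#' @param factor reduction factor (>= 1).
#' @return Integer.
#' @examples
#' subsampleCount(2162299, 200)  # 10811
#' @export
subsampleCount <- function(n, factor) {
  stopifnot(n >= 0, factor >= 1)
  as.integer(floor(n / factor))
}

## deterministic Fibonacci spiral lattice on the unit sphere
.spiralPoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent accessible surface area of coarse-grained beads
#'
#' Rolling-probe SASA by Shrake-Rupley point sampling on a deterministic
#' spiral lattice: for each bead, test points on the sphere of radius
#' (bead radius + probe radius) are counted accessible when outside every
#' other bead's expanded sphere. `sasaPerBead` returns all bead areas;
#' `sasaPerNucleotide` returns the sugar-bead area per nucleotide, the
#' coarse-grained proxy for backbone accessibility probed by hydroxyl
#' radical cleavage.
#'
#' @param coords RNA bead coordinate matrix (nm).
#' @param radii per-bead radii (nm).
#' @param probeRadius probe radius, nm (> 0; default 0.14).
#' @param nPoints test points per bead (default 960).
#' @return `sasaPerBead`: numeric vector of areas (nm^2).
#' @export
sasaPerBead <- function(coords, radii, probeRadius = 0.14, nPoints = 960L) {
  stopifnot(probeRadius > 0, nrow(coords) == length(radii))
  n <- nrow(coords)
  pts <- .spiralPoints(nPoints)
  R <- radii + probeRadius
  out <- numeric(n)
  for (i in seq_len(n)) {
    p <- sweep(pts * R[i], 2, coords[i, ], "+")
    acc <- rep(TRUE, nPoints)
    for (j in seq_len(n)) {
      if (j == i) next
      dij <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (dij >= R[i] + R[j]) next
      d2 <- rowSums(sweep(p, 2, coords[j, ])^2)
      acc <- acc & d2 >= R[j]^2
      if (!any(acc)) break
    }
    out[i] <- mean(acc) * 4 * pi * R[i]^2
  }
  out
}

#' @rdname sasaPerBead
#' @param system a [CGSystem-class].
#' @return `sasaPerNucleotide`: numeric vector, one sugar-bead SASA (nm^2)
#'   per nucleotide.
#' @export
sasaPerNucleotide <- function(coords, system, probeRadius = 0.14,
                              nPoints = 960L) {
  a <- sasaPerBead(coords, system@beadRadius, probeRadius, nPoints)
  a[beadIndices(nNucleotides(system))[, "S"]]
}

#' Footprinting-style protection factors
#'
#' For each folded-state ensemble, the per-nucleotide protection factor is
#' the ratio of mean sugar-bead SASA in the unfolded ensemble to that in
#' the state ensemble, \eqn{F_p(i) = \langle SASA(i)\rangle_{U} /
#' \langle SASA(i)\rangle_{state}}: values above 1 mark nucleotides buried
#' upon folding, mirroring hydroxyl-radical protections. SASA is computed
#' on the coarse-grained beads (sugar bead as the backbone proxy), not on
#' reconstructed all-atom models.
#'
#' @param ensembles named list of frame lists; must include "Unfolded",
#'   plus any state ensembles (e.g. "Native", "Misfold").
#' @param system a [CGSystem-class].
#' @param probeRadius,nPoints see [sasaPerBead()].
#' @return data.frame(state, residue, sasaUnfolded, sasaState, fp); rows
#'   for the Unfolded ensemble itself carry fp = 1 identically.
#' @export
protectionFactors <- function(ensembles, system, probeRadius = 0.14,
                              nPoints = 960L) {
  stopifnot("Unfolded" %in% names(ensembles),
            all(vapply(ensembles, length, 0L) > 0))
  meanSasa <- function(frames) {
    rowMeans(vapply(frames, function(X)
      sasaPerNucleotide(X, system, probeRadius, nPoints),
      numeric(nNucleotides(system))))
  }
  mU <- meanSasa(ensembles$Unfolded)
  out <- lapply(names(ensembles), function(st) {
    mS <- if (st == "Unfolded") mU else meanSasa(ensembles[[st]])
    fp <- mU / mS
    if (any(!is.finite(fp)))
      warning("zero mean SASA for some nucleotides in ", st,
              ": protection factor infinite")
    data.frame(state = st, residue = seq_along(fp), sasaUnfolded = mU,
               sasaState = mS, fp = fp)
  })
  do.call(rbind, out)
}

#' Compare predicted protections with a reference set
#'
#' Thresholds the protection factors (protected when fp >= threshold,
#' closed boundary) and scores the prediction against a reference
#' protected-nucleotide set over the analyzed universe: sensitivity =
#' TP/(TP+FN), specificity = TN/(TN+FP). Nucleotides with non-finite fp
#' are excluded with a warning.
#'
#' @param fp named or plain numeric vector of protection factors (one per
#'   nucleotide of the universe), or a `protectionFactors` result filtered
#'   to one state.
#' @param referenceProtected integer vector of protected residues.
#' @param threshold protection threshold (> 0; default 1.2).
#' @param universe residues under comparison (default: all in `fp`).
#' @return list(sensitivity, specificity, predicted, tp, fp, tn, fn).
#' @export
compareProtection <- function(fp, referenceProtected, threshold = 1.2,
                              universe = NULL) {
  stopifnot(threshold > 0)
  if (is.data.frame(fp)) {
    v <- fp$fp; names(v) <- fp$residue; fp <- v
  }
  if (is.null(names(fp))) names(fp) <- seq_along(fp)
  res <- as.integer(names(fp))
  if (is.null(universe)) universe <- res
  keep <- res %in% universe
  fp <- fp[keep]; res <- res[keep]
  bad <- !is.finite(fp)
  if (any(bad)) {
    warning(sum(bad), " nucleotides with non-finite protection factor excluded")
    fp <- fp[!bad]; res <- res[!bad]
  }
  predicted <- res[fp >= threshold]
  actualPos <- intersect(universe, referenceProtected)
  actualNeg <- setdiff(res, actualPos)
  tp <- length(intersect(predicted, actualPos))
  fn <- length(setdiff(actualPos, predicted))
  fpN <- length(intersect(predicted, actualNeg))
  tn <- length(setdiff(actualNeg, predicted))
  list(sensitivity = tp / (tp + fn), specificity = tn / (tn + fpN),
       predicted = predicted, tp = tp, fp = fpN, tn = tn, fn = fn)
}
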