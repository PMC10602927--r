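test_that("DRID moments match hand computation and rigid-motion invariance", {
  coords <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  res <- c(1, 3, 5)                      # far apart: no adjacency exclusion
  f <- dridFeatures(coords, res, centroids = 1)
  ## reciprocals {1, 1/2}: mu 0.75, nu sqrt(0.0625) = 0.25, xi = 0
  expect_equal(f, c(0.75, 0.25, 0), tolerance = 1e-12)
  expect_equal(dridDistance(f, f), 0)
  th <- 0.9
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  f2 <- dridFeatures(coords %*% t(R) + 3, res, centroids = 1)
  ## mu and nu are invariant to machine precision; the cube root in xi
  ## compresses scale near zero, so float noise of 1e-18 surfaces as ~1e-6
  expect_lt(max(abs(f[-3] - f2[-3])), 1e-10)
  expect_lt(abs(f[3] - f2[3]), 1e-5)
  expect_error(dridFeatures(rbind(coords, coords[1, ]), c(res, 9),
                            centroids = 1), "coincident")
})

test_that("DRID distance is a metric on random conformations", {
  set.seed(5)
  hp <- makeHairpin(4, 4)
  res <- hp$system@beadResidue
  cent <- beadIndices(12)[, "S"]
  fs <- lapply(1:6, function(i)
    dridFeatures(hp$native + matrix(rnorm(105, 0, 0.3), 35, 3), res, cent))
  for (a in 1:5) for (b in (a + 1):6) {
    dab <- dridDistance(fs[[a]], fs[[b]])
    expect_equal(dab, dridDistance(fs[[b]], fs[[a]]))   # symmetry
    expect_gt(dab, 0)
    for (c in seq_len(6)) if (c != a && c != b)
      expect_lte(dab, dridDistance(fs[[a]], fs[[c]]) +
                   dridDistance(fs[[c]], fs[[b]]) + 1e-12)
  }
})

test_that("subsampling arithmetic and reproducibility", {
  expect_identical(subsampleCount(2162299, 200), 10811L)
  expect_identical(subsampleCount(10, 1), 10L)
  hp <- makeHairpin(4, 4)
  ens <- makeConformerEnsemble(hp$native, hp$system@beadResidue,
                               nPerState = 15, seed = 2)
  frames <- c(ens$Native, ens$Misfold)
  cl1 <- clusterCompactEnsemble(frames, hp$system, rgCutoff = 10,
                                subsampleFactor = 2, seed = 7, k = 2)
  cl2 <- clusterCompactEnsemble(frames, hp$system, rgCutoff = 10,
                                subsampleFactor = 2, seed = 7, k = 2)
  expect_identical(cl1$retained, cl2$retained)
  expect_identical(cl1$labels, cl2$labels)
  expect_equal(length(cl1$retained), subsampleCount(30, 2))
})

test_that("Ward clustering separates the two conformational families", {
  hp <- makeHairpin(4, 4)
  ens <- makeConformerEnsemble(hp$native, hp$system@beadResidue,
                               nPerState = 12, seed = 3)
  frames <- c(ens$Native, ens$Misfold)
  truth <- rep(c("N", "M"), each = 12)
  cl <- clusterCompactEnsemble(frames, hp$system, rgCutoff = 10,
                               subsampleFactor = 1, seed = 1)
  expect_equal(cl$k, 2)
  ## purity 1: each cluster is pure in one family
  tab <- table(cl$labels, truth[cl$retained])
  expect_equal(sum(apply(tab, 1, max)), length(cl$retained))
  ## Ward merge heights are monotone nondecreasing
  expect_true(all(diff(cl$hclust$height) >= -1e-12))
  ## representatives are members of their clusters
  expect_equal(unname(cl$labels[cl$representatives]), c(1L, 2L))
})

test_that("identical frames collapse to one cluster with zero spread", {
  hp <- makeHairpin(4, 4)
  frames <- rep(list(hp$native), 8)
  cl <- clusterCompactEnsemble(frames, hp$system, rgCutoff = 10,
                               subsampleFactor = 1, seed = 1, k = 1)
  expect_equal(unname(cl$labels), rep(1L, 8))
  expect_true(all(cl$hclust$height < 1e-12))
  expect_error(clusterCompactEnsemble(frames, hp$system, rgCutoff = 1e-6,
                                      subsampleFactor = 1, seed = 1),
               "no compact frames")
})

test_that("SASA: isolated sphere, burial, additivity, monotone approach", {
  a <- sasaPerBead(matrix(0, 1, 3), radii = 0.2, probeRadius = 0.14)
  expect_equal(a, 4 * pi * 0.34^2, tolerance = 1e-9)
  ## fully enclosed bead has zero area
  shell <- rbind(c(0, 0, 0),
                 as.matrix(expand.grid(x = c(-0.25, 0.25),
                                       y = c(-0.25, 0.25),
                                       z = c(-0.25, 0.25))),
                 c(0.3, 0, 0), c(-0.3, 0, 0), c(0, 0.3, 0), c(0, -0.3, 0),
                 c(0, 0, 0.3), c(0, 0, -0.3))
  aS <- sasaPerBead(shell, radii = c(0.12, rep(0.35, 14)),
                    probeRadius = 0.14)
  expect_equal(aS[1], 0)
  ## two distant beads keep their isolated areas
  a2 <- sasaPerBead(rbind(c(0, 0, 0), c(5, 0, 0)), radii = c(0.2, 0.3),
                    probeRadius = 0.14)
  expect_equal(a2, 4 * pi * c(0.34, 0.44)^2, tolerance = 1e-9)
  ## area of a bead decreases monotonically as a second bead approaches
  ds <- seq(1.2, 0.1, by = -0.1)
  areas <- vapply(ds, function(d)
    sasaPerBead(rbind(c(0, 0, 0), c(d, 0, 0)), radii = c(0.2, 0.2),
                probeRadius = 0.14)[1], 0)
  expect_true(all(diff(areas) <= 1e-9))
})

test_that("protection factors: identity ensembles give Fp = 1; ordering is correct", {
  hp <- makeHairpin(4, 4)
  ens0 <- list(Unfolded = rep(list(hp$native), 3),
               Native = rep(list(hp$native), 3))
  pf0 <- protectionFactors(ens0, hp$system, nPoints = 240)
  expect_true(all(abs(pf0$fp - 1) < 1e-12))
  cmp0 <- compareProtection(pf0[pf0$state == "Native", ],
                            referenceProtected = c(2, 3), threshold = 1.2)
  expect_equal(length(cmp0$predicted), 0)
  ## expanded unfolded ensembles expose more surface: Fp(Native) > 1 at
  ## buried (stem-interior) positions
  ens <- makeConformerEnsemble(hp$native, hp$system@beadResidue,
                               nPerState = 6, seed = 8)
  pf <- protectionFactors(ens[c("Unfolded", "Native", "Misfold")],
                          hp$system, nPoints = 240)
  fpN <- pf$fp[pf$state == "Native"]
  expect_true(all(fpN[c(2, 3, 10, 11)] > 1))
})

test_that("sensitivity/specificity against a reference protected set", {
  ## reference {1,2,3}, predicted {2,3,4}, universe 1..6 -> 2/3 and 2/3
  fp <- c(0.5, 2, 2, 2, 0.5, 0.5)
  cmp <- compareProtection(fp, referenceProtected = 1:3, threshold = 1.2,
                           universe = 1:6)
  expect_equal(cmp$sensitivity, 2 / 3)
  expect_equal(cmp$specificity, 2 / 3)
  expect_equal(cmp$tp, 2); expect_equal(cmp$fn, 1)
  expect_equal(cmp$fp, 1); expect_equal(cmp$tn, 2)
  ## threshold boundary is closed: fp == threshold counts as protected
  expect_equal(compareProtection(c(1.2, 1.19), 1:2, 1.2)$predicted, 1L)
  ## non-finite values are excluded with a warning
  expect_warning(compareProtection(c(Inf, 2, 0.5), 2:3, 1.2), "non-finite")
})

test_that("conformer ensembles order chi as Native > Misfold > Unfolded", {
  hp <- makeHairpin(4, 4)
  res <- hp$system@beadResidue
  ens <- makeConformerEnsemble(hp$native, res, nPerState = 8, seed = 5)
  chiMean <- vapply(ens, function(fr)
    mean(vapply(fr, structuralOverlap, 0, native = hp$native,
                residue = res)), 0)
  expect_gt(chiMean[["Native"]], chiMean[["Misfold"]])
  expect_gt(chiMean[["Misfold"]], chiMean[["Unfolded"]])
})
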