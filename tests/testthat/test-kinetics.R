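test_that("radius of gyration matches closed forms", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(radiusOfGyration(sq), sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(radiusOfGyration(matrix(5, 1, 3)), 0)
})

test_that("ensemble statistics: identical trajectories give zero C.V.", {
  curves <- matrix(rep(seq(8, 3, length.out = 50), each = 5), 5)
  er <- ensembleRg(curves, seq_len(50))
  expect_true(all(er$cv == 0))
  expect_error(ensembleRg(curves, 1:10), "time grid")
})

test_that("collapse model hits its plateaus at t = 0 and t -> Inf", {
  phi <- c(0.76, 0.11, 0.13); tau <- c(0.15, 1.6, 33)
  expect_equal(collapseModel(0, 7.8, 3.0, phi, tau), 7.8)
  expect_equal(collapseModel(1e9, 7.8, 3.0, phi, tau), 3.0, tolerance = 1e-9)
  expect_error(collapseModel(1, 7.8, 3, c(0.5, 0.4), c(1, 2)))  # sum != 1
})

test_that("noiseless three-phase curves are recovered to 4 significant digits", {
  t <- c(0, 10^seq(-3, log10(30), length.out = 150))
  y <- collapseModel(t, 7.8, 3.0, c(0.76, 0.11, 0.13), c(0.15, 1.6, 33))
  f <- fitCollapse(t, y, 3)
  expect_equal(f@phi, c(0.76, 0.11, 0.13), tolerance = 5e-4)
  expect_equal(f@tau, c(0.15, 1.6, 33), tolerance = 5e-4)
  expect_equal(f@rgU, 7.8, tolerance = 1e-4)
  expect_equal(f@rgF, 3.0, tolerance = 1e-3)
  ## fitted model evaluates to the plateaus at the ends
  expect_equal(predictCollapse(f, 0), f@rgU)
  expect_equal(predictCollapse(f, 1e9), f@rgF, tolerance = 1e-6)
  expect_equal(sum(f@phi), 1, tolerance = 1e-10)
  expect_true(all(diff(f@tau) > 0))
})

test_that("noisy ensemble recovery stays within the stated biases", {
  cur <- makeRgEnsemble(nTraj = 95, noiseSigma = 0.3, seed = 3)
  er <- ensembleRg(cur, attr(cur, "time"))
  f3 <- fitCollapse(er$time, er$mean, 3)
  expect_lt(abs(f3@phi[1] - 0.76), 0.04)
  expect_lt(abs(f3@tau[1] - 0.15) / 0.15, 0.10)
  expect_lt(abs(f3@tau[2] - 1.6) / 1.6, 0.25)
  ## tau3 only recoverable to ~20% under 30 ms truncation
  expect_lt(abs(f3@tau[3] - 33) / 33, 0.5)
})

test_that("model selection: three phases beat two on three-phase data, not on one-phase", {
  t <- c(0, 10^seq(-3, log10(30), length.out = 150))
  set.seed(2)
  y3 <- collapseModel(t, 7.8, 3.0, c(0.76, 0.11, 0.13), c(0.15, 1.6, 33)) +
    rnorm(length(t), 0, 0.03)
  expect_lt(fitCollapse(t, y3, 3)@aic, fitCollapse(t, y3, 2)@aic)
  y1 <- collapseModel(t, 7.8, 3.0, 1, 0.5) + rnorm(length(t), 0, 0.03)
  expect_gt(fitCollapse(t, y1, 3)@aic, fitCollapse(t, y1, 1)@aic)
})

test_that("distance distributions integrate to one and place mass correctly", {
  two <- rbind(c(0, 0, 0), c(1, 0, 0))
  pr <- distanceDistribution(two, binWidth = 0.1)
  expect_equal(sum(pr$density) * 0.1, 1, tolerance = 1e-9)
  expect_equal(pr$r[which.max(pr$density)], 0.95, tolerance = 0.051)
  ## 3 beads at mutual distances 1, 1, 2 -> weights 2/3 and 1/3
  three <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  pr3 <- distanceDistribution(three, binWidth = 0.5)
  w <- pr3$density * 0.5
  expect_equal(w[w > 0], c(2 / 3, 1 / 3), tolerance = 1e-9)
  expect_error(distanceDistribution(list(), 0.1), "empty")
  ## normalization holds for arbitrary ensembles
  set.seed(1)
  frames <- lapply(1:3, function(i) matrix(rnorm(30), 10, 3))
  prA <- distanceDistribution(frames, binWidth = 0.2)
  expect_equal(sum(prA$density) * 0.2, 1, tolerance = 1e-9)
})

test_that("RMSD: identity, rigid-motion invariance, and grid-search agreement", {
  hp <- makeHairpin(4, 4)
  X <- hp$native
  expect_equal(rmsdToNative(X, X), 0, tolerance = 1e-10)
  expect_true(classifyFolded(X, X))
  th <- 1.1
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  Xr <- X %*% t(R) + matrix(c(2, -1, 3), nrow(X), 3, byrow = TRUE)
  expect_equal(rmsdToNative(Xr, X), 0, tolerance = 1e-9)
  ## one bead displaced by d: RMSD bounded by d/sqrt(N), and the SVD
  ## solution is at least as good as a brute-force rotation grid
  d <- 0.8
  Xd <- X; Xd[7, 1] <- Xd[7, 1] + d
  rm <- rmsdToNative(Xd, X)
  expect_lte(rm, d / sqrt(nrow(X)) + 1e-9)
  gridBest <- Inf
  y <- sweep(X, 2, colMeans(X)); x <- sweep(Xd, 2, colMeans(Xd))
  for (a in seq(0, 2 * pi, length.out = 13)) for (b in seq(0, pi, length.out = 7)) {
    Ra <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
    Rb <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
    gridBest <- min(gridBest,
                    sqrt(mean(rowSums((x %*% t(Ra %*% Rb) - y)^2))))
  }
  expect_lte(rm, gridBest + 1e-9)
  expect_error(rmsdToNative(X[1:10, ], X), "mismatch")
})

test_that("compactness classifier thresholds Rg", {
  expect_true(classifyCompact(matrix(rnorm(30, 0, 0.5), 10, 3), cutoff = 3.5))
  stretched <- cbind(seq(0, 30, length.out = 10), 0, 0)
  expect_false(classifyCompact(stretched, cutoff = 3.5))
})

test_that("structural overlap: native gives 1, expanded chains near 0", {
  hp <- makeHairpin(4, 4)
  res <- hp$system@beadResidue
  expect_equal(structuralOverlap(hp$native, hp$native, res), 1)
  expanded <- hp$native * 4
  expect_lt(structuralOverlap(expanded, hp$native, res), 0.1)
  ## rank anti-correlation with RMSD along a perturbation ladder
  set.seed(6)
  sig <- c(0.01, 0.05, 0.1, 0.2, 0.4, 0.8)
  stats <- sapply(sig, function(s) {
    Xp <- hp$native + matrix(rnorm(length(hp$native), 0, s),
                             nrow(hp$native), 3)
    c(chi = structuralOverlap(Xp, hp$native, res),
      rmsd = rmsdToNative(Xp, hp$native))
  })
  expect_lte(cor(stats["chi", ], stats["rmsd", ], method = "spearman"), -0.9)
})

test_that("element formation fractions count formed interactions", {
  hp <- makeHairpin(4, 4)
  expect_equal(elementFormationFraction(NULL, hp$system, hp$registry,
                                        "stem"), 1)
  expect_equal(elementFormationFraction(NULL, hp$system, hp$registry,
                                        "tert"), 1)
  stretched <- hp$native * 4
  expect_equal(elementFormationFraction(stretched, hp$system, hp$registry,
                                        "stem"), 0)
  expect_error(elementFormationFraction(NULL, hp$system, hp$registry,
                                        "nosuch"), "unknown element")
  ## 5-pair helix with exactly 2 pairs realized -> 0.4
  lp <- ladderParams()
  sq <- c("G", "G", "G", "G", "G", "A", "A", "A",
          "C", "C", "C", "C", "C")
  reg5 <- data.frame(resI = 1:5, resJ = 13:9, helix = "stem")
  lad <- buildLadder(sq, reg5,
                     formedPairs = data.frame(resI = 1:2, resJ = 13:12),
                     params = lp)
  expect_equal(elementFormationFraction(lad$coords, lad$system,
                                        lad$registry, "stem", params = lp),
               0.4)
})

test_that("mispaired helix scan reports labelled runs of formed non-native pairs", {
  lp <- ladderParams()
  sq <- c("G", "G", "G", "G", "G", "A", "A", "A",
          "C", "C", "C", "C", "C")
  reg5 <- data.frame(resI = 1:5, resJ = 13:9, helix = "stem")
  segs <- list(stem5 = 1:5, loop = 6:8, stem3 = 9:13)
  ## register-shifted duplex: (1,12), (2,11), (3,10), (4,9) - 4 consecutive
  ## non-native pairs
  lad <- buildLadder(sq, reg5,
                     formedPairs = data.frame(resI = 1:4, resJ = 12:9),
                     segments = segs, params = lp)
  hits <- mispairedHelixScan(lad$coords, lad$system, lad$registry,
                             minConsecutive = 4, params = lp)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$length, 4)
  expect_equal(hits$label, "stem5-stem3")
  ## native frame: nothing to report
  ladN <- buildLadder(sq, reg5,
                      formedPairs = data.frame(resI = 1:5, resJ = 13:9),
                      segments = segs, params = lp)
  expect_equal(nrow(mispairedHelixScan(ladN$coords, ladN$system,
                                       ladN$registry, 4, params = lp)), 0)
  ## three consecutive mispairs stay below the default threshold
  lad3 <- buildLadder(sq, reg5,
                      formedPairs = data.frame(resI = 1:3, resJ = 12:10),
                      segments = segs, params = lp)
  expect_equal(nrow(mispairedHelixScan(lad3$coords, lad3$system,
                                       lad3$registry, 4, params = lp)), 0)
})

test_that("first-passage analysis: steps, censoring, DKW band, partitioning", {
  ## all fold at exactly 1 ms
  ev <- data.frame(tauF = rep(1, 10), tauM = NA_real_)
  fp <- firstPassageAnalysis(ev)
  expect_equal(fp$phiF(c(0.99, 1, 2)), c(0, 1, 1))
  ## no events: identically zero, everything censored as "other"
  ev0 <- data.frame(tauF = rep(NA_real_, 5), tauM = rep(NA_real_, 5))
  fp0 <- firstPassageAnalysis(ev0)
  expect_equal(fp0$phiF(c(1, 30)), c(0, 0))
  expect_true(all(fp0$outcomes == "other"))
  ## exponential sampling oracle: empirical Phi^F within the DKW band
  set.seed(10)
  n <- 200
  tf <- rexp(n, 1 / 2)
  fpE <- firstPassageAnalysis(data.frame(tauF = tf, tauM = NA_real_),
                              cap = Inf)
  tg <- seq(0.01, 20, length.out = 400)
  supDiff <- max(abs(fpE$phiF(tg) - pexp(tg, 1 / 2)))
  expect_lt(supDiff, sqrt(log(2 / 0.01) / (2 * n)))
  ## outcome census is mutually exclusive and ordered by the 5 ms split
  ev2 <- data.frame(tauF = c(2, 8, NA, NA), tauM = c(NA, NA, 3, NA))
  fp2 <- firstPassageAnalysis(ev2, cap = 30, rapidCutoff = 5)
  expect_equal(as.vector(fp2$census), c(1, 1, 1, 1))
  ## Phi^F + Phi^M <= 1 and both nondecreasing
  tg2 <- seq(0, 30, by = 0.5)
  tot <- fp2$phiF(tg2) + fp2$phiM(tg2)
  expect_true(all(tot <= 1 + 1e-12))
  expect_true(all(diff(fp2$phiF(tg2)) >= 0))
  expect_true(all(diff(fp2$phiM(tg2)) >= 0))
})

test_that("collapse-time scaling estimate", {
  expect_equal(collapseTimeEstimate(195, 5e-4, 1), 0.0975)
  expect_true(collapseTimeEstimate(195) <= 0.2)
  expect_equal(collapseTimeEstimate(1000, 2, 0), 2)
  expect_equal(collapseTimeEstimate(2 * 50, 1e-3, 1),
               2 * collapseTimeEstimate(50, 1e-3, 1))
})
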