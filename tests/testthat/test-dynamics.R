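## a 1-nt system with all interactions off: two independent free beads
freeSystem <- function() {
  p <- tisParams(kBond = 0, kAngle = 0, epsEv = 0, epsHb = 0,
                 epsHbNonnative = 0, epsHbTertiary = 0, epsSt = 0,
                 epsStTertiary = 0)
  sys <- newCGSystemForTest("A", rbind(c(0, 0, 0), c(0, 0, 0.46)), p)
  list(system = sys, registry = buildRegistry(sys), params = p)
}

## two beads joined by one harmonic bond, everything else off
bondSystem <- function(k = 500) {
  p <- tisParams(kAngle = 0, epsEv = 0, epsHb = 0, epsHbNonnative = 0,
                 epsHbTertiary = 0, epsSt = 0, epsStTertiary = 0, kBond = k)
  sys <- newCGSystemForTest("A", rbind(c(0, 0, 0), c(0, 0, 0.46)), p)
  list(system = sys, registry = buildRegistry(sys), params = p)
}

bondLengths <- function(tr) {
  vapply(seq_len(nFrames(tr)), function(f) {
    X <- frameCoords(tr, f)
    sqrt(sum((X[1, ] - X[2, ])^2))
  }, 0)
}

test_that("ion counts follow concentration * volume and neutrality", {
  proto <- simulationProtocol(boxEdge = 35, cMg = 5, cK = 12,
                              nSteps = 1000L, saveInterval = 1000L)
  cnt <- ionCounts(proto, nPhosphates = 195)
  expect_equal(unname(cnt["MG"]), 129L)
  expect_equal(unname(cnt["K"]), 310L)
  expect_equal(unname(cnt["CL"]), 2L * 129L + 310L - 195L)  # 373
  ## tiny box: extra neutralizing K+ instead of negative Cl-
  proto2 <- simulationProtocol(boxEdge = 5, cMg = 0, cK = 12,
                               nSteps = 1000L, saveInterval = 1000L)
  cnt2 <- ionCounts(proto2, nPhosphates = 11)
  expect_equal(unname(cnt2["K"] - cnt2["CL"]), 11L)
})

test_that("ion insertion respects excluded volume and fails gracefully", {
  hp <- makeHairpin(4, 4, boxEdge = 8)
  proto <- simulationProtocol(boxEdge = 8, cMg = 5, cK = 12,
                              nSteps = 1000L, saveInterval = 1000L)
  sysI <- placeIons(hp$system, proto, seed = 9)
  all <- rbind(beadCoords(sysI), sysI@ionCoords)
  rad <- c(sysI@beadRadius, sysI@ionRadius)
  nb <- nBeads(sysI)
  for (k in seq_len(nrow(sysI@ionCoords))) {
    d <- sweep(all[seq_len(nb + k - 1L), , drop = FALSE], 2,
               sysI@ionCoords[k, ])
    d <- d - 8 * round(d / 8)
    expect_true(all(sqrt(rowSums(d^2)) >=
                      0.8 * (rad[seq_len(nb + k - 1L)] + rad[nb + k]) - 1e-9))
  }
  expect_error(placeIons(hp$system, proto, seed = 1, maxTries = 0L),
               "insertion failed")
})

test_that("free-bead BD reproduces MSD = 6 D t", {
  fs <- freeSystem()
  proto <- simulationProtocol(boxEdge = 35, cMg = 0, cK = 0, dt = 1,
                              saveInterval = 10L, nSteps = 1000L)
  trajs <- lapply(1:40, function(k) {
    pr <- proto; pr@seed <- as.integer(k)
    runBrownianFolding(fs$system, fs$registry, pr, params = fs$params)
  })
  kTint <- tisConstants()$kB * 310.15 * 4.184
  gamS <- 6 * pi * 8.9e-4 * fs$params$radii[["S"]] * 1e-9 * 6.02214076e14
  D <- kTint / gamS                       # nm^2/ps
  m <- msdCurve(trajs, maxLag = 10, sites = 1)
  Dfit <- mean(m$msd / (m$lag * 1e9)) / 6   # lag ms -> ps
  expect_equal(Dfit, D, tolerance = 0.03)
})

test_that("bond-length distribution matches the Boltzmann weight (BD)", {
  bs <- bondSystem(500)
  proto <- simulationProtocol(boxEdge = 35, cMg = 0, cK = 0, dt = 0.01,
                              saveInterval = 50L, nSteps = 500000L, seed = 11)
  tr <- runBrownianFolding(bs$system, bs$registry, proto, params = bs$params)
  r <- bondLengths(tr)[-(1:500)]
  ## quadrature oracle: p(r) dr ~ r^2 exp(-k (r - r0)^2 / kT) dr
  kT <- tisConstants()$kB * 310.15
  w <- function(x) x^2 * exp(-500 * (x - 0.46)^2 / kT)
  Z <- integrate(w, 0, 2)$value
  m1 <- integrate(function(x) x * w(x), 0, 2)$value / Z
  m2 <- integrate(function(x) x^2 * w(x), 0, 2)$value / Z
  expect_equal(mean(r), m1, tolerance = 0.01)
  expect_equal(var(r), m2 - m1^2, tolerance = 0.05)
})

test_that("Langevin sampling is friction-independent and satisfies equipartition", {
  bs <- bondSystem(500)
  kT <- tisConstants()$kB * 310.15
  vars <- sapply(c(0.1, 1), function(fs) {
    proto <- simulationProtocol(boxEdge = 35, cMg = 0, cK = 0, dt = 0.01,
                                saveInterval = 50L, nSteps = 400000L,
                                seed = 5, frictionScale = fs)
    tr <- runLangevinEquilibrium(bs$system, bs$registry, proto,
                                 params = bs$params)
    var(bondLengths(tr)[-(1:500)])
  })
  ## same stationary distribution at both frictions
  expect_equal(vars[1], vars[2], tolerance = 0.1)
  ## and both agree with the quadrature oracle
  w <- function(x) x^2 * exp(-500 * (x - 0.46)^2 / kT)
  Z <- integrate(w, 0, 2)$value
  m1 <- integrate(function(x) x * w(x), 0, 2)$value / Z
  m2 <- integrate(function(x) x^2 * w(x), 0, 2)$value / Z
  expect_equal(vars[2], m2 - m1^2, tolerance = 0.08)
})

test_that("equilibrium preparation refuses Mg2+", {
  hp <- makeHairpin(4, 4, boxEdge = 10)
  proto <- simulationProtocol(boxEdge = 10, cMg = 5, cK = 12,
                              nSteps = 1000L, saveInterval = 1000L)
  sysI <- placeIons(hp$system, proto, seed = 1)
  expect_error(runLangevinEquilibrium(sysI, hp$registry, proto),
               "Mg2\\+")
})

test_that("trajectory restart from a checkpoint is bit-identical", {
  bs <- bondSystem(200)
  prA <- simulationProtocol(boxEdge = 35, cMg = 0, cK = 0, dt = 0.05,
                            saveInterval = 100L, nSteps = 400L, seed = 42)
  trA <- runBrownianFolding(bs$system, bs$registry, prA, params = bs$params)
  prB <- simulationProtocol(boxEdge = 35, cMg = 0, cK = 0, dt = 0.05,
                            saveInterval = 100L, nSteps = 200L, seed = 42)
  trB1 <- runBrownianFolding(bs$system, bs$registry, prB, params = bs$params)
  sys2 <- bs$system
  sys2@beadCoords <- frameCoords(trB1, nFrames(trB1))
  trB2 <- runBrownianFolding(sys2, bs$registry, prB, params = bs$params,
                             stepOffset = 200)
  expect_identical(frameCoords(trA, 5), frameCoords(trB2, 3))
  ## Langevin restart with carried velocities
  prL <- simulationProtocol(boxEdge = 35, cMg = 0, cK = 0, dt = 0.02,
                            saveInterval = 50L, nSteps = 100L, seed = 7,
                            frictionScale = 0.1)
  trL <- runLangevinEquilibrium(bs$system, bs$registry, prL,
                                params = bs$params)
  prL2 <- prL; prL2@nSteps <- 200L
  trFull <- runLangevinEquilibrium(bs$system, bs$registry, prL2,
                                   params = bs$params)
  sys3 <- bs$system
  sys3@beadCoords <- frameCoords(trL, nFrames(trL))
  trL2 <- runLangevinEquilibrium(sys3, bs$registry, prL,
                                 params = bs$params,
                                 velocities = trL@finalVelocities,
                                 stepOffset = 100)
  expect_identical(frameCoords(trFull, 5), frameCoords(trL2, 3))
})

test_that("a stop condition that always fires yields exactly one frame beyond start", {
  bs <- bondSystem(200)
  proto <- simulationProtocol(boxEdge = 35, cMg = 0, cK = 0, dt = 0.05,
                              saveInterval = 100L, nSteps = 1000L, seed = 3)
  tr <- runBrownianFolding(bs$system, bs$registry, proto,
                           stopCondition = function(X, t) TRUE,
                           params = bs$params)
  expect_equal(nFrames(tr), 2)
})

test_that("frame times are uniform, start at the initial condition, and ions persist", {
  hp <- makeHairpin(4, 4, boxEdge = 10)
  proto <- simulationProtocol(boxEdge = 10, cMg = 5, cK = 12, dt = 0.2,
                              saveInterval = 500L, nSteps = 2000L, seed = 2)
  sysI <- placeIons(hp$system, proto, seed = 2)
  tr <- runBrownianFolding(sysI, hp$registry, proto)
  expect_equal(frameCoords(tr, 1),
               rbind(beadCoords(sysI), sysI@ionCoords))
  expect_equal(diff(frameTimes(tr)),
               rep(500 * 0.2 * 1e-9, nFrames(tr) - 1))
  ## no NaNs, all wrapped
  expect_true(all(is.finite(tr@frames)))
  expect_true(all(tr@frames >= 0 & tr@frames <= 10))
})

test_that("well-separated frame selection enforces the minimum RMSD", {
  hp <- makeHairpin(4, 4)
  nb <- nBeads(hp$system)
  set.seed(4)
  frames <- array(0, c(6, nb, 3))
  frames[1, , ] <- hp$native
  frames[2, , ] <- hp$native + matrix(rnorm(nb * 3, 0, 0.01), nb, 3) # near 1
  big <- hp$native
  big[seq_len(nb), 1] <- big[seq_len(nb), 1] * 3
  frames[3, , ] <- big
  frames[4, , ] <- big + matrix(rnorm(nb * 3, 0, 0.01), nb, 3)       # near 3
  frames[5, , ] <- hp$native * 2.2
  frames[6, , ] <- hp$native * 2.2 + 0.01
  proto <- simulationProtocol(nSteps = 5L, saveInterval = 1L)
  tr <- new("Trajectory", frames = frames, times = 0:5 * 1e-6,
            nRnaBeads = nb, boxEdge = Inf, protocol = proto,
            stepOffset = 0, finalVelocities = NULL, nRejected = 0L)
  kept <- selectSeparatedFrames(tr, minRmsd = 0.5)
  expect_equal(kept, c(1L, 3L, 5L))
})

test_that("trajectory CSV round-trips frames and times", {
  bs <- bondSystem(200)
  proto <- simulationProtocol(boxEdge = 35, cMg = 0, cK = 0, dt = 0.05,
                              saveInterval = 100L, nSteps = 300L, seed = 8)
  tr <- runBrownianFolding(bs$system, bs$registry, proto, params = bs$params)
  path <- tempfile(fileext = ".csv")
  writeTrajectoryCSV(tr, path)
  back <- readTrajectoryCSV(path)
  expect_equal(back@frames, tr@frames, tolerance = 1e-12)
  expect_equal(frameTimes(back), frameTimes(tr))
  expect_equal(back@nRnaBeads, tr@nRnaBeads)
})
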