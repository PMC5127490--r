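# Toy structures, Go-model construction, and the Langevin/pulling engine.

test_that("toy structures are deterministic with exact virtual bonds", {
  a <- generateToyStructure(40, seed = 1)
  b <- generateToyStructure(40, seed = 1)
  expect_identical(coords(a), coords(b))
  d <- coords(a)
  bl <- sqrt(rowSums((d[-1, ] - d[-40, ])^2))
  expect_true(all(abs(bl - 0.38) < 1e-9))
  # a different seed jitters the fold but keeps the bonds
  c1 <- generateToyStructure(40, seed = 2)
  expect_false(identical(coords(a), coords(c1)))
  h <- generateToyStructure(30, motif = "helix-bundle", seed = 1)
  bh <- coords(h)
  expect_true(all(abs(sqrt(rowSums((bh[-1, ] - bh[-30, ])^2)) - 0.38) < 1e-9))
})

test_that("a 60-residue toy fold is compact with a rich contact map", {
  s <- generateToyStructure(60, seed = 1)
  m <- buildNativeContactMap(s)
  expect_gte(nrow(m@pairs), 60)
  # at least two topologically distinct strand pairings: contacts at both
  # short and long sequence separations
  sep <- abs(m@pairs$resi - m@pairs$resj)
  expect_gte(length(unique(pmin(sep, 20))), 2)
  expect_true(any(sep < 15) && any(sep > 20))
})

test_that("the Go model is built at its minimum", {
  sys <- toy_system()
  # bonded + native terms are exactly minimized at the native coordinates
  m0 <- sys$model; m0@epsNC <- 0
  e0 <- goEnergy(m0)
  expect_lt(max(abs(e0$forces)), 1e-8)
  expect_lt(e0$potential, 0)  # native contacts dominate at the minimum
  # residual excluded-volume push on just-outside-cutoff pairs is tiny
  e <- goEnergy(sys$model)
  expect_lt(max(abs(e$forces)), 0.05)
})

test_that("a two-bead chain has one bond and no angles, dihedrals or pairs", {
  s2 <- caStructure(cbind(c(0, 0.38), 0, 0))
  m2 <- suppressWarnings(buildCaGoModel(s2))
  expect_equal(nrow(m2@bonds), 1)
  expect_equal(nrow(m2@angles), 0)
  expect_equal(nrow(m2@dihedrals), 0)
  expect_equal(nrow(m2@pairs), 0)
})

test_that("heavy-reference weighting makes pair strengths heterogeneous", {
  # Ca chain of 10; heavy reference built so that residues (2,9) share
  # exactly 3 heavy contacts and (3,8) exactly 1
  ca_xyz <- cbind(0.38 * (0:9), 0, 0)
  ca_xyz[9, ] <- ca_xyz[2, ] + c(0, 0.45, 0)   # bring 9 near 2
  ca_xyz[8, ] <- ca_xyz[3, ] + c(0, 0.45, 0)   # and 8 near 3
  ca_xyz[10, ] <- ca_xyz[9, ] + c(0.38, 0, 0)
  ca_xyz[3, 1] <- ca_xyz[3, 1] + 1.0           # keep (3,8) clear of (2,9)
  ca_xyz[8, 1] <- ca_xyz[8, 1] + 1.0
  ca <- caStructure(ca_xyz)
  mk <- function(resno, base, natoms) {
    atoms <- c("CA", "CB", "CG")[seq_len(natoms)]
    data.frame(moiety_id = paste0(resno, ":", atoms), resno = resno,
               role = "heavy-atom",
               x = base[1] + 0.2 * (seq_len(natoms) - 1), y = base[2],
               z = base[3])
  }
  rows <- list()
  for (r in 1:10) {
    natoms <- if (r %in% c(2, 9)) 3 else if (r == 3) 2 else 1
    rows[[r]] <- mk(r, ca_xyz[r, ], natoms)
  }
  heavy <- Structure(do.call(rbind, rows), resolution = "heavy-atom")
  # cutoff 0.46: only vertically aligned atom pairs (0.45 nm) touch, so
  # (2,9) has 3 heavy contacts, (3,8) has 1
  hc <- contactDefinition("heavy", rCut = 0.46, minSeparation = 4L)
  mod <- buildCaGoModel(ca, heavyReference = heavy, heavyCdef = hc,
                        cdef = contactDefinition("ca", rCut = 0.8,
                                                 minSeparation = 4L),
                        kBond = 100)
  p <- mod@map@pairs
  w29 <- p$weight[p$resi == 2 & p$resj == 9]
  w38 <- p$weight[p$resi == 3 & p$resj == 8]
  expect_equal(w29, 3)
  expect_equal(w38, 1)
  eps <- mod@pairParams[, "eps"]
  expect_equal(mean(eps), 1, tolerance = 1e-12)  # epsilon_c sets the scale
  # epsilon ratio follows the heavy contact count ratio 3:1
  e29 <- eps[p$resi == 2 & p$resj == 9]
  e38 <- eps[p$resi == 3 & p$resj == 8]
  expect_equal(e29 / e38, 3)
  expect_error(buildNativeContactMap(ca, weighting = "heavy-atom-count"),
               "heavyReference")
})

test_that("zero-friction, zero-temperature dynamics conserve energy", {
  sys <- toy_system()
  # stationary at the native minimum
  th0 <- thermostatSettings(0, timeConstant = Inf, seed = 1)
  tr0 <- runLangevin(sys$model, th0, 2000, reportEvery = 500)
  expect_lt(max(abs(tr0@coords[, , 5] - tr0@coords[, , 1])), 1e-3)
  # small perturbation: relative drift of the mean total energy < 1e-3
  set.seed(3)
  x0 <- coords(sys$structure) + matrix(rnorm(120, sd = 0.005), ncol = 3)
  tr <- runLangevin(sys$model, th0, 10000, reportEvery = 100, x0 = x0)
  E <- tr@potential + tr@kinetic
  depth <- abs(goEnergy(sys$model)$potential)
  drift <- abs(mean(tail(E, 10)) - mean(head(E, 10))) / depth
  expect_lt(drift, 1e-3)
})

test_that("the thermostat satisfies equipartition within 3 standard errors", {
  sys <- toy_system()
  th <- thermostatSettings(1.0, timeConstant = 12, timeStep = 0.001, seed = 2)
  tr <- runLangevin(sys$model, th, 150000, reportEvery = 200)
  ke <- tr@kinetic[-(1:150)] / (3 * 40)   # per degree of freedom
  sem <- suppressWarnings(blockAverageSEM(ke))
  expect_lt(abs(mean(ke) - 0.5), 3 * sem)
})

test_that("dynamics are deterministic under a fixed seed", {
  sys <- toy_system()
  th <- thermostatSettings(1.0, seed = 9)
  a <- runLangevin(sys$model, th, 3000, reportEvery = 500)
  b <- runLangevin(sys$model, th, 3000, reportEvery = 500)
  expect_identical(a@coords, b@coords)
  c1 <- runLangevin(sys$model, thermostatSettings(1.0, seed = 10), 3000,
                    reportEvery = 500)
  expect_false(identical(a@coords, c1@coords))
})

test_that("a dragged free bead feels Stokes-like friction", {
  # two non-interacting beads: one tethered, one pulled through the
  # Langevin medium; steady-state spring force ~ gamma * v (mass 1)
  s2 <- caStructure(cbind(c(0, 5), 0, 0))
  m2 <- suppressWarnings(
    buildCaGoModel(s2, cdef = contactDefinition("ca", rCut = 0.1,
                                                minSeparation = 1L)))
  m2@bondParams[, "k"] <- 0   # sever the bond: free beads
  gamma <- 2; v <- 0.5
  th <- thermostatSettings(0, timeConstant = 1 / gamma, timeStep = 0.002,
                           seed = 1)
  tr <- runPull(m2, pullingProtocol(k = 50, v = v, L = 20, pulledBead = 2,
                                    fixedBead = 1), th, reportEvery = 200)
  f <- tr@force
  n <- length(f)
  sel <- seq(floor(n / 2), n)   # steady state
  expect_equal(mean(f[sel]), gamma * v, tolerance = 0.05)
  # extension grows linearly at speed v
  fit <- coef(lm(tr@extension[sel] ~ tr@time[sel]))
  expect_equal(unname(fit[2]), v, tolerance = 0.05)
})

test_that("a harmonic dimer pulled slowly shows the series stiffness", {
  kBond <- 100; kDev <- 50
  s2 <- caStructure(cbind(c(0, 0.38), 0, 0))
  m2 <- suppressWarnings(
    buildCaGoModel(s2, cdef = contactDefinition("ca", rCut = 0.1,
                                                minSeparation = 1L),
                   kBond = kBond))
  th <- thermostatSettings(0, timeConstant = 5, timeStep = 0.002, seed = 1)
  tr <- runPull(m2, pullingProtocol(k = kDev, v = 0.002, L = 0.5,
                                    pulledBead = 2, fixedBead = 1),
                th, reportEvery = 200)
  # drop the initial transient
  n <- length(tr@force)
  sel <- seq(floor(n / 3), n)
  # vs bead-separation change, only the bond compliance is seen
  slopeExt <- unname(coef(lm(tr@force[sel] ~ tr@extension[sel]))[2])
  expect_equal(slopeExt, kBond, tolerance = 0.05)
  # vs reference-point travel v*t, bond + device + tether act in series
  travel <- tr@time * 0.002
  slopeTravel <- unname(coef(lm(tr@force[sel] ~ travel[sel]))[2])
  kSeries <- 1 / (1 / kBond + 1 / kDev + 1 / kDev)
  expect_equal(slopeTravel, kSeries, tolerance = 0.05)
})

test_that("pulling at 0.9 Tf fully unfolds the toy protein", {
  sys <- toy_system()
  th <- thermostatSettings(0.9 * sys$Tf, seed = 7)
  tr <- runPull(sys$model, pullingProtocol(v = 0.02), th, reportEvery = 2000)
  q <- trajectoryQ(tr, sys$map)
  expect_lt(tail(q, 1), 0.1)
  # extension is monotone in time up to thermal noise
  ext <- tr@extension
  expect_gt(cor(seq_along(ext), ext), 0.99)
  # sawtooth: at least one rise-and-drop force event
  f <- tr@force
  expect_gte(sum(diff(f) < -0.25 * max(f)), 1)
})

test_that("temperature scans bracket the folding transition", {
  sys <- toy_system()
  curve <- suppressWarnings(
    runTemperatureScan(sys$model, c(0.6, 1.36, 2.3), nSteps = 40000,
                       seed = 3))
  expect_gt(curve@meanQ[1], 0.8)
  expect_lt(curve@meanQ[3], 0.2)
  expect_s4_class(curve, "MeltingCurve")
})

test_that("REMD mode runs and logs swap acceptance", {
  sys <- toy_system()
  curve <- suppressWarnings(
    runTemperatureScan(sys$model, c(1.1, 1.25, 1.4), nSteps = 20000,
                       mode = "remd", swapEvery = 2000, seed = 5))
  expect_true(is.finite(curve@series$swapAcceptance))
  expect_true(all(curve@meanQ >= 0 & curve@meanQ <= 1))
})

test_that("perturb-and-relax steers a pair apart and then relaxes", {
  sys <- toy_system()
  th <- thermostatSettings(0.9 * sys$Tf, seed = 5)
  tr <- perturbAndRelax(sys$model, c(5, 30), th, nSteps = 20000,
                        reportEvery = 100)
  # the perturbed endpoint really is ~1.5 nm beyond native separation
  x0 <- coords(sys$structure)
  d0 <- sqrt(sum((x0[5, ] - x0[30, ])^2))
  xp <- tr@metadata$perturbedEndpoint
  dp <- sqrt(sum((xp[5, ] - xp[30, ])^2))
  expect_equal(dp - d0, 1.5, tolerance = 0.35)
  # relaxation moves Q back up towards equilibrium
  q <- trajectoryQ(tr, sys$map)
  expect_gt(mean(tail(q, 50)), q[1] - 0.05)
  # same-strand pairs are rejected when a strand map is given
  expect_error(
    perturbAndRelax(sys$model, c(5, 8), th, nSteps = 100,
                    strandRanges = list(1:10, 11:20)),
    "same strand")
  expect_error(perturbAndRelax(sys$model, c(5, 6), th, nSteps = 100),
               "bonded neighbours")
})

test_that("displacement 0 reduces perturb-and-relax to plain dynamics", {
  sys <- toy_system()
  th <- thermostatSettings(0.7, seed = 21)
  tr0 <- perturbAndRelax(sys$model, c(5, 30), th, nSteps = 20000,
                         displacement = 0, rampSteps = 100L,
                         reportEvery = 200)
  trL <- runLangevin(sys$model, thermostatSettings(0.7, seed = 22), 20000,
                     reportEvery = 200)
  q0 <- trajectoryQ(tr0, sys$map)
  qL <- trajectoryQ(trL, sys$map)
  expect_lt(abs(mean(q0) - mean(qL)), 0.03)
})

test_that("the default perturbation pair list matches the 110-residue table", {
  expect_equal(defaultPerturbationPairs(110),
               list(c(13L, 69L), c(20L, 80L), c(35L, 45L), c(60L, 25L),
                    c(95L, 102L)))
  p40 <- defaultPerturbationPairs(40)
  expect_true(all(vapply(p40, function(p) all(p >= 1 & p <= 40), logical(1))))
})

test_that("scripted unfolding trajectories follow the prescribed order", {
  sys <- toy_system()
  ord <- c(31:40, 1:10, 11:30)   # termini first
  tr <- scriptedUnfoldingTrajectory(sys$structure, ord, nFrames = 11,
                                    seed = 1)
  q <- trajectoryQ(tr, sys$map)
  expect_gt(q[1], 0.9)
  expect_lt(tail(q, 1), 0.05)
  expect_true(all(diff(q) < 0.05))  # essentially monotone decreasing
  # determinism
  tr2 <- scriptedUnfoldingTrajectory(sys$structure, ord, nFrames = 11,
                                     seed = 1)
  expect_identical(tr@coords, tr2@coords)
})
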