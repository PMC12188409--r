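test_that("motors build deterministically with the advertised architecture", {
  m <- buildMotor(seed = 0)
  s <- motorAsStructure(m)
  rm <- roleMap(s)
  expect_identical(sum(rm == "beta"), 3L)        # three stator units
  expect_identical(sum(rm == "gamma"), 1L)       # two-layer rotor, one chain
  expect_identical(sum(rm == "inhibitor"), 1L)
  # export / re-import round-trips through PDB
  f <- withr::local_tempfile(fileext = ".pdb")
  writeMultiModelPDB(s, f)
  back <- readPDB(f, roleMap = rm)
  expect_equal(coords(back), round(coords(s), 3), tolerance = 1e-12)

  # inhibitor-free variant
  m0 <- buildMotor(toyMotorParams(nInh = 0L, shortSeg = integer(0),
                                  longSeg = integer(0)), seed = 0)
  expect_identical(nrow(motorState(m0)$inh), 0L)
  expect_false("I" %in% names(roleMap(motorAsStructure(m0))))

  # determinism of construction
  expect_identical(motorState(buildMotor(seed = 7)),
                   motorState(buildMotor(seed = 7)))
  expect_error(buildMotor(toyMotorParams(rProt = -1)), "non-physical")
})

test_that("zero-temperature dynamics relax downhill", {
  m <- buildMotor(seed = 0)
  e <- motorEnergy(m)
  for (chunk in 1:4) {
    r <- runLangevin(m, simProtocol(nSteps = 100, dt = 1e-3, seed = 1,
                                    temperature = 0))
    m <- r$motor
    eNew <- motorEnergy(m)
    expect_lte(eNew, e + 1e-9)
    e <- eNew
  }
})

test_that("the biased protruded ring tracks the target within the friction lag", {
  # decoupled rigid-ish rotor: no gate coupling, no torsion load
  p <- toyMotorParams(nInh = 0L, shortSeg = integer(0), longSeg = integer(0),
                      kCouple = 0, kappaTw = 0, kShape = 200)
  m <- buildMotor(p, seed = 0)
  kappa <- 2000
  b <- rotorBias(kappa = kappa, omegaDegNs = 10, direction = "CCW")
  r <- runLangevin(m, simProtocol(nSteps = 3000, dt = 5e-4, seed = 1,
                                  bias = b, temperature = 0))
  lt <- ledgerTable(r$ledger)
  lag <- tail(lt$theta0_deg - lt$theta_deg, 1) * pi / 180
  # collective friction of the mean angle is nProt * gammaAng
  expected <- p$nProt * p$gammaAng * (10 * pi / 180) / kappa
  expect_equal(lag, expected, tolerance = 0.05)
})

test_that("trajectories are bit-reproducible under a fixed seed", {
  m <- buildMotor(seed = 0)
  b <- rotorBias(kappa = 500, omegaDegNs = 10, direction = "CCW")
  r1 <- runLangevin(m, simProtocol(nSteps = 300, dt = 1e-3, seed = 1,
                                   bias = b))
  r2 <- runLangevin(m, simProtocol(nSteps = 300, dt = 1e-3, seed = 1,
                                   bias = b))
  expect_identical(r1$trajectory@xyz, r2$trajectory@xyz)
  expect_identical(ledgerTable(r1$ledger), ledgerTable(r2$ledger))
  r3 <- runLangevin(m, simProtocol(nSteps = 300, dt = 1e-3, seed = 2,
                                   bias = b))
  expect_false(identical(r1$trajectory@xyz, r3$trajectory@xyz))
})

test_that("gate occupancies match the Boltzmann ratio of the two wells", {
  # reduced barrier, unit-1 target pinned closed: the gate coordinate
  # samples U(g) = 16 b g^2 (1-g)^2 + kC/2 (g-1)^2 at kBT
  p <- toyMotorParams(nInh = 0L, shortSeg = integer(0), longSeg = integer(0),
                      nProt = 6L, barrierGate = 0.8)
  m <- buildMotor(p, seed = 0)
  sw <- data.frame(time = 0, unit = 1, target = 1)
  r <- runLangevin(m, simProtocol(nSteps = 150000, dt = 1e-3, seed = 4,
                                  stride = 20, stateSwitch = sw))
  g1 <- frameMetadata(r$trajectory)$g1
  burn <- g1[-(1:500)]
  expect_gt(sum(diff(burn > 0.5) != 0), 50)   # enough transitions to count
  U <- function(g) 16 * p$barrierGate * g^2 * (1 - g)^2 +
    0.5 * p$kCouple * (g - 1)^2
  gg <- seq(-1.5, 2.5, by = 1e-4)
  w <- exp(-U(gg) / p$kBT)
  predicted <- sum(w[gg > 0.5]) / sum(w)      # quadrature oracle
  expect_equal(mean(burn > 0.5), predicted, tolerance = 0.1)
})

test_that("the inhibitor's contact geometry makes rotation direction-dependent", {
  # regression on the constructed asymmetry: with the inhibitor engaged,
  # synthesis-direction rotation costs more work than hydrolysis at T = 0;
  # without the inhibitor the two directions are exactly symmetric
  m <- buildMotor(seed = 0)
  work40 <- function(mm, dir) {
    b <- rotorBias(kappa = 500, omegaDegNs = 10, direction = dir)
    r <- runLangevin(mm, simProtocol(nSteps = 4000, dt = 1e-3, seed = 1,
                                     bias = b, temperature = 0))
    tail(r$ledger@work, 1)
  }
  wCW <- work40(m, "CW"); wCCW <- work40(m, "CCW")
  expect_gt(wCW - wCCW, 0.05)
  m0 <- buildMotor(toyMotorParams(nInh = 0L, shortSeg = integer(0),
                                  longSeg = integer(0)), seed = 0)
  expect_lt(abs(work40(m0, "CW") - work40(m0, "CCW")), 1e-9)
})

test_that("RMSD steering reaches the target within a tenth of the start", {
  m <- buildMotor(toyMotorParams(nInh = 0L, shortSeg = integer(0),
                                 longSeg = integer(0)), seed = 0)
  # steering a relaxed motor toward its own state exerts no net force
  mRel <- runLangevin(m, simProtocol(nSteps = 3000, dt = 1e-3, seed = 1,
                                     temperature = 0))$motor
  still <- rmsdSteer(mRel, mRel, duration = 0.1, dt = 1e-3, temperature = 0)
  expect_lt(max(abs(motorDOF(still$motor) - motorDOF(mRel))), 1e-3)

  # open-gate motor steered to a closed-gate target
  target <- m
  stT <- motorState(target); stT$g <- c(1, 1, 1)
  target@state <- stT
  steered <- rmsdSteer(m, target, duration = 2, kSteer = 2000, dt = 1e-3,
                       temperature = 0)
  gFinal <- motorState(steered$motor)$g
  expect_true(all(abs(gFinal - 1) < 0.1))
  rmsdFinal <- sqrt(mean((motorDOF(steered$motor) - motorDOF(target))^2))
  rmsd0 <- sqrt(mean((motorDOF(m) - motorDOF(target))^2))
  expect_lt(rmsdFinal, 0.1 * rmsd0)

  expect_error(rmsdSteer(m, target, duration = 0), "duration")
  bad <- buildMotor(toyMotorParams(nInh = 0L, shortSeg = integer(0),
                                   longSeg = integer(0), nProt = 6L),
                    seed = 0)
  expect_error(rmsdSteer(m, bad, duration = 1), "topology")
})

test_that("a run is reproducible from its config echo alone", {
  m <- buildMotor(seed = 0)
  b <- rotorBias(kappa = 400, omegaDegNs = 15, direction = "CW")
  r1 <- runLangevin(m, simProtocol(nSteps = 200, dt = 1e-3, seed = 6,
                                   bias = b))
  f <- withr::local_tempfile(fileext = ".yml")
  writeRunConfig(r1$config, f)
  cfg <- yaml::read_yaml(f)
  p2 <- do.call(toyMotorParams,
                cfg[setdiff(names(cfg), c("seed", "protocol"))])
  m2 <- buildMotor(p2, seed = cfg$seed)
  b2 <- rotorBias(kappa = cfg$protocol$bias$kappa,
                  omegaDegNs = cfg$protocol$bias$omegaDegNs,
                  direction = cfg$protocol$bias$direction,
                  theta0InitDeg = cfg$protocol$bias$theta0InitDeg)
  r2 <- runLangevin(m2, simProtocol(nSteps = cfg$protocol$nSteps,
                                    dt = cfg$protocol$dt,
                                    seed = cfg$protocol$seed,
                                    bias = b2,
                                    stride = cfg$protocol$stride))
  expect_equal(ledgerTable(r2$ledger), ledgerTable(r1$ledger),
               tolerance = 1e-12)
})

test_that("the PCA dataset generator has the advertised covariance structure", {
  ps <- generatePcaDataset(40, noiseSigma = 0, seed = 2)
  X <- sweep(pairCoords(ps), 2, colMeans(pairCoords(ps)))
  expect_identical(qr(X)$rank, 2L)              # exact rank 2 without noise
  expect_error(generatePcaDataset(1), "at least 2")
  gt <- attr(ps, "groundTruth")
  expect_equal(sum(gt$v1 * gt$v2), 0, tolerance = 1e-12)
})

test_that("generated helix chains carry the requested helical fraction", {
  expect_equal(helicity(generateHelixChain(20, 1), 1:20), 1)
  expect_equal(helicity(generateHelixChain(20, 0), 1:20), 0)
  h <- generateHelixChain(30, 0.5)
  tor <- backboneDihedrals(h)
  helical <- with(tor, !is.na(phi) & !is.na(psi) &
                    phi > -100 & phi < -30 & psi > -67 & psi < -7)
  expect_identical(sum(helical[2:29]), 14L)     # 15 assigned, one boundary
  expect_equal(helicity(h, 1:30), 0.5, tolerance = 1 / 30)
})
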