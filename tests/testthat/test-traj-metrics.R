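test_that("helicity follows the dihedral-window criterion", {
  expect_equal(helicity(generateHelixChain(25, 1), "1-25"), 1)
  expect_equal(helicity(generateHelixChain(25, 0), "1-25"), 0)
  expect_equal(helicity(generateHelixChain(25, 0.6), "1-25"), 0.6,
               tolerance = 1 / 25)
  expect_error(helicity(generateHelixChain(10, 1), 5), "at least 2")
  # sub-interval of a mixed chain
  h <- generateHelixChain(40, 0.5)
  expect_equal(helicity(h, "1-10"), 1)
  expect_equal(helicity(h, "25-40"), 0)
})

test_that("contact counts match the brute-force all-pairs oracle", {
  twoRes <- function(d) {
    StructureModel(data.frame(
      chain = c("I", "G"), resno = c(1L, 1L), resname = "ALA",
      elety = "CA", element = "C",
      x = c(0, d), y = 0, z = 0, het = FALSE, stringsAsFactors = FALSE),
      roleMap = c(I = "inhibitor", G = "gamma"))
  }
  sI <- Selection("inhibitor", "1-1", "heavy")
  sG <- Selection("gamma", "1-1", "heavy")
  expect_identical(contactCount(twoRes(4.0), sI, sG)$count, 1L)
  expect_identical(contactCount(twoRes(5.0), sI, sG)$count, 0L)

  # random residue clouds, seed 9: equals the O(N^2) oracle
  set.seed(9)
  nA <- 20L; nB <- 20L
  mkCloud <- function(n, ch, shift) {
    data.frame(chain = ch, resno = rep(seq_len(n), each = 3),
               resname = "ALA", elety = rep(c("N", "CA", "C"), n),
               element = rep(c("N", "C", "C"), n),
               x = rnorm(3 * n, shift, 4), y = rnorm(3 * n, 0, 4),
               z = rnorm(3 * n, 0, 4), het = FALSE,
               stringsAsFactors = FALSE)
  }
  m <- StructureModel(rbind(mkCloud(nA, "I", 0), mkCloud(nB, "G", 3)),
                      roleMap = c(I = "inhibitor", G = "gamma"))
  got <- contactCount(m, Selection("inhibitor", "1-20", "heavy"),
                      Selection("gamma", "1-20", "heavy"), cutoff = 4.5)
  a <- atomData(m)
  A <- a[a$chain == "I", ]; B <- a[a$chain == "G", ]
  oracle <- bruteContacts(as.matrix(A[, c("x", "y", "z")]), A$resno,
                          as.matrix(B[, c("x", "y", "z")]), B$resno, 4.5)
  expect_identical(got$count, oracle)

  # overlapping groups are refused
  expect_error(contactCount(m, Selection("inhibitor", "1-20", "heavy"),
                            Selection("inhibitor", "5-10", "heavy")),
               "disjoint")
})

test_that("relative contacts are percentages of the equilibrium baseline", {
  expect_equal(relativeContacts(10, 10), 100)
  expect_equal(relativeContacts(0, 10), 0)
  expect_equal(relativeContacts(c(10, 5), 10), c(100, 50))
  expect_error(relativeContacts(5, 0), "positive")
  # 30-ns block averaging over non-overlapping windows
  times <- seq(1, 120, by = 1)
  counts <- rep(c(10, 8, 6, 4), each = 30)
  blk <- relativeContacts(counts, 10, times = times, blockLength = 30)
  expect_identical(nrow(blk), 4L)
  expect_equal(blk$percent, c(100, 80, 60, 40))
})

test_that("bending angles reduce to the law of cosines", {
  mk <- function(p1, p2, p3) {
    caChainModel(rbind(p1, p2, p3), chain = "I", resno = c(21L, 38L, 45L),
                 role = "inhibitor")
  }
  expect_equal(bendingAngle(mk(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))), 180)
  expect_equal(bendingAngle(mk(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))), 90)
  set.seed(13)
  p <- matrix(rnorm(9, sd = 5), 3)
  ab <- sqrt(sum((p[1, ] - p[2, ])^2))
  cb <- sqrt(sum((p[3, ] - p[2, ])^2))
  ac <- sqrt(sum((p[1, ] - p[3, ])^2))
  lawCos <- acos((ab^2 + cb^2 - ac^2) / (2 * ab * cb)) * 180 / pi
  expect_equal(bendingAngle(mk(p[1, ], p[2, ], p[3, ])), lawCos,
               tolerance = 1e-9)
  expect_error(bendingAngle(mk(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))),
               "oincident")
})

test_that("chi1 dihedrals are measured in [0, 360) with the residue-type table", {
  mkRes <- function(chi1Deg, resname = "PHE", gname = "CG") {
    N <- c(-0.5, 1.3, 0); CA <- c(0, 0, 0); CB <- c(1.53, 0, 0)
    # place the gamma atom at the requested torsion about the CA-CB axis
    base <- c(1.53 + 1.5 * cos(pi - 1.94), 1.5 * sin(pi - 1.94), 0)
    a <- chi1Deg * pi / 180
    rel <- base - CB
    axis <- (CB - CA) / sqrt(sum((CB - CA)^2))
    # Rodrigues rotation about the CA->CB axis
    rot <- rel * cos(a) + pracmaCross(axis, rel) * sin(a) +
      axis * sum(axis * rel) * (1 - cos(a))
    G <- CB + rot
    StructureModel(data.frame(
      chain = "I", resno = 22L, resname = resname,
      elety = c("N", "CA", "CB", gname),
      element = c("N", "C", "C", substr(gname, 1, 1)),
      x = c(N[1], CA[1], CB[1], G[1]), y = c(N[2], CA[2], CB[2], G[2]),
      z = c(N[3], CA[3], CB[3], G[3]), het = FALSE,
      stringsAsFactors = FALSE), roleMap = c(I = "inhibitor"))
  }
  pracmaCross <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                                  u[3] * v[1] - u[1] * v[3],
                                  u[1] * v[2] - u[2] * v[1])
  # planar cis arrangement: chi1 = 0
  expect_equal(chi1Dihedral(mkRes(0), "I", 22), 0, tolerance = 1e-9)
  # constructed 120-degree twist is recovered exactly
  expect_equal(chi1Dihedral(mkRes(120), "I", 22), 120, tolerance = 1e-9)
  expect_equal(chi1Dihedral(mkRes(240), "I", 22), 240, tolerance = 1e-9)
  # serine uses OG; alanine has no gamma atom
  expect_equal(chi1Dihedral(mkRes(300, "SER", "OG"), "I", 22), 300,
               tolerance = 1e-9)
  expect_error(chi1Dihedral(mkRes(0, "ALA"), "I", 22), "no gamma atom")
})

test_that("chi1 states partition every angle exhaustively and exclusively", {
  expect_identical(as.character(chi1State(200)), "state200")
  expect_identical(as.character(chi1State(300)), "state300")
  expect_identical(as.character(chi1State(250)), "unassigned")
  grid <- seq(0, 359.5, by = 0.5)
  st <- chi1State(grid)
  expect_false(anyNA(st))
  inWindow200 <- abs((grid - 200 + 180) %% 360 - 180) <= 40
  inWindow300 <- abs((grid - 300 + 180) %% 360 - 180) <= 40
  expect_identical(st == "state200", inWindow200)
  expect_identical(st == "state300", inWindow300 & !inWindow200)
})

test_that("minimum residue distances equal the all-pairs oracle", {
  m <- caChainModel(rbind(c(0, 0, 0), c(3, 0, 0)), chain = "I",
                    resno = 1:2, role = "inhibitor")
  expect_equal(minResidueDistance(m, "I", 1, "I", 2), 3)
  set.seed(21)
  a <- data.frame(chain = "I", resno = rep(1:2, each = 5),
                  resname = "GLU", elety = paste0("C", 1:10),
                  element = "C", x = rnorm(10, sd = 4),
                  y = rnorm(10, sd = 4), z = rnorm(10, sd = 4),
                  het = FALSE, stringsAsFactors = FALSE)
  m2 <- StructureModel(a, roleMap = c(I = "inhibitor"))
  A <- as.matrix(a[a$resno == 1, c("x", "y", "z")])
  B <- as.matrix(a[a$resno == 2, c("x", "y", "z")])
  oracle <- min(apply(A, 1, function(p)
    apply(B, 1, function(q) sqrt(sum((p - q)^2)))))
  expect_equal(minResidueDistance(m2, "I", 1, "I", 2), oracle,
               tolerance = 1e-12)
  expect_error(minResidueDistance(m2, "I", 1, "I", 1), "differ")
})

test_that("distance and angle metrics are invariant under rigid motions", {
  m <- buildMotor(seed = 0)
  s <- motorAsStructure(m)
  sI <- Selection("inhibitor", "1-4", "heavy")
  sG <- Selection("gamma", "267-272", "heavy")
  c0 <- contactCount(s, sI, sG)$count
  d0 <- minResidueDistance(s, "I", 1, "G", 267)
  h0 <- helicity(generateHelixChain(20, 0.5), "1-20")
  for (seed in c(31, 32, 33)) {
    rmv <- randomRigidMotion(seed)
    sR <- transformModel(s, rmv)
    expect_identical(contactCount(sR, sI, sG)$count, c0)
    expect_equal(minResidueDistance(sR, "I", 1, "G", 267), d0,
                 tolerance = 1e-9)
    hR <- transformModel(generateHelixChain(20, 0.5), rmv)
    expect_equal(helicity(hR, "1-20"), h0)
  }
})

test_that("per-frame metrics map over trajectories", {
  m <- buildMotor(seed = 0)
  r <- runLangevin(m, simProtocol(nSteps = 50, dt = 1e-3, seed = 2,
                                  stride = 10))
  df <- trajMetric(r$trajectory, minResidueDistance,
                   chainA = "I", resA = 1, chainB = "G", resB = 267,
                   name = "minDist")
  expect_identical(nrow(df), nFrames(r$trajectory))
  expect_identical(unique(df$metric), "minDist")
  expect_true(all(is.finite(df$value)))
})
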