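test_that("a handwritten PDB parses with coordinates echoed exactly", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2      -1.250   0.500  10.125  1.00  0.00           C",
    "ATOM      3  CA  ALA A   3       0.001  -2.000   3.000  1.00  0.00           C"),
    f)
  m <- readPDB(f)
  expect_s4_class(m, "StructureModel")
  expect_identical(nrow(atomData(m)), 3L)
  expect_equal(coords(m),
               matrix(c(1, 2, 3, -1.25, 0.5, 10.125, 0.001, -2, 3),
                      ncol = 3, byrow = TRUE,
                      dimnames = list(NULL, c("x", "y", "z"))))
})

test_that("multi-model files become trajectories with shared atom order", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       2.000   2.000   3.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   1       1.500   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       2.500   2.000   3.000  1.00  0.00           C",
    "ENDMDL"), f)
  tr <- readPDB(f, modelPolicy = "all")
  expect_s4_class(tr, "Trajectory")
  expect_identical(nFrames(tr), 2L)
  expect_equal(coords(tr, 2)[, 1], c(1.5, 2.5))
  # first-model policy returns a single model
  m1 <- readPDB(f, modelPolicy = "first")
  expect_s4_class(m1, "StructureModel")
})

test_that("unreadable coordinate fields raise a parse error with a line number", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       xx.xxx   2.000   3.000  1.00  0.00           C"),
    f)
  expect_error(readPDB(f), "line 2")
})

test_that("write/read round-trips a toy-motor trajectory", {
  m <- buildMotor(seed = 0)
  r <- runLangevin(m, simProtocol(nSteps = 40, dt = 1e-3, seed = 3,
                                  stride = 10))
  f <- withr::local_tempfile(fileext = ".pdb")
  writeMultiModelPDB(r$trajectory, f)
  # 5 MODEL blocks for 5 sampled frames
  expect_identical(sum(grepl("^MODEL", readLines(f))), 5L)
  back <- readPDB(f, modelPolicy = "all",
                  roleMap = roleMap(r$trajectory@topology))
  expect_identical(nFrames(back), nFrames(r$trajectory))
  expect_equal(back@xyz, round(r$trajectory@xyz, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(atomData(back)[, c("chain", "resno", "elety")],
                   atomData(r$trajectory)[, c("chain", "resno", "elety")])
})

test_that("coordinates exceeding the PDB field width are an error, not truncated", {
  xyz <- matrix(c(12345, 0, 0), 1)
  m <- caChainModel(xyz)
  expect_error(writeMultiModelPDB(m, withr::local_tempfile(fileext = ".pdb")),
               "fixed-width")
})

test_that("selections return brute-force residue counts in deterministic order", {
  xyz <- cbind(seq_len(10), 0, 0)
  m <- caChainModel(xyz, chain = "G", role = "gamma")
  out <- selectAtoms(m, Selection("gamma", "1-3", "CA"))
  expect_identical(nrow(out$coords), 3L)
  expect_equal(out$coords[, 1], c(1, 2, 3))

  # gamma-core selection on a full-length synthetic gamma: 26 + 45 residues
  g272 <- caChainModel(cbind(cos(1:272), sin(1:272), (1:272) / 10),
                       chain = "G", resno = 1:272)
  core <- selectAtoms(g272, Selection("gamma", "1-26,228-272", "CA"))
  expect_identical(nrow(core$coords),
                   length(c(1:26, 228:272)))   # brute-force enumeration

  # default pair subsets on a complete synthetic pair, against enumeration
  sf <- generateSyntheticF1()
  subs <- defaultPairSubsets()
  ca <- selectAtoms(sf, subs$alpha, chain = "A")
  cb <- selectAtoms(sf, subs$beta, chain = "D")
  nAlpha <- length(c(24:401, 413:483, 494:509))
  nBeta <- length(c(10:126, 129:310, 312:387, 396:464))
  expect_identical(nrow(ca$coords), nAlpha)
  expect_identical(nrow(cb$coords), nBeta)
  expect_identical(nAlpha + nBeta, 909L)
})

test_that("missing residues in a selection are reported, not dropped", {
  xyz <- cbind(seq_len(10), 0, 0)
  m <- caChainModel(xyz, chain = "B", resno = c(1:4, 8:13), role = "beta")
  expect_error(selectAtoms(m, Selection("beta", "1-10", "CA")), "5, 6, 7")
})

test_that("atom ordering is invariant under record shuffling", {
  sf <- generateSyntheticF1()
  a <- atomData(sf)
  set.seed(42)
  shuffled <- StructureModel(a[sample(nrow(a)), ], roleMap = roleMap(sf))
  expect_identical(atomData(shuffled), a)
})

test_that("chain roles are auto-detected from residue counts", {
  sf <- generateSyntheticF1()
  auto <- chainRoleMap(sf)
  expect_identical(unname(auto[c("A", "B", "C")]), rep("alpha", 3))
  expect_identical(unname(auto[c("D", "E", "F")]), rep("beta", 3))
  expect_identical(unname(auto["G"]), "gamma")
  expect_identical(unname(auto["I"]), "inhibitor")
})

test_that("intersect mode restricts to residues resolved in all structures", {
  full <- caChainModel(cbind(1:20, 0, 0), chain = "G", role = "gamma")
  gappy <- caChainModel(cbind(1:18, 0, 0), chain = "G",
                        resno = c(1:9, 12:20), role = "gamma")
  common <- commonResidues(list(full, gappy), "gamma")
  expect_identical(common, sort(c(1:9, 12:20)))
  out <- selectAtoms(full, Selection("gamma", "1-20", "CA"),
                     restrict = common)
  expect_identical(nrow(out$coords), 18L)
})

test_that("selection configs and frame metadata round-trip through files", {
  cfg <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("gamma_core:",
               "  role: gamma",
               "  ranges: 1-26,228-272",
               "  atoms: CA"), cfg)
  sels <- readSelectionConfig(cfg)
  expect_identical(sels$gamma_core@chainRole, "gamma")
  expect_identical(unname(sels$gamma_core@ranges),
                   matrix(c(1L, 26L, 228L, 272L), 2, byrow = TRUE))

  m <- buildMotor(seed = 0)
  r <- runLangevin(m, simProtocol(nSteps = 30, dt = 1e-3, seed = 1,
                                  stride = 10))
  f <- withr::local_tempfile(fileext = ".csv")
  writeFrameMetadata(r$trajectory, f)
  df <- readFrameMetadata(f)
  expect_identical(names(df)[1:2], c("frame", "time_ns"))
  expect_equal(df$g1, frameMetadata(r$trajectory)$g1, tolerance = 1e-6)
})
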