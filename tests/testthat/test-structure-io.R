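test_that("single ATOM records parse with names, numbering and coordinates", {
  m <- readStructure("ATOM      1  CA  ASP A   1      11.000  22.000  33.000")
  expect_equal(nAtoms(m), 1L)
  a <- atoms(m)
  expect_equal(a$name, "CA")
  expect_equal(a$resname, "ASP")
  expect_equal(a$resid, 1L)
  expect_equal(a$chain, "A")
  expect_equal(unname(atomCoords(m)[1, ]), c(11, 22, 33))
  expect_false(a$hydrogen)
})

test_that("empty and malformed input raise informative parse errors", {
  expect_error(readStructure("REMARK nothing here"), "no ATOM records")
  expect_error(readStructure(""), "no ATOM records")
  bad <- c("ATOM      1  CA  ASP A   1      11.000  22.000  33.000",
           "ATOM      2  CA  ALA A   2      xx.xxx  22.000  33.000")
  expect_error(readStructure(bad), "malformed ATOM record at line 2")
})

test_that("only the first MODEL is used as the structure", {
  txt <- c("MODEL 1",
           "ATOM      1  CA  ASP A   1       1.000   0.000   0.000",
           "ENDMDL",
           "MODEL 2",
           "ATOM      1  CA  ASP A   1       9.000   9.000   9.000",
           "ENDMDL")
  m <- readStructure(txt)
  expect_equal(nAtoms(m), 1L)
  expect_equal(unname(atomCoords(m)[1, ]), c(1, 0, 0))
})

test_that("topology assignment follows the convention tag and is bijective", {
  mkchains <- function(n) {
    df <- data.frame(serial = seq_len(n), name = "CA", resname = "GLY",
                     resid = 1L, chain = c(LETTERS, letters)[seq_len(n)],
                     x = as.numeric(seq_len(n)), y = 0, z = 0,
                     element = "C", hydrogen = FALSE)
    makeModel(df)
  }
  m <- assignTopology(mkchains(9L), 3, 3, "layer-major")
  top <- topologyMap(m)
  expect_equal(top$filament[match(c("A", "B", "C"), top$chain)], c(1L, 2L, 3L))
  expect_equal(top$layer[match(c("A", "B", "C"), top$chain)], c(1L, 1L, 1L))

  mf <- assignTopology(mkchains(9L), 3, 3, "filament-major")
  topf <- topologyMap(mf)
  expect_equal(topf$filament[match(c("A", "B", "C"), topf$chain)], c(1L, 1L, 1L))
  expect_equal(topf$layer[match(c("A", "B", "C"), topf$chain)], c(1L, 2L, 3L))

  m36 <- assignTopology(mkchains(36L), 3, 12)
  grid <- with(topologyMap(m36), paste(filament, layer))
  expect_equal(sort(grid), sort(as.vector(outer(1:3, 1:12, paste))))

  expect_error(assignTopology(mkchains(8L), 3, 3), "expected 9 chains.*found 8")
})

test_that("frames read back congruent and in file order", {
  m <- buildIdealFibril(fibrilBlueprint(nLayers = 2))
  one <- writeStructure(m)
  block <- strsplit(one, "\n")[[1]]
  block <- block[block != "END"]
  txt <- c("MODEL 1", block, "ENDMDL", "MODEL 2", block, "ENDMDL",
           "MODEL 3", block, "ENDMDL")
  fr <- readFrames(txt, m)
  expect_equal(nFrames(fr), 3L)
  expect_equal(frameCoords(fr, 1), frameCoords(fr, 3))
  expect_equal(frameTimes(fr), c(0, 1, 2))

  short <- c("MODEL 1", block, "ENDMDL", "MODEL 2", block[-5], "ENDMDL")
  expect_error(readFrames(short, m), "MODEL 2")
})

test_that("write/read round trips preserve metadata exactly and coordinates to 1e-3", {
  m <- buildIdealFibril(fibrilBlueprint(nLayers = 2))
  m2 <- readStructure(writeStructure(m))
  expect_equal(atoms(m2)$name, atoms(m)$name)
  expect_equal(atoms(m2)$resid, atoms(m)$resid)
  expect_equal(atoms(m2)$resname, atoms(m)$resname)
  expect_equal(atoms(m2)$chain, atoms(m)$chain)
  expect_lt(max(abs(atomCoords(m2) - atomCoords(m))), 1e-3 + 1e-12)

  one <- makeModel(data.frame(serial = 1L, name = "CA", resname = "GLY",
                              resid = 1L, chain = "A", x = 1.2345, y = 0, z = 0,
                              element = "C", hydrogen = FALSE))
  lines <- strsplit(writeStructure(one), "\n")[[1]]
  expect_equal(sum(grepl("^ATOM", lines)), 1L)

  tr <- simulateTrajectory(buildIdealFibril(fibrilBlueprint(nLayers = 2)),
                           trajectoryConfig("stable", nFrames = 2,
                                            jitterSigma = 0.2, seed = 3))
  mm <- buildIdealFibril(fibrilBlueprint(nLayers = 2))
  mt <- writeFrames(tr, mm)
  expect_equal(sum(grepl("^MODEL", strsplit(mt, "\n")[[1]])), 2L)
  rt <- readFrames(mt, mm)
  expect_equal(frameCoords(rt, 2), round(frameCoords(tr, 2), 3),
               ignore_attr = TRUE)
})

test_that("model validity enforces the topology bijection", {
  df <- data.frame(serial = 1:2, name = "CA", resname = "GLY", resid = 1L,
                   chain = c("A", "B"), x = c(0, 1), y = 0, z = 0,
                   element = "C", hydrogen = FALSE)
  bad <- data.frame(chain = c("A", "B"), filament = c(1L, 1L), layer = c(1L, 1L))
  expect_error(new("FibrilModel", atoms = df, topology = bad,
                   nFilaments = 2L, nLayers = 1L), "bijection")
})

test_that("water residues are counted once per molecule", {
  df <- data.frame(serial = 1:7,
                   name = c("CA", "O", "H1", "H2", "O", "H1", "H2"),
                   resname = c("GLY", rep("HOH", 6)),
                   resid = c(1L, 2L, 2L, 2L, 3L, 3L, 3L),
                   chain = "W", x = 0, y = 0, z = as.numeric(1:7),
                   element = c("C", "O", "H", "H", "O", "H", "H"),
                   hydrogen = c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE))
  expect_equal(countWaters(makeModel(df)), 2L)
})
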