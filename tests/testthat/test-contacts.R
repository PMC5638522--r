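twoAtomModel <- function(d) {
  makeModel(data.frame(serial = 1:2, name = "CA", resname = "GLY",
                       resid = c(1L, 2L), chain = c("A", "B"),
                       x = c(0, d), y = 0, z = 0,
                       element = "C", hydrogen = FALSE))
}

test_that("atom-pair contacts use a strict 4 A cutoff and are symmetric", {
  m <- twoAtomModel(3.9)
  expect_equal(atomPairContacts(m, NULL, 1L, 2L), 1L)
  expect_equal(atomPairContacts(twoAtomModel(4.1), NULL, 1L, 2L), 0L)
  # boundary equality counts as no contact
  expect_equal(atomPairContacts(twoAtomModel(4.0), NULL, 1L, 2L), 0L)
  expect_equal(atomPairContacts(m, NULL, 2L, 1L),
               atomPairContacts(m, NULL, 1L, 2L))
  expect_error(atomPairContacts(m, NULL, 1:2, 2L), "disjoint")
})

test_that("grid-accelerated counts equal the brute-force double loop", {
  set.seed(71)
  for (rep in 1:8) {
    nA <- sample(20:60, 1); nB <- sample(20:60, 1)
    A <- matrix(runif(nA * 3, 0, 15), nA)
    B <- matrix(runif(nB * 3, 0, 15), nB)
    df <- data.frame(serial = seq_len(nA + nB), name = "CA", resname = "GLY",
                     resid = 1L, chain = rep(c("A", "B"), c(nA, nB)),
                     x = c(A[, 1], B[, 1]), y = c(A[, 2], B[, 2]),
                     z = c(A[, 3], B[, 3]), element = "C", hydrogen = FALSE)
    m <- makeModel(df)
    expect_equal(atomPairContacts(m, NULL, seq_len(nA), nA + seq_len(nB)),
                 bruteContacts(A, B, 4.0))
  }
})

test_that("hydrogens are excluded under the heavy-atom scope", {
  df <- data.frame(serial = 1:3, name = c("CA", "HA", "CA"),
                   resname = "GLY", resid = c(1L, 1L, 2L),
                   chain = c("A", "A", "B"),
                   x = c(0, 1, 3), y = 0, z = 0,
                   element = c("C", "H", "C"), hydrogen = c(FALSE, TRUE, FALSE))
  m <- makeModel(df)
  expect_equal(atomPairContacts(m, NULL, 1:2, 3L), 2L)
  expect_equal(atomPairContacts(m, NULL, 1:2, 3L,
                                contactDefinition(includeHydrogens = FALSE)), 1L)
})

test_that("residue contact fractions average frames and chain pairs", {
  m <- buildIdealFibril(fibrilBlueprint(nLayers = 2))
  X <- atomCoords(m)
  # residues permanently apart: 0 %
  expect_equal(residueContactFraction(staticFrames(m, 3), m, 1, 30), 0)
  # engineered Arg5-Glu22: in contact on every pair, every frame
  expect_equal(residueContactFraction(staticFrames(m, 3), m, 5, 22), 100)

  # in contact in exactly half the frames on every chain pair: 50 %
  # (displace every arm beyond the cutoff in half the frames)
  away <- X
  allArms <- which(atoms(m)$resid <= 8)
  away[allArms, 3] <- away[allArms, 3] + 100
  half <- makeFrames(list(X, X, away, away))
  expect_equal(residueContactFraction(half, m, 5, 22), 50)

  # alternating-layer behaviour: layer 1 holds, layer 2 loses at t/2 -> 75 %
  top <- topologyMap(m)
  ch12 <- top$chain[top$filament == 1 & top$layer == 2]
  arm2 <- which(atoms(m)$chain == ch12 & atoms(m)$resid <= 8)
  lost <- X; lost[arm2, 3] <- lost[arm2, 3] + 50
  fr <- makeFrames(list(X, X, lost, lost))
  pairs <- data.frame(chainA = top$chain[top$filament == 1 & top$layer %in% 1:2],
                      chainB = top$chain[top$filament == 2 & top$layer %in% 1:2])
  expect_equal(residueContactFraction(fr, m, 5, 22, pairs = pairs), 75)

  # several runs are averaged with equal weight
  expect_equal(residueContactFraction(list(staticFrames(m, 2), half), m, 5, 22),
               75)
})

test_that("the arm-turn contact map lights exactly the engineered cells", {
  m <- buildIdealFibril(fibrilBlueprint(nLayers = 2))
  cm <- contactMap(staticFrames(m), m)
  vals <- mapValues(cm)
  expect_true(all(vals[vals > 0] == 100))
  lit <- which(vals > 0, arr.ind = TRUE)
  lit <- data.frame(row = rownames(vals)[lit[, 1]], col = colnames(vals)[lit[, 2]])
  lit <- lit[order(lit$row, lit$col), ]
  expect_equal(paste(lit$row, lit$col),
               sort(c("ARG5 GLU22", "ARG5 VAL24", "ASP7 SER26", "SER8 SER26")))

  # determinism: identical maps on repeated invocation
  cm2 <- contactMap(staticFrames(m), m)
  expect_identical(mapValues(cm), mapValues(cm2))

  # displacing the arms empties the map completely
  X <- atomCoords(m)
  arm <- which(atoms(m)$resid <= 8)
  X[arm, 3] <- X[arm, 3] + 100
  expect_true(all(mapValues(contactMap(makeFrames(list(X)), m)) == 0))

  # truncated chains cannot produce the map
  tr <- truncateNTerminus(m, 9)
  expect_error(contactMap(staticFrames(tr), tr), "empty-map")
})

test_that("kymographs order chain pairs as in the fibril stack", {
  m6 <- buildIdealFibril(fibrilBlueprint(nLayers = 6))
  ky <- contactKymograph(staticFrames(m6, 3), m6, 5, 22)
  expect_equal(dim(ky), c(18L, 3L))
  expect_true(all(ky == 1))
  expect_equal(rownames(ky)[1], "F1-F2.L01")
  expect_equal(rownames(ky)[18], "F3-F1.L06")

  m12 <- buildIdealFibril(fibrilBlueprint(nLayers = 12))
  expect_equal(nrow(contactKymograph(staticFrames(m12), m12, 5, 22)), 36L)

  # a contact lost at frame k in one row flips only that row
  X <- atomCoords(m6)
  top <- topologyMap(m6)
  ch <- top$chain[top$filament == 1 & top$layer == 3]
  arm <- which(atoms(m6)$chain == ch & atoms(m6)$resid <= 8)
  lost <- X; lost[arm, 3] <- lost[arm, 3] + 50
  ky2 <- contactKymograph(makeFrames(list(X, X, lost)), m6, 5, 22)
  expect_equal(ky2["F1-F2.L03", ], c(1, 1, 0))
  expect_true(all(ky2[rownames(ky2) != "F1-F2.L03", ] == 1))

  # min-distance variant reports the engineered 3.8 A
  kyd <- contactKymograph(staticFrames(m6), m6, 5, 22, value = "mindist")
  expect_equal(unname(kyd[1, 1]), 3.8, tolerance = 1e-6)
})

test_that("inter-filament series normalise per layer and detect the 2+1 course", {
  m3 <- buildIdealFibril(fibrilBlueprint(nLayers = 3))
  m6 <- buildIdealFibril(fibrilBlueprint(nLayers = 6))
  s3 <- interfilamentSeries(staticFrames(m3), m3)
  s6 <- interfilamentSeries(staticFrames(m6), m6)
  # duplicating layers leaves per-layer counts unchanged
  expect_equal(contactCounts(s3), contactCounts(s6))
  expect_equal(totalContacts(s3), sum(contactCounts(s3)[1, ]))
  # C3 symmetry: all three interfaces identical
  expect_equal(unname(contactCounts(s3)[1, 1]), unname(contactCounts(s3)[1, 2]))
  expect_equal(unname(contactCounts(s3)[1, 2]), unname(contactCounts(s3)[1, 3]))

  # separated filaments: all zeros
  X <- atomCoords(m3)
  top <- topologyMap(m3)
  for (f in 2:3) {
    i <- which(atoms(m3)$chain %in% top$chain[top$filament == f])
    X[i, 3] <- X[i, 3] + f * 200
  }
  expect_true(all(contactCounts(interfilamentSeries(makeFrames(list(X)), m3)) == 0))

  # raw counts are per-layer counts times the layer number
  sr <- interfilamentSeries(staticFrames(m6), m6, normalization = "raw")
  expect_equal(contactCounts(sr), contactCounts(s6) * 6)

  # synthetic 2+1 trajectory: one interface ends far above the others and
  # the total dips before recovering
  fx <- fixtureSuite(nFrames = 30)
  s <- interfilamentSeries(fx$two_plus_one$trajectory, fx$two_plus_one$model)
  cc <- contactCounts(s)
  k <- nrow(cc)
  expect_gte(cc[k, 2], 4 * max(cc[k, c(1, 3)]))
  tot <- totalContacts(s)
  expect_lt(min(tot), 0.5 * tot[1])
  expect_gt(tot[k], 2 * min(tot))
})
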