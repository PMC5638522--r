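toyBackbone <- function(coords, resid = NULL) {
  n <- nrow(coords)
  if (is.null(resid)) resid <- 8L + seq_len(n)
  makeModel(data.frame(serial = seq_len(n), name = "CA", resname = "GLY",
                       resid = resid, chain = "A",
                       x = coords[, 1], y = coords[, 2], z = coords[, 3],
                       element = "C", hydrogen = FALSE))
}

test_that("filament axes span the outermost layers and transform equivariantly", {
  m <- buildIdealFibril(fibrilBlueprint(nLayers = 6))
  ax <- filamentAxes(m)
  expect_equal(dim(ax), c(3L, 3L))
  for (f in 1:3) expect_equal(unname(ax[f, ]), c(0, 0, 5 * 4.8))

  set.seed(11)
  rig <- randomRigid()
  ax2 <- filamentAxes(m, applyRigid(atomCoords(m), rig))
  expect_equal(ax2, ax %*% t(rig$R), tolerance = 1e-9)

  m1 <- buildIdealFibril(fibrilBlueprint(nLayers = 1))
  expect_error(filamentAxes(m1), "at least two layers")
})

test_that("mean pairwise angle matches closed forms and a brute-force oracle", {
  expect_equal(meanPairwiseAngle(rbind(c(0, 0, 1), c(0, 0, 1), c(0, 0, 2))), 0)
  tilted <- rbind(c(0, 0, 1), c(0, 0, 1), c(0, sin(pi / 6), cos(pi / 6)))
  expect_equal(meanPairwiseAngle(tilted), 20, tolerance = 1e-9)

  # tilts about distinct radial directions vs direct pairwise acos
  set.seed(21)
  for (theta in c(5, 15, 30)) {
    axes <- t(vapply(1:3, function(f) {
      u <- c(cos(2 * pi * f / 3), sin(2 * pi * f / 3), 0)
      th <- theta * pi / 180
      # rotate z-axis about radial direction u by theta
      k <- u
      v <- c(0, 0, 1)
      v * cos(th) + c(k[2] * v[3] - k[3] * v[2],
                      k[3] * v[1] - k[1] * v[3],
                      k[1] * v[2] - k[2] * v[1]) * sin(th)
    }, numeric(3)))
    oracle <- mean(c(
      acos(sum(axes[1, ] * axes[2, ])),
      acos(sum(axes[2, ] * axes[3, ])),
      acos(sum(axes[1, ] * axes[3, ])))) * 180 / pi
    expect_equal(meanPairwiseAngle(axes), oracle, tolerance = 1e-9)
  }
  expect_error(meanPairwiseAngle(rbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 0))),
               "degenerate-axis")
})

test_that("pore distance averages intra-layer Met35 reference pairs", {
  # three Met35 sulfurs on an equilateral triangle of side 20
  ang <- c(90, 210, 330) * pi / 180
  r <- 20 / sqrt(3)
  df <- data.frame(serial = 1:3, name = "SD", resname = "MET", resid = 35L,
                   chain = c("A", "B", "C"),
                   x = r * cos(ang), y = r * sin(ang), z = 0,
                   element = "S", hydrogen = FALSE)
  m <- makeModel(df, 3L, 1L, assign = TRUE)
  expect_equal(poreDistance(m), 20, tolerance = 1e-9)

  # rigid translation leaves the value unchanged
  shifted <- sweep(atomCoords(m), 2, c(5, -3, 12), "+")
  expect_equal(poreDistance(m, shifted), 20, tolerance = 1e-9)

  ideal <- buildIdealFibril(fibrilBlueprint(nLayers = 3))
  expect_equal(poreDistance(ideal), sqrt(3) * 11.5, tolerance = 1e-9)
  expect_equal(poreDistance(ideal, layers = 2), sqrt(3) * 11.5, tolerance = 1e-9)
})

test_that("backbone RMSD is a superposition minimum matching the SVD oracle", {
  set.seed(31)
  X <- matrix(rnorm(12, sd = 3), 4)
  m <- toyBackbone(X)
  expect_equal(backboneRmsd(m, X, X), 0)

  rig <- randomRigid()
  expect_equal(backboneRmsd(m, applyRigid(X, rig), X), 0, tolerance = 1e-9)

  Y <- X + matrix(rnorm(12, sd = 0.7), 4)
  expect_equal(backboneRmsd(m, X, Y), oracleRmsd(X, Y), tolerance = 1e-9)
  # symmetry
  expect_equal(backboneRmsd(m, X, Y), backboneRmsd(m, Y, X), tolerance = 1e-9)
  expect_error(backboneRmsd(m, X, Y[1:3, ]), "congruence")
  expect_error(backboneRmsd(m, X, Y, residRange = 100:120), "congruence")
})

test_that("backbone RMSF reproduces closed forms", {
  set.seed(41)
  X <- matrix(rnorm(15, sd = 5), 5)
  m <- toyBackbone(X)
  static <- makeFrames(rep(list(X), 4))
  r0 <- backboneRmsf(static, m)
  expect_equal(unname(r0$perAtom), rep(0, 5))
  expect_equal(r0$meanAtom, 0)

  # one atom oscillating +/- d along x, superposition disabled -> RMSF = d
  d <- 0.8
  up <- X; up[3, 1] <- X[3, 1] + d
  dn <- X; dn[3, 1] <- X[3, 1] - d
  osc <- makeFrames(list(up, dn, up, dn))
  r1 <- backboneRmsf(osc, m, superpose = FALSE)
  expect_equal(unname(r1$perAtom[3]), d, tolerance = 1e-12)
  expect_equal(unname(r1$perAtom[1]), 0)

  # isotropic Gaussian jitter sigma -> mean RMSF ~ sigma * sqrt(3)
  sigma <- 0.3
  nfr <- 400
  set.seed(42)
  frames <- lapply(seq_len(nfr), function(i)
    X + matrix(rnorm(15, sd = sigma), 5))
  r2 <- backboneRmsf(makeFrames(frames), m, superpose = FALSE)
  expect_equal(r2$meanAtom, sigma * sqrt(3), tolerance = 0.05)

  expect_error(backboneRmsf(makeFrames(list(X)), m), "degenerate-input")
})

test_that("radius of gyration matches closed forms and the direct-sum oracle", {
  two <- toyBackbone(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(radiusOfGyration(two, massWeighted = FALSE), 1)
  expect_equal(radiusOfGyration(two), 1)  # equal masses

  set.seed(51)
  P <- matrix(rnorm(60, sd = 4), 20)
  cloud <- toyBackbone(P, resid = rep(9:13, 4))
  masses <- rep(12.011, 20)
  expect_equal(radiusOfGyration(cloud), oracleRg(P, masses), tolerance = 1e-9)
  # scaling by k scales Rg by k
  expect_equal(radiusOfGyration(cloud, P * 3),
               3 * radiusOfGyration(cloud), tolerance = 1e-9)

  # per-layer mean on the ideal fibril: every layer identical, so equal to
  # a single layer's Rg and smaller than the whole-assembly value
  m <- buildIdealFibril(fibrilBlueprint(nLayers = 6))
  perLayer <- radiusOfGyration(m, scope = "per_layer_mean")
  l1 <- topologyMap(m)$chain[topologyMap(m)$layer == 1]
  sub <- atoms(m)[atoms(m)$chain %in% l1, ]
  one <- makeModel(sub)
  expect_equal(perLayer, radiusOfGyration(one), tolerance = 1e-9)
  expect_lt(perLayer, radiusOfGyration(m, scope = "whole"))
})

test_that("residue pair distances cover both modes", {
  df <- data.frame(serial = 1:2, name = c("CG", "CG"), resname = "ASP",
                   resid = c(7L, 7L), chain = c("A", "B"),
                   x = c(0, 3), y = c(0, 4), z = 0,
                   element = "C", hydrogen = FALSE)
  m <- makeModel(df)
  expect_equal(residuePairDistance(m, NULL, "A", 7, "B", 7), 5)
  expect_equal(residuePairDistance(m, NULL, "A", 7, "A", 7), 0)
  expect_equal(residuePairDistance(m, NULL, "A", 7, "B", 7,
                                   mode = "named_atoms",
                                   atomA = "CG", atomB = "CG"), 5)
  expect_error(residuePairDistance(m, NULL, "A", 8, "B", 7), "selection error")
})

test_that("geometric metrics are invariant under rigid-body motion", {
  m <- buildIdealFibril(fibrilBlueprint(nLayers = 3))
  X <- atomCoords(m)
  set.seed(61)
  for (i in 1:10) {
    rig <- randomRigid()
    Y <- applyRigid(X, rig)
    expect_lt(abs(meanInterfilamentAngle(m, Y) - meanInterfilamentAngle(m, X)),
              1e-5)
    expect_equal(poreDistance(m, Y), poreDistance(m, X), tolerance = 1e-8)
    expect_equal(radiusOfGyration(m, Y), radiusOfGyration(m, X),
                 tolerance = 1e-8)
    expect_equal(backboneRmsd(m, Y, X), 0, tolerance = 1e-8)
  }
})
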