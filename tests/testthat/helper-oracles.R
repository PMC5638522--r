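# Independent oracles and small model builders shared by the test files.
# Oracles are deliberately written as direct, unoptimised implementations of
# the definitions, separate from the package's code paths.

# O(n^2) brute-force contact count (strict < cutoff), plain double loop
bruteContacts <- function(A, B, cutoff) {
  n <- 0L
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    if (sqrt(sum((A[i, ] - B[j, ])^2)) < cutoff) n <- n + 1L
  }
  n
}

# direct SVD superposition RMSD (Kabsch), written from the definition
oracleRmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P)); Qc <- sweep(Q, 2, colMeans(Q))
  s <- svd(t(Pc) %*% Qc)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
}

# direct-sum definition of the radius of gyration
oracleRg <- function(P, m) {
  cm <- colSums(P * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(P, 2, cm)^2)) / sum(m))
}

# random proper rotation matrix + translation
randomRigid <- function() {
  M <- matrix(rnorm(9), 3)
  qr_ <- qr(M)
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 20))
}

applyRigid <- function(X, rig) sweep(X %*% t(rig$R), 2, rig$t, "+")

# minimal hand-built model from an atom spec data.frame
makeModel <- function(df, nFilaments = 0L, nLayers = 0L, assign = FALSE) {
  need <- c("serial", "name", "resname", "resid", "chain",
            "x", "y", "z", "element", "hydrogen")
  if (!"serial" %in% names(df)) df$serial <- seq_len(nrow(df))
  if (!"element" %in% names(df)) df$element <- substr(df$name, 1, 1)
  if (!"hydrogen" %in% names(df)) df$hydrogen <- df$element == "H"
  m <- new("FibrilModel", atoms = df[, need], topology = data.frame(),
           nFilaments = 0L, nLayers = 0L)
  if (assign) m <- assignTopology(m, nFilaments, nLayers)
  m
}

# trajectory from a list of coordinate matrices
makeFrames <- function(coordList) {
  new("TrajectoryFrames", coords = coordList,
      times = as.numeric(seq_along(coordList) - 1L))
}

staticFrames <- function(model, n = 1L) {
  makeFrames(rep(list(atomCoords(model)), n))
}

# the eight published solvated systems: layers, sequence form, waters, total
tableOneSystems <- function() {
  full <- ABETA40
  trunc <- substr(ABETA40, 9, 40)
  data.frame(
    system = c("AL_3xInf", "AT_3xInf", "AL_3x12", "AT_3x12",
               "AL_3x6", "AT_3x6", "AL_3x3", "AT_3x3"),
    nLayers = c(12L, 12L, 12L, 12L, 6L, 6L, 3L, 3L),
    sequence = c(full, trunc, full, trunc, full, trunc, full, trunc),
    nTerminus = rep(c("charged", "acetyl"), 4),
    nWaters = c(24488L, 16503L, 38302L, 20053L, 33395L, 14903L, 23577L, 13137L),
    totalAtoms = c(95100L, 66897L, 136542L, 77547L, 111003L, 53403L, 76140L, 43758L),
    stringsAsFactors = FALSE)
}
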