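# Per-frame structural order parameters: filament axes and their mean pairwise
# angle, the Met35-Met35 pore dimension, backbone RMSD/RMSF after optimal
# rigid-body superposition, radius of gyration, and residue-pair distances.

.ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                  NA. = 22.990, P = 30.974)

.element_mass <- function(element) {
  m <- .ATOMIC_MASS[ifelse(element == "NA", "NA.", element)]
  m[is.na(m)] <- 12.011  # unknown elements treated as carbon
  unname(m)
}

.coords_or_model <- function(model, coords) {
  if (is.null(coords)) atomCoords(model) else as.matrix(coords)
}

#' Filament axis vectors from the outermost layers
#'
#' The axis of filament f is the vector from the Phe19 Calpha in its
#' bottommost layer to the Phe19 Calpha in its topmost layer. For the
#' periodic (infinite) system these are the first and last layers of the
#' primary cell.
#'
#' @param model a [FibrilModel-class] with assigned topology and >= 2 layers.
#' @param coords optional n x 3 frame coordinates (default: the model's own).
#' @param resid residue whose Calpha anchors the axis (default 19, Phe19).
#' @return F x 3 matrix of axis vectors (rows = filaments).
#' @export
filamentAxes <- function(model, coords = NULL, resid = 19L) {
  L <- nLayers(model)
  if (L < 2L)
    stop("filament axes need at least two layers", call. = FALSE)
  xyz <- .coords_or_model(model, coords)
  F <- nFilaments(model)
  axes <- matrix(NA_real_, F, 3L)
  for (f in seq_len(F)) {
    pick <- function(l) {
      i <- .sel_atoms(model, chain = .chain_at(model, f, l), resid = resid,
                      name = "CA")
      if (length(i) != 1L)
        stop(sprintf("selection error: Calpha of residue %d missing in filament %d, layer %d",
                     resid, f, l), call. = FALSE)
      xyz[i, ]
    }
    axes[f, ] <- pick(L) - pick(1L)
  }
  axes
}

#' Mean pairwise angle between axis vectors
#'
#' Arc-cosine of the normalised dot product, averaged over all unordered
#' pairs of rows; the dot product is clamped to [-1, 1] before acos.
#'
#' @param axes k x 3 matrix of direction vectors (k >= 2).
#' @return mean pairwise angle in degrees, in [0, 180].
#' @examples
#' a <- rbind(c(0, 0, 1), c(0, 0, 1), c(0, sin(pi / 6), cos(pi / 6)))
#' meanPairwiseAngle(a)  # mean of {0, 30, 30} = 20 degrees
#' @export
meanPairwiseAngle <- function(axes) {
  axes <- as.matrix(axes)
  k <- nrow(axes)
  nrm <- sqrt(rowSums(axes^2))
  if (any(nrm < 1e-12))
    stop("degenerate-axis error: zero-norm axis vector", call. = FALSE)
  tot <- 0; n <- 0L
  for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
    d <- sum(axes[i, ] * axes[j, ]) / (nrm[i] * nrm[j])
    tot <- tot + acos(min(1, max(-1, d)))
    n <- n + 1L
  }
  (tot / n) * 180 / pi
}

#' Mean inter-filament torsion angle of one frame
#'
#' Computes the three filament axes (Phe19 Calpha, outermost layers) and
#' returns the mean over the three unordered filament pairs of the angle
#' between the axes. Near zero for an aligned, untwisted stack.
#'
#' @inheritParams filamentAxes
#' @return angle in degrees.
#' @export
meanInterfilamentAngle <- function(model, coords = NULL) {
  meanPairwiseAngle(filamentAxes(model, coords))
}

#' Per-frame inter-filament angle series
#'
#' @param frames a [TrajectoryFrames-class].
#' @param model the congruent [FibrilModel-class].
#' @return numeric vector, one mean inter-filament angle (degrees) per frame.
#' @export
angleSeries <- function(frames, model) {
  vapply(seq_len(nFrames(frames)),
         function(i) meanInterfilamentAngle(model, frameCoords(frames, i)),
         numeric(1))
}

.met_ref_index <- function(model, chain, metAtom) {
  if (metAtom == "centroid") return(NULL)
  i <- .sel_atoms(model, chain = chain, resid = 35L, name = metAtom)
  if (length(i) != 1L)
    stop(sprintf("selection error: Met35 atom %s missing in chain %s", metAtom, chain),
         call. = FALSE)
  i
}

#' Met35-Met35 pore dimension
#'
#' The central water pore of the triple fibril is lined by the C-terminal
#' sheets; its width is read off as the mean distance between the Met35
#' side-chain reference atoms of the three chains within one layer (about 23
#' Angstrom in the deposited structure, relaxing to about 20 Angstrom in
#' simulation). The reference atom defaults to the side-chain sulfur SD and
#' may be set to CE or to the side-chain centroid.
#'
#' @inheritParams filamentAxes
#' @param layers layer indices to average over (default: all layers).
#' @param metAtom `"SD"`, `"CE"`, or `"centroid"` (mean of side-chain heavy
#'   atoms beyond Cbeta, falling back to all Met35 heavy atoms).
#' @return mean intra-layer Met35-Met35 distance in Angstrom.
#' @export
poreDistance <- function(model, coords = NULL, layers = NULL,
                         metAtom = c("SD", "CE", "centroid")) {
  metAtom <- match.arg(metAtom)
  xyz <- .coords_or_model(model, coords)
  if (is.null(layers)) layers <- seq_len(nLayers(model))
  F <- nFilaments(model)
  if (F < 2L) stop("pore distance needs at least two filaments", call. = FALSE)
  refpos <- function(chain) {
    if (metAtom == "centroid") {
      i <- .sel_atoms(model, chain = chain, resid = 35L, heavyOnly = TRUE)
      side <- i[!model@atoms$name[i] %in% c("N", "CA", "C", "O", "CB")]
      if (length(side)) i <- side
      if (length(i) == 0L)
        stop(sprintf("selection error: Met35 missing in chain %s", chain), call. = FALSE)
      colMeans(xyz[i, , drop = FALSE])
    } else {
      xyz[.met_ref_index(model, chain, metAtom), ]
    }
  }
  vals <- c()
  for (l in layers) {
    pos <- t(vapply(seq_len(F), function(f) refpos(.chain_at(model, f, l)),
                    numeric(3)))
    for (i in seq_len(F - 1L)) for (j in seq((i + 1L), F))
      vals <- c(vals, sqrt(sum((pos[i, ] - pos[j, ])^2)))
  }
  mean(vals)
}

#' Per-frame pore-dimension series
#'
#' @inheritParams angleSeries
#' @inheritParams poreDistance
#' @return numeric vector of per-frame mean Met35-Met35 distances (Angstrom).
#' @export
poreSeries <- function(frames, model, layers = NULL,
                       metAtom = c("SD", "CE", "centroid")) {
  metAtom <- match.arg(metAtom)
  vapply(seq_len(nFrames(frames)),
         function(i) poreDistance(model, frameCoords(frames, i), layers, metAtom),
         numeric(1))
}

# Kabsch: rotation + translation minimising RMSD of x (moving) onto y (target)
.superpose <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2L, cx); yc <- sweep(y, 2L, cy)
  s <- svd(crossprod(xc, yc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotate = function(m) sweep(sweep(m, 2L, cx) %*% t(R), 2L, cy, "+"),
       rmsd = sqrt(mean(rowSums((xc %*% t(R) - yc)^2))))
}

.backbone_idx <- function(model, residRange, atomNames) {
  a <- model@atoms
  which(a$resid %in% residRange & a$name %in% atomNames & a$resname != "ACE")
}

#' Backbone RMSD after optimal superposition
#'
#' Root-mean-square deviation of the backbone atoms (those of N, Calpha, C, O
#' present in both structures) over a residue range, minimised over rigid-body
#' transforms (Kabsch/SVD superposition). The range defaults to residues 9-40
#' so that full-length and truncated systems are compared on the same atoms.
#'
#' @param model a [FibrilModel-class] describing both coordinate sets.
#' @param coords n x 3 frame coordinates.
#' @param reference n x 3 reference coordinates (congruent with `coords`).
#' @param residRange residues included (default `9:40`).
#' @param atomNames backbone atom names (default N, CA, C, O).
#' @param superpose superpose before measuring (default TRUE).
#' @return RMSD in Angstrom.
#' @export
backboneRmsd <- function(model, coords, reference, residRange = 9:40,
                         atomNames = c("N", "CA", "C", "O"), superpose = TRUE) {
  coords <- as.matrix(coords); reference <- as.matrix(reference)
  if (!all(dim(coords) == dim(reference)))
    stop("congruence error: coordinate sets differ in size", call. = FALSE)
  idx <- .backbone_idx(model, residRange, atomNames)
  if (length(idx) == 0L)
    stop("congruence error: no backbone atoms in the requested residue range",
         call. = FALSE)
  x <- coords[idx, , drop = FALSE]
  y <- reference[idx, , drop = FALSE]
  if (superpose) .superpose(x, y)$rmsd
  else sqrt(mean(rowSums((x - y)^2)))
}

#' Backbone RMSF about the time-average structure
#'
#' Each frame is superposed onto the reference (default: the first frame) on
#' the selected backbone atoms; the fluctuation of each atom is its RMS
#' deviation about the time-average of the superposed coordinates. Both the
#' per-atom profile and its per-residue reduction (mean over that residue's
#' backbone atoms) are returned, along with both possible scalar summaries.
#'
#' @param frames a [TrajectoryFrames-class] with >= 2 frames.
#' @param model the congruent [FibrilModel-class].
#' @param residRange residues included (default `9:40`).
#' @param atomNames backbone atom names.
#' @param reference optional n x 3 reference coordinates (default first frame).
#' @param superpose superpose each frame first (default TRUE).
#' @return list with `perAtom` (named by atom index), `perResidue` (named by
#'   residue number), `meanAtom` and `meanResidue` (Angstrom).
#' @export
backboneRmsf <- function(frames, model, residRange = 9:40,
                         atomNames = c("N", "CA", "C", "O"), reference = NULL,
                         superpose = TRUE) {
  nf <- nFrames(frames)
  if (nf < 2L)
    stop("degenerate-input error: RMSF needs at least two frames", call. = FALSE)
  idx <- .backbone_idx(model, residRange, atomNames)
  if (length(idx) == 0L)
    stop("selection error: no backbone atoms in the requested residue range",
         call. = FALSE)
  ref <- if (is.null(reference)) frameCoords(frames, 1L) else as.matrix(reference)
  refSel <- ref[idx, , drop = FALSE]
  stack <- array(NA_real_, c(length(idx), 3L, nf))
  for (i in seq_len(nf)) {
    x <- frameCoords(frames, i)[idx, , drop = FALSE]
    stack[, , i] <- if (superpose) .superpose(x, refSel)$rotate(x) else x
  }
  avg <- apply(stack, c(1L, 2L), mean)
  dev2 <- vapply(seq_len(nf), function(i) rowSums((stack[, , i] - avg)^2),
                 numeric(length(idx)))
  dev2 <- matrix(dev2, nrow = length(idx))
  perAtom <- sqrt(rowMeans(dev2))
  resid <- model@atoms$resid[idx]
  perResidue <- tapply(perAtom, resid, mean)
  list(perAtom = stats::setNames(perAtom, idx),
       perResidue = perResidue,
       meanAtom = mean(perAtom),
       meanResidue = mean(perResidue))
}

#' Radius of gyration
#'
#' Mass-weighted radius of gyration, either of the whole assembly or as the
#' mean over layers of each layer's three-chain radius of gyration (the
#' per-layer reading used for the published per-system values).
#'
#' @inheritParams filamentAxes
#' @param scope `"whole"` or `"per_layer_mean"`.
#' @param massWeighted use atomic masses (default TRUE; FALSE = unit masses).
#' @return radius of gyration in Angstrom.
#' @export
radiusOfGyration <- function(model, coords = NULL,
                             scope = c("whole", "per_layer_mean"),
                             massWeighted = TRUE) {
  scope <- match.arg(scope)
  xyz <- .coords_or_model(model, coords)
  rg1 <- function(i) {
    if (length(i) == 0L) stop("selection error: empty selection", call. = FALSE)
    m <- if (massWeighted) .element_mass(model@atoms$element[i]) else rep(1, length(i))
    p <- xyz[i, , drop = FALSE]
    cm <- colSums(p * m) / sum(m)
    sqrt(sum(m * rowSums(sweep(p, 2L, cm)^2)) / sum(m))
  }
  if (scope == "whole") return(rg1(seq_len(nrow(xyz))))
  top <- model@topology
  if (nrow(top) == 0L)
    stop("per-layer radius of gyration needs an assigned topology", call. = FALSE)
  mean(vapply(seq_len(nLayers(model)), function(l) {
    chs <- top$chain[top$layer == l]
    rg1(which(model@atoms$chain %in% chs))
  }, numeric(1)))
}

#' Distance between two residues
#'
#' Default mode is the minimum heavy-atom distance between the two residues;
#' `"named_atoms"` measures between two specific atoms. Side-chain-only
#' variants are available via `sideChainOnly`.
#'
#' @inheritParams filamentAxes
#' @param chainA,resA,chainB,resB the two residues.
#' @param mode `"min_heavy"` or `"named_atoms"`.
#' @param atomA,atomB atom names for `"named_atoms"` mode.
#' @param sideChainOnly restrict `"min_heavy"` to side-chain heavy atoms
#'   (excluding N, CA, C, O).
#' @return distance in Angstrom.
#' @export
residuePairDistance <- function(model, coords = NULL, chainA, resA, chainB, resB,
                                mode = c("min_heavy", "named_atoms"),
                                atomA = NULL, atomB = NULL,
                                sideChainOnly = FALSE) {
  mode <- match.arg(mode)
  xyz <- .coords_or_model(model, coords)
  get <- function(chain, resid, atom) {
    if (mode == "named_atoms") {
      i <- .sel_atoms(model, chain = chain, resid = resid, name = atom)
    } else {
      i <- .sel_atoms(model, chain = chain, resid = resid, heavyOnly = TRUE)
      if (sideChainOnly) {
        side <- i[!model@atoms$name[i] %in% c("N", "CA", "C", "O")]
        if (length(side)) i <- side
      }
    }
    if (length(i) == 0L)
      stop(sprintf("selection error: residue %d of chain %s (atom %s) not found",
                   resid, chain, if (is.null(atom)) "any" else atom), call. = FALSE)
    xyz[i, , drop = FALSE]
  }
  A <- get(chainA, resA, atomA)
  B <- get(chainB, resB, atomB)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(max(0, min(d2)))
}
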