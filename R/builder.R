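# Fibril construction from a template layer: stacking by the mean
# inter-layer displacement vector, N-terminal truncation with acetyl capping,
# and the periodic z-box adjustment for infinite fibrils.

.CHAIN_ID_POOL <- c(LETTERS, letters, as.character(0:9))

#' Mean displacement vector between adjacent fibril layers
#'
#' Averages, over all filaments, all adjacent layer pairs, and all atoms
#' matched by (residue number, atom name), the displacement from layer l to
#' layer l+1. For an untwisted in-register fibril this is the cross-beta
#' stacking vector (norm ~4.8 Angstrom, along the fibril axis).
#'
#' @param model a [FibrilModel-class] with assigned topology and >= 2 layers.
#' @return numeric length-3 displacement vector in Angstrom.
#' @export
meanLayerDisplacement <- function(model) {
  L <- nLayers(model)
  if (L < 2L)
    stop("insufficient layers: need at least 2 layers to measure the stacking vector",
         call. = FALSE)
  a <- model@atoms
  total <- c(0, 0, 0); n <- 0L
  for (f in seq_len(nFilaments(model))) {
    for (l in seq_len(L - 1L)) {
      lo <- a[a$chain == .chain_at(model, f, l), , drop = FALSE]
      hi <- a[a$chain == .chain_at(model, f, l + 1L), , drop = FALSE]
      key_lo <- paste(lo$resid, lo$name)
      key_hi <- paste(hi$resid, hi$name)
      common <- intersect(key_lo, key_hi)
      if (length(common) == 0L)
        stop(sprintf("congruence error: no matched atoms between layers %d and %d of filament %d",
                     l, l + 1L, f), call. = FALSE)
      ilo <- match(common, key_lo); ihi <- match(common, key_hi)
      d <- as.matrix(hi[ihi, c("x", "y", "z")]) - as.matrix(lo[ilo, c("x", "y", "z")])
      total <- total + colSums(d)
      n <- n + nrow(d)
    }
  }
  unname(total / n)
}

#' Replicate a template layer into a multi-layer fibril
#'
#' Builds a regular in-register fibril by translating the template layer by
#' integer multiples of the displacement vector `v` (zero twist, matching the
#' untwisted deposited structure). Chains get fresh single-character
#' identifiers and a layer-major topology map.
#'
#' @param template a [FibrilModel-class] with exactly one layer (topology
#'   assigned with `nLayers = 1`).
#' @param v length-3 displacement vector between adjacent layers (Angstrom).
#' @param nLayers number of layers to build (>= 1).
#' @return a [FibrilModel-class] with `nLayers` layers.
#' @export
replicateLayers <- function(template, v, nLayers) {
  nLayers <- as.integer(nLayers)
  if (nLayers < 1L) stop("nLayers must be >= 1", call. = FALSE)
  if (nLayers(template) != 1L)
    stop("template must contain exactly one layer", call. = FALSE)
  F <- nFilaments(template)
  if (F * nLayers > length(.CHAIN_ID_POOL))
    stop("too many chains for single-character PDB chain identifiers", call. = FALSE)
  a0 <- template@atoms
  chains0 <- vapply(seq_len(F), function(f) .chain_at(template, f, 1L), character(1))
  out <- vector("list", nLayers * F)
  id <- 0L
  for (l in seq_len(nLayers)) {
    for (f in seq_len(F)) {
      id <- id + 1L
      sub <- a0[a0$chain == chains0[f], , drop = FALSE]
      sub$x <- sub$x + (l - 1L) * v[1L]
      sub$y <- sub$y + (l - 1L) * v[2L]
      sub$z <- sub$z + (l - 1L) * v[3L]
      sub$chain <- .CHAIN_ID_POOL[id]
      out[[id]] <- sub
    }
  }
  atoms <- do.call(rbind, out)
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  m <- new("FibrilModel", atoms = atoms, topology = data.frame(),
           nFilaments = 0L, nLayers = 0L)
  assignTopology(m, F, nLayers, chainOrder = "layer-major")
}

# unit vector helper
.unit <- function(v) v / sqrt(sum(v^2))

# any unit vector perpendicular to d
.perp <- function(d) {
  ref <- if (abs(d[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  .unit(ref - sum(ref * d) * d)
}

.acetyl_atoms <- function(pN, dirPrev, resid, chain) {
  d <- .unit(dirPrev)
  w <- .perp(d)
  C <- pN + 1.335 * d
  O <- C + 1.229 * (cos(123 * pi / 180) * (-d) - sin(123 * pi / 180) * w)
  CH3 <- C + 1.510 * (cos(116 * pi / 180) * (-d) + sin(116 * pi / 180) * w)
  u <- .unit(CH3 - C)
  w2 <- .perp(u)
  w3 <- c(u[2] * w2[3] - u[3] * w2[2],
          u[3] * w2[1] - u[1] * w2[3],
          u[1] * w2[2] - u[2] * w2[1])
  hs <- lapply(0:2, function(k) {
    ang <- 2 * pi * k / 3
    CH3 + 1.09 * (cos(109.5 * pi / 180) * u +
                    sin(109.5 * pi / 180) * (cos(ang) * w2 + sin(ang) * w3))
  })
  pos <- rbind(CH3, C, O, hs[[1L]], hs[[2L]], hs[[3L]])
  data.frame(serial = 0L,
             name = c("CH3", "C", "O", "HH31", "HH32", "HH33"),
             resname = "ACE", resid = resid, chain = chain,
             x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
             element = c("C", "C", "O", "H", "H", "H"),
             hydrogen = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
             stringsAsFactors = FALSE)
}

#' Truncate the N-terminus of every chain and add an acetyl cap
#'
#' Removes residues below `firstKeptResidue` from every chain and places a
#' 6-atom acetyl blocking group (CH3 with 3 H, C, O) bonded to the new
#' N-terminal nitrogen, oriented along the former backbone direction. Applied
#' to the full-length peptide with `firstKeptResidue = 9` this substitutes
#' the first eight residues with the cap; on an already-capped model it is a
#' no-op (idempotent on the residue range).
#'
#' @param model a [FibrilModel-class]; every chain must reach down to its
#'   first residue range.
#' @param firstKeptResidue first residue retained (default 9).
#' @return the truncated, capped model (same topology map).
#' @export
truncateNTerminus <- function(model, firstKeptResidue = 9L) {
  firstKeptResidue <- as.integer(firstKeptResidue)
  a <- model@atoms
  out <- list()
  for (ch in unique(a$chain)) {
    sub <- a[a$chain == ch, , drop = FALSE]
    pep <- sub[sub$resname != "ACE", , drop = FALSE]
    if (any(sub$resname == "ACE") && min(pep$resid) == firstKeptResidue) {
      out[[ch]] <- sub  # already truncated and capped at this residue
      next
    }
    if (min(pep$resid) > firstKeptResidue)
      stop(sprintf("incomplete-chain error: chain %s starts at residue %d (> %d)",
                   ch, min(pep$resid), firstKeptResidue), call. = FALSE)
    if (max(pep$resid) < firstKeptResidue)
      stop(sprintf("incomplete-chain error: chain %s ends before residue %d",
                   ch, firstKeptResidue), call. = FALSE)
    first <- pep[pep$resid == firstKeptResidue, , drop = FALSE]
    anchorName <- if ("N" %in% first$name) "N" else first$name[1L]
    pN <- unlist(first[match(anchorName, first$name), c("x", "y", "z")], use.names = FALSE)
    prevRes <- pep[pep$resid == firstKeptResidue - 1L, , drop = FALSE]
    if (nrow(prevRes) > 0L) {
      prevName <- if ("CA" %in% prevRes$name) "CA" else prevRes$name[1L]
      pPrev <- unlist(prevRes[match(prevName, prevRes$name), c("x", "y", "z")],
                      use.names = FALSE)
      dirPrev <- pPrev - pN
    } else {
      # boundary case firstKeptResidue = 1: cap along -(N -> CA)
      caName <- if ("CA" %in% first$name) "CA" else first$name[min(2L, nrow(first))]
      pCA <- unlist(first[match(caName, first$name), c("x", "y", "z")], use.names = FALSE)
      dirPrev <- pN - pCA
      if (sum(dirPrev^2) < 1e-12) dirPrev <- c(1, 0, 0)
    }
    kept <- sub[sub$resname == "ACE" | sub$resid >= firstKeptResidue, , drop = FALSE]
    cap <- .acetyl_atoms(pN, dirPrev, firstKeptResidue - 1L, ch)
    out[[ch]] <- rbind(cap, kept)
  }
  atoms <- do.call(rbind, out)
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  model@atoms <- atoms
  validObject(model)
  model
}

#' Periodic z-box adjustment for an infinite fibril
#'
#' For a fibril aligned with the z axis inside a cuboid box of height `boxZ`,
#' the distance between the topmost layer and the periodic image of the
#' bottommost layer is `d_img = boxZ - (zTop - zBottom)` (measured on matched
#' reference atoms, by default the Calpha centroids of the terminal layers).
#' The box is shrunk by `shrink = d_img - templateSpacing` so that the image
#' spacing equals the template's layer spacing exactly and the fibril becomes
#' continuous across the boundary.
#'
#' @param model a [FibrilModel-class] with assigned topology, fibril axis
#'   along z.
#' @param boxZ cuboid box height (Angstrom), larger than the fibril extent.
#' @param templateSpacing target image spacing = template layer spacing
#'   (Angstrom).
#' @param referenceAtoms atom name(s) used for the terminal-layer reference
#'   centroids (default `"CA"`).
#' @return list with `newZ`, `shrink`, and the achieved `imageSpacing`.
#' @export
periodicZAdjustment <- function(model, boxZ, templateSpacing,
                                referenceAtoms = "CA") {
  a <- model@atoms
  L <- nLayers(model)
  top <- model@topology
  zl <- function(l) {
    chs <- top$chain[top$layer == l]
    sel <- a$chain %in% chs & a$name %in% referenceAtoms
    if (!any(sel)) stop("no reference atoms found in terminal layer", call. = FALSE)
    mean(a$z[sel])
  }
  zBottom <- zl(1L); zTop <- zl(L)
  extent <- zTop - zBottom
  dImg <- boxZ - extent
  if (dImg <= 0)
    stop("geometry error: box height does not exceed the fibril extent",
         call. = FALSE)
  shrink <- dImg - templateSpacing
  newZ <- boxZ - shrink
  if (shrink >= boxZ || newZ < extent)
    stop("geometry error: adjusted box would be smaller than the fibril extent",
         call. = FALSE)
  list(newZ = newZ, shrink = shrink, imageSpacing = newZ - extent)
}

#' Delete waters outside the shrunken periodic box
#'
#' A water is kept iff its oxygen z coordinate lies in the half-open interval
#' `[0, newZ)`; the half-open convention avoids double counting a molecule on
#' the periodic face. Input order is preserved.
#'
#' @param waterOxygens n x 3 matrix of water oxygen positions (Angstrom).
#' @param newZ adjusted box height.
#' @return list with `kept` (the retained rows) and `nDeleted`.
#' @export
pruneWatersOutside <- function(waterOxygens, newZ) {
  waterOxygens <- as.matrix(waterOxygens)
  keep <- waterOxygens[, 3L] >= 0 & waterOxygens[, 3L] < newZ
  list(kept = waterOxygens[keep, , drop = FALSE],
       nDeleted = sum(!keep))
}
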