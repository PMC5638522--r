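# 4 Angstrom atom-pair contact statistics: raw pair counts, residue-level
# contact frequencies (the N-terminal-arm x turn-region map), per-chain-pair
# kymographs, and inter-filament contact series.

#' Construct a contact definition
#'
#' @param cutoff distance cutoff in Angstrom (default 4.0); strict `<`.
#' @param includeHydrogens include hydrogens in the pair counts (default TRUE;
#'   the all-atom reading matches the published inter-filament magnitudes).
#' @return a [ContactDefinition-class].
#' @export
contactDefinition <- function(cutoff = 4.0, includeHydrogens = TRUE) {
  new("ContactDefinition", cutoff = cutoff,
      atomScope = if (includeHydrogens) "all" else "heavy")
}

.scope_filter <- function(model, idx, cd) {
  if (cd@atomScope == "heavy") idx[!model@atoms$hydrogen[idx]] else idx
}

#' Count atom pairs within the contact cutoff
#'
#' Number of atom pairs (a in A, b in B) with distance strictly below the
#' cutoff, computed with a cell-list spatial grid. Selections must be
#' disjoint atom-index sets.
#'
#' @param model a [FibrilModel-class].
#' @param coords optional n x 3 frame coordinates (default: the model's own).
#' @param selectionA,selectionB integer atom indices into the model's atom
#'   table.
#' @param cd a [ContactDefinition-class] (default 4 Angstrom, all atoms).
#' @return integer pair count.
#' @export
atomPairContacts <- function(model, coords = NULL, selectionA, selectionB,
                             cd = contactDefinition()) {
  if (length(intersect(selectionA, selectionB)))
    stop("selection error: selections must be disjoint", call. = FALSE)
  xyz <- .coords_or_model(model, coords)
  ia <- .scope_filter(model, selectionA, cd)
  ib <- .scope_filter(model, selectionB, cd)
  if (length(ia) == 0L || length(ib) == 0L) return(0L)
  as.integer(.cpp_count_contacts(xyz[ia, , drop = FALSE],
                                 xyz[ib, , drop = FALSE], cd@cutoff))
}

# intra-layer cyclic successor chain pairs: (F1 -> F2, F2 -> F3, F3 -> F1)
# in every layer; returns a data.frame of chainA (arm side) / chainB (turn
# side) with the filament pair and layer they belong to.
.successor_pairs <- function(model) {
  F <- nFilaments(model); L <- nLayers(model)
  if (F < 2L) stop("topology error: need at least 2 filaments", call. = FALSE)
  out <- list(); k <- 0L
  for (f in seq_len(F)) {
    fn <- if (f == F) 1L else f + 1L
    for (l in seq_len(L)) {
      k <- k + 1L
      out[[k]] <- data.frame(chainA = .chain_at(model, f, l),
                             chainB = .chain_at(model, fn, l),
                             filament = f, layer = l,
                             stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

.res_pair_contact <- function(model, xyz, chainA, resA, chainB, resB, cd,
                              value = c("contact", "mindist")) {
  value <- match.arg(value)
  ia <- .scope_filter(model, .sel_atoms(model, chain = chainA, resid = resA), cd)
  ib <- .scope_filter(model, .sel_atoms(model, chain = chainB, resid = resB), cd)
  if (length(ia) == 0L || length(ib) == 0L)
    stop(sprintf("selection error: residue %d/%d missing on chains %s/%s",
                 resA, resB, chainA, chainB), call. = FALSE)
  A <- xyz[ia, , drop = FALSE]; B <- xyz[ib, , drop = FALSE]
  if (value == "contact") .cpp_any_contact(A, B, cd@cutoff) else .cpp_min_dist(A, B)
}

#' Residue-pair contact frequency in percent
#'
#' A residue pair is in contact in a frame iff at least one of its atom pairs
#' lies within the cutoff. The frequency is the percentage of frames in
#' contact, averaged over all intra-layer cyclic neighbour chain pairs
#' (filaments 1 to 2, 2 to 3, 3 to 1 in every layer) and, when a list of
#' trajectories is supplied, averaged over runs with equal weight.
#'
#' @param frames a [TrajectoryFrames-class] or a list of them (several runs).
#' @param model the congruent [FibrilModel-class].
#' @param resA residue number on the first (arm-side) chain of each pair.
#' @param resB residue number on the neighbour (turn-side) chain.
#' @param cd a [ContactDefinition-class].
#' @param pairs optional data.frame of chainA/chainB pairs overriding the
#'   cyclic-successor rule.
#' @return percentage in [0, 100].
#' @export
residueContactFraction <- function(frames, model, resA, resB,
                                   cd = contactDefinition(), pairs = NULL) {
  if (is.list(frames) && !is(frames, "TrajectoryFrames")) {
    return(mean(vapply(frames, residueContactFraction, numeric(1),
                       model = model, resA = resA, resB = resB, cd = cd,
                       pairs = pairs)))
  }
  if (is.null(pairs)) pairs <- .successor_pairs(model)
  hits <- 0L; n <- 0L
  for (i in seq_len(nFrames(frames))) {
    xyz <- frameCoords(frames, i)
    for (p in seq_len(nrow(pairs))) {
      hits <- hits + .res_pair_contact(model, xyz, pairs$chainA[p], resA,
                                       pairs$chainB[p], resB, cd)
      n <- n + 1L
    }
  }
  100 * hits / n
}

#' Contact-frequency map between two residue stretches
#'
#' The map of the published analysis: contact frequencies between the
#' N-terminal residues 1-8 of each chain and the turn residues 21-30 of its
#' cyclic neighbour in the same layer, as mean percentages over all layers
#' (and runs, when several trajectories are given).
#'
#' @inheritParams residueContactFraction
#' @param rows,cols residue numbers for the two stretches (defaults 1:8 and
#'   21:30).
#' @return a [ContactMap-class] with residue-labelled dimnames.
#' @export
contactMap <- function(frames, model, rows = 1:8, cols = 21:30,
                       cd = contactDefinition()) {
  present <- unique(model@atoms$resid[model@atoms$resname != "ACE"])
  if (!any(rows %in% present))
    stop(sprintf("empty-map error: none of residues %s are present (truncated model?)",
                 paste(range(rows), collapse = "-")), call. = FALSE)
  vals <- matrix(NA_real_, length(rows), length(cols))
  for (i in seq_along(rows)) for (j in seq_along(cols))
    vals[i, j] <- residueContactFraction(frames, model, rows[i], cols[j], cd)
  lab <- function(res) {
    rn <- model@atoms$resname[match(res, model@atoms$resid)]
    paste0(rn, res)
  }
  dimnames(vals) <- list(lab(rows), lab(cols))
  new("ContactMap", values = vals, rows = as.integer(rows),
      cols = as.integer(cols), cutoff = cd@cutoff)
}

#' Per-chain-pair contact kymograph
#'
#' Time course of one residue-pair interaction for every intra-layer chain
#' pair, ordered as in the fibril stack: rows 1..L are the filament 1-2
#' pairs (layers bottom to top), rows L+1..2L the 2-3 pairs, rows 2L+1..3L
#' the 3-1 pairs, so a 12-layer triple fibril gives 36 rows.
#'
#' @inheritParams residueContactFraction
#' @param value `"contact"` (0/1 matrix) or `"mindist"` (minimum atom-pair
#'   distance in Angstrom).
#' @return matrix with 3L rows and one column per frame; rownames give
#'   filament pair and layer.
#' @export
contactKymograph <- function(frames, model, resA, resB,
                             cd = contactDefinition(),
                             value = c("contact", "mindist")) {
  value <- match.arg(value)
  pairs <- .successor_pairs(model)
  # pair-major ordering: filament pair blocks, layers within
  pairs <- pairs[order(pairs$filament, pairs$layer), , drop = FALSE]
  nf <- nFrames(frames)
  out <- matrix(NA_real_, nrow(pairs), nf)
  for (i in seq_len(nf)) {
    xyz <- frameCoords(frames, i)
    for (p in seq_len(nrow(pairs))) {
      v <- .res_pair_contact(model, xyz, pairs$chainA[p], resA,
                             pairs$chainB[p], resB, cd, value)
      out[p, i] <- as.numeric(v)
    }
  }
  F <- nFilaments(model)
  fn <- ifelse(pairs$filament == F, 1L, pairs$filament + 1L)
  rownames(out) <- sprintf("F%d-F%d.L%02d", pairs$filament, fn, pairs$layer)
  out
}

#' Inter-filament contact series
#'
#' Per-frame atom-pair contact counts between each pair of filaments (all
#' layers included), the published order parameter for the triple vs 2+1 vs
#' dissociated states. With `normalization = "per_layer"` counts are divided
#' by the number of layers, matching the "contacts per layer" reading of the
#' reported magnitudes (about 60 per interface for the stable triple fibril).
#'
#' @inheritParams residueContactFraction
#' @param normalization `"per_layer"` (default) or `"raw"`.
#' @return a [ContactSeries-class].
#' @export
interfilamentSeries <- function(frames, model, cd = contactDefinition(),
                                normalization = c("per_layer", "raw")) {
  normalization <- match.arg(normalization)
  F <- nFilaments(model)
  if (F != 3L)
    stop("topology error: inter-filament series are defined for 3 filaments",
         call. = FALSE)
  top <- model@topology
  filIdx <- lapply(seq_len(F), function(f)
    which(model@atoms$chain %in% top$chain[top$filament == f]))
  filIdx <- lapply(filIdx, function(i) .scope_filter(model, i, cd))
  pairs <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  nf <- nFrames(frames)
  counts <- matrix(0, nf, 3L)
  for (i in seq_len(nf)) {
    xyz <- frameCoords(frames, i)
    for (p in 1:3) {
      counts[i, p] <- .cpp_count_contacts(
        xyz[filIdx[[pairs[p, 1L]]], , drop = FALSE],
        xyz[filIdx[[pairs[p, 2L]]], , drop = FALSE], cd@cutoff)
    }
  }
  if (normalization == "per_layer") counts <- counts / nLayers(model)
  colnames(counts) <- c("F1-F2", "F2-F3", "F3-F1")
  new("ContactSeries", counts = counts, normalization = normalization,
      nLayers = nLayers(model), times = frameTimes(frames))
}
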