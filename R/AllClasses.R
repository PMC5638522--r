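#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib fibrilTools, .registration = TRUE
NULL

.ATOM_COLS <- c("serial", "name", "resname", "resid", "chain",
                "x", "y", "z", "element", "hydrogen")

#' FibrilModel: a fibril structure with a filament/layer topology map
#'
#' The central container of the package: an ordered atom table (one row per
#' atom, PDB-style naming) plus a topology map assigning every chain to a
#' (filament, layer) cell of the F x L fibril grid. The map is empty until
#' [assignTopology()] is called; all per-filament and per-layer analyses
#' require it.
#'
#' @slot atoms data.frame with columns `serial`, `name`, `resname`, `resid`,
#'   `chain`, `x`, `y`, `z`, `element`, `hydrogen`.
#' @slot topology data.frame with columns `chain`, `filament`, `layer`;
#'   zero rows while unassigned. When assigned it is a bijection between
#'   chain identifiers and the filament x layer grid.
#' @slot nFilaments integer, number of filaments F (3 for a triple fibril).
#' @slot nLayers integer, number of layers L.
#'
#' @seealso [readStructure()], [assignTopology()], [buildIdealFibril()]
#' @export
setClass("FibrilModel",
  representation(atoms = "data.frame", topology = "data.frame",
                 nFilaments = "integer", nLayers = "integer"),
  prototype(atoms = data.frame(), topology = data.frame(),
            nFilaments = 0L, nLayers = 0L))

setValidity("FibrilModel", function(object) {
  a <- object@atoms
  if (nrow(a) > 0L && !all(.ATOM_COLS %in% names(a)))
    return(paste("atoms must contain columns:", paste(.ATOM_COLS, collapse = ", ")))
  if (nrow(a) > 0L) {
    xyz <- as.matrix(a[, c("x", "y", "z")])
    if (!all(is.finite(xyz))) return("atom coordinates must be finite")
  }
  top <- object@topology
  if (nrow(top) > 0L) {
    if (!all(c("chain", "filament", "layer") %in% names(top)))
      return("topology must have columns chain, filament, layer")
    F <- object@nFilaments; L <- object@nLayers
    if (nrow(top) != F * L)
      return("topology must cover the full filament x layer grid")
    key <- paste(top$filament, top$layer)
    if (anyDuplicated(key) || anyDuplicated(top$chain))
      return("topology must be a bijection between chains and grid cells")
    if (!all(top$filament %in% seq_len(F)) || !all(top$layer %in% seq_len(L)))
      return("filament/layer indices out of range")
    if (!all(unique(a$chain) %in% top$chain))
      return("every chain in the atom table must appear in the topology map")
  }
  TRUE
})

#' TrajectoryFrames: ordered coordinate frames congruent with one model
#'
#' Holds the per-frame coordinates of a (real or synthetic) trajectory as a
#' list of n_atoms x 3 matrices, all congruent with one [FibrilModel-class]
#' atom table, together with strictly increasing frame times.
#'
#' @slot coords list of numeric matrices, one per frame, each n_atoms x 3.
#' @slot times numeric vector of frame times (ns; synthetic 0, 1, 2, ... when
#'   the source carries none).
#'
#' @seealso [readFrames()], [simulateTrajectory()]
#' @export
setClass("TrajectoryFrames",
  representation(coords = "list", times = "numeric"),
  prototype(coords = list(), times = numeric(0)))

setValidity("TrajectoryFrames", function(object) {
  n <- length(object@coords)
  if (length(object@times) != n) return("times must have one entry per frame")
  if (n > 1L && any(diff(object@times) <= 0)) return("times must be strictly increasing")
  if (n > 0L) {
    na <- nrow(object@coords[[1L]])
    ok <- vapply(object@coords, function(m) is.matrix(m) && ncol(m) == 3L && nrow(m) == na,
                 logical(1))
    if (!all(ok)) return("all frames must be n_atoms x 3 matrices of equal size")
  }
  TRUE
})

#' CompositionReport: atom/ion/water bookkeeping for one simulated system
#'
#' Reproduces the accounting behind a solvated fibril system: per-chain atom
#' count under a fixed protonation convention, net chain charge, the number of
#' Na+ counter ions required for neutrality, water count (3-site water), and
#' the grand total. Its validity method enforces
#' `totalAtoms == proteinAtoms + nCounterions + atomsPerWater * nWaters`.
#'
#' @slot nChains,atomsPerChain,proteinAtoms,netChargePerChain,nCounterions,nWaters,atomsPerWater,totalAtoms integers.
#' @seealso [systemComposition()]
#' @export
setClass("CompositionReport",
  representation(nChains = "integer", atomsPerChain = "integer",
                 proteinAtoms = "integer", netChargePerChain = "integer",
                 nCounterions = "integer", nWaters = "integer",
                 atomsPerWater = "integer", totalAtoms = "integer"))

setValidity("CompositionReport", function(object) {
  if (object@proteinAtoms != object@nChains * object@atomsPerChain)
    return("proteinAtoms must equal nChains * atomsPerChain")
  if (object@totalAtoms !=
      object@proteinAtoms + object@nCounterions + object@atomsPerWater * object@nWaters)
    return("total must equal protein + ions + atomsPerWater * waters")
  if (object@netChargePerChain < 0L &&
      object@nCounterions != -object@nChains * object@netChargePerChain)
    return("counter ions must neutralise the total negative protein charge")
  TRUE
})

#' ContactDefinition: what counts as an atom-pair contact
#'
#' @slot cutoff numeric distance cutoff in Angstrom (default 4.0); a pair is
#'   in contact iff its distance is strictly below the cutoff.
#' @slot atomScope `"all"` (include hydrogens) or `"heavy"`.
#' @seealso [contactDefinition()]
#' @export
setClass("ContactDefinition",
  representation(cutoff = "numeric", atomScope = "character"),
  prototype(cutoff = 4.0, atomScope = "all"))

setValidity("ContactDefinition", function(object) {
  if (length(object@cutoff) != 1L || !is.finite(object@cutoff) || object@cutoff <= 0)
    return("cutoff must be a single positive number")
  if (!object@atomScope %in% c("all", "heavy"))
    return("atomScope must be 'all' or 'heavy'")
  TRUE
})

#' ContactMap: residue-pair contact frequencies in percent
#'
#' @slot values numeric matrix of percentages in [0, 100]; rows are the first
#'   residue stretch (by default the N-terminal arm 1-8), columns the second
#'   (turn residues 21-30 of the cyclic neighbour chain).
#' @slot rows,cols integer residue numbers labelling the axes.
#' @slot cutoff numeric, the contact cutoff used (Angstrom).
#' @export
setClass("ContactMap",
  representation(values = "matrix", rows = "integer", cols = "integer",
                 cutoff = "numeric"))

setValidity("ContactMap", function(object) {
  v <- object@values
  if (nrow(v) != length(object@rows) || ncol(v) != length(object@cols))
    return("values dimensions must match row/col residue labels")
  if (any(v < 0 | v > 100)) return("percentages must lie in [0, 100]")
  TRUE
})

#' ContactSeries: per-frame inter-filament atom-pair contact counts
#'
#' @slot counts numeric matrix, n_frames x 3, columns ordered as the filament
#'   pairs F1-F2, F2-F3, F3-F1.
#' @slot normalization `"per_layer"` (counts divided by the number of layers)
#'   or `"raw"`.
#' @slot nLayers integer, layers of the underlying model.
#' @slot times numeric frame times.
#' @seealso [interfilamentSeries()], [classifyTrajectory()]
#' @export
setClass("ContactSeries",
  representation(counts = "matrix", normalization = "character",
                 nLayers = "integer", times = "numeric"))

setValidity("ContactSeries", function(object) {
  if (ncol(object@counts) != 3L) return("counts must have one column per filament pair")
  if (any(object@counts < 0)) return("contact counts must be nonnegative")
  if (!object@normalization %in% c("raw", "per_layer"))
    return("normalization must be 'raw' or 'per_layer'")
  TRUE
})

#' ClassifierConfig: thresholds for the contact-based topology classifier
#'
#' The study reports approximate per-layer inter-filament contact magnitudes
#' (about 60 per interface for the retained triple fibril, about 160 for the
#' reinforced pair and about 20 for the detached filament in the 2+1 state);
#' the thresholds separate those regimes and are always echoed in results.
#'
#' @slot tLow contacts/layer below which an interface counts as broken (default 10).
#' @slot tHigh contacts/layer above which an interface counts as paired (default 40).
#' @slot window smoothing window in frames for trajectory classification (default 10).
#' @seealso [classifierConfig()], [classifyFrame()]
#' @export
setClass("ClassifierConfig",
  representation(tLow = "numeric", tHigh = "numeric", window = "integer"),
  prototype(tLow = 10, tHigh = 40, window = 10L))

setValidity("ClassifierConfig", function(object) {
  if (object@tLow < 0 || object@tLow >= object@tHigh)
    return("need 0 <= tLow < tHigh")
  if (object@window < 1L) return("window must be >= 1")
  TRUE
})

#' FibrilBlueprint: parameters of the idealized synthetic triple fibril
#'
#' @slot nLayers integer number of layers (default 6).
#' @slot layerSpacing numeric cross-beta layer spacing in Angstrom (default 4.8).
#' @slot poreRadius numeric radial distance of the Met35 side-chain reference
#'   atom from the fibril axis (default 11.5 Angstrom, giving a Met35-Met35
#'   triangle side of sqrt(3) * 11.5 ~ 19.9 Angstrom, the observed ~20
#'   Angstrom pore dimension).
#' @slot sequence `"abeta40"` (full-length 1-40) or `"abeta9_40"` (truncated).
#' @seealso [fibrilBlueprint()], [buildIdealFibril()]
#' @export
setClass("FibrilBlueprint",
  representation(nLayers = "integer", layerSpacing = "numeric",
                 poreRadius = "numeric", sequence = "character"),
  prototype(nLayers = 6L, layerSpacing = 4.8, poreRadius = 11.5,
            sequence = "abeta40"))

setValidity("FibrilBlueprint", function(object) {
  if (object@nLayers < 1L) return("nLayers must be >= 1")
  if (object@layerSpacing <= 0) return("layerSpacing must be positive")
  if (object@poreRadius <= 0) return("poreRadius must be positive")
  if (!object@sequence %in% c("abeta40", "abeta9_40"))
    return("sequence must be 'abeta40' or 'abeta9_40'")
  TRUE
})

#' TrajectoryConfig: parameters of the synthetic rigid-body trajectory
#'
#' @slot mode one of `"stable"`, `"twist"`, `"dissociate"`, `"two_plus_one"`.
#' @slot nFrames integer >= 2.
#' @slot amplitude mode-specific magnitude: twist rate in degrees/frame,
#'   dissociation velocity in Angstrom/frame, or final pairing displacement in
#'   Angstrom for the 2+1 mode.
#' @slot jitterSigma standard deviation (Angstrom) of the i.i.d. isotropic
#'   Gaussian coordinate jitter added to every atom in every frame.
#' @slot seed integer RNG seed; identical configs give bit-identical frames.
#' @seealso [trajectoryConfig()], [simulateTrajectory()]
#' @export
setClass("TrajectoryConfig",
  representation(mode = "character", nFrames = "integer", amplitude = "numeric",
                 jitterSigma = "numeric", seed = "integer"))

setValidity("TrajectoryConfig", function(object) {
  if (!object@mode %in% c("stable", "twist", "dissociate", "two_plus_one"))
    return("unknown trajectory mode")
  if (object@nFrames < 2L) return("nFrames must be >= 2")
  if (object@jitterSigma < 0) return("jitterSigma must be >= 0")
  TRUE
})
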