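#' Accessors for fibril models and trajectories
#'
#' Standard accessor generics: `atoms()` returns the atom table,
#' `atomCoords()` the n x 3 coordinate matrix, `topologyMap()` the
#' chain -> (filament, layer) map, `nFilaments()`/`nLayers()` the grid shape,
#' `chainIds()` the chain identifiers in atom-table order, `nAtoms()` the atom
#' count, `nFrames()`/`frameTimes()` the trajectory shape and
#' `frameCoords(x, i)` the coordinates of frame `i`.
#'
#' @param x a [FibrilModel-class] or [TrajectoryFrames-class] object.
#' @param i frame index (for `frameCoords`).
#' @return See the individual accessor descriptions.
#' @name accessors
#' @aliases atoms atomCoords topologyMap nFilaments nLayers chainIds nAtoms
#'   nFrames frameTimes frameCoords
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("atomCoords", function(x) standardGeneric("atomCoords"))
#' @rdname accessors
#' @export
setGeneric("topologyMap", function(x) standardGeneric("topologyMap"))
#' @rdname accessors
#' @export
setGeneric("nFilaments", function(x) standardGeneric("nFilaments"))
#' @rdname accessors
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))
#' @rdname accessors
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))
#' @rdname accessors
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))

#' @rdname accessors
setMethod("atoms", "FibrilModel", function(x) x@atoms)
#' @rdname accessors
setMethod("atomCoords", "FibrilModel",
          function(x) as.matrix(x@atoms[, c("x", "y", "z")]))
#' @rdname accessors
setMethod("topologyMap", "FibrilModel", function(x) x@topology)
#' @rdname accessors
setMethod("nFilaments", "FibrilModel", function(x) x@nFilaments)
#' @rdname accessors
setMethod("nLayers", "FibrilModel", function(x) x@nLayers)
#' @rdname accessors
setMethod("chainIds", "FibrilModel", function(x) unique(x@atoms$chain))
#' @rdname accessors
setMethod("nAtoms", "FibrilModel", function(x) nrow(x@atoms))

#' @rdname accessors
setMethod("nFrames", "TrajectoryFrames", function(x) length(x@coords))
#' @rdname accessors
setMethod("frameTimes", "TrajectoryFrames", function(x) x@times)
#' @rdname accessors
setMethod("frameCoords", "TrajectoryFrames", function(x, i) x@coords[[i]])

setMethod("show", "FibrilModel", function(object) {
  top <- if (nrow(object@topology)) "assigned" else "unassigned"
  cat(sprintf("FibrilModel: %d atoms, %d chains (%d filaments x %d layers, topology %s)\n",
              nrow(object@atoms), length(unique(object@atoms$chain)),
              object@nFilaments, object@nLayers, top))
})

setMethod("show", "TrajectoryFrames", function(object) {
  n <- length(object@coords)
  na <- if (n) nrow(object@coords[[1L]]) else 0L
  cat(sprintf("TrajectoryFrames: %d frames x %d atoms, t = %s .. %s ns\n",
              n, na,
              if (n) format(object@times[1L]) else "-",
              if (n) format(object@times[n]) else "-"))
})

setMethod("show", "CompositionReport", function(object) {
  cat("CompositionReport\n")
  cat(sprintf("  chains        : %d x %d atoms (net charge %+d e each)\n",
              object@nChains, object@atomsPerChain, object@netChargePerChain))
  cat(sprintf("  protein atoms : %d\n", object@proteinAtoms))
  cat(sprintf("  Na+ ions      : %d\n", object@nCounterions))
  cat(sprintf("  waters        : %d x %d atoms\n", object@nWaters, object@atomsPerWater))
  cat(sprintf("  total atoms   : %d\n", object@totalAtoms))
})

setMethod("show", "ContactMap", function(object) {
  cat(sprintf("ContactMap (%.1f A cutoff): residues %s x %s, %% of frames in contact\n",
              object@cutoff,
              paste(range(object@rows), collapse = "-"),
              paste(range(object@cols), collapse = "-")))
  print(round(object@values, 1))
})

setMethod("show", "ContactSeries", function(object) {
  cat(sprintf("ContactSeries: %d frames, normalization '%s' (%d layers)\n",
              nrow(object@counts), object@normalization, object@nLayers))
  cat(sprintf("  final counts: F1-F2 %.1f, F2-F3 %.1f, F3-F1 %.1f (total %.1f)\n",
              object@counts[nrow(object@counts), 1L],
              object@counts[nrow(object@counts), 2L],
              object@counts[nrow(object@counts), 3L],
              sum(object@counts[nrow(object@counts), ])))
})

#' Total inter-filament contacts per frame
#'
#' @param x a [ContactSeries-class].
#' @return numeric vector: the per-frame sum over the three filament pairs.
#' @export
setGeneric("totalContacts", function(x) standardGeneric("totalContacts"))
#' @rdname totalContacts
setMethod("totalContacts", "ContactSeries", function(x) rowSums(x@counts))

#' Per-pair contact counts of a ContactSeries
#'
#' @param x a [ContactSeries-class].
#' @return the n_frames x 3 count matrix (columns F1-F2, F2-F3, F3-F1).
#' @export
setGeneric("contactCounts", function(x) standardGeneric("contactCounts"))
#' @rdname contactCounts
setMethod("contactCounts", "ContactSeries", function(x) x@counts)

#' Contact-map values in percent
#'
#' @param x a [ContactMap-class].
#' @return numeric matrix of percentages with residue-labelled dimnames.
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))
#' @rdname mapValues
setMethod("mapValues", "ContactMap", function(x) x@values)
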