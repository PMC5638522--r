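# PDB fixed-column reading/writing and topology assignment.
# Only ATOM/HETATM, MODEL/ENDMDL and TER records are interpreted; everything
# else is ignored. Coordinates are carried at the format's 3-decimal precision.

.parse_atom_lines <- function(lines, lineno = seq_along(lines)) {
  sub8 <- function(l, a, b) substr(l, a, b)
  n <- length(lines)
  if (n == 0L)
    stop("no ATOM records found: empty structure input", call. = FALSE)
  serial <- suppressWarnings(as.integer(sub8(lines, 7, 11)))
  x <- suppressWarnings(as.numeric(sub8(lines, 31, 38)))
  y <- suppressWarnings(as.numeric(sub8(lines, 39, 46)))
  z <- suppressWarnings(as.numeric(sub8(lines, 47, 54)))
  resid <- suppressWarnings(as.integer(sub8(lines, 23, 26)))
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z) | is.na(resid))
  if (length(bad))
    stop(sprintf("malformed ATOM record at line %d: '%s'",
                 lineno[bad[1L]], lines[bad[1L]]), call. = FALSE)
  name <- trimws(sub8(lines, 13, 16))
  resname <- trimws(sub8(lines, 18, 20))
  chain <- sub8(lines, 22, 22)
  element <- trimws(sub8(lines, 77, 78))
  guess <- .element_from_name(name)
  element <- ifelse(element == "", guess, element)
  data.frame(serial = serial, name = name, resname = resname, resid = resid,
             chain = chain, x = x, y = y, z = z, element = element,
             hydrogen = element == "H", stringsAsFactors = FALSE)
}

# PDB atom-name heuristic: names like "1HB2"/"HH31" are hydrogens; otherwise
# the first alphabetic character is the element (covers C/N/O/S/H and NA ions).
.element_from_name <- function(name) {
  core <- sub("^[0-9]+", "", name)
  first <- substr(core, 1, 1)
  two <- substr(core, 1, 2)
  el <- ifelse(two %in% c("NA", "CL", "MG", "ZN", "FE") & nchar(name) <= 2, two, first)
  ifelse(substr(core, 1, 1) == "H", "H", el)
}

.model_blocks <- function(lines) {
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) return(list(seq_along(lines)))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines) + 1L)
  lapply(seq_along(starts), function(i) seq(starts[i] + 1L, ends[i] - 1L))
}

#' Read a fibril structure from PDB text
#'
#' Parses ATOM/HETATM records into a [FibrilModel-class] with an unassigned
#' topology map. When the text contains several MODEL blocks, only the first
#' model is used (the deposited triple-fibril template is an NMR multi-model
#' entry; its first model serves as the structure).
#'
#' @param pdbText a single string or character vector of PDB lines.
#' @return a [FibrilModel-class]; call [assignTopology()] before per-filament
#'   analyses.
#' @examples
#' m <- readStructure("ATOM      1  CA  ASP A   1      11.000  22.000  33.000")
#' nAtoms(m)
#' @export
readStructure <- function(pdbText) {
  lines <- if (length(pdbText) == 1L) strsplit(pdbText, "\n", fixed = TRUE)[[1L]] else pdbText
  blocks <- .model_blocks(lines)
  idx <- blocks[[1L]]
  idx <- idx[idx >= 1L & idx <= length(lines)]
  sel <- idx[grepl("^(ATOM  |HETATM)", lines[idx])]
  if (length(sel) == 0L)
    stop("no ATOM records found: empty structure input", call. = FALSE)
  atoms <- .parse_atom_lines(lines[sel], lineno = sel)
  new("FibrilModel", atoms = atoms, topology = data.frame(),
      nFilaments = 0L, nLayers = 0L)
}

#' Assign the filament/layer topology map of a fibril model
#'
#' Maps every chain of the model onto the F x L fibril grid. The deposited
#' entry does not document which chain belongs to which filament, so the
#' assignment is a convention: with `chainOrder = "layer-major"` (default)
#' chains are grouped by layer in order of appearance (chains 1..F form layer
#' 1 with filaments 1..F); `"filament-major"` groups them by filament.
#' An explicit `mapping` data.frame (columns `chain`, `filament`, `layer`)
#' overrides the convention.
#'
#' @param model a [FibrilModel-class].
#' @param nFilaments,nLayers grid shape; `nFilaments * nLayers` must equal the
#'   number of chains.
#' @param chainOrder `"layer-major"` or `"filament-major"`.
#' @param mapping optional explicit chain -> (filament, layer) data.frame.
#' @return the model with its topology slot filled in.
#' @export
assignTopology <- function(model, nFilaments, nLayers,
                           chainOrder = c("layer-major", "filament-major"),
                           mapping = NULL) {
  chainOrder <- match.arg(chainOrder)
  chains <- unique(model@atoms$chain)
  F <- as.integer(nFilaments); L <- as.integer(nLayers)
  if (length(chains) != F * L)
    stop(sprintf("topology error: expected %d chains (%d filaments x %d layers), found %d",
                 F * L, F, L, length(chains)), call. = FALSE)
  if (is.null(mapping)) {
    if (chainOrder == "layer-major") {
      filament <- rep(seq_len(F), times = L)
      layer <- rep(seq_len(L), each = F)
    } else {
      filament <- rep(seq_len(F), each = L)
      layer <- rep(seq_len(L), times = F)
    }
    mapping <- data.frame(chain = chains, filament = filament, layer = layer,
                          stringsAsFactors = FALSE)
  } else {
    if (!all(c("chain", "filament", "layer") %in% names(mapping)))
      stop("mapping must have columns chain, filament, layer", call. = FALSE)
    if (!setequal(mapping$chain, chains))
      stop("mapping chains do not match the model's chains", call. = FALSE)
    mapping <- mapping[, c("chain", "filament", "layer")]
  }
  model@topology <- mapping
  model@nFilaments <- F
  model@nLayers <- L
  validObject(model)
  model
}

#' Read trajectory frames from multi-model PDB text
#'
#' Every MODEL...ENDMDL block becomes one frame; blocks must be atom-congruent
#' with `model`. Frame times are synthetic 0, 1, 2, ... ns (the interchange
#' format carries none).
#'
#' @param pdbText multi-model PDB text (single string or lines).
#' @param model the [FibrilModel-class] the frames belong to.
#' @return a [TrajectoryFrames-class].
#' @export
readFrames <- function(pdbText, model) {
  lines <- if (length(pdbText) == 1L) strsplit(pdbText, "\n", fixed = TRUE)[[1L]] else pdbText
  blocks <- .model_blocks(lines)
  na <- nAtoms(model)
  coords <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    idx <- blocks[[i]]
    sel <- idx[grepl("^(ATOM  |HETATM)", lines[idx])]
    if (length(sel) != na)
      stop(sprintf("congruence error: MODEL %d has %d atoms, model has %d",
                   i, length(sel), na), call. = FALSE)
    a <- .parse_atom_lines(lines[sel], lineno = sel)
    coords[[i]] <- as.matrix(a[, c("x", "y", "z")])
  }
  new("TrajectoryFrames", coords = coords, times = as.numeric(seq_along(coords) - 1L))
}

.format_atom_line <- function(a, serial) {
  name <- a$name
  # PDB convention: short names start in column 14
  name4 <- ifelse(nchar(name) >= 4L, substr(name, 1, 4),
                  sprintf("%-3s", name))
  name4 <- ifelse(nchar(name) >= 4L, name4, paste0(" ", name4))
  sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name4, a$resname, a$chain, a$resid, a$x, a$y, a$z,
          1.0, 0.0, a$element)
}

.atom_lines_for <- function(atoms, coords = NULL) {
  if (!is.null(coords)) {
    atoms$x <- coords[, 1L]; atoms$y <- coords[, 2L]; atoms$z <- coords[, 3L]
  }
  if (any(nchar(atoms$chain) > 1L))
    stop("format error: chain identifiers must be single characters for PDB output",
         call. = FALSE)
  lines <- character(0)
  serial <- 0L
  for (ch in unique(atoms$chain)) {
    sub <- atoms[atoms$chain == ch, , drop = FALSE]
    ser <- serial + seq_len(nrow(sub))
    lines <- c(lines, .format_atom_line(sub, ser))
    serial <- serial + nrow(sub)
    lines <- c(lines, sprintf("TER   %5d      %-3s %1s%4d",
                              serial + 1L, sub$resname[nrow(sub)], ch,
                              sub$resid[nrow(sub)]))
    serial <- serial + 1L
  }
  lines
}

#' Write a fibril model as PDB text
#'
#' @param model a [FibrilModel-class].
#' @return a single string of ATOM/TER records terminated by END; coordinates
#'   carry 3 decimals, so a read/write round trip is exact at 1e-3 Angstrom.
#' @export
writeStructure <- function(model) {
  paste(c(.atom_lines_for(model@atoms), "END", ""), collapse = "\n")
}

#' Write trajectory frames as multi-model PDB text
#'
#' @param frames a [TrajectoryFrames-class].
#' @param model the congruent [FibrilModel-class] supplying atom metadata.
#' @return a single string with one MODEL...ENDMDL block per frame.
#' @export
writeFrames <- function(frames, model) {
  if (nFrames(frames) == 0L) stop("no frames to write", call. = FALSE)
  if (nrow(frames@coords[[1L]]) != nAtoms(model))
    stop("frames are not congruent with the model", call. = FALSE)
  out <- character(0)
  for (i in seq_len(nFrames(frames))) {
    out <- c(out, sprintf("MODEL %8d", i),
             .atom_lines_for(model@atoms, frames@coords[[i]]),
             "ENDMDL")
  }
  paste(c(out, "END", ""), collapse = "\n")
}

#' Count water residues in an atom table
#'
#' Waters are recognised by residue name (HOH, WAT, TIP3, SOL); each distinct
#' (chain, residue number) pair counts once.
#'
#' @param model a [FibrilModel-class] (solvent atoms included).
#' @return integer number of water molecules.
#' @export
countWaters <- function(model) {
  a <- model@atoms
  w <- a[a$resname %in% c("HOH", "WAT", "TIP3", "SOL", "TP3"), , drop = FALSE]
  if (nrow(w) == 0L) return(0L)
  length(unique(paste(w$chain, w$resid)))
}

# internal: atom row indices for (chain, resid, optional atom names)
.sel_atoms <- function(model, chain = NULL, resid = NULL, name = NULL,
                       heavyOnly = FALSE) {
  a <- model@atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resid)) keep <- keep & a$resid %in% resid
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (heavyOnly) keep <- keep & !a$hydrogen
  which(keep)
}

# internal: chain id for a (filament, layer) grid cell
.chain_at <- function(model, filament, layer) {
  top <- model@topology
  if (nrow(top) == 0L)
    stop("model topology is unassigned; call assignTopology() first", call. = FALSE)
  ch <- top$chain[top$filament == filament & top$layer == layer]
  if (length(ch) != 1L)
    stop(sprintf("no chain mapped to filament %d, layer %d", filament, layer),
         call. = FALSE)
  ch
}
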