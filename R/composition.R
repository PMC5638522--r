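# Sequence-level atom and charge bookkeeping for solvated fibril systems.
#
# Atom counts are per residue *as part of a chain* (backbone NH + CO included)
# with hydrogens, under the standard protonation convention at neutral pH:
# Asp/Glu deprotonated, Lys/Arg protonated, His neutral (atom count is
# tautomer-independent). Charged termini add 2 H (NH3+) and 1 O (COO-); an
# acetyl cap adds 6 atoms (CH3 + 3 H, C, O) and no terminal H.

.RESIDUE_ATOMS <- c(
  A = 10L, R = 24L, N = 14L, D = 12L, C = 11L, E = 15L, Q = 17L, G = 7L,
  H = 17L, I = 19L, L = 19L, K = 22L, M = 17L, F = 20L, P = 14L, S = 11L,
  T = 14L, V = 16L, W = 24L, Y = 21L)

.RESIDUE_CHARGE <- c(
  A = 0L, R = 1L, N = 0L, D = -1L, C = 0L, E = -1L, Q = 0L, G = 0L,
  H = 0L, I = 0L, L = 0L, K = 1L, M = 0L, F = 0L, P = 0L, S = 0L,
  T = 0L, V = 0L, W = 0L, Y = 0L)

#' The amyloid-beta 1-40 sequence
#'
#' One-letter sequence of the 40-residue amyloid-beta peptide whose
#' patient-derived triple-symmetric fibril the package models.
#' @export
ABETA40 <- "DAEFRHDSGYEVHHQKLVFFAEDVGSNKGAIIGLMVGGVV"

.check_seq <- function(sequence) {
  letters1 <- strsplit(toupper(sequence), "")[[1L]]
  bad <- setdiff(letters1, names(.RESIDUE_ATOMS))
  if (length(bad))
    stop(sprintf("sequence error: unknown residue letter(s) %s",
                 paste(unique(bad), collapse = ", ")), call. = FALSE)
  letters1
}

#' Count the atoms of one peptide chain from its sequence
#'
#' Total atom count (hydrogens included) of a chain under the standard
#' neutral-pH protonation convention; this convention is the one that
#' reproduces the published solvated-system totals exactly. The full-length
#' 40-mer with charged termini has 598 atoms; the 9-40 truncation with an
#' acetyl cap has 481.
#'
#' @param sequence one-letter amino-acid string.
#' @param nTerminus `"charged"` (NH3+) or `"acetyl"` (CH3-CO- cap).
#' @param cTerminus `"charged"` (COO-); the only supported form.
#' @return integer atom count.
#' @examples
#' countChainAtoms("G")                       # 10: glycine + 2 H + 1 O
#' countChainAtoms(ABETA40)                   # 598
#' countChainAtoms(substr(ABETA40, 9, 40), nTerminus = "acetyl")  # 481
#' @export
countChainAtoms <- function(sequence, nTerminus = c("charged", "acetyl"),
                            cTerminus = "charged") {
  nTerminus <- match.arg(nTerminus)
  cTerminus <- match.arg(cTerminus, "charged")
  letters1 <- .check_seq(sequence)
  total <- sum(.RESIDUE_ATOMS[letters1])
  total <- total + if (nTerminus == "charged") 2L else 6L
  total + 1L  # COO-: one extra O, no extra H
}

#' Net charge of one peptide chain from its sequence
#'
#' Sum of -1 per Asp/Glu, +1 per Lys/Arg, 0 per neutral His, +1 for a charged
#' N-terminus (0 for acetyl) and -1 for the charged C-terminus.
#'
#' @inheritParams countChainAtoms
#' @return integer net charge in elementary charges.
#' @examples
#' netChainCharge(ABETA40)                                        # -3
#' netChainCharge(substr(ABETA40, 9, 40), nTerminus = "acetyl")   # -2
#' @export
netChainCharge <- function(sequence, nTerminus = c("charged", "acetyl"),
                           cTerminus = "charged") {
  nTerminus <- match.arg(nTerminus)
  cTerminus <- match.arg(cTerminus, "charged")
  letters1 <- .check_seq(sequence)
  q <- sum(.RESIDUE_CHARGE[letters1]) - 1L
  if (nTerminus == "charged") q <- q + 1L
  as.integer(q)
}

#' Composition report for a solvated fibril system
#'
#' Computes the full atom bookkeeping of a simulated system from its chain
#' count, sequence/terminus state and water count: protein atoms, Na+
#' counter ions neutralising the net negative protein charge, 3-site waters,
#' and the grand total. Only anionic systems are supported (the study adds
#' Na+ only).
#'
#' @param nFilaments,nLayers fibril grid; `nFilaments * nLayers` chains. For
#'   the infinite fibril the periodic box holds 12 layers.
#' @param sequence one-letter chain sequence.
#' @param nTerminus `"charged"` or `"acetyl"`.
#' @param nWaters number of water molecules in the box.
#' @return a [CompositionReport-class].
#' @examples
#' # the infinite full-length system: 36 chains, 24488 waters -> 95100 atoms
#' systemComposition(3, 12, ABETA40, "charged", 24488)
#' @export
systemComposition <- function(nFilaments, nLayers, sequence,
                              nTerminus = c("charged", "acetyl"), nWaters) {
  nTerminus <- match.arg(nTerminus)
  if (nWaters < 0) stop("nWaters must be >= 0", call. = FALSE)
  nChains <- as.integer(nFilaments) * as.integer(nLayers)
  apc <- countChainAtoms(sequence, nTerminus)
  q <- netChainCharge(sequence, nTerminus)
  if (q > 0L)
    stop("unsupported-ion error: net positive charge would require anions; only Na+ is modelled",
         call. = FALSE)
  ions <- -nChains * q
  protein <- nChains * apc
  new("CompositionReport",
      nChains = nChains, atomsPerChain = apc, proteinAtoms = protein,
      netChargePerChain = q, nCounterions = as.integer(ions),
      nWaters = as.integer(nWaters), atomsPerWater = 3L,
      totalAtoms = as.integer(protein + ions + 3L * nWaters))
}
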