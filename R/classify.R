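# Contact-based classification of fibril topology: triple-symmetric, 2+1,
# dissociated, or other, from the three per-layer inter-filament contact
# counts.

#' Construct a classifier configuration
#'
#' Default thresholds separate the reported per-layer contact regimes: about
#' 60 contacts per interface for the retained triple fibril, about 160 for
#' the reinforced pair and about 20 total for the detached filament in the
#' 2+1 state.
#'
#' @param tLow contacts/layer below which an interface is broken (default 10).
#' @param tHigh contacts/layer above which an interface is paired (default 40).
#' @param window smoothing window in frames (default 10).
#' @return a [ClassifierConfig-class].
#' @export
classifierConfig <- function(tLow = 10, tHigh = 40, window = 10L) {
  new("ClassifierConfig", tLow = tLow, tHigh = tHigh, window = as.integer(window))
}

.TOPOLOGY_LABELS <- c("TRIPLE", "TWO_PLUS_ONE", "DISSOCIATED", "OTHER")

#' Classify one frame from its three inter-filament contact counts
#'
#' Rules, applied in order: TWO_PLUS_ONE if exactly one interface is paired
#' (`>= tHigh`) while the other two are below `2 * tLow`; DISSOCIATED if at
#' least two interfaces are broken (`< tLow`); TRIPLE if all three interfaces
#' hold (`>= tLow`) with a max/min ratio below 3; OTHER otherwise. The
#' precedence makes the strongly asymmetric 2+1 signature (one reinforced
#' interface, two collapsed ones) win over the dissociation rule.
#'
#' @param counts numeric length-3: contacts per layer for the filament pairs
#'   F1-F2, F2-F3, F3-F1.
#' @param cfg a [ClassifierConfig-class].
#' @return character label, one of TRIPLE, TWO_PLUS_ONE, DISSOCIATED, OTHER,
#'   with the counts and thresholds attached as attributes.
#' @examples
#' classifyFrame(c(60, 60, 60))    # TRIPLE
#' classifyFrame(c(160, 7, 7))     # TWO_PLUS_ONE
#' classifyFrame(c(0, 0, 0))       # DISSOCIATED
#' @export
classifyFrame <- function(counts, cfg = classifierConfig()) {
  if (length(counts) != 3L || any(!is.finite(counts)))
    stop("counts must be three finite numbers", call. = FALSE)
  if (any(counts < 0))
    stop("argument error: contact counts must be nonnegative", call. = FALSE)
  label <- local({
    paired <- counts >= cfg@tHigh
    broken <- counts < cfg@tLow
    if (sum(paired) == 1L && all(counts[!paired] < 2 * cfg@tLow)) "TWO_PLUS_ONE"
    else if (sum(broken) >= 2L) "DISSOCIATED"
    else if (all(counts >= cfg@tLow) && max(counts) / min(counts) < 3) "TRIPLE"
    else "OTHER"
  })
  structure(label, counts = counts, tLow = cfg@tLow, tHigh = cfg@tHigh)
}

.moving_average <- function(x, window) {
  if (window <= 1L) return(x)
  n <- length(x)
  out <- numeric(n)
  h <- window %/% 2L
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    out[i] <- mean(x[lo:hi])
  }
  out
}

#' Classify a trajectory and report its end state
#'
#' Smooths each interface's per-layer contact series with a centered moving
#' average (to suppress single-frame flicker), labels every frame with
#' [classifyFrame()], and reports the modal label over the final window as
#' the trajectory's end state.
#'
#' @param series a [ContactSeries-class] (use `normalization = "per_layer"`).
#' @param cfg a [ClassifierConfig-class].
#' @return list with `labels` (per frame), `endState`, and `config` (the
#'   thresholds used, always echoed for reproducibility).
#' @export
classifyTrajectory <- function(series, cfg = classifierConfig()) {
  counts <- contactCounts(series)
  n <- nrow(counts)
  if (n == 0L) stop("empty contact series", call. = FALSE)
  if (cfg@window > n)
    stop("argument error: smoothing window longer than the trajectory", call. = FALSE)
  sm <- apply(counts, 2L, .moving_average, window = cfg@window)
  sm <- matrix(sm, nrow = n)
  labels <- vapply(seq_len(n),
                   function(i) as.character(classifyFrame(sm[i, ], cfg)),
                   character(1))
  tailLab <- labels[seq(n - cfg@window + 1L, n)]
  tab <- table(factor(tailLab, levels = .TOPOLOGY_LABELS))
  list(labels = labels,
       endState = names(tab)[which.max(tab)],
       config = list(tLow = cfg@tLow, tHigh = cfg@tHigh, window = cfg@window))
}
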