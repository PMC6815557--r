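#' Beat class labels
#'
#' The eight heartbeat classes handled by this package, in their fixed
#' integer order: normal (N), left and right bundle branch block (LBBB,
#' RBBB), atrial premature contraction (APC), nodal escape (NESC),
#' aberrated atrial premature (ABERR), nodal premature (NPC) and atrial
#' escape (AESC) beats. Integer labels are 0-based throughout the package.
#'
#' @return Character vector of length 8; element `i + 1` names class `i`.
#' @export
#' @examples
#' beat_classes()
beat_classes <- function() {
  c("N", "LBBB", "RBBB", "APC", "NESC", "ABERR", "NPC", "AESC")
}

# PhysioNet annotation symbol -> 0-based class index.
# Only these eight beat symbols are kept; everything else (other beat
# types, rhythm markers, noise flags, ...) is excluded upstream.
.symbol_map <- c(
  "N" = 0L, "L" = 1L, "R" = 2L, "A" = 3L,
  "j" = 4L, "a" = 5L, "J" = 6L, "e" = 7L
)

#' Map an annotation symbol to a beat class
#'
#' Maps single-character PhysioNet annotation symbols to the package's
#' 0-based class labels: `N`->0, `L`->1, `R`->2, `A`->3, `j`->4, `a`->5,
#' `J`->6, `e`->7. Every other symbol (ventricular beats, paced beats,
#' rhythm-change markers such as `+`, noise annotations, ...) maps to
#' `NA`, meaning the annotation is excluded from the dataset.
#'
#' @param symbol Character vector of single-character annotation symbols.
#' @return Integer vector of 0-based class indices, `NA` where the symbol
#'   is not one of the eight handled beat types. Total function: never
#'   errors on unknown symbols.
#' @export
#' @examples
#' map_beat_symbol(c("N", "A", "V", "+"))
map_beat_symbol <- function(symbol) {
  symbol <- as.character(symbol)
  out <- unname(.symbol_map[symbol])
  storage.mode(out) <- "integer"
  out
}

#' Count beats per class in an annotation table
#'
#' Tallies annotations whose symbol maps to one of the eight beat classes;
#' unmapped symbols are ignored. Counting is additive: the counts of a
#' concatenation of two annotation streams are the sums of the per-stream
#' counts.
#'
#' @param annotations Data frame with a `symbol` column (as returned by
#'   [read_wfdb_annotations()] or [read_text_annotations()]), or a
#'   character vector of symbols.
#' @return Named integer vector of length 8 (names from [beat_classes()]).
#' @export
count_beat_classes <- function(annotations) {
  symbols <- if (is.data.frame(annotations)) annotations$symbol else annotations
  idx <- map_beat_symbol(symbols)
  counts <- tabulate(idx[!is.na(idx)] + 1L, nbins = 8L)
  names(counts) <- beat_classes()
  counts
}

#' Reference MIT-BIH class distribution
#'
#' The per-class beat counts of the eight handled classes in the MIT-BIH
#' arrhythmia database (93,371 beats total), used as the imbalance preset
#' for the synthetic generator.
#'
#' @return Named integer vector of length 8 summing to 93371.
#' @export
mitbih_class_counts <- function() {
  c(N = 75020L, LBBB = 8072L, RBBB = 7255L, APC = 2546L,
    NESC = 229L, ABERR = 150L, NPC = 83L, AESC = 16L)
}
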