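# Beat segmentation, per-beat Z-score normalization, the beat_dataset
# container, stratified splitting and plain-text serialization.

#' Segment a signal into R-peak-centered beats
#'
#' Extracts fixed-length windows centered on annotated R-peaks: for an
#' annotation at sample `r` (0-based) and the default length 250, the
#' window covers samples `r-125` to `r+124` inclusive, putting the
#' R-peak at within-beat position 125 (0-based). Annotations whose symbol
#' does not map to one of the eight classes, and annotations whose window
#' crosses either record boundary, are skipped.
#'
#' @param signal Numeric vector, one channel.
#' @param annotations Data frame with `sample_index` (0-based, ascending)
#'   and `symbol`.
#' @param beat_length Even window length (default 250).
#' @param record_id Record name stored with each beat.
#' @return A `beat_dataset` (see [beat_dataset()]); the number of skipped
#'   boundary beats is attached as attribute `n_boundary_skipped`.
#' @export
segment_beats <- function(signal, annotations, beat_length = 250,
                          record_id = "record") {
  stopifnot(beat_length %% 2 == 0, beat_length >= 2)
  half <- beat_length %/% 2L
  n <- length(signal)
  lab <- map_beat_symbol(annotations$symbol)
  keep <- !is.na(lab)
  r <- annotations$sample_index[keep]
  lab <- lab[keep]
  in_bounds <- (r - half >= 0L) & (r + half - 1L <= n - 1L)
  n_skipped <- sum(!in_bounds)
  r <- r[in_bounds]; lab <- lab[in_bounds]
  x <- matrix(0, nrow = length(r), ncol = beat_length)
  for (k in seq_along(r)) {
    x[k, ] <- signal[(r[[k]] - half + 1L):(r[[k]] + half)]
  }
  ds <- beat_dataset(x, lab, record_id = rep(record_id, length(r)),
                     r_index = r)
  attr(ds, "n_boundary_skipped") <- n_skipped
  ds
}

#' Z-score normalize beats
#'
#' Per-beat standardization: `(x - mean(x)) / sd(x)` with the sample
#' (n-1 denominator) standard deviation, computed independently for each
#' beat. Beats with standard deviation below `1e-12` (constant beats)
#' become all zeros.
#'
#' @param x Numeric vector (one beat), matrix (beats in rows), or a
#'   `beat_dataset`.
#' @return Same shape/class as the input, normalized.
#' @export
zscore_beat <- function(x) {
  if (inherits(x, "beat_dataset")) {
    x$x <- zscore_beat(x$x)
    return(x)
  }
  if (is.matrix(x)) {
    mu <- rowMeans(x)
    sdv <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1L))
    out <- (x - mu) / ifelse(sdv < 1e-12, Inf, sdv)
    return(out)
  }
  mu <- mean(x)
  sdv <- stats::sd(x)
  if (is.na(sdv) || sdv < 1e-12) return(x * 0)
  (x - mu) / sdv
}

#' Construct a beat dataset
#'
#' Container for a set of labeled ECG beats: a numeric matrix with one
#' beat per row plus 0-based integer class labels and per-beat provenance.
#'
#' @param x Numeric matrix, `n` beats x `beat_length` samples.
#' @param label Integer vector of 0-based class labels (0..7).
#' @param record_id Character vector of source record names (recycled).
#' @param r_index Integer vector of original R-peak sample indices.
#' @return An object of class `beat_dataset`: list with `x`, `label`,
#'   `record_id`, `r_index`, `n`.
#' @export
beat_dataset <- function(x, label, record_id = "synthetic", r_index = NA_integer_) {
  x <- as.matrix(x)
  label <- as.integer(label)
  stopifnot(nrow(x) == length(label),
            all(is.na(label) | (label >= 0L & label <= 7L)))
  structure(
    list(x = x, label = label,
         record_id = rep_len(as.character(record_id), nrow(x)),
         r_index = rep_len(as.integer(r_index), nrow(x)),
         n = nrow(x)),
    class = "beat_dataset"
  )
}

#' @export
print.beat_dataset <- function(x, ...) {
  cat(sprintf("beat_dataset: %d beats x %d samples\n", x$n, ncol(x$x)))
  print(class_distribution(x))
  invisible(x)
}

#' Class distribution of a beat dataset
#'
#' @param ds A `beat_dataset`.
#' @return Named integer vector of per-class beat counts (all 8 classes).
#' @export
class_distribution <- function(ds) {
  counts <- tabulate(ds$label + 1L, nbins = 8L)
  names(counts) <- beat_classes()
  counts
}

#' Concatenate beat datasets
#'
#' @param ... `beat_dataset` objects with equal beat lengths.
#' @return Combined `beat_dataset`, beats in argument order.
#' @export
bind_beat_datasets <- function(...) {
  parts <- list(...)
  parts <- parts[vapply(parts, function(p) p$n > 0L, TRUE)]
  if (!length(parts)) {
    return(beat_dataset(matrix(0, 0, 250), integer(0)))
  }
  beat_dataset(do.call(rbind, lapply(parts, `[[`, "x")),
               unlist(lapply(parts, `[[`, "label")),
               unlist(lapply(parts, `[[`, "record_id")),
               unlist(lapply(parts, `[[`, "r_index")))
}

#' Subset a beat dataset
#'
#' @param x A `beat_dataset`. @param i Row (beat) indices. @param ... Unused.
#' @return `beat_dataset` with the selected beats.
#' @export
`[.beat_dataset` <- function(x, i, ...) {
  beat_dataset(x$x[i, , drop = FALSE], x$label[i], x$record_id[i], x$r_index[i])
}

#' Build a beat dataset from ECG records
#'
#' The full preprocessing pipeline: per record, denoise the selected
#' channel with [denoise_db6()], segment R-peak-centered beats with
#' [segment_beats()], and Z-score normalize each beat. Results are
#' concatenated in record order.
#'
#' @param records List of `list(record = <ecg_record>, annotations = <df>)`
#'   pairs.
#' @param denoise Apply wavelet denoising before segmentation (default TRUE).
#' @param beat_length Window length (default 250).
#' @param channel Signal channel to use (default 1, the first channel).
#' @return A `beat_dataset`.
#' @export
build_beat_dataset <- function(records, denoise = TRUE, beat_length = 250,
                               channel = 1L) {
  parts <- lapply(records, function(entry) {
    sig <- entry$record$signals[, channel]
    if (denoise) sig <- denoise_db6(sig, fs = entry$record$fs)
    ds <- segment_beats(sig, entry$annotations, beat_length,
                        record_id = entry$record$record_id)
    zscore_beat(ds)
  })
  do.call(bind_beat_datasets, parts)
}

# Allocate a total of `k` draws across classes proportionally to `sizes`
# (largest-remainder rounding), capped so every class keeps `keep_min`
# members unallocated.
.stratified_alloc <- function(sizes, frac, keep_min = 1L) {
  ideal <- sizes * frac
  alloc <- floor(ideal)
  total <- round(sum(ideal))
  rem <- ideal - alloc
  extra <- total - sum(alloc)
  if (extra > 0) {
    ord <- order(rem, decreasing = TRUE)
    alloc[ord[seq_len(extra)]] <- alloc[ord[seq_len(extra)]] + 1L
  }
  pmin(alloc, pmax(sizes - keep_min, 0L))
}

#' Split a beat dataset into train / validation / test sets
#'
#' Stratified random split: first `test_fraction` of the data (rounded,
#' allocated across classes by largest remainder) is held out as the test
#' set, then `val_fraction` of the remainder as the validation set; the
#' rest is the training set. Where a class is too small to stratify, at
#' least one member is kept in the training set. Deterministic given
#' `seed`; the three parts are disjoint and cover the dataset.
#'
#' @param ds A `beat_dataset` with at least 10 beats.
#' @param test_fraction Fraction of all beats for the test set, in (0,1).
#' @param val_fraction Fraction of the non-test beats for validation, in (0,1).
#' @param seed Integer seed.
#' @return List with `beat_dataset` elements `train`, `validation`, `test`.
#' @export
split_beat_dataset <- function(ds, test_fraction = 0.10, val_fraction = 0.10,
                               seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1 ||
      val_fraction <= 0 || val_fraction >= 1) {
    stop("split fractions must lie in (0, 1)")
  }
  stopifnot(inherits(ds, "beat_dataset"), ds$n >= 10)
  .with_seed(seed, {
    classes <- sort(unique(ds$label))
    by_class <- lapply(classes, function(cl) which(ds$label == cl))

    take <- function(pools, frac, keep_min) {
      alloc <- .stratified_alloc(lengths(pools), frac, keep_min)
      picked <- vector("list", length(pools))
      for (k in seq_along(pools)) {
        pool <- pools[[k]]
        sel <- if (alloc[[k]] > 0L) pool[sample.int(length(pool), alloc[[k]])]
               else integer(0)
        picked[[k]] <- sel
        pools[[k]] <- setdiff(pool, sel)
      }
      list(picked = sort(unlist(c(picked, list(integer(0))))), pools = pools)
    }

    s1 <- take(by_class, test_fraction, keep_min = 1L)
    s2 <- take(s1$pools, val_fraction, keep_min = 1L)
    train_idx <- sort(unlist(c(s2$pools, list(integer(0)))))
    list(train = ds[train_idx], validation = ds[s2$picked], test = ds[s1$picked])
  })
}

#' Write a beat dataset to plain text
#'
#' Two-file serialization: a whitespace-delimited matrix (one beat per
#' row, values at 17 significant digits so doubles round-trip exactly)
#' and a CSV manifest
#' (`row_id,record_id,r_index,label_index,label_name,split`).
#'
#' @param ds A `beat_dataset`.
#' @param matrix_path Path for the beat matrix file.
#' @param manifest_path Path for the manifest CSV (default: matrix path
#'   with `.manifest.csv` appended).
#' @param split Optional character vector assigning each beat to a split
#'   (`"train"`, `"validation"`, `"test"`); recorded in the manifest.
#' @return Invisibly, `matrix_path`.
#' @export
write_beat_dataset <- function(ds, matrix_path,
                               manifest_path = paste0(matrix_path, ".manifest.csv"),
                               split = NA_character_) {
  lines <- apply(ds$x, 1L, function(row) paste(sprintf("%.17g", row), collapse = " "))
  writeLines(as.character(lines), matrix_path)
  manifest <- data.frame(
    row_id = seq_len(ds$n), record_id = ds$record_id, r_index = ds$r_index,
    label_index = ds$label, label_name = beat_classes()[ds$label + 1L],
    split = rep_len(split, ds$n),
    stringsAsFactors = FALSE
  )
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(matrix_path)
}

#' Read a beat dataset written by [write_beat_dataset()]
#'
#' @inheritParams write_beat_dataset
#' @return A `beat_dataset`, bit-identical to the one written; any split
#'   assignments are attached as attribute `split`.
#' @export
read_beat_dataset <- function(matrix_path,
                              manifest_path = paste0(matrix_path, ".manifest.csv")) {
  if (!file.exists(matrix_path)) stop("dataset matrix not found: ", matrix_path)
  if (!file.exists(manifest_path)) stop("dataset manifest not found: ", manifest_path)
  x <- as.matrix(utils::read.table(matrix_path, header = FALSE))
  dimnames(x) <- NULL
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  if (nrow(x) == 0L) x <- matrix(0, 0L, 250L)
  ds <- beat_dataset(x, manifest$label_index, manifest$record_id,
                     manifest$r_index)
  if (!is.null(manifest$split)) attr(ds, "split") <- manifest$split
  ds
}

# Evaluate code under a locally seeded RNG, restoring the caller's RNG
# state afterwards. With seed = NULL the current RNG stream is used.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
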