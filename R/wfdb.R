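# WFDB (PhysioNet waveform-database) file access: text header (.hea),
# format-212 packed signal (.dat) and MIT-format beat annotations (.atr),
# plus a delimited-text fallback so test fixtures need no binary codec.
# Sample indices are 0-based everywhere, indexing the signal arrays directly.

# MIT annotation code <-> symbol table (standard PhysioNet beat/non-beat codes)
.ann_codes <- c(
  "1" = "N", "2" = "L", "3" = "R", "4" = "a", "5" = "V", "6" = "F",
  "7" = "J", "8" = "A", "9" = "S", "10" = "E", "11" = "j", "12" = "/",
  "13" = "Q", "14" = "~", "16" = "|", "18" = "s", "19" = "T", "20" = "*",
  "21" = "D", "22" = "\"", "23" = "=", "24" = "p", "25" = "B", "26" = "^",
  "27" = "t", "28" = "+", "29" = "u", "30" = "?", "31" = "!", "32" = "[",
  "33" = "]", "34" = "e", "35" = "n", "36" = "@", "37" = "x", "38" = "f",
  "39" = "(", "40" = ")", "41" = "r"
)

.symbol_to_code <- function(symbol) {
  codes <- as.integer(names(.ann_codes))[match(symbol, .ann_codes)]
  if (anyNA(codes)) {
    stop("no MIT annotation code for symbol(s): ",
         paste(unique(symbol[is.na(codes)]), collapse = " "))
  }
  codes
}

new_ecg_record <- function(record_id, fs, signals, channel_names = NULL) {
  signals <- as.matrix(signals)
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(ncol(signals)))
  }
  stopifnot(fs > 0, length(channel_names) == ncol(signals))
  structure(
    list(record_id = record_id, fs = fs, signals = signals,
         channel_names = channel_names, n_samples = nrow(signals)),
    class = "ecg_record"
  )
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("ECG record '%s': %d samples x %d channel(s) at %g Hz (%.1f s)\n",
              x$record_id, x$n_samples, ncol(x$signals), x$fs,
              x$n_samples / x$fs))
  cat("channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

.parse_header <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("empty header file: ", hea_path)
  rec <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  record_id <- rec[[1]]
  nsig <- as.integer(rec[[2]])
  fs <- if (length(rec) >= 3) as.numeric(sub("/.*", "", rec[[3]])) else 250
  nsamp <- if (length(rec) >= 4) as.integer(rec[[4]]) else NA_integer_
  sig <- vector("list", nsig)
  for (i in seq_len(nsig)) {
    tok <- strsplit(trimws(lines[[i + 1L]]), "\\s+")[[1]]
    fmt <- as.integer(sub("[x:+].*", "", tok[[2]]))
    gain_tok <- if (length(tok) >= 3) tok[[3]] else "200"
    gain <- as.numeric(sub("[(/].*", "", gain_tok))
    baseline <- if (grepl("\\(", gain_tok)) {
      as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", gain_tok))
    } else NA_real_
    units <- if (grepl("/", gain_tok)) sub(".*/", "", gain_tok) else "mV"
    adczero <- if (length(tok) >= 5) as.numeric(tok[[5]]) else 0
    if (is.na(baseline)) baseline <- adczero
    if (is.na(gain) || gain == 0) gain <- 200
    desc <- if (length(tok) >= 9) paste(tok[9:length(tok)], collapse = " ")
            else paste0("ch", i)
    sig[[i]] <- list(file = tok[[1]], format = fmt, gain = gain,
                     baseline = baseline, units = units, description = desc)
  }
  list(record_id = record_id, nsig = nsig, fs = fs, nsamp = nsamp,
       signals = sig)
}

.decode_212 <- function(raw_bytes, n_values) {
  b <- as.integer(raw_bytes)
  n_triplets <- length(b) %/% 3L
  b1 <- b[seq(1L, by = 3L, length.out = n_triplets)]
  b2 <- b[seq(2L, by = 3L, length.out = n_triplets)]
  b3 <- b[seq(3L, by = 3L, length.out = n_triplets)]
  s1 <- bitwOr(bitwShiftL(bitwAnd(b2, 0x0FL), 8L), b1)
  s2 <- bitwOr(bitwShiftL(bitwAnd(b2, 0xF0L), 4L), b3)
  vals <- numeric(2L * n_triplets)
  vals[seq(1L, by = 2L, length.out = n_triplets)] <- s1
  vals[seq(2L, by = 2L, length.out = n_triplets)] <- s2
  vals <- vals - 4096 * (vals >= 2048)   # 12-bit two's complement
  vals[seq_len(n_values)]
}

.encode_212 <- function(values) {
  v <- as.integer(round(values))
  if (any(v < -2048L | v > 2047L)) stop("sample out of 12-bit range for format 212")
  if (length(v) %% 2L) v <- c(v, 0L)
  v <- v + 4096L * (v < 0L)
  s1 <- v[seq(1L, length(v), by = 2L)]
  s2 <- v[seq(2L, length(v), by = 2L)]
  bytes <- integer(3L * length(s1))
  bytes[seq(1L, by = 3L, length.out = length(s1))] <- bitwAnd(s1, 0xFFL)
  bytes[seq(2L, by = 3L, length.out = length(s1))] <-
    bitwOr(bitwShiftR(s1, 8L), bitwShiftL(bitwShiftR(s2, 8L), 4L))
  bytes[seq(3L, by = 3L, length.out = length(s1))] <- bitwAnd(s2, 0xFFL)
  as.raw(bytes)
}

#' Read a WFDB record
#'
#' Reads a WFDB header (`.hea`) plus its format-212 signal file and returns
#' the signal in physical units (millivolts), computed as
#' `(adc - baseline) / gain` per channel.
#'
#' @param directory Directory containing the record files.
#' @param record_id Record name, e.g. `"100"`.
#' @return An `ecg_record`: list with `record_id`, `fs` (Hz), `signals`
#'   (`n_samples` x `n_channels` numeric matrix, mV), `channel_names`,
#'   `n_samples`.
#' @seealso [write_wfdb_record()], [read_text_record()]
#' @export
read_wfdb_record <- function(directory, record_id) {
  hea <- file.path(directory, paste0(record_id, ".hea"))
  if (!file.exists(hea)) stop("header file not found: ", hea)
  hdr <- .parse_header(hea)
  dat_files <- unique(vapply(hdr$signals, `[[`, "", "file"))
  if (length(dat_files) != 1L) {
    stop("multi-file records are not supported: ", paste(dat_files, collapse = " "))
  }
  fmt <- unique(vapply(hdr$signals, function(s) s$format, 0L))
  if (!identical(fmt, 212L)) stop("unsupported signal format: ", fmt)
  dat <- file.path(directory, dat_files)
  if (!file.exists(dat)) stop("signal file not found: ", dat)
  n_total <- hdr$nsamp * hdr$nsig
  raw_bytes <- readBin(dat, what = "raw", n = ceiling(n_total / 2) * 3)
  if (length(raw_bytes) < ceiling(n_total / 2) * 3 - 2) {
    stop("signal file truncated (channel-count/sample-count mismatch): ", dat)
  }
  adc <- matrix(.decode_212(raw_bytes, n_total), ncol = hdr$nsig, byrow = TRUE)
  phys <- adc
  for (i in seq_len(hdr$nsig)) {
    phys[, i] <- (adc[, i] - hdr$signals[[i]]$baseline) / hdr$signals[[i]]$gain
  }
  new_ecg_record(hdr$record_id, hdr$fs, phys,
                 vapply(hdr$signals, `[[`, "", "description"))
}

#' Write a WFDB record (fixture writer)
#'
#' Writes an `ecg_record` (or plain matrix) as a WFDB header plus
#' format-212 signal file. Used to build round-trip fixtures; quantizes to
#' the ADC grid, so a written-then-read record reproduces the quantized
#' samples exactly.
#'
#' @param record An `ecg_record` or numeric matrix (samples x channels, mV).
#' @param directory Output directory.
#' @param record_id Record name; taken from `record` if an `ecg_record`.
#' @param fs Sampling rate (Hz) when `record` is a matrix.
#' @param gain ADC units per mV. @param baseline ADC value for 0 mV.
#' @return Invisibly, the record id.
#' @export
write_wfdb_record <- function(record, directory, record_id = NULL, fs = 360,
                              gain = 200, baseline = 1024) {
  if (inherits(record, "ecg_record")) {
    signals <- record$signals
    fs <- record$fs
    if (is.null(record_id)) record_id <- record$record_id
    ch <- record$channel_names
  } else {
    signals <- as.matrix(record)
    if (is.null(record_id)) stop("record_id required for a plain matrix")
    ch <- paste0("ch", seq_len(ncol(signals)))
  }
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  adc <- round(signals * gain + baseline)
  n <- nrow(adc); nsig <- ncol(adc)
  hea <- c(
    sprintf("%s %d %g %d", record_id, nsig, fs, n),
    sprintf("%s.dat 212 %g(%g)/mV 12 %g 0 0 0 %s",
            record_id, gain, baseline, baseline, ch)
  )
  writeLines(hea, file.path(directory, paste0(record_id, ".hea")))
  writeBin(.encode_212(as.vector(t(adc))),
           file.path(directory, paste0(record_id, ".dat")))
  invisible(record_id)
}

#' Read WFDB beat annotations
#'
#' Parses a MIT-format annotation file (`.atr`), handling the pseudo-codes
#' SKIP, NUM, SUB, CHN and AUX. All annotations are returned (beat and
#' non-beat alike); class filtering happens later via [map_beat_symbol()].
#'
#' @param directory Directory containing the annotation file.
#' @param record_id Record name.
#' @param extension Annotation file extension (default `"atr"`).
#' @return Data frame with columns `sample_index` (0-based integer,
#'   ascending) and `symbol` (character).
#' @export
read_wfdb_annotations <- function(directory, record_id, extension = "atr") {
  path <- file.path(directory, paste0(record_id, ".", extension))
  if (!file.exists(path)) stop("annotation file not found: ", path)
  bytes <- readBin(path, what = "raw", n = file.info(path)$size)
  b <- as.integer(bytes)
  n_words <- length(b) %/% 2L
  if (n_words == 0L) {
    return(data.frame(sample_index = integer(0), symbol = character(0),
                      stringsAsFactors = FALSE))
  }
  words <- b[seq(1L, by = 2L, length.out = n_words)] +
    256L * b[seq(2L, by = 2L, length.out = n_words)]
  t <- 0
  i <- 1L
  idx <- numeric(0); sym <- character(0)
  while (i <= n_words) {
    w <- words[[i]]
    if (w == 0L) break
    code <- w %/% 1024L
    interval <- w %% 1024L
    if (code == 59L) {            # SKIP: 4-byte interval, high word first
      hi <- words[[i + 1L]]; lo <- words[[i + 2L]]
      delta <- hi * 65536 + lo
      if (delta >= 2147483648) delta <- delta - 4294967296
      t <- t + delta
      i <- i + 3L
    } else if (code %in% c(60L, 61L, 62L)) {   # NUM / SUB / CHN: no time
      i <- i + 1L
    } else if (code == 63L) {     # AUX: interval = byte count, even-padded
      i <- i + 1L + (interval + interval %% 2L) %/% 2L
    } else {
      t <- t + interval
      if (code >= 1L && code <= 49L) {
        s <- .ann_codes[as.character(code)]
        idx <- c(idx, t)
        sym <- c(sym, if (is.na(s)) "Q" else unname(s))
      }
      i <- i + 1L
    }
  }
  out <- data.frame(sample_index = as.integer(idx), symbol = sym,
                    stringsAsFactors = FALSE)
  out[order(out$sample_index), , drop = FALSE]
}

#' Write WFDB beat annotations (fixture writer)
#'
#' Writes a MIT-format annotation file, emitting SKIP pseudo-annotations
#' for inter-beat intervals that exceed the 10-bit field.
#'
#' @param annotations Data frame with `sample_index` (0-based) and `symbol`.
#' @param directory Output directory. @param record_id Record name.
#' @param extension File extension (default `"atr"`).
#' @return Invisibly, the file path.
#' @export
write_wfdb_annotations <- function(annotations, directory, record_id,
                                   extension = "atr") {
  ann <- annotations[order(annotations$sample_index), , drop = FALSE]
  codes <- .symbol_to_code(ann$symbol)
  words <- integer(0)
  t <- 0
  for (k in seq_len(nrow(ann))) {
    diff <- ann$sample_index[[k]] - t
    if (diff > 1023L) {
      words <- c(words, 59L * 1024L, diff %/% 65536L, diff %% 65536L)
      t <- t + diff
      diff <- 0L
    }
    words <- c(words, codes[[k]] * 1024L + diff)
    t <- ann$sample_index[[k]]
  }
  words <- c(words, 0L)
  bytes <- as.raw(rbind(words %% 256L, words %/% 256L))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(directory, paste0(record_id, ".", extension))
  writeBin(bytes, path)
  invisible(path)
}

#' Read a delimited-text ECG record
#'
#' Text fallback for fixtures: one sample per line (whitespace/comma
#' separated columns for multichannel records), amplitudes in mV.
#'
#' @param path Path to the text file.
#' @param fs Sampling rate in Hz.
#' @param record_id Record name (default: file name without extension).
#' @return An `ecg_record`.
#' @export
read_text_record <- function(path, fs, record_id = NULL) {
  if (!file.exists(path)) stop("record file not found: ", path)
  if (is.null(record_id)) record_id <- sub("\\.[^.]*$", "", basename(path))
  m <- as.matrix(utils::read.table(path, sep = "", header = FALSE))
  new_ecg_record(record_id, fs, m)
}

#' Read a text annotation file
#'
#' Text fallback for fixtures: CSV with columns `sample_index,symbol`
#' (0-based indices), with or without a header line.
#'
#' @param path Path to the CSV file.
#' @return Data frame with `sample_index` and `symbol`, sorted ascending.
#' @export
read_text_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!length(first) || !nzchar(trimws(first))) {
    return(data.frame(sample_index = integer(0), symbol = character(0),
                      stringsAsFactors = FALSE))
  }
  header <- grepl("sample_index", first)
  df <- utils::read.csv(path, header = header, colClasses = "character")
  names(df)[1:2] <- c("sample_index", "symbol")
  df$sample_index <- as.integer(df$sample_index)
  df <- df[order(df$sample_index), 1:2, drop = FALSE]
  rownames(df) <- NULL
  df
}
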