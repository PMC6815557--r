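# Workflow commands wiring the modules together: prepare (load/generate,
# preprocess, split, serialize), train (fit + checkpoint + history CSV)
# and evaluate (reports + PR curves). A thin command-line wrapper over
# these functions ships in inst/cli/ecglstm-cli.R.

#' Pipeline configuration
#'
#' Assembles and validates the configuration consumed by
#' [run_prepare()], [run_train()] and [run_evaluate()]. The single `seed`
#' fans out to fixed sub-seeds for noise generation, splitting and
#' training so each stage is independently reproducible.
#'
#' @param data_dir Directory of WFDB records, or `NULL` to use the
#'   synthetic generator.
#' @param records Record ids to load from `data_dir` (default: all
#'   `.hea` files found).
#' @param synthetic_n Total synthetic beats (used when `data_dir` is
#'   NULL; default 2000, distributed per [mitbih_proportions()]).
#' @param noise `noise_spec` for synthetic generation.
#' @param denoise Apply wavelet denoising during preparation.
#' @param beat_length Beat window length (default 250).
#' @param test_fraction,val_fraction Split fractions (defaults 0.10, 0.10).
#' @param hidden,fc,loss,gamma,epochs,batch_size,dropout,learning_rate,peephole
#'   Training settings, as in [ecg_lstm()].
#' @param out_dir Output directory for all artifacts.
#' @param seed Master seed.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(data_dir = NULL, records = NULL,
                            synthetic_n = 2000L, noise = noise_spec(),
                            denoise = TRUE, beat_length = 250L,
                            test_fraction = 0.10, val_fraction = 0.10,
                            hidden = 64L, fc = 32L,
                            loss = c("focal", "cross_entropy"), gamma = 2,
                            epochs = 350L, batch_size = 128L, dropout = 0,
                            learning_rate = 0.004, peephole = TRUE,
                            out_dir = ".", seed = 1L) {
  loss <- match.arg(loss)
  cfg <- list(data_dir = data_dir, records = records,
              synthetic_n = as.integer(synthetic_n),
              noise = unclass(noise), denoise = isTRUE(denoise),
              beat_length = as.integer(beat_length),
              test_fraction = test_fraction, val_fraction = val_fraction,
              hidden = as.integer(hidden), fc = as.integer(fc),
              loss = loss, gamma = gamma, epochs = as.integer(epochs),
              batch_size = as.integer(batch_size), dropout = dropout,
              learning_rate = learning_rate, peephole = isTRUE(peephole),
              out_dir = out_dir, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration
#'
#' JSON on disk; a written-then-read configuration is identical.
#'
#' @param config A `pipeline_config`. @param path File path.
#' @return `write_pipeline_config`: invisibly `path`;
#'   `read_pipeline_config`: the `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  writeLines(jsonlite::toJSON(unclass(config), digits = NA, auto_unbox = TRUE,
                              null = "null"), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg$noise <- do.call(noise_spec, as.list(cfg$noise))
  do.call(pipeline_config, cfg)
}

# Polynomial rolling hash of the serialized config (mod 2^31 - 1),
# embedded in output files so any artifact can be traced to the exact
# configuration that produced it.
config_hash <- function(config) {
  s <- utf8ToInt(as.character(jsonlite::toJSON(unclass(config), digits = NA,
                                               auto_unbox = TRUE, null = "null")))
  h <- 17
  for (b in s) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

.cfg_paths <- function(config) {
  d <- config$out_dir
  list(dataset = file.path(d, "beats.txt"),
       manifest = file.path(d, "beats.txt.manifest.csv"),
       counts = file.path(d, "class_counts.csv"),
       checkpoint = file.path(d, "model.json"),
       history = file.path(d, "history.csv"),
       confusion = file.path(d, "confusion.txt"),
       report = file.path(d, "report.csv"))
}

#' Prepare a beat dataset
#'
#' Loads WFDB records (or generates synthetic beats), preprocesses
#' (denoise, segment, Z-score for WFDB input), assigns a stratified
#' train/validation/test split, and writes the serialized dataset, its
#' manifest (with split column) and a per-class count table.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with the `beat_dataset`, the split
#'   assignment vector and the count table.
#' @export
run_prepare <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- .cfg_paths(config)
  if (is.null(config$data_dir)) {
    ds <- gen_beat_dataset(mitbih_proportions(config$synthetic_n),
                           noise = do.call(noise_spec, as.list(config$noise)),
                           seed = config$seed + 1L,
                           beat_length = config$beat_length,
                           normalize = !config$denoise)
    if (config$denoise) {
      ds$x <- t(apply(ds$x, 1L, denoise_db6, fs = 360))
      ds <- zscore_beat(ds)
    }
  } else {
    if (!dir.exists(config$data_dir)) {
      stop("data directory not readable: ", config$data_dir)
    }
    ids <- config$records
    if (is.null(ids)) {
      ids <- sub("\\.hea$", "", list.files(config$data_dir, "\\.hea$"))
    }
    entries <- lapply(ids, function(id) {
      list(record = read_wfdb_record(config$data_dir, id),
           annotations = read_wfdb_annotations(config$data_dir, id))
    })
    ds <- build_beat_dataset(entries, denoise = config$denoise,
                             beat_length = config$beat_length)
  }
  parts <- split_beat_dataset(ds, config$test_fraction, config$val_fraction,
                              seed = config$seed + 2L)
  combined <- bind_beat_datasets(parts$train, parts$validation, parts$test)
  split <- rep(c("train", "validation", "test"),
               c(parts$train$n, parts$validation$n, parts$test$n))
  write_beat_dataset(combined, p$dataset, p$manifest, split = split)
  counts <- class_distribution(combined)
  counts_df <- data.frame(class = names(counts), beats = as.integer(counts),
                          config = config_hash(config))
  utils::write.csv(counts_df, p$counts, row.names = FALSE)
  invisible(list(dataset = combined, split = split, counts = counts))
}

.load_split <- function(config) {
  p <- .cfg_paths(config)
  ds <- read_beat_dataset(p$dataset, p$manifest)
  split <- attr(ds, "split")
  if (is.null(split)) stop("dataset manifest has no split column; run run_prepare()")
  list(train = ds[split == "train"], validation = ds[split == "validation"],
       test = ds[split == "test"])
}

#' Train the classifier on a prepared dataset
#'
#' Fits [ecg_lstm()] on the train split (validation split monitored),
#' then writes a checkpoint and a per-epoch history CSV
#' (`epoch,train_loss,train_acc,val_loss,val_acc`).
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, the fitted `ecg_lstm`.
#' @export
run_train <- function(config) {
  parts <- .load_split(config)
  fit <- ecg_lstm(parts$train, validation = parts$validation,
                  hidden = config$hidden, fc = config$fc, loss = config$loss,
                  gamma = config$gamma, epochs = config$epochs,
                  batch_size = config$batch_size, dropout = config$dropout,
                  learning_rate = config$learning_rate,
                  peephole = config$peephole, seed = config$seed + 3L)
  p <- .cfg_paths(config)
  write_checkpoint(fit, p$checkpoint)
  history <- fit$history
  history$config <- config_hash(config)
  utils::write.csv(history, p$history, row.names = FALSE)
  invisible(fit)
}

#' Evaluate a trained checkpoint
#'
#' Evaluates the checkpointed model on one split and writes the
#' confusion matrix (plain text), the metric report CSV (per-class rows
#' plus weighted and macro aggregates, columns ACC/RE/SP/PR/F1 in
#' percent) and per-class PR-curve CSV point lists.
#'
#' @param config A `pipeline_config`.
#' @param split Which split to evaluate (default `"test"`).
#' @return Invisibly, the `beat_eval` report.
#' @export
run_evaluate <- function(config, split = "test") {
  parts <- .load_split(config)
  ds <- parts[[split]]
  if (is.null(ds) || ds$n == 0L) stop("empty evaluation split: ", split)
  p <- .cfg_paths(config)
  model <- read_checkpoint(p$checkpoint)
  missing_classes <- setdiff(0:7, unique(ds$label))
  if (length(missing_classes)) {
    warning("classes absent from the ", split, " split: ",
            paste(beat_classes()[missing_classes + 1L], collapse = " "))
  }
  rep <- evaluate_model(model, ds)
  hash <- config_hash(config)
  con <- file(p$confusion, "w")
  writeLines(c(sprintf("# config %s, split %s", hash, split),
               utils::capture.output(print(rep$confusion))), con)
  close(con)
  write_report_csv(rep, p$report)
  curves <- per_class_pr_curves(rep, ds$label)
  for (nm in names(curves)) {
    utils::write.csv(
      data.frame(recall = curves[[nm]]$recall,
                 precision = curves[[nm]]$precision,
                 threshold = curves[[nm]]$threshold,
                 config = hash),
      file.path(config$out_dir, sprintf("pr_curve_%s.csv", nm)),
      row.names = FALSE
    )
  }
  invisible(rep)
}
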