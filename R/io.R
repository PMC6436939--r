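# Serialization. Datasets are stored as a directory: JSON + TSV for
# metadata and events (interoperable, text), RDS for the numeric arrays
# (lossless round trip). Traces, trials and layouts export as plain TSV.

.dataset_format_version <- "cqdecode-dataset-1"

#' Serialize a sequence set to JSON
#' @param sequences A list of [sequence_spec()]s.
#' @param path Output file.
#' @export
write_sequences <- function(sequences, path) {
  jsonlite::write_json(lapply(unname(sequences), unclass), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a sequence set from JSON
#' @param path JSON file written by [write_sequences()].
#' @return Named list of [sequence_spec()]s.
#' @export
read_sequences <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  pick <- function(col, i) {
    if (is.matrix(col)) col[i, ] else unlist(col[[i]])
  }
  out <- lapply(seq_len(nrow(raw)), function(i)
    sequence_spec(raw$id[i], pick(raw$finger_order, i),
                  pick(raw$interval_order, i),
                  raw$finger_order_id[i], raw$interval_order_id[i]))
  names(out) <- raw$id
  out
}

#' Serialize a session schedule to JSON
#' @param schedule A [schedule_session()] object.
#' @param path Output file.
#' @export
write_schedule <- function(schedule, path) {
  jsonlite::write_json(list(seed = schedule$seed, blocks = schedule$blocks),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a session schedule from JSON
#' @param path JSON file written by [write_schedule()].
#' @export
read_schedule <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  blocks <- if (is.matrix(raw$blocks))
    lapply(seq_len(nrow(raw$blocks)), function(i) raw$blocks[i, ])
  else as.list(raw$blocks)
  structure(list(blocks = blocks, seed = as.integer(raw$seed)),
            class = "session_schedule")
}

#' Export per-trial behaviour as TSV
#'
#' Columns: trial, block, sequence_id, press1..press5 (fingers), t_go and
#' t_press1..t_press5 (ms on the session clock; t_go is 0 per trial here
#' since all events are go-referenced).
#'
#' @param dataset A `"cq_dataset"`.
#' @param path Output file.
#' @export
write_trials_tsv <- function(dataset, path) {
  tab <- dataset$trials
  press_f <- t(vapply(dataset$results, `[[`, integer(5), "press_fingers"))
  press_t <- t(vapply(dataset$results, `[[`, numeric(5), "press_times"))
  colnames(press_f) <- paste0("press", 1:5)
  colnames(press_t) <- paste0("t_press", 1:5)
  out <- cbind(tab[, c("trial", "block", "sequence_id")],
               as.data.frame(press_f), t_go = 0, as.data.frame(press_t))
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

# BIDS-style events long table for all trials.
.events_table <- function(dataset) {
  rows <- lapply(seq_along(dataset$results), function(i) {
    r <- dataset$results[[i]]
    ep_events <- if (!is.null(dataset$epochs))
      dataset$epochs[[i]]$events else list(cue = NA_real_, go = 0,
                                           presses = r$press_times)
    data.frame(onset_ms = c(ep_events$cue, 0, r$press_times),
               duration_ms = 0,
               trial = i,
               event_type = c("cue", "go", rep("press", 5)),
               finger = c(NA, NA, r$press_fingers),
               position = c(NA, NA, 1:5),
               sequence_id = r$sequence_id)
  })
  do.call(rbind, rows)
}

#' Write a dataset to a directory
#'
#' Layout: `meta.json` (format version, modality, storage mode, channel count,
#' generator parameters, seed), `trials.tsv`, `events.tsv` (BIDS-style long
#' table) and `arrays.rds` (epoch/feature arrays, trial results, pattern
#' basis). The round trip through [read_dataset()] is lossless.
#'
#' @param dataset A `"cq_dataset"`.
#' @param path Directory to create.
#' @export
write_dataset <- function(dataset, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(format = .dataset_format_version,
               modality = dataset$modality,
               compact = is.null(dataset$epochs),
               n_channels = dataset$n_channels,
               n_trials = nrow(dataset$trials),
               seed = dataset$seed,
               params = unclass(dataset$params))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  data.table::fwrite(dataset$trials, file.path(path, "trials.tsv"),
                     sep = "\t")
  data.table::fwrite(.events_table(dataset), file.path(path, "events.tsv"),
                     sep = "\t")
  write_sequences(dataset$sequences, file.path(path, "sequences.json"))
  saveRDS(list(epochs = dataset$epochs, features = dataset$features,
               results = dataset$results, basis = dataset$basis),
          file.path(path, "arrays.rds"))
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#' @param path Dataset directory.
#' @return A `"cq_dataset"`.
#' @export
read_dataset <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop("not a dataset directory: missing meta.json")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$format, .dataset_format_version))
    stop("dataset format version mismatch: found ", meta$format)
  for (f in c("events.tsv", "trials.tsv", "arrays.rds", "sequences.json"))
    if (!file.exists(file.path(path, f)))
      stop("corrupt dataset: missing ", f)
  arrays <- readRDS(file.path(path, "arrays.rds"))
  trials <- as.data.frame(data.table::fread(file.path(path, "trials.tsv")))
  params <- do.call(generator_params, meta$params)
  out <- list(trials = trials, results = arrays$results,
              sequences = read_sequences(file.path(path, "sequences.json")),
              params = params, basis = arrays$basis,
              modality = meta$modality, seed = as.integer(meta$seed),
              n_channels = as.integer(meta$n_channels))
  if (isTRUE(meta$compact)) out$features <- arrays$features
  else out$epochs <- arrays$epochs
  structure(out, class = "cq_dataset")
}

#' Write / read a fitted classifier
#'
#' Stores the class means, pooled covariance, shrinkage, priors and class
#' labels (RDS container; lossless).
#'
#' @param model A [fit_gaussian_linear()] model.
#' @param path File path.
#' @export
write_model <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  m <- readRDS(path)
  needed <- c("K", "classes", "means", "cov", "chol", "lambda", "priors")
  if (!all(needed %in% names(m))) stop("not a serialized classifier")
  structure(m[needed], class = "gaussian_linear")
}

#' Export probability traces as a long TSV
#'
#' Columns: trial, window_start_ms, p1..p5.
#'
#' @param traces List of `"probability_trace"`s (NULL entries skipped).
#' @param path Output file.
#' @export
write_traces_tsv <- function(traces, path) {
  rows <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    if (is.null(tr)) return(NULL)
    out <- data.frame(trial = i, window_start_ms = tr$window_starts)
    probs <- t(tr$probs)
    colnames(probs) <- paste0("p", seq_len(ncol(probs)))
    cbind(out, probs)
  })
  data.table::fwrite(do.call(rbind, rows), path, sep = "\t")
  invisible(path)
}

#' Write / read a sensor layout TSV (channel, x, y)
#' @param layout Layout data.frame.
#' @param path File path.
#' @export
write_layout <- function(layout, path) {
  data.table::fwrite(layout[, c("channel", "x", "y")], path, sep = "\t")
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  as.data.frame(data.table::fread(path))
}
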