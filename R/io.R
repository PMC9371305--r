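#' Corpus and checkpoint persistence
#'
#' Corpora are stored as one tensor-container file per speaker (the
#' utterance stack) plus a `manifest.csv` (speaker_id, split, label,
#' path, n_utterances) and, for synthetic corpora, a
#' `ground_truth.json`. Model checkpoints are stored as one container
#' file per parameter array plus a JSON manifest naming every array and
#' its shape, the architecture configuration and the seed.
#'
#' @name corpus-io
NULL

#' Write a spectrogram corpus to a directory
#'
#' @param corpus list of [speaker_record()]s with spectrogram
#'   utterances.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(corpus, function(s) {
    d <- dim(s$utterances[[1]])
    ten <- array(0, dim = c(length(s$utterances), d[1], d[2]))
    for (u in seq_along(s$utterances)) ten[u, , ] <- s$utterances[[u]]
    path <- file.path(dir, paste0(s$speaker_id, ".t3f8"))
    write_tensor(ten, path)
    data.frame(speaker_id = s$speaker_id, split = s$split, label = s$label,
               path = basename(path), n_utterances = length(s$utterances))
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  gt <- attr(corpus, "ground_truth")
  if (!is.null(gt))
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"))
  invisible(dir)
}

#' Read a spectrogram corpus from a directory
#'
#' @param dir directory written by [write_corpus()].
#' @return list of [speaker_record()]s.
#' @export
read_corpus <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("missing corpus manifest: ", mf)
  man <- utils::read.csv(mf, stringsAsFactors = FALSE)
  corpus <- lapply(seq_len(nrow(man)), function(i) {
    ten <- read_tensor(file.path(dir, man$path[i]))
    utts <- lapply(seq_len(dim(ten)[1]), function(u) ten[u, , ])
    speaker_record(man$speaker_id[i], man$split[i], man$label[i], utts)
  })
  gtf <- file.path(dir, "ground_truth.json")
  if (file.exists(gtf))
    attr(corpus, "ground_truth") <- jsonlite::fromJSON(gtf)
  corpus
}

#' Write a waveform corpus as WAV files plus manifest
#'
#' One WAV per speaker (the full interview-like signal with silences),
#' a `manifest.csv` with columns speaker_id, split, label, wav_path, and
#' the generator's ground truth as JSON.
#'
#' @param corpus output of [simulate_corpus()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_corpus_wav <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(corpus, function(s) {
    wav <- paste0(s$speaker_id, ".wav")
    write_wav(s$wave, file.path(dir, wav))
    data.frame(speaker_id = s$speaker_id, split = s$split, label = s$label,
               wav_path = wav)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  gt <- attr(corpus, "ground_truth")
  if (!is.null(gt))
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"))
  invisible(dir)
}

#' Load and preprocess a WAV corpus
#'
#' Reads `manifest.csv` (speaker_id, split, label, wav_path), loads each
#' WAV, segments it into utterances, fixes each to 7 s and computes
#' log-mel spectrograms.
#'
#' @param dir directory with `manifest.csv` and WAV files.
#' @param ... passed to [segment_speech()].
#' @return list of [speaker_record()]s with spectrogram utterances.
#'   Speakers yielding zero segments are dropped with a warning.
#' @export
load_wav_corpus <- function(dir, ...) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("missing corpus manifest: ", mf)
  man <- utils::read.csv(mf, stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(man))) {
    w <- read_wav(file.path(dir, man$wav_path[i]))
    utts <- preprocess_waveform(w, ...)
    if (length(utts) == 0L) {
      warning("no speech segments found for speaker ", man$speaker_id[i])
      next
    }
    out[[length(out) + 1L]] <- speaker_record(man$speaker_id[i], man$split[i],
                                              man$label[i], utts)
  }
  out
}

#' Save / load a fitted model checkpoint
#'
#' @param model a fitted `tfnn_model`.
#' @param dir checkpoint directory.
#' @return `save_model` returns `dir` invisibly; `load_model` the
#'   restored `tfnn_model`.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  leaves <- .walk_params(model$params)
  shapes <- lapply(leaves, function(x) if (is.null(dim(x))) length(x) else dim(x))
  for (nm in names(leaves)) {
    write_tensor(leaves[[nm]], file.path(dir, paste0(gsub("\\.", "_", nm), ".t3f8")))
  }
  manifest <- list(arrays = shapes,
                   config = unclass(model$config),
                   train_cfg = unclass(model$train_cfg),
                   bag_size = model$bag_size, threshold = model$threshold,
                   best_epoch = model$best_epoch, dev_ua = model$dev_ua,
                   class_weights = model$class_weights,
                   seed = model$train_cfg$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(model$history, file.path(dir, "history.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("missing checkpoint: no manifest.json in ", dir)
  man <- jsonlite::fromJSON(mf)
  cfg <- man$config
  cfg$ff_dims <- if (is.null(cfg$ff_dims)) NULL else
    lapply(seq_len(nrow(cfg$ff_dims)), function(i) as.numeric(cfg$ff_dims[i, ]))
  cfg$kernels <- if (is.null(cfg$kernels)) NULL else
    lapply(seq_len(nrow(cfg$kernels)), function(i) as.numeric(cfg$kernels[i, ]))
  config <- do.call(model_config, cfg[!vapply(cfg, is.null, logical(1))])
  tc <- man$train_cfg
  train_cfg <- do.call(train_config, tc[setdiff(names(tc), character(0))])
  params <- init_model(config, seed = man$seed)
  leaves <- .walk_params(params)
  for (nm in names(leaves)) {
    x <- read_tensor(file.path(dir, paste0(gsub("\\.", "_", nm), ".t3f8")))
    if (length(dim(x)) == 1L) x <- as.vector(x)
    leaves[[nm]] <- x
  }
  flat <- unlist(leaves, use.names = FALSE)
  history <- utils::read.csv(file.path(dir, "history.csv"))
  structure(list(params = .unflatten_into(params, flat), config = config,
                 train_cfg = train_cfg, bag_size = man$bag_size,
                 history = history, threshold = man$threshold,
                 best_epoch = man$best_epoch, dev_ua = man$dev_ua,
                 n_train_bags = NA_integer_,
                 class_weights = man$class_weights),
            class = "tfnn_model")
}
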