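#' MIL protocol: speakers, bags, thresholding
#'
#' A speaker record carries a variable-length collection of utterance
#' spectrograms and a single binary label; only the speaker label is
#' observed (the MIL assumption). Bags are fixed-size disjoint subsets
#' of one speaker's utterances stacked into an order-3 tensor, each
#' inheriting the speaker label. Speaker-level scores are the mean of
#' the speaker's bag probabilities, thresholded at the Youden-optimal
#' operating point of the validation ROC.
#'
#' @name mil-bagging
NULL

#' Construct a speaker record
#'
#' @param speaker_id identifier.
#' @param split one of `"train"`, `"dev"`, `"test"`.
#' @param label 0 (normal) or 1 (depressed).
#' @param utterances list of `F x T` spectrogram matrices (or, upstream
#'   of the front-end, waveforms).
#' @return a `speaker_record` list.
#' @export
speaker_record <- function(speaker_id, split, label, utterances) {
  split <- match.arg(split, c("train", "dev", "test"))
  if (!label %in% c(0, 1)) stop("label must be 0 or 1")
  if (length(utterances) < 1L) stop("speaker must have at least one utterance")
  structure(list(speaker_id = as.character(speaker_id), split = split,
                 label = as.integer(label), utterances = utterances),
            class = "speaker_record")
}

#' Partition a speaker's utterances into bags
#'
#' Shuffles the speaker's utterances with the given seed and partitions
#' them into `floor(n / k)` disjoint bags of exactly `k`, each stacked
#' into a `k x F x T` tensor carrying the speaker's label. Leftover
#' utterances (`n mod k`) are dropped by default, keeping the
#' without-repetition rule strict; `leftover = "fill"` completes one
#' extra bag by sampling (without replacement) from the speaker's other
#' utterances, for small-data use.
#'
#' @param s a [speaker_record()] with spectrogram utterances.
#' @param k bag size (utterances per bag).
#' @param seed integer seed for the shuffle.
#' @param leftover `"drop"` (default) or `"fill"`.
#' @return list of bags, each a list with `speaker_id`, `bag_index`,
#'   `tensor` (`k x F x T`), `label`. Zero bags (with a warning) if the
#'   speaker has fewer than `k` utterances.
#' @export
make_bags <- function(s, k, seed = 1L, leftover = c("drop", "fill")) {
  leftover <- match.arg(leftover)
  if (k < 1L) stop("k must be >= 1")
  n <- length(s$utterances)
  if (n < k) {
    warning(sprintf("speaker %s has %d < %d utterances; skipped", s$speaker_id, n, k))
    return(list())
  }
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  nb <- n %/% k
  idx_sets <- lapply(seq_len(nb), function(b) perm[((b - 1L) * k + 1L):(b * k)])
  rem <- if (nb * k < n) perm[(nb * k + 1L):n] else integer(0)
  if (leftover == "fill" && length(rem) > 0L) {
    extra <- sample(perm[seq_len(nb * k)], k - length(rem))
    idx_sets <- c(idx_sets, list(c(rem, extra)))
  }
  d <- dim(s$utterances[[1]])
  lapply(seq_along(idx_sets), function(b) {
    ten <- array(0, dim = c(length(idx_sets[[b]]), d[1], d[2]))
    for (j in seq_along(idx_sets[[b]]))
      ten[j, , ] <- s$utterances[[idx_sets[[b]][j]]]
    list(speaker_id = s$speaker_id, bag_index = b, tensor = ten,
         label = s$label, utterance_index = idx_sets[[b]])
  })
}

#' Speaker-level probability from bag probabilities
#'
#' Arithmetic mean of the speaker's bag probabilities.
#'
#' @param bag_probs numeric vector of probabilities, length >= 1.
#' @return scalar probability.
#' @export
aggregate_speaker <- function(bag_probs) {
  if (length(bag_probs) < 1L) stop("need at least one bag probability")
  mean(bag_probs)
}

#' Youden-optimal decision threshold from validation scores
#'
#' Maximizes Youden's J (TPR - FPR) over the ROC of the scores under
#' the decision rule `score >= tau -> positive`. Every distinct score
#' value is a candidate threshold (that set is exhaustive for this
#' rule); ties are broken toward the smaller threshold.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels 0/1 labels; both classes must be present.
#' @return the selected threshold, with attribute `"J"`.
#' @export
select_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present to select a threshold")
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  cand <- sort(unique(scores))
  J <- vapply(cand, function(tau) {
    pred <- as.integer(scores >= tau)
    sum(pred == 1L & labels == 1L) / npos - sum(pred == 1L & labels == 0L) / nneg
  }, numeric(1))
  best <- which.max(J)                        # first max -> smallest tau
  structure(cand[best], J = J[best])
}

#' Classify a speaker-level probability
#'
#' Label 1 iff `p >= tau` (boundary inclusive).
#'
#' @param p probability in `[0, 1]`.
#' @param tau decision threshold.
#' @return integer label 0/1.
#' @export
classify_speaker <- function(p, tau) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  as.integer(p >= tau)
}
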