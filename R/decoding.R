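#' Assemble a decoding dataset from band-power tables
#'
#' One sample per subject x task (the visually-guided label coded +1,
#' memory-guided -1); the features at each time bin are the dB values of
#' one band at the chosen electrodes (3 features for the parietal group,
#' 1 for a single electrode such as C3 or Fz). The conventional analysis
#' windows are the second before reach onset (-1..0 s, reach-aligned) and
#' the second after feedback (0..1 s, feedback-aligned).
#'
#' @param bandTable a [bandAverage()] table row-bound over all
#'   recordings (columns `subject`, `task`, `alignment`, `channel`,
#'   `band`, `time_s`, `db`).
#' @param band band name (e.g. `"delta"`).
#' @param electrodes electrode names forming the feature vector.
#' @param alignment epoch alignment the features come from.
#' @param window (start, end) seconds; bins with centers inside
#'   (inclusive) are used.
#' @return list of class `"decodingDataset"`: `X` (samples x features x
#'   bins array), `y` (+1/-1), `subjects`, `times`, plus the selection
#'   descriptors.
#' @export
assembleFeatures <- function(bandTable, band, electrodes, alignment,
                             window) {
  sub <- bandTable[bandTable$band == band &
                   bandTable$alignment == alignment &
                   bandTable$channel %in% electrodes, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no band-power rows for band '", band, "' at alignment '",
         alignment, "'")
  eps <- 1e-6
  times <- sort(unique(sub$time_s))
  times <- times[times >= window[1] - eps & times <= window[2] + eps]
  if (length(times) == 0L)
    stop("analysis window [", window[1], ", ", window[2],
         "] s is not covered by the band-power table")
  subjects <- sort(unique(sub$subject))
  n <- 2L * length(subjects)
  X <- array(NA_real_, dim = c(n, length(electrodes), length(times)))
  y <- numeric(n)
  subjIdx <- integer(n)
  i <- 0L
  for (s in subjects) for (tk in .TASKS) {
    i <- i + 1L
    y[i] <- if (tk == "visual") 1 else -1
    subjIdx[i] <- match(s, subjects)
    for (e in seq_along(electrodes)) {
      cell <- sub[sub$subject == s & sub$task == tk &
                  sub$channel == electrodes[e], , drop = FALSE]
      if (nrow(cell) == 0L)
        stop("missing subject x task cell: subject ", s, ", ", tk,
             ", electrode ", electrodes[e])
      v <- cell$db[match(round(times / 0.05), round(cell$time_s / 0.05))]
      X[i, e, ] <- v
    }
  }
  if (anyNA(X))
    stop("NA features in the analysis window (invalid wavelet bins?); ",
         "narrow the window or drop the affected band")
  structure(list(X = X, y = y, subjects = subjIdx, times = times,
                 band = band, electrodes = electrodes,
                 alignment = alignment, window = window),
            class = "decodingDataset")
}

#' Leave-one-subject-out decoding accuracy per time bin
#'
#' For each time bin and each held-out subject, trains a linear
#' maximum-margin classifier (regularization constant `C`) on the
#' remaining subjects' 2(n-1) samples with within-fold feature
#' standardization, predicts the held-out subject's two samples, and
#' pools correct predictions over folds (accuracy = correct / 2n).
#' Decision ties predict the first label (visual) so runs are
#' reproducible.
#'
#' @param dataset a `"decodingDataset"` from [assembleFeatures()].
#' @param C regularization constant (default 1).
#' @return numeric accuracy per time bin.
#' @export
losoAccuracy <- function(dataset, C = 1) {
  stopifnot(inherits(dataset, "decodingDataset"))
  ns <- max(dataset$subjects)
  if (ns < 2L) stop("need at least 2 subjects for LOSO")
  tab <- table(dataset$subjects, dataset$y)
  if (any(tab != 1L))
    stop("each subject must contribute exactly one sample per task")
  cpp_loso_accuracy(dataset$X, dataset$y,
                    as.integer(dataset$subjects - 1L), C)
}

#' Permutation null, chance level and significance threshold
#'
#' Each permutation independently flips each subject's pair of task
#' labels with probability 1/2 (a paired-design shuffle that preserves
#' the two-samples-per-subject structure) and recomputes the LOSO
#' accuracy curve. In the default `"max"` mode the null statistic is each
#' permutation's maximum accuracy over the window, which controls the
#' family-wise error over time bins; `"perbin"` keeps an uncorrected
#' per-bin null for comparison. The chance level is the median of the
#' null and the threshold its 95th percentile; a bin is significant when
#' the true accuracy strictly exceeds the threshold.
#'
#' @param dataset a `"decodingDataset"`.
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed for the label flips.
#' @param mode `"max"` (default) or `"perbin"`.
#' @param C regularization constant (default 1).
#' @param accuracy optional precomputed [losoAccuracy()] curve.
#' @return a [DecodingResult-class].
#' @export
permutationNull <- function(dataset, nPerm = 1000, seed = 1,
                            mode = c("max", "perbin"), C = 1,
                            accuracy = NULL) {
  stopifnot(inherits(dataset, "decodingDataset"))
  mode <- match.arg(mode)
  if (nPerm < 1) stop("nPerm must be >= 1")
  if (is.null(accuracy)) accuracy <- losoAccuracy(dataset, C)
  ns <- max(dataset$subjects)
  set.seed(deriveSeed(seed, "permutation"))
  flips <- matrix(sample(c(0L, 1L), nPerm * ns, replace = TRUE),
                  nrow = nPerm)
  null <- cpp_loso_perm(dataset$X, dataset$y,
                        as.integer(dataset$subjects - 1L), flips, C)
  if (mode == "max") {
    stat <- apply(null, 1, max)
    chance <- median(stat)
    threshold <- unname(quantile(stat, 0.95))
  } else {
    stat <- numeric(0)
    chance <- apply(null, 2, median)
    threshold <- unname(apply(null, 2, quantile, 0.95))
  }
  new("DecodingResult", accuracy = accuracy, times = dataset$times,
      null = null, nullStat = stat, chance = chance,
      threshold = threshold,
      significant = accuracy > threshold + 0,  # strict inequality
      mode = mode, nPerm = as.integer(nPerm))
}

#' Decode task type from one band/electrode configuration
#'
#' Convenience wrapper: [losoAccuracy()] plus [permutationNull()].
#'
#' @inheritParams permutationNull
#' @return a [DecodingResult-class].
#' @export
decodeTaskType <- function(dataset, nPerm = 1000, seed = 1,
                           mode = c("max", "perbin"), C = 1) {
  acc <- losoAccuracy(dataset, C)
  permutationNull(dataset, nPerm = nPerm, seed = seed,
                  mode = match.arg(mode), C = C, accuracy = acc)
}
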