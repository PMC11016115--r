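# On-disk dataset dialect
#
#   dir/trials.csv         one row per trial (full double precision)
#   dir/trajectories.csv   long form: subject, task, trial, t_s, x_mm, y_mm
#   dir/eeg/s<subject>_<task>.f32   32-bit little-endian floats,
#                                   channel-major (all samples of channel
#                                   1, then channel 2, ...)
#   dir/eeg/s<subject>_<task>.txt   sidecar: subject, task, fs, n_samples,
#                                   channels, then one 'label,sample,trial'
#                                   line per marker; sample indices 0-based

# format numeric columns so the CSV round-trips doubles exactly
.writeTableExact <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  data.table::fwrite(out, path)
}

.eegStem <- function(subject, task) sprintf("s%d_%s", subject, task)

#' Write an EEG recording (binary floats + text sidecar)
#'
#' @param rec an [EEGRecording-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths written.
#' @export
writeEEGRecording <- function(rec, dir) {
  stopifnot(is(rec, "EEGRecording"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, .eegStem(rec@subject, rec@task))
  binPath <- paste0(stem, ".f32")
  con <- file(binPath, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(rec@data)), con, size = 4L, endian = "little")
  close(con); on.exit()
  side <- c(
    sprintf("subject: %d", rec@subject),
    sprintf("task: %s", rec@task),
    sprintf("fs: %.17g", rec@fs),
    sprintf("n_samples: %d", ncol(rec@data)),
    sprintf("channels: %s", paste(rec@channels, collapse = ",")),
    "markers:",
    sprintf("%s,%d,%d", rec@markers$label, rec@markers$sample - 1L,
            rec@markers$trial))
  writeLines(side, paste0(stem, ".txt"))
  invisible(c(binPath, paste0(stem, ".txt")))
}

#' Read an EEG recording written by [writeEEGRecording()]
#'
#' @param stem path prefix (without `.f32`/`.txt`).
#' @return an [EEGRecording-class].
#' @export
readEEGRecording <- function(stem) {
  sidePath <- paste0(stem, ".txt")
  binPath <- paste0(stem, ".f32")
  for (p in c(sidePath, binPath))
    if (!file.exists(p)) stop("missing file: ", p)
  lines <- readLines(sidePath)
  mstart <- match("markers:", lines)
  if (is.na(mstart)) stop(sidePath, ": no 'markers:' section")
  hdr <- lines[seq_len(mstart - 1L)]
  getField <- function(key) {
    hit <- grep(paste0("^", key, ": "), hdr, value = TRUE)
    if (length(hit) != 1L)
      stop(sidePath, ": header field '", key, "' missing or duplicated")
    sub(paste0("^", key, ": "), "", hit)
  }
  subject <- as.integer(getField("subject"))
  task <- getField("task")
  fs <- as.numeric(getField("fs"))
  nSamples <- as.integer(getField("n_samples"))
  channels <- strsplit(getField("channels"), ",", fixed = TRUE)[[1]]
  mlines <- lines[seq(mstart + 1L, length(lines))]
  mlines <- mlines[nzchar(mlines)]
  parts <- strsplit(mlines, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop(sidePath, ": malformed marker at line ", mstart + bad[1],
         ": '", mlines[bad[1]], "'")
  samp <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  tri <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3L)))
  bad <- which(is.na(samp) | is.na(tri))
  if (length(bad))
    stop(sidePath, ": non-numeric marker field at line ", mstart + bad[1],
         ": '", mlines[bad[1]], "'")
  markers <- data.frame(label = vapply(parts, `[`, "", 1L),
                        sample = samp + 1L, trial = tri)
  expected <- length(channels) * nSamples
  sz <- file.info(binPath)$size
  if (sz != 4 * expected)
    stop(binPath, ": expected ", 4 * expected, " bytes (",
         length(channels), " channels x ", nSamples, " samples), found ",
         sz)
  con <- file(binPath, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = expected, size = 4L,
                  endian = "little")
  new("EEGRecording", channels = channels, fs = fs,
      data = t(matrix(vals, nrow = nSamples, ncol = length(channels))),
      markers = markers, subject = subject, task = task)
}

#' Write a full dataset to a directory
#'
#' @param behavior list with `trials` and `trajectories`
#'   ([simulateBehavior()]).
#' @param recordings optional named list of [EEGRecording-class] objects
#'   ([simulateEEG()]).
#' @param dir output directory.
#' @return invisibly, `dir`.
#' @export
writeDataset <- function(behavior, recordings = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .writeTableExact(behavior$trials, file.path(dir, "trials.csv"))
  .writeTableExact(behavior$trajectories,
                   file.path(dir, "trajectories.csv"))
  if (!is.null(recordings))
    for (rec in recordings) writeEEGRecording(rec, file.path(dir, "eeg"))
  invisible(dir)
}

#' Read a dataset written by [writeDataset()]
#'
#' @param dir dataset directory.
#' @param readEEG logical, also load the EEG recordings (default TRUE).
#' @return list with `trials`, `trajectories` and (when present)
#'   `recordings`.
#' @export
readDataset <- function(dir, readEEG = TRUE) {
  tPath <- file.path(dir, "trials.csv")
  if (!file.exists(tPath)) stop("missing file: ", tPath)
  trials <- as.data.frame(data.table::fread(tPath))
  trajectories <- as.data.frame(
    data.table::fread(file.path(dir, "trajectories.csv")))
  out <- list(trials = trials, trajectories = trajectories)
  eegDir <- file.path(dir, "eeg")
  if (readEEG && dir.exists(eegDir)) {
    stems <- sub("\\.f32$", "",
                 list.files(eegDir, pattern = "\\.f32$", full.names = TRUE))
    out$recordings <- setNames(lapply(stems, readEEGRecording),
                               basename(stems))
  }
  out
}
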