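# Epoched-dataset container and I/O: the fixture format (single
# hierarchical binary file via R serialization), and a GDF epoch reader
# that delegates raw-file parsing to the MNE backend through `python`.

#' Epoched EEG dataset
#'
#' The universal input container: a trials x channels x samples array (in
#' microvolts), 0-based integer class labels, sampling rate and metadata.
#'
#' @param data Numeric array (trials, channels, samples).
#' @param labels Integer labels in `[0, n_classes)`, one per trial.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_names Optional electrode names.
#' @param subject_id Subject identifier string.
#' @param session_tag `"train"` or `"test"`.
#' @return Object of class `epoched_eeg`.
#' @export
epoched_eeg <- function(data, labels, sampling_rate,
                        channel_names = NULL, subject_id = "unknown",
                        session_tag = c("train", "test")) {
  check_trials_array(data)
  session_tag <- match.arg(session_tag)
  labels <- as.integer(labels)
  if (length(labels) != dim(data)[1]) {
    stop("labels must have one entry per trial")
  }
  if (any(labels < 0)) stop("labels must be nonnegative (0-based)")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (is.null(channel_names)) {
    channel_names <- paste0("CH", seq_len(dim(data)[2]))
  }
  if (length(channel_names) != dim(data)[2]) {
    stop("channel_names must have one entry per channel")
  }
  structure(list(data = data, labels = labels,
                 sampling_rate = sampling_rate,
                 channel_names = channel_names,
                 subject_id = subject_id, session_tag = session_tag,
                 meta = list()),
            class = "epoched_eeg")
}

#' @export
print.epoched_eeg <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "Epoched EEG: %d trials x %d channels x %d samples @ %g Hz\n",
    d[1], d[2], d[3], x$sampling_rate))
  cat(sprintf("  subject %s (%s session), %d classes\n", x$subject_id,
              x$session_tag, length(unique(x$labels))))
  invisible(x)
}

#' Write / read an epoched dataset fixture
#'
#' Lossless round trip of data, labels and metadata through a single
#' hierarchical binary file (R serialization). Reading a truncated or
#' foreign file raises a parse error rather than returning partial data.
#'
#' @param dataset An [epoched_eeg()] object.
#' @param path Fixture file path.
#' @return `write_epochs` returns `path` invisibly; `read_epochs` returns
#'   the dataset.
#' @export
write_epochs <- function(dataset, path) {
  stopifnot(inherits(dataset, "epoched_eeg"))
  saveRDS(list(format = "bfatcnet-epochs-1",
               dataset = unclass(dataset)), path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  payload <- tryCatch(readRDS(path), error = function(e) {
    stop("parse error reading epoch fixture '", path, "': ",
         conditionMessage(e))
  })
  if (!is.list(payload) || !identical(payload$format, "bfatcnet-epochs-1")) {
    stop("parse error: '", path, "' is not an epoch fixture")
  }
  ds <- payload$dataset
  out <- epoched_eeg(ds$data, ds$labels, ds$sampling_rate,
                     ds$channel_names, ds$subject_id, ds$session_tag)
  out$meta <- ds$meta
  out
}

#' Default motor-imagery cue event map (BCI Competition IV-2a codes)
#'
#' Annotation codes 769-772 for left hand, right hand, feet and tongue
#' cues, mapped to 0-based labels. Override per dataset as needed.
#'
#' @return Named integer vector.
#' @export
default_event_map <- function() {
  c("769" = 0L, "770" = 1L, "771" = 2L, "772" = 3L)
}

#' Read epochs from a GDF recording
#'
#' Extracts fixed-length epochs starting `offset_seconds` after each cue
#' event, using the MNE backend (invoked through `python`) to parse the
#' GDF container. No filtering or artifact rejection is applied. Unknown
#' event codes are reported and skipped; a file without any mapped events
#' is an error.
#'
#' @param path GDF file path.
#' @param event_map Named vector mapping annotation codes to 0-based
#'   labels; defaults to the IV-2a motor-imagery cues.
#' @param window_seconds Epoch length in seconds (4.5 s at 250 Hz gives
#'   1125 samples).
#' @param offset_seconds Epoch start relative to the cue.
#' @param python Python executable with `mne` available.
#' @return An [epoched_eeg()] dataset in microvolts.
#' @export
read_gdf_epochs <- function(path, event_map = default_event_map(),
                            window_seconds = 4.5, offset_seconds = 2,
                            python = Sys.which("python")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!nzchar(python)) stop("no python executable found for the GDF backend")
  out_bin <- tempfile(fileext = ".bin")
  out_json <- tempfile(fileext = ".json")
  on.exit(unlink(c(out_bin, out_json)), add = TRUE)
  script <- paste(
    "import json, sys",
    "import numpy as np",
    "import mne",
    "path, out_bin, out_json, off, wlen = sys.argv[1:6]",
    "event_map = json.loads(sys.argv[6])",
    "raw = mne.io.read_raw_gdf(path, preload=True, verbose='ERROR')",
    "sf = raw.info['sfreq']",
    "n = int(round(float(wlen) * sf))",
    "X = raw.get_data()",
    "trials, labels, skipped = [], [], {}",
    "for desc, onset in zip(raw.annotations.description,",
    "                       raw.annotations.onset):",
    "    key = str(desc)",
    "    if key in event_map:",
    "        s = int(round((onset + float(off)) * sf))",
    "        if 0 <= s and s + n <= X.shape[1]:",
    "            trials.append(X[:, s:s + n])",
    "            labels.append(int(event_map[key]))",
    "    else:",
    "        skipped[key] = skipped.get(key, 0) + 1",
    "meta = {'n_trials': len(trials), 'n_channels': int(X.shape[0]),",
    "        'n_samples': n, 'sfreq': float(sf), 'labels': labels,",
    "        'ch_names': list(raw.ch_names), 'skipped': skipped}",
    "if trials:",
    "    np.stack(trials).astype('float64').tofile(out_bin)",
    "json.dump(meta, open(out_json, 'w'))",
    sep = "\n")
  em <- as.list(stats::setNames(as.integer(event_map), names(event_map)))
  status <- system2(python, c("-c", shQuote(script), shQuote(path),
                              shQuote(out_bin), shQuote(out_json),
                              offset_seconds, window_seconds,
                              shQuote(jsonlite::toJSON(em,
                                                       auto_unbox = TRUE))),
                    stdout = TRUE, stderr = TRUE)
  if (!file.exists(out_json)) {
    stop("GDF backend failed: ", paste(status, collapse = "\n"))
  }
  meta <- jsonlite::read_json(out_json, simplifyVector = TRUE)
  if (meta$n_trials == 0) {
    stop("empty dataset: no mapped cue events found in ", path)
  }
  if (length(meta$skipped) > 0) {
    warning("skipped unmapped event codes: ",
            paste(names(meta$skipped), collapse = ", "))
  }
  v <- readBin(out_bin, what = "double",
               n = meta$n_trials * meta$n_channels * meta$n_samples)
  # numpy writes row-major (trial, channel, sample); R fills column-major
  arr <- aperm(array(v, c(meta$n_samples, meta$n_channels, meta$n_trials)),
               c(3, 2, 1))
  epoched_eeg(arr * 1e6, meta$labels, meta$sfreq, meta$ch_names,
              subject_id = sub("\\.[^.]*$", "", basename(path)))
}
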