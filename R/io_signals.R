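#' Read an EEG recording from disk
#'
#' Reads a multichannel EEG recording from a European Data Format (EDF) file
#' or a plain CSV file (one header row of channel labels, one column per
#' channel, values in microvolts). Channel labels are normalized to canonical
#' 10-20 names (case-insensitive; reference suffixes such as `-A1` and an
#' `EEG` prefix are stripped) and reordered into canonical montage order;
#' channels outside the montage are dropped with a warning.
#'
#' For CSV input the sampling rate is taken from the `fs` argument, or, if
#' that is `NULL`, from a YAML sidecar file `<path>.meta` with an `fs:` key.
#'
#' @param path file to read.
#' @param format `"edf"`, `"csv"` or `"auto"` (by file extension).
#' @param fs sampling rate in Hz, required for CSV input without a sidecar.
#' @return A [Recording-class].
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(Fp1 = rnorm(256), Fp2 = rnorm(256)), f,
#'           row.names = FALSE)
#' rec <- readRecording(f, fs = 256)
#' channelLabels(rec)
#' @export
readRecording <- function(path, format = c("auto", "edf", "csv"), fs = NULL) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("file not found: ", path)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- if (ext == "edf") "edf" else "csv"
    }
    if (format == "edf") {
        edf <- .readEDF(path)
        mat <- .canonicalizeSignal(edf$data, edf$labels)
        return(Recording(mat, edf$fs))
    }
    if (is.null(fs)) {
        sidecar <- paste0(path, ".meta")
        if (file.exists(sidecar)) {
            meta <- yaml::read_yaml(sidecar)
            fs <- meta$fs
        }
    }
    if (is.null(fs)) stop("sampling rate 'fs' is required for CSV input")
    tab <- utils::read.csv(path, check.names = FALSE)
    mat <- .canonicalizeSignal(as.matrix(tab), colnames(tab))
    Recording(mat, fs)
}

#' Write an EEG recording to disk
#'
#' Writes a [Recording-class] as EDF (16-bit, physical scaling chosen per
#' channel) or as a CSV with one column per channel plus a YAML sidecar
#' `<path>.meta` carrying the sampling rate.
#'
#' @param rec a [Recording-class].
#' @param path output file.
#' @param format `"edf"`, `"csv"` or `"auto"` (by file extension).
#' @return `path`, invisibly.
#' @export
writeRecording <- function(rec, path, format = c("auto", "edf", "csv")) {
    format <- match.arg(format)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- if (ext == "edf") "edf" else "csv"
    }
    if (format == "edf") return(invisible(.writeEDF(rec, path)))
    utils::write.csv(as.data.frame(signalMatrix(rec)), path,
                     row.names = FALSE)
    yaml::write_yaml(list(fs = samplingRate(rec)), paste0(path, ".meta"))
    invisible(path)
}

#' Select the central window of a recording
#'
#' Keeps the samples in the half-open window `[start_s * fs, end_s * fs)`
#' (0-based sample indices), the central 180 seconds by default, discarding
#' the start and end of the recording where settling and electrode-handling
#' artifacts concentrate.
#'
#' @param rec a [Recording-class].
#' @param start_s window start in seconds (default 60).
#' @param end_s window end in seconds (default 240).
#' @return A [Recording-class] of duration `end_s - start_s`.
#' @export
trimCentral <- function(rec, start_s = 60, end_s = 240) {
    stopifnot(is(rec, "Recording"), end_s > start_s, start_s >= 0)
    fs <- samplingRate(rec)
    if (recordingDuration(rec) < end_s)
        stop(sprintf("recording too short: %.1f s < end_s = %g s",
                     recordingDuration(rec), end_s))
    idx <- (floor(start_s * fs) + 1L):floor(end_s * fs)
    Recording(signalMatrix(rec)[idx, , drop = FALSE], fs)
}

#' Resample a recording to a target rate
#'
#' Fourier-method resampling: the spectrum of each channel is truncated (an
#' ideal anti-alias low-pass at the target Nyquist) or zero-padded, and the
#' inverse transform evaluated on the new sample grid. The sample count is
#' scaled by `target_fs / fs`. With `target_fs == fs` the recording is
#' returned unchanged.
#'
#' @param rec a [Recording-class].
#' @param target_fs target sampling rate in Hz (default 256).
#' @return A [Recording-class] at `target_fs`.
#' @export
resampleTo <- function(rec, target_fs = 256) {
    stopifnot(is(rec, "Recording"))
    if (!is.numeric(target_fs) || target_fs <= 0)
        stop("target_fs must be positive")
    fs <- samplingRate(rec)
    if (fs == target_fs) return(rec)
    n <- nSamples(rec)
    n_out <- round(n * target_fs / fs)
    if (abs(n_out - n * target_fs / fs) > 1e-9)
        n_out <- floor(n * target_fs / fs)
    mat <- apply(signalMatrix(rec), 2, .fftResample, n_out = n_out)
    colnames(mat) <- channelLabels(rec)
    Recording(mat, target_fs)
}

# Fourier-method resampling of one channel to n_out samples (truncate or
# zero-pad the spectrum, keeping it conjugate-symmetric).
.fftResample <- function(x, n_out) {
    n <- length(x)
    m <- n_out
    X <- stats::fft(x)
    Y <- complex(m)
    N <- min(n, m)
    pos <- N %/% 2 + 1L                 # DC .. +floor(N/2)
    neg <- N - pos                      # strictly negative frequencies kept
    Y[seq_len(pos)] <- X[seq_len(pos)]
    if (neg > 0)
        Y[(m - neg + 1L):m] <- X[(n - neg + 1L):n]
    if (N %% 2 == 0) {
        if (m < n) {
            # fold the dropped negative counterpart into the new Nyquist bin
            Y[pos] <- X[pos] + X[n - N %/% 2 + 1L]
        } else if (m > n) {
            # split the old Nyquist bin across +/- frequencies
            Y[pos] <- X[pos] / 2
            Y[m - N %/% 2 + 1L] <- X[pos] / 2
        }
    }
    Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Standard preprocessing of a raw recording
#'
#' The two preprocessing steps applied to every raw recording before feature
#' extraction: select the central window (default 60-240 s) with
#' [trimCentral()], then normalize the sampling rate with [resampleTo()]
#' (default 256 Hz).
#'
#' @inheritParams trimCentral
#' @param target_fs target sampling rate in Hz.
#' @return A preprocessed [Recording-class].
#' @export
preprocessRecording <- function(rec, start_s = 60, end_s = 240,
                                target_fs = 256) {
    resampleTo(trimCentral(rec, start_s, end_s), target_fs)
}
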