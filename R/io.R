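#' Read an epoch container
#'
#' Reads the native epoch container: a directory holding \code{epochs.json}
#' (subject, channel labels, sampling rate, trial list) plus one raw
#' little-endian float64 binary per trial, row-major channels x samples.
#' The format is lossless and ragged-trial friendly;
#' \code{readEpochs(writeEpochs(e))} reproduces \code{e} bit-exactly.
#'
#' @param path directory created by [writeEpochs()] (or the path of its
#'   \code{epochs.json}).
#' @return an [EpochSet-class]; trial order is preserved.
#' @seealso [writeEpochs()]
#' @export
readEpochs <- function(path) {
  meta_path <- if (dir.exists(path)) file.path(path, "epochs.json") else path
  if (!file.exists(meta_path))
    stop("epoch container format error: metadata file not found at ",
         meta_path)
  meta <- jsonlite::fromJSON(meta_path, simplifyVector = TRUE)
  need <- c("subject_id", "channel_labels", "sampling_rate", "trials")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("epoch container format error: missing metadata field(s) ",
         paste(miss, collapse = ", "))
  M <- length(meta$channel_labels)
  base <- dirname(meta_path)
  trials <- vector("list", nrow(meta$trials))
  for (n in seq_len(nrow(meta$trials))) {
    f <- file.path(base, meta$trials$file[n])
    Tn <- meta$trials$n_samples[n]
    if (!file.exists(f))
      stop(sprintf("epoch container format error: trial %d file missing (%s)",
                   n, f))
    nval <- file.size(f) / 8
    if (nval != M * Tn)
      stop(sprintf(paste0("epoch container format error: trial %d has %d ",
                          "values but metadata declares %d channels x %d ",
                          "samples"), n, nval, M, Tn))
    con <- file(f, "rb")
    x <- readBin(con, "double", n = M * Tn, size = 8, endian = "little")
    close(con)
    if (!all(is.finite(x)))
      stop(sprintf("epoch container format error: trial %d contains %s",
                   n, "non-finite samples"))
    trials[[n]] <- matrix(x, nrow = M, ncol = Tn, byrow = TRUE)
  }
  EpochSet(meta$subject_id, trials, meta$channel_labels, meta$sampling_rate)
}

#' Write an epoch container
#'
#' @param epochs a valid [EpochSet-class].
#' @param path directory to create (must be creatable/writable).
#' @return the container path, invisibly.
#' @export
writeEpochs <- function(epochs, path) {
  stopifnot(is(epochs, "EpochSet"))
  validObject(epochs)
  if (!dir.exists(path) && !dir.create(path, recursive = TRUE))
    stop("I/O error: cannot create directory ", path)
  files <- sprintf("trial_%03d.bin", seq_along(epochs@trials))
  for (n in seq_along(epochs@trials)) {
    con <- file(file.path(path, files[n]), "wb")
    # row-major channels x samples: write the transpose column-major
    writeBin(as.vector(t(epochs@trials[[n]])), con, size = 8,
             endian = "little")
    close(con)
  }
  meta <- list(
    subject_id = epochs@subject,
    channel_labels = epochs@channels,
    sampling_rate = epochs@rate,
    trials = data.frame(file = files,
                        n_samples = vapply(epochs@trials, ncol, 1L)))
  jsonlite::write_json(meta, file.path(path, "epochs.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a ratings table
#'
#' Reads a CSV with header exactly \code{subject,trial,MOS,VAL,ARL} and
#' validates the rating ranges: MOS on 1 (Bad) to 5 (Excellent), VAL and ARL
#' on 1 to 9 self-assessment-manikin scales.
#'
#' @param path CSV file path.
#' @return data.frame with one row per (subject, trial).
#' @export
readRatings <- function(path) {
  if (!file.exists(path)) stop("ratings file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(df), c("subject", "trial", "MOS", "VAL", "ARL")))
    stop("ratings format error: header must be subject,trial,MOS,VAL,ARL")
  validateRatings(df)
  df
}

#' Validate a ratings table
#'
#' @param df data.frame with columns subject, trial, MOS, VAL, ARL.
#' @return the validated data.frame, invisibly.
#' @export
validateRatings <- function(df) {
  chk <- function(col, lo, hi) {
    v <- df[[col]]
    bad <- which(!is.finite(v) | v < lo | v > hi)
    if (length(bad))
      stop(sprintf("ratings range error: %s = %s outside [%g, %g] at row %d",
                   col, format(v[bad[1]]), lo, hi, bad[1]))
  }
  chk("MOS", 1, 5); chk("VAL", 1, 9); chk("ARL", 1, 9)
  if (anyDuplicated(df[, c("subject", "trial")]))
    stop("ratings format error: duplicated (subject, trial) row")
  invisible(df)
}

#' Band-pass filter and decimate an EpochSet
#'
#' Applies a zero-phase (forward-backward) Butterworth band-pass, realized
#' as a cascade of a gentle high-pass at the low edge and a steeper
#' low-pass at the high edge, then integer-factor decimation with
#' anti-alias filtering. Defaults follow common EEG practice: 0.5-50 Hz
#' pass band and a 256 Hz target rate. The cascade is used because a
#' single 2n-pole band-pass with a cutoff this far below the Nyquist
#' frequency is numerically unstable in transfer-function form; zero-phase
#' filtering preserves the cross-channel phase relations that the PHD
#' features measure, and the whole operation is linear in the input
#' samples.
#'
#' @param epochs an [EpochSet-class].
#' @param low,high band edges in Hz, 0 < low < high < rate / 2.
#' @param targetRate output sampling rate; must divide the current rate
#'   (default: no decimation).
#' @param orderLow,orderHigh Butterworth orders of the high-pass section at
#'   \code{low} (default 2) and the low-pass section at \code{high}
#'   (default 8; about 28 dB rejection of 60 Hz mains with the default
#'   band, applied forward and backward).
#' @return a filtered, decimated [EpochSet-class].
#' @export
preprocessEpochs <- function(epochs, low = 0.5, high = 50,
                             targetRate = samplingRate(epochs),
                             orderLow = 2, orderHigh = 8) {
  stopifnot(is(epochs, "EpochSet"))
  rate <- epochs@rate
  if (!(low > 0 && low < high && high < rate / 2))
    stop("parameter error: band edges must satisfy 0 < low < high < rate/2")
  q <- rate / targetRate
  if (targetRate <= 0 || abs(q - round(q)) > 1e-9)
    stop("parameter error: targetRate must divide the sampling rate")
  q <- as.integer(round(q))
  hp <- signal::butter(orderLow, low / (rate / 2), type = "high")
  lp <- signal::butter(orderHigh, high / (rate / 2), type = "low")
  trials <- lapply(epochs@trials, function(tr) {
    out <- t(apply(tr, 1, function(ch)
      signal::filtfilt(lp, signal::filtfilt(hp, ch))))
    if (q > 1L)
      out <- t(apply(out, 1, function(ch) signal::decimate(ch, q)))
    out
  })
  EpochSet(epochs@subject, trials, epochs@channels, targetRate)
}

#' Write features as a long-format CSV
#'
#' One row per (trial, feature): columns trial, kind (PSD/PWD/PHD),
#' channel1, channel2 (empty for PSD), band, value.
#'
#' @param features a [FeatureSet-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeFeatures <- function(features, path) {
  stopifnot(is(features, "FeatureSet"))
  fm <- buildFeatureMatrix(features)
  im <- fm@indexMap
  N <- nrow(fm@values)
  out <- data.frame(
    trial = rep(seq_len(N), each = nrow(im)),
    kind = rep(im$kind, N),
    channel1 = rep(im$channel1, N),
    channel2 = rep(ifelse(is.na(im$channel2), "", im$channel2), N),
    band = rep(im$band, N),
    value = as.vector(t(fm@values)))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
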