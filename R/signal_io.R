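#' Construct a single-lead ECG record
#'
#' @param samples Numeric vector of amplitudes in millivolts.
#' @param fs Sampling frequency in Hz.
#' @param subject_id Subject identifier.
#' @param label Class label: `"normal"`, `"scd"` or `"unknown"`.
#' @param onset_s For `"scd"` records, the annotated time of SCD onset in
#'   seconds from record start.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, subject_id = "anon",
                       label = c("unknown", "normal", "scd"),
                       onset_s = NULL) {
  label <- match.arg(label)
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  if (!is.numeric(samples) || length(samples) == 0L)
    abort("`samples` must be a non-empty numeric vector", "scdemd_record_error")
  if (anyNA(samples) || any(!is.finite(samples)))
    abort("all samples must be finite", "scdemd_record_error")
  dur <- length(samples) / fs
  if (!is.null(onset_s)) {
    stopifnot_scalar_number(onset_s, "onset_s", positive = TRUE)
    if (onset_s > dur)
      abort("`onset_s` lies beyond the end of the record", "scdemd_record_error")
  }
  structure(list(subject_id = as.character(subject_id),
                 samples = as.numeric(samples), fs = fs,
                 label = label, onset_s = onset_s),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record %s: %d samples @ %g Hz (%.1f s), label=%s%s>\n",
              x$subject_id, length(x$samples), x$fs,
              length(x$samples) / x$fs, x$label,
              if (is.null(x$onset_s)) "" else sprintf(", onset=%gs", x$onset_s)))
  invisible(x)
}

ecg_window <- function(samples, fs, minute_index, subject_id, label) {
  structure(list(samples = as.numeric(samples), fs = fs,
                 minute_index = as.integer(minute_index),
                 subject_id = as.character(subject_id), label = label),
            class = "ecg_window")
}

#' Read an ECG record from disk
#'
#' Supports two dialects: plain CSV with a header row and columns
#' `time_s,mv`, and WFDB-style header/signal pairs (`.hea` plus `.dat`,
#' single lead, formats 16 and 212; a minimal reader, not a full WFDB
#' implementation). Class label and onset metadata come from the arguments
#' or from a cohort manifest (see [load_cohort()]).
#'
#' @param path Path to the `.csv` file or the WFDB `.hea` header.
#' @param format `"csv"` or `"wfdb"`; guessed from the extension if missing.
#' @param fs Sampling frequency override for CSV files; inferred from the
#'   time column when `NULL`.
#' @param label,onset_s Metadata forwarded to [ecg_record()].
#' @param subject_id Subject id; defaults to the file stem.
#' @return An [ecg_record()].
#' @export
load_record <- function(path, format = c("auto", "csv", "wfdb"), fs = NULL,
                        label = "unknown", onset_s = NULL, subject_id = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.hea$", path)) "wfdb" else "csv"
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), "scdemd_format_error")
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "csv") {
    df <- tryCatch(utils::read.csv(path),
                   error = function(e) abort(
                     sprintf("corrupt CSV record %s: %s", path, conditionMessage(e)),
                     "scdemd_format_error"))
    if (ncol(df) < 2L || nrow(df) == 0L)
      abort("CSV record must have columns time_s,mv", "scdemd_format_error")
    tm <- as.numeric(df[[1L]]); mv <- as.numeric(df[[2L]])
    if (is.null(fs)) {
      dt <- diff(tm)
      if (length(dt) == 0L || any(dt <= 0))
        abort("cannot infer fs: time column not strictly increasing",
              "scdemd_invalid_record")
      fs <- 1 / stats::median(dt)
    }
    ecg_record(mv, fs, subject_id, label, onset_s)
  } else {
    rec <- read_wfdb(path)
    ecg_record(rec$mv, rec$fs, subject_id, label, onset_s)
  }
}

#' Write an ECG record to disk
#'
#' CSV output is lossless (full double precision); WFDB output quantises to
#' integer ADC units via the stored gain, so round-trip error is bounded by
#' one quantisation step (`1/gain` mV).
#'
#' @param rec An [ecg_record()].
#' @param path Output path (`.csv`, or `.hea` for WFDB).
#' @param format `"csv"` or `"wfdb"`.
#' @param wfdb_format WFDB storage format: 16 (little-endian int16) or
#'   212 (packed 12-bit).
#' @param gain ADC units per millivolt for WFDB storage.
#' @return The path written, invisibly.
#' @export
save_record <- function(rec, path, format = c("csv", "wfdb"),
                        wfdb_format = 212L, gain = 200) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "ecg_record"))
  if (length(rec$samples) == 0L)
    abort("refusing to write an empty record", "scdemd_record_error")
  if (format == "csv") {
    tm <- (seq_along(rec$samples) - 1) / rec$fs
    utils::write.csv(data.frame(time_s = tm, mv = rec$samples), path,
                     row.names = FALSE, quote = FALSE)
  } else {
    write_wfdb(rec, path, wfdb_format, gain)
  }
  invisible(path)
}

# --- minimal WFDB dialect (single signal, formats 16 and 212) -------------

read_wfdb <- function(hea_path) {
  lines <- tryCatch(readLines(hea_path, warn = FALSE),
                    error = function(e) abort("unreadable WFDB header",
                                              "scdemd_format_error"))
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L)
    abort("WFDB header must have a record line and a signal line",
          "scdemd_format_error")
  rl <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  if (length(rl) < 3L) abort("corrupt WFDB record line", "scdemd_format_error")
  fs <- suppressWarnings(as.numeric(rl[3L]))
  n <- suppressWarnings(as.integer(rl[4L]))
  if (is.na(fs) || fs <= 0)
    abort("absent or non-positive sampling frequency in WFDB header",
          "scdemd_invalid_record")
  sl <- strsplit(trimws(lines[2L]), "\\s+")[[1L]]
  dat_file <- sl[1L]
  fmt <- suppressWarnings(as.integer(sub("x.*", "", sl[2L])))
  gain_tok <- if (length(sl) >= 3L) sl[3L] else "200"
  baseline <- 0L
  gm <- regmatches(gain_tok, regexec("^([0-9.eE+-]+)(\\(([0-9-]+)\\))?", gain_tok))[[1L]]
  gain <- suppressWarnings(as.numeric(gm[2L]))
  if (!is.na(gm[4L]) && nzchar(gm[4L])) baseline <- as.integer(gm[4L])
  if (is.na(gain) || gain == 0) gain <- 200
  dat_path <- file.path(dirname(hea_path), dat_file)
  if (!file.exists(dat_path))
    abort(sprintf("WFDB signal file missing: %s", dat_path), "scdemd_format_error")
  raw <- readBin(dat_path, "raw", n = file.size(dat_path))
  adc <- switch(as.character(fmt),
    "16" = readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
                   signed = TRUE, endian = "little"),
    "212" = decode_212(raw),
    abort(sprintf("unsupported WFDB format %s", fmt), "scdemd_format_error"))
  if (!is.na(n) && n > 0L) adc <- adc[seq_len(min(n, length(adc)))]
  list(mv = (adc - baseline) / gain, fs = fs)
}

decode_212 <- function(raw) {
  b <- as.integer(raw)
  nb <- (length(b) %/% 3L) * 3L
  b1 <- b[seq(1L, nb, 3L)]; b2 <- b[seq(2L, nb, 3L)]; b3 <- b[seq(3L, nb, 3L)]
  s1 <- b1 + bitwAnd(b2, 15L) * 256L          # low byte + low nibble
  s2 <- b3 + bitwAnd(b2, 240L) %/% 16L * 256L # low byte + high nibble
  s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)    # 12-bit two's complement
  s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
  as.integer(rbind(s1, s2))
}

encode_212 <- function(adc) {
  if (length(adc) %% 2L == 1L) adc <- c(adc, 0L)  # pad to sample pairs
  if (any(adc > 2047L | adc < -2048L))
    abort("sample out of 12-bit range for WFDB format 212",
          "scdemd_format_error")
  u <- ifelse(adc < 0L, adc + 4096L, adc)
  s1 <- u[seq(1L, length(u), 2L)]; s2 <- u[seq(2L, length(u), 2L)]
  b1 <- bitwAnd(s1, 255L)
  b2 <- bitwAnd(s1 %/% 256L, 15L) + bitwAnd(s2 %/% 256L, 15L) * 16L
  b3 <- bitwAnd(s2, 255L)
  as.raw(rbind(b1, b2, b3))
}

write_wfdb <- function(rec, hea_path, wfdb_format = 212L, gain = 200) {
  if (!grepl("\\.hea$", hea_path))
    abort("WFDB output path must end in .hea", "scdemd_format_error")
  stem <- sub("\\.hea$", "", basename(hea_path))
  dat_name <- paste0(stem, ".dat")
  adc <- as.integer(round(rec$samples * gain))
  n <- length(adc)
  if (wfdb_format == 212L) {
    if (any(adc > 2047L | adc < -2048L))
      abort("signal exceeds 12-bit range at this gain; lower `gain` or use format 16",
            "scdemd_format_error")
    bytes <- encode_212(adc)
  } else if (wfdb_format == 16L) {
    bytes <- writeBin(adc, raw(), size = 2L, endian = "little")
  } else {
    abort("unsupported WFDB output format", "scdemd_format_error")
  }
  hdr <- c(sprintf("%s 1 %g %d", stem, rec$fs, n),
           sprintf("%s %d %g(0) 12 0 %d 0 0 ECG", dat_name, wfdb_format,
                   gain, adc[1L]))
  writeLines(hdr, hea_path)
  writeBin(bytes, file.path(dirname(hea_path), dat_name))
  invisible(hea_path)
}

#' Load a cohort from a manifest file
#'
#' The manifest is a tab-separated file with columns `subject_id`, `path`
#' (relative to the manifest), `label` and `onset_s` (empty for normal
#' subjects).
#'
#' @param manifest_path Path to the manifest TSV.
#' @return A list of [ecg_record()] objects.
#' @export
load_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path))
    abort("manifest not found", "scdemd_format_error")
  mf <- utils::read.delim(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "path", "label", "onset_s")
  if (!all(need %in% names(mf)))
    abort("manifest must have columns subject_id, path, label, onset_s",
          "scdemd_format_error")
  lapply(seq_len(nrow(mf)), function(i) {
    onset <- mf$onset_s[i]
    if (is.na(onset)) onset <- NULL
    load_record(file.path(dirname(manifest_path), mf$path[i]),
                label = mf$label[i], onset_s = onset,
                subject_id = mf$subject_id[i])
  })
}

#' Resample a record to a new sampling frequency
#'
#' Rational-ratio polyphase resampling: the signal is upsampled by `L`,
#' low-pass filtered with a linear-phase Kaiser-window FIR (cutoff at
#' 0.9 of the narrower Nyquist, group delay compensated exactly), and
#' decimated by `M`, where `target_fs/fs = L/M` in lowest terms. Onset
#' metadata stays in seconds and is unchanged.
#'
#' @param rec An [ecg_record()].
#' @param target_fs Target sampling frequency in Hz.
#' @return A resampled [ecg_record()].
#' @export
resample_record <- function(rec, target_fs) {
  stopifnot(inherits(rec, "ecg_record"))
  stopifnot_scalar_number(target_fs, "target_fs", positive = TRUE)
  if (target_fs == rec$fs) return(rec)
  fr <- rational_ratio(target_fs / rec$fs)
  y <- upfirdn_resample(rec$samples, fr$num, fr$den)
  out <- rec
  out$samples <- y
  out$fs <- target_fs
  out
}

rational_ratio <- function(r, max_den = 4096L) {
  # continued-fraction rational approximation of the resampling ratio
  best <- c(1L, 1L); x <- r
  num0 <- 0L; den0 <- 1L; num1 <- 1L; den1 <- 0L
  for (i in 1:64) {
    a <- floor(x)
    num2 <- a * num1 + num0; den2 <- a * den1 + den0
    if (den2 > max_den) break
    best <- c(num2, den2)
    if (abs(num2 / den2 - r) < 1e-12) break
    frac <- x - a
    if (frac < 1e-15) break
    x <- 1 / frac
    num0 <- num1; den0 <- den1; num1 <- num2; den1 <- den2
  }
  list(num = as.integer(best[1L]), den = as.integer(best[2L]))
}

upfirdn_resample <- function(x, L, M, ofac = 24) {
  n <- length(x)
  up <- numeric(n * L)
  up[seq(1L, n * L, by = L)] <- x * L
  needs_filter <- (L > 1L || M > 1L)
  if (needs_filter) {
    cutoff <- 0.9 / max(L, M)
    ord <- 2L * as.integer(ceiling(ofac * max(L, M) / 2))
    h <- signal::fir1(ord, cutoff, type = "low",
                      window = signal::kaiser(ord + 1L, 7))
    filt <- signal::fftfilt(h, c(up, numeric(ord)))
    up <- filt[(ord / 2 + 1):(ord / 2 + n * L)]  # remove FIR group delay
  }
  m <- (n * L - 1L) %/% M + 1L
  up[seq(1L, by = M, length.out = m)]
}

#' Cut the pre-onset one-minute windows of an SCD record
#'
#' Window `k` covers the half-open interval `[onset - k*60, onset - (k-1)*60)`
#' seconds, so `minute_index = 1` is the minute immediately before onset and
#' the windows tile `[onset - n_minutes*60, onset)` exactly.
#'
#' @param rec An [ecg_record()] with `label == "scd"` and onset metadata.
#' @param n_minutes Number of minutes before onset to analyse (default 25).
#' @return A list of `n_minutes` windows, `minute_index` from 1 to
#'   `n_minutes`.
#' @export
segment_pre_onset <- function(rec, n_minutes = 25L) {
  stopifnot(inherits(rec, "ecg_record"))
  if (rec$label != "scd")
    abort("pre-onset segmentation requires an SCD-labelled record",
          "scdemd_record_error")
  if (is.null(rec$onset_s))
    abort("SCD record has no onset annotation", "scdemd_record_error")
  wlen <- round(60 * rec$fs)
  onset_idx <- round(rec$onset_s * rec$fs)     # 0-based sample of onset
  if (onset_idx < n_minutes * wlen)
    abort(sprintf("insufficient history: need %d min before onset", n_minutes),
          "scdemd_insufficient_history")
  lapply(seq_len(n_minutes), function(k) {
    start <- onset_idx - k * wlen               # 0-based, inclusive
    ecg_window(rec$samples[(start + 1L):(start + wlen)], rec$fs,
               minute_index = k, subject_id = rec$subject_id, label = "scd")
  })
}

#' Draw a random one-minute window from a normal record
#'
#' The window start is uniform over all feasible sample positions;
#' reproducible under `seed`. `minute_index` is 0 by convention for
#' normal-group windows.
#'
#' @param rec An [ecg_record()] with `label == "normal"`.
#' @param seed Integer seed.
#' @return An `ecg_window`.
#' @export
random_normal_window <- function(rec, seed) {
  stopifnot(inherits(rec, "ecg_record"))
  if (rec$label != "normal")
    abort("random window selection is defined for normal-group records",
          "scdemd_record_error")
  wlen <- round(60 * rec$fs)
  n <- length(rec$samples)
  if (n < wlen)
    abort("record shorter than one minute", "scdemd_record_error")
  start <- with_seed(seed, sample.int(n - wlen + 1L, 1L))  # 1-based
  ecg_window(rec$samples[start:(start + wlen - 1L)], rec$fs,
             minute_index = 0L, subject_id = rec$subject_id, label = "normal")
}
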