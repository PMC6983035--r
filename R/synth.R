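#' Configuration for the synthetic ECG generator
#'
#' The generator produces seeded single-lead ECG with PQRST morphology,
#' Gaussian RR variability and additive band-limited noise. The
#' `complexity` knob controls the broadband/narrowband balance of the
#' non-cardiac component: high complexity mixes in broadband irregularity
#' (raising fractal dimension and permutation entropy of the mid-frequency
#' modes), low complexity substitutes slowly drifting narrowband
#' oscillations (lowering them). Pre-SCD records therefore default to a
#' lower complexity than normal records, mirroring the empirical direction
#' of the group differences in HI(IMF3) and PEI(IMF5).
#'
#' @param label `"normal"` or `"scd"`.
#' @param fs Sampling frequency in Hz (default 128).
#' @param duration_s Record duration in seconds (>= 60).
#' @param hr_mean Mean heart rate in bpm (default 70 normal, 90 scd).
#' @param hr_sd Beat-to-beat heart-rate standard deviation in bpm.
#' @param noise_mv Amplitude (mV) of the additive non-cardiac component.
#' @param complexity In `[0, 1]`: weight of broadband vs narrowband
#'   irregularity (default 0.65 normal, 0.35 scd).
#' @param onset_s SCD onset time in seconds (scd only; default 60 s before
#'   the record end).
#' @param seed Integer seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(label = c("normal", "scd"), fs = 128,
                         duration_s = 120, hr_mean = NULL, hr_sd = 3,
                         noise_mv = 0.08, complexity = NULL,
                         onset_s = NULL, seed = 1L) {
  label <- match.arg(label)
  stopifnot_scalar_number(fs, "fs", positive = TRUE)
  if (duration_s < 60)
    abort("`duration_s` must be at least 60 s", "scdemd_config_error")
  if (is.null(hr_mean)) hr_mean <- if (label == "normal") 70 else 90
  if (is.null(complexity)) complexity <- if (label == "normal") 0.65 else 0.35
  if (complexity < 0 || complexity > 1)
    abort("`complexity` must lie in [0, 1]", "scdemd_config_error")
  if (hr_mean < 30 || hr_mean > 200)
    abort("`hr_mean` outside physiological range [30, 200] bpm",
          "scdemd_config_error")
  if (label == "scd" && is.null(onset_s)) onset_s <- duration_s - 60
  structure(list(label = label, fs = fs, duration_s = duration_s,
                 hr_mean = hr_mean, hr_sd = hr_sd, noise_mv = noise_mv,
                 complexity = complexity, onset_s = onset_s,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Generate beat onset times
#'
#' RR intervals are drawn from a seeded Gaussian with mean `60/hr_mean` s
#' and standard deviation `60*hr_sd/hr_mean^2` s (the first-order
#' propagation of the bpm spread), truncated to the physiological range
#' `[0.3, 2]` s.
#'
#' @param cfg A [synth_config()].
#' @return Numeric vector of beat onset times (s) covering the record.
#' @export
generate_beat_train <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  rr_mean <- 60 / cfg$hr_mean
  rr_sd <- 60 * cfg$hr_sd / cfg$hr_mean^2
  n_max <- ceiling(cfg$duration_s / 0.3) + 2L
  rr <- with_seed(cfg$seed, {
    r <- stats::rnorm(n_max, rr_mean, rr_sd)
    pmin(pmax(r, 0.3), 2)
  })
  beats <- cumsum(c(0, rr))
  beats[beats < cfg$duration_s + 2]    # one spill-over beat keeps the tail shaped
}

# PQRST template: sum of five Gaussians on the beat phase axis (fraction of
# the RR interval). Amplitudes in mV, loosely lead-II shaped.
pqrst_wave <- function(phase) {
  centers <- c(P = 0.12, Q = 0.23, R = 0.26, S = 0.29, T = 0.55)
  widths  <- c(P = 0.035, Q = 0.012, R = 0.016, S = 0.012, T = 0.06)
  amps    <- c(P = 0.12, Q = -0.12, R = 1.0, S = -0.22, T = 0.3)
  w <- numeric(length(phase))
  for (g in seq_along(centers))
    w <- w + amps[g] * exp(-(phase - centers[g])^2 / (2 * widths[g]^2))
  w
}

#' Synthesize a single-lead ECG record
#'
#' A PQRST template (five Gaussians on the beat-phase axis) is evaluated on
#' a seeded beat train; a non-cardiac component of amplitude `noise_mv` is
#' added, mixing band-limited broadband noise (weight `complexity^2`) with
#' slowly drifting narrowband oscillations near 8.5 Hz and 2.2 Hz (weight
#' `1 - complexity`), placed to dominate the third and fifth intrinsic
#' modes of a one-minute 128 Hz window. For `label = "scd"` this mixing is
#' applied from 26 minutes before `onset_s` onward (earlier samples carry
#' the normal-class default mixing), so every analysed pre-onset window
#' carries the class signature. This is a test
#' fixture emulating the measured direction of the class differences, not a
#' cardiac electrophysiology model.
#'
#' @param cfg A [synth_config()].
#' @return An [ecg_record()].
#' @export
#' @examples
#' rec <- synthesize_ecg(synth_config("normal", duration_s = 60, seed = 7))
#' rec
synthesize_ecg <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n <- round(cfg$duration_s * cfg$fs)
  t <- (seq_len(n) - 1) / cfg$fs
  beats <- generate_beat_train(cfg)
  # map every sample to its beat phase
  idx <- findInterval(t, beats)
  idx[idx < 1L] <- 1L
  rr_next <- c(diff(beats), 60 / cfg$hr_mean)
  phase <- (t - beats[idx]) / rr_next[idx]
  x <- pqrst_wave(phase)
  if (cfg$noise_mv > 0) {
    comp <- with_seed(derive_seed(cfg$seed, 1L), {
      # broadband: white noise low-passed to ~0.35*fs, unit sd
      w <- stats::rnorm(n)
      b <- signal::fir1(64L, 0.7, type = "low")
      bb <- signal::fftfilt(b, c(w, numeric(64L)))[33:(32 + n)]
      bb <- bb / stats::sd(bb)
      # narrowband oscillations with slow phase drift, tuned to land in the
      # mid (~8.5 Hz) and low (~2.2 Hz) oscillatory modes of one-minute
      # 128 Hz windows
      drift1 <- cumsum(stats::rnorm(n, 0, 0.01))
      drift2 <- cumsum(stats::rnorm(n, 0, 0.006))
      nb <- 2.0 * sin(2 * pi * 8.5 * t + drift1) +
        1.2 * sin(2 * pi * 2.2 * t + drift2)
      list(bb = bb, nb = nb)
    })
    # broadband irregularity scales quadratically with the knob so that a
    # low-complexity record's mid-frequency modes are tone-dominated
    mix <- function(cx) cx^2 * comp$bb + (1 - cx) * comp$nb
    noise <- mix(cfg$complexity)
    if (cfg$label == "scd") {
      # class signature restricted to the analysed pre-onset span; earlier
      # samples carry the normal-class default mixing
      from_s <- max(0, (if (is.null(cfg$onset_s)) cfg$duration_s else cfg$onset_s) -
                      26 * 60)
      gate <- as.numeric(t >= from_s)
      noise <- gate * noise + (1 - gate) * mix(0.65)
    }
    x <- x + cfg$noise_mv * noise
  }
  ecg_record(x, cfg$fs, subject_id = sprintf("synth-%s-%d", cfg$label, cfg$seed),
             label = cfg$label, onset_s = cfg$onset_s)
}

#' Generate a synthetic cohort on disk
#'
#' Writes `n_normal + n_scd` CSV records plus a manifest TSV consumable by
#' [load_cohort()]. Per-subject seeds are derived deterministically from
#' `seed`.
#'
#' @param n_normal,n_scd Number of records per class.
#' @param dir Output directory (created if needed).
#' @param seed Master seed.
#' @param normal_cfg,scd_cfg Template [synth_config()]s; per-subject seed is
#'   substituted.
#' @return Path to the manifest file, invisibly.
#' @export
make_cohort <- function(n_normal, n_scd, dir, seed = 1L,
                        normal_cfg = synth_config("normal", duration_s = 120),
                        scd_cfg = synth_config("scd", duration_s = 27 * 60)) {
  if (n_normal < 1L || n_scd < 1L)
    abort("need at least one record per class", "scdemd_config_error")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  write_one <- function(cfg, i, tag) {
    cfg$seed <- derive_seed(seed, i)
    rec <- synthesize_ecg(cfg)
    rec$subject_id <- sprintf("%s%02d", tag, i)
    fn <- paste0(rec$subject_id, ".csv")
    save_record(rec, file.path(dir, fn), "csv")
    data.frame(subject_id = rec$subject_id, path = fn, label = cfg$label,
               onset_s = if (is.null(cfg$onset_s)) NA_real_ else cfg$onset_s)
  }
  for (i in seq_len(n_normal)) rows[[length(rows) + 1L]] <-
    write_one(normal_cfg, i, "N")
  for (i in seq_len(n_scd)) rows[[length(rows) + 1L]] <-
    write_one(scd_cfg, n_normal + i, "S")
  mf <- do.call(rbind, rows)
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(mf, manifest, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Generate a synthetic cohort in memory
#'
#' Like [make_cohort()] but returns the records directly without touching
#' disk; used by the end-to-end tests and the evaluation script.
#'
#' @inheritParams make_cohort
#' @return List of [ecg_record()]s.
#' @export
simulate_cohort <- function(n_normal, n_scd, seed = 1L,
                            normal_cfg = synth_config("normal", duration_s = 120),
                            scd_cfg = synth_config("scd", duration_s = 27 * 60)) {
  recs <- vector("list", n_normal + n_scd)
  for (i in seq_len(n_normal)) {
    cfg <- normal_cfg; cfg$seed <- derive_seed(seed, i)
    recs[[i]] <- synthesize_ecg(cfg)
    recs[[i]]$subject_id <- sprintf("N%02d", i)
  }
  for (i in seq_len(n_scd)) {
    cfg <- scd_cfg; cfg$seed <- derive_seed(seed, n_normal + i)
    recs[[n_normal + i]] <- synthesize_ecg(cfg)
    recs[[n_normal + i]]$subject_id <- sprintf("S%02d", n_normal + i)
  }
  recs
}
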