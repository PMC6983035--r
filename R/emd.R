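#' EMD configuration
#'
#' Parameters controlling the sifting process used by [emd_decompose()].
#'
#' @param max_imfs Maximum number of intrinsic mode functions to extract.
#'   The pipeline analyses the first six modes of each one-minute window;
#'   later modes are dominated by interpolation error and are discarded.
#' @param sd_threshold Sifting stop criterion: iteration ends when the
#'   normalised squared difference between successive sift candidates,
#'   `sum((h_prev - h)^2) / sum(h_prev^2)`, falls below this value (Huang's
#'   standard SD criterion; default 0.2) and the candidate satisfies the
#'   extrema/zero-crossing condition.
#' @param max_sift_iters Hard cap on sifting iterations per mode.
#' @param boundary Envelope boundary handling: `"mirror"` reflects the two
#'   extrema nearest each end before spline fitting (default), `"clamp"`
#'   treats the end samples as extrema.
#'
#' @return An object of class `emd_config`.
#' @export
#' @examples
#' cfg <- emd_config(max_imfs = 6)
emd_config <- function(max_imfs = 6L, sd_threshold = 0.2,
                       max_sift_iters = 100L,
                       boundary = c("mirror", "clamp")) {
  boundary <- match.arg(boundary)
  if (max_imfs < 1L) abort("`max_imfs` must be >= 1", "scdemd_config_error")
  stopifnot_scalar_number(sd_threshold, "sd_threshold", positive = TRUE)
  structure(
    list(max_imfs = as.integer(max_imfs), sd_threshold = sd_threshold,
         max_sift_iters = as.integer(max_sift_iters), boundary = boundary),
    class = "emd_config")
}

#' Locate strict local extrema of a sampled signal
#'
#' Plateaus (runs of equal values flanked by lower/higher samples) are
#' collapsed to a single extremum at the plateau midpoint (left-of-centre
#' sample for even-length plateaus). Endpoints are never extrema.
#'
#' @param x Numeric vector, length >= 3.
#' @return A list with integer vectors `maxima` and `minima` (ascending).
#' @export
#' @examples
#' find_extrema(c(0, 1, 0))$maxima  # 2
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) abort("signal too short for extrema detection (need >= 3 samples)",
                    "scdemd_signal_error")
  s <- sign(diff(x))
  r <- rle(s)
  vals <- r$values
  ends <- cumsum(r$lengths)            # run ends, indices into diff (1..n-1)
  starts <- ends - r$lengths + 1L
  nz <- which(vals != 0)               # runs of actual rise/fall
  if (length(nz) < 2L) return(list(maxima = integer(0), minima = integer(0)))
  ia <- nz[-length(nz)]
  ib <- nz[-1L]
  keep <- vals[ia] != vals[ib]         # sign change, possibly across a plateau
  ia <- ia[keep]; ib <- ib[keep]
  if (length(ia) == 0L) return(list(maxima = integer(0), minima = integer(0)))
  ps <- ends[ia] + 1L                  # first sample of the extremum plateau
  pe <- starts[ib]                     # last sample of the plateau
  idx <- ps + (pe - ps) %/% 2L         # midpoint, left-of-centre on ties
  is_max <- vals[ia] > 0
  list(maxima = idx[is_max], minima = idx[!is_max])
}

# Count zero crossings: strict sign changes; exact zeros counted once.
count_zero_crossings <- function(x) {
  s <- sign(x)
  nz <- s[s != 0]
  if (length(nz) < 2L) return(0L)
  sum(diff(nz) != 0)
}

# Both IMF conditions reduced to the countable one: the number of extrema
# and zero crossings differ by at most one.
is_imf_candidate <- function(x) {
  ex <- find_extrema(x)
  n_ext <- length(ex$maxima) + length(ex$minima)
  abs(n_ext - count_zero_crossings(x)) <= 1L
}

# Mirror-extend extrema about the signal ends so the spline envelopes do
# not collapse toward the boundary samples.
extend_extrema <- function(idx, val, n, k = 2L) {
  if (length(idx) == 0L) return(list(x = idx, y = val))
  m <- min(k, length(idx))
  left_x <- 2 - rev(idx[seq_len(m)])       # reflect about sample 1
  left_y <- rev(val[seq_len(m)])
  tail_i <- seq(length(idx) - m + 1L, length(idx))
  right_x <- 2L * n - rev(idx[tail_i])     # reflect about sample n
  right_y <- rev(val[tail_i])
  list(x = c(left_x, idx, right_x), y = c(left_y, val, right_y))
}

#' Mean of the cubic-spline upper and lower envelopes
#'
#' Natural cubic splines are fitted through the (boundary-extended) maxima
#' and minima and averaged, giving the local mean signal removed at each
#' sifting step.
#'
#' @param x Numeric signal.
#' @param maxima,minima Integer index vectors as returned by [find_extrema()].
#' @param boundary `"mirror"` (reflect two extrema about each end) or
#'   `"clamp"` (append the end samples as extrema).
#' @return Numeric vector `(upper + lower) / 2`, same length as `x`.
#' @export
envelope_mean <- function(x, maxima, minima, boundary = "mirror") {
  n <- length(x)
  if (length(maxima) < 2L || length(minima) < 2L)
    abort("insufficient extrema for envelope construction",
          "scdemd_monotonic_signal")
  if (boundary == "mirror") {
    up <- extend_extrema(maxima, x[maxima], n)
    lo <- extend_extrema(minima, x[minima], n)
  } else {
    up <- list(x = c(1L, maxima, n), y = c(x[1L], x[maxima], x[n]))
    lo <- list(x = c(1L, minima, n), y = c(x[1L], x[minima], x[n]))
  }
  upper <- stats::spline(up$x, up$y, xout = seq_len(n), method = "natural")$y
  lower <- stats::spline(lo$x, lo$y, xout = seq_len(n), method = "natural")$y
  (upper + lower) / 2
}

#' Extract one intrinsic mode function by sifting
#'
#' Repeatedly subtracts the envelope mean until the candidate satisfies the
#' IMF conditions and Huang's SD stopping criterion (see [emd_config()]).
#'
#' @param x Numeric signal (non-monotonic).
#' @param config An [emd_config()].
#' @return A list with `imf` (numeric vector) and `iterations` (integer).
#' @export
sift_imf <- function(x, config = emd_config()) {
  h <- x
  for (it in seq_len(config$max_sift_iters)) {
    ex <- find_extrema(h)
    if (length(ex$maxima) < 2L || length(ex$minima) < 2L) {
      if (it == 1L)
        abort("signal is monotonic: no IMF can be extracted",
              "scdemd_monotonic_signal")
      return(list(imf = h, iterations = it - 1L))
    }
    m <- envelope_mean(h, ex$maxima, ex$minima, config$boundary)
    h_new <- h - m
    sd_crit <- sum((h - h_new)^2) / max(sum(h^2), .Machine$double.eps)
    h <- h_new
    if (sd_crit < config$sd_threshold && is_imf_candidate(h))
      return(list(imf = h, iterations = it))
  }
  list(imf = h, iterations = config$max_sift_iters)
}

is_monotonic <- function(x) {
  ex <- find_extrema(x)
  length(ex$maxima) < 2L || length(ex$minima) < 2L
}

#' Empirical mode decomposition
#'
#' Decomposes a signal (or an `ecg_window`) into intrinsic mode functions and
#' a final residue by the sifting process. The decomposition is complete:
#' the modes and residue sum back to the input to numerical precision.
#'
#' @param x Numeric vector or an `ecg_window`.
#' @param config An [emd_config()].
#' @return An object of class `imf_set`: list with `imfs` (list of numeric
#'   vectors), `residue`, `n_sift_iterations`, `source_length`.
#' @export
#' @examples
#' t <- seq(0, 2, by = 1/128)
#' x <- sin(2 * pi * 8 * t) + sin(2 * pi * 0.5 * t)
#' d <- emd_decompose(x, emd_config(max_imfs = 4))
#' length(d$imfs)
emd_decompose <- function(x, config = emd_config()) {
  if (inherits(x, "ecg_window")) x <- x$samples
  if (!is.numeric(x)) abort("input must be numeric", "scdemd_signal_error")
  if (length(x) < 3L) abort("signal too short to decompose", "scdemd_signal_error")
  imfs <- list()
  iters <- integer(0)
  resid <- x
  for (k in seq_len(config$max_imfs)) {
    if (is_monotonic(resid)) break
    s <- sift_imf(resid, config)
    imfs[[k]] <- s$imf
    iters[k] <- s$iterations
    resid <- resid - s$imf
  }
  structure(list(imfs = imfs, residue = resid, n_sift_iterations = iters,
                 source_length = length(x)),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set: %d IMFs + residue, %d samples>\n",
              length(x$imfs), x$source_length))
  invisible(x)
}

#' Reconstruct the input signal from an `imf_set`
#'
#' @param object An `imf_set`.
#' @return Numeric vector: elementwise sum of all IMFs plus the residue.
#' @export
reconstruct <- function(object) {
  stopifnot(inherits(object, "imf_set"))
  Reduce(`+`, object$imfs, object$residue)
}

#' @export
plot.imf_set <- function(x, ...) {
  k <- length(x$imfs) + 1L
  old <- graphics::par(mfrow = c(k, 1), mar = c(1.5, 4, 0.5, 0.5))
  on.exit(graphics::par(old))
  for (i in seq_along(x$imfs))
    graphics::plot(x$imfs[[i]], type = "l", ylab = paste0("IMF", i), xlab = "")
  graphics::plot(x$residue, type = "l", ylab = "residue", xlab = "")
  invisible(x)
}
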