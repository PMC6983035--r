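#' Parameters for the nonlinear diagnostic indices
#'
#' @param sei_bits ADC bit depth `b` for the Shannon entropy index; the
#'   window range is quantised into `2^b` uniform levels and the entropy is
#'   bounded by `b` bits (default 12, a 12-bit ADC).
#' @param pei_m Ordinal pattern order `m` for permutation entropy
#'   (default 3).
#' @param pei_tau Time lag `tau` between samples of an ordinal pattern
#'   (default 1).
#' @param hi_qmax Maximum scale (skip) for the Higuchi fractal dimension
#'   (default 64, about K/120 for 7680-sample one-minute windows at 128 Hz).
#' @param bdi_dt Sampling-time interval `dt` in seconds for the box
#'   dimension (default `1/128`; must be positive and different from 1).
#'
#' @return An object of class `index_params`.
#' @export
index_params <- function(sei_bits = 12L, pei_m = 3L, pei_tau = 1L,
                         hi_qmax = 64L, bdi_dt = 1 / 128) {
  if (sei_bits < 1L || sei_bits > 24L)
    abort("`sei_bits` must be in [1, 24]", "scdemd_config_error")
  if (pei_m < 2L) abort("`pei_m` must be >= 2", "scdemd_config_error")
  if (pei_tau < 1L) abort("`pei_tau` must be >= 1", "scdemd_config_error")
  if (hi_qmax < 2L) abort("`hi_qmax` must be >= 2", "scdemd_config_error")
  stopifnot_scalar_number(bdi_dt, "bdi_dt", positive = TRUE)
  if (bdi_dt == 1) abort("`bdi_dt` must differ from 1 (log(dt) = 0)",
                         "scdemd_config_error")
  structure(list(sei_bits = as.integer(sei_bits), pei_m = as.integer(pei_m),
                 pei_tau = as.integer(pei_tau), hi_qmax = as.integer(hi_qmax),
                 bdi_dt = bdi_dt),
            class = "index_params")
}

#' Shannon entropy index (SEI)
#'
#' The signal is quantised onto `2^sei_bits` uniform levels spanning its own
#' min-max range and the Shannon entropy (bits) of the level relative
#' frequencies is returned. A constant signal occupies one level and scores
#' 0; a signal spreading uniformly over all levels scores `sei_bits`.
#'
#' @param x Numeric vector (an IMF), length >= 2.
#' @param params An [index_params()].
#' @return Entropy in bits, in `[0, sei_bits]`.
#' @export
#' @examples
#' shannon_entropy(c(0, 0, 1, 1), index_params(sei_bits = 1))  # 1 bit
shannon_entropy <- function(x, params = index_params()) {
  if (length(x) < 2L) abort("need >= 2 samples", "scdemd_signal_error")
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  nlev <- 2^params$sei_bits
  # bin edges over the observed range; top edge closed
  lev <- floor((x - rng[1]) / (rng[2] - rng[1]) * nlev)
  lev[lev == nlev] <- nlev - 1
  p <- tabulate(as.integer(lev) + 1L, nbins = nlev)
  p <- p[p > 0] / length(x)
  -sum(p * log2(p))
}

#' Permutation entropy index (PEI)
#'
#' Normalised Shannon entropy of the ordinal (rank-order) patterns of
#' length `m` at lag `tau`: 0 for a fully regular series (one pattern),
#' 1 when all `m!` patterns are equally frequent. Ties within a pattern are
#' broken by earlier-index-first ordering.
#'
#' @param x Numeric vector, length >= `(m-1)*tau + 2`.
#' @param params An [index_params()].
#' @return Normalised entropy in `[0, 1]`.
#' @export
#' @examples
#' permutation_entropy(c(4, 7, 9, 10, 6, 11, 3),
#'                     index_params(pei_m = 2))  # ~0.918
permutation_entropy <- function(x, params = index_params()) {
  m <- params$pei_m; tau <- params$pei_tau
  K <- length(x)
  n_pat <- K - (m - 1L) * tau
  if (n_pat < 2L)
    abort("signal too short for the requested pattern order/lag",
          "scdemd_signal_error")
  # embed: row i = (x[i], x[i+tau], ..., x[i+(m-1)tau])
  emb <- vapply(0:(m - 1L), function(j) x[seq_len(n_pat) + j * tau],
                numeric(n_pat))
  if (is.null(dim(emb))) emb <- matrix(emb, nrow = 1L)
  # within-pattern rank of each position, ties broken earlier-index-first;
  # the rank vector identifies the ordinal pattern uniquely
  id <- numeric(n_pat)
  for (j in seq_len(m)) {
    r_j <- rep(0L, n_pat)
    for (k in seq_len(m)) {
      if (k == j) next
      if (k < j) r_j <- r_j + (emb[, k] <= emb[, j])
      else       r_j <- r_j + (emb[, k] <  emb[, j])
    }
    id <- id * m + r_j                 # base-m positional encoding of ranks
  }
  f <- table(id)
  p <- as.numeric(f) / n_pat
  h <- -sum(p * log(p))
  h / log(factorial(m))
}

#' Katz fractal dimension (KI)
#'
#' `log10(L/a) / log10(d/a)` where `L` is the summed absolute successive
#' difference (curve length), `a = L/(K-1)` the mean step, and `d` the
#' maximum absolute excursion from the first sample.
#'
#' @param x Numeric vector, length >= 3, non-constant.
#' @return Katz dimension (unitless); 1 for a monotone ramp.
#' @export
#' @examples
#' katz_fd(c(0, 2, 1, 3, 2))  # 2
katz_fd <- function(x) {
  K <- length(x)
  if (K < 3L) abort("need >= 3 samples", "scdemd_signal_error")
  L <- sum(abs(diff(x)))
  if (L == 0) abort("constant signal: Katz dimension undefined",
                    "scdemd_undefined_index")
  a <- L / (K - 1)
  d <- max(abs(x - x[1L]))
  if (d == a) abort("degenerate signal (d == a): Katz dimension undefined",
                    "scdemd_undefined_index")
  log10(L / a) / log10(d / a)
}

#' Higuchi fractal dimension (HI)
#'
#' For each scale `p = 1..hi_qmax` the signal is decimated into `p` offset
#' subsequences; their normalised curve lengths are pooled into the mean
#' curve length `L(p)` which scales as `p^-D`. `D` is the negated slope of
#' the ordinary least-squares line of `ln L(p)` on `ln p`. Values lie near 1
#' for smooth curves and near 2 for noise-like traces.
#'
#' @param x Numeric vector, length >= `2 * hi_qmax`.
#' @param params An [index_params()].
#' @return Higuchi dimension (unitless).
#' @export
higuchi_fd <- function(x, params = index_params()) {
  K <- length(x)
  qmax <- params$hi_qmax
  if (K < 2L * qmax)
    abort("signal too short for the requested hi_qmax", "scdemd_config_error")
  Lp <- numeric(qmax)
  for (p in seq_len(qmax)) {
    ad <- abs(x[(1L + p):K] - x[1L:(K - p)])  # lag-p absolute differences
    tot <- 0
    for (q in seq_len(p)) {
      nseg <- (K - q) %/% p
      # curve length of subsequence starting at q, normalised by
      # (K-1) / (nseg * p); the extra 1/p below converts the pooled sum
      # to the standard mean curve length with scaling exponent -D
      idx <- seq.int(q, by = p, length.out = nseg)
      tot <- tot + sum(ad[idx]) * (K - 1) / (nseg * p)
    }
    Lp[p] <- tot / p^2
  }
  ok <- Lp > 0
  if (sum(ok) < 2L)
    abort("degenerate signal: Higuchi dimension undefined",
          "scdemd_undefined_index")
  lx <- log(seq_len(qmax)[ok]); ly <- log(Lp[ok])
  -(sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2))
}

#' Box dimension index (BDI)
#'
#' `-ln(sum(|diff(x)|) / dt) / ln(dt)` with `dt` the sampling interval in
#' seconds; a one-evaluation box-counting style complexity measure.
#'
#' @param x Numeric vector, length >= 2, non-constant.
#' @param params An [index_params()].
#' @return Box dimension (unitless).
#' @export
#' @examples
#' box_dimension(c(0, 0.5, 0), index_params(bdi_dt = 0.5))  # 1
box_dimension <- function(x, params = index_params()) {
  dt <- params$bdi_dt
  if (dt == 1) abort("`bdi_dt` must differ from 1", "scdemd_config_error")
  if (length(x) < 2L) abort("need >= 2 samples", "scdemd_signal_error")
  L <- sum(abs(diff(x)))
  if (L == 0) abort("constant signal: box dimension undefined",
                    "scdemd_undefined_index")
  -log(L / dt) / log(dt)
}
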