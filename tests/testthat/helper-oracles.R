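# Independent, deliberately naive re-implementations of the diagnostic
# indices and small signal generators. These share no code with the package
# (direct loops, different pattern encodings, lm() for slopes) and serve as
# oracles.

naive_katz <- function(x) {
  K <- length(x)
  L <- 0
  for (k in 2:K) L <- L + abs(x[k] - x[k - 1])
  a <- L / (K - 1)
  d <- 0
  for (k in 1:K) d <- max(d, abs(x[k] - x[1]))
  log10(L / a) / log10(d / a)
}

naive_higuchi <- function(x, qmax) {
  K <- length(x)
  Lp <- numeric(qmax)
  for (p in 1:qmax) {
    tot <- 0
    for (q in 1:p) {
      nseg <- floor((K - q) / p)
      sub <- x[q + (0:nseg) * p]          # the decimated subsequence
      s <- sum(abs(diff(sub)))
      tot <- tot + s * (K - 1) / (nseg * p)
    }
    Lp[p] <- tot / p^2
  }
  fit <- stats::lm(log(Lp) ~ log(1:qmax))
  -unname(stats::coef(fit)[2])
}

naive_pei <- function(x, m, tau) {
  n_pat <- length(x) - (m - 1) * tau
  pats <- character(n_pat)
  for (i in 1:n_pat) {
    v <- x[i + (0:(m - 1)) * tau]
    pats[i] <- paste(order(v), collapse = "-")
  }
  p <- as.numeric(table(pats)) / n_pat
  -sum(p * log(p)) / log(factorial(m))
}

naive_sei <- function(x, bits) {
  rng <- range(x)
  if (diff(rng) == 0) return(0)
  nlev <- 2^bits
  edges <- seq(rng[1], rng[2], length.out = nlev + 1)
  lev <- cut(x, breaks = edges, include.lowest = TRUE, labels = FALSE)
  p <- as.numeric(table(lev)) / length(x)
  -sum(p * log2(p))
}

naive_bdi <- function(x, dt) -log(sum(abs(diff(x))) / dt) / log(dt)

naive_anova_F <- function(a, b) {
  gm <- mean(c(a, b))
  ssb <- length(a) * (mean(a) - gm)^2 + length(b) * (mean(b) - gm)^2
  ssw <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
  (ssb / 1) / (ssw / (length(a) + length(b) - 2))
}

# zero-crossing / extrema condition check independent of the package's
# internal helper
check_imf_condition <- function(x) {
  ex <- find_extrema(x)
  n_ext <- length(ex$maxima) + length(ex$minima)
  s <- sign(x); s <- s[s != 0]
  zc <- sum(diff(s) != 0)
  abs(n_ext - zc) <= 1
}

# sine sampled so that every peak falls exactly on a sample (fs multiple of
# 4*freq): its spline envelopes are exactly flat
peak_aligned_sine <- function(freq = 8, fs = 128, dur = 4) {
  sin(2 * pi * freq * (0:(dur * fs - 1)) / fs)
}

rel_l2 <- function(a, b) sqrt(sum((a - b)^2) / max(sum(b^2), 1e-300))
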