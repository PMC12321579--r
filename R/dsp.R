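# Signal-processing primitives: IIR (Butterworth) design and filtering,
# Hilbert envelope, Savitzky-Golay smoothing, Slepian tapers, Morlet wavelets,
# pink noise and polyphase-style resampling.  No external DSP dependency is
# available offline, so these are implemented here and validated in the test
# suite against independently computed (scipy.signal) oracle values.

#' Design a digital Butterworth filter
#'
#' Computes transfer-function coefficients for a digital Butterworth filter
#' via the analog prototype and bilinear transform (matching the usual
#' MATLAB/scipy `butter` convention).
#'
#' @param order Prototype filter order. For `"pass"`/`"stop"` the resulting
#'   digital filter has `2 * order` poles.
#' @param w Critical frequency (or length-2 band) as a fraction of the
#'   Nyquist frequency, in (0, 1).
#' @param type One of `"low"`, `"high"`, `"pass"`.
#' @return A list with numerator `b` and denominator `a` coefficients.
#' @examples
#' bf <- butter_design(2, c(50, 85) / 625, "pass")
#' @export
butter_design <- function(order, w, type = c("low", "high", "pass")) {
  type <- match.arg(type)
  if (any(w <= 0) || any(w >= 1)) {
    stop("critical frequencies must lie strictly inside (0, 1) x Nyquist")
  }
  n <- as.integer(order)
  stopifnot(n >= 1L)
  # analog lowpass prototype poles (unit cutoff), gain 1, no zeros
  k_idx <- seq_len(n)
  p <- exp(1i * pi * (2 * k_idx + n - 1) / (2 * n))
  k <- 1
  fs <- 2
  warped <- 2 * fs * tan(pi * w / fs)
  z <- complex(0)
  if (type == "low") {
    wo <- warped[1]
    p <- p * wo
    k <- k * wo^n
  } else if (type == "high") {
    wo <- warped[1]
    k <- k * Re(prod(-p))
    p <- wo / p
    z <- rep(0 + 0i, n)
  } else {
    if (length(w) != 2) stop("bandpass design needs two critical frequencies")
    bw <- warped[2] - warped[1]
    wo <- sqrt(warped[1] * warped[2])
    p <- p * bw / 2
    p <- c(p + sqrt(p^2 - wo^2 + 0i), p - sqrt(p^2 - wo^2 + 0i))
    z <- rep(0 + 0i, n)
    k <- k * bw^n
  }
  # bilinear transform
  fs2 <- 2 * fs
  kd <- k * Re(prod(fs2 - z) / prod(fs2 - p))
  zd <- (fs2 + z) / (fs2 - z)
  pd <- (fs2 + p) / (fs2 - p)
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))
  b <- Re(poly_from_roots(zd)) * kd
  a <- Re(poly_from_roots(pd))
  # second-order sections for numerically robust application (the plain
  # transfer-function form is ill-conditioned for narrow low-frequency bands)
  list(b = b, a = a, sos = zpk_to_sos(zd, pd, kd))
}

# Group conjugate pole pairs (closest to the unit circle first) with their
# nearest zeros into biquad sections.  Butterworth digital zeros are real
# (at +1/-1), which keeps the pairing logic simple.
zpk_to_sos <- function(z, p, k) {
  ord_p <- order(abs(1 - Mod(p)))
  p <- p[ord_p]
  used_p <- rep(FALSE, length(p))
  used_z <- rep(FALSE, length(z))
  secs <- list()
  for (i in seq_along(p)) {
    if (used_p[i]) next
    p1 <- p[i]
    used_p[i] <- TRUE
    if (abs(Im(p1)) > 1e-10) {
      j <- which(!used_p & abs(p - Conj(p1)) < 1e-8)[1]
      if (is.na(j)) stop("unpaired complex pole")
      p_pair <- c(p1, p[j])
      used_p[j] <- TRUE
    } else {
      j <- which(!used_p & abs(Im(p)) <= 1e-10)[1]
      if (!is.na(j)) {
        p_pair <- c(p1, p[j])
        used_p[j] <- TRUE
      } else {
        p_pair <- p1
      }
    }
    z_pair <- complex(0)
    for (rep_i in seq_len(length(p_pair))) {
      cand <- which(!used_z)
      if (!length(cand)) break
      j <- cand[which.min(abs(z[cand] - p_pair[rep_i]))]
      z_pair <- c(z_pair, z[j])
      used_z[j] <- TRUE
    }
    bsec <- Re(poly_from_roots(z_pair))
    asec <- Re(poly_from_roots(p_pair))
    bsec <- c(bsec, rep(0, 3 - length(bsec)))
    asec <- c(asec, rep(0, 3 - length(asec)))
    secs[[length(secs) + 1]] <- c(bsec, asec)
  }
  sos <- do.call(rbind, secs)
  sos[1, 1:3] <- sos[1, 1:3] * k
  sos
}

# monic polynomial coefficients (descending powers) from complex roots
poly_from_roots <- function(r) {
  cf <- 1 + 0i
  for (ri in r) cf <- c(cf, 0) - c(0, cf) * ri
  cf
}

#' Apply an IIR filter causally
#'
#' Direct-form filtering with zero initial conditions, i.e. strictly causal:
#' the output at sample `t` depends only on inputs up to `t`.
#'
#' @param x Numeric signal.
#' @param coef A list with `b` and `a` as returned by [butter_design()].
#' @return Filtered signal, same length as `x`.
#' @export
filter_causal <- function(x, coef) {
  if (!is.null(coef$sos)) {
    y <- x
    for (s in seq_len(nrow(coef$sos))) {
      y <- iir_once(y, coef$sos[s, 1:3], coef$sos[s, 4:6])
    }
    return(y)
  }
  iir_once(x, coef$b, coef$a)
}

iir_once <- function(x, b, a) {
  if (a[1] != 1) {
    b <- b / a[1]
    a <- a / a[1]
  }
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[nb:(nb - 1 + length(x))]
  a <- a[seq_len(max(which(a != 0)))]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

#' Zero-phase (forward-backward) filtering
#'
#' Filters forward and backward with odd-symmetric edge extension so that the
#' net result has zero phase distortion, as appropriate for offline event
#' detection where timing must be preserved.
#'
#' @param x Numeric signal.
#' @param coef Filter coefficients from [butter_design()].
#' @param padlen Edge-extension length in samples (clipped to `length(x) - 1`).
#' @return Zero-phase filtered signal.
#' @export
filtfilt_ba <- function(x, coef, padlen = 1000L) {
  n <- length(x)
  padlen <- min(as.integer(padlen), n - 1L)
  if (padlen > 0) {
    pre <- 2 * x[1] - x[(padlen + 1):2]
    post <- 2 * x[n] - x[(n - 1):(n - padlen)]
    ext <- c(pre, x, post)
  } else {
    ext <- x
  }
  y <- filter_causal(ext, coef)
  y <- rev(filter_causal(rev(y), coef))
  y[(padlen + 1):(padlen + n)]
}

#' Bandpass a signal with a zero-phase Butterworth filter
#'
#' @param x Signal.
#' @param fs Sampling rate (Hz).
#' @param low,high Band edges (Hz); `low = NULL` gives a lowpass,
#'   `high = NULL` a highpass.
#' @param order Prototype order (default 4).
#' @param padlen Edge padding passed to [filtfilt_ba()].
#' @return Filtered signal.
#' @export
bandpass <- function(x, fs, low, high, order = 4, padlen = NULL) {
  nyq <- fs / 2
  if (!is.null(high) && high >= nyq) {
    warning("band upper edge clipped below Nyquist")
    high <- 0.99 * nyq
  }
  coef <- if (is.null(low)) {
    butter_design(order, high / nyq, "low")
  } else if (is.null(high)) {
    butter_design(order, low / nyq, "high")
  } else {
    butter_design(order, c(low, high) / nyq, "pass")
  }
  if (is.null(padlen)) {
    # long enough for the slowest edge frequency to ring down
    f0 <- if (is.null(low)) high else low
    padlen <- ceiling(3 * fs / max(f0, 0.5))
  }
  filtfilt_ba(x, coef, padlen = padlen)
}

#' Analytic-signal amplitude envelope
#'
#' Computes the Hilbert-transform amplitude envelope `|x + i H(x)|` via the
#' frequency domain.
#'
#' @param x Real signal.
#' @return Envelope, same length as `x`.
#' @export
hilbert_envelope <- function(x) {
  n <- length(x)
  nf <- stats::nextn(n, c(2, 3, 5))
  X <- stats::fft(c(x, rep(0, nf - n)))
  h <- numeric(nf)
  if (nf %% 2 == 0) {
    h[1] <- 1
    h[nf / 2 + 1] <- 1
    h[2:(nf / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((nf + 1) / 2)] <- 2
  }
  z <- stats::fft(X * h, inverse = TRUE) / nf
  Mod(z[seq_len(n)])
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local polynomial smoothing with symmetric window; edge
#' samples are smoothed with the same central weights applied to a
#' replicate-padded signal.
#'
#' @param x Signal.
#' @param window Odd window length in samples.
#' @param order Polynomial order (< window).
#' @return Smoothed signal.
#' @export
savgol_smooth <- function(x, window = 11L, order = 3L) {
  window <- as.integer(window)
  if (window %% 2 == 0) stop("window must be odd")
  if (order >= window) stop("order must be < window")
  m <- (window - 1L) %/% 2L
  A <- outer(-m:m, 0:order, `^`)
  h <- A %*% solve(crossprod(A), t(A))
  w <- h[m + 1L, ]
  ext <- c(rep(x[1], m), x, rep(x[length(x)], m))
  y <- stats::filter(ext, rev(w), method = "convolution", sides = 2)
  as.numeric(y)[(m + 1L):(m + length(x))]
}

#' Gaussian-kernel smoothing
#'
#' Convolution with a normalized Gaussian kernel truncated at 4 standard
#' deviations, replicate-padded at the edges.
#'
#' @param x Signal.
#' @param sd_samples Kernel standard deviation in samples.
#' @return Smoothed signal.
#' @export
gaussian_smooth <- function(x, sd_samples) {
  if (sd_samples <= 0) return(x)
  m <- max(1L, ceiling(4 * sd_samples))
  k <- stats::dnorm(-m:m, sd = sd_samples)
  k <- k / sum(k)
  ext <- c(rep(x[1], m), x, rep(x[length(x)], m))
  if (length(k) > 128) {
    y <- fft_convolve_same(ext, k)
  } else {
    y <- as.numeric(stats::filter(ext, k, method = "convolution", sides = 2))
  }
  y[(m + 1L):(m + length(x))]
}

# centered same-length convolution via FFT (kernel length must be odd)
fft_convolve_same <- function(x, k) {
  n <- length(x)
  m <- (length(k) - 1L) %/% 2L
  nf <- stats::nextn(n + length(k) - 1L, c(2, 3, 5))
  X <- stats::fft(c(x, rep(0, nf - n)))
  K <- stats::fft(c(k, rep(0, nf - length(k))))
  y <- Re(stats::fft(X * K, inverse = TRUE)) / nf
  y[(m + 1L):(m + n)]
}

#' Seeded pink (1/f) noise
#'
#' Gaussian noise shaped to a 1/f amplitude spectrum and rescaled to a target
#' standard deviation; the LFP background of the synthetic generator.
#'
#' @param n Number of samples.
#' @param sd Target standard deviation.
#' @return Numeric vector of length `n` (uses the current RNG stream).
#' @export
pink_noise <- function(n, sd = 1) {
  nf <- stats::nextn(n, c(2, 3, 5))
  w <- stats::rnorm(nf)
  W <- stats::fft(w)
  f <- c(1, seq_len(nf - 1))
  f <- pmin(f, nf - f + 1)           # symmetric frequency index
  W <- W / sqrt(f)
  x <- Re(stats::fft(W, inverse = TRUE) / nf)[seq_len(n)]
  x <- x - mean(x)
  x * (sd / stats::sd(x))
}

#' Slepian (DPSS) tapers
#'
#' Computes the first `k` discrete prolate spheroidal sequences of length `n`
#' with time-bandwidth product `nw`, using Lanczos iteration with full
#' reorthogonalization on the standard symmetric tridiagonal formulation
#' (avoids a dense n x n eigendecomposition).
#'
#' @param n Sequence length.
#' @param nw Time-bandwidth product (default 3).
#' @param k Number of tapers (default `2 * nw - 1`).
#' @return An `n x k` matrix of unit-energy tapers, ordered by decreasing
#'   spectral concentration.
#' @export
dpss_tapers <- function(n, nw = 3, k = 2 * nw - 1) {
  W <- nw / n
  t_idx <- 0:(n - 1)
  diag_v <- ((n - 1 - 2 * t_idx) / 2)^2 * cos(2 * pi * W)
  off_v <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  matvec <- function(v) {
    r <- diag_v * v
    r[1:(n - 1)] <- r[1:(n - 1)] + off_v * v[2:n]
    r[2:n] <- r[2:n] + off_v * v[1:(n - 1)]
    r
  }
  m <- min(n, max(8L * k, 120L))
  Q <- matrix(0, n, m)
  alpha <- numeric(m)
  beta <- numeric(m)
  # deterministic start vector with both symmetric and antisymmetric content
  # (the tridiagonal operator preserves parity, so a pure-parity start vector
  # would miss half the tapers)
  set_local <- sin(pi * (t_idx + 0.5) / n) + 0.5 * sin(2 * pi * (t_idx + 0.5) / n)
  q <- set_local / sqrt(sum(set_local^2))
  Q[, 1] <- q
  for (j in seq_len(m)) {
    v <- matvec(Q[, j])
    alpha[j] <- sum(Q[, j] * v)
    v <- v - alpha[j] * Q[, j]
    if (j > 1) v <- v - beta[j - 1] * Q[, j - 1]
    v <- v - Q[, 1:j, drop = FALSE] %*% crossprod(Q[, 1:j, drop = FALSE], v)
    bn <- sqrt(sum(v^2))
    if (j < m) {
      if (bn < 1e-12) {
        m <- j
        break
      }
      beta[j] <- bn
      Q[, j + 1] <- v / bn
    }
  }
  Tm <- diag(alpha[1:m])
  if (m > 1) {
    for (j in 1:(m - 1)) {
      Tm[j, j + 1] <- beta[j]
      Tm[j + 1, j] <- beta[j]
    }
  }
  es <- eigen(Tm, symmetric = TRUE)
  tap <- Q[, 1:m, drop = FALSE] %*% es$vectors[, 1:k, drop = FALSE]
  # polish each Ritz pair by inverse iteration on the tridiagonal matrix
  for (j in seq_len(k)) {
    v <- tap[, j] / sqrt(sum(tap[, j]^2))
    lam <- es$values[j]
    for (it in 1:4) {
      sol <- tridiag_shift_solve(diag_v, off_v, lam, v)
      if (is.null(sol)) break
      v <- sol / sqrt(sum(sol^2))
      lam <- sum(v * matvec(v))
      res <- sqrt(sum((matvec(v) - lam * v)^2))
      if (res < 1e-9 * abs(lam)) break
    }
    tap[, j] <- v
  }
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    # sign conventions: symmetric tapers have positive mean, antisymmetric
    # ones start positive
    if (abs(sum(tap[, j])) > 1e-8) {
      if (sum(tap[, j]) < 0) tap[, j] <- -tap[, j]
    } else if (tap[2, j] < 0) {
      tap[, j] <- -tap[, j]
    }
  }
  tap
}

#' Morlet (Gabor) wavelet spectrogram
#'
#' Analytic complex Morlet wavelet transform computed in the frequency
#' domain.  Power is normalized so that for a pure sinusoid of amplitude `A`
#' at frequency `f0`, power at `f0` equals the signal variance `A^2 / 2`.
#'
#' @param x Signal.
#' @param fs Sampling rate (Hz).
#' @param freqs Frequencies of interest (Hz), all in `(0, fs / 2)`.
#' @param n_cycles Wavelet width in cycles (default 7).
#' @return A list with `power` (length(freqs) x length(x) matrix), `freqs`
#'   and `times_s`.
#' @export
gabor_spectrogram <- function(x, fs, freqs, n_cycles = 7) {
  if (any(freqs <= 0) || any(freqs >= fs / 2)) {
    stop("wavelet frequencies must lie in (0, Nyquist)")
  }
  n <- length(x)
  nf <- stats::nextn(n, c(2, 3, 5))
  X <- stats::fft(c(x, rep(0, nf - n)))
  om <- 2 * pi * fs * (0:(nf - 1)) / nf
  om[om > pi * fs] <- om[om > pi * fs] - 2 * pi * fs
  pw <- matrix(0, length(freqs), n)
  for (i in seq_along(freqs)) {
    f0 <- freqs[i]
    sig_t <- n_cycles / (2 * pi * f0)
    H <- 2 * exp(-0.5 * sig_t^2 * (om - 2 * pi * f0)^2)
    H[om <= 0] <- 0
    wt <- stats::fft(X * H, inverse = TRUE) / nf
    pw[i, ] <- 0.5 * Mod(wt[seq_len(n)])^2
  }
  list(power = pw, freqs = freqs, times_s = (seq_len(n) - 1) / fs)
}

#' Anti-aliased rational resampling
#'
#' Resamples a signal from `fs_in` to `fs_out` by zero-stuffing, windowed-sinc
#' lowpass filtering and decimation.
#'
#' @param x Signal.
#' @param fs_in,fs_out Input/output sampling rates (Hz).
#' @return Resampled signal of length `round(length(x) * fs_out / fs_in)`.
#' @export
resample_signal <- function(x, fs_in, fs_out) {
  if (fs_in == fs_out) return(x)
  r <- fs_out / fs_in
  frac <- function(p, q) {
    g <- gcd_int(p, q)
    c(p / g, q / g)
  }
  # rationalize with denominator limit
  best <- frac(round(fs_out * 1000), round(fs_in * 1000))
  L <- best[1]
  M <- best[2]
  if (L > 1000 || M > 1000) stop("resampling ratio too irrational")
  n <- length(x)
  up <- numeric(n * L)
  up[seq(1, n * L, by = L)] <- x * L
  cutoff <- 0.5 / max(L, M)          # relative to upsampled rate
  ntaps <- 2L * 10L * max(L, M) + 1L
  m <- (ntaps - 1L) / 2L
  t_id <- -m:m
  hs <- 2 * cutoff * sinc(2 * cutoff * t_id)
  hs <- hs * (0.54 + 0.46 * cos(pi * t_id / m))  # Hamming window
  ext <- c(rep(0, m), up, rep(0, m))
  y <- stats::filter(ext, rev(hs), method = "convolution", sides = 2)
  y <- as.numeric(y)[(m + 1):(m + length(up))]
  y[seq(1, length(y), by = M)][seq_len(round(n * r))]
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Solve (T - lam I) x = b for symmetric tridiagonal T given by (d, e) using
# the Thomas algorithm with a tiny regularizing jitter on near-zero pivots.
tridiag_shift_solve <- function(d, e, lam, b) {
  n <- length(d)
  dd <- d - lam
  cp <- numeric(n)
  bp <- numeric(n)
  piv <- dd[1]
  if (abs(piv) < 1e-12) piv <- 1e-12
  cp[1] <- e[1] / piv
  bp[1] <- b[1] / piv
  for (i in 2:n) {
    piv <- dd[i] - e[i - 1] * cp[i - 1]
    if (abs(piv) < 1e-12) piv <- sign(piv + 1e-300) * 1e-12
    if (i < n) cp[i] <- e[i] / piv
    bp[i] <- (b[i] - e[i - 1] * bp[i - 1]) / piv
  }
  x <- numeric(n)
  x[n] <- bp[n]
  for (i in (n - 1):1) x[i] <- bp[i] - cp[i] * x[i + 1]
  if (any(!is.finite(x))) return(NULL)
  x
}

gcd_int <- function(p, q) {
  while (q != 0) {
    t <- q
    q <- p %% q
    p <- t
  }
  p
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package functions never perturb the global stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stream-specific seed from a master seed
#'
#' Deterministic integer hash used to give each session/day/analysis its own
#' reproducible RNG stream while staying inside 32-bit integer range.
#'
#' @param master Master seed (integer).
#' @param index Stream index (integer >= 0).
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index) {
  m <- as.double(master) %% 2147483647
  h <- (m * 48271 + as.double(index) * 8191 + 1013904223) %% 2147483647
  h <- (h * 69621 + 12345) %% 2147483647
  as.integer(h %% 2147483646 + 1)
}
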