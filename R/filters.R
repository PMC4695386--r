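# LFP containers and filtering. An lfp_channel is a uniformly sampled voltage
# trace (uV); ripples are taken in the 100-300 Hz band, theta in 4-12 Hz and
# delta in 1-4 Hz.

#' Construct an LFP channel
#' @param samples numeric voltage samples (uV).
#' @param fs sampling rate (Hz), nominal 2000.
#' @param t0 time of the first sample (s).
#' @param band optional length-2 band annotation (Hz).
#' @export
lfp_channel <- function(samples, fs = 2000, t0 = 0, band = NULL) {
  stopifnot(is.numeric(samples), all(is.finite(samples)), fs > 0)
  structure(list(samples = as.numeric(samples), fs = fs, t0 = t0, band = band),
            class = "lfp_channel")
}

#' Sample times of an LFP channel
#' @param lfp an `lfp_channel`.
#' @export
lfp_times <- function(lfp) lfp$t0 + (seq_along(lfp$samples) - 1) / lfp$fs

#' Zero-phase band-pass filter
#'
#' Linear-phase FIR design (Blackman window, [signal::fir1()]) applied by FFT
#' convolution with the group delay removed, so the output is zero phase. The
#' number of taps scales with the low cut-off so that narrow low bands (theta,
#' delta) get an adequately sharp transition.
#'
#' @param lfp an `lfp_channel`.
#' @param band length-2 numeric `(low, high)` in Hz, within Nyquist.
#' @param taps optional odd FIR order override.
#' @return a filtered `lfp_channel` of the same length and rate.
#' @export
bandpass <- function(lfp, band, taps = NULL) {
  fs <- lfp$fs
  if (band[1] <= 0 || band[2] >= fs / 2 || band[2] <= band[1])
    stop("bandpass: band must lie strictly within (0, Nyquist)")
  if (is.null(taps)) {
    taps <- min(8191L, as.integer(2 * ceiling(2 * fs / band[1]) + 1L))
    taps <- max(taps, 31L)
  }
  if (taps %% 2L == 0L) taps <- taps + 1L
  h <- signal::fir1(taps - 1L, band / (fs / 2), type = "pass",
                    window = signal::blackman(taps))
  y <- fft_convolve_same(lfp$samples, h)
  lfp_channel(y, fs = fs, t0 = lfp$t0, band = band)
}

# Symmetric-kernel "same" convolution via FFT with reflected padding;
# zero phase because the kernel is symmetric and the delay is trimmed.
fft_convolve_same <- function(x, h) {
  n <- length(x); m <- length(h); half <- (m - 1L) %/% 2L
  pad <- min(half, n - 1L)
  xp <- c(x[(pad + 1L):2L], x, x[(n - 1L):(n - pad)])
  L <- length(xp) + m - 1L
  Lfft <- stats::nextn(L, 2)
  X <- stats::fft(c(xp, numeric(Lfft - length(xp))))
  H <- stats::fft(c(h, numeric(Lfft - m)))
  y <- Re(stats::fft(X * H, inverse = TRUE)) / Lfft
  y[(pad + half + 1L):(pad + half + n)]
}

#' Analytic-signal phase and envelope (Hilbert transform)
#'
#' @param x numeric vector (typically a band-passed LFP).
#' @return list with `phase` (radians; 0 at the oscillation peak) and
#'   `envelope` (instantaneous amplitude).
#' @export
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  hmul <- numeric(n)
  if (n %% 2L == 0L) {
    hmul[c(1L, n / 2L + 1L)] <- 1
    hmul[2:(n / 2L)] <- 2
  } else {
    hmul[1L] <- 1
    hmul[2:((n + 1L) / 2L)] <- 2
  }
  z <- stats::fft(X * hmul, inverse = TRUE) / n
  list(phase = Arg(z), envelope = Mod(z))
}

#' Band power of an LFP in sliding windows
#' @param lfp an `lfp_channel`.
#' @param band length-2 band (Hz).
#' @param win,hop window length and hop (s).
#' @return data frame with window `t0`, `t1`, `power` (mean squared amplitude
#'   of the band-passed trace).
#' @export
band_power_windows <- function(lfp, band, win = 10, hop = 5) {
  fb <- bandpass(lfp, band)
  tt <- lfp_times(lfp)
  starts <- seq(tt[1], max(tt[1], tt[length(tt)] - win), by = hop)
  p <- vapply(starts, function(s) {
    i0 <- max(1L, ceiling((s - lfp$t0) * lfp$fs) + 1L)
    i1 <- min(length(fb$samples), i0 + as.integer(win * lfp$fs) - 1L)
    mean(fb$samples[i0:i1]^2)
  }, numeric(1))
  data.frame(t0 = starts, t1 = starts + win, power = p)
}
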