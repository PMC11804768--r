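# spectral: Welch-averaged power spectral densities of COP signals and
# group averages for device comparison. Hann window, 5 s windows, 50%
# overlap, per-window mean removal, one-sided density scaling (cm^2/Hz), so
# the integral of power over frequency approximates the signal variance.

#' Welch power spectral density
#'
#' Averaged modified periodogram: the series is split into `window_s`-second
#' windows with `overlap` fractional overlap, each window is mean-removed,
#' Hann-tapered, Fourier transformed, and the one-sided periodograms are
#' averaged with density scaling `|X|^2 / (fs * sum(w^2))` (interior bins
#' doubled).
#'
#' @param series Numeric series (cm).
#' @param rate Sampling rate (Hz).
#' @param window_s Window length in seconds (default 5).
#' @param overlap Fractional window overlap in `[0, 1)` (default 0.5).
#' @return An object of class `psd_estimate`: `freqs` (Hz), `power`
#'   (cm^2/Hz), `n_segments_averaged`, `df`.
#' @export
psd_welch <- function(series, rate, window_s = 5, overlap = 0.5) {
  nwin <- as.integer(round(window_s * rate))
  if (length(series) < nwin) {
    stop_coptools(sprintf("series (%d samples) shorter than one %g s window",
                          length(series), window_s), "parameter_error")
  }
  w <- 0.5 - 0.5 * cos(2 * pi * seq.int(0L, nwin - 1L) / nwin)  # periodic Hann
  u <- sum(w^2)
  step <- max(1L, as.integer(round(nwin * (1 - overlap))))
  starts <- seq.int(1L, length(series) - nwin + 1L, by = step)
  n_one <- nwin %/% 2L + 1L
  acc <- numeric(n_one)
  for (s in starts) {
    seg <- series[seq.int(s, s + nwin - 1L)]
    seg <- seg - mean(seg)
    spec <- Mod(fft(seg * w))^2 / (rate * u)
    one <- spec[seq_len(n_one)]
    # double interior bins (not DC; not Nyquist when nwin is even)
    last_double <- if (nwin %% 2L == 0L) n_one - 1L else n_one
    if (last_double >= 2L) one[2:last_double] <- 2 * one[2:last_double]
    acc <- acc + one
  }
  structure(list(freqs = seq.int(0L, n_one - 1L) * rate / nwin,
                 power = acc / length(starts),
                 n_segments_averaged = length(starts),
                 df = rate / nwin),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d bins, 0..%g Hz (df %g), %d window(s); total power %.4g\n",
              length(x$freqs), max(x$freqs), x$df, x$n_segments_averaged,
              sum(x$power) * x$df))
  invisible(x)
}

#' Group-average spectrum
#'
#' Arithmetic mean of per-participant spectral power, bin by bin. All inputs
#' must share one frequency grid.
#'
#' @param psds List of [psd_welch()] estimates.
#' @return A `psd_estimate` whose `n_segments_averaged` is the total over
#'   inputs.
#' @export
psd_group_average <- function(psds) {
  if (length(psds) == 0L) stop_coptools("empty spectrum list", "parameter_error")
  f0 <- psds[[1]]$freqs
  for (p in psds) {
    if (length(p$freqs) != length(f0) || any(abs(p$freqs - f0) > 1e-9)) {
      stop_coptools("frequency grids differ between spectra", "parameter_error")
    }
  }
  pw <- rowMeans(vapply(psds, function(p) p$power, numeric(length(f0))))
  structure(list(freqs = f0, power = pw,
                 n_segments_averaged = sum(vapply(psds, function(p)
                   p$n_segments_averaged, integer(1))),
                 df = psds[[1]]$df),
            class = "psd_estimate")
}
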