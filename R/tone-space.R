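#' Configuration of a circular Shepard-tone space
#'
#' A Shepard tone complex (STC) space maps the angles 1--360 degrees onto one
#' octave of fundamental frequencies, so that the per-degree frequency ratio
#' is exactly \eqn{2^{1/360}} and degree 360 sits one step below the octave of
#' degree 1. Tones synthesized from this space carry a clear pitch chroma but
#' an ambiguous pitch height, which is what makes the space perceptually
#' circular.
#'
#' @param base_frequency Fundamental frequency (Hz) anchored at 1 degree.
#' @param degrees_per_octave Number of degrees spanning one octave.
#' @param band_low,band_high Frequency band (Hz) holding the octave-spaced
#'   components; the band is half-open, \code{[band_low, band_high)}.
#' @param sample_rate Sampling frequency in Hz.
#' @param duration Tone duration in seconds.
#' @param ramp Raised-cosine on/off ramp duration in seconds.
#'
#' @return An object of class \code{tone_space}.
#' @examples
#' sp <- tone_space()
#' degree_to_frequency(240, sp)   # 441.14 Hz
#' @export
tone_space <- function(base_frequency = 278.4375,
                       degrees_per_octave = 360,
                       band_low = 30,
                       band_high = 16000,
                       sample_rate = 44100,
                       duration = 0.5,
                       ramp = 0.01) {
  stopifnot(base_frequency > 0, band_low > 0)
  if (band_high / band_low <= 2)
    stop("band must span more than one octave", call. = FALSE)
  if (2 * base_frequency < band_low || 2 * base_frequency > band_high)
    stop("the octave above base_frequency must lie inside the band", call. = FALSE)
  if (duration <= 2 * ramp)
    stop("duration must exceed twice the ramp length", call. = FALSE)
  structure(
    list(base_frequency = base_frequency,
         degrees_per_octave = degrees_per_octave,
         band_low = band_low, band_high = band_high,
         sample_rate = sample_rate, duration = duration, ramp = ramp),
    class = "tone_space")
}

#' @export
print.tone_space <- function(x, ...) {
  cat("Circular Shepard-tone space\n")
  cat(sprintf("  base frequency : %.4f Hz at 1 degree\n", x$base_frequency))
  cat(sprintf("  octave span    : %d degrees (ratio 2^(1/%d) per degree)\n",
              x$degrees_per_octave, x$degrees_per_octave))
  cat(sprintf("  component band : [%g, %g) Hz\n", x$band_low, x$band_high))
  cat(sprintf("  sampling       : %g Hz, %.3f s, %.0f ms ramps\n",
              x$sample_rate, x$duration, 1000 * x$ramp))
  invisible(x)
}

#' Map a degree on the circular space to its fundamental frequency
#'
#' The convention anchors 1 degree at \code{base_frequency}, so
#' \eqn{f(d) = f_1 \, 2^{(d-1)/360}} and degree 360 is one step of
#' \eqn{2^{1/360}} below the full octave.
#'
#' @param degree Angle in degrees, in \code{[1, 360]}; real values are allowed
#'   (continuous report). Wrap out-of-range angles first.
#' @param space A \code{\link{tone_space}}.
#' @return Fundamental frequency in Hz.
#' @export
degree_to_frequency <- function(degree, space = tone_space()) {
  if (any(!is.finite(degree)) || any(degree < 1) || any(degree > 360))
    stop("degree must lie in [1, 360]; wrap angles before converting",
         call. = FALSE)
  space$base_frequency * 2^((degree - 1) / space$degrees_per_octave)
}

#' Inverse mapping from fundamental frequency to degree
#'
#' Exact inverse of \code{\link{degree_to_frequency}} for frequencies within
#' the octave starting at \code{base_frequency}; octave-reduce first if
#' needed.
#'
#' @param frequency Frequency in Hz.
#' @inheritParams degree_to_frequency
#' @return Degree in \code{[1, 360]}.
#' @export
frequency_to_degree <- function(frequency, space = tone_space()) {
  if (any(!is.finite(frequency)) || any(frequency <= 0))
    stop("frequency must be positive", call. = FALSE)
  d <- 1 + space$degrees_per_octave * log2(frequency / space$base_frequency)
  if (any(d < 1 - 1e-9) || any(d > 361 - 1e-9))
    stop("frequency outside the base octave; reduce by octaves first",
         call. = FALSE)
  d
}

#' Octave-spaced component frequencies of a Shepard tone
#'
#' All transpositions \code{fundamental * 2^k} (integer k) that fall in the
#' half-open band \code{[band_low, band_high)}, sorted ascending. A 500 Hz
#' fundamental under the default band yields the nine components 31.25,
#' 62.5, 125, 250, 500, 1000, 2000, 4000 and 8000 Hz.
#'
#' @param fundamental Fundamental frequency in Hz.
#' @inheritParams degree_to_frequency
#' @return Numeric vector of component frequencies (Hz).
#' @export
component_frequencies <- function(fundamental, space = tone_space()) {
  stopifnot(is.finite(fundamental), fundamental > 0)
  k_lo <- ceiling(log2(space$band_low / fundamental) - 1e-12)
  k_hi <- floor(log2(space$band_high / fundamental) + 1e-12)
  k <- seq.int(k_lo, length.out = max(0L, k_hi - k_lo + 1L))
  f <- fundamental * 2^k
  f <- f[f >= space$band_low & f < space$band_high]
  if (!length(f))
    stop("no octave transposition of the fundamental lies in the band",
         call. = FALSE)
  sort(f)
}

#' Fixed cos-squared spectral envelope over the component band
#'
#' Amplitude weight for a component at \code{frequency}: with
#' \eqn{l = \log_2 f}, \eqn{c} the midpoint and \eqn{h} the half-width of the
#' log2 band, the weight is \eqn{\cos^2(\pi (l - c) / (2h))} -- 1 at the
#' geometric band center, 0 at both edges, symmetric in log frequency. The
#' envelope is fixed over the band (not tied to the fundamental), which is
#' what makes the synthesized space circular: degree 360 and degree 1 receive
#' nearly identical component-amplitude profiles.
#'
#' @param frequency Frequency in Hz; values outside the band get weight 0.
#' @inheritParams degree_to_frequency
#' @return Amplitude weight in \code{[0, 1]}.
#' @export
spectral_envelope <- function(frequency, space = tone_space()) {
  l <- log2(frequency)
  lo <- log2(space$band_low); hi <- log2(space$band_high)
  cen <- (lo + hi) / 2
  hw <- (hi - lo) / 2
  a <- cos(pi * (l - cen) / (2 * hw))^2
  a[frequency < space$band_low | frequency > space$band_high | !is.finite(l)] <- 0
  a
}

#' Synthesize a Shepard tone complex at a given degree
#'
#' Sums phase-zero sinusoids at every in-band octave component of the degree's
#' fundamental, weighted by the fixed \code{\link{spectral_envelope}},
#' renormalizes the peak to 0.99, and applies raised-cosine on/off ramps.
#'
#' @inheritParams degree_to_frequency
#' @param duration Optional override of the space's duration (seconds).
#' @return An object of class \code{shepard_tone}: list with \code{degree},
#'   \code{fundamental}, \code{components} (data.frame frequency/amplitude)
#'   and \code{samples} in \code{[-1, 1]}.
#' @examples
#' tn <- shepard_tone(120)
#' length(tn$samples)  # 0.5 s at 44.1 kHz -> 22050
#' @export
shepard_tone <- function(degree, space = tone_space(), duration = NULL) {
  if (!is.null(duration)) {
    if (duration <= 0) stop("duration must be positive", call. = FALSE)
    space$duration <- duration
  }
  fund <- degree_to_frequency(degree, space)
  freqs <- component_frequencies(fund, space)
  amps <- spectral_envelope(freqs, space)
  n <- round(space$duration * space$sample_rate)
  t <- seq.int(0, n - 1) / space$sample_rate
  x <- numeric(n)
  for (i in seq_along(freqs))
    x <- x + amps[i] * sin(2 * pi * freqs[i] * t)
  peak <- max(abs(x))
  if (peak > 0) x <- x * (0.99 / peak)
  x <- x * cosine_ramp(n, space$ramp * space$sample_rate)
  structure(
    list(degree = degree, fundamental = fund,
         components = data.frame(frequency = freqs, amplitude = amps),
         samples = x, sample_rate = space$sample_rate),
    class = "shepard_tone")
}

#' @export
print.shepard_tone <- function(x, ...) {
  cat(sprintf("Shepard tone at %.4g degrees (fundamental %.2f Hz)\n",
              x$degree, x$fundamental))
  cat(sprintf("  %d octave components in [%.4g, %.4g] Hz; %d samples at %g Hz\n",
              nrow(x$components), min(x$components$frequency),
              max(x$components$frequency), length(x$samples), x$sample_rate))
  invisible(x)
}

# raised-cosine on/off window: 0 -> 1 over ramp_n samples at each end
cosine_ramp <- function(n, ramp_n) {
  w <- rep(1, n)
  r <- round(ramp_n)
  if (r > 0 && 2 * r <= n) {
    up <- 0.5 * (1 - cos(pi * seq.int(0, r - 1) / r))
    w[seq_len(r)] <- up
    w[seq.int(n - r + 1, n)] <- rev(up)
  }
  w
}

#' Equalize the root-mean-square amplitude of a set of waveforms
#'
#' Rescales each waveform so all share one RMS (the mean RMS of the inputs);
#' shapes are unchanged up to scaling. Used to remove loudness cues when
#' comparing tones.
#'
#' @param waveforms List of numeric sample vectors.
#' @return List of rescaled waveforms.
#' @export
rms_equalize <- function(waveforms) {
  stopifnot(is.list(waveforms), length(waveforms) >= 1)
  rms <- vapply(waveforms, function(w) sqrt(mean(w^2)), numeric(1))
  if (any(rms == 0)) stop("cannot RMS-equalize a silent waveform", call. = FALSE)
  target <- mean(rms)
  Map(function(w, r) w * (target / r), waveforms, rms)
}

#' Logarithmically spaced pure-tone set for delayed match-to-sample tasks
#'
#' Generates \code{n} pure tones at \eqn{f_{low} \, 2^{(i-1)/12}},
#' i = 1..n (semitone spacing, so tone 13 would close the octave at
#' \eqn{2 f_{low}}), RMS-equalized.
#'
#' @param f_low Frequency of the first tone (Hz).
#' @param n Number of tones.
#' @param duration Tone duration (seconds).
#' @param sample_rate Sampling frequency (Hz).
#' @param ramp Raised-cosine ramp (seconds).
#' @return List with \code{frequencies} and \code{waveforms}.
#' @export
dmst_tone_set <- function(f_low = 1000, n = 12, duration = 0.75,
                          sample_rate = 44100, ramp = 0.01) {
  stopifnot(n >= 2, f_low > 0, duration > 0)
  freqs <- f_low * 2^((seq_len(n) - 1) / 12)
  ns <- round(duration * sample_rate)
  t <- seq.int(0, ns - 1) / sample_rate
  w <- lapply(freqs, function(f)
    0.9 * sin(2 * pi * f * t) * cosine_ramp(ns, ramp * sample_rate))
  list(frequencies = freqs, waveforms = rms_equalize(w))
}
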