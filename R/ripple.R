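#' Parameters of a dynamic ripple sound
#'
#' Dynamic ripple sounds are broadband stimuli built from many log-spaced
#' sinusoidal carriers whose joint spectrotemporal envelope drifts at a
#' "ripple velocity" of `velocity` cycles/s and a spectral density of
#' `ripple_density` cycles/octave. They are spectrotemporally speech-like
#' but carry no semantic content, which makes them suited to auditory
#' working-memory tasks where verbal rehearsal must be ruled out.
#'
#' The envelope of the carrier at octave position `g = log2(f / f0)` is
#' `s(g, t) = D0 + D * cos(2*pi*(velocity*t + ripple_density*g) + phase)`.
#'
#' @param velocity ripple velocity omega, cycles/s.
#' @param ripple_density spectral ripple density Omega, cycles/octave.
#' @param base_intensity carrier base intensity D0 (a.u.).
#' @param modulation_depth modulation depth D (a.u., >= 0).
#' @param phase ripple phase psi (radians).
#' @param f0 lowest carrier frequency (Hz).
#' @param f_max highest carrier frequency (Hz).
#' @param sinusoids_per_octave carriers per octave (inclusive log2 grid).
#' @param duration stimulus duration (s).
#' @param sample_rate synthesis rate (Hz); must be >= 2 * f_max.
#' @return an object of class `ripple_params`.
#' @export
#' @examples
#' p <- ripple_params(velocity = 8)
#' w <- generate_ripple(p, seed = 1)
ripple_params <- function(velocity = 8, ripple_density = 1,
                          base_intensity = 1, modulation_depth = 0.9,
                          phase = 0, f0 = 200, f_max = 1600,
                          sinusoids_per_octave = 20, duration = 1,
                          sample_rate = 16000) {
  stopifnot(f0 > 0, modulation_depth >= 0, duration > 0,
            sinusoids_per_octave >= 1)
  if (f_max <= f0) stop("f_max must exceed f0")
  if (sample_rate < 2 * f_max) {
    stop("sample_rate must be at least 2 * f_max (aliasing)")
  }
  structure(list(velocity = velocity, ripple_density = ripple_density,
                 base_intensity = base_intensity,
                 modulation_depth = modulation_depth, phase = phase,
                 f0 = f0, f_max = f_max,
                 sinusoids_per_octave = sinusoids_per_octave,
                 duration = duration, sample_rate = sample_rate),
            class = "ripple_params")
}

#' Carrier frequencies of a ripple stimulus
#'
#' Inclusive log2-spaced grid from `f0` to `f_max` at
#' `sinusoids_per_octave` carriers per octave: for the default 200-1600 Hz
#' range (3 octaves) at 20/octave this yields 61 carriers.
#'
#' @param params a [ripple_params()] object.
#' @return vector of carrier frequencies (Hz).
#' @export
ripple_carriers <- function(params) {
  n_oct <- log2(params$f_max / params$f0)
  steps <- seq(0, n_oct, by = 1 / params$sinusoids_per_octave)
  # include the top edge if the grid does not land on it exactly
  if (abs(steps[length(steps)] - n_oct) > 1e-9) steps <- c(steps, n_oct)
  params$f0 * 2^steps
}

#' Synthesize a dynamic ripple sound
#'
#' Superimposes log-spaced sinusoidal carriers, each with an independent
#' random starting phase, amplitude-modulated by the drifting ripple
#' envelope `s(g, t) = D0 + D * cos(2*pi*(omega*t + Omega*g) + psi)` with
#' `g = log2(f / f0)`. The output is normalized to peak |amplitude| <= 1.
#'
#' @param params a [ripple_params()] object.
#' @param seed integer seed controlling the carrier phases.
#' @return numeric waveform of `round(duration * sample_rate)` samples,
#'   with attributes `sample_rate` and `carriers`.
#' @export
generate_ripple <- function(params, seed = 1) {
  stopifnot(inherits(params, "ripple_params"))
  freqs <- ripple_carriers(params)
  n <- round(params$duration * params$sample_rate)
  t <- (seq_len(n) - 1) / params$sample_rate
  set.seed(seed)
  phases <- runif(length(freqs), 0, 2 * pi)
  g <- log2(freqs / params$f0)
  x <- numeric(n)
  for (j in seq_along(freqs)) {
    env <- params$base_intensity + params$modulation_depth *
      cos(2 * pi * (params$velocity * t + params$ripple_density * g[j]) +
            params$phase)
    x <- x + env * sin(2 * pi * freqs[j] * t + phases[j])
  }
  peak <- max(abs(x))
  if (peak > 0) x <- x / peak
  attr(x, "sample_rate") <- params$sample_rate
  attr(x, "carriers") <- freqs
  x
}

#' Write a waveform to a WAV file
#'
#' Minimal RIFF/WAVE writer supporting 16-bit PCM and 32-bit IEEE float,
#' mono. Input samples are expected in \[-1, 1\]; PCM output clips.
#'
#' @param x numeric waveform in \[-1, 1\].
#' @param path output file path.
#' @param sample_rate sampling rate in Hz (default: the waveform's
#'   `sample_rate` attribute).
#' @param format `"pcm16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, path, sample_rate = attr(x, "sample_rate"),
                      format = c("pcm16", "float32")) {
  format <- match.arg(format)
  stopifnot(is.numeric(x), length(x) > 0, is.numeric(sample_rate))
  sample_rate <- as.integer(sample_rate)
  bits <- if (format == "pcm16") 16L else 32L
  block <- bits / 8L
  data_bytes <- length(x) * block
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v, size) writeBin(as.integer(v), con, size = size,
                                   endian = "little")
  writeChar("RIFF", con, eos = NULL)
  wi(36L + data_bytes, 4)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  wi(16L, 4)
  wi(if (format == "pcm16") 1L else 3L, 2)   # audio format tag
  wi(1L, 2)                                  # mono
  wi(sample_rate, 4)
  wi(sample_rate * block, 4)                 # byte rate
  wi(block, 2)                               # block align
  wi(bits, 2)
  writeChar("data", con, eos = NULL)
  wi(data_bytes, 4)
  if (format == "pcm16") {
    s <- as.integer(round(clip(x, -1, 1) * 32767))
    writeBin(s, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(x), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file written by [write_wav()]
#'
#' @param path WAV file path.
#' @return numeric waveform with a `sample_rate` attribute.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4)
  stopifnot(hdr == "RIFF")
  readBin(con, "integer", 1, 4, endian = "little")
  stopifnot(readChar(con, 4) == "WAVE")
  stopifnot(readChar(con, 4) == "fmt ")
  readBin(con, "integer", 1, 4, endian = "little")
  fmt <- readBin(con, "integer", 1, 2, endian = "little")
  readBin(con, "integer", 1, 2, endian = "little")  # channels (mono assumed)
  sr <- readBin(con, "integer", 1, 4, endian = "little")
  readBin(con, "integer", 1, 4, endian = "little")
  readBin(con, "integer", 1, 2, endian = "little")
  bits <- readBin(con, "integer", 1, 2, endian = "little")
  stopifnot(readChar(con, 4) == "data")
  nbytes <- readBin(con, "integer", 1, 4, endian = "little")
  n <- nbytes / (bits / 8)
  x <- if (fmt == 1) {
    readBin(con, "integer", n, 2, endian = "little") / 32767
  } else {
    readBin(con, "numeric", n, 4, endian = "little")
  }
  attr(x, "sample_rate") <- sr
  x
}
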