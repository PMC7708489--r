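# Internal helpers: seeded substreams, speckle field synthesis, small math.

#' Derive a named substream seed from a master seed
#'
#' One master seed is split into independent named substreams (patterns,
#' field_tm, intensity_tm, noise, init, probe, ...) so each stochastic
#' component of a run is independently reproducible.
#'
#' @param master integer master seed.
#' @param name substream name (any string).
#' @return an integer seed < 2^31.
#' @export
substream_seed <- function(master, name) {
  chars <- utf8ToInt(name)
  h <- 0
  for (ch in chars) h <- (h * 31 + ch) %% 2147480009
  as.integer((abs(as.numeric(master)) %% 1e8 * 7919 + h) %% 2147480009)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Centered FFT frequencies in cycles/pixel.
fft_freq <- function(n) {
  (((0:(n - 1)) + floor(n / 2)) %% n - floor(n / 2)) / n
}

#' Generate a fully developed complex speckle field
#'
#' Complex circular-Gaussian field with Gaussian power spectrum, synthesized
#' by filtering white noise in the Fourier domain. The intensity |field|^2 is
#' a fully developed speckle with unit contrast and grain size `grain` pixels
#' (the 1/e half-width of the field autocorrelation is about grain/2).
#'
#' @param rows,cols grid size in pixels.
#' @param grain speckle grain size in pixels (>= 2 for Nyquist sampling).
#' @return complex matrix `rows` x `cols`, normalized to unit mean intensity.
#' @export
speckle_field <- function(rows, cols, grain = 2) {
  if (grain < 2) stop("speckle grain must be >= 2 pixels")
  fx <- matrix(fft_freq(cols), rows, cols, byrow = TRUE)
  fy <- matrix(fft_freq(rows), rows, cols)
  mask <- exp(-(fx^2 + fy^2) * (pi * grain)^2 / 4)
  z <- matrix(stats::rnorm(rows * cols), rows, cols) +
    1i * matrix(stats::rnorm(rows * cols), rows, cols)
  f <- stats::fft(mask * z, inverse = TRUE)
  f / sqrt(mean(Mod(f)^2))
}

# Circular complex Gaussian vector, unit per-component variance.
ccg <- function(n) {
  complex(real = stats::rnorm(n, sd = sqrt(0.5)),
          imaginary = stats::rnorm(n, sd = sqrt(0.5)))
}

# Phase-invariant cosine similarity between two complex vectors.
#' Phase-invariant cosine similarity
#'
#' |<a, b>| / (||a|| ||b||); equals 1 iff `b` is a complex scalar multiple of
#' `a`. The standard quality metric for phase-retrieval solutions, which are
#' only defined up to a global phase.
#'
#' @param a,b complex (or numeric) vectors of equal length.
#' @return scalar in [0, 1].
#' @export
tm_cosine <- function(a, b) {
  stopifnot(length(a) == length(b))
  Mod(sum(Conj(a) * b)) / sqrt(sum(Mod(a)^2) * sum(Mod(b)^2))
}

# Robust z-scores: (x - median) / mad.
robust_z <- function(x) {
  m <- stats::median(x)
  s <- stats::mad(x)
  if (s == 0) s <- stats::sd(x)
  if (isTRUE(s == 0) || is.na(s)) return(rep(0, length(x)))
  (x - m) / s
}
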