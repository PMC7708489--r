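# Forward model: random SLM patterns, field-TM, intensity-TM, acquisitions.
#
# Geometry and conventions
#  - Camera grid: rows x cols pixels, 0-based (row, col) coordinates,
#    column-major flattening into D = rows*cols pixel vectors.
#  - Memory effect: Gaussian decorrelation c(d) = exp(-d^2 / (2 me_range^2)).
#  - All randomness is drawn from named substreams of the master seed.

#' Simulation configuration
#'
#' Bundles the physical and numerical parameters of a synthetic acquisition:
#' a fluorescent object of `n_targets` emitters behind a scattering medium,
#' illuminated through an SLM with `n_slm` phase segments by `n_patterns`
#' random wavefronts, and observed in epi-detection on a `grid[1] x grid[2]`
#' pixel camera.
#'
#' @param n_targets number of fluorescent emitters N.
#' @param n_slm number of SLM phase segments.
#' @param grid camera grid as c(rows, cols); D = rows*cols pixels.
#' @param n_patterns number of random input patterns P.
#' @param me_range memory-effect decorrelation scale, in camera pixels:
#'   speckles at two points separated by d decorrelate as
#'   exp(-d^2/(2 me_range^2)).
#' @param speckle_grain speckle grain size at the object/camera plane in
#'   pixels; must be >= 2 (Nyquist-sampled speckle).
#' @param excitation_exponent 1 for linear (one-photon) fluorescence, 2 for
#'   two-photon excitation.
#' @param photon_budget mean detected photons per pixel per frame; `Inf`
#'   disables Poisson noise (noiseless mode, the default).
#' @param read_noise_sd camera read noise, in photons.
#' @param seed master integer seed; split into named substreams.
#' @return an object of class `sim_config`.
#' @export
simulation_config <- function(n_targets, n_slm, grid = c(64, 64), n_patterns,
                              me_range = 12, speckle_grain = 2,
                              excitation_exponent = 1,
                              photon_budget = Inf, read_noise_sd = 0,
                              seed = 1L) {
  stopifnot(n_targets >= 1, n_slm >= 1, n_patterns >= 1,
            length(grid) == 2, all(grid >= 1))
  if (speckle_grain < 2) stop("speckle_grain must be >= 2 pixels")
  if (me_range <= 0) stop("me_range must be > 0")
  if (!excitation_exponent %in% c(1, 2))
    stop("excitation_exponent must be 1 (linear) or 2 (two-photon)")
  if (photon_budget <= 0) stop("photon_budget must be > 0 (Inf = noiseless)")
  structure(list(
    n_targets = as.integer(n_targets), n_slm = as.integer(n_slm),
    grid = as.integer(grid), n_pixels = as.integer(prod(grid)),
    n_patterns = as.integer(n_patterns),
    me_range = me_range, speckle_grain = speckle_grain,
    excitation_exponent = excitation_exponent,
    photon_budget = photon_budget, read_noise_sd = read_noise_sd,
    seed = as.integer(seed)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> N = %d emitters | N_SLM = %d | D = %dx%d | P = %d\n",
    x$n_targets, x$n_slm, x$grid[1], x$grid[2], x$n_patterns))
  cat(sprintf("  ME range %g px, grain %g px, excitation exponent %d, %s\n",
              x$me_range, x$speckle_grain, x$excitation_exponent,
              if (is.finite(x$photon_budget))
                sprintf("photon budget %g", x$photon_budget) else "noiseless"))
  invisible(x)
}

#' Emitter map
#'
#' Positions and brightnesses of the fluorescent targets on the camera grid.
#'
#' @param positions N x 2 matrix of 0-based (row, col) coordinates in camera
#'   pixels.
#' @param brightness positive weights, recycled to N (default all 1).
#' @return an object of class `emitter_map` (data.frame with columns
#'   id, row, col, brightness).
#' @export
emitter_map <- function(positions, brightness = 1) {
  positions <- matrix(as.numeric(positions), ncol = 2)
  n <- nrow(positions)
  brightness <- rep_len(as.numeric(brightness), n)
  if (any(brightness <= 0)) stop("brightness must be > 0")
  structure(data.frame(id = seq_len(n), row = positions[, 1],
                       col = positions[, 2], brightness = brightness),
            class = c("emitter_map", "data.frame"))
}

#' Random emitter placement with a minimum separation
#'
#' Draws emitter positions uniformly inside the camera grid (with a margin),
#' rejecting draws closer than `min_sep` pixels to an accepted emitter so
#' targets are resolvable (at least one speckle grain apart).
#'
#' @param n number of emitters.
#' @param config a [simulation_config()].
#' @param min_sep minimum pairwise separation, px; default 2 speckle grains.
#' @param margin border kept free, px.
#' @param brightness emitter weights (recycled).
#' @param seed optional seed (defaults to the config's emitter substream).
#' @return an [emitter_map()].
#' @export
random_emitters <- function(n, config, min_sep = 2 * config$speckle_grain,
                            margin = 4, brightness = 1, seed = NULL) {
  if (is.null(seed)) seed <- substream_seed(config$seed, "emitters")
  rows <- config$grid[1]; cols <- config$grid[2]
  with_seed(seed, {
    pos <- matrix(NA_real_, n, 2)
    k <- 0; tries <- 0
    while (k < n && tries < 20000L) {
      cand <- c(stats::runif(1, margin, rows - 1 - margin),
                stats::runif(1, margin, cols - 1 - margin))
      ok <- k == 0 ||
        min(sqrt(rowSums(sweep(pos[seq_len(k), , drop = FALSE], 2, cand)^2))) >=
          min_sep
      if (ok) { k <- k + 1; pos[k, ] <- cand }
      tries <- tries + 1
    }
    if (k < n) stop("could not place ", n, " emitters at min_sep = ", min_sep)
    emitter_map(round(pos), brightness)
  })
}

#' Generate random SLM phase patterns
#'
#' P phase-only input wavefronts with i.i.d. phases uniform on [0, 2pi).
#'
#' @param n_slm number of SLM segments.
#' @param n_patterns number of patterns P.
#' @param seed integer seed.
#' @return object of class `phase_patterns`: list with `phases`
#'   (n_slm x n_patterns matrix).
#' @export
generate_random_patterns <- function(n_slm, n_patterns, seed = 1L) {
  if (n_slm < 1 || n_patterns < 1) stop("dimensions must be positive")
  phases <- with_seed(seed, matrix(stats::runif(n_slm * n_patterns, 0, 2 * pi),
                                   n_slm, n_patterns))
  structure(list(phases = phases, n_slm = as.integer(n_slm),
                 n_patterns = as.integer(n_patterns), seed = as.integer(seed)),
            class = "phase_patterns")
}

#' Input fields of a pattern set
#'
#' @param patterns a `phase_patterns` object (or a bare phase matrix).
#' @return complex matrix E_in = exp(i * phases), unit amplitude per segment.
#' @export
pattern_fields <- function(patterns) {
  ph <- if (inherits(patterns, "phase_patterns")) patterns$phases else patterns
  exp(1i * ph)
}

#' @export
print.phase_patterns <- function(x, ...) {
  cat(sprintf("<phase_patterns> %d segments x %d patterns (seed %d)\n",
              x$n_slm, x$n_patterns, x$seed))
  invisible(x)
}

# Deterministic per-segment pupil coordinates in [-1/2, 1/2]^2; segment s of
# the SLM sits at pupil position (gr[s], gc[s]). A shift x at the object plane
# corresponds to the tilt exp(i 2 pi (gr*dr + gc*dc) / grain), so moving by
# one speckle grain sweeps one full fringe across the pupil.
slm_pupil_coords <- function(n_slm) {
  m <- ceiling(sqrt(n_slm))
  idx <- seq_len(n_slm) - 1L
  gr <- ((idx %/% m) - (m - 1) / 2) / m
  gc <- ((idx %% m) - (m - 1) / 2) / m
  cbind(gr, gc)
}

tilt_phase <- function(coords, dr, dc, grain) {
  2 * pi * (coords[, 1] * dr + coords[, 2] * dc) / grain
}

#' Ground-truth ingoing field transmission matrix
#'
#' Builds the complex field-TM T (N x N_SLM) relating SLM segments to the
#' excitation field at each emitter, with a tilt-shift memory-effect model:
#' row n is c(d_n) * (a * tilt(x_n)) + sqrt(1 - c(d_n)^2) * g_n, where `a` is
#' one shared circular-Gaussian pupil field, tilt(x) the linear phase ramp
#' that translates the speckle by x, g_n an independent circular-Gaussian
#' row, d_n the distance from the first (reference) emitter, and
#' c(d) = exp(-d^2 / (2 me_range^2)). Excitation speckles |t_n E_in|^2 are
#' exponentially distributed (fully developed).
#'
#' @param config a [simulation_config()].
#' @param emitters an [emitter_map()].
#' @return object of class `field_tm`: list with complex `matrix` (N x N_SLM)
#'   plus the emitter map.
#' @export
make_field_tm <- function(config, emitters) {
  stopifnot(inherits(config, "sim_config"))
  pos <- cbind(emitters$row, emitters$col)
  if (any(pos[, 1] < 0 | pos[, 1] > config$grid[1] - 1 |
          pos[, 2] < 0 | pos[, 2] > config$grid[2] - 1))
    stop("emitters outside the camera grid")
  n <- nrow(pos)
  coords <- slm_pupil_coords(config$n_slm)
  with_seed(substream_seed(config$seed, "field_tm"), {
    a <- ccg(config$n_slm)
    d <- sqrt((pos[, 1] - pos[1, 1])^2 + (pos[, 2] - pos[1, 2])^2)
    cc <- exp(-d^2 / (2 * config$me_range^2))
    tm <- matrix(0i, n, config$n_slm)
    for (k in seq_len(n)) {
      tl <- exp(1i * tilt_phase(coords, pos[k, 1] - pos[1, 1],
                                pos[k, 2] - pos[1, 2], config$speckle_grain))
      tm[k, ] <- cc[k] * (a * tl) + sqrt(1 - cc[k]^2) * ccg(config$n_slm)
    }
    structure(list(matrix = tm, emitters = emitters, me_corr = cc,
                   config = config), class = "field_tm")
  })
}

#' @export
print.field_tm <- function(x, ...) {
  cat(sprintf("<field_tm> %d emitters x %d SLM segments\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Ground-truth outgoing intensity transmission matrix
#'
#' Builds the non-negative intensity-TM W (D x N): column n is the
#' fluorescent eigen-pattern that emitter n casts on the epi-detection
#' camera. Patterns of emitters i, j separated by d_ij are correlated
#' translated copies: the correlated component of pattern j is *exactly*
#' pattern i shifted by x_j - x_i, with intensity correlation
#' c(d_ij) = exp(-d_ij^2 / (2 me_range^2)) for every pair. Implemented as a
#' mixture of `n_mix` shared complex mother speckles, windowed at each
#' emitter's offset and combined with Gaussian-process weights over emitter
#' positions (field kernel sqrt(c), hence intensity kernel c).
#'
#' @param config a [simulation_config()].
#' @param emitters an [emitter_map()].
#' @param n_mix number of mixture components controlling how tightly the
#'   realized pairwise correlations concentrate around c(d); default 64.
#' @return object of class `intensity_tm`: list with `matrix` (D x N), the
#'   grid and the emitter map.
#' @export
make_intensity_tm <- function(config, emitters, n_mix = 64L) {
  stopifnot(inherits(config, "sim_config"))
  rows <- config$grid[1]; cols <- config$grid[2]
  pos <- cbind(emitters$row, emitters$col)
  if (any(pos[, 1] < 0 | pos[, 1] > rows - 1 |
          pos[, 2] < 0 | pos[, 2] > cols - 1))
    stop("emitters outside the camera grid")
  n <- nrow(pos)
  span_r <- diff(range(pos[, 1])); span_c <- diff(range(pos[, 2]))
  mr <- rows + span_r; mc <- cols + span_c
  with_seed(substream_seed(config$seed, "intensity_tm"), {
    # GP weights over emitter positions; field kernel sqrt(c(d)).
    dd <- as.matrix(stats::dist(pos))
    S <- exp(-dd^2 / (4 * config$me_range^2))
    U <- chol(S + diag(1e-8, n))
    Vw <- matrix(stats::rnorm(n_mix * n), n_mix, n) %*% U
    Vw <- sweep(Vw, 2, sqrt(colSums(Vw^2)), "/")
    # Shared mother speckle fields on the padded grid.
    mothers <- lapply(seq_len(n_mix), function(k)
      speckle_field(mr, mc, config$speckle_grain))
    maxr <- max(pos[, 1]); maxc <- max(pos[, 2])
    W <- matrix(0, rows * cols, n)
    for (e in seq_len(n)) {
      ri <- (1:rows) + (maxr - pos[e, 1]); ci <- (1:cols) + (maxc - pos[e, 2])
      f <- matrix(0i, rows, cols)
      for (k in seq_len(n_mix)) f <- f + Vw[k, e] * mothers[[k]][ri, ci]
      patt <- Mod(f)^2
      W[, e] <- emitters$brightness[e] * patt / mean(patt)
    }
    structure(list(matrix = W, grid = config$grid, emitters = emitters,
                   config = config), class = "intensity_tm")
  })
}

#' @export
print.intensity_tm <- function(x, ...) {
  cat(sprintf("<intensity_tm> %d pixels (%dx%d) x %d eigen-patterns\n",
              nrow(x$matrix), x$grid[1], x$grid[2], ncol(x$matrix)))
  invisible(x)
}

#' Simulate an epi-detected fluorescence acquisition
#'
#' Applies the forward model I_out(p) = W (|T E_in(p)|^2)^e for every input
#' pattern p, then (optionally) Poisson photon noise at `photon_budget` mean
#' photons/pixel and additive Gaussian read noise, clipped at zero. The
#' noiseless path is bit-reproducible for a fixed seed.
#'
#' @param field_tm a [make_field_tm()] result (or bare complex N x N_SLM
#'   matrix).
#' @param intensity_tm a [make_intensity_tm()] result (or bare D x N matrix).
#' @param patterns a [generate_random_patterns()] result.
#' @param config a [simulation_config()].
#' @return object of class `speckle_stack`: list with `images` (D x P
#'   non-negative matrix), `grid`, excitation matrix `H` (N x P, the
#'   noise-free |T E_in|^2 ^ e), and metadata.
#' @export
simulate_acquisition <- function(field_tm, intensity_tm, patterns, config) {
  TT <- if (inherits(field_tm, "field_tm")) field_tm$matrix else field_tm
  W <- if (inherits(intensity_tm, "intensity_tm")) intensity_tm$matrix
       else intensity_tm
  E <- pattern_fields(patterns)
  if (ncol(TT) != nrow(E))
    stop("dimension mismatch on the SLM axis: T has ", ncol(TT),
         " columns but E_in has ", nrow(E), " rows")
  if (ncol(W) != nrow(TT))
    stop("dimension mismatch on the target axis: W has ", ncol(W),
         " columns but T has ", nrow(TT), " rows")
  H <- Mod(TT %*% E)^2
  if (config$excitation_exponent != 1) H <- H^config$excitation_exponent
  I <- W %*% H
  if (is.finite(config$photon_budget) || config$read_noise_sd > 0) {
    I <- with_seed(substream_seed(config$seed, "noise"), {
      if (is.finite(config$photon_budget)) {
        s <- config$photon_budget / mean(I)
        I <- matrix(stats::rpois(length(I), I * s), nrow(I), ncol(I)) / s
      }
      if (config$read_noise_sd > 0)
        I <- I + matrix(stats::rnorm(length(I), sd = config$read_noise_sd),
                        nrow(I), ncol(I))
      pmax(I, 0)
    })
  }
  speckle_stack(I, config$grid, seed = config$seed, H = H)
}

#' Construct a speckle stack
#'
#' @param images non-negative D x P matrix, one epi-detected frame per
#'   column (column-major pixel flattening).
#' @param grid c(rows, cols) with rows*cols == D.
#' @param seed seed recorded in the metadata.
#' @param H optional ground-truth excitation matrix (N x P).
#' @return object of class `speckle_stack`.
#' @export
speckle_stack <- function(images, grid, seed = NA_integer_, H = NULL) {
  images <- as.matrix(images)
  if (prod(grid) != nrow(images))
    stop("grid ", grid[1], "x", grid[2], " does not match D = ", nrow(images))
  if (any(images < 0)) stop("speckle stack must be non-negative")
  structure(list(images = images, grid = as.integer(grid),
                 n_patterns = ncol(images), seed = seed, H = H),
            class = "speckle_stack")
}

#' @export
print.speckle_stack <- function(x, ...) {
  cat(sprintf("<speckle_stack> %d frames of %dx%d px (D = %d)\n",
              x$n_patterns, x$grid[1], x$grid[2], nrow(x$images)))
  invisible(x)
}

#' Extract one frame of a stack as a matrix
#' @param stack a `speckle_stack`.
#' @param p frame index.
#' @return rows x cols matrix.
#' @export
stack_frame <- function(stack, p) {
  matrix(stack$images[, p], stack$grid[1], stack$grid[2])
}

#' Speckle contrast of an image
#'
#' Contrast = sd / mean over pixels. A single fully developed polarized
#' speckle has contrast 1; the incoherent sum over N equal emitters under
#' random illumination has mean frame contrast ~ sqrt(2/N) (linear
#' excitation).
#'
#' @param image non-negative image (matrix or vector) with nonzero mean.
#' @return scalar contrast.
#' @export
speckle_contrast <- function(image) {
  m <- mean(image)
  if (m == 0) stop("zero-mean image has undefined contrast")
  stats::sd(as.vector(image)) / m
}

#' Ensemble speckle contrast of a stack
#'
#' Contrast of the speckle ensemble over many frames. The default
#' "pooled" estimator, sqrt(mean over frames of the frame variance) divided
#' by the mean over frames of the frame mean, is a consistent estimator of
#' the ensemble contrast and converges to sqrt(2/N) for N equal emitters
#' under linear excitation. Averaging per-frame sd/mean ratios
#' ("per-frame") is also offered; it carries a downward Jensen bias of
#' order 1/N at small N.
#'
#' @param stack a `speckle_stack` or D x P matrix.
#' @param method "pooled" (default) or "per-frame".
#' @return scalar contrast.
#' @export
stack_contrast <- function(stack, method = c("pooled", "per-frame")) {
  method <- match.arg(method)
  m <- if (inherits(stack, "speckle_stack")) stack$images else as.matrix(stack)
  if (method == "pooled") {
    sqrt(mean(apply(m, 2, stats::var))) / mean(colMeans(m))
  } else {
    mean(apply(m, 2, speckle_contrast))
  }
}

#' Combine two polarization channels into unpolarized detection
#'
#' Unpolarized detection averages two independent speckle realizations (the
#' two polarization channels), dropping the contrast by sqrt(2) relative to a
#' single polarized channel.
#'
#' @param stack_a,stack_b two `speckle_stack`s of identical shape, simulated
#'   with independent intensity-TM realizations.
#' @return a `speckle_stack`, the pixelwise average.
#' @export
polarization_channels <- function(stack_a, stack_b) {
  if (!identical(dim(stack_a$images), dim(stack_b$images)) ||
      !identical(stack_a$grid, stack_b$grid))
    stop("polarization channels must have identical shape")
  speckle_stack((stack_a$images + stack_b$images) / 2, stack_a$grid,
                seed = stack_a$seed)
}
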