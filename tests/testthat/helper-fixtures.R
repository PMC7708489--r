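# Shared in-code fixtures. Everything is generated at test time from fixed
# seeds; builders are memoized so several test files can reuse one scene.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- builder()
  fixture_env[[key]]
}

# Small noiseless scene: 5 emitters, 32 SLM segments, 512 patterns, 48x48.
small_scene <- function() memo("small_scene", function() {
  sc <- simulation_config(5, 32, grid = c(48, 48), n_patterns = 512,
                          me_range = 10, seed = 7)
  em <- random_emitters(5, sc, min_sep = 6)
  TT <- make_field_tm(sc, em)
  W <- make_intensity_tm(sc, em)
  patt <- generate_random_patterns(32, 512, substream_seed(7, "patterns"))
  stack <- simulate_acquisition(TT, W, patt, sc)
  list(sc = sc, em = em, TT = TT, W = W, patt = patt, stack = stack,
       hp = high_pass_filter(stack, 6))
})

# Planted phase-retrieval problem: known t, random patterns, h = |t E|^2.
planted_pr <- function(n_slm, P, seed = 1) {
  set.seed(seed)
  t_true <- complex(real = rnorm(n_slm), imaginary = rnorm(n_slm))
  E <- pattern_fields(generate_random_patterns(n_slm, P, seed + 1))
  h <- Mod(drop(t(E) %*% t_true))^2
  list(t = t_true, E = E, h = h)
}

# A chain of emitters with overlapping memory-effect patches spanning
# several patch diameters; used for stitching tests.
chain_emitters <- function(n, spacing, grid = c(64, 64), seed = 3) {
  set.seed(seed)
  # snake path across the grid with roughly `spacing` steps
  pos <- matrix(NA_real_, n, 2)
  pos[1, ] <- c(grid[1] / 2, 6)
  ang <- 0
  for (k in 2:n) {
    repeat {
      ang_new <- ang + runif(1, -0.6, 0.6)
      cand <- pos[k - 1, ] + spacing * c(sin(ang_new), cos(ang_new))
      if (all(cand >= 3 & cand <= grid - 4)) { ang <- ang_new; break }
      ang <- ang + pi / 2
    }
    pos[k, ] <- cand
  }
  emitter_map(round(pos))
}
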