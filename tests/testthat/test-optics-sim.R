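# Forward model: pattern statistics, field/intensity TM structure, Eq.-(1)
# acquisition, contrast laws.

test_that("random patterns are reproducible, uniform and unit-modulus", {
  p1 <- generate_random_patterns(64, 100, seed = 5)
  p2 <- generate_random_patterns(64, 100, seed = 5)
  p3 <- generate_random_patterns(64, 100, seed = 6)
  expect_identical(p1$phases, p2$phases)
  expect_lt(abs(cor(as.vector(p1$phases), as.vector(p3$phases))), 0.05)
  expect_true(all(p1$phases >= 0 & p1$phases < 2 * pi))
  expect_gt(suppressWarnings(ks.test(as.vector(p1$phases),
                                     "punif", 0, 2 * pi))$p.value, 1e-4)
  expect_equal(Mod(pattern_fields(p1)),
               matrix(1, 64, 100), tolerance = 1e-12)
  expect_error(generate_random_patterns(0, 10), "positive")
})

test_that("zero phases give a field column of ones", {
  pp <- generate_random_patterns(4, 1, seed = 1)
  pp$phases[] <- 0
  expect_equal(drop(pattern_fields(pp)), rep(1 + 0i, 4))
})

test_that("field-TM memory-effect correlation follows c(d) vs the reference emitter", {
  sc <- simulation_config(2, 256, grid = c(64, 64), n_patterns = 4,
                          me_range = 8, seed = 2)
  # same position: identical rows (c = 1)
  em0 <- emitter_map(rbind(c(30, 30), c(30, 30)))
  tm0 <- make_field_tm(sc, em0)
  expect_equal(tm0$matrix[1, ], tm0$matrix[2, ], tolerance = 1e-12)
  # far separation: near-zero row correlation (Monte-Carlo over seeds)
  cors_far <- sapply(1:20, function(s) {
    sci <- simulation_config(2, 256, grid = c(64, 64), n_patterns = 4,
                             me_range = 5, seed = s)
    tm <- make_field_tm(sci, emitter_map(rbind(c(5, 5), c(60, 60))))
    tm_cosine(tm$matrix[1, ], tm$matrix[2, ])
  })
  expect_lt(mean(cors_far), 0.15)
  expect_error(make_field_tm(sc, emitter_map(rbind(c(100, 5), c(5, 5)))),
               "outside")
})

test_that("tilt-compensated refocusing decays as c(d)^2 across the ME patch", {
  # memory effect: the focusing pattern of emitter 1, tilted by the
  # emitter separation, refocuses on emitter 2 with efficiency c(d)^2
  me <- 8; ds <- c(0, 4, 8, 12)
  coords <- specklemix:::slm_pupil_coords(256)
  ratio <- sapply(ds, function(d) {
    mean(sapply(1:12, function(s) {
      sc <- simulation_config(2, 256, grid = c(64, 64), n_patterns = 4,
                              me_range = me, seed = 200 + 17 * s)
      em <- emitter_map(rbind(c(30, 30), c(30, 30 + d)))
      tm <- make_field_tm(sc, em)
      tilt <- specklemix:::tilt_phase(coords, 0, d, sc$speckle_grain)
      pat <- (conjugate_focus_pattern(tm$matrix[1, ]) - tilt) %% (2 * pi)
      I2 <- Mod(sum(tm$matrix[2, ] * exp(1i * pat)))^2
      I2 / sum(Mod(tm$matrix[2, ]))^2
    }))
  })
  cd2 <- exp(-ds^2 / (2 * me^2))^2
  expect_equal(ratio, cd2, tolerance = 0.15)
  expect_true(all(diff(ratio) < 0))   # monotone decay with separation
})

test_that("excitation speckle intensities are exponentially distributed", {
  # one emitter, many independent patterns: h = |t . E_in|^2 ~ Exp
  sc <- simulation_config(1, 128, grid = c(16, 16), n_patterns = 4000,
                          me_range = 5, seed = 3)
  tm <- make_field_tm(sc, emitter_map(rbind(c(8, 8))))
  E <- pattern_fields(generate_random_patterns(128, 4000, 4))
  h <- Mod(drop(tm$matrix %*% E))^2
  expect_equal(sd(h) / mean(h), 1, tolerance = 0.08)   # contrast -> 1
  expect_gt(suppressWarnings(ks.test(h / mean(h), "pexp"))$p.value, 1e-3)
})

test_that("eigen-patterns shift exactly with emitter separation within the ME", {
  sc <- simulation_config(2, 16, grid = c(64, 64), n_patterns = 4,
                          me_range = 20, seed = 5)
  em <- emitter_map(rbind(c(20, 20), c(26, 31)))
  W <- make_intensity_tm(sc, em)
  # construction oracle: planted shift is (6, 11), pixel-exact
  cc <- cross_correlate(W$matrix[, 1], W$matrix[, 2], grid = c(64, 64))
  expect_identical(cc$u, c(6L, 11L))
  expect_gt(cc$peak, 0.5)
  # zero separation: identical columns
  W0 <- make_intensity_tm(sc, emitter_map(rbind(c(20, 20), c(20, 20))))
  expect_equal(W0$matrix[, 1], W0$matrix[, 2], tolerance = 1e-3)
})

test_that("eigen-patterns far beyond the ME are uncorrelated against the null", {
  # Monte-Carlo: peak for far pairs should look like the no-correlation null
  peaks_far <- sapply(1:8, function(s) {
    sc <- simulation_config(2, 16, grid = c(64, 64), n_patterns = 4,
                            me_range = 5, seed = 20 + s)
    W <- make_intensity_tm(sc, emitter_map(rbind(c(8, 8), c(56, 56))))
    cross_correlate(W$matrix[, 1], W$matrix[, 2], grid = c(64, 64))$peak
  })
  peaks_null <- sapply(1:8, function(s) {
    set.seed(40 + s)
    a <- Mod(speckle_field(64, 64, 2))^2
    b <- Mod(speckle_field(64, 64, 2))^2
    cross_correlate(a, b)$peak
  })
  expect_lt(abs(mean(peaks_far) - mean(peaks_null)),
            3 * sd(peaks_null) / sqrt(8) + 3 * sd(peaks_far) / sqrt(8) + 0.02)
})

test_that("noiseless acquisition equals W (|T E_in|^2)^e exactly", {
  sn <- small_scene()
  E <- pattern_fields(sn$patt)
  H <- Mod(sn$TT$matrix %*% E)^2
  expect_equal(sn$stack$images, sn$W$matrix %*% H, tolerance = 1e-12)
  # two-photon: exponent applied to the excitation, not the fluorescence sum
  sc2 <- sn$sc; sc2$excitation_exponent <- 2
  st2 <- simulate_acquisition(sn$TT, sn$W, sn$patt, sc2)
  expect_equal(st2$images, sn$W$matrix %*% H^2, tolerance = 1e-12)
})

test_that("noiseless stack has matrix rank min(N, D, P)", {
  sn <- small_scene()
  sv <- svd(sn$stack$images, nu = 0, nv = 0)$d
  expect_equal(sum(sv > sv[1] * 1e-9), 5)
})

test_that("acquisition validates axis dimensions with a named error", {
  sn <- small_scene()
  bad_patt <- generate_random_patterns(16, 10, 1)
  expect_error(simulate_acquisition(sn$TT, sn$W, bad_patt, sn$sc), "SLM")
  expect_error(simulate_acquisition(sn$TT$matrix[, ],
                                    sn$W$matrix[, 1:3], sn$patt, sn$sc),
               "target")
})

test_that("Poisson + read-noise path is seeded, non-negative and unbiased", {
  sn <- small_scene()
  scn <- sn$sc; scn$photon_budget <- 50; scn$read_noise_sd <- 2
  st1 <- simulate_acquisition(sn$TT, sn$W, sn$patt, scn)
  st2 <- simulate_acquisition(sn$TT, sn$W, sn$patt, scn)
  expect_identical(st1$images, st2$images)      # same seed, same noise
  expect_true(all(st1$images >= 0))
  expect_equal(mean(st1$images), mean(sn$stack$images), tolerance = 0.05)
  expect_false(identical(st1$images, sn$stack$images))
})

test_that("speckle contrast: constant image 0, single speckle 1, sqrt(2/N) law", {
  expect_equal(speckle_contrast(matrix(3, 10, 10)), 0)
  expect_error(speckle_contrast(matrix(0, 5, 5)), "zero-mean")
  set.seed(11)
  I1 <- Mod(speckle_field(256, 256, 2))^2
  expect_equal(speckle_contrast(I1), 1, tolerance = 0.05)
  # N equal emitters, linear excitation: ensemble contrast sqrt(2/N)
  for (N in c(4, 16)) {
    sc <- simulation_config(N, 64, grid = c(64, 64), n_patterns = 60,
                            me_range = 3, seed = 30 + N)
    em <- random_emitters(N, sc, min_sep = 5)
    st <- simulate_acquisition(make_field_tm(sc, em),
                               make_intensity_tm(sc, em),
                               generate_random_patterns(64, 60, 31 + N), sc)
    expect_equal(stack_contrast(st), sqrt(2 / N), tolerance = 0.10)
  }
})

test_that("two-photon excitation raises the frame contrast", {
  sc1 <- simulation_config(6, 64, grid = c(48, 48), n_patterns = 40,
                           me_range = 3, seed = 13)
  em <- random_emitters(6, sc1, min_sep = 5)
  TT <- make_field_tm(sc1, em); W <- make_intensity_tm(sc1, em)
  patt <- generate_random_patterns(64, 40, 14)
  sc2 <- sc1; sc2$excitation_exponent <- 2
  c1 <- stack_contrast(simulate_acquisition(TT, W, patt, sc1))
  c2 <- stack_contrast(simulate_acquisition(TT, W, patt, sc2))
  expect_gt(c2, c1)
})

test_that("unpolarized detection halves the variance: contrast ratio sqrt(2)", {
  # identical channels: contrast unchanged
  sn <- small_scene()
  expect_equal(stack_contrast(polarization_channels(sn$stack, sn$stack)),
               stack_contrast(sn$stack), tolerance = 1e-12)
  # independent channels, N = 1: ratio sqrt(2)
  sc <- simulation_config(1, 64, grid = c(64, 64), n_patterns = 50,
                          me_range = 5, seed = 17)
  em <- emitter_map(rbind(c(32, 32)))
  TT <- make_field_tm(sc, em)
  patt <- generate_random_patterns(64, 50, 18)
  sc_b <- sc; sc_b$seed <- 9917L   # independent W realization
  a <- simulate_acquisition(TT, make_intensity_tm(sc, em), patt, sc)
  b <- simulate_acquisition(TT, make_intensity_tm(sc_b, em), patt, sc_b)
  ratio <- stack_contrast(a) / stack_contrast(polarization_channels(a, b))
  expect_equal(ratio, sqrt(2), tolerance = 0.05)
  # k independent channels: contrast ~ 1/sqrt(k)
  set.seed(19)
  specks <- lapply(1:4, function(k) Mod(speckle_field(128, 128, 2))^2)
  c_k <- sapply(1:4, function(k)
    speckle_contrast(Reduce(`+`, specks[1:k]) / k))
  expect_equal(c_k, 1 / sqrt(1:4), tolerance = 0.1)
  expect_error(polarization_channels(a, speckle_stack(matrix(1, 4, 2), c(2, 2))),
               "shape")
})

test_that("stack round-trips through TIFF within the quantization bound", {
  sn <- small_scene()
  sub <- speckle_stack(sn$stack$images[, 1:5], sn$sc$grid, seed = 7)
  path <- withr::local_tempfile(fileext = ".tiff")
  write_stack(sub, path)
  back <- read_stack(path)
  expect_identical(back$grid, sub$grid)
  q <- max(sub$images) / 65535
  expect_lt(max(abs(back$images - sub$images)), 0.5 * q + 1e-9)
})
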