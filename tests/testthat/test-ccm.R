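# Delay embedding, simplex cross-mapping, convergence, causality rules.

test_that("delay embedding follows the index contract", {
  m <- delay_embed(1:10, E = 2, tau = 1)
  expect_equal(nrow(m$points), 9)
  m1 <- delay_embed(c(5, 7, 9, 11), E = 1, tau = 1)
  expect_equal(as.numeric(m1$points), c(5, 7, 9, 11))
  ramp <- delay_embed(0:9, E = 3, tau = 2)
  expect_equal(unname(ramp$points[1, ]), c(4, 2, 0))
  expect_equal(ramp$times[1], 5)
  expect_equal(nrow(ramp$points), 10 - 2 * 2)
  expect_error(delay_embed(1:5, E = 3, tau = 3), "too short")
})

test_that("cross-mapping a series from its own manifold is near perfect", {
  xy <- generate_coupled_logistic(coupling_spec(length = 1100, burn_in = 100,
                                                seed = 3))
  r <- cross_map_skill(xy$x, xy$x, E = 3, tau = 1, repeats = 3,
                       seed = 1)$r_mean
  expect_gte(r, 0.99)
})

test_that("independent white noise has near-zero cross-map skill", {
  set.seed(5)
  x <- rnorm(1000)
  y <- rnorm(1000)
  r <- cross_map_skill(x, y, E = 3, tau = 1, repeats = 10, seed = 2)$r_mean
  expect_lt(abs(r), 0.1)
})

test_that("unidirectional coupling yields asymmetric converged skill", {
  xy <- generate_coupled_logistic(coupling_spec(beta_yx = 0.32, length = 1100,
                                                burn_in = 100, seed = 7))
  mx <- cross_map_skill(xy$x, xy$y, E = 3, tau = 1, lib_size = 900,
                        repeats = 3, seed = 11)$r_mean
  my <- cross_map_skill(xy$y, xy$x, E = 3, tau = 1, lib_size = 900,
                        repeats = 3, seed = 12)$r_mean
  expect_gt(mx, my)
  expect_gt(mx, 0.9)
})

test_that("skill converges with library length in the causal direction", {
  xy <- generate_coupled_logistic(coupling_spec(beta_yx = 0.32, length = 1100,
                                                burn_in = 100, seed = 9))
  cv <- convergence_analysis(xy$x, xy$y, E = 3, tau = 1,
                             lib_sizes = c(50, 150, 400, 900),
                             repeats = 5, seed = 3)
  expect_s3_class(cv, "ccm_curve")
  expect_equal(nrow(cv$curve), 8)
  expect_gt(cv$trend[["x_from_y"]], 0)
  expect_equal(cv$mx_skill,
               cv$curve$r_mean[cv$curve$direction == "x_from_y" &
                                 cv$curve$lib_size == 900])
  # identical series: converged everywhere
  cv2 <- convergence_analysis(xy$x, xy$x, E = 3, tau = 1,
                              lib_sizes = c(200, 900), repeats = 2, seed = 4)
  expect_true(all(cv2$curve$r_mean > 0.97))
})

test_that("segment lists embed like their concatenation with gaps", {
  xy <- generate_coupled_logistic(coupling_spec(length = 700, burn_in = 100,
                                                seed = 5))
  segs_x <- split(xy$x, rep(1:3, each = 200))
  segs_y <- split(xy$y, rep(1:3, each = 200))
  r_seg <- cross_map_skill(segs_x, segs_y, E = 3, tau = 1, repeats = 2,
                           seed = 6)
  expect_true(is.finite(r_seg$r_mean))
  expect_equal(r_seg$lib_size, 3 * (200 - 2))
})

test_that("constant series produce zero skill with a warning", {
  x <- rep(1, 200)
  y <- sin(seq(0, 10, length.out = 200))
  expect_warning(r <- cross_map_skill(x, y, E = 2, tau = 1, repeats = 1,
                                      seed = 1)$r_mean, "degenerate|few")
  expect_equal(r, 0)
})

test_that("the four causality rules reproduce the stated verdicts", {
  v <- classify_causality(0.90, 0.50)
  expect_equal(v$direction, "x_to_y")
  expect_equal(v$rule, 1L)
  v <- classify_causality(0.60, 0.55)
  expect_equal(v$direction, "none")
  expect_equal(v$rule, 2L)
  v <- classify_causality(0.45, 0.25)
  expect_equal(v$direction, "x_to_y")
  expect_equal(v$rule, 4L)
  v <- classify_causality(0.70, 0.50)
  expect_equal(v$direction, "none")
  expect_equal(v$rule, 3L)
})

test_that("rule boundaries fall as documented", {
  expect_equal(classify_causality(0.45, 0.35)$rule, 2L) # D = 0.1 -> rule 2
  v <- classify_causality(0.45, 0.15) # D = 0.3 -> rules 3/4 band
  expect_equal(v$direction, "x_to_y")
  expect_equal(v$rule, 4L)
  expect_equal(classify_causality(0.80, 0.50)$rule, 3L) # D = 0.3, mx > 0.5
  v <- classify_causality(0.50, 0.30) # mx = 0.5 -> rule 3
  expect_equal(v$direction, "none")
  expect_equal(v$rule, 3L)
  expect_error(classify_causality(1.2, 0), "\\[-1, 1\\]")
})

test_that("classification is antisymmetric over a skill grid", {
  grid <- seq(0, 1, 0.1)
  for (a in grid) {
    for (b in grid) {
      f <- classify_causality(a, b)$direction
      g <- classify_causality(b, a)$direction
      if (f == "x_to_y") expect_equal(g, "y_to_x")
      if (f == "y_to_x") expect_equal(g, "x_to_y")
      if (f == "none") expect_equal(g, "none")
    }
  }
})

test_that("envelopes track a known amplitude modulation", {
  set.seed(8)
  rate <- 2000
  n <- 20000
  carrier <- signal::filtfilt(signal::butter(4, c(20, 450) / (rate / 2),
                                             type = "pass"), rnorm(n))
  m <- 1 + 0.8 * sin(2 * pi * 2 * (1:n) / rate)
  env <- emg_envelope(carrier * m, rate, cutoff = 10, decimate = 20)
  expect_equal(attr(env, "rate"), 100)
  expect_equal(length(env), 1000)
  m_dec <- m[seq(1, n, 20)]
  expect_gt(cor(as.numeric(env), m_dec), 0.9)
  expect_error(emg_envelope(rnorm(100), 10, cutoff = 10), "Nyquist")
})

test_that("phase envelopes window the continuous envelope per repetition", {
  cfg <- sim_config(n_channels = 2, group_assignment = c(1, 1), seed = 6,
                    n_repetitions = 3)
  rec <- generate_recording(cfg)$recording
  pe <- phase_envelopes(rec, phase = "lift", decimate = 20)
  expect_equal(names(pe), c("V1", "V2"))
  expect_length(pe[["V1"]], 3)
  expect_equal(lengths(pe[["V1"]]), rep(150, 3))
  # ratio detrending: cross-repetition mean profile is removed
  prof <- rowMeans(vapply(pe[["V1"]], identity, numeric(150)))
  expect_lt(max(abs(prof)), 1e-9)
  # whole-repetition windows
  pw <- phase_envelopes(rec, phase = NULL, decimate = 20)
  expect_equal(lengths(pw[["V1"]]), rep(400, 3))
  expect_error(phase_envelopes(rec, phase = "swing"), "no 'swing'")
})

test_that("uniform as-printed weights remain a valid estimator", {
  xy <- generate_coupled_logistic(coupling_spec(length = 600, burn_in = 100,
                                                seed = 10))
  r <- cross_map_skill(xy$x, xy$x, E = 3, tau = 1, repeats = 2,
                       weights = "as_printed", seed = 2)$r_mean
  expect_gt(r, 0.9) # self-manifold still predictive, if less sharp
  expect_lte(r, 1)
})
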