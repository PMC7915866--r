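# Synthetic EMG generator: determinism, planted structure, envelope
# scaling, coupled logistic benchmark system.

tiny_cfg <- function(..., n_channels = 4, rate = 250, band = c(20, 100),
                     phase_durations = c(lift = 0.6, hold = 0.4, lower = 0.6),
                     n_repetitions = 2, seed = 1) {
  sim_config(n_channels = n_channels, rate = rate, band = band,
             phase_durations = phase_durations,
             n_repetitions = n_repetitions, seed = seed, ...)
}

test_that("generation is deterministic and has the contracted shape", {
  cfg <- tiny_cfg(group_assignment = c(1, 1, 2, 2))
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  expect_identical(a$recording$signals, b$recording$signals)
  n_expected <- 2 * sum(round(c(0.6, 0.4, 0.6) * 250))
  expect_equal(dim(a$recording$signals), c(n_expected, 4))
  expect_equal(a$recording$channels, paste0("V", 1:4))
  # phase table partitions the recording
  ph <- a$recording$phases
  expect_equal(nrow(ph), 6) # 2 reps x 3 phases
  expect_equal(min(ph$start), 1)
  expect_equal(max(ph$end), n_expected)
  expect_true(all(ph$end >= ph$start))
  covered <- sum(ph$end - ph$start + 1)
  expect_equal(covered, n_expected)
  # truth record covers every channel exactly once
  expect_equal(sort(names(a$truth$groups)), sort(paste0("V", 1:4)))
})

test_that("fully shared source with no noise yields identical channels", {
  cfg <- tiny_cfg(n_channels = 2, group_assignment = c(1, 1),
                  group_strength = 1, global_strength = 0)
  rec <- generate_recording(cfg)$recording
  expect_equal(rec$signals[, 1], rec$signals[, 2])
  seg <- segment_phase(rec, "lift")[[1]]
  expect_equal(mutual_information(seg$signals[, 1], seg$signals[, 2],
                                  normalize = TRUE), 1)
})

test_that("independent channels show near-zero normalized MI", {
  vals <- vapply(1:3, function(s) {
    cfg <- sim_config(n_channels = 4, group_strength = 0,
                      global_strength = 0, n_repetitions = 1, seed = s)
    rec <- generate_recording(cfg)$recording
    seg <- segment_phase(rec, "lift")[[1]]
    W <- build_mi_matrix(list(seg), B = 16)$w
    mean(W[upper.tri(W)])
  }, numeric(1))
  expect_lt(mean(vals), 0.1)
})

test_that("within-group dependence exceeds between-group dependence", {
  ok <- vapply(1:3, function(s) {
    cfg <- sim_config(n_channels = 6, group_assignment = rep(1:2, each = 3),
                      group_strength = 0.6, global_strength = 0,
                      n_repetitions = 2, seed = s)
    rec <- generate_recording(cfg)$recording
    W <- build_mi_matrix(segment_phase(rec, "lift"))$w
    within <- mean(c(W[1, 2], W[1, 3], W[2, 3], W[4, 5], W[4, 6], W[5, 6]))
    between <- mean(W[1:3, 4:6])
    within > between
  }, logical(1))
  expect_true(all(ok))
})

test_that("per-phase RMS follows the configured envelope", {
  # slow amplitude modulation off: the check isolates the deterministic
  # lift/hold/lower envelope from the stochastic common drive
  cfg <- sim_config(n_channels = 3, group_strength = 0.5, seed = 4,
                    n_repetitions = 2, am_strength = 0)
  rec <- generate_recording(cfg)$recording
  ph <- rec$phases
  rms <- function(i) sqrt(mean(rec$signals[ph$start[i]:ph$end[i], 1]^2))
  n_lift <- ph$end[1] - ph$start[1] + 1
  expected_ratio <- sqrt(mean(seq(0.1, 1, length.out = n_lift)^2))
  expect_lt(abs(rms(1) / rms(2) - expected_ratio) / expected_ratio, 0.1)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(rate = 500, band = c(20, 450)), "band edge")
  expect_error(sim_config(n_channels = 1), "n_channels")
  expect_error(sim_config(group_strength = 1.5), "group_strength")
  expect_error(sim_config(phase_durations = c(1, -1, 1)), "positive")
  expect_error(
    sim_config(coupling = data.frame(from = "V1", to = "V1", strength = 0.2)),
    "self-loop"
  )
  expect_error(
    sim_config(coupling = data.frame(from = "V99", to = "V1", strength = 0.2)),
    "unknown"
  )
})

test_that("planted couplings are echoed in the truth record", {
  cfg <- tiny_cfg(group_assignment = rep(1, 4),
                  coupling = data.frame(from = "V1", to = c("V3", "V4"),
                                        strength = 0.3, lag = 0.1))
  tr <- generate_recording(cfg)$truth
  expect_equal(tr$edges$from, c(1L, 1L))
  expect_equal(sort(tr$edges$to), c(3L, 4L))
  expect_setequal(names(tr$modulators), c("1", "3", "4"))
  # modulators are positive, mean ~1, and deterministic with the seed
  expect_true(all(tr$modulators[["1"]] > 0))
  expect_equal(mean(tr$modulators[["1"]]), 1, tolerance = 1e-8)
  tr2 <- generate_recording(cfg)$truth
  expect_identical(tr$modulators, tr2$modulators)
})

test_that("coupled logistic maps behave like the canonical benchmark", {
  spec <- coupling_spec(beta_yx = 0.32, length = 600, burn_in = 100, seed = 3)
  xy <- generate_coupled_logistic(spec)
  expect_length(xy$x, 500)
  expect_true(all(xy$x > 0 & xy$x < 1))
  expect_true(all(xy$y > 0 & xy$y < 1))
  # deterministic
  xy2 <- generate_coupled_logistic(spec)
  expect_identical(xy$x, xy2$x)
  # decoupled series are plain logistic maps, so x is unaffected by beta_yx
  a <- generate_coupled_logistic(coupling_spec(length = 600, seed = 5))
  b <- generate_coupled_logistic(coupling_spec(beta_yx = 0.3, length = 600,
                                               seed = 5))
  expect_identical(a$x, b$x)
  expect_false(identical(a$y, b$y))
})

test_that("degenerate coupled-logistic specs fail loudly", {
  expect_error(coupling_spec(length = 100, burn_in = 100), "exceed")
  expect_error(coupling_spec(init = c(0, 0.5)), "init")
  expect_error(
    generate_coupled_logistic(coupling_spec(beta_yx = 3, length = 600,
                                            seed = 1)),
    "left \\(0, 1\\)"
  )
})

test_that("recordings round-trip through CSV plus JSON sidecar", {
  cfg <- tiny_cfg(n_channels = 3, group_assignment = rep(1, 3), seed = 8)
  gen <- generate_recording(cfg)
  csv <- tempfile(fileext = ".csv")
  write_recording(gen$recording, csv, truth = gen$truth)
  back <- read_recording(csv)
  expect_equal(back$signals, gen$recording$signals, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$rate, gen$recording$rate)
  expect_equal(back$condition, gen$recording$condition)
  expect_equal(back$phases$start, gen$recording$phases$start)
  truth <- attr(back, "truth")
  expect_equal(unname(truth$groups), unname(gen$truth$groups))
  unlink(c(csv, sub("\\.csv$", ".json", csv)))
})
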