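test_that("state signal has the right length, labels and determinism", {
  rec <- simulate_state_signal("Idle", 10, seed = 5)
  expect_identical(length(rec), 1000L)
  expect_true(all(rec$labels == 0L))

  again <- simulate_state_signal("Idle", 10, seed = 5)
  expect_identical(rec$samples, again$samples)

  other <- simulate_state_signal("Idle", 10, seed = 6)
  expect_false(identical(rec$samples, other$samples))

  expect_error(simulate_state_signal("Stone", 0.001), "too short")
  cfg <- default_sim_config()
  cfg$profiles$Stone <- NULL
  expect_error(simulate_state_signal("Stone", 1, cfg), "config error")
})

test_that("silent profile yields an all-zero trace and scaling is linear", {
  cfg <- default_sim_config(profiles = list(
    Idle = state_profile(noise_sigma = 0),
    Stone = state_profile(noise_sigma = 0),
    Tissue = state_profile(noise_sigma = 0)))
  expect_true(all(simulate_state_signal("Idle", 2, cfg, seed = 1)$samples == 0))

  # doubling noise_sigma and burst_amplitude doubles every sample
  base <- default_sim_config()
  doubled <- default_sim_config(profiles = lapply(base$profiles, function(p) {
    p$noise_sigma <- 2 * p$noise_sigma
    p$burst_amplitude <- 2 * p$burst_amplitude
    p
  }))
  for (st in c("Idle", "Stone", "Tissue")) {
    a <- simulate_state_signal(st, 5, base, seed = 42)
    b <- simulate_state_signal(st, 5, doubled, seed = 42)
    expect_equal(b$samples, 2 * a$samples, tolerance = 1e-12)
  }
})

test_that("burst arrivals follow the configured Poisson rate", {
  cfg <- default_sim_config(profiles = list(
    Idle = state_profile(),
    Stone = state_profile(0.05, 5, 1.0, 35, 0.05, 0.1),
    Tissue = state_profile(0.05, 5, 0.2, 12, 0.08, 0.1)))
  counts <- vapply(seq_len(200), function(s) {
    simulate_state_signal("Stone", 60, cfg, seed = s)$meta$simulator$n_bursts
  }, numeric(1))
  # mean of 200 Poisson(300) draws: 3 sigma of the mean is 3*sqrt(300/200)
  expect_lt(abs(mean(counts) - 300), 3 * sqrt(300 / 200))
})

test_that("sessions concatenate labeled blocks order-invariantly", {
  rec <- simulate_session(list(list("Idle", 1), list("Stone", 1),
                               list("Tissue", 1)), seed = 3)
  expect_identical(length(rec), 300L)
  expect_identical(rec$labels, rep(0:2, each = 100L))

  # single-entry schedule reduces to simulate_state_signal at the same seed
  one <- simulate_session(list(list("Stone", 2)), seed = 9)
  direct <- simulate_state_signal("Stone", 2, seed = 9)
  expect_identical(one$samples, direct$samples)

  # shuffling the schedule permutes blocks but keeps the label multiset
  fwd <- simulate_session(list(list("Stone", 1), list("Tissue", 2)), seed = 4)
  rev <- simulate_session(list(list("Tissue", 2), list("Stone", 1)), seed = 4)
  expect_identical(sort(table(fwd$labels)), sort(table(rev$labels)))
  expect_false(identical(fwd$labels, rev$labels))

  expect_error(simulate_session(list(list("Idle", -1)), seed = 1), "positive")
  expect_error(simulate_session(list(), seed = 1), "nonempty")
})

test_that("simulated magnitudes are nonnegative like the logged traces", {
  for (st in c("Idle", "Stone", "Tissue")) {
    expect_true(all(simulate_state_signal(st, 5, seed = 8)$samples >= 0))
  }
})

test_that("default profiles produce the expected spectral dominance", {
  sp <- class_average_spectrum(default_sim_segments())
  stone_over_idle <- mean(sp$Stone$magnitude > sp$Idle$magnitude)
  full_order <- mean(sp$Stone$magnitude > sp$Tissue$magnitude &
                       sp$Tissue$magnitude > sp$Idle$magnitude)
  expect_gte(stone_over_idle, 0.8)
  expect_gte(full_order, 0.8)
})
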