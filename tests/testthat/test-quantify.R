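test_that("dF/F0 of a constant trace is identically zero", {
  rec <- flat_recording(100)
  dff <- compute_dff(rec)
  expect_equal(dff$values, rep(0, 100))
  expect_false(dff$corrected)
})

test_that("a 5% fluorescence step reads as 0.05 dF/F0", {
  tr <- c(rep(100, 16), rep(105, 84))
  dff <- compute_dff(recording(tr, stimulus_id = "x"))
  expect_equal(dff$values[17:100], rep(0.05, 84))
  expect_equal(response_amplitude(dff), 5.0)
})

test_that("dF/F0 matches the element-wise oracle on random positive traces", {
  set.seed(31)
  for (i in 1:10) {
    tr <- runif(100, 50, 500)
    dff <- compute_dff(recording(tr, stimulus_id = "x"))
    f0 <- mean(tr[11:15])
    expect_equal(dff$values, (tr - f0) / f0, tolerance = 1e-14)
    # algebraic identity: zero mean over the baseline window
    expect_equal(mean(dff$values[11:15]), 0, tolerance = 1e-14)
  }
})

test_that("degenerate baselines are rejected", {
  tr <- c(rep(0, 15), rep(10, 85))
  expect_error(compute_dff(recording(tr, stimulus_id = "x")), "F0 <= 0")
  expect_error(compute_dff(flat_recording(), baseline_frames = c(14, 16)),
               "before stimulus onset")
  expect_error(quantify_config(baseline_frames = c(12, 16)),
               "before stimulus onset")
})

test_that("blank self-subtraction gives the zero trace exactly", {
  sc <- tci_scenario(seed = 8, blank_noise = TRUE)
  blank <- simulate_blank(sc)
  bdff <- average_blank_dff(list(blank))
  out <- bleach_correct(bdff, bdff)
  expect_identical(out$values, rep(0, 100))
  expect_true(out$corrected)
})

test_that("bleach correction is an exact additive subtraction", {
  sc <- quiet_scenario(seed = 9)
  bdff <- average_blank_dff(list(simulate_blank(sc)))
  shifted <- bdff
  shifted$values <- bdff$values + 0.02
  shifted$from_blank <- FALSE
  out <- bleach_correct(shifted, bdff)
  expect_equal(out$values, rep(0.02, 100), tolerance = 1e-14)
})

test_that("bleach correction guards its preconditions", {
  sc <- quiet_scenario(seed = 10)
  dff <- compute_dff(simulate_recording(sc, "odorant_01"))
  expect_error(bleach_correct(dff, dff), "blank")
  short <- average_blank_dff(list(simulate_blank(sc)))
  short$values <- short$values[1:50]
  expect_error(bleach_correct(dff, short), "length mismatch")
})

test_that("noise-free bleached transients recover the kernel-predicted amplitude", {
  # tau_bleach = 30 s, true peak amplitude 5%: after blank subtraction the
  # window mean must land within 0.5 percentage points of a * mean(kernel)
  sc <- quiet_scenario(seed = 12, bleach_tau_s = 30,
                       tuning = c(odorA = 0.05))
  rec <- simulate_recording(sc, "odorA")
  bdff <- average_blank_dff(list(simulate_blank(sc)))
  amp <- response_amplitude(bleach_correct(compute_dff(rec), bdff))
  expect_lt(abs(amp - predicted_amplitude(sc, 0.05)), 0.5)
})

test_that("response_amplitude is the window mean, in percent, and linear", {
  dff <- compute_dff(flat_recording())
  expect_equal(response_amplitude(dff), 0)
  set.seed(32)
  x <- compute_dff(recording(runif(100, 50, 150), stimulus_id = "x"))
  y <- compute_dff(recording(runif(100, 50, 150), stimulus_id = "y"))
  expect_equal(response_amplitude(x), 100 * mean(x$values[17:31]),
               tolerance = 1e-14)
  z <- x
  z$values <- 2.5 * x$values + 0.3 * y$values
  expect_equal(response_amplitude(z),
               2.5 * response_amplitude(x) + 0.3 * response_amplitude(y),
               tolerance = 1e-12)
  expect_error(response_amplitude(x, c(90, 110)), "out of range")
})

test_that("the response matrix matches the generative closed form at zero noise", {
  sc <- quiet_scenario(seed = 13, bleach_tau_s = Inf,
                       tuning = c(a = 0.05, b = 0.02, c = 0))
  panel <- simulate_panel(sc, stimuli = c("a", "b", "c"), n_flies = 2)
  rm <- build_response_matrix(panel$recordings, panel$blanks)
  expect_equal(dim(rm$amplitudes), c(2, 4))  # 3 odorants + solvent
  for (s in c("a", "b", "c"))
    expect_equal(unname(rm$amplitudes[, s]),
                 rep(predicted_amplitude(sc, sc$tuning[[s]]), 2),
                 tolerance = 1e-9)
  # solvent column is retained as the negative control, at zero
  expect_true("solvent" %in% colnames(rm$amplitudes))
  expect_equal(unname(rm$amplitudes[, "solvent"]), c(0, 0),
               tolerance = 1e-9)
})

test_that("a stimulus trace identical to the blank quantifies to zero", {
  sc <- quiet_scenario(seed = 14)
  blank <- simulate_blank(sc)
  ghost <- recording(blank$trace, stimulus_id = "ghost")
  rm <- build_response_matrix(list(ghost), list(blank))
  expect_equal(unname(rm$amplitudes["fly1", "ghost"]), 0, tolerance = 1e-12)
})

test_that("response-matrix assembly enforces blanks and uniqueness", {
  sc <- quiet_scenario(seed = 15)
  rec <- simulate_recording(sc, "odorant_01")
  expect_error(build_response_matrix(list(rec), list()), "no blank")
  blank <- simulate_blank(sc)
  expect_error(build_response_matrix(list(rec, rec), list(blank)),
               "duplicate unindexed")
  other <- simulate_blank(sc, fly_id = "fly9")
  expect_error(build_response_matrix(list(rec), list(other)),
               "no blank recording for fly fly1")
  # global blank scope accepts any fly's blank
  rm <- build_response_matrix(list(rec), list(other),
                              quantify_config(blank_scope = "global"))
  expect_equal(nrow(rm$amplitudes), 1)
})

test_that("a 16-fly panel yields a 16-row matrix", {
  sc <- tci_scenario(seed = 16)
  panel <- simulate_panel(sc, n_flies = 16)
  rm <- build_response_matrix(panel$recordings, panel$blanks)
  expect_equal(nrow(rm$amplitudes), 16)
  expect_equal(ncol(rm$amplitudes), 15)
  expect_false(anyNA(rm$amplitudes))
})

test_that("amplitude estimation is unbiased over many noisy flies", {
  # 200 flies, known activation, additive sensor noise only; the grand
  # mean must sit within 2 standard errors of the kernel prediction
  sc <- tci_scenario(seed = 17, bleach_tau_s = Inf, gain_cv = 0,
                     blank_noise = FALSE, tuning = c(odorA = 0.05))
  n <- 200
  amps <- vapply(seq_len(n), function(i) {
    rec <- simulate_recording(sc, "odorA", fly_id = paste0("fly", i),
                              seed = 500 + i)
    bdff <- average_blank_dff(list(simulate_blank(sc)))
    response_amplitude(bleach_correct(compute_dff(rec), bdff))
  }, numeric(1))
  sigma_pct <- 100 * sc$noise_sd / sc$baseline_level
  tol <- 2 * sigma_pct / sqrt(15 * n)
  expect_lt(abs(mean(amps) - predicted_amplitude(sc, 0.05)), tol)
})

test_that("stimulations-to-half-max matches direct enumeration", {
  geo <- 10 * 0.9^(0:39)
  res <- stimulations_to_half_max(longevity_series(geo))
  expect_equal(res$count, 7L)   # 0.9^6 = 0.531 >= 0.5 > 0.9^7 = 0.478
  expect_false(res$censored)

  const <- stimulations_to_half_max(longevity_series(rep(4, 25)))
  expect_true(const$censored)
  expect_equal(const$count, 25L)

  expect_equal(stimulations_to_half_max(c(10, 4, 8, 9))$count, 1L)
  expect_error(stimulations_to_half_max(rep(0, 5)), "half-max undefined")
})
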