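test_that("circular helpers wrap and measure angles correctly", {
  expect_equal(wrap_phase(5 * pi / 2), pi / 2)
  expect_equal(wrap_phase(-pi / 2), 3 * pi / 2)
  expect_equal(circ_dist(0.1, 2 * pi - 0.1), 0.2, tolerance = 1e-12)
  expect_equal(circ_signed_diff(0.1, 2 * pi - 0.1), 0.2, tolerance = 1e-12)
  expect_equal(circ_signed_diff(2 * pi - 0.1, 0.1), -0.2, tolerance = 1e-12)
  expect_equal(circ_signed_diff(pi, 0), pi)  # boundary maps to +pi
})

test_that("initialization is seed-deterministic and respects frequency bands", {
  p <- model_params()
  e1 <- init_ensemble(p, seed = 42)
  e2 <- init_ensemble(p, seed = 42)
  expect_identical(e1, e2)
  expect_true(all(e1$phases >= 0 & e1$phases < 2 * pi))
  expect_true(all(e1$freqs >= 0.01 & e1$freqs <= 1))
  expect_true(all(e1$last_reset == 0))
  expect_identical(e1$t, 0L)
  a <- init_ensemble(auditory_params(), targets = auditory_targets(), seed = 7)
  expect_true(all(a$freqs >= 5 & a$freqs <= 6))
})

test_that("phase advance follows the noiseless map and wraps", {
  e <- manual_ensemble(c(0, 0, 3 * pi / 2), c(0, 0.5, 0.5))
  e2 <- advance_phases(e)
  expect_equal(as.vector(e2$phases), c(0, pi, pi / 2), tolerance = 1e-12)
  expect_identical(e2$t, 1L)
  expect_equal(e2$freqs, e$freqs)
})

test_that("state classification uses circular distance to the nearest target", {
  tg <- unimodal_targets()
  p <- model_params()
  cl <- classify_state(c(pi / 2, pi / 2 + pi / 12, pi), tg, p)
  expect_equal(cl$state, c("locked", "locking", "in_transit"))
  expect_equal(cl$symbol[1:2], c("B", "B"))
  # pi is equidistant from both targets: tie breaks to the first map entry
  expect_equal(cl$symbol[3], "B")
  expect_error(classify_state(1, data.frame(), p), "non-empty")
})

test_that("match update resets the phase and retunes by the scaled phase error", {
  u <- match_update(pi / 2, 0.7, pi / 2, 3)
  expect_equal(u$phase, pi / 2)
  expect_equal(u$freq, 0.7)  # zero phase error
  u2 <- match_update(pi / 2 + pi / 12, 0.5, pi / 2, 2)
  expect_equal(u2$phase, pi / 2)
  expect_equal(u2$freq, 0.5 - 1 / 48, tolerance = 1e-12)
  # the error term is circular: a phase just below the target retunes upward
  u3 <- match_update(pi / 2 - pi / 12, 0.5, pi / 2, 2)
  expect_equal(u3$freq, 0.5 + 1 / 48, tolerance = 1e-12)
  expect_error(match_update(0, 0.5, 0, 0))
})

test_that("repeated match updates recover the input period", {
  # Oracle: one update sets f*P to the nearest integer, so any start within
  # half a cycle of 1/P lands exactly on 1/P and stays there.
  for (case in list(c(P = 2, f0 = 0.61), c(P = 5, f0 = 0.27),
                    c(P = 10, f0 = 0.12))) {
    P <- case[["P"]]; f <- case[["f0"]]
    phase <- pi / 2
    for (k in 1:4) {
      phase <- wrap_phase(phase + 2 * pi * f * P)  # free-run P steps
      u <- match_update(phase, f, pi / 2, P)
      phase <- u$phase; f <- u$freq
    }
    expect_equal(f, 1 / P, tolerance = 1e-6)
  }
})

test_that("mismatch update inverts the phase and shifts arrival by one cycle", {
  # phase inversion, both targets
  expect_equal(mismatch_update(pi / 2, 0.3, pi / 2, 2)$phase, 3 * pi / 2)
  expect_equal(mismatch_update(3 * pi / 2, 0.3, 3 * pi / 2, 2)$phase, pi / 2)
  # sub-cycle oscillator at an attuned point: frequency is a fixed point
  expect_equal(mismatch_update(pi / 2, 0.2, pi / 2, 5)$freq, 0.2,
               tolerance = 1e-12)
  # locked oscillator completing 5 cycles per revisit steps one cycle down
  m <- mismatch_update(3 * pi / 2, 0.5, 3 * pi / 2, 10, locked = TRUE)
  expect_equal(m$freq, 0.4, tolerance = 1e-12)
  expect_equal(m$freq * 10, round(0.5 * 10) - 1)  # one cycle later, exactly
  # a lagging locking oscillator steps one cycle up instead
  m2 <- mismatch_update(pi / 2 - pi / 12, 0.5, pi / 2, 10)
  expect_equal(m2$freq, 0.6, tolerance = 1e-12)
  # literal readings stay available and match their printed formulas
  del <- pi / 12
  a <- mismatch_update(pi / 2 + del, 0.3, pi / 2, 4, variant = "a")
  expect_equal(a$freq, 0.3 + (0.3 - (2 * pi + del) / (2 * pi * 4)) / 4,
               tolerance = 1e-12)
  b <- mismatch_update(pi / 2 + del, 0.3, pi / 2, 4, variant = "b")
  dpsi <- circ_signed_diff(pi / 2 + del, 3 * pi / 2)
  expect_equal(b$freq, 0.3 + (0.3 - dpsi / (2 * pi * 4)) / 4,
               tolerance = 1e-12)
})

test_that("a full step retunes only locking/locked oscillators and sums the reset-weighted error", {
  # oscillators placed (post-advance, f = 0) at: locking toward W, in transit,
  # locking toward W; last resets chosen so pre-reset DeltaT = (7, -, 4)
  e <- manual_ensemble(
    phases = c(3 * pi / 2 + 0.1, pi, 3 * pi / 2 - 0.1),
    freqs = c(0, 0, 0),
    t = 10L, last_reset = c(4, 0, 7)
  )
  out <- step_ensemble(e, "W", record_states = TRUE)
  expect_equal(out$result$error, 11)
  expect_equal(as.vector(out$result$resets), c(TRUE, FALSE, TRUE))
  expect_equal(as.vector(out$result$states), c("locking", "in_transit", "locking"))
  expect_equal(as.vector(out$state$phases)[c(1, 3)], rep(3 * pi / 2, 2))
  expect_equal(as.vector(out$state$phases)[2], pi)     # in transit untouched
  expect_equal(as.vector(out$state$last_reset), c(11, 0, 11))
  # blank slot: no learning, zero error
  out0 <- step_ensemble(out$state, "0")
  expect_equal(out0$result$error, 0)
  expect_false(any(out0$result$resets))
  expect_error(step_ensemble(e, "Q"), "unknown input symbol")
})

test_that("locked oscillators are stable on matching input but reset by a violation", {
  e <- manual_ensemble(phases = 3 * pi / 2, freqs = 1, t = 20L,
                       last_reset = 10)
  ok <- step_ensemble(e, "W")           # phase advances one full cycle: locked
  expect_false(any(ok$result$resets))
  expect_equal(ok$result$error, 0)
  bad <- step_ensemble(e, "B")          # the learned slot suddenly shows black
  expect_true(all(bad$result$resets))
  expect_equal(bad$result$error, 11)    # DeltaT = 21 - 10
  expect_equal(as.vector(bad$state$phases), pi / 2)  # inverted onto B's phase
})

test_that("congruence decision compares the current error with the running maximum", {
  expect_false(decide_congruence(c(50, 12, 3), 20))
  expect_true(decide_congruence(c(50, 12, 3), 60))
  expect_false(decide_congruence(c(50, 12, 3), 50))  # strict inequality
  expect_false(decide_congruence(numeric(0), 5))     # empty history
})

test_that("phases stay in [0, 2*pi) under arbitrary driving", {
  p <- model_params(n_oscillators = 40, noise_std = 0.3)
  e <- init_ensemble(p, seed = 3)
  set.seed(99)
  for (t in 1:60) {
    s <- sample(c("0", "B", "W"), 1)
    e <- step_ensemble(e, s)$state
    expect_true(all(e$phases >= 0 & e$phases < 2 * pi))
  }
  expect_identical(e$t, 60L)
})
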