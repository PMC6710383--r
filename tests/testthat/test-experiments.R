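test_that("pooled error equals the sum of per-ensemble errors exactly", {
  b <- build_streams(unimodal_sequence("-H-V-V-V-V"), repetitions = 3,
                     resolution = 8)
  r <- simulate_run(b, seed = 5)
  expect_identical(r$errors, colSums(r$channel_errors))
  expect_true(all(r$errors >= 0))
  # blank slots (odd steps) carry zero error
  expect_true(all(r$errors[seq(1, length(r$errors), 2)] == 0))
})

test_that("runs are bit-identical under a fixed seed", {
  b <- build_streams(unimodal_sequence(21), repetitions = 4, resolution = 6)
  r1 <- simulate_run(b, seed = 123)
  r2 <- simulate_run(b, seed = 123)
  expect_identical(r1$errors, r2$errors)
  expect_identical(r1$network$phases, r2$network$phases)
  expect_identical(r1$network$freqs, r2$network$freqs)
  tr1 <- run_trial(unimodal_sequence(21), 8, congruent = FALSE, seed = 9,
                   resolution = 6)
  tr2 <- run_trial(unimodal_sequence(21), 8, congruent = FALSE, seed = 9,
                   resolution = 6)
  expect_identical(tr1$errors, tr2$errors)
  expect_identical(tr1$decision, tr2$decision)
})

test_that("trials score correctness against the ground truth of the test item", {
  tr <- run_trial("-H-V-V-V-V", test_index = 8, congruent = TRUE, seed = 2,
                  resolution = 6)
  expect_equal(tr$test_step, 16)
  expect_equal(tr$correct, tr$decision == "congruent")
  tr2 <- run_trial("-H-V-V-V-V", test_index = 8, congruent = FALSE, seed = 2,
                   resolution = 6)
  expect_equal(tr2$correct, tr2$decision == "incongruent")
  expect_error(run_trial("-H-V-V-V-V", test_index = 4, congruent = TRUE),
               "sequence length")
})

test_that("an attuned model accepts congruent continuations reliably", {
  ok <- vapply(1:50, function(s) {
    run_trial("-H-V-V-V-V", test_index = 81, congruent = TRUE, seed = s,
              resolution = 6)$correct
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("accuracy curves separate congruent and incongruent test items early", {
  seqs <- enumerate_unimodal()[seq(2, 32, 4)]
  acc <- accuracy_curve(seqs, test_indices = 6:10, n_runs = 4,
                        base_seed = 11, resolution = 8)
  expect_equal(nrow(acc), 5)
  expect_true(all(acc$acc_combined >= 0 & acc$acc_combined <= 1))
  expect_equal(acc$acc_combined,
               (acc$acc_congruent + acc$acc_incongruent) / 2)
  # congruence is recognized after a few repetitions; violations take longer
  expect_gt(mean(acc$acc_congruent), mean(acc$acc_incongruent))
  # the incongruent curve is modulated by the position within the cycle:
  # the first position of the new cycle stands out against positions 2-5
  expect_gt(acc$acc_incongruent[1], mean(acc$acc_incongruent[2:5]))
})

test_that("combined accuracy rises well above chance with more repetitions", {
  seqs <- enumerate_unimodal()[seq(2, 32, 8)]
  early <- accuracy_curve(seqs, test_indices = 7, n_runs = 5,
                          base_seed = 3, resolution = 8)
  late <- accuracy_curve(seqs, test_indices = 71, n_runs = 5,
                         base_seed = 3, resolution = 8)
  expect_gt(late$acc_combined, early$acc_combined + 0.2)
  expect_gt(late$acc_combined, 0.75)
})

test_that("per-sequence accuracies group by entropy with the trivial sequences easiest", {
  ps <- per_sequence_accuracy(test_indices = c(8, 11, 14), n_runs = 3,
                              base_seed = 5, resolution = 6)
  expect_equal(nrow(ps$per_sequence), 32)
  expect_equal(ps$per_sequence$code, 0:31)
  expect_equal(nrow(ps$by_entropy), 3)
  expect_true(all(ps$per_sequence$accuracy >= 0 &
                  ps$per_sequence$accuracy <= 1))
  # zero-entropy (single-pattern) sequences are learned most easily
  expect_equal(which.max(ps$by_entropy$accuracy), 1L)
})

test_that("the multimodal model runs end to end, including degenerate input", {
  tr <- run_multimodal("AH-VL-VH-VH", test_index = 5, congruent = FALSE,
                       seed = 4, resolution = 8)
  expect_s3_class(tr, "osc_trial")
  expect_equal(tr$test_step, 10)
  # an all-visual item list is rejected by the enumerator but can be run
  tr2 <- run_multimodal(crossmodal_sequence("VL-VH-VL-VH",
                                            allow_unimodal = TRUE),
                        test_index = 5, congruent = TRUE, seed = 4,
                        resolution = 8)
  expect_s3_class(tr2, "osc_trial")
})
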