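# Coerce user input (string or object) to a sequence object.
.as_sequence <- function(x) {
  if (inherits(x, c("unimodal_sequence", "crossmodal_sequence"))) return(x)
  s <- gsub("-", "", as.character(x))
  if (grepl("^[HV]{5}$", s)) unimodal_sequence(x) else crossmodal_sequence(x)
}

# Resolve the per-module parameter list for a bundle. `params` may be NULL
# (defaults: visual band everywhere, auditory band for a module named
# "auditory"), a single osc_params applied to every module, or a named
# list keyed by module name.
.module_params <- function(bundle, params) {
  lapply(bundle$modules, function(m) {
    if (is.null(params)) {
      if (identical(m$name, "auditory")) auditory_params() else model_params()
    } else if (inherits(params, "osc_params")) {
      params
    } else {
      p <- params[[m$name]]
      if (is.null(p)) stop(sprintf("no parameters for module '%s'", m$name),
                           call. = FALSE)
      p
    }
  })
}

#' Run a network through an input stream bundle
#'
#' Initializes one oscillator ensemble per channel and steps the network
#' through every time step of the bundle, recording the pooled and
#' per-channel error signals. Pooling is by summation, so the pooled error
#' at each step equals the sum of the per-ensemble errors exactly.
#'
#' @param bundle a `stream_bundle` from [build_streams()],
#'   [build_trial_streams()] or [input_streams()].
#' @param params `NULL` (module defaults: the visual parameter set, and
#'   the auditory set for a module named `"auditory"`), a single
#'   [model_params()] applied to all modules, or a named list of
#'   `osc_params` keyed by module name.
#' @param seed integer seed; the run is fully deterministic given it.
#' @param record_states logical; record per-step counts of
#'   locked/locking/in-transit oscillators (needed by
#'   [locked_fraction_timeseries()]).
#' @param trajectory_channels integer vector of channels whose
#'   per-oscillator phase/frequency/state/reset trajectories are recorded.
#' @return an object of class `osc_run`: list with `network` (final
#'   state), `errors` (pooled e(t), length T), `channel_errors` (C x T),
#'   `state_counts` (T x 3 or NULL), `trajectory` (or NULL), `bundle`.
#' @export
#' @examples
#' b <- input_streams("0W0W0W0W0W", repetitions = 3)
#' r <- simulate_run(b, model_params(n_oscillators = 20), seed = 1)
#' r$errors
simulate_run <- function(bundle, params = NULL, seed = NULL,
                         record_states = FALSE,
                         trajectory_channels = integer(0)) {
  stopifnot(inherits(bundle, "stream_bundle"))
  pars <- .module_params(bundle, params)
  modules <- lapply(seq_along(bundle$modules), function(m) {
    list(name = bundle$modules[[m]]$name, params = pars[[m]],
         targets = bundle$modules[[m]]$targets)
  })
  net <- init_network(modules, bundle$channel_module, seed = seed)
  C <- nrow(bundle$streams)
  Tt <- ncol(bundle$streams)
  N <- nrow(net$phases)
  codes <- matrix(0L, C, Tt)
  for (m in seq_along(modules)) {
    cols <- net$module_cols[[m]]
    if (!length(cols)) next
    syms <- modules[[m]]$targets$symbol
    sub <- bundle$streams[cols, , drop = FALSE]
    idx <- match(sub, syms)
    idx[sub == "0"] <- 0L
    if (anyNA(idx)) {
      stop(sprintf("stream contains symbols unknown to module '%s'",
                   modules[[m]]$name), call. = FALSE)
    }
    codes[cols, ] <- idx
  }
  want_traj <- length(trajectory_channels) > 0
  rec_states <- record_states || want_traj
  errors <- numeric(Tt)
  channel_errors <- matrix(0, C, Tt)
  state_counts <- if (rec_states) {
    matrix(0, Tt, 3, dimnames = list(NULL, c("locked", "locking", "in_transit")))
  }
  traj <- if (want_traj) {
    list(channels = trajectory_channels,
         phase = array(NA_real_, c(Tt, N, length(trajectory_channels))),
         freq = array(NA_real_, c(Tt, N, length(trajectory_channels))),
         state = array(NA_integer_, c(Tt, N, length(trajectory_channels))),
         reset = array(FALSE, c(Tt, N, length(trajectory_channels))))
  }
  for (t in seq_len(Tt)) {
    res <- .osc_step(net, codes[, t], record_states = rec_states,
                     record_resets = want_traj)
    net <- res$net
    errors[t] <- res$error
    channel_errors[, t] <- res$channel_error
    if (rec_states) state_counts[t, ] <- res$state_counts
    if (want_traj) {
      traj$phase[t, , ] <- net$phases[, trajectory_channels]
      traj$freq[t, , ] <- net$freqs[, trajectory_channels]
      traj$state[t, , ] <- res$states[, trajectory_channels]
      traj$reset[t, , ] <- res$resets[, trajectory_channels]
    }
  }
  structure(
    list(network = net, errors = errors, channel_errors = channel_errors,
         state_counts = if (record_states || want_traj) state_counts,
         trajectory = traj, bundle = bundle, seed = seed),
    class = "osc_run"
  )
}

#' @export
print.osc_run <- function(x, ...) {
  cat(sprintf("<osc_run> %d step(s), %d channel(s); final pooled e(t) = %g\n",
              length(x$errors), nrow(x$channel_errors),
              x$errors[length(x$errors)]))
  invisible(x)
}

#' Learn a sequence (no test item)
#'
#' Convenience wrapper: builds the streams for `repetitions` presentations
#' of `sequence` and runs the network through them.
#'
#' @inheritParams simulate_run
#' @param sequence a sequence object or string accepted by
#'   [unimodal_sequence()] / [crossmodal_sequence()].
#' @param repetitions number of presentations.
#' @param resolution pixel grid side length.
#' @param geometry disc geometry for crossmodal sequences.
#' @return an `osc_run`.
#' @export
learn_sequence <- function(sequence, repetitions = 20, seed = NULL,
                           params = NULL, resolution = 20,
                           geometry = "disjoint", record_states = FALSE,
                           trajectory_channels = integer(0)) {
  sequence <- .as_sequence(sequence)
  bundle <- build_streams(sequence, repetitions, resolution = resolution,
                          geometry = geometry)
  simulate_run(bundle, params = params, seed = seed,
               record_states = record_states,
               trajectory_channels = trajectory_channels)
}

#' Run one congruence-classification trial
#'
#' Presents the cyclic continuation of `sequence` up to the tested item,
#' ending with a congruent or incongruent test item, pools the error
#' signal across all ensembles by summation, and applies the decision rule
#' at the test step: the item is called incongruent iff its error strictly
#' exceeds every earlier error of the trial. The response is *correct*
#' when the decision matches the ground truth of the test item.
#'
#' @inheritParams learn_sequence
#' @param test_index 1-based position of the tested item in the cyclic
#'   continuation; must be at least `length(sequence) + 1`. Defaults to
#'   the first testable item.
#' @param congruent logical ground truth of the test item.
#' @param return_network logical; keep the final network state in the
#'   result.
#' @return an object of class `osc_trial`: list with `decision`
#'   (`"congruent"`/`"incongruent"`), `incongruent` (logical decision),
#'   `correct`, `errors` (full e(t) trace), `test_step`, `sequence`,
#'   `test_index`, `congruent`, and optionally `network`.
#' @export
#' @examples
#' tr <- run_trial("-H-V-V-V-V", test_index = 101, congruent = FALSE,
#'                 seed = 1, resolution = 6)
#' tr$decision
run_trial <- function(sequence, test_index = NULL, congruent = TRUE,
                      seed = NULL, params = NULL, resolution = 20,
                      geometry = "disjoint", return_network = FALSE) {
  sequence <- .as_sequence(sequence)
  if (is.null(test_index)) test_index <- length(sequence$items) + 1L
  bundle <- build_trial_streams(sequence, test_index, congruent,
                                resolution = resolution, geometry = geometry)
  run <- simulate_run(bundle, params = params, seed = seed)
  Tt <- length(run$errors)
  inc <- decide_congruence(run$errors[-Tt], run$errors[Tt])
  structure(
    list(
      decision = if (inc) "incongruent" else "congruent",
      incongruent = inc,
      correct = (inc == !congruent),
      errors = run$errors,
      test_step = Tt,
      sequence = sequence,
      test_index = test_index,
      congruent = congruent,
      seed = seed,
      network = if (return_network) run$network
    ),
    class = "osc_trial"
  )
}

#' @export
print.osc_trial <- function(x, ...) {
  cat(sprintf(
    "<osc_trial> %s, item %d tested (%s): decision %s (%s)\n",
    format(x$sequence), x$test_index,
    if (x$congruent) "congruent" else "incongruent",
    x$decision, if (x$correct) "correct" else "wrong"))
  invisible(x)
}

#' @describeIn run_trial alias emphasizing the two-module (visual +
#'   auditory) configuration; `sequence` must be crossmodal. The auditory
#'   module is initialized in the [5, 6] frequency band by default.
#' @export
run_multimodal <- function(sequence, test_index = NULL, congruent = TRUE,
                           seed = NULL, params = NULL, resolution = 20,
                           geometry = "disjoint", return_network = FALSE) {
  sequence <- crossmodal_sequence(sequence, allow_unimodal = TRUE)
  run_trial(sequence, test_index = test_index, congruent = congruent,
            seed = seed, params = params, resolution = resolution,
            geometry = geometry, return_network = return_network)
}

#' Response accuracy as a function of the tested item
#'
#' Monte-Carlo sweep over sequences, congruent/incongruent test items and
#' random initializations. Run r of every (sequence, test item,
#' congruency) cell uses seed `base_seed + r - 1`, so cells are paired
#' across congruency and sequences. Combined accuracy weights the
#' congruent and incongruent accuracies equally (the test-item ratio is
#' 0.5).
#'
#' @inheritParams run_trial
#' @param sequences list of sequence objects (or strings); e.g.
#'   [enumerate_unimodal()].
#' @param test_indices integer vector of tested item positions.
#' @param n_runs random initializations per cell (100 reproduces the
#'   reference operating point; reduce for quick sweeps).
#' @param base_seed first seed of the shared seed list.
#' @return data.frame with one row per tested item: `test_index`,
#'   `acc_congruent`, `acc_incongruent`, `acc_combined`, `n_trials` (per
#'   congruency).
#' @export
accuracy_curve <- function(sequences, test_indices, n_runs = 100,
                           base_seed = 1, params = NULL, resolution = 20,
                           geometry = "disjoint") {
  stopifnot(n_runs >= 1)
  if (inherits(sequences, c("unimodal_sequence", "crossmodal_sequence"))) {
    sequences <- list(sequences)
  }
  sequences <- lapply(sequences, .as_sequence)
  seeds <- base_seed + seq_len(n_runs) - 1L
  rows <- lapply(test_indices, function(ti) {
    acc <- c("TRUE" = 0, "FALSE" = 0)
    n <- 0L
    for (sq in sequences) {
      for (cong in c(TRUE, FALSE)) {
        bundle <- build_trial_streams(sq, ti, cong, resolution = resolution,
                                      geometry = geometry)
        for (s in seeds) {
          run <- simulate_run(bundle, params = params, seed = s)
          Tt <- length(run$errors)
          inc <- decide_congruence(run$errors[-Tt], run$errors[Tt])
          acc[[as.character(cong)]] <-
            acc[[as.character(cong)]] + (inc == !cong)
        }
      }
      n <- n + n_runs
    }
    data.frame(
      test_index = ti,
      acc_congruent = acc[["TRUE"]] / n,
      acc_incongruent = acc[["FALSE"]] / n,
      acc_combined = (acc[["TRUE"]] + acc[["FALSE"]]) / (2 * n),
      n_trials = n
    )
  })
  do.call(rbind, rows)
}

#' Per-sequence accuracy and entropy grouping
#'
#' Combined accuracy of every one of the 32 unimodal sequences, averaged
#' over the given tested-item range, plus group means over the three
#' entropy levels (0, ~0.722 and ~0.971 bits) that quantify sequence
#' complexity.
#'
#' @inheritParams accuracy_curve
#' @return list of class `per_sequence_accuracy` with elements
#'   `per_sequence` (data.frame: `code`, `sequence`, `entropy`,
#'   `accuracy`, `n_trials`) and `by_entropy` (data.frame: `entropy`,
#'   `accuracy`, `n_sequences`).
#' @export
per_sequence_accuracy <- function(test_indices = 6:20, n_runs = 100,
                                  base_seed = 1, params = NULL,
                                  resolution = 20) {
  seqs <- enumerate_unimodal()
  seeds <- base_seed + seq_len(n_runs) - 1L
  rows <- lapply(seqs, function(sq) {
    hits <- 0L
    n <- 0L
    for (ti in test_indices) {
      for (cong in c(TRUE, FALSE)) {
        bundle <- build_trial_streams(sq, ti, cong, resolution = resolution)
        for (s in seeds) {
          run <- simulate_run(bundle, params = params, seed = s)
          Tt <- length(run$errors)
          inc <- decide_congruence(run$errors[-Tt], run$errors[Tt])
          hits <- hits + (inc == !cong)
          n <- n + 1L
        }
      }
    }
    data.frame(code = sq$code, sequence = format(sq),
               entropy = sequence_entropy(sq), accuracy = hits / n,
               n_trials = n)
  })
  per_sequence <- do.call(rbind, rows)
  ent <- round(per_sequence$entropy, 6)
  by_entropy <- do.call(rbind, lapply(sort(unique(ent)), function(e) {
    sel <- ent == e
    data.frame(entropy = e,
               accuracy = mean(per_sequence$accuracy[sel]),
               n_sequences = sum(sel))
  }))
  structure(list(per_sequence = per_sequence, by_entropy = by_entropy),
            class = "per_sequence_accuracy")
}

#' @export
print.per_sequence_accuracy <- function(x, ...) {
  cat("<per_sequence_accuracy>\n")
  print(x$by_entropy, row.names = FALSE)
  invisible(x)
}
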