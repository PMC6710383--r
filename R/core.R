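#' Initialize a network of oscillator ensembles
#'
#' A network holds one ensemble of `N` phase oscillators per input channel.
#' Channels are grouped into *modules* (e.g. a visual and an auditory
#' module) that share a parameter set and a symbol-to-target-phase map.
#' Initial phases are uniform on `[0, 2*pi)`; initial frequencies are
#' uniform on the module's `freq_init` band; all reset clocks start at 0.
#'
#' @param modules list of modules, each a list with elements `name`
#'   (character), `params` (an [model_params()] object) and `targets` (a
#'   [target_map()]). All modules must share the same `n_oscillators`.
#' @param channel_module integer vector, one entry per channel, indexing
#'   into `modules`.
#' @param seed optional integer seed; given the seed the state is fully
#'   deterministic.
#' @return an object of class `osc_network` with fields `phases`, `freqs`,
#'   `last_reset` (N x C matrices), `t` (current time step), `module`
#'   (channel-to-module index) and `modules`.
#' @seealso [init_ensemble()] for the single-channel case,
#'   [step_ensemble()] to drive the network.
#' @export
init_network <- function(modules, channel_module, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  channel_module <- as.integer(channel_module)
  C <- length(channel_module)
  if (C < 1) stop("need at least one channel", call. = FALSE)
  if (any(channel_module < 1 | channel_module > length(modules))) {
    stop("channel_module indexes outside 'modules'", call. = FALSE)
  }
  ns <- vapply(modules, function(m) m$params$n_oscillators, integer(1))
  if (length(unique(ns)) != 1) {
    stop("all modules must share n_oscillators", call. = FALSE)
  }
  N <- ns[1]
  phases <- matrix(stats::runif(N * C, 0, 2 * pi), N, C)
  freqs <- matrix(0, N, C)
  for (m in seq_along(modules)) {
    cols <- which(channel_module == m)
    if (!length(cols)) next
    fi <- modules[[m]]$params$freq_init
    freqs[, cols] <- stats::runif(N * length(cols), fi[1], fi[2])
  }
  structure(
    list(
      phases = phases,
      freqs = freqs,
      last_reset = matrix(0, N, C),
      t = 0L,
      module = channel_module,
      module_cols = lapply(seq_along(modules),
                           function(m) which(channel_module == m)),
      modules = modules
    ),
    class = "osc_network"
  )
}

#' Initialize a single oscillator ensemble
#'
#' Convenience wrapper around [init_network()] for one channel.
#'
#' @param params an [model_params()] object.
#' @param targets a [target_map()]; defaults to the binary black/white map.
#' @param seed integer seed; defaults to `params$seed`. Two calls with the
#'   same seed return identical states.
#' @return an object of class `c("osc_ensemble", "osc_network")` with one
#'   channel; `phases`, `freqs` and `last_reset` are `N x 1` matrices.
#' @export
#' @examples
#' e <- init_ensemble(model_params(), seed = 1)
#' range(e$freqs)  # inside [0.01, 1]
init_ensemble <- function(params, targets = unimodal_targets(),
                          seed = params$seed) {
  net <- init_network(
    modules = list(list(name = "ensemble", params = params, targets = targets)),
    channel_module = 1L,
    seed = seed
  )
  class(net) <- c("osc_ensemble", class(net))
  net
}

#' @export
print.osc_network <- function(x, ...) {
  cat(sprintf("<osc_network> %d channel(s) x %d oscillators, t = %d\n",
              ncol(x$phases), nrow(x$phases), x$t))
  for (m in seq_along(x$modules)) {
    cat(sprintf("  module %d '%s': %d channel(s), symbols {%s}\n",
                m, x$modules[[m]]$name, length(x$module_cols[[m]]),
                paste(x$modules[[m]]$targets$symbol, collapse = ", ")))
  }
  invisible(x)
}

#' @export
as.data.frame.osc_network <- function(x, ...) {
  N <- nrow(x$phases); C <- ncol(x$phases)
  data.frame(
    channel = rep(seq_len(C), each = N),
    oscillator = rep(seq_len(N), C),
    phase = as.vector(x$phases),
    freq = as.vector(x$freqs),
    last_reset = as.vector(x$last_reset)
  )
}

# Eq.-1 phase advance for the whole network: phi <- phi + 2*pi*f + eta,
# wrapped into [0, 2*pi). Returns the new phase matrix only.
.advanced_phases <- function(net) {
  ph <- net$phases + (2 * pi) * net$freqs
  N <- nrow(ph)
  for (m in seq_along(net$modules)) {
    sd <- net$modules[[m]]$params$noise_std
    cols <- net$module_cols[[m]]
    if (sd > 0 && length(cols)) {
      ph[, cols] <- ph[, cols] + stats::rnorm(N * length(cols), 0, sd)
    }
  }
  ph %% (2 * pi)
}

#' Advance all phases by one time step (no learning)
#'
#' Applies the free-running phase map `phi(t+1) = phi(t) + 2*pi*f(t) + eta`
#' with Gaussian noise `eta`, wraps into `[0, 2*pi)` and increments the
#' clock. Frequencies are unchanged. This is the update every oscillator
#' receives on blank input and that locked/in-transit oscillators receive
#' always; [step_ensemble()] combines it with the learning rule.
#'
#' @param state an `osc_network` (or `osc_ensemble`).
#' @return the advanced state.
#' @export
advance_phases <- function(state) {
  state$phases <- .advanced_phases(state)
  state$t <- state$t + 1L
  state
}

#' Classify oscillator phases as locked / locking / in transit
#'
#' Each phase is compared to its *nearest* target phase by circular
#' distance (ties to the earlier map entry). With distance `d` to that
#' target, the state is `locked` if `d < theta_locked`, `locking` if
#' `theta_locked <= d < theta_locking`, and `in_transit` otherwise.
#'
#' @param phase numeric vector of phases in radians.
#' @param targets a [target_map()].
#' @param params an [model_params()] object supplying the two thresholds.
#' @return data.frame with columns `state` (character) and `symbol` (the
#'   nearest target's symbol).
#' @export
#' @examples
#' classify_state(c(pi / 2, pi / 2 + pi / 12, pi), unimodal_targets(),
#'                model_params())
classify_state <- function(phase, targets, params) {
  if (!inherits(targets, "target_map") || nrow(targets) == 0) {
    stop("targets must be a non-empty target_map", call. = FALSE)
  }
  phase <- wrap_phase(as.numeric(phase))
  D <- vapply(targets$phase, function(a) circ_dist(phase, a),
              numeric(length(phase)))
  D <- matrix(D, nrow = length(phase))
  nearest <- max.col(-D, ties.method = "first")
  d <- D[cbind(seq_along(phase), nearest)]
  state <- ifelse(d < params$theta_locked, "locked",
                  ifelse(d < params$theta_locking, "locking", "in_transit"))
  data.frame(state = state, symbol = targets$symbol[nearest],
             stringsAsFactors = FALSE)
}

#' Learning update for a matching input (phase reset + frequency retune)
#'
#' When the input symbol matches the target an oscillator is locking to,
#' its phase is reset exactly to the target phase and its frequency is
#' corrected by the signed circular phase error scaled by the time since
#' the last reset:
#' `f' = f - wrap(phi - phi_hat) / (2*pi*delta_t)`, with `wrap` the minimal
#' signed difference in `(-pi, pi]`. An oscillator that is repeatedly
#' matched by a period-P input converges to a frequency with `f * P`
#' integer; starting within half a cycle of `1/P` it lands on `1/P`.
#'
#' @param phase,freq current phase (radians) and frequency (cycles/step);
#'   vectors are allowed.
#' @param target_phase target phase of the matched symbol.
#' @param delta_t steps since the oscillator's last phase reset (>= 1;
#'   callers clamp 0 to 1).
#' @return list with components `phase` and `freq`.
#' @export
match_update <- function(phase, freq, target_phase, delta_t) {
  stopifnot(all(delta_t >= 1))
  err <- circ_signed_diff(wrap_phase(phase), target_phase)
  list(
    phase = rep_len(wrap_phase(target_phase), length(err)),
    freq = freq - err / (2 * pi * delta_t)
  )
}

#' Learning update for a mismatching input (phase inversion)
#'
#' When the input differs from the symbol an oscillator is locking (or
#' locked) to, the phase is inverted to `2*pi - phi_hat` and the period is
#' lengthened or shortened so that the oscillator, free-running at its new
#' frequency, reaches the target phase about one sequence item later or
#' earlier than it would have. The frequency part of this rule is stated
#' ambiguously in the literature this model derives from, so three
#' readings are provided; `wrap` below is the minimal signed circular
#' difference in `(-pi, pi]`.
#'
#' * variant `"intent"` (default). Let `n = round(f * dT)` be the number
#'   of full cycles the oscillator completed over the `dT` steps since its
#'   last reset. The frequency is stepped one cycle on the
#'   revisit-harmonic grid so that, free-running at the new frequency, the
#'   oscillator reaches the target phase one recurrence slot later or
#'   earlier over the same interval: `f' = (n - 1)/dT` when the phase
#'   leads the target (`wrap(phi - phi_hat) >= 0`, which includes the
#'   attuned case of a locked oscillator hit by a changed item), and
#'   `f' = (n + 1)/dT` when it lags. A `locked` oscillator always steps
#'   down (its phase error is essentially zero and the violated item must
#'   be found at a later slot). When the shifted cycle count would fall
#'   below one — a period extension would stall the oscillator entirely —
#'   the frequency instead relaxes toward one cycle per revisit interval:
#'   `f' = f - (1/dT) * (f - (2*pi + wrap(phi - phi_hat)) / (2*pi*dT))`.
#'   This reading is dynamically stable and reproduces the reported
#'   attractors (0.5 for a stable two-step input rhythm, 0.1 for an
#'   alternating five-item sequence, the auditory base band in the
#'   crossmodal model); see the package vignette for the analysis.
#' * variant `"a"`: the literal grouping
#'   `f' = f + (1/dT) * (f - (2*pi + wrap(phi - phi_hat)) / (2*pi*dT))`.
#'   Note the leading `+`: this makes the rule a repeller around
#'   `f = (2*pi + wrap(phi - phi_hat))/(2*pi*dT)`, which collapses or
#'   explodes frequencies under repeated mismatches.
#' * variant `"b"`: the alternative grouping with the error taken relative
#'   to the inverted target,
#'   `f' = f + (1/dT) * (f - wrap(phi - (2*pi - phi_hat)) / (2*pi*dT))`;
#'   unstable for the same reason as `"a"`.
#'
#' @inheritParams match_update
#' @param variant `"intent"`, `"a"` or `"b"`.
#' @param locked logical (vectorized); whether the oscillator was in the
#'   locked state when the mismatching input arrived. Only used by the
#'   `"intent"` variant, which always lengthens the period of a locked
#'   oscillator.
#' @return list with components `phase` and `freq`.
#' @export
mismatch_update <- function(phase, freq, target_phase, delta_t,
                            variant = c("intent", "a", "b"),
                            locked = FALSE) {
  variant <- match.arg(variant)
  stopifnot(all(delta_t >= 1))
  phase <- wrap_phase(phase)
  inv <- wrap_phase(2 * pi - target_phase)
  two_pi <- 2 * pi
  if (variant == "intent") {
    delta <- circ_signed_diff(phase, target_phase)
    n_cyc <- round(freq * delta_t)
    soft <- freq - (1 / delta_t) * (freq - (two_pi + delta) / (two_pi * delta_t))
    step <- ifelse(locked | delta >= 0, 1, -1)
    shifted <- n_cyc - step
    f_new <- ifelse(n_cyc >= 1 & shifted >= 1, shifted / delta_t, soft)
  } else if (variant == "a") {
    delta <- circ_signed_diff(phase, target_phase)
    f_new <- freq + (1 / delta_t) * (freq - (two_pi + delta) / (two_pi * delta_t))
  } else {
    dpsi <- circ_signed_diff(phase, inv)
    f_new <- freq + (1 / delta_t) * (freq - dpsi / (two_pi * delta_t))
  }
  list(phase = rep_len(inv, length(f_new)), freq = f_new)
}

# One full network step on integer-coded input.
#
# code: integer vector, one entry per channel; 0 = blank, k >= 1 indexes
# the k-th symbol of the channel's module target map.
# Returns list(net, error, channel_error, state_counts?, states?, resets?).
.osc_step <- function(net, code, record_states = FALSE,
                      record_resets = FALSE) {
  two_pi <- 2 * pi
  t1 <- net$t + 1L
  N <- nrow(net$phases)
  C <- ncol(net$phases)
  ph <- .advanced_phases(net)
  freqs <- net$freqs
  lr <- net$last_reset
  chan_err <- numeric(C)
  state_counts <- NULL
  states_out <- if (record_states) matrix(NA_integer_, N, C)
  resets_out <- if (record_resets) matrix(FALSE, N, C)

  for (m in seq_along(net$modules)) {
    mod <- net$modules[[m]]
    cols <- net$module_cols[[m]]
    if (!length(cols)) next
    pars <- mod$params
    tp <- mod$targets$phase
    K <- length(tp)
    active_any <- any(code[cols] > 0L)
    if (!record_states && !active_any) next
    want <- if (record_states) cols else cols[code[cols] > 0L]
    nw <- length(want)
    P <- ph[, want, drop = FALSE]
    n_el <- N * nw
    Dm <- vapply(tp, function(a) {
      dd <- abs(P - a)
      pmin(dd, two_pi - dd)
    }, numeric(n_el))
    Dm <- matrix(Dm, nrow = n_el, ncol = K)
    nearest <- max.col(-Dm, ties.method = "first")
    d <- Dm[cbind(seq_len(n_el), nearest)]
    locked <- d < pars$theta_locked
    locking <- !locked & d < pars$theta_locking
    if (record_states) {
      st <- ifelse(locked, 1L, ifelse(locking, 2L, 3L))
      states_out[, want] <- st
    }
    if (!active_any) next
    S <- rep(code[want], each = N)
    act <- S > 0L
    upd_match <- locking & act & (nearest == S)
    upd_mis <- (locking | locked) & act & (nearest != S)
    upd <- upd_match | upd_mis
    if (!any(upd)) next
    dtv <- pmax(t1 - as.vector(lr[, want, drop = FALSE]), 1)
    chan_err[want] <- colSums(matrix(dtv * upd, N))
    Pv <- as.vector(P)
    fv <- as.vector(freqs[, want, drop = FALSE])
    tpn <- tp[nearest]
    if (any(upd_match)) {
      err <- circ_signed_diff(Pv[upd_match], tpn[upd_match])
      fv[upd_match] <- fv[upd_match] - err / (two_pi * dtv[upd_match])
      Pv[upd_match] <- tpn[upd_match]
    }
    if (any(upd_mis)) {
      tpm <- tpn[upd_mis]
      inv <- (two_pi - tpm) %% two_pi
      dts <- dtv[upd_mis]
      f0 <- fv[upd_mis]
      locked_mis <- locked[upd_mis]
      if (pars$eq5_variant == "intent") {
        delta <- circ_signed_diff(Pv[upd_mis], tpm)
        n_cyc <- round(f0 * dts)
        soft <- f0 - (1 / dts) * (f0 - (two_pi + delta) / (two_pi * dts))
        stp <- ifelse(locked_mis | delta >= 0, 1, -1)
        shifted <- n_cyc - stp
        fv[upd_mis] <- ifelse(n_cyc >= 1 & shifted >= 1, shifted / dts, soft)
      } else if (pars$eq5_variant == "a") {
        delta <- circ_signed_diff(Pv[upd_mis], tpm)
        fv[upd_mis] <- f0 + (1 / dts) * (f0 - (two_pi + delta) / (two_pi * dts))
      } else {
        dpsi <- circ_signed_diff(Pv[upd_mis], inv)
        fv[upd_mis] <- f0 + (1 / dts) * (f0 - dpsi / (two_pi * dts))
      }
      Pv[upd_mis] <- inv
    }
    fv[upd] <- pmax(fv[upd], pars$freq_floor)
    lrv <- as.vector(lr[, want, drop = FALSE])
    lrv[upd] <- t1
    ph[, want] <- Pv
    freqs[, want] <- fv
    lr[, want] <- lrv
    if (record_resets) {
      rv <- resets_out[, want, drop = FALSE]
      rv[matrix(upd, N)] <- TRUE
      resets_out[, want] <- rv
    }
  }

  net$phases <- ph
  net$freqs <- freqs
  net$last_reset <- lr
  net$t <- t1
  if (record_states) {
    state_counts <- c(
      locked = sum(states_out == 1L),
      locking = sum(states_out == 2L),
      in_transit = sum(states_out == 3L)
    )
  }
  list(net = net, error = sum(chan_err), channel_error = chan_err,
       state_counts = state_counts, states = states_out,
       resets = resets_out)
}

# Map per-channel character symbols to integer codes for .osc_step().
.code_input <- function(net, input) {
  C <- ncol(net$phases)
  input <- as.character(input)
  if (length(input) != C) {
    stop(sprintf("input must supply one symbol per channel (%d)", C),
         call. = FALSE)
  }
  code <- integer(C)
  for (m in seq_along(net$modules)) {
    cols <- net$module_cols[[m]]
    if (!length(cols)) next
    syms <- net$modules[[m]]$targets$symbol
    idx <- match(input[cols], syms)
    idx[input[cols] == "0"] <- 0L
    if (anyNA(idx)) {
      bad <- unique(input[cols][is.na(idx)])
      stop(sprintf("unknown input symbol(s) for module '%s': %s",
                   net$modules[[m]]$name, paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    code[cols] <- idx
  }
  code
}

#' Drive a network one time step with an input symbol per channel
#'
#' Performs one full update: (1) every oscillator advances by the noisy
#' phase map; (2) on non-blank input, every oscillator whose post-advance
#' state is *locking* receives [match_update()] if the input matches its
#' nearest target and [mismatch_update()] otherwise, and every *locked*
#' oscillator whose nearest target mismatches the input also receives the
#' mismatch update (so that violations of an already-learned rhythm
#' re-trigger tuning); in-transit oscillators are untouched; (3) each
#' updated oscillator counts as a phase reset and its reset clock restarts;
#' (4) the error signal is `e(t) = sum_i delta_i(t) * DeltaT_i` with
#' `DeltaT_i` the steps since oscillator i's last reset, evaluated before
#' the reset is recorded and clamped to at least 1. Blank input (`"0"`)
#' performs only the phase advance and yields `e(t) = 0`.
#'
#' @param state an `osc_network` or `osc_ensemble`.
#' @param input character vector of input symbols, one per channel (`"0"`
#'   for no input). For a single-channel ensemble a single symbol.
#' @param record_states logical; also classify and return every
#'   oscillator's state label.
#' @return list with elements `state` (the updated network) and `result`,
#'   itself a list with `error` (pooled e(t)), `channel_error`, `resets`
#'   (N x C logical matrix of reset indicators) and, if requested,
#'   `states` (N x C character matrix) and `state_counts`.
#' @export
#' @examples
#' e <- init_ensemble(model_params(), seed = 1)
#' out <- step_ensemble(e, "W")
#' out$result$error
step_ensemble <- function(state, input, record_states = FALSE) {
  code <- .code_input(state, input)
  res <- .osc_step(state, code, record_states = record_states,
                   record_resets = TRUE)
  states <- NULL
  if (record_states) {
    states <- matrix(c("locked", "locking", "in_transit")[res$states],
                     nrow(res$states), ncol(res$states))
  }
  list(
    state = res$net,
    result = list(
      error = res$error,
      channel_error = res$channel_error,
      resets = res$resets,
      states = states,
      state_counts = res$state_counts
    )
  )
}

#' Decide whether the current item is an incongruent continuation
#'
#' The current item is flagged incongruent if and only if its error signal
#' strictly exceeds every error observed earlier in the trial:
#' `e(t) > max(e(1), ..., e(t-1))`. With no prior history the item is
#' accepted as congruent (the maximum over an empty set is undefined, and
#' the model is only queried after at least one presentation).
#'
#' @param history numeric vector of previous per-step errors (may be empty).
#' @param current_error the error signal at the test step.
#' @return `TRUE` if incongruent, `FALSE` if congruent.
#' @export
#' @examples
#' decide_congruence(c(50, 12, 3), 20)  # FALSE
#' decide_congruence(c(50, 12, 3), 60)  # TRUE
decide_congruence <- function(history, current_error) {
  stopifnot(length(current_error) == 1)
  if (length(history) == 0) return(FALSE)
  current_error > max(history)
}
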