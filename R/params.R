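#' Model parameters for an oscillator ensemble
#'
#' Bundles the tuning constants of the phase-locked-loop ensemble. The
#' defaults are the standard operating point of the model: ensembles of 100
#' oscillators, a locked band of pi/60 radians and a locking band of pi/6
#' radians around each target phase, phase noise with standard deviation
#' 1e-10 radians per step, and initial frequencies drawn uniformly from
#' [0.01, 1] cycles per time step (the visual band; see [auditory_params()]
#' for the auditory band [5, 6]).
#'
#' @param n_oscillators number of oscillators per ensemble (N).
#' @param theta_locked radians; an oscillator within this circular distance
#'   of a target phase at input time is *locked* (stable, not retuned on a
#'   matching input).
#' @param theta_locking radians; within this distance (but beyond
#'   `theta_locked`) the oscillator is *locking* and is retuned by every
#'   input. Beyond it the oscillator is *in transit* and left alone.
#' @param noise_std standard deviation (radians) of the Gaussian phase
#'   noise added at every step.
#' @param freq_init length-2 numeric, lower/upper bound (cycles per time
#'   step) of the uniform distribution of initial frequencies.
#' @param freq_floor frequencies are clamped to this small positive floor
#'   after learning updates, since a non-positive frequency has no reading
#'   in the phase-advance map.
#' @param eq5_variant `"intent"` (default), `"a"` or `"b"`; which reading
#'   of the mismatch-frequency update to use (see [mismatch_update()]).
#' @param seed optional integer; default RNG seed used by
#'   [init_ensemble()] when no explicit seed is given.
#' @return an object of class `osc_params`.
#' @seealso [auditory_params()], [init_ensemble()], [step_ensemble()]
#' @export
#' @examples
#' p <- model_params()
#' p$theta_locked * 60 / pi  # 1
model_params <- function(n_oscillators = 100,
                         theta_locked = pi / 60,
                         theta_locking = pi / 6,
                         noise_std = 1e-10,
                         freq_init = c(0.01, 1),
                         freq_floor = 1e-6,
                         eq5_variant = c("intent", "a", "b"),
                         seed = NULL) {
  eq5_variant <- match.arg(eq5_variant)
  stopifnot(
    length(n_oscillators) == 1, n_oscillators >= 1,
    n_oscillators == as.integer(n_oscillators)
  )
  if (!(theta_locked > 0 && theta_locked < theta_locking && theta_locking < pi)) {
    stop("need 0 < theta_locked < theta_locking < pi", call. = FALSE)
  }
  if (noise_std < 0) stop("noise_std must be >= 0", call. = FALSE)
  if (!(length(freq_init) == 2 && freq_init[1] > 0 &&
        freq_init[1] < freq_init[2])) {
    stop("freq_init must be increasing positive bounds", call. = FALSE)
  }
  if (freq_floor <= 0) stop("freq_floor must be > 0", call. = FALSE)
  structure(
    list(
      n_oscillators = as.integer(n_oscillators),
      theta_locked = theta_locked,
      theta_locking = theta_locking,
      noise_std = noise_std,
      freq_init = as.numeric(freq_init),
      freq_floor = freq_floor,
      eq5_variant = eq5_variant,
      seed = if (is.null(seed)) NULL else as.integer(seed)
    ),
    class = "osc_params"
  )
}

#' Parameters for the auditory module
#'
#' Identical to [model_params()] except that initial frequencies are drawn
#' from the auditory base band [5, 6] cycles per time step, five times the
#' upper edge of the visual band.
#'
#' @param ... overrides passed to [model_params()].
#' @return an `osc_params` object.
#' @export
auditory_params <- function(...) {
  args <- list(...)
  if (is.null(args$freq_init)) args$freq_init <- c(5, 6)
  do.call(model_params, args)
}

#' @export
print.osc_params <- function(x, ...) {
  cat("<osc_params>\n")
  cat(sprintf("  N = %d oscillators\n", x$n_oscillators))
  cat(sprintf("  theta_locked = %.5g, theta_locking = %.5g rad\n",
              x$theta_locked, x$theta_locking))
  cat(sprintf("  noise_std = %g rad, freq_init = [%g, %g] cycles/step\n",
              x$noise_std, x$freq_init[1], x$freq_init[2]))
  cat(sprintf("  eq5_variant = %s\n", x$eq5_variant))
  invisible(x)
}

#' Symbol-to-target-phase map
#'
#' Associates each non-blank input symbol with the phase an oscillator must
#' occupy at input time to have "predicted" that symbol. The blank symbol
#' `"0"` is reserved and may not be mapped.
#'
#' @param symbols character vector of unique input symbols.
#' @param phases numeric vector of target phases in `[0, 2*pi)`.
#' @return an object of class `target_map` (data.frame with columns
#'   `symbol`, `phase`).
#' @export
#' @examples
#' unimodal_targets()
target_map <- function(symbols, phases) {
  symbols <- as.character(symbols)
  if (length(symbols) == 0) stop("target map must be non-empty", call. = FALSE)
  if (anyDuplicated(symbols)) stop("symbols must be unique", call. = FALSE)
  if ("0" %in% symbols) stop('"0" is reserved for no input', call. = FALSE)
  if (length(phases) != length(symbols)) {
    stop("symbols and phases must have equal length", call. = FALSE)
  }
  if (any(phases < 0 | phases >= 2 * pi)) {
    stop("target phases must lie in [0, 2*pi)", call. = FALSE)
  }
  structure(
    data.frame(symbol = symbols, phase = as.numeric(phases),
               stringsAsFactors = FALSE),
    class = c("target_map", "data.frame")
  )
}

#' @describeIn target_map default map for binary visual input:
#'   black -> pi/2, white -> 3*pi/2.
#' @export
unimodal_targets <- function() {
  target_map(c("B", "W"), c(pi / 2, 3 * pi / 2))
}

#' @describeIn target_map map for the visual channels of the crossmodal
#'   model: the single symbol `"bright"` at phase 3*pi/2.
#' @export
crossmodal_visual_targets <- function() {
  target_map("bright", 3 * pi / 2)
}

#' @describeIn target_map map for the auditory channel: low pitch -> pi/2,
#'   high pitch -> 3*pi/2.
#' @export
auditory_targets <- function() {
  target_map(c("low", "high"), c(pi / 2, 3 * pi / 2))
}
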