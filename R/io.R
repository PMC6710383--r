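#' Export run artifacts as plain text
#'
#' Writers for the standard artifacts of a simulation run: the pooled
#' error trace, per-oscillator trajectories, the final oscillator state,
#' and phase-frequency histograms. All formats are plain CSV/JSON for
#' language-agnostic reuse.
#'
#' @param run an `osc_run`.
#' @param path output file path.
#' @return the path, invisibly.
#' @name oscseq-io
NULL

#' @rdname oscseq-io
#' @export
write_error_trace <- function(run, path) {
  stopifnot(inherits(run, "osc_run"))
  utils::write.csv(data.frame(t = seq_along(run$errors), error = run$errors),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname oscseq-io
#' @export
write_trajectory <- function(run, path) {
  stopifnot(inherits(run, "osc_run"))
  tr <- run$trajectory
  if (is.null(tr)) {
    stop("run was recorded without trajectory_channels", call. = FALSE)
  }
  Tt <- dim(tr$phase)[1]
  N <- dim(tr$phase)[2]
  lab <- c("locked", "locking", "in_transit")
  rows <- lapply(seq_along(tr$channels), function(k) {
    data.frame(
      t = rep(seq_len(Tt), N),
      channel = tr$channels[k],
      oscillator_id = rep(seq_len(N), each = Tt),
      phase = as.vector(tr$phase[, , k]),
      freq = as.vector(tr$freq[, , k]),
      state = lab[as.vector(tr$state[, , k])],
      reset = as.integer(as.vector(tr$reset[, , k]))
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname oscseq-io
#' @param x an `osc_network` (for `write_state_csv`) or a `pf_histogram`
#'   (for `write_histogram_json`).
#' @export
write_state_csv <- function(x, path) {
  net <- .as_network(x)
  utils::write.csv(as.data.frame(net), path, row.names = FALSE)
  invisible(path)
}

#' @rdname oscseq-io
#' @export
read_state_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("channel", "oscillator", "phase", "freq")
  if (!all(need %in% names(df))) {
    stop("state file must have columns channel, oscillator, phase, freq",
         call. = FALSE)
  }
  C <- max(df$channel)
  N <- max(df$oscillator)
  ph <- matrix(NA_real_, N, C)
  fr <- matrix(NA_real_, N, C)
  ph[cbind(df$oscillator, df$channel)] <- df$phase
  fr[cbind(df$oscillator, df$channel)] <- df$freq
  lr <- matrix(0, N, C)
  if ("last_reset" %in% names(df)) {
    lr[cbind(df$oscillator, df$channel)] <- df$last_reset
  }
  structure(
    list(phases = ph, freqs = fr, last_reset = lr, t = NA_integer_,
         module = rep(1L, C), module_cols = list(seq_len(C)),
         modules = list(list(name = "loaded", params = model_params(),
                             targets = unimodal_targets()))),
    class = "osc_network"
  )
}

#' @rdname oscseq-io
#' @export
write_histogram_json <- function(x, path) {
  stopifnot(inherits(x, "pf_histogram"))
  obj <- list(
    mode = attr(x, "mode_"),
    phase_bin = attr(x, "phase_bin"),
    freq_bin = attr(x, "freq_bin"),
    n = attr(x, "n"),
    phase_edges = as.numeric(rownames(x)),
    freq_centers = as.numeric(colnames(x)),
    counts = unname(apply(unclass(x), 1, function(r) r, simplify = FALSE))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Experiment run configuration
#'
#' A serializable description of a reproducible run: which experiment,
#' which sequences, which tested items, how many runs, the base seed, the
#' pixel grid, and the mismatch-rule variant. Configurations round-trip
#' through YAML (default) or JSON.
#'
#' @param experiment free-form name.
#' @param sequence_set `"unimodal"`, `"crossmodal"`, or `"explicit"`.
#' @param sequences character vector of sequence strings (used when
#'   `sequence_set = "explicit"`).
#' @param test_indices integer vector of tested item positions.
#' @param n_runs runs per cell.
#' @param base_seed first RNG seed.
#' @param resolution pixel grid side length.
#' @param geometry disc geometry.
#' @param eq5_variant `"a"` or `"b"`.
#' @param out_dir output directory.
#' @return a `run_config` list.
#' @export
run_config <- function(experiment = "run", sequence_set = "unimodal",
                       sequences = character(0), test_indices = 6:20,
                       n_runs = 100, base_seed = 1, resolution = 20,
                       geometry = "disjoint", eq5_variant = "a",
                       out_dir = ".") {
  structure(
    list(experiment = experiment, sequence_set = sequence_set,
         sequences = as.character(sequences),
         test_indices = as.integer(test_indices),
         n_runs = as.integer(n_runs), base_seed = as.integer(base_seed),
         resolution = as.integer(resolution), geometry = geometry,
         eq5_variant = eq5_variant, out_dir = out_dir),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path file path; `.yaml`/`.yml` or `.json`.
#' @export
save_run_config <- function(config, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA)
  } else {
    yaml::write_yaml(unclass(config), path, precision = 15)
  }
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(run_config, raw)
}
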