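# Extract the osc_network from either a network or an osc_run.
.as_network <- function(x) {
  if (inherits(x, "osc_network")) return(x)
  if (inherits(x, "osc_run")) return(x$network)
  stop("expected an osc_network or osc_run", call. = FALSE)
}

#' Two-dimensional phase-frequency histogram of an ensemble
#'
#' Bins the (phase, frequency) pairs of the oscillators of the selected
#' channels. Phase bins have width `pi/12` over `[0, 2*pi)`; frequency
#' bins have width 0.1 with centers at multiples of 0.1 (a frequency `f`
#' falls into the bin whose center is nearest).
#'
#' @param x an `osc_network` / `osc_ensemble` or an `osc_run`.
#' @param channels integer vector of channels to pool (default: all).
#' @param mode `"raw"` (counts, summing to the number of binned
#'   oscillators) or `"relative"` (counts divided by the maximum bin).
#' @param phase_bin,freq_bin bin widths (radians; cycles per step).
#' @param freq_max upper frequency covered by the binning (defaults to the
#'   data maximum); pass a common value to make histograms comparable
#'   across channels.
#' @return a `pf_histogram`: numeric matrix (phase bins x frequency bins)
#'   with the frequency-bin centers as column names; attributes `mode`,
#'   `phase_bin`, `freq_bin`, `n`.
#' @export
#' @examples
#' e <- init_ensemble(model_params(), seed = 1)
#' h <- phase_freq_histogram(e)
#' sum(h)  # 100
phase_freq_histogram <- function(x, channels = NULL,
                                 mode = c("raw", "relative"),
                                 phase_bin = pi / 12, freq_bin = 0.1,
                                 freq_max = NULL) {
  mode <- match.arg(mode)
  net <- .as_network(x)
  if (is.null(channels)) channels <- seq_len(ncol(net$phases))
  ph <- as.vector(net$phases[, channels, drop = FALSE])
  fr <- as.vector(net$freqs[, channels, drop = FALSE])
  if (!length(ph)) stop("no oscillators selected", call. = FALSE)
  n_phase <- max(1L, round(2 * pi / phase_bin))
  pidx <- pmin(floor(wrap_phase(ph) / phase_bin) + 1L, n_phase)
  if (is.null(freq_max)) freq_max <- max(fr)
  kmax <- max(0L, floor(freq_max / freq_bin + 0.5))
  fidx <- pmin(floor(fr / freq_bin + 0.5), kmax) + 1L
  counts <- matrix(0, n_phase, kmax + 1L)
  tab <- tabulate(pidx + (fidx - 1L) * n_phase, nbins = n_phase * (kmax + 1L))
  counts[] <- tab
  dimnames(counts) <- list(
    phase = as.character(round((seq_len(n_phase) - 1L) * phase_bin, 6)),
    freq = as.character(round((0:kmax) * freq_bin, 6))
  )
  n <- length(ph)
  if (mode == "relative" && max(counts) > 0) counts <- counts / max(counts)
  structure(counts, class = c("pf_histogram", "matrix"), mode_ = mode,
            phase_bin = phase_bin, freq_bin = freq_bin, n = n)
}

#' @export
print.pf_histogram <- function(x, ...) {
  cat(sprintf("<pf_histogram> %d phase x %d freq bins (%s, n = %d)\n",
              nrow(x), ncol(x), attr(x, "mode_"), attr(x, "n")))
  invisible(x)
}

#' @export
plot.pf_histogram <- function(x, ...) {
  freq <- as.numeric(colnames(x))
  phase <- as.numeric(rownames(x)) + attr(x, "phase_bin") / 2
  graphics::image(freq, phase, t(unclass(x)), xlab = "frequency (cycles/step)",
                  ylab = "phase (rad)", ...)
  invisible(x)
}

#' Dominant frequency of a phase-frequency histogram
#'
#' Center of the frequency bin with the largest marginal count; ties go to
#' the lowest frequency.
#'
#' @param hist a [phase_freq_histogram()].
#' @return frequency-bin center (cycles per time step).
#' @export
dominant_frequency <- function(hist) {
  stopifnot(inherits(hist, "pf_histogram"))
  marg <- colSums(hist)
  if (all(marg == 0)) stop("empty histogram", call. = FALSE)
  as.numeric(colnames(hist))[which.max(marg)]
}

# Per-channel relative histograms on shared binning.
.channel_histograms <- function(net, channels, phase_bin = pi / 12,
                                freq_bin = 0.1) {
  fmax <- max(net$freqs)
  lapply(channels, function(ch) {
    phase_freq_histogram(net, channels = ch, mode = "relative",
                         phase_bin = phase_bin, freq_bin = freq_bin,
                         freq_max = fmax)
  })
}

#' Group channels into clusters of similar phase-frequency tuning
#'
#' After learning, ensembles that received the same input stream attune to
#' the same combinations of phase and frequency; grouping channels by the
#' similarity of their phase-frequency histograms therefore recovers the
#' functional segmentation of the stimulus. Channels that never received
#' input keep their random initial distribution and are assigned the
#' reserved background cluster 1 by construction.
#'
#' Two modes are available: `"similarity"` (default) computes cosine
#' similarity between flattened relative histograms and merges channels by
#' single linkage over the graph of similarities at or above `threshold`;
#' `"oracle"` labels channels by their exact input-stream pattern and
#' serves as ground truth for validating the similarity clustering.
#'
#' @param x an `osc_network` or `osc_run` holding the attuned state.
#' @param bundle the `stream_bundle` the network was driven with (used to
#'   identify background channels, and the patterns in oracle mode).
#' @param mode `"similarity"` or `"oracle"`.
#' @param threshold cosine-similarity threshold for merging (default 0.9).
#' @param phase_bin,freq_bin histogram binning.
#' @return a `cluster_map`: list with `labels` (integer per channel,
#'   contiguous from 1; background = 1 when present), `n_clusters`,
#'   `mode`, and `grid` (labels of the pixel channels as a resolution x
#'   resolution matrix, when the bundle has a pixel grid).
#' @export
cluster_ensembles <- function(x, bundle, mode = c("similarity", "oracle"),
                              threshold = 0.9, phase_bin = pi / 12,
                              freq_bin = 0.1) {
  mode <- match.arg(mode)
  net <- .as_network(x)
  C <- nrow(bundle$streams)
  if (ncol(net$phases) != C) {
    stop("network and bundle disagree on channel count", call. = FALSE)
  }
  background <- apply(bundle$streams == "0", 1, all)
  labels <- integer(C)
  if (mode == "oracle") {
    pat <- apply(bundle$streams, 1, paste, collapse = "")
    fg <- which(!background)
    labels[background] <- 1L
    offset <- if (any(background)) 1L else 0L
    labels[fg] <- offset + as.integer(factor(pat[fg], levels = unique(pat[fg])))
  } else {
    fg <- which(!background)
    labels[background] <- 1L
    offset <- if (any(background)) 1L else 0L
    if (length(fg)) {
      hists <- .channel_histograms(net, fg, phase_bin, freq_bin)
      X <- do.call(rbind, lapply(hists, as.vector))
      nrm <- sqrt(rowSums(X^2))
      nrm[nrm == 0] <- 1
      Xn <- X / nrm
      sim <- Xn %*% t(Xn)
      adj <- sim >= threshold
      comp <- integer(length(fg))
      cur <- 0L
      for (i in seq_along(fg)) {
        if (comp[i] == 0L) {
          cur <- cur + 1L
          queue <- i
          comp[i] <- cur
          while (length(queue)) {
            v <- queue[[1]]
            queue <- queue[-1]
            nb <- which(adj[v, ] & comp == 0L)
            comp[nb] <- cur
            queue <- c(queue, nb)
          }
        }
      }
      labels[fg] <- offset + comp
    }
  }
  grid <- NULL
  if (!is.na(bundle$resolution)) {
    res <- bundle$resolution
    grid <- matrix(labels[seq_len(res^2)], res, res)
  }
  structure(
    list(labels = labels, n_clusters = length(unique(labels)), mode = mode,
         threshold = if (mode == "similarity") threshold else NA,
         grid = grid),
    class = "cluster_map"
  )
}

#' @export
print.cluster_map <- function(x, ...) {
  cat(sprintf("<cluster_map> %d cluster(s) over %d channel(s) [%s mode]\n",
              x$n_clusters, length(x$labels), x$mode))
  invisible(x)
}

#' @export
plot.cluster_map <- function(x, ...) {
  if (is.null(x$grid)) stop("no pixel grid to plot", call. = FALSE)
  res <- nrow(x$grid)
  graphics::image(seq_len(res), seq_len(res),
                  t(x$grid[res:1, , drop = FALSE]),
                  xlab = "pixel column", ylab = "pixel row", ...)
  invisible(x)
}

#' Fraction of locked oscillators over time
#'
#' @param run an `osc_run` produced with `record_states = TRUE`.
#' @return numeric vector, one entry per time step: the fraction of all
#'   oscillators classified as locked at that step.
#' @export
locked_fraction_timeseries <- function(run) {
  stopifnot(inherits(run, "osc_run"))
  if (is.null(run$state_counts)) {
    stop("run was not recorded with record_states = TRUE", call. = FALSE)
  }
  sc <- run$state_counts
  sc[, "locked"] / rowSums(sc)
}
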