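#' Five-item binary visual sequence
#'
#' A unimodal sequence is five items, each a horizontally (`H`) or
#' vertically (`V`) oriented Gabor patch. Sequences are indexed by a
#' 5-bit binary code with `H` = 0 and `V` = 1, most significant bit first,
#' so code 0 is `HHHHH` and code 31 is `VVVVV`.
#'
#' @param x a compact string (`"HVVVV"` or `"-H-V-V-V-V"`), a character
#'   vector of five items, or an integer code in 0..31.
#' @return an object of class `unimodal_sequence` with fields `items`
#'   (character(5)) and `code` (integer).
#' @export
#' @examples
#' unimodal_sequence("-H-V-V-V-V")$code  # 15
#' unimodal_sequence(15)$items
unimodal_sequence <- function(x) {
  if (inherits(x, "unimodal_sequence")) return(x)
  if (is.numeric(x) && length(x) == 1) {
    code <- as.integer(x)
    if (code < 0 || code > 31) stop("code must be in 0..31", call. = FALSE)
    bits <- as.integer(intToBits(code))[5:1]
    items <- c("H", "V")[bits + 1L]
  } else {
    items <- as.character(x)
    if (length(items) == 1) {
      items <- strsplit(gsub("-", "", items), "")[[1]]
    }
    if (length(items) != 5 || !all(items %in% c("H", "V"))) {
      stop("a unimodal sequence is exactly 5 items from {H, V}",
           call. = FALSE)
    }
    code <- sum((items == "V") * 2L^(4:0))
  }
  structure(list(items = items, code = as.integer(code)),
            class = "unimodal_sequence")
}

#' @export
format.unimodal_sequence <- function(x, ...) {
  paste0("-", paste(x$items, collapse = "-"))
}

#' @export
print.unimodal_sequence <- function(x, ...) {
  cat(sprintf("<unimodal_sequence> %s (code %d)\n", format(x), x$code))
  invisible(x)
}

#' Enumerate all 32 unimodal sequences
#'
#' @return list of [unimodal_sequence()] objects ordered by binary code
#'   0..31.
#' @export
enumerate_unimodal <- function() {
  lapply(0:31, unimodal_sequence)
}

#' Four-item crossmodal (audiovisual) sequence
#'
#' Each item is a visual (`V`) or auditory (`A`) stimulus at a high (`H`)
#' or low (`L`) feature level: a bright disc above/below the midline, or a
#' high/low-pitched beep. Strictly unimodal sequences (all-`V` or all-`A`)
#' are not valid crossmodal sequences.
#'
#' @param x a compact string like `"AH-VL-VH-VH"` or a character vector of
#'   four item labels from `{VH, VL, AH, AL}`.
#' @param allow_unimodal logical; permit all-visual/all-auditory item
#'   lists (used for degenerate-input experiments).
#' @return an object of class `crossmodal_sequence` with field `items`
#'   (character(4)).
#' @export
#' @examples
#' crossmodal_sequence("AH-VL-VH-VH")
crossmodal_sequence <- function(x, allow_unimodal = FALSE) {
  if (inherits(x, "crossmodal_sequence")) return(x)
  items <- as.character(x)
  if (length(items) == 1) items <- strsplit(items, "-", fixed = TRUE)[[1]]
  if (length(items) != 4 || !all(items %in% c("VH", "VL", "AH", "AL"))) {
    stop("a crossmodal sequence is exactly 4 items from {VH, VL, AH, AL}",
         call. = FALSE)
  }
  mods <- substr(items, 1, 1)
  if (!allow_unimodal && length(unique(mods)) == 1) {
    stop("strictly unimodal item lists are not crossmodal sequences",
         call. = FALSE)
  }
  structure(list(items = items), class = "crossmodal_sequence")
}

#' @export
format.crossmodal_sequence <- function(x, ...) {
  paste(x$items, collapse = "-")
}

#' @export
print.crossmodal_sequence <- function(x, ...) {
  cat(sprintf("<crossmodal_sequence> %s\n", format(x)))
  invisible(x)
}

#' Enumerate all 224 truly crossmodal sequences
#'
#' All `4^4 = 256` four-item combinations of `{VH, VL, AH, AL}` minus the
#' 32 strictly unimodal ones (all-visual or all-auditory).
#'
#' @return list of [crossmodal_sequence()] objects in a fixed
#'   lexicographic order.
#' @export
enumerate_crossmodal <- function() {
  lab <- c("VH", "VL", "AH", "AL")
  g <- expand.grid(i4 = lab, i3 = lab, i2 = lab, i1 = lab,
                   stringsAsFactors = FALSE)
  out <- list()
  for (r in seq_len(nrow(g))) {
    items <- c(g$i1[r], g$i2[r], g$i3[r], g$i4[r])
    if (length(unique(substr(items, 1, 1))) > 1) {
      out[[length(out) + 1L]] <- crossmodal_sequence(items)
    }
  }
  out
}

#' Render a binary Gabor patch frame
#'
#' An ideal sinusoidal grating of 0.5 cycles per degree across a 10-degree
#' square field, thresholded at its mean (zero) into black (`"B"`) and
#' white (`"W"`) pixels inside a centered circular aperture; pixels outside
#' the aperture are background (`"0"`, no input). The horizontal patch
#' varies along the vertical axis and is the transpose of the vertical
#' patch.
#'
#' @param orientation `"H"` or `"V"`.
#' @param resolution grid side length in pixels (default 20).
#' @return a `resolution x resolution` character matrix with entries in
#'   `{"B", "W", "0"}` and class `pixel_frame`.
#' @export
#' @examples
#' f <- render_gabor("H")
#' table(f)
render_gabor <- function(orientation = c("H", "V"), resolution = 20) {
  orientation <- match.arg(orientation)
  deg <- ((seq_len(resolution) - 0.5) / resolution - 0.5) * 10
  stripe <- ifelse(sin(2 * pi * 0.5 * deg) > 0, "W", "B")
  frame <- if (orientation == "H") {
    matrix(stripe, resolution, resolution, byrow = FALSE)  # varies by row
  } else {
    matrix(stripe, resolution, resolution, byrow = TRUE)   # varies by column
  }
  r2 <- outer(deg^2, deg^2, "+")
  frame[sqrt(r2) > 5] <- "0"
  structure(frame, class = c("pixel_frame", class(frame)))
}

#' Render a bright-disc frame (crossmodal visual stimulus)
#'
#' A filled disc of `"bright"` pixels, 6 degrees across, above (`"H"`) or
#' below (`"L"`) the horizontal midline of a 12-degree square field; all
#' other pixels are background (`"0"`). With the default `"disjoint"`
#' geometry the two discs touch at the midline and share no pixels; the
#' `"overlap"` geometry moves the disc centers to +/- 1.5 degrees so that
#' a central band of pixels is bright at both levels (at the cost of each
#' disc crossing the midline).
#'
#' @param level `"H"` (upper) or `"L"` (lower).
#' @param resolution grid side length in pixels (default 20).
#' @param geometry `"disjoint"` (default) or `"overlap"`.
#' @return a `resolution x resolution` character matrix with entries in
#'   `{"bright", "0"}` and class `pixel_frame`.
#' @export
render_disc <- function(level = c("H", "L"), resolution = 20,
                        geometry = c("disjoint", "overlap")) {
  level <- match.arg(level)
  geometry <- match.arg(geometry)
  span <- 12
  deg <- ((seq_len(resolution) - 0.5) / resolution - 0.5) * span
  x <- matrix(deg, resolution, resolution, byrow = TRUE)   # column -> x
  y <- matrix(-deg, resolution, resolution, byrow = FALSE) # row 1 = top
  cy <- if (geometry == "disjoint") 3 else 1.5
  if (level == "L") cy <- -cy
  frame <- matrix("0", resolution, resolution)
  frame[x^2 + (y - cy)^2 <= 9] <- "bright"
  structure(frame, class = c("pixel_frame", class(frame)))
}

# Item labels of the cyclic continuation: positions 1..n of the repeated
# sequence.
.cyclic_items <- function(sequence, n) {
  items <- sequence$items
  items[((seq_len(n) - 1L) %% length(items)) + 1L]
}

#' Test item for a given position of the cyclic continuation
#'
#' The congruent test item is the item the repeated sequence would produce
#' at `position`; the incongruent item is that item with its label flipped
#' (`H` <-> `V` for unimodal sequences; feature level flipped with the
#' modality preserved for crossmodal sequences).
#'
#' @param sequence a [unimodal_sequence()] or [crossmodal_sequence()].
#' @param position 1-based item position in the cyclic continuation;
#'   defaults to the item after one full presentation.
#' @param congruent logical.
#' @return a single item label.
#' @export
#' @examples
#' make_test_item(unimodal_sequence("-H-V-V-V-V"), 101, congruent = FALSE)
make_test_item <- function(sequence, position = NULL, congruent = TRUE) {
  L <- length(sequence$items)
  if (is.null(position)) position <- L + 1L
  due <- sequence$items[((position - 1L) %% L) + 1L]
  if (congruent) return(due)
  if (inherits(sequence, "unimodal_sequence")) {
    c(H = "V", V = "H")[[due]]
  } else {
    paste0(substr(due, 1, 1), c(H = "L", L = "H")[[substr(due, 2, 2)]])
  }
}

#' Shannon entropy of a sequence's item labels
#'
#' `-sum(p * log2(p))` over the distribution of item labels (orientation
#' for unimodal sequences, feature level for crossmodal sequences). Over
#' the 32 unimodal sequences the entropy takes exactly the three values
#' 0, ~0.722 and ~0.971 bits.
#'
#' @param sequence a sequence object.
#' @return entropy in bits.
#' @export
#' @examples
#' sequence_entropy(unimodal_sequence("HVVVV"))
sequence_entropy <- function(sequence) {
  labels <- if (inherits(sequence, "crossmodal_sequence")) {
    substr(sequence$items, 2, 2)
  } else {
    unimodal_sequence(sequence)$items
  }
  p <- table(labels) / length(labels)
  -sum(p * log2(p))
}

.bundle <- function(streams, channel_module, modules, resolution = NA,
                    n_items = NA, sequence = NULL, test_step = NA) {
  structure(
    list(streams = streams, channel_module = as.integer(channel_module),
         modules = modules, resolution = resolution, n_items = n_items,
         sequence = sequence, test_step = test_step),
    class = "stream_bundle"
  )
}

#' @export
print.stream_bundle <- function(x, ...) {
  cat(sprintf("<stream_bundle> %d channel(s) x %d step(s), %s item(s)\n",
              nrow(x$streams), ncol(x$streams),
              ifelse(is.na(x$n_items), "?", x$n_items)))
  invisible(x)
}

# Lay (blank, frame) pairs for a list of item labels into a channel x step
# symbol matrix. `frame_of` maps an item label to a pixel frame or to a
# length-1 auditory symbol.
.items_to_streams <- function(items, visual_frames, n_visual,
                              auditory = FALSE) {
  C <- n_visual + as.integer(auditory)
  Tt <- 2L * length(items)
  S <- matrix("0", C, Tt)
  for (j in seq_along(items)) {
    it <- items[j]
    if (auditory && substr(it, 1, 1) == "A") {
      S[C, 2L * j] <- c(H = "high", L = "low")[[substr(it, 2, 2)]]
    } else {
      key <- if (auditory) substr(it, 2, 2) else it
      S[seq_len(n_visual), 2L * j] <- as.vector(visual_frames[[key]])
    }
  }
  S
}

#' Build per-channel input streams from a stimulus sequence
#'
#' Renders each item of the repeated sequence into its pixel frame and
#' concatenates (blank, frame) pairs, so one item spans two time steps and
#' one repetition of a k-item sequence spans 2k steps. Unimodal sequences
#' yield one channel per pixel; crossmodal sequences additionally append
#' one auditory channel that carries the pitch symbol on auditory items
#' and `"0"` elsewhere (and the pixel channels carry `"0"` on auditory
#' items).
#'
#' @param sequence a [unimodal_sequence()] or [crossmodal_sequence()].
#' @param repetitions number of full presentations of the sequence.
#' @param test_item optional single item label appended (as one more
#'   blank/frame pair) after the repetitions.
#' @param resolution pixel grid side length.
#' @param geometry disc geometry for crossmodal sequences, see
#'   [render_disc()].
#' @return a `stream_bundle`: channel-by-step character matrix of symbols
#'   plus the channel-to-module map and the per-module [target_map()]s.
#' @export
#' @examples
#' b <- build_streams(unimodal_sequence("-H-V-V-V-V"), repetitions = 2,
#'                    resolution = 10)
#' dim(b$streams)  # 100 channels x 20 steps
build_streams <- function(sequence, repetitions, test_item = NULL,
                          resolution = 20, geometry = "disjoint") {
  stopifnot(repetitions >= 1)
  if (inherits(sequence, "unimodal_sequence")) {
    items <- rep(sequence$items, repetitions)
    if (!is.null(test_item)) {
      if (!test_item %in% c("H", "V")) {
        stop("unimodal test item must be H or V", call. = FALSE)
      }
      items <- c(items, test_item)
    }
    frames <- list(H = render_gabor("H", resolution),
                   V = render_gabor("V", resolution))
    S <- .items_to_streams(items, frames, resolution^2, auditory = FALSE)
    .bundle(S, rep(1L, resolution^2),
            modules = list(list(name = "visual", targets = unimodal_targets())),
            resolution = resolution, n_items = length(items),
            sequence = sequence,
            test_step = if (is.null(test_item)) NA else ncol(S))
  } else if (inherits(sequence, "crossmodal_sequence")) {
    items <- rep(sequence$items, repetitions)
    if (!is.null(test_item)) {
      if (!test_item %in% c("VH", "VL", "AH", "AL")) {
        stop("crossmodal test item must be one of VH, VL, AH, AL",
             call. = FALSE)
      }
      items <- c(items, test_item)
    }
    frames <- list(H = render_disc("H", resolution, geometry),
                   L = render_disc("L", resolution, geometry))
    frames$H[frames$H == "bright"] <- "bright"
    S <- .items_to_streams(items, frames, resolution^2, auditory = TRUE)
    .bundle(S, c(rep(1L, resolution^2), 2L),
            modules = list(
              list(name = "visual", targets = crossmodal_visual_targets()),
              list(name = "auditory", targets = auditory_targets())
            ),
            resolution = resolution, n_items = length(items),
            sequence = sequence,
            test_step = if (is.null(test_item)) NA else ncol(S))
  } else {
    stop("sequence must be a unimodal_sequence or crossmodal_sequence",
         call. = FALSE)
  }
}

#' Build the input streams of a congruence-test trial
#'
#' Presents the cyclic continuation of `sequence` up to item
#' `test_index - 1` and appends the test item at position `test_index`:
#' the due item if `congruent`, its flip otherwise.
#'
#' @inheritParams build_streams
#' @param test_index 1-based position of the tested item; must lie beyond
#'   one full presentation of the sequence.
#' @param congruent logical.
#' @return a `stream_bundle` with `test_step` set to the step at which the
#'   test frame appears (the final step).
#' @export
build_trial_streams <- function(sequence, test_index, congruent,
                                resolution = 20, geometry = "disjoint") {
  L <- length(sequence$items)
  if (test_index < L + 1) {
    stop("test_index must be at least sequence length + 1", call. = FALSE)
  }
  pre <- .cyclic_items(sequence, test_index - 1L)
  test <- make_test_item(sequence, test_index, congruent)
  if (inherits(sequence, "unimodal_sequence")) {
    frames <- list(H = render_gabor("H", resolution),
                   V = render_gabor("V", resolution))
    S <- .items_to_streams(c(pre, test), frames, resolution^2,
                           auditory = FALSE)
    b <- .bundle(S, rep(1L, resolution^2),
                 modules = list(list(name = "visual",
                                     targets = unimodal_targets())),
                 resolution = resolution, n_items = test_index,
                 sequence = sequence, test_step = ncol(S))
  } else {
    frames <- list(H = render_disc("H", resolution, geometry),
                   L = render_disc("L", resolution, geometry))
    S <- .items_to_streams(c(pre, test), frames, resolution^2,
                           auditory = TRUE)
    b <- .bundle(S, c(rep(1L, resolution^2), 2L),
                 modules = list(
                   list(name = "visual", targets = crossmodal_visual_targets()),
                   list(name = "auditory", targets = auditory_targets())
                 ),
                 resolution = resolution, n_items = test_index,
                 sequence = sequence, test_step = ncol(S))
  }
  b
}

#' Build a stream bundle from raw symbol streams
#'
#' Accepts user-defined input directly: one stream per channel, either as
#' a character matrix (channels x steps), as strings of
#' whitespace-separated symbols, or as compact strings of single-character
#' symbols such as `"0W0W0W0W0W"`.
#'
#' @param x character matrix or character vector (one entry per channel).
#' @param targets the [target_map()] interpreting the symbols.
#' @param repetitions repeat each stream this many times end to end.
#' @param name module name.
#' @return a `stream_bundle` with a single module.
#' @export
#' @examples
#' b <- input_streams("0W0W0W0W0W", repetitions = 20)
#' ncol(b$streams)  # 200
input_streams <- function(x, targets = unimodal_targets(), repetitions = 1,
                          name = "visual") {
  if (!is.matrix(x)) {
    rows <- lapply(as.character(x), function(s) {
      if (grepl("[[:space:]]", s)) {
        strsplit(trimws(s), "[[:space:]]+")[[1]]
      } else {
        strsplit(s, "")[[1]]
      }
    })
    len <- unique(lengths(rows))
    if (length(len) != 1) {
      stop("all channel streams must have equal length", call. = FALSE)
    }
    x <- do.call(rbind, rows)
  }
  if (repetitions > 1) {
    x <- x[, rep(seq_len(ncol(x)), repetitions), drop = FALSE]
  }
  bad <- setdiff(unique(as.vector(x)), c("0", targets$symbol))
  if (length(bad)) {
    stop(sprintf("symbols not in target map: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  .bundle(x, rep(1L, nrow(x)),
          modules = list(list(name = name, targets = targets)),
          n_items = ncol(x) / 2)
}

#' Write / read input streams as plain text
#'
#' One line per channel, whitespace-separated symbols, `"0"` for blank.
#'
#' @param bundle a `stream_bundle`.
#' @param path file path.
#' @return `write_streams` returns `path` invisibly; `read_streams`
#'   returns a `stream_bundle`.
#' @export
write_streams <- function(bundle, path) {
  writeLines(apply(bundle$streams, 1, paste, collapse = " "), path)
  invisible(path)
}

#' @rdname write_streams
#' @inheritParams input_streams
#' @export
read_streams <- function(path, targets = unimodal_targets(),
                         name = "visual") {
  input_streams(readLines(path), targets = targets, name = name)
}
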