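#' Factorial task designs
#'
#' A task design describes the factorial structure of a recording session:
#' an ordered set of task-parameter levels (e.g. reach targets, wrist
#' orientations or grip types), two visual conditions (light/dark), and the
#' temporal binning of each trial. Time runs over a fixed window around the
#' primary alignment event in half-open bins: bin `t` (0-based) covers
#' `[start + t * bin_width, start + (t + 1) * bin_width)` ms.
#'
#' Designs with two alignment events (the grip-type task aligns epochs on
#' object illumination and on movement onset) concatenate the two epochs
#' along the time axis; `epoch_boundary` records the 1-based bin index at
#' which the second epoch starts so that downstream interval reports never
#' span the concatenation point.
#'
#' @param name design label, one of `"reach_direction"`, `"wrist_orientation"`,
#'   `"grip_type"`, or any custom string.
#' @param parameter_levels ordered character vector of task-parameter levels
#'   (length >= 2).
#' @param visual_levels ordered pair of visual-condition labels;
#'   default `c("light", "dark")`.
#' @param bin_width bin width in ms (default 40).
#' @param window length-2 numeric, window in ms relative to the primary
#'   alignment event (default `c(-4500, 2500)`); its length must be divisible
#'   by `bin_width`.
#' @param alignment_events one or two event labels; with two events the time
#'   axis is a concatenation of two epochs.
#' @param epoch_boundary 1-based bin index where the second epoch begins
#'   (required iff two alignment events are given).
#' @return An object of class `"task_design"` with fields `name`,
#'   `parameter_levels`, `visual_levels`, `bin_width`, `window`,
#'   `alignment_events`, `epoch_boundary`, `n_bins`, and `bin_starts_ms`.
#' @examples
#' d <- reach_design()
#' d$n_bins  # 175 bins of 40 ms covering -4500..+2500 ms
#' @export
task_design <- function(name,
                        parameter_levels,
                        visual_levels = c("light", "dark"),
                        bin_width = 40,
                        window = c(-4500, 2500),
                        alignment_events = "movement_onset",
                        epoch_boundary = NULL) {
  parameter_levels <- as.character(parameter_levels)
  visual_levels <- as.character(visual_levels)
  abort_if(length(parameter_levels) < 2L,
           "a task design needs at least 2 parameter levels")
  abort_if(anyDuplicated(parameter_levels) > 0L, "duplicate parameter levels")
  abort_if(length(visual_levels) != 2L,
           "exactly 2 visual conditions are required")
  abort_if(length(window) != 2L || window[2] <= window[1],
           "window must be an increasing pair of ms offsets")
  span <- window[2] - window[1]
  abort_if(span %% bin_width != 0,
           "window length (%g ms) is not divisible by bin width (%g ms)",
           span, bin_width)
  n_events <- length(alignment_events)
  abort_if(!n_events %in% 1:2, "1 or 2 alignment events are supported")
  n_bins <- as.integer(span / bin_width)
  if (n_events == 2L) {
    abort_if(is.null(epoch_boundary),
             "a dual-aligned design needs an epoch_boundary bin index")
    epoch_boundary <- as.integer(epoch_boundary)
    abort_if(epoch_boundary < 2L || epoch_boundary > n_bins,
             "epoch_boundary must lie inside the binned window")
  } else {
    abort_if(!is.null(epoch_boundary),
             "epoch_boundary only applies to dual-aligned designs")
  }
  structure(list(
    name = name,
    parameter_levels = parameter_levels,
    visual_levels = visual_levels,
    bin_width = bin_width,
    window = as.numeric(window),
    alignment_events = alignment_events,
    epoch_boundary = epoch_boundary,
    n_bins = n_bins,
    bin_starts_ms = window[1] + bin_width * (seq_len(n_bins) - 1L)
  ), class = "task_design")
}

#' @rdname task_design
#' @details `reach_design()` (3 targets x 2 visual conditions),
#'   `wrist_design()` (2 orientations x 2), and `grip_design()` (5 grips x 2,
#'   dual-aligned on object illumination and movement onset) are the presets
#'   used throughout: 40 ms bins from -4500 ms before movement onset to
#'   +2500 ms after it (175 bins).
#' @param ... overrides passed on to [task_design()].
#' @export
reach_design <- function(...) {
  defaults <- list(name = "reach_direction",
                   parameter_levels = c("left", "center", "right"))
  do.call(task_design, utils::modifyList(defaults, list(...)))
}

#' @rdname task_design
#' @export
wrist_design <- function(...) {
  defaults <- list(name = "wrist_orientation",
                   parameter_levels = c("horizontal", "vertical"))
  do.call(task_design, utils::modifyList(defaults, list(...)))
}

#' @rdname task_design
#' @export
grip_design <- function(...) {
  defaults <- list(
    name = "grip_type",
    parameter_levels = c("whole_hand", "finger", "hook",
                         "primitive_precision", "advanced_precision"),
    alignment_events = c("object_illumination", "movement_onset"),
    # first epoch: 60 bins (-4500..-2100 ms re illumination); second epoch
    # aligned on movement onset fills the remainder of the window
    epoch_boundary = 61L)
  do.call(task_design, utils::modifyList(defaults, list(...)))
}

#' @export
print.task_design <- function(x, ...) {
  cat("Task design:", x$name, "\n")
  cat(sprintf("  %d parameter levels: %s\n", length(x$parameter_levels),
              paste(x$parameter_levels, collapse = ", ")))
  cat(sprintf("  visual conditions: %s\n",
              paste(x$visual_levels, collapse = ", ")))
  cat(sprintf("  %d bins of %g ms over %g..%g ms (aligned on %s)\n",
              x$n_bins, x$bin_width, x$window[1], x$window[2],
              paste(x$alignment_events, collapse = " + ")))
  invisible(x)
}

#' Read and write task designs as JSON
#'
#' Serializes every design field losslessly; `read_design_json()` rebuilds
#' the validated object through [task_design()].
#' @param design a `task_design`.
#' @param path file path.
#' @export
write_design_json <- function(design, path) {
  stopifnot(inherits(design, "task_design"))
  fields <- design[c("name", "parameter_levels", "visual_levels",
                     "bin_width", "window", "alignment_events")]
  if (!is.null(design$epoch_boundary))
    fields$epoch_boundary <- design$epoch_boundary
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_design_json
#' @export
read_design_json <- function(path) {
  fields <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(task_design, fields)
}
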