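# Piecewise-constant stimulus schedules for one input signal.

#' Define a piecewise-constant stimulus protocol
#'
#' @param input Name of the input signal the protocol drives (e.g. `"k24"`).
#' @param segments Data frame with columns `start`, `end`, `value` (times in
#'   seconds); may be empty. Segments must be sorted and non-overlapping.
#' @param default Signal value outside all segments.
#' @return An object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(input, segments = NULL, default = 0) {
  if (is.null(segments)) {
    segments <- data.frame(start = numeric(0), end = numeric(0),
                           value = numeric(0))
  }
  segments <- as.data.frame(segments)
  stopifnot(all(c("start", "end", "value") %in% names(segments)))
  if (nrow(segments)) {
    o <- order(segments$start)
    segments <- segments[o, , drop = FALSE]
    if (any(segments$end <= segments$start)) {
      stop("protocol segment with end <= start", call. = FALSE)
    }
    if (nrow(segments) > 1L &&
        any(segments$start[-1] < segments$end[-nrow(segments)])) {
      stop("protocol segments overlap", call. = FALSE)
    }
    if (!all(is.finite(segments$value))) {
      stop("protocol values must be finite", call. = FALSE)
    }
  }
  structure(list(input = input, segments = segments,
                 default = default),
            class = "stimulus_protocol")
}

#' Constant-input protocol
#' @param input Input signal name.
#' @param value Constant value.
#' @export
protocol_constant <- function(input = "k24", value = 1) {
  stimulus_protocol(input, default = value)
}

#' Periodic pulse-train protocol
#'
#' Pulses of height `value` and width `width` seconds delivered every
#' `period` seconds starting at `t0`, on a baseline of `default`.
#'
#' @param input Input signal name.
#' @param width Pulse width (s).
#' @param period Inter-pulse period (s).
#' @param t_end End of schedule (s).
#' @param value Pulse height.
#' @param default Baseline value.
#' @param t0 Time of the first pulse onset (s).
#' @export
protocol_pulsed <- function(input = "k24", width = 300, period = 6000,
                            t_end = 6e5, value = 1, default = 0, t0 = 0) {
  starts <- seq(t0, t_end, by = period)
  starts <- starts[starts < t_end]
  stimulus_protocol(input,
                    data.frame(start = starts,
                               end = pmin(starts + width, t_end),
                               value = value),
                    default = default)
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat("<stimulus_protocol> input ", x$input, ", default ", x$default,
      ", ", nrow(x$segments), " segment(s)\n", sep = "")
  invisible(x)
}

# Value of the signal at time t (vectorised).
protocol_value <- function(protocol, t) {
  v <- rep(protocol$default, length(t))
  seg <- protocol$segments
  for (i in seq_len(nrow(seg))) {
    v[t >= seg$start[i] & t < seg$end[i]] <- seg$value[i]
  }
  v
}

# Discontinuity times within (0, t_end): the integrator restarts at each.
protocol_edges <- function(protocol, t_end) {
  e <- c(protocol$segments$start, protocol$segments$end)
  sort(unique(e[e > 0 & e < t_end]))
}
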