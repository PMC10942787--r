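#' Spike-counting window
#'
#' A response window defined by its latency offset after stimulus onset and
#' its duration, both in seconds. Spikes are counted over the half-open
#' interval `[latency_offset, latency_offset + duration)`, so adjacent
#' windows never double-count a spike. Counts over a window of duration
#' `d` convert to rates in Hz by multiplying by `1/d` (5 for the standard
#' 200 ms window).
#'
#' @param latency_offset window start after stimulus onset, seconds (>= 0).
#' @param duration window length, seconds (> 0).
#' @return an object of class `count_window`.
#' @seealso [window_preset()] for the standard area-specific windows.
#' @examples
#' w <- count_window(0.03, 0.2)
#' count_spikes(c(0.05, 0.10, 0.25), w)
#' @export
count_window <- function(latency_offset, duration) {
  if (!is.numeric(latency_offset) || length(latency_offset) != 1 ||
      !is.finite(latency_offset) || latency_offset < 0)
    stop_input("`latency_offset` must be a single finite number >= 0")
  if (!is.numeric(duration) || length(duration) != 1 ||
      !is.finite(duration) || duration <= 0)
    stop_input("`duration` must be a single finite number > 0")
  structure(list(latency_offset = latency_offset, duration = duration),
            class = "count_window")
}

#' Standard response windows
#'
#' `"MT"` counts spikes 30-230 ms after stimulus onset (middle temporal
#' area response latency ~30 ms); `"IT"` counts 50-250 ms (inferotemporal
#' cortex latency ~50 ms); `"IT_long"` is the 50-450 ms sensitivity
#' variant usable when stimuli stay on for 400 ms.
#'
#' @param name one of `"MT"`, `"IT"`, `"IT_long"`.
#' @return a [count_window()].
#' @export
window_preset <- function(name = c("MT", "IT", "IT_long")) {
  switch(match.arg(name),
         MT      = count_window(0.030, 0.200),
         IT      = count_window(0.050, 0.200),
         IT_long = count_window(0.050, 0.400))
}

#' @export
print.count_window <- function(x, ...) {
  cat(sprintf("<count_window> [%g, %g) s after onset (%g ms duration)\n",
              x$latency_offset, x$latency_offset + x$duration,
              1000 * x$duration))
  invisible(x)
}

#' Count spikes inside a response window
#'
#' Counts the timestamps `t` (seconds relative to stimulus onset) with
#' `latency_offset <= t < latency_offset + duration`.
#'
#' @param spike_times numeric vector of spike timestamps; may be empty.
#' @param window a [count_window()].
#' @return a non-negative integer.
#' @export
count_spikes <- function(spike_times, window) {
  if (!inherits(window, "count_window"))
    stop_input("`window` must be a count_window")
  if (length(spike_times) == 0) return(0L)
  if (!is.numeric(spike_times) || any(!is.finite(spike_times)))
    stop_input("`spike_times` must be finite numeric timestamps")
  lo <- window$latency_offset
  hi <- lo + window$duration
  sum(spike_times >= lo & spike_times < hi)
}
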