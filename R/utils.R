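# internal numerics shared across modules

#' @keywords internal
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)  # all -Inf (or any +Inf/NaN) short-circuits
  m + log(sum(exp(x - m)))
}

#' @keywords internal
#' @noRd
is_count_vector <- function(x) {
  is.numeric(x) && length(x) > 0 && all(is.finite(x)) &&
    all(x >= 0) && all(x == floor(x))
}

#' @keywords internal
#' @noRd
stop_input <- function(...) stop(..., call. = FALSE)

# Derive a child seed from a master seed and a counter so that adding
# later specs never perturbs earlier draws. Kept below 2^31 - 1.
#' @keywords internal
#' @noRd
child_seed <- function(master, index) {
  as.integer(((as.double(master) %% 2147483647) * 48271 +
                1009 * as.double(index)) %% 2147483647)
}
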