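# Internal helpers shared across modules.

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Intensity class labels, in increasing order of energy cost.
intensity_levels <- c("sedentary", "light", "mvpa")

# Effort levels for effort-ranked activities, in increasing order.
effort_levels <- c("light", "medium", "hard")

stop_par24 <- function(msg, class) {
  abort(msg, class = c(class, "par24_error"))
}

# Recycle vectors to a common length, erroring on incompatible lengths.
recycle_common <- function(...) {
  xs <- list(...)
  n <- max(vapply(xs, length, integer(1)))
  lapply(xs, function(x) {
    if (length(x) == n) return(x)
    if (length(x) == 1L) return(rep(x, n))
    stop_par24("arguments must have length 1 or a common length", "par24_contract_error")
  })
}

is_whole <- function(x) {
  is.numeric(x) & !is.na(x) & abs(x - round(x)) < 1e-8
}

# Run-length segments of a vector: tibble(value, start, end) with half-open
# [start, end) 0-based indexing.
rle_segments <- function(x) {
  r <- rle(as.vector(x))
  end <- cumsum(r$lengths)
  tibble(value = r$values, start = end - r$lengths, end = end)
}
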