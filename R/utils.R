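#' @importFrom rlang %||% .data abort
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join anti_join semi_join distinct bind_rows n row_number across
#' @importFrom tibble tibble as_tibble
#' @importFrom stats median sd rnorm rpois rbinom rmultinom runif dhyper
#'   setNames is.leaf
#' @importFrom utils head
NULL

# round half away from zero, as printed frequency tables do
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# fraction in [0, 1]
check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1], got %s",
                  name, paste(format(x), collapse = ", ")))
  }
  invisible(x)
}

check_count <- function(x, name, positive = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x == trunc(x) &&
    (x > 0 || (!positive && x >= 0))
  if (!ok) {
    abort(sprintf("`%s` must be a single %s integer",
                  name, if (positive) "positive" else "non-negative"))
  }
  invisible(x)
}

check_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("`%s` is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# maximal runs of TRUE in a logical vector; returns tibble(start, end, length)
find_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & !is.na(r$values)
  tibble(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}
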