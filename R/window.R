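#' Select a population's assessment window
#'
#' Trends are assessed over the three most recent generations, anchored
#' at the last survey: the window is
#' `[last_year - 3 * generation_time, last_year]`, inclusive at both
#' ends. When the series spans less than three generations the full span
#' is used instead, and the population is only eligible for a trend fit
#' if that span is at least ten years (the minimum assessment period
#' used in IUCN-style decline criteria). Eligibility additionally
#' requires at least three estimates inside the window; ineligible
#' populations are classified Unknown downstream.
#'
#' Historical estimates falling inside a long window are retained; the
#' robust regression downweights high-leverage points.
#'
#' @param series abundance data frame for one population (columns as in
#'   [read_abundance_table()]), non-empty.
#' @param generation_time generation time in years (> 0).
#' @return an object of class `windowed_series`: list with
#'   `population_id`, `points` (rows inside the window, ordered by
#'   year), `window` (start, end), `basis` (`"three_generations"` or
#'   `"min_ten_years"`), `eligible`, `generation_time`.
#' @export
#' @examples
#' s <- data.frame(
#'   population_id = "p1", year = seq(1950, 2008, by = 2),
#'   abundance = 1000, error_kind = "none", error_lo = NA, error_hi = NA,
#'   is_pup_count = FALSE, acid_rank = 4
#' )
#' select_window(s, generation_time = 10)
select_window <- function(series, generation_time) {
  if (is.null(series) || nrow(series) == 0) {
    stop("cannot window an empty series", call. = FALSE)
  }
  if (!is.finite(generation_time) || generation_time <= 0) {
    stop("generation_time must be > 0", call. = FALSE)
  }
  series <- series[order(series$year), , drop = FALSE]
  last_year <- series$year[nrow(series)]
  span <- last_year - series$year[1]
  three_gen <- 3 * generation_time

  if (span >= three_gen) {
    window <- c(last_year - three_gen, last_year)
    basis <- "three_generations"
    span_ok <- TRUE
  } else {
    window <- c(series$year[1], last_year)
    basis <- "min_ten_years"
    span_ok <- span >= 10
  }
  points <- series[series$year >= window[1] & series$year <= window[2], ,
    drop = FALSE
  ]
  structure(
    list(
      population_id = series$population_id[1],
      points = points,
      window = window,
      basis = basis,
      eligible = span_ok && nrow(points) >= 3,
      generation_time = generation_time
    ),
    class = "windowed_series"
  )
}

#' Is a windowed series eligible for a trend fit?
#'
#' True iff the window holds at least three estimates and the span rule
#' is satisfied (three full generations, or a shorter series covering at
#' least ten years). A `FALSE` here forces the Unknown classification.
#'
#' @param windowed a `windowed_series` from [select_window()].
#' @return logical.
#' @export
eligibility <- function(windowed) {
  stopifnot(inherits(windowed, "windowed_series"))
  span_ok <- if (windowed$basis == "three_generations") {
    TRUE
  } else {
    (windowed$window[2] - windowed$window[1]) >= 10
  }
  span_ok && nrow(windowed$points) >= 3
}

#' @export
print.windowed_series <- function(x, ...) {
  cat(sprintf(
    "Windowed series %s: %d point(s) in [%.1f, %.1f] (%s), %s\n",
    x$population_id, nrow(x$points), x$window[1], x$window[2],
    x$basis, if (x$eligible) "eligible" else "not eligible"
  ))
  invisible(x)
}
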