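#' Percent decline from a historical abundance to the observed minimum
#'
#' `100 * (H - N_min) / H`, the magnitude of the historical decline
#' relative to the historical abundance estimate H. A minimum above the
#' historical estimate (possible when the "historical" figure predates
#' a later peak) is clamped to a 0% decline with a warning.
#'
#' @param historical historical abundance estimate H (> 0).
#' @param n_min minimum observed abundance (>= 0).
#' @return percent decline in `[0, 100]`.
#' @export
#' @examples
#' decline_pct(100, 29) # 71
decline_pct <- function(historical, n_min) {
  if (any(!is.finite(historical)) || any(historical <= 0)) {
    stop("historical abundance must be > 0", call. = FALSE)
  }
  if (any(n_min < 0)) stop("n_min must be >= 0", call. = FALSE)
  if (any(n_min > historical)) {
    warning("minimum abundance exceeds the historical estimate; ",
      "decline clamped at 0%",
      call. = FALSE
    )
  }
  pmax(100 * (historical - n_min) / historical, 0)
}

#' Percent recovery of a historical abundance
#'
#' `100 * N_recent / H`: the most recent abundance as a percentage of
#' the historical estimate. Values above 100% occur when the recent
#' abundance exceeds the best available historical estimate and are
#' retained, not capped.
#'
#' @param historical historical abundance estimate H (> 0).
#' @param n_recent most recent abundance (>= 0).
#' @return percent recovery (>= 0, possibly > 100).
#' @export
#' @examples
#' recovery_pct(100, 61) # 61
#' recovery_pct(100, 120) # 120
recovery_pct <- function(historical, n_recent) {
  if (any(!is.finite(historical)) || any(historical <= 0)) {
    stop("historical abundance must be > 0", call. = FALSE)
  }
  if (any(n_recent < 0)) stop("n_recent must be >= 0", call. = FALSE)
  100 * n_recent / historical
}

#' Historical decline and recent recovery for one population
#'
#' A population enters the decline-recovery analysis when it has at
#' least one historical abundance estimate, a non-empty series, and a
#' most recent estimate strictly above the series minimum (i.e. some
#' evidence of recent increase). Decline and recovery percentages are
#' computed against every historical estimate and averaged
#' arithmetically.
#'
#' @param record one-row population metadata data frame (or list) with
#'   `population_id` and `historical_estimates`.
#' @param series the population's (deduplicated) abundance data frame.
#' @return list of class `decline_recovery` with `population_id`,
#'   `eligible`, `reason` (when ineligible), `n_historical`, `n_min`,
#'   `n_recent`, `per_historical` (data frame: `historical`,
#'   `decline_pct`, `recovery_pct`), `mean_decline_pct`,
#'   `mean_recovery_pct`.
#' @export
population_decline_recovery <- function(record, series) {
  hist <- historical_estimates(as.data.frame(record))[[1]]
  pid <- record$population_id
  ineligible <- function(reason) {
    structure(
      list(
        population_id = pid, eligible = FALSE, reason = reason,
        n_historical = length(hist),
        n_min = NA_real_, n_recent = NA_real_,
        per_historical = NULL,
        mean_decline_pct = NA_real_, mean_recovery_pct = NA_real_
      ),
      class = "decline_recovery"
    )
  }
  if (length(hist) == 0) {
    return(ineligible("no historical estimate"))
  }
  if (is.null(series) || nrow(series) == 0) {
    return(ineligible("empty series"))
  }
  n_min <- min(series$abundance)
  n_recent <- series$abundance[which.max(series$year)]
  if (!(n_recent > n_min)) {
    return(ineligible("no evidence of recent increase"))
  }
  per <- data.frame(
    historical = hist,
    decline_pct = decline_pct(hist, n_min),
    recovery_pct = recovery_pct(hist, n_recent)
  )
  structure(
    list(
      population_id = pid, eligible = TRUE, reason = NA_character_,
      n_historical = length(hist),
      n_min = n_min, n_recent = n_recent,
      per_historical = per,
      mean_decline_pct = mean(per$decline_pct),
      mean_recovery_pct = mean(per$recovery_pct)
    ),
    class = "decline_recovery"
  )
}

#' @export
print.decline_recovery <- function(x, ...) {
  if (!x$eligible) {
    cat(sprintf(
      "Population %s: excluded from decline/recovery (%s)\n",
      x$population_id, x$reason
    ))
  } else {
    cat(sprintf(
      "Population %s: mean decline %.1f%%, mean recovery %.1f%% (%d historical estimate(s))\n",
      x$population_id, x$mean_decline_pct, x$mean_recovery_pct,
      x$n_historical
    ))
  }
  invisible(x)
}

#' Collect eligible decline-recovery records into a table
#'
#' @param records list of `decline_recovery` objects.
#' @return data frame (eligible populations only) with `population_id`,
#'   `n_historical`, `n_min`, `n_recent`, `mean_decline_pct`,
#'   `mean_recovery_pct`.
#' @export
decline_recovery_table <- function(records) {
  rows <- lapply(records, function(r) {
    if (!r$eligible) {
      return(NULL)
    }
    data.frame(
      population_id = r$population_id,
      n_historical = r$n_historical,
      n_min = r$n_min,
      n_recent = r$n_recent,
      mean_decline_pct = r$mean_decline_pct,
      mean_recovery_pct = r$mean_recovery_pct,
      stringsAsFactors = FALSE
    )
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) {
    return(data.frame(
      population_id = character(0), n_historical = integer(0),
      n_min = numeric(0), n_recent = numeric(0),
      mean_decline_pct = numeric(0), mean_recovery_pct = numeric(0)
    ))
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Group means of decline and recovery percentages
#'
#' Unweighted arithmetic means (with SD) of the per-population mean
#' decline and recovery percentages, for each taxon/habitat grouping
#' (same grouping keys as [summarize_group()]). Groups with no eligible
#' population are absent.
#'
#' @param dr_table data frame from [decline_recovery_table()].
#' @param populations population metadata data frame.
#' @param grouping optional character vector restricting group labels.
#' @return data frame with `group`, `n`, `mean_decline_pct`,
#'   `sd_decline_pct`, `mean_recovery_pct`, `sd_recovery_pct`.
#' @export
group_mean_decline_recovery <- function(dr_table, populations,
                                        grouping = NULL) {
  if (nrow(dr_table) == 0) {
    return(data.frame(
      group = character(0), n = integer(0),
      mean_decline_pct = numeric(0), sd_decline_pct = numeric(0),
      mean_recovery_pct = numeric(0), sd_recovery_pct = numeric(0)
    ))
  }
  populations <- populations[
    match(dr_table$population_id, populations$population_id), ,
    drop = FALSE
  ]
  groups <- group_membership(populations)
  if (!is.null(grouping)) {
    unknown <- setdiff(grouping, names(groups))
    if (length(unknown) > 0) {
      stop(sprintf(
        "unknown grouping key(s): %s",
        paste(unknown, collapse = ", ")
      ), call. = FALSE)
    }
    groups <- groups[grouping]
  }
  rows <- list()
  for (g in names(groups)) {
    sub <- dr_table[groups[[g]], , drop = FALSE]
    if (nrow(sub) == 0) next
    rows[[g]] <- data.frame(
      group = g,
      n = nrow(sub),
      mean_decline_pct = mean(sub$mean_decline_pct),
      sd_decline_pct = stats::sd(sub$mean_decline_pct),
      mean_recovery_pct = mean(sub$mean_recovery_pct),
      sd_recovery_pct = stats::sd(sub$mean_recovery_pct),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}
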