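#' Mid-point of a survey year range
#'
#' Abundance estimates surveyed over a range of years are dated at the
#' mid-point of the range; a single-year survey keeps its year.
#'
#' @param year_start first year of the survey (numeric).
#' @param year_end last year of the survey; must be `>= year_start`.
#' @return decimal year `(year_start + year_end) / 2`.
#' @export
#' @examples
#' midpoint_year(1990, 1994) # 1992
#' midpoint_year(2000, 2001) # 2000.5
midpoint_year <- function(year_start, year_end) {
  if (any(!is.finite(year_start)) || any(!is.finite(year_end))) {
    stop("survey years must be finite", call. = FALSE)
  }
  if (any(year_end < year_start)) {
    stop("year_end must be >= year_start", call. = FALSE)
  }
  (year_start + year_end) / 2
}

.abundance_cols <- c(
  "population_id", "year_start", "year_end", "abundance", "error_kind",
  "error_lo", "error_hi", "is_pup_count", "acid_rank"
)
.error_kinds <- c("none", "cv", "se", "ci95")

validate_abundance <- function(df, file = "<data>") {
  bad <- which(!is.finite(df$abundance))
  if (length(bad) > 0) {
    stop(sprintf(
      "%s: missing or non-numeric abundance on row(s) %s",
      file, paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  bad <- which(df$abundance < 0)
  if (length(bad) > 0) {
    stop(sprintf(
      "%s: negative abundance on row(s) %s",
      file, paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  bad <- which(!(df$acid_rank %in% 1:6))
  if (length(bad) > 0) {
    stop(sprintf(
      "%s: acid_rank outside 1..6 on row(s) %s",
      file, paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  bad <- which(!(df$error_kind %in% .error_kinds))
  if (length(bad) > 0) {
    stop(sprintf(
      "%s: unknown error_kind on row(s) %s",
      file, paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  ci <- df$error_kind == "ci95"
  bad <- which(ci & !(df$error_lo <= df$abundance & df$abundance <= df$error_hi))
  if (length(bad) > 0) {
    stop(sprintf(
      "%s: ci95 bounds do not bracket the abundance on row(s) %s",
      file, paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(df)
}

#' Read an abundance time-series table
#'
#' Reads the comma-separated abundance table (UTF-8, header row, "."
#' decimal) with columns `population_id, year_start, year_end, abundance,
#' error_kind, error_lo, error_hi, is_pup_count, acid_rank`. Survey year
#' ranges are collapsed to their mid-point into a single `year` column.
#' `error_kind` is one of `none`, `cv`, `se`, `ci95`; for `cv`/`se` the
#' value sits in `error_lo`, for `ci95` both bounds are used.
#'
#' Rows with missing abundance, a confidence rank outside 1..6, or ci95
#' bounds that do not bracket the estimate raise a validation error
#' naming the offending rows.
#'
#' @param path file path.
#' @return data frame with columns `population_id, year, abundance,
#'   error_kind, error_lo, error_hi, is_pup_count, acid_rank`.
#' @export
read_abundance_table <- function(path) {
  df <- utils::read.csv(path,
    stringsAsFactors = FALSE,
    colClasses = c(population_id = "character")
  )
  missing_cols <- setdiff(.abundance_cols, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf(
      "%s: missing mandatory column(s): %s",
      path, paste(missing_cols, collapse = ", ")
    ), call. = FALSE)
  }
  if (nrow(df) == 0) {
    stop(sprintf("%s: abundance file contains no data rows", path),
      call. = FALSE
    )
  }
  df$error_kind[is.na(df$error_kind) | df$error_kind == ""] <- "none"
  df$is_pup_count <- as.logical(df$is_pup_count)
  validate_abundance(df, file = path)
  out <- data.frame(
    population_id = df$population_id,
    year = midpoint_year(df$year_start, df$year_end),
    abundance = as.numeric(df$abundance),
    error_kind = df$error_kind,
    error_lo = as.numeric(df$error_lo),
    error_hi = as.numeric(df$error_hi),
    is_pup_count = df$is_pup_count,
    acid_rank = as.integer(df$acid_rank),
    stringsAsFactors = FALSE
  )
  out[order(out$population_id, out$year), , drop = FALSE]
}

#' Write an abundance table
#'
#' Inverse of [read_abundance_table()]: in-memory estimates (with a
#' single decimal `year`) are written with `year_start = year_end = year`
#' so a write/read round trip reproduces the records.
#'
#' @param estimates data frame as returned by [read_abundance_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(estimates, path) {
  out <- data.frame(
    population_id = estimates$population_id,
    year_start = estimates$year,
    year_end = estimates$year,
    abundance = estimates$abundance,
    error_kind = estimates$error_kind,
    error_lo = estimates$error_lo,
    error_hi = estimates$error_hi,
    is_pup_count = estimates$is_pup_count,
    acid_rank = estimates$acid_rank,
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Approximate 95% confidence half-width of each abundance estimate
#'
#' Heterogeneous reported error (CV, SE, or explicit 95% CI bounds) is
#' converted to a single internal representation, the approximate 95%
#' half-width: CI bounds as given (half the interval), `SE * 1.96`, or
#' `CV * abundance * 1.96`. Estimates without error information get `NA`.
#'
#' @param estimates abundance data frame (see [read_abundance_table()]).
#' @return numeric vector of half-widths, `NA` where no error was given.
#' @export
error_halfwidth95 <- function(estimates) {
  hw <- rep(NA_real_, nrow(estimates))
  k <- estimates$error_kind
  hw[k == "ci95"] <- (estimates$error_hi[k == "ci95"] -
    estimates$error_lo[k == "ci95"]) / 2
  hw[k == "se"] <- estimates$error_lo[k == "se"] * 1.96
  hw[k == "cv"] <- estimates$error_lo[k == "cv"] *
    estimates$abundance[k == "cv"] * 1.96
  hw
}

.population_cols <- c(
  "population_id", "species_name", "species_type", "sub_type",
  "dolphin_or_porpoise", "habitat", "generation_time", "area_label",
  "contains", "historical_estimates"
)

#' Read a population metadata table
#'
#' Comma-separated table with one row per population: species and taxon
#' groupings, habitat, generation time in years, area label, the
#' population ids nested inside this one (semicolon-joined in
#' `contains`), and any historical abundance estimates (semicolon-joined
#' numbers in `historical_estimates`). Containment must be acyclic and a
#' population may not contain itself.
#'
#' @param path file path.
#' @return data frame with the population metadata columns.
#' @seealso [population_contains()], [historical_estimates()]
#' @export
read_population_table <- function(path) {
  df <- utils::read.csv(path,
    stringsAsFactors = FALSE,
    colClasses = c(population_id = "character")
  )
  missing_cols <- setdiff(.population_cols, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf(
      "%s: missing mandatory column(s): %s",
      path, paste(missing_cols, collapse = ", ")
    ), call. = FALSE)
  }
  df$contains <- as.character(df$contains)
  df$contains[is.na(df$contains)] <- ""
  df$historical_estimates <- as.character(df$historical_estimates)
  df$historical_estimates[is.na(df$historical_estimates)] <- ""
  df$dolphin_or_porpoise <- as.logical(df$dolphin_or_porpoise)
  validate_populations(df, file = path)
  df
}

validate_populations <- function(df, file = "<data>") {
  if (anyDuplicated(df$population_id)) {
    stop(sprintf("%s: duplicated population_id", file), call. = FALSE)
  }
  bad <- which(!is.finite(df$generation_time) | df$generation_time <= 0)
  if (length(bad) > 0) {
    stop(sprintf(
      "%s: generation_time must be > 0 (row(s) %s)",
      file, paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  kids <- population_contains(df)
  for (id in names(kids)) {
    if (id %in% kids[[id]]) {
      stop(sprintf("%s: population %s contains itself", file, id),
        call. = FALSE
      )
    }
    unknown <- setdiff(kids[[id]], df$population_id)
    if (length(unknown) > 0) {
      stop(sprintf(
        "%s: population %s contains unknown id(s) %s",
        file, id, paste(unknown, collapse = ", ")
      ), call. = FALSE)
    }
  }
  containment_closure(kids) # errors on a cycle
  invisible(df)
}

#' Write a population metadata table
#'
#' @param populations data frame as returned by [read_population_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_population_table <- function(populations, path) {
  utils::write.csv(populations[, .population_cols], path,
    row.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(path)
}

#' Parse the nesting relation of a population table
#'
#' @param populations population metadata data frame.
#' @return named list: for each population id, the character vector of
#'   ids directly nested inside it (possibly empty).
#' @export
population_contains <- function(populations) {
  out <- lapply(populations$contains, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(character(0))
    }
    trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  })
  names(out) <- populations$population_id
  out
}

#' Parse historical abundance estimates from a population table
#'
#' @param populations population metadata data frame.
#' @return named list of numeric vectors (possibly empty) of historical
#'   abundances per population.
#' @export
historical_estimates <- function(populations) {
  out <- lapply(populations$historical_estimates, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(numeric(0))
    }
    as.numeric(trimws(strsplit(s, ";", fixed = TRUE)[[1]]))
  })
  names(out) <- populations$population_id
  out
}

# transitive closure of the direct-containment lists; errors on a cycle
containment_closure <- function(kids) {
  closure <- list()
  visiting <- character(0)
  descend <- function(id) {
    if (!is.null(closure[[id]])) {
      return(closure[[id]])
    }
    if (id %in% visiting) {
      stop(sprintf("containment cycle involving population %s", id),
        call. = FALSE
      )
    }
    visiting <<- c(visiting, id)
    direct <- kids[[id]]
    all_desc <- direct
    for (d in direct) {
      if (d %in% names(kids)) all_desc <- union(all_desc, descend(d))
    }
    visiting <<- setdiff(visiting, id)
    closure[[id]] <<- all_desc
    all_desc
  }
  for (id in names(kids)) descend(id)
  closure
}

#' Choose between duplicate regular and pup-count series
#'
#' Some populations are indexed both by whole-population ("regular")
#' surveys and by pup counts at rookeries. Only one series per population
#' enters the analysis: the regular series is used unless the pup-count
#' series has strictly more points inside the population's assessment
#' window (ties keep the regular series). The chosen series carries a
#' `series_source` attribute (`"regular"` or `"pup"`).
#'
#' @param regular abundance data frame for the regular series (may have
#'   zero rows).
#' @param pup abundance data frame for the pup-count series (may have
#'   zero rows).
#' @param generation_time generation time in years, used to place each
#'   series' own assessment window (see [select_window()]).
#' @return the chosen series with attribute `series_source`.
#' @export
deduplicate_series <- function(regular, pup, generation_time) {
  n_reg <- if (is.null(regular)) 0L else nrow(regular)
  n_pup <- if (is.null(pup)) 0L else nrow(pup)
  if (n_reg == 0 && n_pup == 0) {
    stop("both the regular and the pup-count series are empty",
      call. = FALSE
    )
  }
  in_window <- function(series) {
    if (is.null(series) || nrow(series) == 0) {
      return(0L)
    }
    nrow(select_window(series, generation_time)$points)
  }
  if (in_window(pup) > in_window(regular)) {
    structure(pup, series_source = "pup")
  } else {
    structure(regular, series_source = "regular")
  }
}

.results_cols <- c(
  "population_id", "model_form", "slope", "se", "ci_lo", "ci_hi",
  "t_value", "p_value", "classification", "n_points",
  "window_start", "window_end"
)

#' Write (or read back) a trend-regression results table
#'
#' One row per population: selected model form, scaled slope, robust SE,
#' 95% CI, t and p values, the four-way classification, point count and
#' assessment window. Extra columns (e.g. both models' R-squared) are
#' preserved.
#'
#' @param results results data frame (see [run_pipeline()]).
#' @param path file path.
#' @return `path` (write) or the data frame (read).
#' @export
write_results_table <- function(results, path) {
  missing_cols <- setdiff(.results_cols, names(results))
  if (length(missing_cols) > 0) {
    stop(sprintf(
      "results table lacks column(s): %s",
      paste(missing_cols, collapse = ", ")
    ), call. = FALSE)
  }
  utils::write.csv(results, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  df <- utils::read.csv(path,
    stringsAsFactors = FALSE,
    colClasses = c(population_id = "character")
  )
  missing_cols <- setdiff(.results_cols, names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf(
      "%s: missing mandatory column(s): %s",
      path, paste(missing_cols, collapse = ", ")
    ), call. = FALSE)
  }
  df
}

#' Read a species-level reference trend table
#'
#' A local table of external species-level trend assessments (for
#' example, Red List trend listings) with columns `species_name` and
#' `category`.
#'
#' @param path file path.
#' @return data frame with `species_name` and `category`.
#' @export
read_species_trend_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("species_name", "category"), names(df))
  if (length(missing_cols) > 0) {
    stop(sprintf(
      "%s: missing mandatory column(s): %s",
      path, paste(missing_cols, collapse = ", ")
    ), call. = FALSE)
  }
  df
}
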