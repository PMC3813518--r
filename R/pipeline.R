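#' Configuration for an end-to-end pipeline run
#'
#' @param abundance path to the abundance CSV, or an already-read
#'   abundance data frame.
#' @param populations path to the population metadata CSV, or a data
#'   frame.
#' @param reference optional path to (or data frame of) a species-level
#'   reference trend table for the agreement comparison.
#' @param area_mode `"largest"` or `"smallest"`: which non-nested
#'   population set the group summaries and decline/recovery analysis
#'   use.
#' @param settings a [robust_settings()] object.
#' @param out_dir optional output directory for the CSV bundle.
#' @param seed integer seed recorded in the run log and passed to the
#'   robust fits.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(abundance, populations, reference = NULL,
                            area_mode = c("largest", "smallest"),
                            settings = robust_settings(),
                            out_dir = NULL, seed = 1L) {
  structure(
    list(
      abundance = abundance, populations = populations,
      reference = reference, area_mode = match.arg(area_mode),
      settings = settings, out_dir = out_dir, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

resolve_table <- function(x, reader) {
  if (is.character(x)) reader(x) else x
}

#' Run the full trend-assessment pipeline
#'
#' Sequences every stage of the assessment: read and validate the
#' abundance and metadata tables; collapse duplicate regular/pup-count
#' series (regular kept unless the pup series has strictly more
#' in-window points); select each population's three-generation (or
#' minimum ten-year) assessment window; fit the confidence-weighted
#' robust linear and log-linear trend regressions; compare the two model
#' forms by robust R-squared and classify each population from the
#' selected fit; tally classifications by taxon/habitat groupings over
#' the chosen non-nested population set; aggregate to species level and,
#' when a reference table is supplied, cross-tabulate against it; and
#' compute historical-decline/recent-recovery statistics for eligible
#' non-nested populations. Per-population failures are caught and
#' surfaced as Unknown classifications with the population id and
#' reason, so one bad series never aborts a run.
#'
#' The run is deterministic given the inputs, configuration and seed.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result`: `results` (one row per
#'   population: selected model fit statistics, both models' R-squared,
#'   classification), `fits` (per population: `linear`, `loglinear`
#'   fit objects and the comparison verdict), `summaries` (group tally
#'   data frame), `area_set` (ids of the non-nested set used),
#'   `species` (species-level trends), `agreement` (or `NULL`),
#'   `decline_recovery` (per-population table), `decline_recovery_groups`,
#'   `counts` (series at each filtering stage), `seed`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  abundance <- resolve_table(config$abundance, read_abundance_table)
  if (nrow(abundance) == 0) {
    stop("abundance table contains no rows", call. = FALSE)
  }
  populations <- resolve_table(config$populations, read_population_table)
  validate_abundance(abundance)
  validate_populations(populations)
  reference <- if (is.null(config$reference)) {
    NULL
  } else {
    resolve_table(config$reference, read_species_trend_table)
  }
  settings <- config$settings
  settings$seed <- config$seed

  missing_meta <- setdiff(
    unique(abundance$population_id),
    populations$population_id
  )
  if (length(missing_meta) > 0) {
    stop(sprintf(
      "abundance rows for population(s) %s lack metadata",
      paste(missing_meta, collapse = ", ")
    ), call. = FALSE)
  }

  # stage 1: split duplicate regular/pup series and deduplicate
  series_split <- split(abundance, abundance$population_id)
  n_input_series <- sum(vapply(
    series_split,
    function(s) length(unique(s$is_pup_count)),
    integer(1)
  ))
  gen_time <- stats::setNames(
    populations$generation_time, populations$population_id
  )
  series <- lapply(names(series_split), function(id) {
    s <- series_split[[id]]
    deduplicate_series(
      regular = s[!s$is_pup_count, , drop = FALSE],
      pup = s[s$is_pup_count, , drop = FALSE],
      generation_time = gen_time[[id]]
    )
  })
  names(series) <- names(series_split)

  # stage 2-4: window, fit both model forms, classify
  fits <- list()
  results_rows <- list()
  for (id in names(series)) {
    res <- tryCatch(
      {
        w <- select_window(series[[id]], gen_time[[id]])
        fit_lin <- fit_trend(w, "linear", settings)
        fit_log <- fit_trend(w, "loglinear", settings)
        verdict <- compare_models(fit_lin, fit_log)
        sel <- switch(verdict,
          linear_better = fit_lin,
          loglinear_better = ,
          similar = fit_log,
          unknown = fit_log
        )
        list(
          linear = fit_lin, loglinear = fit_log, verdict = verdict,
          selected = sel, window = w
        )
      },
      error = function(e) {
        message(sprintf(
          "population %s: %s (classified UNKNOWN)",
          id, conditionMessage(e)
        ))
        list(
          linear = unknown_fit("error", "linear"),
          loglinear = unknown_fit(conditionMessage(e), "loglinear"),
          verdict = "unknown",
          selected = unknown_fit(conditionMessage(e), "loglinear"),
          window = NULL
        )
      }
    )
    fits[[id]] <- res
    sel <- res$selected
    known <- inherits(sel, "trend_fit")
    r2 <- function(f) if (inherits(f, "trend_fit")) f$r_squared else NA_real_
    results_rows[[id]] <- data.frame(
      population_id = id,
      model_form = sel$model_form,
      slope = if (known) sel$slope else NA_real_,
      se = if (known) sel$se else NA_real_,
      ci_lo = if (known) sel$ci[1] else NA_real_,
      ci_hi = if (known) sel$ci[2] else NA_real_,
      t_value = if (known) sel$t_value else NA_real_,
      p_value = if (known) sel$p_value else NA_real_,
      classification = classify_trend(sel),
      n_points = sel$n_points,
      window_start = sel$window[1],
      window_end = sel$window[2],
      r_squared_linear = r2(res$linear),
      r_squared_loglinear = r2(res$loglinear),
      model_comparison = res$verdict,
      series_source = attr(series[[id]], "series_source"),
      stringsAsFactors = FALSE
    )
  }
  results <- do.call(rbind, c(results_rows, make.row.names = FALSE))
  classifications <- stats::setNames(
    results$classification, results$population_id
  )

  # stage 5: non-nested set, group summaries, species-level comparison
  area_set <- select_nonoverlapping(
    populations[populations$population_id %in% names(classifications), ,
      drop = FALSE
    ],
    config$area_mode
  )
  summaries <- summarize_group(
    classifications[area_set$population_id], area_set
  )
  species <- species_trends(classifications, populations, abundance)
  agreement <- if (is.null(reference)) {
    NULL
  } else {
    compare_with_reference(species, reference)
  }

  # stage 6: decline / recovery over the non-nested set
  dr_records <- lapply(seq_len(nrow(area_set)), function(i) {
    rec <- area_set[i, , drop = FALSE]
    population_decline_recovery(rec, series[[rec$population_id]])
  })
  dr_table <- decline_recovery_table(dr_records)
  dr_groups <- group_mean_decline_recovery(dr_table, populations)

  counts <- c(
    input_series = n_input_series,
    deduplicated = length(series),
    eligible = sum(vapply(
      fits,
      function(f) !is.null(f$window) && f$window$eligible,
      logical(1)
    )),
    classified = sum(classifications != "UNKNOWN")
  )
  message(paste(
    sprintf("%s: %d", names(counts), counts),
    collapse = " -> "
  ))

  out <- structure(
    list(
      results = results, fits = fits, summaries = summaries,
      area_set = area_set$population_id, species = species,
      agreement = agreement, decline_recovery = dr_table,
      decline_recovery_groups = dr_groups, counts = counts,
      seed = config$seed
    ),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(out, config$out_dir)
  }
  out
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_results_table(result$results, file.path(out_dir, "results.csv"))
  utils::write.csv(result$summaries, file.path(out_dir, "summaries.csv"),
    row.names = FALSE, fileEncoding = "UTF-8"
  )
  utils::write.csv(result$decline_recovery,
    file.path(out_dir, "decline_recovery.csv"),
    row.names = FALSE, fileEncoding = "UTF-8"
  )
  utils::write.csv(result$species, file.path(out_dir, "species_trends.csv"),
    row.names = FALSE, fileEncoding = "UTF-8"
  )
  if (!is.null(result$agreement)) {
    utils::write.csv(as.data.frame(result$agreement$table),
      file.path(out_dir, "agreement.csv"),
      row.names = FALSE, fileEncoding = "UTF-8"
    )
  }
  info <- data.frame(
    key = c("seed", names(result$counts)),
    value = c(result$seed, unname(result$counts))
  )
  utils::write.csv(info, file.path(out_dir, "run_info.csv"),
    row.names = FALSE, fileEncoding = "UTF-8"
  )
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Trend-assessment pipeline result\n")
  cat(
    "  stages:",
    paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", "),
    "\n"
  )
  all_row <- x$summaries[x$summaries$group == "all", ]
  if (nrow(all_row) > 0) {
    cat(sprintf(
      "  %s over %d non-nested populations\n",
      paste(sprintf(
        "%s %.0f%%", all_row$category, all_row$percent
      ), collapse = ", "),
      sum(all_row$count)
    ))
  }
  if (nrow(x$decline_recovery) > 0) {
    cat(sprintf(
      "  decline/recovery (n=%d): mean decline %.1f%%, mean recovery %.1f%%\n",
      nrow(x$decline_recovery),
      mean(x$decline_recovery$mean_decline_pct),
      mean(x$decline_recovery$mean_recovery_pct)
    ))
  }
  invisible(x)
}
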