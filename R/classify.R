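#' The four trend categories
#'
#' @format character vector of the four population trend categories.
#' @export
trend_categories <- c(
  "SIG_INCREASING", "SIG_DECREASING", "NON_SIGNIFICANT", "UNKNOWN"
)

#' Classify a population trend from its robust fit
#'
#' A population is Significantly Increasing when the slope is positive
#' and the 95% confidence interval excludes zero, Significantly
#' Decreasing when the slope is negative and the interval excludes zero,
#' and Non-Significant Change when the interval contains zero. An
#' ineligible series (too few points or too short a span), a
#' non-converged fit, or a degenerate (constant-response) series is
#' Unknown.
#'
#' @param fit a `trend_fit` or `unknown_fit` from [fit_trend()].
#' @return one of `"SIG_INCREASING"`, `"SIG_DECREASING"`,
#'   `"NON_SIGNIFICANT"`, `"UNKNOWN"`.
#' @export
#' @examples
#' w <- select_window(
#'   data.frame(
#'     population_id = "p", year = 1990:2008,
#'     abundance = exp(0.1 * (0:18)) * 100, error_kind = "none",
#'     error_lo = NA, error_hi = NA, is_pup_count = FALSE, acid_rank = 5
#'   ),
#'   generation_time = 5
#' )
#' classify_trend(fit_trend(w, "loglinear"))
classify_trend <- function(fit) {
  if (inherits(fit, "unknown_fit")) {
    return("UNKNOWN")
  }
  stopifnot(inherits(fit, "trend_fit"))
  if (!fit$converged || any(is.na(fit$ci))) {
    return("UNKNOWN")
  }
  if (fit$slope > 0 && fit$ci[1] > 0) {
    return("SIG_INCREASING")
  }
  if (fit$slope < 0 && fit$ci[2] < 0) {
    return("SIG_DECREASING")
  }
  "NON_SIGNIFICANT"
}

#' Select the largest or smallest non-nested population set
#'
#' Populations whose survey areas are nested inside one another index
#' overlapping sets of animals; analysing them together double-counts
#' individuals. Using the (acyclic) containment relation from the
#' metadata table, this returns either every maximal population (not
#' contained in any other; `mode = "largest"`) or every minimal one
#' (containing no other; `mode = "smallest"`). No two returned
#' populations are related by containment. When no containment edges
#' exist the two modes coincide.
#'
#' @param populations population metadata data frame.
#' @param mode `"largest"` or `"smallest"`.
#' @return the subset of `populations` rows, in input order.
#' @export
select_nonoverlapping <- function(populations, mode = c("largest", "smallest")) {
  mode <- match.arg(mode)
  kids <- population_contains(populations)
  closure <- containment_closure(kids)
  if (mode == "largest") {
    contained <- unique(unlist(closure, use.names = FALSE))
    keep <- !(populations$population_id %in% contained)
  } else {
    keep <- lengths(closure[populations$population_id]) == 0
  }
  populations[keep, , drop = FALSE]
}

# group membership indicator lists built from the metadata columns;
# groupings are deliberately not mutually exclusive (a dolphin population
# counts under all, cetacean, odontocete and dolphin_porpoise)
group_membership <- function(populations) {
  groups <- list(all = rep(TRUE, nrow(populations)))
  for (v in unique(populations$species_type)) {
    groups[[v]] <- populations$species_type == v
  }
  for (v in unique(populations$sub_type)) {
    groups[[v]] <- populations$sub_type == v
  }
  if (any(populations$dolphin_or_porpoise)) {
    groups[["dolphin_porpoise"]] <- populations$dolphin_or_porpoise
  }
  for (v in setdiff(unique(populations$habitat), "not_applicable")) {
    groups[[v]] <- populations$habitat == v
  }
  groups
}

#' Tally trend classifications by taxon and habitat groupings
#'
#' Counts and percentages of the four trend categories within each
#' grouping: all populations, each species type (cetacean, pinniped,
#' other), each sub-type (mysticete, odontocete, otariid, phocid, ...),
#' the dolphin-and-porpoise subset, and each habitat type. Groupings are
#' data-driven from the metadata columns and overlap by design. Empty
#' groups are absent from the output.
#'
#' @param classifications named character vector mapping population_id
#'   to a trend category.
#' @param populations population metadata data frame covering (at least)
#'   the classified populations.
#' @param grouping optional character vector restricting the reported
#'   group labels.
#' @return data frame with `group`, `category`, `count`, `percent`;
#'   within each group the percentages sum to 100 up to rounding of the
#'   counts.
#' @export
summarize_group <- function(classifications, populations, grouping = NULL) {
  populations <- populations[
    populations$population_id %in% names(classifications), ,
    drop = FALSE
  ]
  if (!all(populations$population_id %in% names(classifications))) {
    stop("every population must be classified", call. = FALSE)
  }
  cls <- classifications[populations$population_id]
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
    member_cls <- cls[groups[[g]]]
    n <- length(member_cls)
    if (n == 0) next
    counts <- table(factor(member_cls, levels = trend_categories))
    rows[[g]] <- data.frame(
      group = g,
      category = trend_categories,
      count = as.integer(counts),
      percent = 100 * as.integer(counts) / n,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

# population-level category -> species-level label
.species_label <- c(
  SIG_INCREASING = "Increasing",
  SIG_DECREASING = "Decreasing",
  NON_SIGNIFICANT = "Non-Significant",
  UNKNOWN = "Unknown"
)

#' Species-level trend from its populations' classifications
#'
#' External assessments (e.g. Red List trends) are made at the species
#' level, while trends here are fit per population. A species' trend is
#' the category of the population holding the majority (> 50%) of the
#' species' summed recent abundance; when no population dominates, the
#' most frequent category among the (non-nested) populations is used,
#' and when no unique mode exists the species is listed as Unknown.
#'
#' @param classifications named character vector (population_id ->
#'   category) for the populations of one species.
#' @param abundance_shares named numeric vector of each population's
#'   recent abundance (same names); used to find a majority holder.
#' @return one of `Increasing`, `Decreasing`, `Non-Significant`,
#'   `Unknown`.
#' @export
#' @examples
#' species_level_classification(
#'   c(a = "SIG_INCREASING", b = "SIG_INCREASING", c = "SIG_DECREASING"),
#'   c(a = 100, b = 100, c = 100)
#' )
species_level_classification <- function(classifications, abundance_shares) {
  stopifnot(
    length(classifications) >= 1,
    all(names(classifications) %in% names(abundance_shares))
  )
  shares <- abundance_shares[names(classifications)]
  if (sum(shares) > 0) {
    frac <- shares / sum(shares)
    if (max(frac) > 0.5) {
      return(unname(.species_label[classifications[which.max(frac)]]))
    }
  }
  counts <- table(classifications)
  top <- counts[counts == max(counts)]
  if (length(top) == 1) {
    return(unname(.species_label[names(top)]))
  }
  "Unknown"
}

#' Species-level trends for a whole analysis
#'
#' Applies [species_level_classification()] to every species, using the
#' non-nested (largest-area) populations of the species and each
#' population's most recent abundance estimate as its share.
#'
#' @param classifications named character vector (population_id ->
#'   category).
#' @param populations population metadata data frame.
#' @param abundance abundance data frame (all series).
#' @return data frame with `species_name`, `category`, `n_populations`,
#'   and `source = "this_pipeline"`.
#' @export
species_trends <- function(classifications, populations, abundance) {
  populations <- populations[
    populations$population_id %in% names(classifications), ,
    drop = FALSE
  ]
  nonnested <- select_nonoverlapping(populations, "largest")
  recent <- vapply(
    nonnested$population_id,
    function(id) {
      s <- abundance[abundance$population_id == id, , drop = FALSE]
      if (nrow(s) == 0) {
        return(0)
      }
      s$abundance[which.max(s$year)]
    },
    numeric(1)
  )
  names(recent) <- nonnested$population_id
  rows <- lapply(split(nonnested, nonnested$species_name), function(sp) {
    ids <- sp$population_id
    data.frame(
      species_name = sp$species_name[1],
      category = species_level_classification(
        classifications[ids], recent[ids]
      ),
      n_populations = length(ids),
      source = "this_pipeline",
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Compare species-level trends with a reference table
#'
#' Cross-tabulates this pipeline's species-level categories against an
#' external reference (e.g. Red List trend listings), joining on the
#' species name after trimming and case-folding. Species present on only
#' one side are listed separately, not treated as errors.
#'
#' @param ours data frame with `species_name`, `category`.
#' @param reference data frame with `species_name`, `category`.
#' @return list of class `trend_agreement`: `table` (cross-tab,
#'   rows = ours), `ours_percent` and `reference_percent` (per-category
#'   percentages over the matched species), `n_matched`,
#'   `unmatched_ours`, `unmatched_reference`, `agreement_percent`
#'   (exact category agreement over matched species).
#' @export
compare_with_reference <- function(ours, reference) {
  norm <- function(x) tolower(trimws(x))
  key_o <- norm(ours$species_name)
  key_r <- norm(reference$species_name)
  matched <- intersect(key_o, key_r)
  o <- ours$category[match(matched, key_o)]
  r <- reference$category[match(matched, key_r)]
  tab <- table(ours = o, reference = r)
  pct <- function(x) {
    if (length(x) == 0) {
      return(numeric(0))
    }
    100 * table(x) / length(x)
  }
  structure(
    list(
      table = tab,
      ours_percent = pct(o),
      reference_percent = pct(r),
      n_matched = length(matched),
      unmatched_ours = ours$species_name[!(key_o %in% matched)],
      unmatched_reference = reference$species_name[!(key_r %in% matched)],
      agreement_percent = if (length(matched) > 0) {
        100 * mean(o == r)
      } else {
        NA_real_
      }
    ),
    class = "trend_agreement"
  )
}

#' @export
print.trend_agreement <- function(x, ...) {
  cat("Species-level trend agreement (", x$n_matched, " matched species)\n",
    sep = ""
  )
  print(x$table)
  cat(sprintf("Exact agreement: %.1f%%\n", x$agreement_percent))
  if (length(x$unmatched_ours) > 0) {
    cat(
      "Not in reference:", paste(x$unmatched_ours, collapse = ", "),
      "\n"
    )
  }
  invisible(x)
}
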