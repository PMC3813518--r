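# builders for in-memory abundance series and metadata tables

make_series <- function(years, abundance, id = "p1", acid_rank = 5L,
                        is_pup_count = FALSE, error_kind = "none",
                        error_lo = NA_real_, error_hi = NA_real_) {
  data.frame(
    population_id = id,
    year = years,
    abundance = abundance,
    error_kind = error_kind,
    error_lo = error_lo,
    error_hi = error_hi,
    is_pup_count = is_pup_count,
    acid_rank = as.integer(acid_rank),
    stringsAsFactors = FALSE
  )
}

# noise-free exponential series N0 * exp(r * (t - t0))
make_exp_series <- function(years, r, n0 = 1000, id = "p1", acid_rank = 5L) {
  make_series(years, n0 * exp(r * (years - years[1])),
    id = id,
    acid_rank = acid_rank
  )
}

make_population <- function(id, species = "Species X",
                            species_type = "pinniped",
                            sub_type = "phocid",
                            dolphin_or_porpoise = FALSE,
                            habitat = "not_applicable",
                            generation_time = 10,
                            contains = "",
                            historical = "") {
  data.frame(
    population_id = id,
    species_name = species,
    species_type = species_type,
    sub_type = sub_type,
    dolphin_or_porpoise = dolphin_or_porpoise,
    habitat = habitat,
    generation_time = generation_time,
    area_label = paste("area", id),
    contains = contains,
    historical_estimates = historical,
    stringsAsFactors = FALSE
  )
}

windowed_from <- function(series, generation_time = 10) {
  select_window(series, generation_time)
}
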