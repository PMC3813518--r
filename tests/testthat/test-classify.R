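fake_fit <- function(slope, ci, converged = TRUE) {
  structure(
    list(
      model_form = "loglinear", slope = slope, ci = ci,
      converged = converged, n_points = 10L
    ),
    class = "trend_fit"
  )
}

test_that("the CI rule yields the four-way classification", {
  expect_identical(classify_trend(fake_fit(0.5, c(0.2, 0.8))), "SIG_INCREASING")
  expect_identical(classify_trend(fake_fit(-0.3, c(-0.5, -0.1))), "SIG_DECREASING")
  expect_identical(classify_trend(fake_fit(0.1, c(-0.1, 0.3))), "NON_SIGNIFICANT")
  expect_identical(classify_trend(fake_fit(0.1, c(-0.1, 0.3), FALSE)), "UNKNOWN")
  # classification is a pure function of (slope, CI): same inputs in any
  # order of evaluation give the same answer
  fits <- list(
    fake_fit(0.5, c(0.2, 0.8)), fake_fit(-0.3, c(-0.5, -0.1)),
    fake_fit(0, c(-0.2, 0.2))
  )
  direct <- vapply(fits, classify_trend, character(1))
  shuffled <- vapply(fits[c(3, 1, 2)], classify_trend, character(1))
  expect_identical(direct, shuffled[c(2, 3, 1)])
})

test_that("largest/smallest non-nested selection follows the containment order", {
  chain <- rbind(
    make_population("A", contains = "B"),
    make_population("B", contains = "C"),
    make_population("C")
  )
  expect_identical(
    select_nonoverlapping(chain, "largest")$population_id, "A"
  )
  expect_identical(
    select_nonoverlapping(chain, "smallest")$population_id, "C"
  )
  disjoint <- rbind(make_population("A"), make_population("B"))
  expect_identical(
    select_nonoverlapping(disjoint, "largest")$population_id,
    select_nonoverlapping(disjoint, "smallest")$population_id
  )
  cyc <- rbind(
    make_population("A", contains = "B"),
    make_population("B", contains = "A")
  )
  expect_error(select_nonoverlapping(cyc, "largest"), "cycle")

  # forest with one nested pair: largest drops the child, smallest the parent
  forest <- rbind(
    make_population("P", contains = "Q"),
    make_population("Q"),
    make_population("R")
  )
  expect_setequal(
    select_nonoverlapping(forest, "largest")$population_id, c("P", "R")
  )
  expect_setequal(
    select_nonoverlapping(forest, "smallest")$population_id, c("Q", "R")
  )
})

test_that("group summaries count overlapping groupings and sum to 100%", {
  pops <- rbind(
    make_population("c1",
      species_type = "cetacean", sub_type = "odontocete",
      dolphin_or_porpoise = TRUE, habitat = "coastal"
    ),
    make_population("c2",
      species_type = "cetacean", sub_type = "mysticete",
      habitat = "offshore"
    ),
    make_population("p1", species_type = "pinniped", sub_type = "otariid"),
    make_population("p2", species_type = "pinniped", sub_type = "phocid"),
    make_population("o1", species_type = "other", sub_type = "otter")
  )
  pops <- pops[rep(1:5, 2), ]
  pops$population_id <- paste0(pops$population_id, rep(c("", "x"), each = 5))
  cls <- stats::setNames(
    c(
      "SIG_INCREASING", "SIG_INCREASING", "SIG_INCREASING", "SIG_INCREASING",
      "SIG_DECREASING", "NON_SIGNIFICANT", "NON_SIGNIFICANT",
      "NON_SIGNIFICANT", "UNKNOWN", "UNKNOWN"
    ),
    pops$population_id
  )
  sm <- summarize_group(cls, pops)
  all_rows <- sm[sm$group == "all", ]
  expect_equal(all_rows$percent, c(40, 10, 30, 20))
  expect_equal(sum(all_rows$count), 10)
  # every group's percentages sum to 100 up to rounding
  for (g in unique(sm$group)) {
    expect_equal(sum(sm$percent[sm$group == g]), 100, tolerance = 1e-9)
  }
  # a dolphin population is tallied in all, cetacean, odontocete and the
  # dolphin/porpoise subgroup
  for (g in c("all", "cetacean", "odontocete", "dolphin_porpoise")) {
    expect_true(g %in% sm$group)
    expect_gte(sum(sm$count[sm$group == g & sm$category == "SIG_INCREASING"]), 1)
  }
  expect_false("not_applicable" %in% sm$group)
  expect_error(summarize_group(cls, pops, grouping = "nope"), "unknown grouping")
})

test_that("species-level classification follows majority abundance then the mode", {
  # equal shares, modal category wins
  expect_identical(
    species_level_classification(
      c(a = "SIG_INCREASING", b = "SIG_INCREASING", c = "SIG_DECREASING"),
      c(a = 100, b = 100, c = 100)
    ),
    "Increasing"
  )
  # three different categories, no mode: Unknown
  expect_identical(
    species_level_classification(
      c(a = "SIG_INCREASING", b = "SIG_DECREASING", c = "NON_SIGNIFICANT"),
      c(a = 100, b = 100, c = 100)
    ),
    "Unknown"
  )
  # a single population speaks for the species
  expect_identical(
    species_level_classification(c(a = "NON_SIGNIFICANT"), c(a = 5)),
    "Non-Significant"
  )
  # a majority-abundance holder overrides the mode
  expect_identical(
    species_level_classification(
      c(a = "SIG_DECREASING", b = "SIG_INCREASING", c = "SIG_INCREASING"),
      c(a = 1000, b = 10, c = 10)
    ),
    "Decreasing"
  )
})

test_that("reference comparison cross-tabulates and reports unmatched species", {
  ours <- data.frame(
    species_name = c("A sp", "B sp", "C sp"),
    category = c("Increasing", "Decreasing", "Unknown")
  )
  identical_ref <- ours
  agr <- compare_with_reference(ours, identical_ref)
  expect_equal(agr$agreement_percent, 100)
  expect_equal(sum(diag(agr$table)), 3)
  expect_equal(sum(agr$table) - sum(diag(agr$table)), 0)

  ref2 <- ours
  ref2$category[2] <- "Stable"
  agr2 <- compare_with_reference(ours, ref2)
  expect_equal(sum(agr2$table) - sum(diag(agr2$table[
    intersect(rownames(agr2$table), colnames(agr2$table)),
    intersect(rownames(agr2$table), colnames(agr2$table))
  ])), 1)
  expect_equal(agr2$agreement_percent, 100 * 2 / 3)

  ref3 <- rbind(identical_ref, data.frame(
    species_name = "D sp", category = "Increasing"
  ))
  agr3 <- compare_with_reference(ours[1:2, ], ref3)
  expect_equal(agr3$n_matched, 2)
  expect_setequal(agr3$unmatched_reference, c("C sp", "D sp"))
})

test_that("a planted species composition is reported back exactly", {
  set.seed(23)
  planted <- rep(
    c("Increasing", "Decreasing", "Non-Significant", "Unknown"),
    times = c(10, 5, 3, 9)
  ) # 27 species
  ours <- data.frame(
    species_name = sprintf("Species %02d", 1:27),
    category = sample(planted)
  )
  ref <- data.frame(
    species_name = sprintf("species %02d  ", 1:27), # case/space normalised
    category = sample(planted)
  )
  agr <- compare_with_reference(ours, ref)
  expect_equal(agr$n_matched, 27)
  expect_equal(
    as.numeric(agr$ours_percent[c(
      "Increasing", "Decreasing", "Non-Significant", "Unknown"
    )]),
    100 * c(10, 5, 3, 9) / 27
  )
  expect_equal(sum(agr$table), 27)
})
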