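test_that("death records read back with label mapping and rejection tally", {
  df <- data.frame(age = c(14, 28, 41), year = c(2002, 2008, 2014),
                   schooling = c("none", "PROFESIONAL", "secondary"),
                   marginalization = c("very_high", "low", "nonsense"),
                   medical_care = c("yes", "no", "unknown"),
                   affiliation = c("no", "yes", "yes"))
  path <- write_deaths_csv(df)

  rec <- suppressWarnings(
    read_death_records(path,
                       label_maps = list(schooling = c(PROFESIONAL = "professional"))))
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$age, c(14L, 28L, 41L))
  expect_equal(rec$year, c(2002L, 2008L, 2014L))
  expect_equal(rec$schooling[2], "professional")
  # unmapped string falls back to unknown, with a warning tally
  expect_equal(rec$marginalization[3], "unknown")
  expect_equal(attr(rec, "n_unknown"), 1L)

  # malformed age -> row rejected and tallied
  df$age <- as.character(df$age)
  df$age[2] <- "n/a"
  path2 <- write_deaths_csv(df)
  expect_warning(rec2 <- read_death_records(path2), "rejected")
  expect_equal(nrow(rec2), 2L)
  expect_equal(attr(rec2, "n_rejected"), 1L)

  # missing column is a hard error naming the column
  df3 <- df[, setdiff(names(df), "affiliation")]
  expect_error(read_death_records(write_deaths_csv(df3)), "affiliation")
})

test_that("build_lexis counts deaths into cells and derives the cohort", {
  deaths <- data.frame(age = c(20, 20), year = c(2005, 2005),
                       schooling = "none", marginalization = "low",
                       medical_care = "yes", affiliation = "yes")
  births <- data.frame(mother_age = 20, year = 2005, births = 10000)
  tab <- build_lexis(deaths, births, c(20, 20), c(2005, 2005))
  expect_s3_class(tab, "lexis_table")
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$cohort, 1985)
  expect_equal(tab$deaths, 2L)
  expect_equal(tab$exposure, 10000)

  # deaths in a cell with no birth entry: cell dropped with a warning
  deaths2 <- rbind(deaths,
                   data.frame(age = 21, year = 2005, schooling = "none",
                              marginalization = "low", medical_care = "yes",
                              affiliation = "yes"))
  expect_warning(tab2 <- build_lexis(deaths2, births, c(20, 21), c(2005, 2005)),
                 "dropped")
  expect_equal(nrow(tab2), 1L)
  expect_false(21 %in% tab2$age)

  # duplicate birth keys are an error
  expect_error(build_lexis(deaths, rbind(births, births),
                           c(20, 20), c(2005, 2005)), "duplicate")
  # empty intersection is an error
  expect_error(build_lexis(deaths, births, c(30, 35), c(2005, 2005)),
               "no death records")
})

test_that("tabulating a full synthetic record stream preserves totals", {
  sim <- fixture_sim(seed = 7)
  births <- data.frame(mother_age = sim$table$age, year = sim$table$period,
                       births = sim$table$exposure)
  tab <- build_lexis(sim$records, births, c(10, 54), c(2002, 2014))
  expect_equal(nrow(tab), 45 * 13)
  expect_equal(sum(tab$deaths), nrow(sim$records))
  expect_equal(tab$cohort, tab$period - tab$age)
  # brute-force recount of a handful of cells straight from the records
  for (i in c(1, 100, 300, 585)) {
    expect_equal(tab$deaths[i],
                 sum(sim$records$age == tab$age[i] &
                       sim$records$year == tab$period[i]))
  }
})

test_that("crude_mmr computes rates per 100,000 with a grand total", {
  tab <- lexis_table(data.frame(age = 20, period = 2005, cohort = 1985,
                                deaths = 2, exposure = 10000))
  out <- crude_mmr(tab)
  expect_equal(out$rate, 20)
  expect_equal(out$stratum, "total")

  # the MDG target arithmetic: 429 deaths / 1,923,767 births = 22.3
  tab2 <- lexis_table(data.frame(age = 25, period = 2015, cohort = 1990,
                                 deaths = 429, exposure = 1923767))
  expect_equal(crude_mmr(tab2)$rate, 22.3, tolerance = 0.05 / 22.3)

  # per-period rates against an independent groupby recomputation
  sim <- fixture_sim(seed = 11)
  by_period <- crude_mmr(sim$table, by = "period")
  expect_equal(nrow(by_period), 13 + 1)
  agg <- aggregate(cbind(deaths, exposure) ~ period,
                   data = as.data.frame(sim$table), FUN = sum)
  expect_equal(by_period$rate[seq_len(13)],
               agg$deaths / agg$exposure * 1e5)
})

test_that("crude_mmr invariants: scale equivariance and undefined strata", {
  sim <- fixture_sim(seed = 3)
  tab <- sim$table
  r1 <- crude_mmr(tab, by = "age")
  tab2 <- tab
  tab2$exposure <- tab2$exposure * 2
  r2 <- crude_mmr(lexis_table(as.data.frame(tab2)), by = "age")
  expect_equal(r2$rate, r1$rate / 2)
})
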