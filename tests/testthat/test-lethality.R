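test_that("single-drug counts match hand-enumerated fixtures", {
  deaths <- make_deaths(
    list("fentanyl", c("fentanyl", "cocaine"), "fentanyl"),
    years = c(2017, 2017, 2016)
  )
  expect_equal(count_single_drug_deaths(deaths, "fentanyl", 2017), 1L)
  expect_equal(count_single_drug_deaths(deaths, "fentanyl", 2016), 1L)
  expect_equal(count_single_drug_deaths(deaths[0, ], "fentanyl", 2017), 0L)

  seiz <- make_seizures(list("fentanyl", c("fentanyl", "heroin")))
  expect_equal(count_single_drug_seizures(seiz, "fentanyl", 2017), 1L)
  expect_equal(count_all_seizures(seiz, "fentanyl", 2017), 2L)
  expect_equal(count_all_seizures(seiz, "heroin", 2017), 1L)
  expect_equal(count_single_drug_seizures(seiz[0, ], "fentanyl", 2017), 0L)
})

test_that("'other' substances break single-drug status unless ignored", {
  deaths <- make_deaths(list(c("fentanyl", "other:alcohol")))
  expect_equal(count_single_drug_deaths(deaths, "fentanyl", 2017), 0L)
  expect_equal(
    count_single_drug_deaths(deaths, "fentanyl", 2017, ignore_other_substances = TRUE),
    1L
  )
})

test_that("counting operations agree with the exhaustive-scan oracle on synthetic data", {
  sim <- generate_market(small_market(seed = 11L))
  tal <- sim$log$drug_year
  for (i in seq_len(nrow(tal))) {
    d <- tal$drug[i]; y <- tal$year[i]
    expect_equal(
      count_single_drug_seizures(sim$seizures, d, y),
      brute_count(sim$seizures, "substances", "date", d, y, single_only = TRUE)
    )
    expect_equal(
      count_all_seizures(sim$seizures, d, y),
      brute_count(sim$seizures, "substances", "date", d, y)
    )
    expect_equal(
      count_single_drug_deaths(sim$deaths, d, y),
      brute_count(sim$deaths, "tox_substances", "date_of_death", d, y,
                  single_only = TRUE)
    )
    expect_gte(count_all_seizures(sim$seizures, d, y),
               count_single_drug_seizures(sim$seizures, d, y))
  }
})

test_that("lethality ratios divide exactly and report at 3 decimals", {
  round3 <- function(x) sign(x) * floor(abs(x) * 1000 + 0.5) / 1000
  expect_equal(round3(lethality_ratio(1497, 3812)), 0.393)
  expect_equal(round3(lethality_ratio(28, 5437)), 0.005)
  # half-away-from-zero at the reporting layer: 254/5781 = 0.0439... -> 0.044
  expect_equal(round3(lethality_ratio(254, 5781)), 0.044)
  expect_equal(lethality_ratio(0, 100), 0)
  expect_equal(lethality_ratio(1, 3), 1 / 3) # full precision kept
  expect_error(lethality_ratio(5, 0), class = "sdli_degenerate_error")
  expect_error(lethality_ratio(5, 0, drug = "heroin"), "heroin")
})

test_that("ratio is scale-consistent", {
  for (k in c(2L, 7L, 100L)) {
    expect_equal(lethality_ratio(21 * k, 392 * k), lethality_ratio(21, 392))
  }
})

test_that("the lethality table excludes drugs without single-drug seizures", {
  seiz <- make_seizures(list("fentanyl", "cocaine", c("heroin", "fentanyl")))
  deaths <- make_deaths(list("fentanyl"))
  expect_warning(
    tab <- build_lethality_table(deaths, seiz, 2017,
                                 drugs = c("fentanyl", "cocaine", "heroin")),
    "heroin"
  )
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$lr[tab$drug == "fentanyl"], 1)
  expect_equal(attr(tab, "reference_year"), 2017L)
  expect_error(build_lethality_table(deaths, seiz, 2017, drugs = character()),
               class = "sdli_config_error")
})

test_that("SALI sums lethality-weighted seizure counts", {
  # one drug, lr = 0.5, 10 seizures -> 5.0
  seiz <- make_seizures(rep(list("fentanyl"), 10))
  deaths <- make_deaths(rep(list("fentanyl"), 5))
  tab <- build_lethality_table(deaths, seiz, 2017, drugs = "fentanyl")
  sali <- compute_sali_series(tab, seiz, 2017)
  expect_equal(sali$sali, 5)

  # two drugs, lr 0.1 and 0.2 with 10 and 5 seizures -> 2.0
  seiz2 <- make_seizures(c(rep(list("fentanyl"), 10), rep(list("cocaine"), 5)))
  deaths2 <- make_deaths(c(rep(list("fentanyl"), 1), rep(list("cocaine"), 1)))
  tab2 <- build_lethality_table(deaths2, seiz2, 2017,
                                drugs = c("fentanyl", "cocaine"))
  expect_equal(tab2$lr, c(0.1, 0.2))
  expect_equal(compute_sali_series(tab2, seiz2, 2017)$sali, 2)
})

test_that("SALI equals a from-scratch recomputation on synthetic data", {
  sim <- generate_market(small_market(seed = 11L))
  drugs <- sim$params$drugs
  years <- sim$params$years
  deaths <- filter_unintentional(sim$deaths)
  tab <- build_lethality_table(deaths, sim$seizures, 2018, drugs = drugs)
  sali <- compute_sali_series(tab, sim$seizures, years)

  # spreadsheet-style recomputation from raw records
  for (y in years) {
    expected <- 0
    for (d in tab$drug) {
      lr <- count_single_drug_deaths(deaths, d, 2018) /
        count_single_drug_seizures(sim$seizures, d, 2018)
      expected <- expected + lr * count_all_seizures(sim$seizures, d, y)
    }
    expect_equal(sali$sali[sali$year == y], expected)
  }
  # the per-drug SDLI detail sums to the series
  sdli_long <- attr(sali, "sdli")
  agg <- tapply(sdli_long$sdli, sdli_long$year, sum)
  expect_equal(as.numeric(agg[as.character(sali$year)]), sali$sali)
})

test_that("SALI is linear in seizure counts and additive over disjoint drug sets", {
  sim <- generate_market(small_market(seed = 13L))
  deaths <- filter_unintentional(sim$deaths)
  tab <- build_lethality_table(deaths, sim$seizures, 2018,
                               drugs = sim$params$drugs)
  years <- sim$params$years
  sali <- compute_sali_series(tab, sim$seizures, years)

  # doubling every seizure record doubles each year's SALI
  doubled <- sim$seizures
  doubled2 <- doubled
  doubled2$seizure_id <- paste0(doubled2$seizure_id, "b")
  both <- rbind(doubled, doubled2)
  sali2 <- compute_sali_series(tab, both, years)
  expect_equal(sali2$sali, 2 * sali$sali)

  # additivity: SALI over {fentanyl} + SALI over {cocaine, heroin}
  tab_a <- tab[tab$drug == "fentanyl", ]
  tab_b <- tab[tab$drug != "fentanyl", ]
  attr(tab_a, "reference_year") <- attr(tab, "reference_year")
  attr(tab_b, "reference_year") <- attr(tab, "reference_year")
  sali_a <- compute_sali_series(tab_a, sim$seizures, years)
  sali_b <- compute_sali_series(tab_b, sim$seizures, years)
  expect_equal(sali_a$sali + sali_b$sali, sali$sali)
})

test_that("annual seizure counts partition across years", {
  sim <- generate_market(small_market(seed = 17L))
  years <- sim$params$years
  for (d in sim$params$drugs) {
    per_year <- vapply(years, function(y) count_all_seizures(sim$seizures, d, y),
                       integer(1))
    total <- sum(vapply(sim$seizures$substances, function(s) d %in% s, logical(1)))
    expect_equal(sum(per_year), total)
  }
})

test_that("annual death totals respect scope", {
  deaths <- make_deaths(
    list("fentanyl", c("fentanyl", "cocaine"), "other:xylazine"),
    years = c(2017, 2017, 2018)
  )
  all_scope <- annual_deaths(deaths, 2017:2018)
  expect_equal(all_scope$deaths, c(2L, 1L))
  indexed <- annual_deaths(deaths, 2017:2018, scope = "indexed_drugs_only")
  expect_equal(indexed$deaths, c(2L, 0L))
})
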