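# A pool carrying the variable names used by the published query examples.
query_fixture <- function(seed = 1) {
  tab <- make_county_fixture(
    4, seed = seed,
    qualitative = list(
      race = c("White", "Black", "Other"),
      Highest_Level_of_education = c("Dropout", "HighSchool", "College")),
    quantitative = list(
      income_per_capita = c(15000, 90000),
      `EXTRACRANIAL_PROCEDURES_W-O_CC-mcc_avg_charge` = c(5000, 60000)))
  pool <- build_pool(tab, "pop", 1000, seed = seed)
  for (v in c("race", "Highest_Level_of_education")) {
    pool <- integrate_qualitative(pool, v, tab)
  }
  for (v in c("income_per_capita", "EXTRACRANIAL_PROCEDURES_W-O_CC-mcc_avg_charge")) {
    pool <- integrate_quantitative(pool, v, tab)
  }
  list(pool = pool, summary = build_summary(list(tab)))
}

test_that("the published income/race query parses to its stated filter structure", {
  fx <- query_fixture()
  q <- parse_query(paste0("income_per_capita[min]=60000&race=White&race=Black",
                          "&reqVar=EXTRACRANIAL_PROCEDURES_W-O_CC-mcc_avg_charge"),
                   fx$summary)
  expect_equal(q$filters$income_per_capita$type, "bounds")
  expect_equal(q$filters$income_per_capita$min, 60000)
  expect_null(q$filters$income_per_capita$max)
  expect_equal(q$filters$race$type, "categories")
  expect_setequal(q$filters$race$labels, c("White", "Black"))
  expect_equal(q$requested_vars, "EXTRACRANIAL_PROCEDURES_W-O_CC-mcc_avg_charge")
})

test_that("the published education query parses: one category filter plus reqVar", {
  fx <- query_fixture()
  q <- parse_query("reqVar=income_per_capita&Highest_Level_of_education=Dropout",
                   fx$summary)
  expect_equal(names(q$filters), "Highest_Level_of_education")
  expect_equal(q$filters$Highest_Level_of_education$labels, "Dropout")
  expect_equal(q$requested_vars, "income_per_capita")
})

test_that("a filterless query is vacuous and malformed queries fail by name", {
  fx <- query_fixture()
  q <- parse_query("reqVar=income_per_capita", fx$summary)
  expect_length(q$filters, 0)
  expect_equal(nrow(execute_query(fx$pool, q)), nrow(fx$pool))

  expect_error(parse_query("race=White", fx$summary), "reqVar")
  expect_error(parse_query("reqVar=nope", fx$summary), "nope")
  expect_error(parse_query("race[min]=3&reqVar=income_per_capita", fx$summary),
               "qualitative")
  expect_error(parse_query("income_per_capita=White&reqVar=income_per_capita",
                           fx$summary), "quantitative")
  expect_error(parse_query("", fx$summary), "empty")
})

test_that("query execution equals the filter-engine path on the same pool", {
  fx <- query_fixture(3)
  q <- parse_query(paste0("income_per_capita[min]=60000&race=White&race=Black",
                          "&reqVar=EXTRACRANIAL_PROCEDURES_W-O_CC-mcc_avg_charge"),
                   fx$summary)
  res <- execute_query(fx$pool, q)

  state <- new_filter_state()
  state <- set_filter(state, "income_per_capita", flt_interval(60000, Inf))
  state <- set_filter(state, "race", flt_categories("White", "Black"))
  expect_identical(res$sample_id, current_selection(fx$pool, state))
  expect_identical(
    res$`EXTRACRANIAL_PROCEDURES_W-O_CC-mcc_avg_charge`,
    filter_samples(fx$pool, state)$`EXTRACRANIAL_PROCEDURES_W-O_CC-mcc_avg_charge`)

  # selecting nothing is an empty result, not an error
  q0 <- parse_query("income_per_capita[min]=1e9&reqVar=race", fx$summary)
  expect_equal(nrow(execute_query(fx$pool, q0)), 0)

  # several requested variables project onto the same row set
  q2 <- parse_query("race=White&reqVar=income_per_capita&reqVar=race", fx$summary)
  r2 <- execute_query(fx$pool, q2)
  expect_true(all(c("income_per_capita", "race") %in% names(r2)))
  expect_identical(r2$sample_id,
                   execute_query(fx$pool, parse_query(
                     "race=White&reqVar=race", fx$summary))$sample_id)
})

test_that("repeated bounds merge to the tightest interval", {
  fx <- query_fixture()
  q <- parse_query(paste0("income_per_capita[min]=20000&income_per_capita[min]=40000",
                          "&income_per_capita[max]=80000&income_per_capita[max]=60000",
                          "&reqVar=race"), fx$summary)
  expect_equal(q$filters$income_per_capita$min, 40000)
  expect_equal(q$filters$income_per_capita$max, 60000)
})

test_that("rendering a query spec and re-parsing it is the identity", {
  fx <- query_fixture(5)
  set.seed(11)
  for (rep in 1:25) {
    q <- random_query_spec(fx$summary)
    q2 <- parse_query(render_query(q), fx$summary)
    srt <- function(f) if (length(f)) f[sort(names(f))] else f
    expect_equal(srt(q2$filters), srt(q$filters))
    expect_equal(q2$requested_vars, q$requested_vars)
  }
})

test_that("export honours filters, displayed variables, and determinism", {
  fx <- query_fixture(9)
  state <- new_filter_state()
  state <- set_filter(state, "race", flt_categories("White"))
  state <- set_filter(state, "income_per_capita", flt_interval(40000, 60000))

  csv <- export_csv(fx$pool, state, c("race", "income_per_capita"))
  lines <- strsplit(csv, "\n")[[1]]
  expect_equal(lines[1], "race,income_per_capita,weight")
  expect_equal(length(lines) - 1, length(current_selection(fx$pool, state)))

  # export equals the API result for the equivalent query
  q <- parse_query(paste0("race=White&income_per_capita[min]=40000",
                          "&income_per_capita[max]=60000",
                          "&reqVar=race&reqVar=income_per_capita"), fx$summary)
  api <- execute_query(fx$pool, q)
  expect_equal(readr::read_csv(I(csv), show_col_types = FALSE)$income_per_capita,
               api$income_per_capita)

  # unchanged state exports identical bytes
  expect_identical(csv, export_csv(fx$pool, state, c("race", "income_per_capita")))

  # empty selection gives a header-only CSV
  empty <- set_filter(state, "income_per_capita", flt_interval(1, 2))
  expect_equal(export_csv(fx$pool, empty, "race"), "race,weight\n")

  expect_error(export_csv(fx$pool, state, "nope"), "not integrated")
})

test_that("raw endpoints return unfiltered values keyed by geography", {
  tab <- make_county_fixture(3, seed = 13)
  inc <- raw_variable(tab, "income_per_capita")
  expect_equal(nrow(inc), 3)
  expect_named(inc, c("geo_id", "value"))
  gen <- raw_variable(tab, "gender")
  expect_named(gen, c("geo_id", "category", "count"))
  expect_equal(nrow(gen), 6)   # 3 counties x 2 categories
  expect_error(raw_variable(tab, "nope"), "unknown variable")

  pool <- random_pool(13)
  rv <- raw_variable(pool, "income_per_capita")
  expect_equal(nrow(rv), nrow(pool))
  expect_error(raw_variable(pool, "nope"), "unknown variable")
})
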