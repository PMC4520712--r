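# Independent naive-scan oracles and small random generators used across
# the suite. The oracles deliberately share no code with the engine: they
# loop over samples and test each predicate with plain base R.

# Does one sample row satisfy one predicate? (hand-rolled, no engine code)
naive_pass <- function(value, pred) {
  if (is.na(value)) return(FALSE)
  if (pred$type == "interval") {
    value >= pred$lo && value <= pred$hi
  } else {
    value %in% pred$labels
  }
}

# Full-scan selection: sample ids passing the conjunction of all predicates.
naive_selection <- function(pool, state, exclude = NULL) {
  preds <- state$predicates[setdiff(names(state$predicates), exclude)]
  keep <- vapply(seq_len(nrow(pool)), function(i) {
    for (v in names(preds)) {
      if (!naive_pass(pool[[v]][i], preds[[v]])) return(FALSE)
    }
    TRUE
  }, logical(1))
  sort(pool$sample_id[keep])
}

# Full-scan group counts over a qualitative dimension, excluding the
# dimension's own predicate.
naive_group_count <- function(pool, state, var, levels) {
  ids <- naive_selection(pool, state, exclude = var)
  rows <- pool[pool$sample_id %in% ids, ]
  vapply(levels, function(g) sum(!is.na(rows[[var]]) & rows[[var]] == g),
         numeric(1))
}

# Full-scan bin counts over a quantitative dimension given explicit edges
# (half-open bins, closed top), excluding the dimension's own predicate.
naive_bin_count <- function(pool, state, var, edges) {
  ids <- naive_selection(pool, state, exclude = var)
  v <- pool[[var]][pool$sample_id %in% ids]
  n <- length(edges) - 1L
  counts <- numeric(n)
  for (x in v) {
    if (is.na(x) || x < edges[1] || x > edges[n + 1]) next
    k <- max(which(x >= edges[-length(edges)]))  # linear scan over edges
    if (x == edges[n + 1]) k <- n
    counts[k] <- counts[k] + 1
  }
  counts
}

# A small fused pool with qualitative and quantitative variables.
random_pool <- function(seed, n_counties = 3, pop_range = c(2000, 40000),
                        denom = 1000) {
  tab <- make_county_fixture(n_counties, seed = seed, pop_range = pop_range)
  pool <- build_pool(tab, "pop", scale_denominator = denom, seed = seed)
  pool <- integrate_qualitative(pool, "gender", tab)
  pool <- integrate_qualitative(pool, "race", tab)
  pool <- integrate_quantitative(pool, "income_per_capita", tab)
  pool <- integrate_quantitative(pool, "unemployment_rate", tab)
  attr(pool, "source_table") <- tab
  pool
}

# A random filter state touching up to `max_dims` of the pool's variables.
random_state <- function(pool, seed, max_dims = 4) {
  set.seed(seed)
  vars <- sample(c("gender", "race", "income_per_capita", "unemployment_rate"),
                 sample(0:max_dims, 1))
  state <- new_filter_state()
  metas <- attr(pool, "metas")
  for (v in vars) {
    kind <- metas$kind[metas$name == v]
    if (kind == "qualitative") {
      cats <- metas$categories[metas$name == v][[1]]
      state <- set_filter(state, v, flt_categories(
        sample(cats, sample(seq_along(cats), 1))))
    } else {
      r <- range(pool[[v]])
      cuts <- sort(runif(2, r[1] - 1, r[2] + 1))
      state <- set_filter(state, v, flt_interval(cuts[1], cuts[2]))
    }
  }
  state
}

# A random parsed query over the variables of a summary: random bounds on
# quantitative variables, random category sets on qualitative ones, and a
# random non-empty set of requested variables. Uses the current RNG stream.
random_query_spec <- function(summary) {
  parts <- character()
  for (i in seq_len(nrow(summary))) {
    if (runif(1) > 0.5) next
    v <- summary$name[i]
    if (summary$kind[i] == "quantitative") {
      if (runif(1) < 0.8) {
        parts <- c(parts, paste0(v, "[min]=", round(runif(1, 0, 50000), 2)))
      }
      if (runif(1) < 0.8) {
        parts <- c(parts, paste0(v, "[max]=", round(runif(1, 50000, 120000), 2)))
      }
    } else {
      cats <- summary$categories[[i]]
      pick <- sample(cats, sample(seq_along(cats), 1))
      parts <- c(parts, paste0(v, "=", pick))
    }
  }
  req <- sample(summary$name, sample(1:2, 1))
  parts <- c(parts, paste0("reqVar=", req))
  parse_query(paste(parts, collapse = "&"), summary)
}

# In-memory anchored dataset from a tibble of raw strings.
parse_anchored_for_test <- function(df, label) {
  mashboard:::parse_anchored(df, label)
}

write_temp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}

# Drop all non-structural attributes: just the columns, as a plain tibble.
bare <- function(x) {
  out <- as.data.frame(x)
  attributes(out) <- attributes(out)[c("names", "row.names")]
  class(out) <- "data.frame"
  tibble::as_tibble(out)
}

# Structural equality of two marginal tables: records, metadata, label and
# state fallbacks (ignores QC/schema bookkeeping attributes).
expect_marginal_equal <- function(a, b) {
  expect_equal(bare(a), bare(b))
  expect_equal(variable_meta(a), variable_meta(b))
  expect_identical(dataset_label(a), dataset_label(b))
  expect_equal(
    dplyr::arrange(state_fallbacks(a), state_prefix, variable, category),
    dplyr::arrange(state_fallbacks(b), state_prefix, variable, category)
  )
}
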