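#' The worked single-county example
#'
#' One Michigan county (FIPS 26161) with population 8,000 and gender counts
#' \{male: 3,000, female: 5,000\}. At the default 1/1,000 scale this county
#' fuses to 8 samples, of which on average 3 draw male and 5 female.
#'
#' @return A validated `marginal_table` labelled `"worked_example"`.
#' @examples
#' pool <- build_pool(worked_example_fixture(), "pop", seed = 7)
#' glance(pool)
#' @export
worked_example_fixture <- function() {
  records <- tibble(
    geo_id = "26161",
    variable = c("gender", "gender", "pop"),
    category = c("female", "male", NA),
    value = c(5000, 3000, 8000)
  )
  metas <- tibble(
    name = c("pop", "gender"),
    source = "worked_example",
    kind = c("quantitative", "qualitative"),
    categories = list(NULL, c("male", "female")),
    units = c("persons", NA_character_)
  )
  new_marginal_table(records, label = "worked_example", metas = metas,
                     validated = TRUE,
                     qc = new_qc_report("worked_example", 1L, 0L, 0L))
}

#' Generate a toy county-marginal dataset
#'
#' Emulates the shape of national county marginal files: a population
#' variable, qualitative variables with per-county category counts (county
#' proportions drawn from a flat Dirichlet and scaled to the population),
#' and quantitative variables with county means drawn uniformly from a
#' declared range. Deterministic given `seed`; the output always passes
#' [validate_records()] with zero fixes and drops.
#'
#' @param n_counties Number of counties (0 gives an empty table).
#' @param seed Integer seed.
#' @param pop_range Population range, drawn uniformly and rounded.
#' @param qualitative Named list: variable -> category labels.
#' @param quantitative Named list: variable -> `c(lo, hi)` mean range.
#' @param label Dataset label.
#' @param include_pop Include the `"pop"` population variable (required for
#'   the census base dataset; other marginal sources may omit it).
#' @return A validated `marginal_table`; with `include_pop = TRUE` it
#'   carries the `"pop"` population variable.
#' @export
make_county_fixture <- function(n_counties, seed = 1L,
                                pop_range = c(1000, 50000),
                                qualitative = list(
                                  gender = c("male", "female"),
                                  race = c("White", "Black", "Other")),
                                quantitative = list(
                                  income_per_capita = c(15000, 65000),
                                  unemployment_rate = c(2, 15)),
                                label = "synthetic_census",
                                include_pop = TRUE) {
  metas <- bind_rows(
    if (include_pop)
      tibble(name = "pop", source = label, kind = "quantitative",
             categories = list(NULL), units = "persons"),
    purrr::imap_dfr(quantitative, function(rg, nm) {
      tibble(name = nm, source = label, kind = "quantitative",
             categories = list(NULL), units = "")
    }),
    purrr::imap_dfr(qualitative, function(cats, nm) {
      tibble(name = nm, source = label, kind = "qualitative",
             categories = list(cats), units = NA_character_)
    })
  )
  if (n_counties == 0L) {
    return(new_marginal_table(
      tibble(geo_id = character(), variable = character(),
             category = character(), value = numeric()),
      label = label, metas = metas, validated = TRUE,
      qc = new_qc_report(label, 0L, 0L, 0L)))
  }
  records <- with_seed(seed, {
    geo <- random_fips(n_counties)
    pop <- round(runif(n_counties, pop_range[1], pop_range[2]))
    parts <- if (include_pop) {
      list(tibble(geo_id = geo, variable = "pop",
                  category = NA_character_, value = pop))
    } else list()
    for (nm in names(quantitative)) {
      rg <- quantitative[[nm]]
      parts[[length(parts) + 1L]] <- tibble(
        geo_id = geo, variable = nm, category = NA_character_,
        value = round(runif(n_counties, rg[1], rg[2]), 2))
    }
    for (nm in names(qualitative)) {
      cats <- qualitative[[nm]]
      for (i in seq_len(n_counties)) {
        w <- rgamma(length(cats), 1)
        counts <- pmax(1, round(pop[i] * w / sum(w)))
        parts[[length(parts) + 1L]] <- tibble(
          geo_id = geo[i], variable = nm, category = cats, value = counts)
      }
    }
    bind_rows(parts)
  })
  records <- arrange(records, .data$geo_id, .data$variable, .data$category)
  new_marginal_table(records, label = label, metas = metas, validated = TRUE,
                     qc = new_qc_report(label, n_counties, 0L, 0L))
}

# n distinct county FIPS codes, never state-level (county part != 000).
random_fips <- function(n) {
  stopifnot(n <= 5000)
  repeat {
    state <- sample(1:56, n, replace = TRUE)
    county <- sample(1:998, n, replace = TRUE)
    geo <- sprintf("%02d%03d", state, county)
    if (!anyDuplicated(geo)) return(geo)
  }
}

#' Generate a location-free anchored CSV
#'
#' Emulates user-supplied study exports that share an anchor column (by
#' default `cerebellum_Volume` over `[0, 300000]`, the range used with 300
#' cohorts of width 1,000) alongside further quantitative and qualitative
#' columns. Returns CSV text, byte-identical across runs with equal seeds.
#'
#' @param n_rows Number of records (0 gives a header-only CSV).
#' @param anchor_name Anchor column name.
#' @param anchor_range `c(lo, hi)` range the anchor is drawn from.
#' @param quantitative Named list: column -> `c(lo, hi)` range.
#' @param qualitative Named list: column -> level set.
#' @param seed Integer seed.
#' @return A single CSV string (header row included).
#' @export
make_anchored_fixture <- function(n_rows,
                                  anchor_name = "cerebellum_Volume",
                                  anchor_range = c(0, 300000),
                                  quantitative = list(
                                    orbitofrontal_Volume = c(8000, 30000),
                                    age = c(35, 90)),
                                  qualitative = list(sex = c("M", "F")),
                                  seed = 1L) {
  cols <- with_seed(seed, {
    out <- list()
    out[[anchor_name]] <- round(runif(n_rows, anchor_range[1], anchor_range[2]), 1)
    for (nm in names(quantitative)) {
      rg <- quantitative[[nm]]
      out[[nm]] <- round(runif(n_rows, rg[1], rg[2]), 1)
    }
    for (nm in names(qualitative)) {
      out[[nm]] <- sample(qualitative[[nm]], n_rows, replace = TRUE)
    }
    out
  })
  readr::format_csv(as_tibble(cols))
}

#' The two-study anchored fixture pair
#'
#' Two synthetic study exports sharing the `cerebellum_Volume` anchor —
#' stand-ins for the shape of a Parkinson's and an Alzheimer's cohort file.
#' Cohorting both with `cohort_spec("cerebellum_Volume", 0, 300000, 300)`
#' and merging exercises the free-anchored pipeline end to end.
#'
#' @param seed Integer seed.
#' @return Named list of two CSV strings: `parkinsons_synthetic`,
#'   `alzheimers_synthetic`.
#' @export
cerebellum_fixture_pair <- function(seed = 42L) {
  list(
    parkinsons_synthetic = make_anchored_fixture(
      120, seed = var_seed(seed, "parkinsons_synthetic"),
      qualitative = list(sex = c("M", "F"))),
    alzheimers_synthetic = make_anchored_fixture(
      90, seed = var_seed(seed, "alzheimers_synthetic"),
      quantitative = list(orbitofrontal_Volume = c(7000, 28000),
                          age = c(55, 95)),
      qualitative = list(sex = c("M", "F"), apoe4 = c("carrier", "non-carrier")))
  )
}

#' Corrupt a clean marginal table into a dirty CSV with known QC truth
#'
#' Renders the table to the wide CSV layout (`fips` + one column per
#' quantitative variable + one column per qualitative category, named
#' `var_category`), then injects defects at the given per-row rates:
#' auto-fixable ones (surrounding whitespace, thousands separators,
#' leading-zero-stripped FIPS) and droppable ones (negative category count,
#' non-numeric value, 6-digit FIPS). Fix and drop rows are disjoint, so the
#' expected QC report is known exactly.
#'
#' @param clean A validated `marginal_table`.
#' @param fix_rate,drop_rate Per-row injection rates in `[0, 1]`.
#' @param seed Integer seed.
#' @return List: `csv` (dirty CSV text), `schema` (the matching
#'   [marginal_schema()]), `label`, and the ground-truth counts
#'   `n_auto_fixed`, `n_dropped`, `n_rows`.
#' @export
make_dirty_fixture <- function(clean, fix_rate = 0.1, drop_rate = 0.1, seed = 1L) {
  stopifnot(inherits(clean, "marginal_table"), isTRUE(attr(clean, "validated")),
            fix_rate >= 0, drop_rate >= 0, fix_rate + drop_rate <= 1)
  metas <- variable_meta(clean)
  quant <- metas$name[metas$kind == "quantitative"]
  qual <- metas$name[metas$kind == "qualitative"]
  schema <- marginal_schema(
    geo_col = "fips",
    quantitative = quant,
    qualitative = setNames(purrr::map(qual, function(v) {
      cats <- metas$categories[metas$name == v][[1]]
      setNames(paste0(v, "_", cats), cats)
    }), qual),
    source = dataset_label(clean)
  )
  rec <- as_tibble(clean)
  wide <- rec |>
    mutate(col = ifelse(is.na(.data$category), .data$variable,
                        paste0(.data$variable, "_", .data$category))) |>
    select("geo_id", "col", "value") |>
    tidyr::pivot_wider(names_from = "col", values_from = "value") |>
    rename(fips = "geo_id")
  chr <- as_tibble(purrr::map(wide, function(x) {
    if (is.numeric(x)) format(x, trim = TRUE, scientific = FALSE) else x
  }))
  n <- nrow(chr)
  n_fix <- round(fix_rate * n)
  n_drop <- round(drop_rate * n)
  count_cols <- unlist(purrr::map(qual, function(v) {
    paste0(v, "_", metas$categories[metas$name == v][[1]])
  }))
  value_cols <- setdiff(names(chr), "fips")
  with_seed(seed, {
    rows <- sample(n, n_fix + n_drop)
    fix_rows <- rows[seq_len(n_fix)]
    drop_rows <- rows[n_fix + seq_len(n_drop)]
    for (i in fix_rows) {
      col <- sample(value_cols, 1)
      v <- chr[[col]][i]
      kind <- sample(c("ws", "sep", "fips0"), 1)
      if (kind == "sep" && grepl("^[0-9]{4,}$", v)) {
        chr[[col]][i] <- prettyNum(v, big.mark = ",")
      } else if (kind == "fips0" && grepl("^0", chr$fips[i])) {
        chr$fips[i] <- sub("^0+", "", chr$fips[i])
      } else {
        chr[[col]][i] <- paste0("  ", v, " ")
      }
    }
    for (i in drop_rows) {
      kind <- sample(c("neg", "text", "longfips"), 1)
      pos_counts <- count_cols[vapply(count_cols, function(cc) {
        isTRUE(suppressWarnings(as.numeric(chr[[cc]][i])) > 0)
      }, logical(1))]
      if (kind == "neg" && length(pos_counts)) {
        col <- sample(pos_counts, 1)
        chr[[col]][i] <- paste0("-", chr[[col]][i])
      } else if (kind == "text") {
        col <- sample(value_cols, 1)  # draw once: the target index must not
        chr[[col]][i] <- "invalid"    # be re-evaluated by the assignment
      } else {
        chr$fips[i] <- paste0(chr$fips[i], "9")
      }
    }
  })
  list(csv = readr::format_csv(chr), schema = schema,
       label = paste0(dataset_label(clean), "_dirty"),
       n_auto_fixed = n_fix, n_dropped = n_drop, n_rows = n)
}
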