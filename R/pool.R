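#' Build the synthetic sample pool from census marginals
#'
#' The pool represents a population by weighted samples: each sample stands
#' for `scale_denominator` persons (1,000 at the default 1/1,000 scale) in
#' one county. A county with population P contributes
#' `round_half_up(P / scale_denominator)` samples, so an 8,000-person county
#' yields 8 samples at the default scale. Samples start with no attributes;
#' variables are added by the `integrate_*` functions, each drawing from its
#' own seeded sub-stream so the order of integration does not matter.
#'
#' Because each sample only ever carries county or state aggregates, the
#' pool contains no individual-level record: the smallest representable unit
#' is `scale_denominator` persons.
#'
#' @param census A validated `marginal_table` providing the population
#'   variable for every county (the mandatory base dataset).
#' @param population_var Name of the quantitative population variable.
#' @param scale_denominator Persons represented by one sample (default
#'   1000).
#' @param seed Integer pool seed; all later integrations derive their
#'   sub-streams from it.
#' @return A `sample_pool` tibble with columns `sample_id`, `geo_id`,
#'   `weight`, one column per integrated variable, and pool-level metadata.
#' @examples
#' pool <- build_pool(worked_example_fixture(), "pop", seed = 1)
#' nrow(pool)  # 8 samples for the 8,000-person county
#' @export
build_pool <- function(census, population_var, scale_denominator = 1000L,
                       seed = 1L) {
  stopifnot(inherits(census, "marginal_table"), scale_denominator >= 1)
  pops <- filter(as_tibble(census),
                 .data$variable == population_var, is.na(.data$category))
  counties <- unique(as_tibble(census)$geo_id)
  missing <- setdiff(counties, pops$geo_id)
  if (length(missing)) {
    abort(paste0("census is missing '", population_var, "' for counties: ",
                 paste(missing, collapse = ", ")))
  }
  if (any(pops$value < 0)) abort("negative county population")
  n_samples <- round_half_up(pops$value / scale_denominator)
  samples <- tibble(
    sample_id = seq_len(sum(n_samples)),
    geo_id = rep(pops$geo_id, n_samples),
    weight = as.numeric(scale_denominator)
  )
  new_sample_pool(samples, scale_denominator = as.integer(scale_denominator),
                  seed = as.integer(seed),
                  metas = variable_meta(census)[0, ],
                  populations = select(pops, "geo_id", population = "value"))
}

new_sample_pool <- function(samples, scale_denominator, seed, metas,
                            populations = NULL) {
  out <- if (inherits(samples, "tbl_df")) samples else as_tibble(samples)
  attr(out, "scale_denominator") <- scale_denominator
  attr(out, "rng_seed") <- seed
  attr(out, "metas") <- metas
  attr(out, "populations") <- populations
  class(out) <- c("sample_pool", "tbl_df", "tbl", "data.frame")
  out
}

restore_pool <- function(samples, template, metas = NULL) {
  new_sample_pool(samples, scale_denominator = attr(template, "scale_denominator"),
                  seed = attr(template, "rng_seed"),
                  metas = metas %||% attr(template, "metas"),
                  populations = attr(template, "populations"))
}

#' @export
print.sample_pool <- function(x, ...) {
  cat("<sample_pool> ", nrow(x), " samples x ", attr(x, "scale_denominator"),
      " persons, ", dplyr::n_distinct(x$geo_id), " geo units, seed ",
      attr(x, "rng_seed"), "\n", sep = "")
  vars <- attr(x, "metas")$name
  if (length(vars)) cat("  integrated: ", paste(vars, collapse = ", "), "\n", sep = "")
  NextMethod()
}

pool_scale <- function(pool) attr(pool, "scale_denominator")
pool_seed <- function(pool) attr(pool, "rng_seed")

integrated_vars <- function(pool) attr(pool, "metas")$name

variable_kind <- function(pool, var) {
  metas <- attr(pool, "metas")
  kind <- metas$kind[metas$name == var]
  if (!length(kind)) abort(paste0("variable not integrated: ", var))
  kind
}

check_not_integrated <- function(pool, var) {
  if (var %in% integrated_vars(pool)) {
    abort(paste0("variable already integrated: ", var))
  }
}

# County-level category counts for `var`, with the state-fallback rule:
# a pool county with no county-level counts uses the dataset's explicit
# state-level counts if present, else the sum of counts over the dataset's
# counties in the same state; with neither, integration fails.
county_counts_for <- function(pool, table, var) {
  sel <- table$variable == var & !is.na(table$category)
  rec <- tibble::new_tibble(
    list(geo_id = table$geo_id[sel], category = table$category[sel],
         value = table$value[sel]),
    nrow = sum(sel))
  counties <- unique(pool$geo_id)
  missing <- setdiff(counties, rec$geo_id)
  if (length(missing)) {
    fb <- filter(state_fallbacks(table), .data$variable == var,
                 !is.na(.data$category))
    agg <- bind_rows(
      select(fb, "state_prefix", "category", "value"),
      rec |>
        mutate(state_prefix = state_prefix_of(.data$geo_id)) |>
        filter(!(.data$state_prefix %in% fb$state_prefix)) |>
        group_by(.data$state_prefix, .data$category) |>
        summarise(value = sum(.data$value), .groups = "drop")
    )
    filled <- tibble(geo_id = missing, state_prefix = state_prefix_of(missing)) |>
      left_join(agg, by = "state_prefix", relationship = "many-to-many")
    still <- unique(filled$geo_id[is.na(filled$value)])
    if (length(still)) {
      abort(paste0("no county- or state-level counts of '", var,
                   "' for counties: ", paste(still, collapse = ", ")))
    }
    rec <- bind_rows(rec, select(filled, "geo_id", "category", "value"))
  }
  rec
}

#' Integrate a qualitative variable by simple random sampling
#'
#' For each county a probability distribution over the variable's categories
#' is formed from the county's category counts, and every sample in the
#' county independently draws its label from that distribution. So the
#' worked 8-sample county with counts \{male: 3,000, female: 5,000\} gets on
#' average 3 male and 5 female samples. Counties without county-level counts
#' fall back to state-level counts (explicit state records if present,
#' otherwise the within-state sum); a county with all-zero counts is an
#' error, since no distribution exists.
#'
#' @param pool A `sample_pool`.
#' @param var Qualitative variable name (declared in `table`'s metadata).
#' @param table The validated `marginal_table` carrying the counts.
#' @param seed Base seed; defaults to the pool seed. The draw uses the
#'   sub-stream derived from `(seed, var)`, so replicate integrations with
#'   distinct seeds are independent and integration order is immaterial.
#' @return The pool with a new column `var` of category labels.
#' @export
integrate_qualitative <- function(pool, var, table, seed = NULL) {
  stopifnot(inherits(pool, "sample_pool"), inherits(table, "marginal_table"))
  check_not_integrated(pool, var)
  metas_t <- variable_meta(table)
  meta <- metas_t[metas_t$name == var, ]
  if (nrow(meta) != 1L || meta$kind != "qualitative") {
    abort(paste0("'", var, "' is not a declared qualitative variable of ",
                 dataset_label(table)))
  }
  counts <- county_counts_for(pool, table, var)
  tot <- rowsum(counts$value, counts$geo_id)
  zero <- rownames(tot)[tot[, 1] <= 0]
  zero <- intersect(zero, pool$geo_id)
  if (length(zero)) {
    abort(paste0("all-zero counts of '", var, "' in counties: ",
                 paste(zero, collapse = ", ")))
  }
  seed <- var_seed(seed %||% pool_seed(pool), var)
  geo <- pool$geo_id
  values <- character(length(geo))
  with_seed(seed, {
    for (g in unique(geo)) {
      idx <- which(geo == g)
      sel <- counts$geo_id == g
      values[idx] <- sample(counts$category[sel], length(idx), replace = TRUE,
                            prob = counts$value[sel] / sum(counts$value[sel]))
    }
  })
  samples <- as_tibble(pool)
  samples[[var]] <- values
  restore_pool(samples, pool, metas = bind_rows(attr(pool, "metas"), meta))
}

#' Integrate a quantitative variable as county (or state) means
#'
#' Every sample in a county is set to the county mean exactly; there is no
#' simulated deviation, so the within-county sample variance of any
#' quantitative variable is zero. Where the county mean is missing the
#' state-level mean is used; a county with neither is an error.
#'
#' @inheritParams integrate_qualitative
#' @param var Quantitative variable name declared in `table`'s metadata.
#' @return The pool with a new numeric column `var`. Deterministic: no seed
#'   is involved.
#' @export
integrate_quantitative <- function(pool, var, table) {
  stopifnot(inherits(pool, "sample_pool"), inherits(table, "marginal_table"))
  check_not_integrated(pool, var)
  metas_t <- variable_meta(table)
  meta <- metas_t[metas_t$name == var, ]
  if (nrow(meta) != 1L || meta$kind != "quantitative") {
    abort(paste0("'", var, "' is not a declared quantitative variable of ",
                 dataset_label(table)))
  }
  sel <- table$variable == var & is.na(table$category)
  county_value <- setNames(table$value[sel], table$geo_id[sel])
  fb <- state_fallbacks(table)
  fsel <- fb$variable == var & is.na(fb$category)
  state_value <- setNames(fb$value[fsel], fb$state_prefix[fsel])

  geo <- unique(pool$geo_id)
  value <- unname(county_value[geo])
  use_state <- is.na(value)
  value[use_state] <- unname(state_value[state_prefix_of(geo[use_state])])
  bad <- geo[is.na(value)]
  if (length(bad)) {
    abort(paste0("no county or state mean of '", var, "' for counties: ",
                 paste(bad, collapse = ", ")))
  }
  samples <- as_tibble(pool)
  samples[[var]] <- value[match(samples$geo_id, geo)]
  restore_pool(samples, pool, metas = bind_rows(attr(pool, "metas"), meta))
}

#' Integrate a variable, dispatching on its declared kind
#'
#' Convenience wrapper over [integrate_qualitative()] and
#' [integrate_quantitative()].
#'
#' @inheritParams integrate_qualitative
#' @export
integrate_variable <- function(pool, var, table, seed = NULL) {
  meta <- filter(variable_meta(table), .data$name == var)
  if (nrow(meta) != 1L) {
    abort(paste0("'", var, "' is not declared in ", dataset_label(table)))
  }
  if (meta$kind == "qualitative") {
    integrate_qualitative(pool, var, table, seed = seed)
  } else {
    integrate_quantitative(pool, var, table)
  }
}

#' Derive a new quantitative variable by per-sample arithmetic
#'
#' Mirrors the dashboard's "Customize" operation: users combine two
#' integrated quantitative variables by addition, subtraction or
#' multiplication into a new named variable.
#'
#' @param pool A `sample_pool`.
#' @param new_name Unused variable name for the result.
#' @param left,right Names of integrated quantitative operands.
#' @param op One of `"add"`, `"subtract"`, `"multiply"`.
#' @return The pool with the derived quantitative column added.
#' @export
derive_variable <- function(pool, new_name, left, op = c("add", "subtract", "multiply"),
                            right) {
  op <- match.arg(op)
  stopifnot(inherits(pool, "sample_pool"))
  check_not_integrated(pool, new_name)
  for (v in c(left, right)) {
    if (variable_kind(pool, v) != "quantitative") {
      abort(paste0("operand '", v, "' is not quantitative"))
    }
  }
  f <- switch(op, add = `+`, subtract = `-`, multiply = `*`)
  samples <- as_tibble(pool)
  samples[[new_name]] <- f(samples[[left]], samples[[right]])
  meta <- tibble(name = new_name, source = "derived", kind = "quantitative",
                 categories = list(NULL),
                 units = paste0(left, " ", op, " ", right))
  restore_pool(samples, pool, metas = bind_rows(attr(pool, "metas"), meta))
}

#' @export
tidy.sample_pool <- function(x, ...) {
  metas <- attr(x, "metas")
  tibble(
    variable = metas$name,
    kind = metas$kind,
    source = metas$source,
    n_distinct = vapply(metas$name, function(v) dplyr::n_distinct(x[[v]]), integer(1))
  )
}

#' @export
glance.sample_pool <- function(x, ...) {
  tibble(
    n_samples = nrow(x),
    n_counties = dplyr::n_distinct(x$geo_id),
    scale_denominator = pool_scale(x),
    total_weight = sum(x$weight),
    n_integrated = length(integrated_vars(x)),
    rng_seed = pool_seed(x)
  )
}

#' Serialize / restore a sample pool as JSON
#'
#' Records the samples, the scale denominator, the pool seed and the
#' integrated variable metadata, so a pool can be rebuilt byte-identically
#' for provenance.
#'
#' @param pool A `sample_pool`.
#' @param path File path.
#' @return `read_pool_json()` returns the restored `sample_pool`.
#' @export
write_pool_json <- function(pool, path) {
  obj <- list(
    scale_denominator = pool_scale(pool),
    rng_seed = pool_seed(pool),
    meta = metas_to_json(attr(pool, "metas")),
    samples = as_tibble(pool)
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                              dataframe = "columns"),
             path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_pool_json
#' @export
read_pool_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  metas <- json_to_metas(obj$meta)
  samples <- as_tibble(purrr::map(obj$samples, function(col) {
    unlist(purrr::map(col, function(v) if (is.null(v)) NA else v))
  }))
  samples$sample_id <- as.integer(samples$sample_id)
  new_sample_pool(samples, scale_denominator = as.integer(obj$scale_denominator),
                  seed = as.integer(obj$rng_seed), metas = metas)
}
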