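#' Marginal tables
#'
#' A `marginal_table` is a long tibble of per-county marginals: one row per
#' (county, variable, category) for qualitative counts and one row per
#' (county, variable) for quantitative means (`category` is `NA`). County
#' geo ids are 5-character zero-padded FIPS strings; state-level records
#' (county code `000`) are held separately as fallbacks used when a county
#' value is missing at fusion time.
#'
#' @param records Tibble with columns `geo_id`, `variable`, `category`,
#'   `value`.
#' @param label Dataset label.
#' @param metas Variable metadata tibble (see [marginal_schema()]).
#' @param state_fallbacks Tibble of state-level records with columns
#'   `state_prefix`, `variable`, `category`, `value`.
#' @param validated Has [validate_records()] run on this table?
#' @param qc A QC report, or `NULL`.
#' @return A `marginal_table`.
#' @keywords internal
new_marginal_table <- function(records, label, metas,
                               state_fallbacks = empty_fallbacks(),
                               validated = FALSE, qc = NULL) {
  out <- as_tibble(records)
  attr(out, "dataset_label") <- label
  attr(out, "metas") <- metas
  attr(out, "state_fallbacks") <- as_tibble(state_fallbacks)
  attr(out, "validated") <- validated
  attr(out, "qc") <- qc
  class(out) <- c("marginal_table", class(tibble()))
  out
}

empty_fallbacks <- function() {
  tibble(state_prefix = character(), variable = character(),
         category = character(), value = numeric())
}

# Rebuild the marginal_table attributes after a dplyr verb stripped them.
restore_marginal <- function(records, template, ...) {
  dots <- list(...)
  new_marginal_table(
    records,
    label = dots$label %||% attr(template, "dataset_label"),
    metas = dots$metas %||% attr(template, "metas"),
    state_fallbacks = dots$state_fallbacks %||% attr(template, "state_fallbacks"),
    validated = dots$validated %||% attr(template, "validated"),
    qc = if ("qc" %in% names(dots)) dots$qc else attr(template, "qc")
  )
}

#' @export
print.marginal_table <- function(x, ...) {
  cat("<marginal_table> dataset: ", attr(x, "dataset_label"),
      if (isTRUE(attr(x, "validated"))) "  [validated]" else "  [raw]",
      "\n", sep = "")
  metas <- variable_meta(x)
  cat("  ", dplyr::n_distinct(x$geo_id), " counties, ",
      nrow(metas), " variables (",
      sum(metas$kind == "quantitative"), " quantitative, ",
      sum(metas$kind == "qualitative"), " qualitative)\n", sep = "")
  NextMethod()
}

#' Accessors for marginal-table components
#'
#' @param x A `marginal_table` (or, for `variable_meta()`, a `sample_pool`).
#' @return `variable_meta()` the metadata tibble; `dataset_label()` the label
#'   string; `state_fallbacks()` the state-level fallback records.
#' @export
variable_meta <- function(x) attr(x, "metas")

#' @rdname variable_meta
#' @export
dataset_label <- function(x) attr(x, "dataset_label")

#' @rdname variable_meta
#' @export
state_fallbacks <- function(x) attr(x, "state_fallbacks")

#' Read a marginal CSV into a raw marginal table
#'
#' Reads an RFC-4180 CSV (header row, comma delimiter, `.` decimal mark) and
#' reshapes it to long per-county records according to `schema`. Values are
#' kept as raw strings: no cleaning happens here, so that
#' [validate_records()] can account for every fix and drop. Rows that cannot
#' even be located (no geo id cell) are still carried through and left to
#' the validator.
#'
#' @param path CSV file path.
#' @param schema A [marginal_schema()].
#' @param label Dataset label; defaults to the file name without extension.
#' @return A raw (unvalidated) `marginal_table`.
#' @examples
#' csv <- tempfile(fileext = ".csv")
#' writeLines(c("fips,pop,male,female", "26161,8000,3000,5000"), csv)
#' sch <- marginal_schema("fips", quantitative = "pop",
#'                        qualitative = list(gender = c("male", "female")))
#' tab <- read_marginal_csv(csv, sch)
#' validate_records(tab)
#' @export
read_marginal_csv <- function(path, schema, label = NULL) {
  stopifnot(inherits(schema, "marginal_schema"))
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  label <- label %||% sub("\\.[^.]*$", "", basename(path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         trim_ws = FALSE, progress = FALSE,
                         name_repair = "minimal")
  if (nrow(raw) == 0L) abort(paste0("empty marginal CSV: ", path))
  if (!schema$geo_col %in% names(raw)) {
    abort(paste0("schema error: geo column '", schema$geo_col,
                 "' not present in ", path))
  }
  needed <- c(unname(schema$quantitative),
              unlist(lapply(schema$qualitative, unname), use.names = FALSE))
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    abort(paste0("schema error: declared columns absent from CSV: ",
                 paste(missing_cols, collapse = ", ")))
  }

  geo <- raw[[schema$geo_col]]
  rows <- seq_len(nrow(raw))
  pieces <- list()
  for (v in names(schema$quantitative)) {
    pieces[[length(pieces) + 1L]] <- tibble(
      .row = rows, geo_id = geo, variable = v, category = NA_character_,
      value = raw[[schema$quantitative[[v]]]]
    )
  }
  for (v in names(schema$qualitative)) {
    cats <- schema$qualitative[[v]]
    for (k in names(cats)) {
      pieces[[length(pieces) + 1L]] <- tibble(
        .row = rows, geo_id = geo, variable = v, category = k,
        value = raw[[cats[[k]]]]
      )
    }
  }
  records <- arrange(bind_rows(pieces), .data$.row, .data$variable, .data$category)
  out <- new_marginal_table(records, label = label,
                            metas = schema_metas(schema, label))
  attr(out, "schema") <- schema
  out
}

#' Validate and repair a marginal table
#'
#' Applies the automatic QC policy and returns the clean table with a QC
#' report attached (retrieve it with [qc_report()]). The policy is a closed
#' list. Auto-fixes: short geo ids are completed/zero-padded to 5-digit
#' FIPS, surrounding whitespace is stripped, and numeric strings with
#' thousands separators are parsed. Drops (whole CSV row): non-numeric geo
#' ids or ids longer than 5 digits, values that do not parse as numbers,
#' and negative category counts. Nothing is ever raised as an error: every
#' defect is either repaired and counted or dropped and counted.
#'
#' State-level rows (county code `000`) are routed to the table's
#' state-fallback store rather than the county records.
#'
#' Running the validator on an already-clean table is the identity and
#' reports a zero error rate.
#'
#' @param table A `marginal_table` from [read_marginal_csv()] (raw or
#'   already validated).
#' @return The clean, validated `marginal_table` with a [qc_report()]
#'   attribute.
#' @export
validate_records <- function(table) {
  stopifnot(inherits(table, "marginal_table"))
  schema <- attr(table, "schema")
  state_prefix <- if (!is.null(schema)) schema$state_prefix else NULL
  rec <- as_tibble(table)
  if (!".row" %in% names(rec)) rec$.row <- match(rec$geo_id, unique(rec$geo_id))
  n_input <- dplyr::n_distinct(rec$.row)

  geo_raw <- as.character(rec$geo_id)
  val_raw <- if (is.numeric(rec$value)) rec$value else as.character(rec$value)

  fixed <- logical(nrow(rec))
  bad <- logical(nrow(rec))

  # --- geo id channel ---
  geo <- trimws(geo_raw)
  fixed <- fixed | (!is.na(geo_raw) & geo != geo_raw)
  numeric_geo <- !is.na(geo) & grepl("^[0-9]+$", geo)
  bad <- bad | !numeric_geo | (numeric_geo & nchar(geo) > 5L)
  short <- numeric_geo & nchar(geo) < 5L
  geo <- pad_fips(geo, state_prefix)
  fixed <- fixed | short

  # --- value channel ---
  if (is.numeric(val_raw)) {
    val <- val_raw
  } else {
    v <- trimws(val_raw)
    fixed <- fixed | (!is.na(val_raw) & !is.na(v) & v != val_raw)
    grouped <- !is.na(v) & grepl("^-?[0-9]{1,3}(,[0-9]{3})+(\\.[0-9]+)?$", v)
    v[grouped] <- gsub(",", "", v[grouped])
    fixed <- fixed | grouped
    val <- suppressWarnings(as.numeric(v))
    bad <- bad | is.na(val)
  }
  # negative category counts are unrepairable
  bad <- bad | (!is.na(val) & !is.na(rec$category) & val < 0)

  # a CSV row with any unrepairable cell is dropped whole
  drop_rows <- unique(rec$.row[bad])
  keep <- !(rec$.row %in% drop_rows)
  fix_rows <- setdiff(unique(rec$.row[fixed]), drop_rows)

  clean <- tibble(geo_id = geo[keep], variable = rec$variable[keep],
                  category = rec$category[keep], value = val[keep])
  is_state <- grepl("000$", clean$geo_id)
  fb <- clean[is_state, ] |>
    mutate(state_prefix = state_prefix_of(.data$geo_id)) |>
    select("state_prefix", "variable", "category", "value")
  clean <- clean[!is_state, ] |>
    arrange(.data$geo_id, .data$variable, .data$category)

  qc <- new_qc_report(
    dataset_label = attr(table, "dataset_label"),
    n_input_rows = n_input,
    n_auto_fixed = length(fix_rows),
    n_dropped = length(drop_rows)
  )
  prior_fb <- state_fallbacks(table)
  out <- restore_marginal(clean, table, validated = TRUE, qc = qc,
                          state_fallbacks = distinct(bind_rows(prior_fb, fb)))
  attr(out, "schema") <- schema
  out
}

#' QC report of a validated marginal table
#'
#' @param table A validated `marginal_table`.
#' @return A `qc_report`: dataset label, input row count, rows auto-fixed,
#'   rows dropped, and the resulting error rate
#'   `(n_auto_fixed + n_dropped) / n_input_rows`.
#' @export
qc_report <- function(table) {
  qc <- attr(table, "qc")
  if (is.null(qc)) abort("no QC report: run validate_records() first")
  qc
}

new_qc_report <- function(dataset_label, n_input_rows, n_auto_fixed, n_dropped) {
  stopifnot(n_auto_fixed + n_dropped <= n_input_rows)
  structure(
    list(dataset_label = dataset_label,
         n_input_rows = n_input_rows,
         n_auto_fixed = n_auto_fixed,
         n_dropped = n_dropped,
         error_rate = if (n_input_rows > 0) (n_auto_fixed + n_dropped) / n_input_rows else 0),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report> ", x$dataset_label, "\n",
      "  rows in: ", x$n_input_rows,
      "   auto-fixed: ", x$n_auto_fixed,
      "   dropped: ", x$n_dropped, "\n",
      "  error rate: ", format(100 * x$error_rate, digits = 4), "%\n", sep = "")
  invisible(x)
}

#' @export
tidy.qc_report <- function(x, ...) {
  tibble(
    outcome = c("clean", "auto_fixed", "dropped"),
    rows = c(x$n_input_rows - x$n_auto_fixed - x$n_dropped,
             x$n_auto_fixed, x$n_dropped)
  )
}

#' @export
glance.qc_report <- function(x, ...) {
  tibble(dataset_label = x$dataset_label, n_input_rows = x$n_input_rows,
         n_auto_fixed = x$n_auto_fixed, n_dropped = x$n_dropped,
         error_rate = x$error_rate)
}

#' @export
autoplot.qc_report <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$outcome, y = .data$rows)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(title = paste0("QC outcome: ", object$dataset_label),
                  x = NULL, y = "CSV rows") +
    ggplot2::theme_minimal()
}
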