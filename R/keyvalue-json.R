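#' Write a marginal table in the key-value JSON dataset format
#'
#' The dataset format is a single UTF-8 JSON object:
#' \preformatted{
#' {"dataset": "<label>",
#'  "meta": [{"name": ..., "source": ..., "kind": ...,
#'            "categories": [...] | "units": "..."}, ...],
#'  "records": {"<fips>": {"<var>": <mean> | {"<category>": <count>}}},
#'  "state_fallbacks": {"<state prefix>": {"<var>": ...}}}
#' }
#' Counts are written as integers, means as decimals. The format round-trips
#' exactly: [read_keyvalue_json()] on the output reproduces the input table.
#'
#' @param table A validated `marginal_table`.
#' @param path Output file path, or `NULL` to return the JSON string.
#' @param metas Variable metadata; defaults to the table's own. Every
#'   variable appearing in the table must be declared here.
#' @return The JSON string, invisibly when written to `path`.
#' @export
write_keyvalue_json <- function(table, path = NULL, metas = variable_meta(table)) {
  stopifnot(inherits(table, "marginal_table"))
  if (!isTRUE(attr(table, "validated"))) {
    abort("run validate_records() before serializing")
  }
  undeclared <- setdiff(unique(table$variable), metas$name)
  if (length(undeclared)) {
    abort(paste0("variables without metadata: ", paste(undeclared, collapse = ", ")))
  }
  obj <- list(
    dataset = attr(table, "dataset_label"),
    meta = metas_to_json(metas),
    records = records_to_json(as_tibble(table), key = "geo_id"),
    state_fallbacks = records_to_json(
      rename(state_fallbacks(table), geo_id = "state_prefix"), key = "geo_id")
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path, useBytes = TRUE)
  invisible(json)
}

metas_to_json <- function(metas) {
  purrr::pmap(metas, function(name, source, kind, categories, units) {
    m <- list(name = name, source = source, kind = kind)
    if (kind == "qualitative") m$categories <- as.list(categories)
    else m$units <- units %||% ""
    m
  })
}

records_to_json <- function(records, key = "geo_id") {
  split(records, records[[key]]) |>
    purrr::map(function(g) {
      split(g, g$variable)[unique(g$variable)] |>
        purrr::map(function(vr) {
          if (all(is.na(vr$category))) {
            vr$value[[1]]
          } else {
            as.list(setNames(as.integer(vr$value), vr$category))
          }
        })
    })
}

#' Read a key-value JSON dataset
#'
#' @param path Path to a file written by [write_keyvalue_json()].
#' @return A validated `marginal_table`.
#' @export
read_keyvalue_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  metas <- json_to_metas(obj$meta)
  records <- json_to_records(obj$records, key = "geo_id")
  fb <- json_to_records(obj$state_fallbacks, key = "geo_id") |>
    rename(state_prefix = "geo_id")
  new_marginal_table(
    arrange(records, .data$geo_id, .data$variable, .data$category),
    label = obj$dataset, metas = metas,
    state_fallbacks = fb, validated = TRUE
  )
}

json_to_metas <- function(meta_list) {
  if (length(meta_list) == 0L) {
    return(tibble(name = character(), source = character(), kind = character(),
                  categories = list(), units = character()))
  }
  out <- purrr::map_dfr(meta_list, function(m) {
    tibble(name = m$name, source = m$source, kind = m$kind,
           categories = list(if (m$kind == "qualitative")
             unlist(m$categories) else NULL),
           units = if (m$kind == "quantitative") m$units %||% "" else NA_character_)
  })
  validate_metas(out)
  out
}

json_to_records <- function(rec_list, key = "geo_id") {
  if (is.null(rec_list) || length(rec_list) == 0L) {
    return(tibble(geo_id = character(), variable = character(),
                  category = character(), value = numeric()))
  }
  purrr::imap_dfr(rec_list, function(vars, geo) {
    purrr::imap_dfr(vars, function(v, var) {
      if (is.list(v)) {
        tibble(geo_id = geo, variable = var,
               category = names(v), value = as.numeric(unlist(v)))
      } else {
        tibble(geo_id = geo, variable = var,
               category = NA_character_, value = as.numeric(v))
      }
    })
  })
}

#' Combine dataset metadata into a cross-dataset summary
#'
#' The summary is the catalogue a front-end would load first: every dataset
#' with its variable set. Variable names must be globally unique across
#' datasets; a collision is an ingest error, not a merge.
#'
#' @param datasets List of validated `marginal_table`s.
#' @return A `summary_meta` tibble: one row per variable with its dataset
#'   label, kind, categories and units. Dataset order is preserved.
#' @export
build_summary <- function(datasets) {
  if (inherits(datasets, "marginal_table")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1L,
            all(vapply(datasets, inherits, logical(1), "marginal_table")))
  out <- purrr::map_dfr(datasets, function(t) {
    mutate(variable_meta(t), dataset = dataset_label(t), .before = 1)
  })
  dup <- unique(out$name[duplicated(out$name)])
  if (length(dup)) {
    abort(paste0("variable name collision across datasets: ",
                 paste(dup, collapse = ", ")))
  }
  class(out) <- c("summary_meta", class(out))
  out
}

#' Write / read the summary-metadata JSON file
#'
#' @param summary A `summary_meta` from [build_summary()].
#' @param path File path (for the reader, a file written by the writer).
#' @return The reader returns a `summary_meta` tibble.
#' @export
write_summary_json <- function(summary, path) {
  by_ds <- split(summary, factor(summary$dataset, levels = unique(summary$dataset)))
  obj <- purrr::imap(by_ds, function(g, ds) {
    list(dataset = ds, variables = metas_to_json(select(g, -"dataset")))
  })
  writeLines(jsonlite::toJSON(unname(obj), auto_unbox = TRUE, digits = NA),
             path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_summary_json
#' @export
read_summary_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- purrr::map_dfr(obj, function(ds) {
    mutate(json_to_metas(ds$variables), dataset = ds$dataset, .before = 1)
  })
  class(out) <- c("summary_meta", class(out))
  out
}
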