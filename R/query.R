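#' Parse the dashboard query-string grammar
#'
#' The machine API uses URL query strings: `name[min]=v` / `name[max]=v`
#' set inclusive bounds on a quantitative variable, repeated `name=label`
#' pairs union into a category set on a qualitative variable (disjunction
#' within the variable, conjunction across variables), and each
#' `reqVar=name` appends one requested output variable. For example
#'
#' `income_per_capita[min]=60000&race=White&race=Black&reqVar=...`
#'
#' selects records with income of at least 60,000 whose race is White or
#' Black. Keys and values are percent-decoded (`+` decodes to a space).
#'
#' @param query_string Non-empty query string (the part after `?`).
#' @param summary A `summary_meta` from [build_summary()]; every variable in
#'   the query must be declared there.
#' @return A `query_spec`: `filters` (named list of `bounds` / `categories`
#'   elements) and `requested_vars` (ordered character vector).
#' @export
parse_query <- function(query_string, summary) {
  stopifnot(is.character(query_string), length(query_string) == 1L)
  query_string <- sub("^\\?", "", query_string)
  if (!nzchar(query_string)) abort("empty query string")
  pairs <- strsplit(query_string, "&", fixed = TRUE)[[1]]
  pairs <- pairs[nzchar(pairs)]
  filters <- list()
  requested <- character()
  for (p in pairs) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq < 0) abort(paste0("malformed query pair (no '='): ", p))
    key <- url_decode(substr(p, 1L, eq - 1L))
    val <- url_decode(substr(p, eq + 1L, nchar(p)))
    if (key == "reqVar") {
      check_known(val, summary)
      requested <- c(requested, val)
      next
    }
    bound <- regmatches(key, regexec("^(.*)\\[(min|max)\\]$", key))[[1]]
    if (length(bound)) {
      var <- bound[2]; side <- bound[3]
      check_known(var, summary, kind = "quantitative",
                  why = paste0("[", side, "] bound"))
      cur <- filters[[var]] %||% list(type = "bounds", min = NULL, max = NULL)
      if (cur$type != "bounds") {
        abort(paste0("variable '", var, "' has both category and bound filters"))
      }
      v <- suppressWarnings(as.numeric(val))
      if (is.na(v)) abort(paste0("non-numeric bound for '", var, "': ", val))
      # repeated bounds merge to the tightest
      cur[[side]] <- if (is.null(cur[[side]])) v
                     else if (side == "min") max(cur[[side]], v) else min(cur[[side]], v)
      filters[[var]] <- cur
    } else {
      check_known(key, summary, kind = "qualitative", why = "category filter")
      cur <- filters[[key]] %||% list(type = "categories", labels = character())
      if (cur$type != "categories") {
        abort(paste0("variable '", key, "' has both category and bound filters"))
      }
      cur$labels <- union(cur$labels, val)
      filters[[key]] <- cur
    }
  }
  if (!length(requested)) abort("query requests no variables: add reqVar=<name>")
  structure(list(filters = filters, requested_vars = unique(requested)),
            class = "query_spec")
}

check_known <- function(var, summary, kind = NULL, why = "request") {
  row <- summary[summary$name == var, ]
  if (!nrow(row)) abort(paste0("unknown variable in query: '", var, "'"))
  if (!is.null(kind) && row$kind[1] != kind) {
    abort(paste0("'", var, "' is ", row$kind[1], "; a ", why,
                 " needs a ", kind, " variable"))
  }
  invisible(TRUE)
}

url_decode <- function(x) {
  URLdecode(gsub("+", " ", x, fixed = TRUE))
}

url_encode_component <- function(x) {
  vapply(x, function(s) utils::URLencode(s, reserved = TRUE), character(1),
         USE.NAMES = FALSE)
}

# Full-precision numeric rendering so parse(render(spec)) is exact.
fmt_num <- function(x) sprintf("%.17g", x)

#' @export
print.query_spec <- function(x, ...) {
  cat("<query_spec>\n  filters:\n")
  for (v in names(x$filters)) {
    f <- x$filters[[v]]
    if (f$type == "bounds") {
      cat("    ", v, " in [", f$min %||% "-Inf", ", ", f$max %||% "Inf", "]\n", sep = "")
    } else {
      cat("    ", v, " in {", paste(f$labels, collapse = ", "), "}\n", sep = "")
    }
  }
  cat("  requested: ", paste(x$requested_vars, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Render a query spec back to a query string
#'
#' Inverse of [parse_query()] up to pair order: re-parsing the rendered
#' string yields an equal spec.
#'
#' @param spec A `query_spec`.
#' @return A URL query string.
#' @export
render_query <- function(spec) {
  stopifnot(inherits(spec, "query_spec"))
  parts <- character()
  for (v in names(spec$filters)) {
    f <- spec$filters[[v]]
    ev <- url_encode_component(v)
    if (f$type == "bounds") {
      if (!is.null(f$min)) parts <- c(parts, paste0(ev, "%5Bmin%5D=", fmt_num(f$min)))
      if (!is.null(f$max)) parts <- c(parts, paste0(ev, "%5Bmax%5D=", fmt_num(f$max)))
    } else {
      parts <- c(parts, paste0(ev, "=", url_encode_component(f$labels)))
    }
  }
  parts <- c(parts, paste0("reqVar=", url_encode_component(spec$requested_vars)))
  paste(parts, collapse = "&")
}

# Translate query filters to the engine's filter state.
query_filter_state <- function(spec) {
  state <- new_filter_state()
  for (v in names(spec$filters)) {
    f <- spec$filters[[v]]
    pred <- if (f$type == "bounds") {
      flt_interval(f$min %||% -Inf, f$max %||% Inf)
    } else {
      flt_categories(f$labels)
    }
    state <- set_filter(state, v, pred)
  }
  state
}

#' Execute a parsed query against a fused pool
#'
#' Applies the query's filters through the same selection semantics as the
#' filter engine — the machine API and the GUI path return identical record
#' sets — and projects the requested variables.
#'
#' @param pool A `sample_pool` with every referenced variable integrated.
#' @param spec A `query_spec` from [parse_query()].
#' @return Tibble of the selected samples: `sample_id`, `geo_id`, `weight`,
#'   then the requested variables in query order. Rows are ordered by
#'   `sample_id`; a query whose filters select nothing returns an empty
#'   tibble, not an error.
#' @export
execute_query <- function(pool, spec) {
  stopifnot(inherits(pool, "sample_pool"), inherits(spec, "query_spec"))
  needed <- unique(c(names(spec$filters), spec$requested_vars))
  missing <- setdiff(needed, integrated_vars(pool))
  if (length(missing)) {
    abort(paste0("variables not integrated into the pool: ",
                 paste(missing, collapse = ", ")))
  }
  state <- query_filter_state(spec)
  rows <- filter_samples(pool, state)
  select(rows, "sample_id", "geo_id", "weight", all_of(spec$requested_vars))
}

#' Run a query string end to end
#'
#' @inheritParams execute_query
#' @param query_string Raw query string.
#' @param summary A `summary_meta` used to validate names; defaults to one
#'   built from the pool's integrated metadata.
#' @export
run_query <- function(pool, query_string, summary = NULL) {
  summary <- summary %||% pool_summary(pool)
  execute_query(pool, parse_query(query_string, summary))
}

# A summary_meta view of a pool's integrated variables.
pool_summary <- function(pool) {
  out <- mutate(attr(pool, "metas"), dataset = .data$source, .before = 1)
  class(out) <- c("summary_meta", class(out))
  out
}

#' Export the filtered pool as CSV (the Export-tile semantics)
#'
#' Only samples that pass every currently applied filter are exported, and
#' only the displayed variables are represented, plus the sample weight.
#' The output is the CSV equivalent of the corresponding API query.
#'
#' @param pool A `sample_pool`.
#' @param state A `filter_state`.
#' @param displayed_vars Integrated variables currently on display, in
#'   column order.
#' @param path Optional output file; when `NULL` the CSV text is returned.
#' @return CSV content as a string (RFC 4180, header row), invisibly when
#'   written to `path`.
#' @export
export_csv <- function(pool, state, displayed_vars, path = NULL) {
  stopifnot(inherits(pool, "sample_pool"))
  missing <- setdiff(displayed_vars, integrated_vars(pool))
  if (length(missing)) {
    abort(paste0("displayed variables not integrated: ",
                 paste(missing, collapse = ", ")))
  }
  rows <- filter_samples(pool, state)
  out <- select(rows, all_of(displayed_vars), "weight")
  csv <- readr::format_csv(out)
  if (is.null(path)) return(csv)
  readr::write_file(csv, path)
  invisible(csv)
}

#' Unfiltered raw values of one variable
#'
#' The raw endpoints bypass all filtering. On a `marginal_table` the
#' quantitative form returns one mean per county and the qualitative form
#' the per-county category counts, exactly as ingested; on a `sample_pool`
#' it returns every sample's value with its geo id.
#'
#' @param x A `marginal_table` or `sample_pool`.
#' @param var Variable name.
#' @return A tibble keyed by `geo_id`.
#' @export
raw_variable <- function(x, var) UseMethod("raw_variable")

#' @export
raw_variable.marginal_table <- function(x, var) {
  metas <- variable_meta(x)
  if (!var %in% metas$name) abort(paste0("unknown variable: '", var, "'"))
  rec <- filter(as_tibble(x), .data$variable == var)
  if (metas$kind[metas$name == var] == "quantitative") {
    select(rec, "geo_id", "value")
  } else {
    select(rec, "geo_id", "category", count = "value")
  }
}

#' @export
raw_variable.sample_pool <- function(x, var) {
  if (!var %in% integrated_vars(x)) abort(paste0("unknown variable: '", var, "'"))
  tibble(geo_id = x$geo_id, value = x[[var]])
}
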