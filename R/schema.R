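#' Declare the column roles of a marginal CSV file
#'
#' A marginal CSV carries one row per county and one column per measured
#' quantity. The schema names the geo-id column, the quantitative variables
#' (one column each, holding a county mean), and the qualitative variables
#' (one column per category, holding category counts).
#'
#' @param geo_col Name of the column holding the county FIPS identifier.
#' @param quantitative Character vector of quantitative variable names. If
#'   named, names are the variable names and values the CSV column names;
#'   if unnamed, the variable name and column name coincide.
#' @param qualitative Named list: variable name -> categories. Each element
#'   is a character vector of category labels; if named, values give the CSV
#'   column holding each category's count, otherwise the label is also the
#'   column name.
#' @param units Optional named character vector mapping quantitative variable
#'   names to free-text units.
#' @param source Free-text dataset source label recorded in variable
#'   metadata (defaults to the dataset label at read time).
#' @param state_prefix Optional 2-digit state FIPS prefix. When declared,
#'   geo ids of 1-3 digits are completed with this prefix (e.g. `"161"` in a
#'   Michigan file becomes `"26161"`); otherwise short ids are zero-padded
#'   to width 5.
#' @return A `marginal_schema` object.
#' @examples
#' marginal_schema(
#'   geo_col = "fips",
#'   quantitative = "pop",
#'   qualitative = list(gender = c("male", "female"))
#' )
#' @export
marginal_schema <- function(geo_col, quantitative = character(),
                            qualitative = list(), units = NULL,
                            source = NULL, state_prefix = NULL) {
  stopifnot(is.character(geo_col), length(geo_col) == 1L)
  if (length(quantitative)) {
    nm <- names(quantitative) %||% quantitative
    nm[nm == ""] <- quantitative[nm == ""]
    quantitative <- setNames(unname(quantitative), nm)
  }
  qualitative <- purrr::imap(qualitative, function(cats, var) {
    nm <- names(cats) %||% cats
    nm[nm == ""] <- cats[nm == ""]
    setNames(unname(cats), nm)  # category label -> CSV column
  })
  all_names <- c(names(quantitative), names(qualitative))
  if (anyDuplicated(all_names)) {
    abort(paste0("duplicate variable name in schema: ",
                 paste(unique(all_names[duplicated(all_names)]), collapse = ", ")))
  }
  if (!is.null(state_prefix)) {
    state_prefix <- as.character(state_prefix)
    stopifnot(grepl("^[0-9]{2}$", state_prefix))
  }
  structure(
    list(geo_col = geo_col, quantitative = quantitative,
         qualitative = qualitative, units = units %||% character(),
         source = source, state_prefix = state_prefix),
    class = "marginal_schema"
  )
}

#' @export
print.marginal_schema <- function(x, ...) {
  cat("<marginal_schema>\n")
  cat("  geo column:  ", x$geo_col,
      if (!is.null(x$state_prefix)) paste0(" (state prefix ", x$state_prefix, ")"),
      "\n", sep = "")
  cat("  quantitative:", paste(names(x$quantitative), collapse = ", "), "\n")
  cat("  qualitative: ",
      paste(vapply(seq_along(x$qualitative), function(i) {
        paste0(names(x$qualitative)[i], " {",
               paste(names(x$qualitative[[i]]), collapse = ", "), "}")
      }, character(1)), collapse = ", "), "\n")
  invisible(x)
}

# Variable metadata tibble for a schema: one row per variable, with
# categories as a list-column (qualitative only) and units (quantitative).
schema_metas <- function(schema, label) {
  source <- schema$source %||% label
  quant <- tibble(
    name = names(schema$quantitative) %||% character(),
    source = source,
    kind = "quantitative",
    categories = list(NULL),
    units = unname(schema$units[names(schema$quantitative)] %||%
                     rep("", length(schema$quantitative)))
  )
  if (nrow(quant)) quant$units[is.na(quant$units)] <- ""
  qual <- tibble(
    name = names(schema$qualitative) %||% character(),
    source = source,
    kind = "qualitative",
    categories = purrr::map(schema$qualitative, names),
    units = NA_character_
  )
  out <- bind_rows(quant, qual)
  validate_metas(out)
  out
}

validate_metas <- function(metas) {
  stopifnot(all(c("name", "source", "kind", "categories", "units") %in% names(metas)))
  if (anyDuplicated(metas$name)) {
    abort("variable names must be unique within a dataset")
  }
  if (!all(metas$kind %in% c("qualitative", "quantitative"))) {
    abort("variable kind must be 'qualitative' or 'quantitative'")
  }
  qual <- metas$kind == "qualitative"
  ok_cats <- vapply(metas$categories[qual], function(cc) {
    length(cc) > 0 && !anyDuplicated(cc)
  }, logical(1))
  if (!all(ok_cats)) {
    abort("qualitative variables need a non-empty set of distinct categories")
  }
  invisible(metas)
}
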