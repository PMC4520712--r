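#' Infer a column's kind from its raw entries
#'
#' A column is quantitative iff every non-missing entry parses as a finite
#' number; any other non-missing entry makes it qualitative. Missing tokens
#' (empty string, `NA`, `n/a`, `NaN`, case-insensitive) are ignored. No
#' user-provided metadata is needed.
#'
#' @param values Character vector of raw column entries.
#' @return `"quantitative"` or `"qualitative"`.
#' @examples
#' infer_variable_kind(c("1.5", "2", "3e1"))   # quantitative
#' infer_variable_kind(c("Male", "Female"))    # qualitative
#' @export
infer_variable_kind <- function(values) {
  if (!length(values)) abort("cannot infer the kind of an empty column")
  values <- as.character(values)
  present <- !is_missing_token(values)
  if (!any(present)) abort("cannot infer the kind of an all-missing column")
  if (all(is_number_string(trimws(values[present])))) "quantitative" else "qualitative"
}

#' A cohort specification for free-anchored integration
#'
#' Cohorts replace geography when datasets have no location key: records are
#' binned on a shared anchor variable into `n_cohorts` equal-width bins over
#' `[lo, hi]`. Bin edges are computed as `lo + i * (hi - lo) / n_cohorts`
#' (division, never repeated addition), bins are half-open
#' `[edge_i, edge_{i+1})` and the final bin is closed at `hi`.
#'
#' @param anchor_var Anchor column name (also used as the cohort name).
#' @param lo,hi Anchor range; `lo < hi`.
#' @param n_cohorts Number of cohorts (>= 1).
#' @return A `cohort_spec`.
#' @examples
#' cohort_spec("cerebellum_Volume", 0, 300000, 300)  # 1,000-wide cohorts
#' @export
cohort_spec <- function(anchor_var, lo, hi, n_cohorts) {
  stopifnot(is.character(anchor_var), length(anchor_var) == 1L,
            is.numeric(lo), is.numeric(hi), lo < hi, n_cohorts >= 1)
  structure(list(anchor_var = anchor_var, lo = as.numeric(lo),
                 hi = as.numeric(hi), n_cohorts = as.integer(n_cohorts)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", x$anchor_var, ": ", x$n_cohorts, " cohorts over [",
      x$lo, ", ", x$hi, "], width ", (x$hi - x$lo) / x$n_cohorts, "\n", sep = "")
  invisible(x)
}

#' Cohort bin edges
#'
#' @param spec A [cohort_spec()].
#' @return Numeric vector of `n_cohorts + 1` edges; the last edge is exactly
#'   `hi`.
#' @export
cohort_edges <- function(spec) {
  n <- spec$n_cohorts
  edges <- spec$lo + (0:n) * (spec$hi - spec$lo) / n
  edges[n + 1L] <- spec$hi
  edges
}

#' Read a location-free user CSV with automatic kind inference
#'
#' @param path CSV path (RFC-4180, header row).
#' @param label Dataset label; defaults to the file name without extension.
#' @return An `anchored_dataset` tibble. Quantitative columns are parsed to
#'   numeric; recognised missing tokens become `NA`. The inferred kind of
#'   each column is available via [inferred_kinds()].
#' @export
read_anchored_csv <- function(path, label = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  label <- label %||% sub("\\.[^.]*$", "", basename(path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  parse_anchored(raw, label)
}

# Shared by the CSV reader and the in-memory fixture path.
parse_anchored <- function(raw, label) {
  raw <- as_tibble(raw)
  kinds <- vapply(raw, function(col) infer_variable_kind(as.character(col)),
                  character(1))
  cols <- purrr::imap(raw, function(col, nm) {
    col <- as.character(col)
    col[is_missing_token(col)] <- NA
    if (kinds[[nm]] == "quantitative") as.numeric(col) else col
  })
  out <- as_tibble(cols)
  attr(out, "label") <- label
  attr(out, "inferred") <- kinds
  attr(out, "n_dropped") <- 0L
  class(out) <- c("anchored_dataset", class(tibble()))
  out
}

#' @rdname read_anchored_csv
#' @param dataset An `anchored_dataset`.
#' @export
inferred_kinds <- function(dataset) attr(dataset, "inferred")

#' Assign every record to a cohort on the anchor variable
#'
#' A record with anchor value `v` gets cohort `floor((v - lo) / width)`;
#' `v = hi` lands in the top cohort (closed top bin). Records with `v`
#' outside `[lo, hi]` or a missing anchor are dropped and counted (query
#' the count with `attr(x, "n_dropped")`).
#'
#' @param dataset An `anchored_dataset`.
#' @param spec A [cohort_spec()]; its `anchor_var` must be a quantitative
#'   column of `dataset`.
#' @return The dataset restricted to in-range records, with an integer
#'   `.cohort` column in `[0, n_cohorts)`.
#' @export
assign_cohorts <- function(dataset, spec) {
  stopifnot(inherits(dataset, "anchored_dataset"), inherits(spec, "cohort_spec"))
  av <- spec$anchor_var
  if (!av %in% names(dataset)) {
    abort(paste0("anchor column '", av, "' not present in dataset '",
                 attr(dataset, "label"), "'"))
  }
  if (inferred_kinds(dataset)[[av]] != "quantitative") {
    abort(paste0("anchor column '", av, "' is qualitative; cohorts need a ",
                 "quantitative anchor"))
  }
  v <- dataset[[av]]
  width <- (spec$hi - spec$lo) / spec$n_cohorts
  idx <- floor((v - spec$lo) / width)
  idx[!is.na(v) & v == spec$hi] <- spec$n_cohorts - 1L
  keep <- !is.na(v) & v >= spec$lo & v <= spec$hi
  out <- as_tibble(dataset)[keep, ]
  out$.cohort <- as.integer(idx[keep])
  attr(out, "label") <- attr(dataset, "label")
  attr(out, "inferred") <- inferred_kinds(dataset)
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "cohort_spec") <- spec
  class(out) <- c("anchored_dataset", class(tibble()))
  out
}

#' Merge cohort-assigned datasets into a filterable pool
#'
#' Records from all datasets are pooled with the cohort index playing the
#' role the county FIPS plays in the location-anchored mode. Columns are
#' prefixed with their dataset label (`label.column`) to avoid collisions;
#' the anchor column and the cohort index are shared. The result is a
#' `sample_pool` (unit weights, scale denominator 1) whose variables —
#' including the quantitative `cohort` index itself — feed
#' [crossfilter()] dimensions directly. A record carries `NA` for the other
#' datasets' variables, and missing values never pass a predicate, so
#' cross-dataset comparison goes through the shared cohort/anchor
#' dimensions.
#'
#' @param datasets List of cohort-assigned `anchored_dataset`s (same
#'   [cohort_spec()] for all).
#' @param spec The shared [cohort_spec()].
#' @return A `sample_pool` of merged records.
#' @export
merge_on_cohort <- function(datasets, spec) {
  stopifnot(length(datasets) >= 1L,
            all(vapply(datasets, inherits, logical(1), "anchored_dataset")))
  for (d in datasets) {
    dspec <- attr(d, "cohort_spec")
    if (is.null(dspec)) {
      abort(paste0("dataset '", attr(d, "label"), "' has no cohort assignment"))
    }
    if (!identical(unclass(dspec), unclass(spec))) {
      abort(paste0("dataset '", attr(d, "label"),
                   "' was cohorted under a different spec"))
    }
  }
  labels <- vapply(datasets, function(d) attr(d, "label"), character(1))
  if (anyDuplicated(labels)) abort("dataset labels must be distinct")

  av <- spec$anchor_var
  parts <- purrr::map(datasets, function(d) {
    lab <- attr(d, "label")
    keep_as_is <- c(av, ".cohort")
    renames <- setdiff(names(d), keep_as_is)
    out <- as_tibble(d)
    names(out)[match(renames, names(out))] <- paste0(lab, ".", renames)
    out$.source <- lab
    out
  })
  merged <- bind_rows(parts)
  merged$cohort <- as.numeric(merged$.cohort)
  merged <- tibble(
    sample_id = seq_len(nrow(merged)),
    geo_id = sprintf("%05d", merged$.cohort),
    weight = 1
  ) |>
    dplyr::bind_cols(select(merged, -".cohort"))

  metas <- purrr::map2_dfr(datasets, labels, function(d, lab) {
    kinds <- inferred_kinds(d)
    purrr::imap_dfr(kinds, function(kind, nm) {
      col <- if (nm == av) av else paste0(lab, ".", nm)
      vals <- merged[[col]]
      tibble(name = col, source = lab, kind = kind,
             categories = list(if (kind == "qualitative")
               sort(unique(vals[!is.na(vals)])) else NULL),
             units = if (kind == "quantitative") "" else NA_character_)
    })
  }) |>
    distinct(.data$name, .keep_all = TRUE)
  metas <- bind_rows(
    metas,
    tibble(name = "cohort", source = "cohort", kind = "quantitative",
           categories = list(NULL), units = "cohort index")
  )
  new_sample_pool(merged, scale_denominator = 1L, seed = 0L, metas = metas)
}
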