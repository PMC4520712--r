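#' Filter predicates
#'
#' Two predicate forms exist, matching the two variable kinds: a closed
#' numeric interval `[lo, hi]` for quantitative dimensions and a category
#' set (disjunction of labels) for qualitative ones. Missing values never
#' satisfy a predicate.
#'
#' @param lo,hi Interval endpoints (both inclusive); either may be infinite.
#' @param ... Category labels (character), or a single character vector.
#' @return A `mash_predicate`.
#' @examples
#' flt_interval(40000, 60000)
#' flt_categories("White", "Black")
#' @export
flt_interval <- function(lo = -Inf, hi = Inf) {
  stopifnot(is.numeric(lo), is.numeric(hi), length(lo) == 1, length(hi) == 1)
  if (lo > hi) abort("interval requires lo <= hi")
  structure(list(type = "interval", lo = lo, hi = hi), class = "mash_predicate")
}

#' @rdname flt_interval
#' @export
flt_categories <- function(...) {
  labels <- unique(as.character(c(...)))
  if (!length(labels)) abort("category set must be non-empty")
  structure(list(type = "categories", labels = labels), class = "mash_predicate")
}

#' @export
print.mash_predicate <- function(x, ...) {
  if (x$type == "interval") {
    cat("<predicate> [", x$lo, ", ", x$hi, "]\n", sep = "")
  } else {
    cat("<predicate> {", paste(x$labels, collapse = ", "), "}\n", sep = "")
  }
  invisible(x)
}

#' Shared filter state
#'
#' A `filter_state` holds at most one active predicate per variable; setting
#' a predicate on a variable replaces any prior one (the dashboard's brush
#' semantics), and all predicates combine as a conjunction.
#'
#' @return An empty `filter_state`.
#' @export
new_filter_state <- function() {
  structure(list(predicates = list()), class = "filter_state")
}

#' Set or clear one dimension's predicate
#'
#' @param state A `filter_state` or a [crossfilter()] engine.
#' @param var Variable name.
#' @param predicate A [flt_interval()] or [flt_categories()] predicate.
#' @param ... Unused.
#' @return The updated state (or engine).
#' @export
set_filter <- function(state, var, predicate, ...) UseMethod("set_filter")

#' @export
set_filter.filter_state <- function(state, var, predicate, ...) {
  stopifnot(inherits(predicate, "mash_predicate"))
  state$predicates[[var]] <- predicate
  state
}

#' @rdname set_filter
#' @export
clear_filter <- function(state, var, ...) UseMethod("clear_filter")

#' @export
clear_filter.filter_state <- function(state, var, ...) {
  state$predicates[[var]] <- NULL
  state
}

#' @export
print.filter_state <- function(x, ...) {
  if (!length(x$predicates)) {
    cat("<filter_state> (no active filters)\n")
    return(invisible(x))
  }
  cat("<filter_state>\n")
  for (v in names(x$predicates)) {
    p <- x$predicates[[v]]
    desc <- if (p$type == "interval") paste0("[", p$lo, ", ", p$hi, "]")
            else paste0("{", paste(p$labels, collapse = ", "), "}")
    cat("  ", v, " in ", desc, "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.filter_state <- function(x, ...) {
  purrr::imap_dfr(x$predicates, function(p, v) {
    tibble(variable = v, type = p$type,
           lo = if (p$type == "interval") p$lo else NA_real_,
           hi = if (p$type == "interval") p$hi else NA_real_,
           labels = list(if (p$type == "categories") p$labels else NULL))
  })
}

# Logical mask of one predicate over a pool column. NA never passes.
predicate_mask <- function(values, predicate) {
  if (predicate$type == "interval") {
    if (!is.numeric(values)) abort("interval predicate on a qualitative dimension")
    !is.na(values) & values >= predicate$lo & values <= predicate$hi
  } else {
    if (is.numeric(values)) abort("category predicate on a quantitative dimension")
    !is.na(values) & values %in% predicate$labels
  }
}

selection_mask <- function(pool, state, exclude = NULL) {
  mask <- rep(TRUE, nrow(pool))
  for (v in setdiff(names(state$predicates), exclude)) {
    if (!v %in% names(pool)) abort(paste0("filtered variable not integrated: ", v))
    mask <- mask & predicate_mask(pool[[v]], state$predicates[[v]])
  }
  mask
}

#' Samples satisfying all active filters
#'
#' `current_selection()` returns the ids of the samples that satisfy the
#' conjunction of every active predicate (category sets are disjunctions
#' within their own dimension); `filter_samples()` returns the corresponding
#' rows of the pool.
#'
#' @param pool A `sample_pool` (or a [crossfilter()] engine, in which case
#'   `state` is taken from the engine).
#' @param state A `filter_state`.
#' @return `current_selection()`: sorted integer vector of sample ids;
#'   `filter_samples()`: the selected rows as a tibble.
#' @export
current_selection <- function(pool, state = new_filter_state()) {
  UseMethod("current_selection")
}

#' @export
current_selection.sample_pool <- function(pool, state = new_filter_state()) {
  sort(pool$sample_id[selection_mask(pool, state)])
}

#' @rdname current_selection
#' @export
filter_samples <- function(pool, state = new_filter_state()) {
  stopifnot(inherits(pool, "sample_pool"))
  out <- as_tibble(pool)[selection_mask(pool, state), ]
  arrange(out, .data$sample_id)
}
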