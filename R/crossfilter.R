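#' A crossfilter-style engine over a sample pool
#'
#' The engine keeps one registered dimension per charted variable and a
#' shared [new_filter_state()]. Per-dimension boolean masks are cached, so
#' changing one dimension's predicate only recomputes that dimension's mask
#' while the other cached masks are reused — repeated re-filtering does not
#' rescan every dimension. Correctness is defined by the naive full scan:
#' the engine must always agree with it.
#'
#' The number of simultaneous views is capped (30 by default, the
#' dashboard's chart limit), and a view may involve between 1 and
#' `max_vars_per_view` variables.
#'
#' @param pool A `sample_pool`.
#' @param max_views Maximum number of registered dimensions.
#' @param max_vars_per_view Maximum variables a single view may combine.
#' @return A `crossfilter` engine.
#' @examples
#' pool <- build_pool(worked_example_fixture(), "pop", seed = 1)
#' pool <- integrate_qualitative(pool, "gender", worked_example_fixture())
#' cf <- crossfilter(pool)
#' cf <- add_dimension(cf, "gender")
#' cf <- set_filter(cf, "gender", flt_categories("male"))
#' current_selection(cf)
#' @export
crossfilter <- function(pool, max_views = 30L, max_vars_per_view = 6L) {
  stopifnot(inherits(pool, "sample_pool"))
  structure(
    list(pool = pool,
         dimensions = tibble(var = character(), kind = character()),
         state = new_filter_state(),
         masks = list(),
         max_views = max_views,
         max_vars_per_view = max_vars_per_view),
    class = "crossfilter"
  )
}

#' @export
print.crossfilter <- function(x, ...) {
  cat("<crossfilter> ", nrow(x$pool), " samples, ",
      nrow(x$dimensions), "/", x$max_views, " dimensions\n", sep = "")
  print(x$state)
  invisible(x)
}

#' Register a dimension on an integrated variable
#'
#' Creating a dimension never changes the current selection; it only makes
#' the variable filterable and groupable.
#'
#' @param cf A [crossfilter()] engine.
#' @param var Integrated variable name.
#' @return The engine with the dimension registered.
#' @export
add_dimension <- function(cf, var) {
  stopifnot(inherits(cf, "crossfilter"))
  if (var %in% cf$dimensions$var) return(cf)
  kind <- variable_kind(cf$pool, var)  # errors if not integrated
  if (nrow(cf$dimensions) + 1L > cf$max_views) {
    abort(paste0("view limit reached: at most ", cf$max_views,
                 " simultaneous dimensions"))
  }
  cf$dimensions <- bind_rows(cf$dimensions, tibble(var = var, kind = kind))
  cf
}

#' @export
set_filter.crossfilter <- function(state, var, predicate, ...) {
  cf <- state
  if (!var %in% cf$dimensions$var) cf <- add_dimension(cf, var)
  kind <- cf$dimensions$kind[cf$dimensions$var == var]
  if (predicate$type == "interval" && kind != "quantitative") {
    abort(paste0("interval predicate on qualitative dimension '", var, "'"))
  }
  if (predicate$type == "categories" && kind != "qualitative") {
    abort(paste0("category predicate on quantitative dimension '", var, "'"))
  }
  cf$state <- set_filter(cf$state, var, predicate)
  # only this dimension's mask is recomputed; others stay cached
  cf$masks[[var]] <- predicate_mask(cf$pool[[var]], predicate)
  cf
}

#' @export
clear_filter.crossfilter <- function(state, var, ...) {
  cf <- state
  cf$state <- clear_filter(cf$state, var)
  cf$masks[[var]] <- NULL
  cf
}

#' @export
current_selection.crossfilter <- function(pool, state = NULL) {
  cf <- pool
  mask <- Reduce(`&`, cf$masks, init = rep(TRUE, nrow(cf$pool)))
  sort(cf$pool$sample_id[mask])
}

#' Group aggregation that excludes the grouped dimension's own filter
#'
#' Aggregates samples per category (qualitative dimension) or per bin
#' (quantitative dimension, half-open bins with a closed top bin) under all
#' active filters except the one on the grouped dimension itself. This is
#' the coordinated-views convention: brushing a chart restricts every other
#' chart while the brushed chart keeps showing its full axis.
#'
#' @param cf A [crossfilter()] engine.
#' @param var Grouped dimension (registered automatically if needed).
#' @param stat `"count"`, `"sum"` or `"mean"`; the latter two aggregate
#'   `target`.
#' @param target Quantitative variable to sum/average (ignored for
#'   `"count"`).
#' @param breaks For quantitative dimensions: bin edge vector, or a single
#'   integer number of equal-width bins over the variable's full range.
#' @return A `mash_groups` tibble with one row per category/bin: `group`,
#'   `value`, and for quantitative dimensions the numeric edges `lo`, `hi`.
#' @export
group_aggregate <- function(cf, var, stat = c("count", "sum", "mean"),
                            target = NULL, breaks = 10L) {
  stopifnot(inherits(cf, "crossfilter"))
  stat <- match.arg(stat)
  cf <- add_dimension(cf, var)
  kind <- cf$dimensions$kind[cf$dimensions$var == var]
  n_vars <- length(unique(c(var, target)))
  if (n_vars > cf$max_vars_per_view) {
    abort(paste0("a view may combine at most ", cf$max_vars_per_view, " variables"))
  }
  if (stat != "count") {
    if (is.null(target)) abort(paste0("stat '", stat, "' needs a target variable"))
    if (variable_kind(cf$pool, target) != "quantitative") {
      abort(paste0("cannot ", stat, " qualitative variable '", target, "'"))
    }
  }
  other <- cf$masks[setdiff(names(cf$masks), var)]
  mask <- Reduce(`&`, other, init = rep(TRUE, nrow(cf$pool)))

  values <- cf$pool[[var]]
  if (kind == "qualitative") {
    meta <- filter(attr(cf$pool, "metas"), .data$name == var)
    levels <- meta$categories[[1]] %||% sort(unique(values[!is.na(values)]))
    groups <- tibble(group = levels)
    in_group <- function(g) mask & !is.na(values) & values == g
  } else {
    edges <- bin_edges(values, breaks)
    groups <- tibble(
      group = paste0("[", format_edge(edges[-length(edges)]), ", ",
                     format_edge(edges[-1]), ")"),
      lo = edges[-length(edges)], hi = edges[-1]
    )
    groups$group[nrow(groups)] <- sub("\\)$", "]", groups$group[nrow(groups)])
    idx <- bin_index(values, edges)
    in_group <- function(g) {
      i <- which(groups$group == g)
      mask & !is.na(idx) & idx == i
    }
  }
  agg <- vapply(groups$group, function(g) {
    sel <- in_group(g)
    switch(stat,
           count = sum(sel),
           sum = sum(cf$pool[[target]][sel]),
           mean = if (any(sel)) mean(cf$pool[[target]][sel]) else NA_real_)
  }, numeric(1))
  groups$value <- unname(agg)
  structure(groups, class = c("mash_groups", class(groups)),
            var = var, stat = stat, target = target, kind = kind)
}

# Equal-width edges computed from the range by division (never by repeated
# addition), so edge k is exactly lo + k * (hi - lo) / n and the last edge
# is exactly the top of the range.
bin_edges <- function(values, breaks) {
  if (length(breaks) > 1L) {
    stopifnot(!is.unsorted(breaks))
    return(as.numeric(breaks))
  }
  r <- range(values, na.rm = TRUE)
  if (r[1] == r[2]) r[2] <- r[1] + 1
  n <- as.integer(breaks)
  edges <- r[1] + (0:n) * (r[2] - r[1]) / n
  edges[n + 1L] <- r[2]
  edges
}

# Half-open bins [e_i, e_{i+1}) with the final bin closed at the top edge;
# values outside the edge range get NA.
bin_index <- function(values, edges) {
  n <- length(edges) - 1L
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  idx[!is.na(values) & (values < edges[1] | values > edges[n + 1L])] <- NA_integer_
  idx[idx == 0L] <- NA_integer_
  idx
}

format_edge <- function(x) format(x, trim = TRUE, scientific = FALSE, digits = 7)

#' @export
autoplot.mash_groups <- function(object, ...) {
  var <- attr(object, "var")
  stat <- attr(object, "stat")
  lab <- if (stat == "count") "samples" else paste(stat, "of", attr(object, "target"))
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$group, levels = .data$group),
                               y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = var, y = lab) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar-chart view of a grouped dimension
#'
#' Convenience wrapper: `plot_dimension(cf, var)` is
#' `autoplot(group_aggregate(cf, var, "count"))`.
#'
#' @inheritParams group_aggregate
#' @export
plot_dimension <- function(cf, var, breaks = 10L) {
  autoplot(group_aggregate(cf, var, "count", breaks = breaks))
}
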