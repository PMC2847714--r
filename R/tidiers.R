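#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy methods for phenoxp result objects
#'
#' `tidy()` returns one row per elementary result (an edge, a finding, a
#' queue entry); `glance()` returns a one-row summary.
#'
#' @param x a phenoxp result object.
#' @param ... unused.
#' @return A tibble.
#' @name phenoxp-tidiers
NULL

#' @rdname phenoxp-tidiers
#' @export
tidy.closure_graph <- function(x, ...) {
  x$edges
}

#' @rdname phenoxp-tidiers
#' @export
glance.closure_graph <- function(x, ...) {
  tibble(
    n_classes = length(x$classes),
    n_edges = nrow(x$edges),
    n_asserted = sum(x$edges$status == "asserted"),
    n_inferred = sum(x$edges$status == "inferred"),
    n_definitions = length(x$definitions)
  )
}

#' @rdname phenoxp-tidiers
#' @export
tidy.recap_report <- function(x, ...) {
  bind_rows(
    mutate(x$recovered, category = "recovered"),
    mutate(x$missed, category = "missed"),
    transmute(x$novel, subject = .data$subject, object = .data$object,
              category = "novel")
  )
}

#' @rdname phenoxp-tidiers
#' @export
glance.recap_report <- function(x, ...) {
  tibble(
    n_asserted = x$n_asserted,
    n_recovered = nrow(x$recovered),
    n_missed = nrow(x$missed),
    n_novel = nrow(x$novel),
    recall_all = x$recall_all,
    recall_defined = x$recall_defined
  )
}

#' @rdname phenoxp-tidiers
#' @export
tidy.xp_coverage <- function(x, ...) {
  x$by_prefix
}

#' @rdname phenoxp-tidiers
#' @export
glance.xp_coverage <- function(x, ...) {
  x$summary
}

#' @rdname phenoxp-tidiers
#' @export
tidy.xp_batch <- function(x, ...) {
  x$queue
}

#' @rdname phenoxp-tidiers
#' @export
glance.xp_batch <- function(x, ...) {
  tibble(
    n_classes = x$n_classes,
    n_accepted = x$n_accepted,
    n_queued = nrow(x$queue),
    coverage = x$coverage
  )
}

#' Plot a recapitulation report
#'
#' Bar chart of recovered, missed and novel link counts.
#'
#' @param object a [recapitulate()] report.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.recap_report <- function(object, ...) {
  df <- tibble(
    category = factor(c("recovered", "missed", "novel"),
                      levels = c("recovered", "missed", "novel")),
    n = c(nrow(object$recovered), nrow(object$missed), nrow(object$novel))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = NULL, y = "is_a links",
      title = sprintf("Recapitulation: recall %.1f%% of %d asserted links",
                      100 * object$recall_all, object$n_asserted)
    )
}

#' Plot definition coverage by entity ontology
#'
#' @param object a [coverage_stats()] result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.xp_coverage <- function(object, ...) {
  ggplot2::ggplot(object$by_prefix,
                  ggplot2::aes(x = stats::reorder(.data$prefix,
                                                  -.data$n_definitions),
                               y = .data$n_definitions)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "entity ontology", y = "definitions",
      title = sprintf("%d / %d classes defined (%.1f%%)",
                      object$summary$defined, object$summary$total_classes,
                      object$summary$pct)
    )
}
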