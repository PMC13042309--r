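#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy and glance methods
#'
#' `tidy()` returns the underlying table as a plain tibble; `glance()`
#' returns a one-row summary.
#'
#' @param x A `malines` result object.
#' @param ... Unused.
#' @return A tibble.
#' @name malines-broom
NULL

#' @rdname malines-broom
#' @export
tidy.ma_candidates <- function(x, ...) as_tibble(unclass_result(x))

#' @rdname malines-broom
#' @export
glance.ma_candidates <- function(x, ...) {
  tibble(
    n_candidates = nrow(x),
    n_snv = sum(x$mtype == "SNV"),
    n_ins = sum(x$mtype == "insertion"),
    n_del = sum(x$mtype == "deletion"),
    n_lines = dplyr::n_distinct(x$line_id),
    n_removed_linked = attr(x, "n_removed_linked") %||% NA_integer_
  )
}

#' @rdname malines-broom
#' @export
tidy.ma_rates <- function(x, ...) as_tibble(unclass_result(x))

#' @rdname malines-broom
#' @param candidates,genome,annotation,ci Passed to [group_summary()].
#' @export
glance.ma_rates <- function(x, candidates = NULL, genome = NULL,
                            annotation = NULL, ci = "sem", ...) {
  as_tibble(unclass_result(group_summary(x, candidates, genome, annotation, ci)))
}

#' @rdname malines-broom
#' @export
tidy.ma_test <- function(x, ...) as_tibble(unclass_result(x))

#' @rdname malines-broom
#' @export
glance.ma_test <- tidy.ma_test

#' @rdname malines-broom
#' @export
tidy.ma_sharing <- function(x, ...) as_tibble(unclass_result(x))

#' @rdname malines-broom
#' @export
tidy.ma_spectrum <- function(x, ...) as_tibble(unclass_result(x))

unclass_result <- function(x) {
  attr(x, "attrition") <- NULL
  attr(x, "n_removed_linked") <- NULL
  attr(x, "means") <- NULL
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}

#' Plot per-line mutation rates
#'
#' One point per line per mutation type, with the group mean marked —
#' the per-group panel of a rate-comparison figure.
#'
#' @param object An [per_line_rates()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ma_rates <- function(object, ...) {
  long <- tidy(object) |>
    tidyr::pivot_longer(dplyr::starts_with("rate_"),
                        names_to = "mtype", values_to = "rate") |>
    mutate(mtype = dplyr::recode(.data$mtype, rate_snv = "SNV",
                                 rate_ins = "insertion", rate_del = "deletion"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mtype, y = .data$rate)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3, colour = "firebrick") +
    ggplot2::labs(
      x = NULL, y = "rate (site⁻¹ generation⁻¹)",
      title = attr(object, "group_name") %||% NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot a six-class SNV spectrum
#'
#' @param object A [spectrum_table()] result.
#' @param ... Unused.
#' @return A ggplot (fraction of SNVs per class).
#' @export
autoplot.ma_spectrum <- function(object, ...) {
  d <- tidy(object) |> mutate(class = factor(.data$class, levels = SNV_CLASSES))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$class, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "fraction of SNVs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot indel length distributions
#'
#' @param object An [indel_lengths()] result.
#' @param ... Unused.
#' @return A ggplot (count by absolute length, one facet per type).
#' @export
autoplot.ma_indel_lengths <- function(object, ...) {
  d <- as_tibble(unclass_result(object))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$length, y = .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~mtype, scales = "free") +
    ggplot2::labs(x = "length (bp)", y = "count") +
    ggplot2::theme_minimal()
}
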