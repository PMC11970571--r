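## broom-style accessors for report objects.

#' Tidy a correlation report
#'
#' @param x a `radcorr_report` from [correlation_report()].
#' @param ... unused.
#' @return the pairs tibble (one row per column pair).
#' @export
tidy.radcorr_report <- function(x, ...) {
  x$pairs
}

#' One-row summary of a correlation report
#'
#' @param x a `radcorr_report`.
#' @param ... unused.
#' @return tibble with `n_patients`, `n_columns`, `n_pairs`,
#'   `n_undefined`, `n_dropped_for_volume`, `n_significant`, `alpha`.
#' @export
glance.radcorr_report <- function(x, ...) {
  tibble::tibble(
    n_patients = x$n_patients,
    n_columns = x$n_columns,
    n_pairs = nrow(x$pairs),
    n_undefined = nrow(x$undefined_pairs),
    n_dropped_for_volume = if (is.null(x$dropped)) 0L else nrow(x$dropped),
    n_significant = sum(x$pairs$significant),
    alpha = x$alpha
  )
}

#' Tidy a correlation summary
#'
#' @param x a `radcorr_summary` from [summarize_correlations()].
#' @param ... unused.
#' @return the per-class/per-group summary tibble.
#' @export
tidy.radcorr_summary <- function(x, ...) {
  x$by_group
}
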