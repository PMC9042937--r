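#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cohort test result
#'
#' One row per post-hoc comparison, or a single omnibus row when the test
#' has no post hoc.
#' @param x An `hv_test`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hv_test <- function(x, ...) {
  if (is.null(x$post_hoc)) {
    tibble::tibble(method = x$method, comparison = "omnibus",
                   statistic = x$statistic,
                   df1 = if (length(x$df) >= 1) x$df[1] else NA_real_,
                   df2 = if (length(x$df) >= 2) x$df[2] else NA_real_,
                   p_value = x$p_value, significant = x$p_value < x$alpha)
  } else {
    ph <- x$post_hoc
    tibble::tibble(method = paste0(x$method, "_posthoc"),
                   comparison = ph$comparison,
                   statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
                   p_value = if ("adjusted_p" %in% names(ph)) ph$adjusted_p else ph$p_value,
                   significant = ph$significant)
  }
}

#' One-row summary of a cohort test result
#' @param x An `hv_test`.
#' @param ... Unused.
#' @return A one-row tibble with the omnibus statistic, df, p-value, the
#'   number of post-hoc comparisons and how many were significant.
#' @export
glance.hv_test <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 df1 = if (length(x$df) >= 1) x$df[1] else NA_real_,
                 df2 = if (length(x$df) >= 2) x$df[2] else NA_real_,
                 p_value = x$p_value, alpha = x$alpha,
                 n_post_hoc = if (is.null(x$post_hoc)) 0L else nrow(x$post_hoc),
                 n_significant = if (is.null(x$post_hoc)) NA_integer_
                                 else sum(x$post_hoc$significant))
}

#' Tidy a quartile segmentation
#' @param x A `quartile_seg`.
#' @param ... Unused.
#' @return A tibble `quartile, cutoff_db, n_pixels, degenerate`.
#' @export
tidy.quartile_seg <- function(x, ...) {
  tibble::tibble(quartile = names(x$cutoffs_db),
                 cutoff_db = as.numeric(x$cutoffs_db),
                 n_pixels = x$counts, degenerate = x$degenerate)
}

#' Tidy a singular spectrum
#' @param x A `singular_spectrum`.
#' @param ... Unused.
#' @return A tibble `index, singular_value`.
#' @export
tidy.singular_spectrum <- function(x, ...) {
  tibble::tibble(index = seq_along(x$d), singular_value = x$d)
}
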