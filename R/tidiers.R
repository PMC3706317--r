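#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a Comparison Map Profile result
#'
#' @param x A `cmp_result` from [run_cmp()].
#' @param ... Unused.
#' @return The index profile as a tibble: `index`, `scale`, `value`,
#'   `n_defined` (number of defined window centres at that scale).
#' @method tidy cmp_result
#' @export
tidy.cmp_result <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(index = x$index), x$profile)
}

#' @rdname tidy.cmp_result
#' @return For `glance()`: a one-row tibble with `index`, `global_0`
#'   (monoscale-0 whole-map statistic), `profile_mean` (mean over scales
#'   `1..max_scale`) and `max_scale`.
#' @method glance cmp_result
#' @export
glance.cmp_result <- function(x, ...) {
  tibble::tibble(
    index = x$index, global_0 = x$global_0,
    profile_mean = x$profile_mean, max_scale = max(x$scales)
  )
}

#' @method tidy model_validation
#' @export
tidy.model_validation <- function(x, ...) tidy(x$cmp)

#' @method glance model_validation
#' @export
glance.model_validation <- function(x, ...) x$record

#' @method tidy model_comparison
#' @export
tidy.model_comparison <- function(x, ...) {
  dplyr::bind_rows(tidy(x$cmp_d), tidy(x$cmp_cc))
}

#' @method glance model_comparison
#' @export
glance.model_comparison <- function(x, ...) x$record

#' @method tidy null_baseline
#' @export
tidy.null_baseline <- function(x, ...) x$per_scale

#' @method glance null_baseline
#' @export
glance.null_baseline <- function(x, ...) {
  tibble::tibble(
    p = x$p, n_replicates = x$n_replicates, max_scale = x$max_scale,
    min_scale_for_mean = x$min_scale_for_mean, grand_mean = x$grand_mean
  )
}
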