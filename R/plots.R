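#' Plot a raster map
#'
#' ggplot2 tile plot of a [score_map()] or [binary_map()] in cell-centre
#' lon/lat coordinates; invalid cells are left blank.
#'
#' @param map A raster map.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_map <- function(map, title = NULL) {
  stopifnot(inherits(map, "raster_map"))
  df <- dplyr::filter(as_tibble(map), .data$valid)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = "value", title = title)
}

#' @describeIn run_cmp Plot a CMP result: `type = "profile"` draws the
#'   per-scale index profile, `type = "multiscale"` the multiscale map.
#' @param object A `cmp_result`.
#' @param type `"profile"` or `"multiscale"`.
#' @param ... Unused.
#' @method autoplot cmp_result
#' @export
autoplot.cmp_result <- function(object, type = c("profile", "multiscale"), ...) {
  type <- match.arg(type)
  if (type == "multiscale") {
    return(plot_map(
      object$multiscale,
      title = sprintf("Multiscale %s map", object$index)
    ))
  }
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$scale, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Scale (window radius, pixels)", y = object$index,
      title = sprintf(
        "%s profile (%s_0 = %.3f, %s_mean = %.3f)",
        object$index, object$index, object$global_0,
        object$index, object$profile_mean
      )
    )
}

#' @method autoplot model_validation
#' @export
autoplot.model_validation <- function(object, ...) {
  autoplot(object$cmp, ...)
}

#' @method autoplot null_baseline
#' @export
autoplot.null_baseline <- function(object, ...) {
  ggplot2::ggplot(object$per_scale, ggplot2::aes(x = .data$scale, y = .data$mean_kappa)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = .data$mean_kappa - 2 * .data$se,
        ymax = .data$mean_kappa + 2 * .data$se
      ),
      alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Scale (window radius, pixels)", y = "Mean kappa",
      title = sprintf(
        "Random-pattern null: mean kappa over scales %d..%d = %.4f",
        object$min_scale_for_mean, object$max_scale, object$grand_mean
      )
    )
}
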