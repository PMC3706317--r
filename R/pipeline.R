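#' Validate a model projection against an observed distribution
#'
#' The single-model validation stage: AUC from the ROC of the standardised
#' scores against the observed presence/absence map; the species presence
#' threshold (SPT) at the ROC point farthest from the 1:1 line; the
#' projection dichotomised at SPT; whole-map Cohen's kappa of that
#' prediction (`kappa_0`); and the multiscale moving-window kappa profile,
#' whose mean over scales `1..max_scale` is `kappa_mean`.
#'
#' @param scores A standardised [score_map()] of model output.
#' @param observed A co-registered [binary_map()] of the observed
#'   distribution.
#' @param max_scale Largest comparison window radius (default 20).
#' @param ... Passed to [run_cmp()] (`min_valid_fraction`, `min_cells`,
#'   `keep_monoscale`).
#' @return A `model_validation` object: list with `record` (one-row tibble
#'   `auc`, `spt`, `kappa_0`, `kappa_mean`), `roc` ([roc_curve()]),
#'   `prediction` ([binary_map()]) and `cmp` (the kappa `cmp_result`).
#' @examples
#' cl <- make_climate(grid_meta(25, 30), seed = 2)
#' sc <- standardize(envelope_model(cl, toy_species_limits()))
#' obs <- observed_distribution(sc, flip_noise = 0.05, seed = 3)
#' v <- validate_model(sc, obs, max_scale = 4)
#' glance(v)
#' @export
validate_model <- function(scores, observed, max_scale = 20, ...) {
  roc <- roc_curve(scores, observed)
  spt <- spt_threshold(roc)
  prediction <- dichotomize(scores, spt)
  cmp <- run_cmp(prediction, observed, "kappa", max_scale = max_scale, ...)
  structure(
    list(
      record = tibble::tibble(
        auc = auc(roc), spt = spt,
        kappa_0 = cmp$global_0, kappa_mean = cmp$profile_mean
      ),
      roc = roc, prediction = prediction, cmp = cmp
    ),
    class = "model_validation"
  )
}

#' Compare two model projections across scales
#'
#' Pairwise model-model comparison: absolute distance (D) and
#' cross-correlation (CC) Comparison Map Profiles between two standardised
#' score maps, summarised as the whole-map `d_0` / `cc_0` and the
#' profile means `d_mean` / `cc_mean` over scales `1..max_scale`.
#'
#' @param a,b Standardised, co-registered [score_map()]s.
#' @inheritParams validate_model
#' @return A `model_comparison` object: list with `record` (one-row tibble
#'   `d_0`, `d_mean`, `cc_0`, `cc_mean`) and the two `cmp_result`s
#'   (`cmp_d`, `cmp_cc`).
#' @export
compare_models <- function(a, b, max_scale = 20, ...) {
  cmp_d <- run_cmp(a, b, "D", max_scale = max_scale, ...)
  cmp_cc <- run_cmp(a, b, "CC", max_scale = max_scale, ...)
  structure(
    list(
      record = tibble::tibble(
        d_0 = cmp_d$global_0, d_mean = cmp_d$profile_mean,
        cc_0 = cmp_cc$global_0, cc_mean = cmp_cc$profile_mean
      ),
      cmp_d = cmp_d, cmp_cc = cmp_cc
    ),
    class = "model_comparison"
  )
}

#' Kappa anomaly profiles across models
#'
#' For a set of models validated against the same observation, computes the
#' per-scale cross-model mean kappa and each model's relative anomaly
#' `(kappa_m - mean) / mean`. Anomalies sum to zero across models at every
#' scale where the mean is non-zero; they are `NA` where it is zero.
#'
#' @param cmps Named list (length >= 2) of kappa `cmp_result`s sharing the
#'   same scales, e.g. `purrr::map(validations, "cmp")`.
#' @return A tibble with columns `scale`, `model`, `kappa`, `mean_kappa`,
#'   `anomaly`.
#' @export
kappa_anomaly_profiles <- function(cmps) {
  stopifnot(length(cmps) >= 2, !is.null(names(cmps)), all(names(cmps) != ""))
  scales <- cmps[[1]]$scales
  ok <- vapply(cmps, function(x) identical(x$scales, scales), logical(1))
  if (!all(ok)) stop("all cmp results must share the same scale list", call. = FALSE)
  long <- purrr::imap_dfr(cmps, function(x, nm) {
    tibble::tibble(scale = x$scales, model = nm, kappa = x$profile$value)
  })
  long |>
    dplyr::group_by(.data$scale) |>
    dplyr::mutate(
      mean_kappa = mean(.data$kappa),
      anomaly = dplyr::if_else(
        .data$mean_kappa == 0, NA_real_,
        (.data$kappa - .data$mean_kappa) / .data$mean_kappa
      )
    ) |>
    dplyr::ungroup()
}

#' Bioclimatic-limit nesting decomposition
#'
#' Quantifies how much of the hybrid model's potential growth area the
#' bioclimatic gates remove: valid-cell counts of the positive-growth area,
#' the survival zone and the establishment zone, and the percentage
#' reductions `(1 - zone / growth_area) * 100`. By construction of the
#' model the areas nest (establishment within survival within growth), so
#' the establishment reduction is always at least the survival reduction.
#'
#' @param hybrid A `hybrid_model_output` from [hybrid_model()].
#' @return A one-row tibble with columns `growth_area`, `survival_area`,
#'   `establishment_area`, `survival_reduction_pct`,
#'   `establishment_reduction_pct`.
#' @export
decomposition <- function(hybrid) {
  stopifnot(inherits(hybrid, "hybrid_model_output"))
  g <- hybrid$growth
  growth_area <- sum(g$values[g$mask] > 0)
  if (growth_area == 0) {
    stop("degenerate decomposition: growth area is empty", call. = FALSE)
  }
  sz <- hybrid$survival_zone
  ez <- hybrid$establishment_zone
  survival_area <- sum(sz$values[sz$mask] == 1)
  establishment_area <- sum(ez$values[ez$mask] == 1)
  tibble::tibble(
    growth_area = growth_area,
    survival_area = survival_area,
    establishment_area = establishment_area,
    survival_reduction_pct = (1 - survival_area / growth_area) * 100,
    establishment_reduction_pct = (1 - establishment_area / growth_area) * 100
  )
}

#' Random-pattern kappa null baseline
#'
#' The chance-agreement floor of the multiscale kappa profile: pairs of
#' independent Bernoulli(`p`) binary maps are compared with the kappa CMP,
#' and the profile values are averaged per scale over replicates. Pure
#' random patterns give per-scale mean kappa near zero; the headline
#' summary is the grand mean over scales broader than 2 (default
#' `min_scale_for_mean = 3`), whose magnitude stays at or below about 0.01.
#'
#' @param meta A [grid_meta()] for the random maps (a fully valid grid).
#' @param p Presence probability (default 0.5).
#' @param n_replicates Number of independent map pairs.
#' @param max_scale Largest window radius.
#' @param seed Integer seed; per-replicate map seeds are derived from it.
#' @param min_scale_for_mean Smallest scale entering the grand mean.
#' @param ... Passed to [run_cmp()].
#' @return A `null_baseline` object: list with `replicates` (tibble
#'   `replicate`, `scale`, `value`), `per_scale` (tibble `scale`,
#'   `mean_kappa`, `se`), `grand_mean` (mean over replicates and scales
#'   `>= min_scale_for_mean`), and the generating parameters.
#' @export
null_baseline <- function(meta, p = 0.5, n_replicates = 10, max_scale = 20,
                          seed = 1, min_scale_for_mean = 3, ...) {
  stopifnot(n_replicates >= 1)
  map_seeds <- withr::with_seed(
    as.integer(seed),
    matrix(sample.int(.Machine$integer.max, 2 * n_replicates), ncol = 2)
  )
  reps <- purrr::map_dfr(seq_len(n_replicates), function(i) {
    a <- random_binary_map(meta, p, seed = map_seeds[i, 1])
    b <- random_binary_map(meta, p, seed = map_seeds[i, 2])
    cmp <- run_cmp(a, b, "kappa",
      max_scale = max_scale, keep_monoscale = FALSE, ...
    )
    tibble::tibble(replicate = i, scale = cmp$scales, value = cmp$profile$value)
  })
  per_scale <- reps |>
    dplyr::group_by(.data$scale) |>
    dplyr::summarise(
      mean_kappa = mean(.data$value),
      se = stats::sd(.data$value) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  grand <- mean(reps$value[reps$scale >= min_scale_for_mean])
  structure(
    list(
      replicates = reps, per_scale = per_scale, grand_mean = grand,
      p = p, n_replicates = n_replicates, max_scale = max_scale,
      min_scale_for_mean = min_scale_for_mean, meta = meta
    ),
    class = "null_baseline"
  )
}

#' @export
print.null_baseline <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<null_baseline> %d replicate pairs of Bernoulli(%.2f) maps on %d x %d\n",
      "  mean kappa over scales %d..%d: %.5f\n"
    ),
    x$n_replicates, x$p, x$meta$n_rows, x$meta$n_cols,
    x$min_scale_for_mean, x$max_scale, x$grand_mean
  ))
  invisible(x)
}
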