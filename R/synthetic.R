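#' Default grid for synthetic experiments
#'
#' A 100 x 120 cell grid at 10-arcminute resolution with its north-west
#' corner near (-11E, 72N) — a desk-scale stand-in for a European climate
#' grid, small enough for multiscale comparison up to scale 20.
#'
#' @return A [grid_meta()].
#' @export
default_grid <- function() {
  grid_meta(n_rows = 100, n_cols = 120, cell_size = 1 / 6, origin = c(-11, 72))
}

# separable Gaussian smoothing with edge renormalisation (smooth of ones)
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  smooth1 <- function(x) {
    # x: matrix; smooth along rows (dim 1) via padded convolution
    nr <- nrow(x)
    out <- matrix(0, nr, ncol(x))
    pad <- rbind(matrix(0, r, ncol(x)), x, matrix(0, r, ncol(x)))
    for (j in seq_along(k)) {
      out <- out + k[j] * pad[(j):(j + nr - 1), , drop = FALSE]
    }
    out
  }
  num <- t(smooth1(t(smooth1(m))))
  den <- t(smooth1(t(smooth1(matrix(1, nrow(m), ncol(m))))))
  num / den
}

# smoothed white noise rescaled to unit sd (spatially correlated noise)
correlated_noise <- function(n_rows, n_cols, correlation_length) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  z <- gaussian_smooth(z, correlation_length)
  s <- stats::sd(z)
  if (s > 0) z / s else z
}

#' Generate synthetic climate fields
#'
#' Builds the derived bioclimatic variables the toy species distribution
#' models consume, with the statistical structure of a mid-latitude climate
#' grid: `t_cold` (minimum temperature of the coldest month, degrees C)
#' decreasing from south to north, `gdd5` (growing degree-days above 5
#' degrees C) decreasing towards the north and floored at 0, and a
#' dimensionless `moisture` index in `[0, 1]` decreasing from west to east.
#' Each field is a linear gradient plus spatially correlated noise
#' (Gaussian-smoothed white noise). A configurable fraction of cells is
#' masked as sea in spatially contiguous blobs. Fully deterministic given
#' `seed`.
#'
#' @param meta A [grid_meta()]; row 1 is the northernmost row.
#' @param seed Integer seed (mandatory — generators hold no hidden random
#'   state).
#' @param params Named list overriding any of the defaults in
#'   `climate_params()`: gradient endpoints (`t_cold_south = 8`,
#'   `t_cold_north = -22`, `gdd5_south = 4500`, `gdd5_north = 300`,
#'   `moisture_west = 0.85`, `moisture_east = 0.25`), noise standard
#'   deviations (`t_cold_noise_sd = 2`, `gdd5_noise_sd = 250`,
#'   `moisture_noise_sd = 0.1`), `noise_correlation_length = 5` cells, and
#'   `sea_fraction = 0.25`.
#' @return A `climate_fields` object: list with `meta`, matrices `t_cold`,
#'   `gdd5`, `moisture`, and logical `mask` (TRUE = land).
#' @examples
#' cl <- make_climate(grid_meta(30, 40), seed = 1)
#' range(cl$moisture)
#' @export
make_climate <- function(meta, seed, params = list()) {
  stopifnot(inherits(meta, "grid_meta"), length(seed) == 1)
  p <- utils::modifyList(climate_params(), params)
  nr <- meta$n_rows
  nc <- meta$n_cols
  lat_frac <- matrix((seq_len(nr) - 1) / max(1, nr - 1), nr, nc) # 0 north, 1 south
  lon_frac <- matrix((seq_len(nc) - 1) / max(1, nc - 1), nr, nc, byrow = TRUE)
  withr::with_seed(as.integer(seed), {
    t_cold <- p$t_cold_north + lat_frac * (p$t_cold_south - p$t_cold_north)
    if (p$t_cold_noise_sd > 0) {
      t_cold <- t_cold + p$t_cold_noise_sd *
        correlated_noise(nr, nc, p$noise_correlation_length)
    }
    gdd5 <- p$gdd5_north + lat_frac * (p$gdd5_south - p$gdd5_north)
    if (p$gdd5_noise_sd > 0) {
      gdd5 <- gdd5 + p$gdd5_noise_sd *
        correlated_noise(nr, nc, p$noise_correlation_length)
    }
    gdd5 <- pmax(gdd5, 0)
    moisture <- p$moisture_west + lon_frac * (p$moisture_east - p$moisture_west)
    if (p$moisture_noise_sd > 0) {
      moisture <- moisture + p$moisture_noise_sd *
        correlated_noise(nr, nc, p$noise_correlation_length)
    }
    moisture <- pmin(pmax(moisture, 0), 1)
    mask <- matrix(TRUE, nr, nc)
    if (p$sea_fraction > 0) {
      blob <- correlated_noise(nr, nc, p$noise_correlation_length)
      mask <- blob >= stats::quantile(blob, p$sea_fraction)
    }
  })
  structure(
    list(meta = meta, t_cold = t_cold, gdd5 = gdd5, moisture = moisture, mask = mask),
    class = "climate_fields"
  )
}

#' @rdname make_climate
#' @export
climate_params <- function() {
  list(
    t_cold_south = 8, t_cold_north = -22, t_cold_noise_sd = 2,
    gdd5_south = 4500, gdd5_north = 300, gdd5_noise_sd = 250,
    moisture_west = 0.85, moisture_east = 0.25, moisture_noise_sd = 0.1,
    noise_correlation_length = 5, sea_fraction = 0.25
  )
}

#' Extract one climate field as a score map
#'
#' @param climate A `climate_fields` object from [make_climate()].
#' @param which One of `"t_cold"`, `"gdd5"`, `"moisture"`.
#' @return A [score_map()] carrying the land/sea mask.
#' @export
climate_layer <- function(climate, which = c("t_cold", "gdd5", "moisture")) {
  which <- match.arg(which)
  v <- climate[[which]]
  v[!climate$mask] <- NA_real_
  score_map(climate$meta, v, climate$mask)
}

#' Bioclimatic limits of a toy species
#'
#' The four hard bioclimatic gates used by the hybrid growth model —
#' minimum growing degree-days for establishment, minimum coldest-month
#' temperature for survival and (more restrictive) for establishment,
#' maximum coldest-month temperature for establishment — plus a minimum
#' moisture index used by the envelope model.
#'
#' @param gdd5min_e Minimum GDD5 for establishment (degree-days).
#' @param t_cold_min_s Minimum coldest-month temperature for survival
#'   (degrees C).
#' @param t_cold_min_e Minimum coldest-month temperature for establishment;
#'   must be `>= t_cold_min_s` (establishment is at least as restrictive as
#'   survival).
#' @param t_cold_max_e Maximum coldest-month temperature for establishment;
#'   must exceed `t_cold_min_e`.
#' @param moisture_min Minimum moisture index.
#' @return A `toy_species_limits` object.
#' @export
toy_species_limits <- function(gdd5min_e = 900, t_cold_min_s = -17,
                               t_cold_min_e = -14, t_cold_max_e = 6,
                               moisture_min = 0.3) {
  if (t_cold_min_e < t_cold_min_s) {
    stop("t_cold_min_e must be >= t_cold_min_s (establishment at least as ",
      "restrictive as survival)",
      call. = FALSE
    )
  }
  if (t_cold_max_e <= t_cold_min_e) {
    stop("t_cold_max_e must exceed t_cold_min_e", call. = FALSE)
  }
  structure(
    list(
      gdd5min_e = gdd5min_e, t_cold_min_s = t_cold_min_s,
      t_cold_min_e = t_cold_min_e, t_cold_max_e = t_cold_max_e,
      moisture_min = moisture_min
    ),
    class = "toy_species_limits"
  )
}

# trapezoidal response: 0 at/below the hard limit, linear ramp of `width`
# inside it, 1 in the core; direction = -1 flips it into an upper limit
trapezoid_response <- function(v, limit, width, upper = FALSE) {
  x <- if (upper) limit - v else v - limit
  if (width <= 0) {
    return(as.numeric(x > 0))
  }
  pmin(pmax(x / width, 0), 1)
}

#' Correlative envelope model (toy)
#'
#' A bioclimatic envelope in the style of a correlative species
#' distribution model: each climate variable contributes a trapezoidal
#' response — exactly 0 outside its hard limit (the on-off switch), a
#' linear ramp of the given width inside it, 1 in the core (the graded
#' establishment-success weighting) — and the suitability score is the
#' product of the responses. Any cell failing a hard limit scores exactly
#' 0, so the envelope has a sharply bounded footprint.
#'
#' @param climate A `climate_fields` object.
#' @param limits A [toy_species_limits()].
#' @param ramp_width Named list of ramp widths per variable:
#'   `t_cold` (degrees C, applied to both the lower survival limit and the
#'   upper establishment limit), `gdd5` (degree-days), `moisture` (index
#'   units).
#' @return A [score_map()] of suitability in `[0, 1]`.
#' @export
envelope_model <- function(climate, limits,
                           ramp_width = list(t_cold = 4, gdd5 = 400, moisture = 0.15)) {
  stopifnot(inherits(climate, "climate_fields"), inherits(limits, "toy_species_limits"))
  score <- trapezoid_response(climate$t_cold, limits$t_cold_min_s, ramp_width$t_cold) *
    trapezoid_response(climate$t_cold, limits$t_cold_max_e, ramp_width$t_cold, upper = TRUE) *
    trapezoid_response(climate$gdd5, limits$gdd5min_e, ramp_width$gdd5) *
    trapezoid_response(climate$moisture, limits$moisture_min, ramp_width$moisture)
  score[!climate$mask] <- NA_real_
  score_map(climate$meta, score, climate$mask)
}

#' Hybrid growth model with bioclimatic gates (toy)
#'
#' Mimics the structure of a dynamic vegetation model: a smooth saturating
#' growth index (toy NPP/LAI — a logistic response in heat sum and in
#' moisture, product-combined and rescaled above a small floor so that
#' climates below the floor support no growth at all), gated by hard
#' bioclimatic limits. The survival zone requires positive growth and
#' coldest-month temperature above the survival limit; the establishment
#' zone additionally requires the narrower establishment temperature window
#' and the minimum heat sum. By construction the three areas nest:
#' establishment within survival within positive growth.
#'
#' @inheritParams envelope_model
#' @param growth_params Named list: logistic midpoints and rates
#'   `gdd5_half` (degree-days), `gdd5_rate`, `moisture_half`,
#'   `moisture_rate`, and `floor` (the raw logistic product below which
#'   growth is cut to exactly 0).
#' @param apply_bioclim_limits If `TRUE` (default) the reported LAI proxy is
#'   growth masked to the establishment zone; if `FALSE`, unmasked growth —
#'   the "no bioclimatic constraints" variant used to disentangle the
#'   contribution of the gates from the growth process.
#' @return A `hybrid_model_output`: list with [score_map()]s `lai` and
#'   `growth` and [binary_map()]s `survival_zone`, `establishment_zone`.
#' @seealso [decomposition()]
#' @export
hybrid_model <- function(climate, limits,
                         growth_params = list(
                           gdd5_half = 800, gdd5_rate = 300,
                           moisture_half = 0.3, moisture_rate = 0.08,
                           floor = 0.05
                         ),
                         apply_bioclim_limits = TRUE) {
  stopifnot(inherits(climate, "climate_fields"), inherits(limits, "toy_species_limits"))
  g <- growth_params
  raw <- stats::plogis((climate$gdd5 - g$gdd5_half) / g$gdd5_rate) *
    stats::plogis((climate$moisture - g$moisture_half) / g$moisture_rate)
  growth <- pmax(raw - g$floor, 0) / (1 - g$floor)
  survival <- (growth > 0) & (climate$t_cold >= limits$t_cold_min_s)
  establishment <- survival &
    (climate$t_cold >= limits$t_cold_min_e) &
    (climate$t_cold <= limits$t_cold_max_e) &
    (climate$gdd5 >= limits$gdd5min_e)
  lai <- if (apply_bioclim_limits) growth * establishment else growth
  as_map <- function(v) {
    v[!climate$mask] <- NA_real_
    v
  }
  structure(
    list(
      lai = score_map(climate$meta, as_map(lai), climate$mask),
      growth = score_map(climate$meta, as_map(growth), climate$mask),
      survival_zone = binary_map(climate$meta, as_map(survival * 1), climate$mask),
      establishment_zone = binary_map(climate$meta, as_map(establishment * 1), climate$mask)
    ),
    class = "hybrid_model_output"
  )
}

#' Process-based fitness model (toy)
#'
#' Mimics a process-based model in which a species' performance is the
#' product of its probability of surviving climatic stress (frost and
#' drought, each a logistic response) and its probability of producing
#' viable seeds within the annual cycle (seeds ripen only if enough heat
#' accumulates — a logistic response in the heat sum above a requirement).
#' All components are smooth, so the fitness surface has no hard boundary.
#'
#' @inheritParams envelope_model
#' @param frost Named list `t50` (degrees C at which frost survival is 0.5)
#'   and `scale` (logistic scale, degrees C).
#' @param drought Named list `m50` and `scale` on the moisture index.
#' @param phenology Named list `gdd_requirement` (degree-days needed to
#'   ripen seed) and `scale`.
#' @return A `fitness_model_output`: list of [score_map()]s `fitness`,
#'   `survival_p`, `reproduction_p`, with
#'   `fitness = survival_p * reproduction_p` cell-wise.
#' @export
fitness_model <- function(climate,
                          frost = list(t50 = -15, scale = 3),
                          drought = list(m50 = 0.25, scale = 0.07),
                          phenology = list(gdd_requirement = 900, scale = 250)) {
  stopifnot(inherits(climate, "climate_fields"))
  survival_p <- stats::plogis((climate$t_cold - frost$t50) / frost$scale) *
    stats::plogis((climate$moisture - drought$m50) / drought$scale)
  reproduction_p <- stats::plogis(
    (climate$gdd5 - phenology$gdd_requirement) / phenology$scale
  )
  fitness <- survival_p * reproduction_p
  as_map <- function(v) {
    v[!climate$mask] <- NA_real_
    score_map(climate$meta, v, climate$mask)
  }
  structure(
    list(
      fitness = as_map(fitness),
      survival_p = as_map(survival_p),
      reproduction_p = as_map(reproduction_p)
    ),
    class = "fitness_model_output"
  )
}

#' Derive a noisy observed distribution from a truth map
#'
#' Stands in for an observed species atlas: presence wherever the
#' (standardised) truth score reaches the occupancy threshold, then each
#' valid cell's label is flipped independently with probability
#' `flip_noise` (observation error). Deterministic given `seed`.
#'
#' @param truth_score A standardised [score_map()].
#' @param occupancy_threshold Score at or above which the species truly
#'   occurs.
#' @param flip_noise Per-cell label flip probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A [binary_map()] with the same mask.
#' @export
observed_distribution <- function(truth_score, occupancy_threshold = 0.5,
                                  flip_noise = 0.1, seed = 1) {
  stopifnot(inherits(truth_score, "score_map"))
  if (length(flip_noise) != 1 || is.na(flip_noise) || flip_noise < 0 || flip_noise > 1) {
    stop("`flip_noise` must be a probability in [0, 1]", call. = FALSE)
  }
  v <- truth_score$values
  obs <- v
  idx <- which(truth_score$mask)
  obs[idx] <- as.numeric(v[idx] >= occupancy_threshold)
  withr::with_seed(as.integer(seed), {
    flips <- stats::runif(length(idx)) < flip_noise
  })
  obs[idx[flips]] <- 1 - obs[idx[flips]]
  binary_map(truth_score$meta, obs, truth_score$mask)
}

#' Random binary map (pure random pattern)
#'
#' Independent Bernoulli(`p`) presence at every valid cell — the
#' "pure random pattern" used for the kappa null baseline.
#'
#' @param meta A [grid_meta()].
#' @param p Presence probability in `[0, 1]`.
#' @param seed Integer seed.
#' @param mask Optional logical validity matrix (default: all valid).
#' @return A [binary_map()].
#' @seealso [null_baseline()]
#' @export
random_binary_map <- function(meta, p = 0.5, seed = 1, mask = NULL) {
  stopifnot(inherits(meta, "grid_meta"), p >= 0, p <= 1)
  if (is.null(mask)) mask <- matrix(TRUE, meta$n_rows, meta$n_cols)
  v <- matrix(NA_real_, meta$n_rows, meta$n_cols)
  withr::with_seed(as.integer(seed), {
    v[mask] <- as.numeric(stats::runif(sum(mask)) < p)
  })
  binary_map(meta, v, mask)
}
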