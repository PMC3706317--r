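#' Circular window offsets at a given scale
#'
#' The comparison window at scale `s` is the Euclidean disc of integer
#' offsets `(d_row, d_col)` with `d_row^2 + d_col^2 <= s^2`. Scale 1 spans
#' `(2 * 1 + 1)` cells across, i.e. 0.5 degrees on a 10-arcminute grid;
#' scale 20 spans about 8 degrees.
#'
#' @param scale Window radius in pixels, integer `>= 0`.
#' @return A `window_spec`: list with `scale` and an integer matrix
#'   `offsets` (columns `d_row`, `d_col`), symmetric under negation and
#'   containing `(0, 0)`.
#' @examples
#' nrow(window_offsets(1)$offsets) # 5
#' nrow(window_offsets(2)$offsets) # 13
#' @export
window_offsets <- function(scale) {
  if (length(scale) != 1 || is.na(scale) || scale < 0 || scale != floor(scale)) {
    stop("`scale` must be a single non-negative integer", call. = FALSE)
  }
  structure(
    list(scale = as.integer(scale), offsets = disc_ring(-1L, as.integer(scale))),
    class = "window_spec"
  )
}

# integer offsets with s_lo^2 < d_row^2 + d_col^2 <= s_hi^2 (s_lo = -1 gives
# the full disc including the centre)
disc_ring <- function(s_lo, s_hi) {
  r <- seq(-s_hi, s_hi)
  g <- expand.grid(d_row = r, d_col = r)
  d2 <- g$d_row^2 + g$d_col^2
  lo2 <- if (s_lo < 0) -1 else s_lo^2
  as.matrix(g[d2 > lo2 & d2 <= s_hi^2, , drop = FALSE])
}

#' Physical window span at a scale
#'
#' @param scale Window radius in pixels.
#' @param cell_size Degrees per pixel (default 1/6, i.e. 10 arcminutes).
#' @return Window edge length in degrees, `(2 * scale + 1) * cell_size`.
#' @examples
#' window_span_degrees(1) # 0.5
#' @export
window_span_degrees <- function(scale, cell_size = 1 / 6) {
  (2 * scale + 1) * cell_size
}

# ---- moving-window sum engine ---------------------------------------------

# Accumulates, for each requested scale (ascending), the disc-window sum of
# each plane at every grid cell. Windows are clipped at the border (no
# padding) and invalid cells contribute zero; planes must already be zeroed
# outside the mask. Sums are built incrementally: going from scale s-1 to s
# only the new ring of offsets is added, so the arithmetic is identical to
# summing the full disc directly.
moving_disc_sums <- function(planes, scales) {
  stopifnot(!is.unsorted(scales, strictly = TRUE), min(scales) >= 1)
  nr <- nrow(planes[[1]])
  nc <- ncol(planes[[1]])
  p <- max(scales)
  padded <- lapply(planes, function(m) {
    out <- matrix(0, nr + 2 * p, nc + 2 * p)
    out[(p + 1):(p + nr), (p + 1):(p + nc)] <- m
    out
  })
  acc <- lapply(planes, function(m) matrix(0, nr, nc))
  out <- vector("list", length(scales))
  disc_sizes <- integer(length(scales))
  prev <- -1L
  n_off <- 0L
  for (i in seq_along(scales)) {
    s <- scales[i]
    ring <- disc_ring(prev, s)
    for (k in seq_len(nrow(ring))) {
      ri <- (p + 1 + ring[k, 1]):(p + nr + ring[k, 1])
      ci <- (p + 1 + ring[k, 2]):(p + nc + ring[k, 2])
      for (nm in names(planes)) {
        acc[[nm]] <- acc[[nm]] + padded[[nm]][ri, ci]
      }
    }
    n_off <- n_off + nrow(ring)
    disc_sizes[i] <- n_off
    out[[i]] <- acc
    prev <- s
  }
  list(sums = out, disc_sizes = disc_sizes)
}

# vectorised kappa from window sums of two binary planes
kappa_from_sums <- function(sa, sb, sab, n) {
  tp <- sab
  fp <- sa - sab
  fn <- sb - sab
  tn <- n - sa - sb + sab
  p_o <- (tp + tn) / n
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  k <- (p_o - p_e) / (1 - p_e)
  deg <- is.finite(p_e) & p_e > 1 - 1e-12
  k[deg] <- as.numeric(p_o[deg] > 1 - 1e-12)
  k
}

cmp_planes <- function(a, b, index) {
  mask <- a$mask
  av <- a$values
  bv <- b$values
  av[!mask] <- 0
  bv[!mask] <- 0
  n <- matrix(as.numeric(mask), nrow(av), ncol(av))
  switch(index,
    kappa = list(a = av, b = bv, ab = av * bv, n = n),
    D = list(s = abs(av - bv), n = n),
    CC = list(
      a = av, b = bv, aa = av * av, bb = bv * bv, ab = av * bv, n = n
    )
  )
}

index_from_sums <- function(index, sums) {
  n <- sums$n
  switch(index,
    kappa = kappa_from_sums(sums$a, sums$b, sums$ab, n),
    D = sums$s / n,
    CC = {
      sxx <- sums$aa - sums$a^2 / n
      syy <- sums$bb - sums$b^2 / n
      sxy <- sums$ab - sums$a * sums$b / n
      r <- sxy / sqrt(sxx * syy)
      r[!is.finite(r) | sxx <= 1e-12 * n | syy <= 1e-12 * n] <- NA_real_
      pmin(pmax(r, -1), 1)
    }
  )
}

check_cmp_inputs <- function(a, b, index) {
  if (index == "kappa") {
    stopifnot(inherits(a, "binary_map"), inherits(b, "binary_map"))
  } else {
    stopifnot(inherits(a, "raster_map"), inherits(b, "raster_map"))
  }
  assert_coregistered(a, b)
}

monoscale_index <- function(a, b, index, scale, min_valid_fraction, min_cells) {
  check_cmp_inputs(a, b, index)
  stopifnot(scale >= 1)
  eng <- moving_disc_sums(cmp_planes(a, b, index), scales = scale)
  vals <- index_from_sums(index, eng$sums[[1]])
  quota <- pmax(min_cells, min_valid_fraction * eng$disc_sizes[1])
  defined <- a$mask & eng$sums[[1]]$n >= quota & !is.na(vals)
  vals[!defined] <- NA_real_
  score_map(a$meta, vals, defined)
}

#' Monoscale moving-window comparison maps
#'
#' Compute one index map at a single window scale: at every valid centre
#' cell the index is evaluated over the valid cells of the circular window
#' (clipped at the grid border, invalid cells excluded). Centres whose
#' window holds fewer than `min_cells` valid cells or less than
#' `min_valid_fraction` of the full disc are undefined and masked out.
#'
#' `monoscale_kappa()` takes two [binary_map()]s and computes Cohen's kappa
#' per window (windows where both maps are constant score 1 if identical,
#' else 0). `monoscale_distance()` averages `|a - b|` over the window — maps
#' should be [standardize()]d first so values stay in `[0, 1]`.
#' `monoscale_cc()` computes the Pearson correlation of paired window
#' values; windows with fewer than 3 valid cells or zero variance in either
#' map are undefined.
#'
#' @param a,b Co-registered maps (binary for kappa, continuous for D/CC).
#' @param scale Window radius in pixels, `>= 1`.
#' @param min_valid_fraction Minimum fraction of the full (unclipped) disc
#'   that must be valid for the centre to be defined.
#' @param min_cells Minimum number of valid window cells.
#' @return A [score_map()] whose mask marks the cells where the index is
#'   defined.
#' @name monoscale
NULL

#' @rdname monoscale
#' @export
monoscale_kappa <- function(a, b, scale, min_valid_fraction = 0.5, min_cells = 3) {
  monoscale_index(a, b, "kappa", scale, min_valid_fraction, min_cells)
}

#' @rdname monoscale
#' @export
monoscale_distance <- function(a, b, scale, min_valid_fraction = 0.5, min_cells = 3) {
  monoscale_index(a, b, "D", scale, min_valid_fraction, min_cells)
}

#' @rdname monoscale
#' @export
monoscale_cc <- function(a, b, scale, min_valid_fraction = 0.5, min_cells = 3) {
  monoscale_index(a, b, "CC", scale, min_valid_fraction, min_cells)
}

#' Whole-map (monoscale 0) comparison index
#'
#' The pixel-by-pixel statistic over all valid cells jointly: whole-map
#' Cohen's kappa, mean absolute distance, or whole-map Pearson correlation.
#' This is the `kappa_0` / `D_0` / `CC_0` entry of the reporting tables.
#'
#' @inheritParams monoscale
#' @param index One of `"kappa"`, `"D"`, `"CC"`.
#' @return A single number.
#' @export
global_index <- function(a, b, index = c("kappa", "D", "CC")) {
  index <- match.arg(index)
  check_cmp_inputs(a, b, index)
  av <- a$values[a$mask]
  bv <- b$values[b$mask]
  switch(index,
    kappa = cohen_kappa(confusion(a, b)),
    D = mean(abs(av - bv)),
    CC = {
      if (stats::sd(av) == 0 || stats::sd(bv) == 0) {
        stop("global CC undefined: a map has zero variance over valid cells",
          call. = FALSE
        )
      }
      stats::cor(av, bv)
    }
  )
}

#' Run a full Comparison Map Profile
#'
#' The multiscale comparison of two co-registered maps: monoscale index maps
#' for every window radius `1..max_scale`, the index profile (per-scale mean
#' over defined window centres), the multiscale map (pixel-wise mean of the
#' monoscale maps over the scales where the pixel is defined), and the
#' whole-map monoscale-0 statistic. `profile_mean` — the mean of the profile
#' over all computed scales — is the `Kappa_mean` / `D_mean` / `CC_mean`
#' summary of the reporting tables; monoscale 0 is kept separate because a
#' radius-0 window cannot support kappa or a correlation.
#'
#' @inheritParams monoscale
#' @param index One of `"kappa"` (binary maps), `"D"`, `"CC"` (continuous
#'   maps, standardised for D).
#' @param max_scale Largest window radius (default 20).
#' @param keep_monoscale Keep the per-scale maps in the result (set `FALSE`
#'   to save memory on large grids; the profile and multiscale map are
#'   always kept).
#' @return A `cmp_result` object: list with elements `index`, `scales`,
#'   `global_0`, `profile` (tibble `scale`, `value`, `n_defined`),
#'   `profile_mean`, `monoscale` (list of [score_map()]s or `NULL`),
#'   `multiscale` ([score_map()]), `meta`, `mask`.
#'   Use [tidy()][generics::tidy()], [glance()][generics::glance()] and
#'   [ggplot2::autoplot()] on it.
#' @examples
#' meta <- grid_meta(12, 12)
#' set.seed(7)
#' a <- binary_map(meta, matrix(rbinom(144, 1, 0.5), 12))
#' b <- binary_map(meta, matrix(rbinom(144, 1, 0.5), 12))
#' res <- run_cmp(a, b, "kappa", max_scale = 3)
#' tidy(res)
#' @export
run_cmp <- function(a, b, index = c("kappa", "D", "CC"), max_scale = 20,
                    min_valid_fraction = 0.5, min_cells = 3,
                    keep_monoscale = TRUE) {
  index <- match.arg(index)
  check_cmp_inputs(a, b, index)
  stopifnot(max_scale >= 1)
  scales <- seq_len(max_scale)
  eng <- moving_disc_sums(cmp_planes(a, b, index), scales)
  nr <- a$meta$n_rows
  nc <- a$meta$n_cols
  mono <- if (keep_monoscale) vector("list", length(scales))
  profile_value <- numeric(length(scales))
  n_defined <- integer(length(scales))
  ms_sum <- matrix(0, nr, nc)
  ms_n <- matrix(0L, nr, nc)
  for (i in seq_along(scales)) {
    vals <- index_from_sums(index, eng$sums[[i]])
    quota <- pmax(min_cells, min_valid_fraction * eng$disc_sizes[i])
    defined <- a$mask & eng$sums[[i]]$n >= quota & !is.na(vals)
    vals[!defined] <- NA_real_
    # row-major traversal fixed for reproducible accumulation
    profile_value[i] <- mean(t(vals)[t(defined)])
    n_defined[i] <- sum(defined)
    ms_sum[defined] <- ms_sum[defined] + vals[defined]
    ms_n <- ms_n + defined
    if (keep_monoscale) mono[[i]] <- score_map(a$meta, vals, defined)
  }
  ms_vals <- ms_sum / ms_n
  ms_mask <- ms_n > 0L
  ms_vals[!ms_mask] <- NA_real_
  structure(
    list(
      index = index,
      scales = scales,
      global_0 = global_index(a, b, index),
      profile = tibble::tibble(
        scale = scales, value = profile_value, n_defined = n_defined
      ),
      profile_mean = mean(profile_value),
      monoscale = mono,
      multiscale = score_map(a$meta, ms_vals, ms_mask),
      meta = a$meta,
      mask = a$mask
    ),
    class = "cmp_result"
  )
}

#' @export
print.cmp_result <- function(x, ...) {
  cat(sprintf(
    "<cmp_result: %s>\n  scales 1..%d on %d x %d grid\n  %s_0 = %.4f   %s_mean = %.4f\n",
    x$index, max(x$scales), x$meta$n_rows, x$meta$n_cols,
    x$index, x$global_0, x$index, x$profile_mean
  ))
  invisible(x)
}
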