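# Independent brute-force oracles and small fixture builders. The oracles
# deliberately share no code with the package internals: windows are
# materialised as explicit cell lists and the statistics recomputed from
# first principles.

rand_binary <- function(n_rows, n_cols, p = 0.5, mask = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(mask)) mask <- matrix(TRUE, n_rows, n_cols)
  v <- matrix(NA_real_, n_rows, n_cols)
  v[mask] <- rbinom(sum(mask), 1, p)
  binary_map(grid_meta(n_rows, n_cols), v, mask)
}

rand_score <- function(n_rows, n_cols, mask = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(mask)) mask <- matrix(TRUE, n_rows, n_cols)
  v <- matrix(NA_real_, n_rows, n_cols)
  v[mask] <- runif(sum(mask))
  score_map(grid_meta(n_rows, n_cols), v, mask)
}

rand_mask <- function(n_rows, n_cols, p_valid = 0.85) {
  m <- matrix(runif(n_rows * n_cols) < p_valid, n_rows, n_cols)
  if (!any(m)) m[1, 1] <- TRUE
  m
}

# kappa from an explicitly tabulated 2x2 confusion table
oracle_kappa_cells <- function(x, y) {
  n <- length(x)
  tp <- sum(x == 1 & y == 1)
  fp <- sum(x == 1 & y == 0)
  fn <- sum(x == 0 & y == 1)
  tn <- sum(x == 0 & y == 0)
  p_o <- (tp + tn) / n
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  if (p_e > 1 - 1e-12) {
    return(if (p_o > 1 - 1e-12) 1 else 0)
  }
  (p_o - p_e) / (1 - p_e)
}

# one monoscale map by direct enumeration of every window's cell list
oracle_monoscale <- function(a, b, index, scale,
                             min_valid_fraction = 0.5, min_cells = 3) {
  nr <- a$meta$n_rows
  nc <- a$meta$n_cols
  offs <- expand.grid(dr = -scale:scale, dc = -scale:scale)
  offs <- offs[offs$dr^2 + offs$dc^2 <= scale^2, ]
  disc_size <- nrow(offs)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      if (!a$mask[r, cc]) next
      xs <- numeric(0)
      ys <- numeric(0)
      for (k in seq_len(disc_size)) {
        rr <- r + offs$dr[k]
        ck <- cc + offs$dc[k]
        if (rr < 1 || rr > nr || ck < 1 || ck > nc) next
        if (!a$mask[rr, ck]) next
        xs <- c(xs, a$values[rr, ck])
        ys <- c(ys, b$values[rr, ck])
      }
      n <- length(xs)
      if (n < max(min_cells, min_valid_fraction * disc_size)) next
      out[r, cc] <- switch(index,
        kappa = oracle_kappa_cells(xs, ys),
        D = mean(abs(xs - ys)),
        CC = {
          if (sd(xs) == 0 || sd(ys) == 0) NA_real_ else cor(xs, ys)
        }
      )
    }
  }
  out
}

# Mann-Whitney pair-counting AUC with ties counted 1/2
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# exhaustive-search SPT: max of tpr - fpr over all candidate thresholds
oracle_spt <- function(scores, labels) {
  cands <- sort(unique(scores))
  j <- vapply(cands, function(t) {
    pred <- as.numeric(scores >= t)
    tpr <- sum(pred == 1 & labels == 1) / sum(labels == 1)
    fpr <- sum(pred == 1 & labels == 0) / sum(labels == 0)
    tpr - fpr
  }, numeric(1))
  min(cands[j >= max(j) - 1e-12])
}
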