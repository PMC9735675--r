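# Independent oracles used to cross-check the package implementation.
# They deliberately share no code with the package internals.

# OLS via the normal equations
oracle_ols <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# empirical quantile by sorting and linear interpolation between order
# statistics at h = (n - 1) p + 1
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

# separation criterion recomputed pairwise from raw draws
# draws: compounds x conditions x draws array; point: compounds x conditions
oracle_separation <- function(draws, point, hw_left, hw_right, p = 0.10) {
  n_cond <- ncol(point)
  out <- numeric(n_cond)
  for (j in seq_len(n_cond)) {
    ord <- order(point[, j], decreasing = TRUE)
    q <- numeric(length(ord) - 1)
    for (k in seq_len(length(ord) - 1)) {
      a <- ord[k]; b <- ord[k + 1]
      q[k] <- oracle_quantile(
        draws[a, j, ] - draws[b, j, ] - hw_left[a] - hw_right[b], p)
    }
    out[j] <- min(q)
  }
  out
}

# analysis-time criterion recomputed per condition
oracle_analysis_time <- function(draws, p = 0.90) {
  n_cond <- dim(draws)[2]
  vapply(seq_len(n_cond), function(j) {
    max(vapply(seq_len(dim(draws)[1]),
               function(i) oracle_quantile(draws[i, j, ], p), numeric(1)))
  }, numeric(1))
}

# finite-difference derivative magnitudes, stencil by stencil
oracle_sensitivity <- function(S) {
  np <- nrow(S); nt <- ncol(S)
  hp <- 2 / (np - 1); ht <- 2 / (nt - 1)
  R <- matrix(NA_real_, np, nt)
  for (i in seq_len(np)) {
    for (j in seq_len(nt)) {
      dp <- if (i == 1) (S[2, j] - S[1, j]) / hp
            else if (i == np) (S[np, j] - S[np - 1, j]) / hp
            else (S[i + 1, j] - S[i - 1, j]) / (2 * hp)
      dt <- if (j == 1) (S[i, 2] - S[i, 1]) / ht
            else if (j == nt) (S[i, nt] - S[i, nt - 1]) / ht
            else (S[i, j + 1] - S[i, j - 1]) / (2 * ht)
      R[i, j] <- (abs(dp) + abs(dt)) / 2
    }
  }
  R
}

# recursive flood fill over a logical mask
oracle_flood_fill <- function(mask, connectivity = 8) {
  labels <- matrix(0L, nrow(mask), ncol(mask))
  nbrs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    lapply(seq_len(8), function(k) {
      o <- expand.grid(dr = -1:1, dc = -1:1)
      o <- o[!(o$dr == 0 & o$dc == 0), ]
      c(o$dr[k], o$dc[k])
    })
  }
  lab <- 0L
  for (start in which(mask & labels == 0)) {
    lab <- lab + 1L
    stack <- start
    while (length(stack)) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (labels[cur] != 0L) next
      labels[cur] <- lab
      r <- (cur - 1L) %% nrow(mask) + 1L
      cc <- (cur - 1L) %/% nrow(mask) + 1L
      for (o in nbrs) {
        rr <- r + o[1]; ccc <- cc + o[2]
        if (rr >= 1 && rr <= nrow(mask) && ccc >= 1 && ccc <= ncol(mask) &&
            mask[rr, ccc] && labels[rr, ccc] == 0L)
          stack <- c(stack, (ccc - 1L) * nrow(mask) + rr)
      }
    }
  }
  labels
}

# component cell-sets as canonical strings, for label-invariant comparison
component_signature <- function(labels) {
  ids <- setdiff(unique(as.vector(labels)), 0L)
  sort(vapply(ids, function(id)
    paste(sort(which(labels == id)), collapse = ","), character(1)))
}

# brute-force desirability index, one weight draw at a time
oracle_probability <- function(d_mat, weight_draws, threshold) {
  n_cond <- nrow(d_mat)
  count <- numeric(n_cond)
  for (w_i in seq_len(nrow(weight_draws))) {
    w <- weight_draws[w_i, ]
    for (j in seq_len(n_cond)) {
      D <- prod(d_mat[j, ]^w)
      if (D >= threshold) count[j] <- count[j] + 1
    }
  }
  count / nrow(weight_draws)
}

# small random full-rank retention design for a given case
random_design <- function(case, n_extra = 4, seed = 1) {
  set.seed(seed)
  ph <- switch(case,
    NO_PH = runif(6, 2.7, 8),
    ONE_PLATEAU = rep(sample(seq(2.7, 8, by = 0.5), 5), 2),
    TWO_PLATEAU = rep(sample(seq(2.7, 8, by = 0.5), 5), 2))
  tg <- switch(case,
    NO_PH = rep(c(20, 60), 3),
    rep(c(20, 60), each = 5))
  n <- length(ph)
  data.frame(ph = ph, gradient_time_min = tg,
             retention_time_min = exp(runif(n, 1.5, 3.2)))
}
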