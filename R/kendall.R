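#' Kendall rank correlation (tau-b) with significance
#'
#' Tie-corrected Kendall tau-b between two aligned series, the statistic
#' behind the predator-prey screen. Community count series contain many
#' tied zeros, so the tie-corrected (tau-b) form is used throughout:
#' \deqn{\tau_b = (C - D) / \sqrt{(n_0 - n_1)(n_0 - n_2)}}
#' with C/D the concordant/discordant pair counts and n1, n2 the tied pairs
#' within each series. The two-sided p-value comes from the tie-corrected
#' normal approximation of C - D for n >= 9, and from exact enumeration of
#' the pair statistic over all n! pairings for n < 9 (valid under ties).
#'
#' @param x,y numeric series of equal length (n >= 3), aligned by sample.
#' @return one-row tibble with `tau`, `p_value`, `n`, `method`. A series
#'   with zero variance (all values tied) yields `tau = NA` — an undefined
#'   correlation, which can never become an edge.
#' @examples
#' kendall_tau(c(1, 2, 3, 4), c(2, 1, 4, 3))  # tau = 1/3
#' @export
kendall_tau <- function(x, y) {
  n <- length(x)
  if (length(y) != n) abort("series must have equal length")
  if (n < 3) abort("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) abort("missing values are not supported")
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  sx <- dx[up]
  sy <- dy[up]
  den <- sqrt(sum(sx^2)) * sqrt(sum(sy^2))
  if (den == 0) {
    return(tibble(tau = NA_real_, p_value = NA_real_, n = n, method = "undefined"))
  }
  num <- sum(sx * sy)  # C - D
  tau <- num / den
  if (n < 9) {
    perms <- all_permutations(n)
    tobs <- abs(num)
    tperm <- apply(perms, 1, function(p) sum(dx[up] * sign(outer(y[p], y[p], "-"))[up]))
    p <- mean(abs(tperm) >= tobs - 1e-12)
    method <- "exact"
  } else {
    p <- kendall_p_normal(num, x, y)
    method <- "normal"
  }
  tibble(tau = tau, p_value = p, n = n, method = method)
}

# tie-corrected normal approximation for the null distribution of C - D
kendall_p_normal <- function(num, x, y) {
  n <- length(x)
  tt <- tie_terms(x)
  uu <- tie_terms(y)
  v0 <- n * (n - 1) * (2 * n + 5)
  v <- (v0 - tt$v - uu$v) / 18 +
    tt$t2 * uu$t2 / (2 * n * (n - 1)) +
    tt$t3 * uu$t3 / (9 * n * (n - 1) * (n - 2))
  if (v <= 0) return(NA_real_)
  z <- num / sqrt(v)
  min(1, 2 * pnorm(-abs(z)))
}

# per-series tie aggregates: v = sum t(t-1)(2t+5), t2 = sum t(t-1),
# t3 = sum t(t-1)(t-2)
tie_terms <- function(x) {
  t <- as.numeric(table(x))
  t <- t[t > 1]
  list(v = sum(t * (t - 1) * (2 * t + 5)),
       t2 = sum(t * (t - 1)),
       t3 = sum(t * (t - 1) * (t - 2)))
}

#' All-pairs Kendall screen between two series matrices
#'
#' Vectorized tau-b and p-values for every (column of `X`) x (column of `Y`)
#' pair. Each series is reduced to its pairwise sign pattern over the
#' n(n-1)/2 sample pairs; C - D for a pair of series is then the inner
#' product of the two patterns and tau-b their cosine similarity, so the
#' whole screen is one matrix product. Agrees exactly with [kendall_tau()]
#' column by column (the same normal approximation is used for n >= 9; for
#' 3 <= n < 9 the screen falls back to per-pair exact enumeration).
#'
#' @param X,Y numeric matrices with samples in rows (aligned) and series in
#'   columns.
#' @return list with matrices `tau` and `p` (rows = columns of `X`,
#'   columns = columns of `Y`); undefined pairs are `NA`.
#' @export
kendall_screen <- function(X, Y) {
  n <- nrow(X)
  if (nrow(Y) != n) abort("X and Y must have the same samples")
  if (n < 3) abort("need at least 3 paired observations")
  pr <- which(upper.tri(diag(n)), arr.ind = TRUE)
  sx <- sign(X[pr[, 1], , drop = FALSE] - X[pr[, 2], , drop = FALSE])
  sy <- sign(Y[pr[, 1], , drop = FALSE] - Y[pr[, 2], , drop = FALSE])
  num <- crossprod(sx, sy)                      # C - D for every pair
  dx <- colSums(sx^2)                           # n0 - n1 per X series
  dy <- colSums(sy^2)                           # n0 - n2 per Y series
  den <- sqrt(outer(dx, dy))
  tau <- ifelse(den > 0, num / den, NA_real_)
  if (n >= 9) {
    tx <- apply(X, 2, function(v) unlist(tie_terms(v)))
    ty <- apply(Y, 2, function(v) unlist(tie_terms(v)))
    v0 <- n * (n - 1) * (2 * n + 5)
    v <- (v0 - outer(tx["v", ], ty["v", ], "+")) / 18 +
      outer(tx["t2", ], ty["t2", ]) / (2 * n * (n - 1)) +
      outer(tx["t3", ], ty["t3", ]) / (9 * n * (n - 1) * (n - 2))
    p <- ifelse(v > 0, 2 * pnorm(-abs(num) / sqrt(pmax(v, 0))), NA_real_)
    p <- pmin(p, 1)
  } else {
    p <- matrix(NA_real_, nrow(tau), ncol(tau))
    for (i in seq_len(ncol(X))) {
      for (j in seq_len(ncol(Y))) {
        p[i, j] <- kendall_tau(X[, i], Y[, j])$p_value
      }
    }
  }
  p[is.na(tau)] <- NA_real_
  dimnames(tau) <- dimnames(p) <- list(colnames(X), colnames(Y))
  list(tau = tau, p = p)
}
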