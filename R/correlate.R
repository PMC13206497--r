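# Rank-correlation machinery shared by the co-occurrence and taxon-volatile
# networks. Spearman's rho is computed as the Pearson correlation of midranks
# (ties receive average ranks). Two-sided p-values are exact by full
# enumeration of the n! permutations for n <= exact_n (default 9), and use
# the t approximation with n - 2 degrees of freedom otherwise.

.perm_cache <- new.env(parent = emptyenv())

# All permutations of 1:n as an n! x n integer matrix, memoised per session.
# Built by inserting n into every position of each permutation of 1:(n-1).
permutation_matrix <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  if (n == 1L) {
    out <- matrix(1L, 1L, 1L)
  } else {
    p <- permutation_matrix(n - 1L)
    m <- nrow(p)
    out <- matrix(0L, m * n, n)
    for (i in seq_len(n)) {
      rows <- ((i - 1L) * m + 1L):(i * m)
      out[rows, i] <- n
      out[rows, setdiff(seq_len(n), i)] <- p
    }
  }
  .perm_cache[[key]] <- out
  out
}

midrank <- function(x) rank(x, ties.method = "average")

t_approx_p <- function(rho, n) {
  # two-sided; |rho| = 1 gives t = Inf hence p = 0
  t_stat <- abs(rho) * sqrt((n - 2) / pmax(1 - rho^2, 0))
  2 * pt(t_stat, df = n - 2, lower.tail = FALSE)
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Computes Spearman's rho as the Pearson correlation of midranks. The
#' two-sided p-value is exact — the proportion of all `n!` permutations of one
#' vector whose |rho| reaches the observed |rho| — for `n <= exact_n`, and
#' uses the t approximation with `n - 2` degrees of freedom for larger `n`.
#' A constant input yields `rho = NA` and `p = NA` (undefined, to be excluded
#' from networks) rather than an error.
#'
#' @param x,y Equal-length numeric vectors, `n >= 4`, finite values.
#' @param exact_n Largest n for which the exact permutation p-value is used.
#' @return A one-row tibble with columns `rho`, `p`, `n`, `method`.
#' @export
#' @examples
#' spearman(1:6, c(2, 1, 4, 3, 6, 5))
spearman <- function(x, y, exact_n = 9L) {
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have equal length.")
  if (n < 4) abort("need at least 4 paired observations.")
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("inputs must be finite.")
  rx <- midrank(x); ry <- midrank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(tibble(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  rho <- cor(rx, ry)
  if (n <= exact_n) {
    p <- spearman_exact_p(rx, ry, rho)
    method <- "exact"
  } else {
    p <- t_approx_p(rho, n)
    method <- "t-approx"
  }
  tibble(rho = rho, p = p, n = n, method = method)
}

spearman_exact_p <- function(rx, ry, rho_obs) {
  n <- length(rx)
  perms <- permutation_matrix(n)
  rxc <- (rx - mean(rx))
  ryc <- (ry - mean(ry))
  denom <- sqrt(sum(rxc^2) * sum(ryc^2))
  # rho for every permutation of ry against fixed rx
  rho_all <- as.vector(matrix(ryc[perms], nrow(perms), n) %*% rxc) / denom
  mean(abs(rho_all) >= abs(rho_obs) - 1e-12)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment, returned in input order. NA
#' entries (e.g. correlations undefined for constant vectors) propagate as NA.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(pvalues, method = "BH")
}

# All pairwise Spearman tests within the columns of `x` (samples x variables),
# or between columns of `x` and `y` when `y` is given. Returns a tibble
# (item_a, item_b, rho, p) with constant variables reported as NA and a
# warning. q-values are NOT added here: the caller owns the test family.
correlate_pairs <- function(x, y = NULL, exact_n = 9L) {
  n <- nrow(x)
  rx <- apply(x, 2, midrank)
  const_x <- apply(rx, 2, sd) == 0
  if (any(const_x)) {
    warn(sprintf("constant variable(s) excluded from correlation testing: %s",
                 paste(colnames(x)[const_x], collapse = ", ")))
  }
  if (is.null(y)) {
    rho_m <- suppressWarnings(cor(rx))
    rho_m[const_x, ] <- NA_real_
    rho_m[, const_x] <- NA_real_
    idx <- which(upper.tri(rho_m), arr.ind = TRUE)
    out <- tibble(
      item_a = colnames(x)[idx[, 1]],
      item_b = colnames(x)[idx[, 2]],
      rho = rho_m[idx]
    )
    pair_cols <- list(a = idx[, 1], b = idx[, 2])
    ry <- rx
  } else {
    if (nrow(y) != n) abort("`x` and `y` must have the same number of rows.")
    ry <- apply(y, 2, midrank)
    const_y <- apply(ry, 2, sd) == 0
    if (any(const_y)) {
      warn(sprintf("constant variable(s) excluded from correlation testing: %s",
                   paste(colnames(y)[const_y], collapse = ", ")))
    }
    rho_m <- suppressWarnings(cor(rx, ry))
    rho_m[const_x, ] <- NA_real_
    rho_m[, const_y] <- NA_real_
    idx <- as.matrix(expand.grid(a = seq_len(ncol(x)), b = seq_len(ncol(y))))
    out <- tibble(
      item_a = colnames(x)[idx[, 1]],
      item_b = colnames(y)[idx[, 2]],
      rho = rho_m[idx]
    )
    pair_cols <- list(a = idx[, 1], b = idx[, 2])
  }
  if (n <= exact_n) {
    ys <- if (is.null(y)) rx else ry
    out$p <- vapply(seq_len(nrow(out)), function(k) {
      if (is.na(out$rho[k])) return(NA_real_)
      spearman_exact_p(rx[, pair_cols$a[k]], ys[, pair_cols$b[k]], out$rho[k])
    }, numeric(1))
  } else {
    out$p <- t_approx_p(out$rho, n)
  }
  out
}
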