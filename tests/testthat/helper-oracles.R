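# Independent oracles, written from the definitions rather than the package's
# code paths, plus small fixture builders used across test files.

# all permutations of 1:n as a list, by plain recursion
oracle_permutations <- function(n) {
  if (n == 1) return(list(1L))
  smaller <- oracle_permutations(n - 1L)
  out <- list()
  for (p in smaller) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# Spearman rho as cor() on average ranks; exact two-sided p by exhaustive
# enumeration of permutations of y
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  perms <- oracle_permutations(length(y))
  rhos <- vapply(perms, function(p) cor(rx, ry[p]), numeric(1))
  list(rho = rho, p = mean(abs(rhos) >= abs(rho) - 1e-12))
}

# Benjamini-Hochberg step-up evaluated literally from its definition:
# q_(i) = min_{j >= i} m * p_(j) / j, capped at 1, in input order
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[ord][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# minimum total within-segment SS over all contiguous k-splits, by
# enumeration of boundary placements
oracle_segment_cost <- function(y, k) {
  y <- as.matrix(y)
  n <- nrow(y)
  ss <- function(rows) {
    sum(apply(y[rows, , drop = FALSE], 2, function(v) sum((v - mean(v))^2)))
  }
  best <- Inf
  splits <- utils::combn(n - 1, k - 1)
  for (col in seq_len(ncol(splits))) {
    ends <- c(splits[, col], n)
    starts <- c(1, utils::head(ends, -1) + 1)
    cost <- sum(mapply(function(a, b) ss(a:b), starts, ends))
    best <- min(best, cost)
  }
  best
}

# small abundance table with simple metadata
make_abund <- function(values, days = NULL, normalized = FALSE,
                       level = "species") {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("taxon_%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  if (is.null(days)) days <- seq_len(ncol(values)) - 1
  meta <- tibble::tibble(sample_id = colnames(values), day = days,
                         replicate = 1L, group = "test")
  abundance_table(values, meta, level = level, normalized = normalized)
}

make_volatiles <- function(values, classes = NULL, days = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("vol_%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  }
  if (is.null(classes)) {
    classes <- rep(volatile_classes(), length.out = nrow(values))
  }
  if (is.null(days)) days <- seq_len(ncol(values)) - 1
  compounds <- tibble::tibble(compound = rownames(values), class = classes)
  meta <- tibble::tibble(sample_id = colnames(values), day = days,
                         replicate = 1L, group = "test")
  volatile_table(values, compounds, meta)
}
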