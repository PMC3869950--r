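# Naive loop-based re-implementations used as independent oracles.
# Deliberately slow and literal: no vectorized ranking, no log-space tricks.

# Ratio matrix for submatrix z = [A columns | B columns], na columns of A.
naive_ratio <- function(z, na) {
  n <- ncol(z); nb <- n - na
  y <- matrix(NA_real_, nrow(z), na * nb)
  m <- 0L
  for (ai in seq_len(na)) for (bi in (na + 1L):n) {
    m <- m + 1L
    y[, m] <- z[, bi] - z[, ai]
  }
  y
}

# Average-tie rank of each element of v; direction "up" = largest first.
naive_rank_col <- function(v, direction) {
  vapply(seq_along(v), function(i) {
    if (direction == "up") sum(v > v[i]) + (sum(v == v[i]) + 1) / 2
    else sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
  }, numeric(1))
}

naive_rp <- function(y, direction) {
  r <- vapply(seq_len(ncol(y)),
              function(m) naive_rank_col(y[, m], direction),
              numeric(nrow(y)))
  r <- matrix(r, nrow(y), ncol(y))
  apply(r, 1L, function(ri) prod(ri)^(1 / length(ri)))
}

# Empirical p from explicit permutation index matrices (p x n each):
# zp[i, j] = z[i, P[i, j]].
naive_perm_p <- function(z, na, direction, perms) {
  obs <- naive_rp(naive_ratio(z, na), direction)
  k <- numeric(nrow(z))
  for (P in perms) {
    zp <- z
    for (i in seq_len(nrow(z))) zp[i, ] <- z[i, P[i, ]]
    star <- naive_rp(naive_ratio(zp, na), direction)
    # same tie tolerance as the package: equal rank multisets tie exactly
    k <- k + (star <= obs * (1 + 1e-9))
  }
  k / length(perms)
}

# Deterministic permutation schedule shared between package and oracle.
draw_perms <- function(p, n, n_perm, seed) {
  withr::with_seed(seed, replicate(n_perm, rpmeta:::perm_indices(p, n),
                                   simplify = FALSE))
}

# Small labelled expression matrix + design for pair tests.
toy_dataset <- function(p, na, nb, seed = 1, integer_valued = FALSE) {
  withr::with_seed(seed, {
    vals <- if (integer_valued) sample(0:6, p * (na + nb), replace = TRUE)
            else rnorm(p * (na + nb), 6, 1)
    x <- matrix(vals, p, na + nb,
                dimnames = list(sprintf("g%02d", seq_len(p)),
                                c(sprintf("a%d", seq_len(na)),
                                  sprintf("b%d", seq_len(nb)))))
    design <- group_design(colnames(x), c(rep("N", na), rep("L", nb)))
    list(x = x, design = design)
  })
}

# Stub meta_test with chosen p-values, for pattern-module tests.
stub_test <- function(probe_id, p_up, p_down, pair, alpha = 0.001) {
  tab <- data.frame(probe_id = probe_id, rp_up = NA_real_, p_up = p_up,
                    rp_down = NA_real_, p_down = p_down,
                    de_up = p_up < alpha, de_down = p_down < alpha,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, pair = pair,
                 alt_up = paste0(pair[1], "<", pair[2]),
                 alt_down = paste0(pair[1], ">", pair[2]),
                 alpha = alpha, n_perm = NA_integer_, seed = NULL),
            class = "meta_test")
}
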