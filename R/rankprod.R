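#' Pairwise cross-group log ratios
#'
#' Builds the ratio matrix underlying the rank-product statistic: one column
#' per ordered cross-group sample pair, holding the difference of log-scale
#' expression values. For an ordered pair of groups `(A, B)` with sizes
#' `n_A` and `n_B` the result has `M = n_A * n_B` columns; entry
#' `Y[i, m]` is `X[i, b] - X[i, a]` (second-listed group minus first) where
#' `m` runs over pairs with the outer loop over A's samples in matrix order
#' and the inner loop over B's.
#'
#' @param x Numeric matrix of log-scale intensities, probes in rows (unique
#'   rownames), samples in columns (unique colnames matching the design).
#' @param design A group design as returned by [group_design()]: a data frame
#'   with columns `sample_id`, `group` (and optionally `study`).
#' @param pair Character vector of two group labels, e.g. `c("N", "L")`.
#' @return Numeric matrix with `nrow(x)` rows and `n_A * n_B` columns; column
#'   names are `"<a>|<b>"` for the contributing sample ids. Attribute `pair`
#'   records the ordered group pair.
#' @seealso [rank_within_comparisons()], [rank_product()]
#' @export
pairwise_log_ratios <- function(x, design, pair) {
  stopifnot(is.matrix(x), is.numeric(x))
  design <- validate_design(design, x)
  if (length(pair) != 2L || anyDuplicated(pair))
    stop("'pair' must be two distinct group labels", call. = FALSE)
  a_ids <- design$sample_id[design$group == pair[1L]]
  b_ids <- design$sample_id[design$group == pair[2L]]
  if (length(a_ids) == 0L || length(b_ids) == 0L)
    stop("empty group in pair: ", pair[if (length(a_ids) == 0L) 1L else 2L],
         call. = FALSE)
  # keep matrix column order within each group
  a_ids <- colnames(x)[colnames(x) %in% a_ids]
  b_ids <- colnames(x)[colnames(x) %in% b_ids]
  na <- length(a_ids); nb <- length(b_ids)
  ai <- rep(seq_len(na), each = nb)
  bi <- rep(seq_len(nb), times = na)
  y <- x[, b_ids[bi], drop = FALSE] - x[, a_ids[ai], drop = FALSE]
  dimnames(y) <- list(rownames(x), paste(a_ids[ai], b_ids[bi], sep = "|"))
  attr(y, "pair") <- pair
  y
}

#' Rank probes within each comparison column
#'
#' Ranks the probes of each column of a ratio matrix independently. For
#' `direction = "up"` rank 1 goes to the largest value (strongest
#' up-regulation of the second group over the first); for `"down"` rank 1
#' goes to the smallest. Ties receive the average rank, which makes the up
#' and down rankings complementary: `r_up + r_down == p + 1` elementwise.
#'
#' @param y Ratio matrix from [pairwise_log_ratios()] (probes x comparisons).
#' @param direction `"up"` or `"down"`.
#' @return Matrix of ranks with the same dimensions as `y`.
#' @export
rank_within_comparisons <- function(y, direction = c("up", "down")) {
  direction <- match.arg(direction)
  y <- as.matrix(y)
  r <- col_ranks_desc(y)
  if (direction == "down") r <- nrow(y) + 1 - r
  dimnames(r) <- dimnames(y)
  r
}

# Descending average-tie ranks of every column at once. A single order() over
# (column, -value) gives the sort permutation; ties are averaged by run.
col_ranks_desc <- function(y) {
  p <- nrow(y); m <- ncol(y)
  if (p == 0L || m == 0L) return(y)
  o <- order(rep(seq_len(m), each = p), -as.vector(y))
  ys <- as.vector(y)[o]
  n <- length(ys)
  # runs of equal values within a column get the average of their
  # consecutive ranks: first rank of the run + (run length - 1) / 2
  new_run <- c(TRUE, ys[-1L] != ys[-n] | (seq_len(n - 1L) %% p) == 0L)
  run_id <- cumsum(new_run)
  first_pos <- which(new_run)
  run_len <- diff(c(first_pos, n + 1L))
  sorted_rank <- rep.int(seq_len(p), m)
  r <- numeric(n)
  r[o] <- sorted_rank[first_pos][run_id] + (run_len[run_id] - 1) / 2
  matrix(r, p, m)
}

#' Rank-product statistic
#'
#' The rank product of a probe is the geometric mean of its ranks across all
#' comparisons, `RP_i = (prod_m R[i, m])^(1/M)`, computed in log space to
#' avoid overflow. It lies in `[1, p]`; small values indicate consistent
#' strong regulation across comparisons.
#'
#' @param r Rank matrix from [rank_within_comparisons()].
#' @return Named numeric vector of rank products, one per probe.
#' @export
rank_product <- function(r) {
  r <- as.matrix(r)
  if (any(r < 1)) stop("ranks must be >= 1", call. = FALSE)
  stats::setNames(exp(rowMeans(log(r))), rownames(r))
}

# One round of row-wise permutation indices: P[i, ] is a random permutation
# of 1..n, drawn by sorting one uniform key per cell. Consumes p*n uniforms
# from the current RNG stream.
perm_indices <- function(p, n) {
  key <- stats::runif(p * n)
  o <- order(rep(seq_len(p), times = n), key)
  matrix(((o - rep(seq_len(p), each = n)) %/% p) + 1L, p, n, byrow = TRUE)
}

# Observed (or permuted) rank products in both directions for the submatrix
# pair (za: p x nA, zb: p x nB). Returns list(up=, down=).
rp_both <- function(za, zb) {
  na <- ncol(za); nb <- ncol(zb)
  ai <- rep(seq_len(na), each = nb)
  bi <- rep(seq_len(nb), times = na)
  y <- zb[, bi, drop = FALSE] - za[, ai, drop = FALSE]
  ru <- col_ranks_desc(y)
  p1 <- nrow(y) + 1
  list(up = exp(rowMeans(log(ru))), down = exp(rowMeans(log(p1 - ru))))
}

# Shared engine: observed RP in both directions plus permutation counts
# k[i] = #{rounds : RP*_i <= RP_i}. 'perms' may supply precomputed index
# matrices (p x n integer, row-wise permutations) to bypass the RNG.
rp_perm_engine <- function(x, design, pair, n_perm, seed = NULL,
                           scheme = c("per_probe", "sample_label"),
                           null = c("per_probe", "pooled"),
                           perms = NULL) {
  scheme <- match.arg(scheme)
  null <- match.arg(null)
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  design <- validate_design(design, x)
  a_ids <- colnames(x)[colnames(x) %in% design$sample_id[design$group == pair[1L]]]
  b_ids <- colnames(x)[colnames(x) %in% design$sample_id[design$group == pair[2L]]]
  if (length(a_ids) == 0L || length(b_ids) == 0L)
    stop("empty group in pair", call. = FALSE)
  z <- x[, c(a_ids, b_ids), drop = FALSE]
  p <- nrow(z); n <- ncol(z); na <- length(a_ids)
  obs <- rp_both(z[, seq_len(na), drop = FALSE],
                 z[, na + seq_len(n - na), drop = FALSE])

  one_pass <- function() {
    k_up <- numeric(p); k_dn <- numeric(p)
    pooled_up <- if (null == "pooled") sort(obs$up) else NULL
    pooled_dn <- if (null == "pooled") sort(obs$down) else NULL
    tot_up <- numeric(p); tot_dn <- numeric(p)
    for (r in seq_len(n_perm)) {
      pm <- if (!is.null(perms)) perms[[r]]
            else if (scheme == "sample_label")
              matrix(sample.int(n), p, n, byrow = TRUE)
            else perm_indices(p, n)
      zp <- matrix(z[as.vector(seq_len(p) + (pm - 1L) * p)], p, n)
      star <- rp_both(zp[, seq_len(na), drop = FALSE],
                      zp[, na + seq_len(n - na), drop = FALSE])
      # ties count as successes; the relative tolerance makes rank products
      # from equal rank multisets compare equal despite log-space rounding
      if (null == "per_probe") {
        k_up <- k_up + (star$up <= obs$up * (1 + 1e-9))
        k_dn <- k_dn + (star$down <= obs$down * (1 + 1e-9))
      } else {
        tot_up <- tot_up + findInterval(obs$up * (1 + 1e-9), sort(star$up))
        tot_dn <- tot_dn + findInterval(obs$down * (1 + 1e-9),
                                        sort(star$down))
      }
    }
    if (null == "per_probe") list(k_up = k_up, k_dn = k_dn, denom = n_perm)
    else list(k_up = tot_up, k_dn = tot_dn, denom = n_perm * p)
  }
  counts <- if (is.null(seed) || !is.null(perms)) one_pass()
            else withr::with_seed(seed, one_pass())
  list(rp_up = stats::setNames(obs$up, rownames(z)),
       rp_down = stats::setNames(obs$down, rownames(z)),
       k_up = counts$k_up, k_dn = counts$k_dn, denom = counts$denom)
}

#' Permutation-based empirical p-values for the rank product
#'
#' Generates the permutation null of the rank-product statistic and returns
#' empirical p-values. In each of `n_perm` rounds every probe's values across
#' the two groups' samples are independently permuted (the default
#' `scheme = "per_probe"`), the permuted statistic `RP*` is recomputed, and
#' `p_i = (1/n_perm) * sum I(RP*_i <= RP_i)`; ties count as successes, so
#' consistently strong regulation (small `RP`) yields p near 0.
#'
#' @inheritParams pairwise_log_ratios
#' @param direction `"up"` (alternative `A<B`) or `"down"` (`A>B`).
#' @param n_perm Number of permutation rounds (the study default is 5000).
#' @param seed Integer seed; the permutation stream is scoped so the caller's
#'   RNG state is untouched.
#' @param scheme `"per_probe"` permutes each probe independently;
#'   `"sample_label"` permutes whole columns (one relabeling per round).
#' @param null `"per_probe"` compares each probe against its own null;
#'   `"pooled"` against the null statistics of all probes.
#' @param plus_one If `TRUE`, use the `(k+1)/(n_perm+1)` small-sample
#'   correction instead of `k/n_perm`.
#' @param perms Optional list of `n_perm` precomputed `p x n` integer index
#'   matrices (row-wise permutations), mainly for oracle testing.
#' @return Named numeric vector of empirical p-values (resolution
#'   `1/n_perm`), with attribute `rp` holding the observed rank products.
#' @export
permutation_null <- function(x, design, pair, direction = c("up", "down"),
                             n_perm = 5000L, seed = NULL,
                             scheme = c("per_probe", "sample_label"),
                             null = c("per_probe", "pooled"),
                             plus_one = FALSE, perms = NULL) {
  direction <- match.arg(direction)
  eng <- rp_perm_engine(x, design, pair, n_perm = n_perm, seed = seed,
                        scheme = scheme, null = null, perms = perms)
  k <- if (direction == "up") eng$k_up else eng$k_dn
  pv <- if (plus_one) (k + 1) / (eng$denom + 1) else k / eng$denom
  pv <- stats::setNames(pv, names(eng$rp_up))
  attr(pv, "rp") <- if (direction == "up") eng$rp_up else eng$rp_down
  pv
}

#' Run one pairwise rank-product meta-test in both directions
#'
#' Computes the rank product and permutation p-value for both one-sided
#' alternatives of a group pair (`A<B` and `A>B`) using a shared permutation
#' schedule, and flags differentially expressed probes at strict `p < alpha`.
#'
#' @inheritParams permutation_null
#' @param alpha Significance level for the DE call (study default 0.001).
#' @return An object of class `meta_test`: a list with `table` (data frame of
#'   per-probe `rp_up`, `p_up`, `rp_down`, `p_down`, `de_up`, `de_down`),
#'   the alternative labels (`alt_up`, e.g. `"N<L"`), and the configuration.
#' @examples
#' spec <- synthetic_spec(n_probes = 50, group_sizes = c(N = 4, L = 4),
#'                        n_studies = 1, planted = list(), seed = 7)
#' d <- generate_meta_dataset(spec)
#' mt <- run_meta_test(d$expr, d$design, c("N", "L"), alpha = 0.05,
#'                     n_perm = 100, seed = 7)
#' summary(mt)
#' @export
run_meta_test <- function(x, design, pair, alpha = 0.001, n_perm = 5000L,
                          seed = NULL, scheme = c("per_probe", "sample_label"),
                          null = c("per_probe", "pooled"), plus_one = FALSE,
                          perms = NULL) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  eng <- rp_perm_engine(x, design, pair, n_perm = n_perm, seed = seed,
                        scheme = scheme, null = null, perms = perms)
  mk_p <- function(k) if (plus_one) (k + 1) / (eng$denom + 1) else k / eng$denom
  tab <- data.frame(probe_id = names(eng$rp_up),
                    rp_up = unname(eng$rp_up), p_up = mk_p(eng$k_up),
                    rp_down = unname(eng$rp_down), p_down = mk_p(eng$k_dn),
                    stringsAsFactors = FALSE)
  tab$de_up <- tab$p_up < alpha
  tab$de_down <- tab$p_down < alpha
  structure(list(table = tab, pair = pair,
                 alt_up = paste0(pair[1L], "<", pair[2L]),
                 alt_down = paste0(pair[1L], ">", pair[2L]),
                 alpha = alpha, n_perm = n_perm, seed = seed),
            class = "meta_test")
}

#' @export
print.meta_test <- function(x, ...) {
  cat("Rank-product meta-test:", paste(x$pair, collapse = " vs "),
      sprintf("(%d probes, %d permutations, alpha = %g)\n",
              nrow(x$table), x$n_perm, x$alpha))
  cat(sprintf("  DE [%s]: %d   DE [%s]: %d\n", x$alt_up, sum(x$table$de_up),
              x$alt_down, sum(x$table$de_down)))
  invisible(x)
}

#' Summarize a set of meta-tests as a DE-count table
#'
#' Produces the per-test layout used for reporting: DE counts under each
#' one-sided alternative, their total, and the percentage of all probes.
#'
#' @param object A `meta_test`, or a list of them via [summarize_meta_tests()].
#' @param ... Unused.
#' @export
summary.meta_test <- function(object, ...) {
  summarize_meta_tests(list(object))
}

#' @rdname summary.meta_test
#' @param tests List of `meta_test` objects.
#' @return Data frame with one row per test: pair, DE counts per alternative,
#'   total DE probes, and percentage of the probe universe.
#' @export
summarize_meta_tests <- function(tests) {
  stopifnot(length(tests) >= 1L)
  rows <- lapply(tests, function(t) {
    stopifnot(inherits(t, "meta_test"))
    n_up <- sum(t$table$de_up); n_dn <- sum(t$table$de_down)
    data.frame(test = paste0(t$pair[1L], t$pair[2L]),
               alt_up = t$alt_up, de_up = n_up,
               alt_down = t$alt_down, de_down = n_dn,
               de_total = n_up + n_dn,
               pct_of_probes = 100 * (n_up + n_dn) / nrow(t$table),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
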