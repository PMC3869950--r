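test_that("pairwise_log_ratios builds the ordered cross-pair differences", {
  x <- matrix(c(5, 3), 1, 2, dimnames = list("g1", c("a", "b")))
  d <- group_design(c("a", "b"), c("N", "L"))
  y <- pairwise_log_ratios(x, d, c("N", "L"))
  expect_identical(dim(y), c(1L, 1L))
  expect_equal(y[1, 1], -2)  # second-listed minus first: 3 - 5
  # reversing the pair flips the sign
  expect_equal(pairwise_log_ratios(x, d, c("L", "N"))[1, 1], 2)

  td <- toy_dataset(4, 2, 3, seed = 11)
  y <- pairwise_log_ratios(td$x, td$design, c("N", "L"))
  expect_identical(ncol(y), 6L)  # M = n_A * n_B
  # column order: outer over A samples, inner over B
  expect_identical(colnames(y)[1:3], c("a1|b1", "a1|b2", "a1|b3"))
  expect_equal(y[, "a2|b3"], td$x[, "b3"] - td$x[, "a2"])
  # constant probe gives an all-zero row
  td$x[2, ] <- 4.4
  expect_true(all(pairwise_log_ratios(td$x, td$design, c("N", "L"))[2, ] == 0))
})

test_that("pairwise_log_ratios validates the design", {
  td <- toy_dataset(3, 2, 2)
  expect_error(pairwise_log_ratios(td$x, td$design, c("N", "H")),
               "empty group")
  d2 <- td$design[-1, ]
  expect_error(pairwise_log_ratios(td$x, d2, c("N", "L")),
               "missing from design")
  expect_error(pairwise_log_ratios(td$x, td$design, c("N", "N")), "distinct")
})

test_that("rank_within_comparisons ranks each column with average ties", {
  expect_equal(rank_within_comparisons(cbind(c(3, 1, 2)), "up")[, 1],
               c(1, 3, 2))
  expect_equal(rank_within_comparisons(cbind(c(3, 1, 2)), "down")[, 1],
               c(3, 1, 2))
  expect_equal(rank_within_comparisons(cbind(c(2, 2, 1)), "up")[, 1],
               c(1.5, 1.5, 3))
  # brute-force check, multiple columns, ties everywhere
  withr::with_seed(42, {
    for (rep in 1:20) {
      y <- matrix(sample(seq(0, 2, by = 0.5), 40, replace = TRUE), 8, 5)
      expect_equal(rank_within_comparisons(y, "up"),
                   apply(y, 2, function(v) rank(-v)), ignore_attr = TRUE)
      expect_equal(rank_within_comparisons(y, "down"),
                   apply(y, 2, rank), ignore_attr = TRUE)
    }
  })
})

test_that("up and down ranks are complementary (p + 1), ties included", {
  withr::with_seed(7, {
    y <- matrix(sample(1:4, 60, replace = TRUE), 12, 5)
    ru <- rank_within_comparisons(y, "up")
    rd <- rank_within_comparisons(y, "down")
    expect_equal(ru + rd, matrix(13, 12, 5), ignore_attr = TRUE)
  })
})

test_that("rank_product is the geometric mean rank", {
  expect_equal(unname(rank_product(matrix(1, 1, 5))), 1)
  expect_equal(unname(rank_product(matrix(c(1, 4), 1, 2))), 2)
  withr::with_seed(3, {
    r <- matrix(sample(1:5, 20, replace = TRUE), 5, 4)
    expect_equal(unname(rank_product(r)),
                 apply(r, 1, function(v) prod(v)^(1 / 4)))
  })
  expect_error(rank_product(matrix(0.5, 2, 2)), ">= 1")
})

test_that("RP is invariant under monotone transforms of a ratio column", {
  td <- toy_dataset(6, 3, 3, seed = 5)
  y <- pairwise_log_ratios(td$x, td$design, c("N", "L"))
  r1 <- rank_product(rank_within_comparisons(y, "up"))
  y2 <- y
  y2[, 2] <- exp(y2[, 2])          # strictly increasing
  y2[, 5] <- 3 * y2[, 5] + 100
  r2 <- rank_product(rank_within_comparisons(y2, "up"))
  expect_equal(r1, r2)
})

test_that("RP and empirical p match the naive oracle on small instances", {
  withr::with_seed(99, grid <- data.frame(p = sample(2:6, 6, TRUE),
                                          na = sample(1:3, 6, TRUE),
                                          nb = sample(1:3, 6, TRUE)))
  for (i in seq_len(nrow(grid))) {
    p <- grid$p[i]; na <- grid$na[i]; nb <- grid$nb[i]
    td <- toy_dataset(p, na, nb, seed = 100 + i,
                      integer_valued = i %% 2 == 0)  # ties in half the cases
    z <- td$x
    y <- pairwise_log_ratios(z, td$design, c("N", "L"))
    for (dir in c("up", "down")) {
      expect_equal(unname(rank_product(rank_within_comparisons(y, dir))),
                   naive_rp(naive_ratio(z, na), dir), tolerance = 1e-12)
    }
    perms <- draw_perms(p, na + nb, 60, seed = 200 + i)
    for (dir in c("up", "down")) {
      pv <- permutation_null(z, td$design, c("N", "L"), dir,
                             n_perm = 60, perms = perms)
      expect_equal(as.numeric(pv), naive_perm_p(z, na, dir, perms),
                   tolerance = 1e-12)
    }
  }
})

test_that("seeded permutation stream equals the explicit-perms path", {
  td <- toy_dataset(10, 4, 3, seed = 8)
  perms <- draw_perms(10, 7, 50, seed = 77)
  p_seed <- permutation_null(td$x, td$design, c("N", "L"), "up",
                             n_perm = 50, seed = 77)
  p_explicit <- permutation_null(td$x, td$design, c("N", "L"), "up",
                                 n_perm = 50, perms = perms)
  expect_equal(as.numeric(p_seed), as.numeric(p_explicit))
})

test_that("permutation_null edge cases behave per contract", {
  # identity permutation with n_perm = 1 reproduces RP* = RP, so p = 1
  td <- toy_dataset(4, 2, 2, seed = 2)
  ident <- list(matrix(1:4, 4, 4, byrow = TRUE))
  pv <- permutation_null(td$x, td$design, c("N", "L"), "up", n_perm = 1,
                         perms = ident)
  expect_equal(as.numeric(pv), rep(1, 4))
  # planted enormous effect -> p = 0 (10+10 samples: the chance that some
  # permutation reconstitutes the group split is negligible)
  td2 <- toy_dataset(50, 10, 10, seed = 3)
  td2$x[1, 11:20] <- td2$x[1, 11:20] + 50
  pv2 <- permutation_null(td2$x, td2$design, c("N", "L"), "up",
                          n_perm = 200, seed = 4)
  expect_equal(unname(pv2[1]), 0)
  expect_error(permutation_null(td$x, td$design, c("N", "L"), "up",
                                n_perm = 0), "n_perm")
})

test_that("plus-one correction and pooled null produce valid p-values", {
  td <- toy_dataset(20, 3, 3, seed = 21)
  pv <- permutation_null(td$x, td$design, c("N", "L"), "up", n_perm = 19,
                         seed = 5, plus_one = TRUE)
  expect_true(all(pv >= 1 / 20 & pv <= 1))
  expect_true(all(abs(pv * 20 - round(pv * 20)) < 1e-9))
  pvp <- permutation_null(td$x, td$design, c("N", "L"), "up", n_perm = 19,
                          seed = 5, null = "pooled")
  expect_true(all(pvp >= 0 & pvp <= 1))
  # pooled denominator is n_perm * p
  expect_true(all(abs(pvp * 19 * 20 - round(pvp * 19 * 20)) < 1e-6))
  # sample-label scheme runs and is deterministic under seed
  a <- permutation_null(td$x, td$design, c("N", "L"), "up", n_perm = 25,
                        seed = 6, scheme = "sample_label")
  b <- permutation_null(td$x, td$design, c("N", "L"), "up", n_perm = 25,
                        seed = 6, scheme = "sample_label")
  expect_identical(a, b)
})

test_that("run_meta_test flags DE at strict p < alpha in both directions", {
  spec <- synthetic_spec(n_probes = 120, group_sizes = c(N = 8, L = 8),
                         n_studies = 1, study_shift_sd = 0, noise_sd = 0.6,
                         planted = list(list(pattern = "N<L", n = 8,
                                             effect = 4)),
                         seed = 31)
  d <- generate_meta_dataset(spec)
  mt <- run_meta_test(d$expr, d$design, c("N", "L"), alpha = 0.01,
                      n_perm = 300, seed = 32)
  planted <- d$truth$pattern == "N<L"
  # planted N<L probes are DE under the N<L alternative, not under N>L
  expect_true(all(mt$table$de_up[planted]))
  expect_false(any(mt$table$de_down[planted]))
  expect_identical(mt$table$de_up, mt$table$p_up < 0.01)
  expect_identical(mt$table$de_down, mt$table$p_down < 0.01)
  expect_identical(mt$alt_up, "N<L")
  # summary layout
  s <- summary(mt)
  expect_identical(s$de_total, s$de_up + s$de_down)
  expect_equal(s$pct_of_probes, 100 * s$de_total / 120)
  expect_identical(s$alt_up, "N<L")
  expect_error(run_meta_test(d$expr, d$design, c("N", "L"), alpha = 1.2,
                             n_perm = 10), "alpha")
})

test_that("mean planted p is non-increasing in effect size", {
  mean_p <- vapply(c(0.5, 1, 2), function(eff) {
    spec <- synthetic_spec(n_probes = 150, group_sizes = c(N = 5, L = 5),
                           n_studies = 1, study_shift_sd = 0, noise_sd = 1,
                           planted = list(list(pattern = "N<L", n = 20,
                                               effect = eff)),
                           seed = 50)  # same seed: same noise realization
    d <- generate_meta_dataset(spec)
    mt <- run_meta_test(d$expr, d$design, c("N", "L"), n_perm = 150,
                        seed = 51)
    mean(mt$table$p_up[d$truth$pattern == "N<L"])
  }, numeric(1))
  expect_true(all(diff(mean_p) <= 0))
})
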