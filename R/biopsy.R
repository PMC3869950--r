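#' Grouped numeric values with summary statistics
#'
#' Light container used by the cohort tests: a named list of numeric
#' vectors plus per-group n, mean and sample standard deviation.
#'
#' @param values Named list of numeric vectors, one per group.
#' @return Object of class `grouped_values` with elements `values`, `n`,
#'   `mean`, `sd`.
#' @export
grouped_values <- function(values) {
  stopifnot(is.list(values), !is.null(names(values)))
  values <- lapply(values, as.numeric)
  structure(list(values = values,
                 n = vapply(values, length, integer(1)),
                 mean = vapply(values, mean, numeric(1)),
                 sd = vapply(values, stats::sd, numeric(1))),
            class = "grouped_values")
}

#' @export
print.grouped_values <- function(x, ...) {
  print(data.frame(group = names(x$values), n = x$n,
                   mean = round(x$mean, 2), sd = round(x$sd, 2),
                   row.names = NULL))
  invisible(x)
}

#' Group biopsy records by WHO grade
#'
#' Metastatic records are excluded; grades I--II form the `low` group and
#' III--IV the `high` group. For the qRT-PCR measure, records with an absent
#' ratio are dropped while literal zeros ("non-detected") are retained --
#' the convention under which the cohort's Welch statistic reproduces.
#'
#' @param records A `biopsy_cohort` (see [load_biopsy_fixture()]) or any
#'   data frame with `who_grade` and the measure column.
#' @param measure `"microarray"` or `"qrt_pcr"`.
#' @return A [grouped_values()] with groups `low` and `high`.
#' @export
group_by_grade <- function(records, measure = c("microarray", "qrt_pcr")) {
  measure <- match.arg(measure)
  bad <- setdiff(unique(records$who_grade),
                 c("I", "II", "III", "IV", "metastatic"))
  if (length(bad) > 0L)
    stop("unknown WHO grade label: ", paste(bad, collapse = ", "),
         call. = FALSE)
  prim <- records[records$who_grade != "metastatic", , drop = FALSE]
  v <- prim[[measure]]
  keep <- !is.na(v)
  grp <- ifelse(prim$who_grade %in% c("I", "II"), "low", "high")
  grouped_values(list(low = v[keep & grp == "low"],
                      high = v[keep & grp == "high"]))
}

#' Group biopsy records by tumor tissue type
#'
#' The four-type grouping of the cohort analysis: meningioma; astrocytoma
#' (pilocytic, grade II, gemistocytic and anaplastic astrocytoma);
#' glioblastoma; and adenocarcinoma (all metastatic carcinomas). Anaplastic
#' ependymoma and haemangioblastoma fit none of the four and are excluded.
#'
#' @inheritParams group_by_grade
#' @return A [grouped_values()] with the four tissue groups.
#' @export
group_by_tissue <- function(records, measure = "microarray") {
  astro <- c("astrocytoma", "pilocytic astrocytoma",
             "gemistocytic astrocytoma", "anaplastic astrocytoma")
  tissue <- ifelse(records$tumor_type == "meningioma", "meningioma",
            ifelse(records$tumor_type %in% astro, "astrocytoma",
            ifelse(records$tumor_type == "glioblastoma", "glioblastoma",
            ifelse(grepl("^metastatic", records$tumor_type),
                   "adenocarcinoma", NA_character_))))
  keep <- !is.na(tissue) & !is.na(records[[measure]])
  v <- split(records[[measure]][keep], tissue[keep])
  grouped_values(v[c("meningioma", "astrocytoma", "glioblastoma",
                     "adenocarcinoma")])
}

#' Two-sample t-test (pooled or Welch)
#'
#' Classical equal-variance statistic with `n_a + n_b - 2` df, or Welch's
#' unequal-variance statistic with Welch--Satterthwaite df. The one-tailed
#' p-value tests the alternative `mean(a) > mean(b)` (it halves the
#' two-tailed value when the effect is in that direction).
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param variant `"pooled"` or `"welch"`.
#' @param tail `"two"` or `"one"`.
#' @return List with `t`, `df`, `p`.
#' @export
two_sample_t <- function(a, b, variant = c("pooled", "welch"),
                         tail = c("two", "one")) {
  variant <- match.arg(variant); tail <- match.arg(tail)
  a <- as.numeric(a); b <- as.numeric(b)
  na <- length(a); nb <- length(b)
  if (na < 2L || nb < 2L)
    stop("each group needs n >= 2", call. = FALSE)
  va <- stats::var(a); vb <- stats::var(b)
  if (variant == "pooled") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    if (!is.finite(va) || !is.finite(vb))
      stop("non-finite variance", call. = FALSE)
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (mean(a) - mean(b)) / se
  p <- if (tail == "two") 2 * stats::pt(-abs(t), df)
       else stats::pt(t, df, lower.tail = FALSE)
  list(t = t, df = df, p = p)
}

#' One-way analysis of variance
#'
#' Standard between/within sum-of-squares decomposition; p from the F
#' distribution with `(k - 1, N - k)` df. With all values equal the F
#' statistic is undefined and reported as `NaN`.
#'
#' @param groups A [grouped_values()] with >= 2 groups, each n >= 2.
#' @return List with `F`, `df_between`, `df_within`, `p`, `ms_within`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(inherits(groups, "grouped_values"))
  if (length(groups$values) < 2L || any(groups$n < 2L))
    stop("ANOVA needs >= 2 groups with n >= 2 each", call. = FALSE)
  all_v <- unlist(groups$values, use.names = FALSE)
  gm <- mean(all_v)
  ss_b <- sum(groups$n * (groups$mean - gm)^2)
  ss_w <- sum(vapply(groups$values, function(v) sum((v - mean(v))^2),
                     numeric(1)))
  df_b <- length(groups$values) - 1L
  df_w <- length(all_v) - length(groups$values)
  ms_w <- ss_w / df_w
  f <- (ss_b / df_b) / ms_w
  list(F = f, df_between = df_b, df_within = df_w,
       p = stats::pf(f, df_b, df_w, lower.tail = FALSE), ms_within = ms_w)
}

#' Tukey--Kramer all-pairs post hoc comparisons
#'
#' After a one-way ANOVA, compares every unordered pair of groups using the
#' studentized-range distribution with the Tukey--Kramer unequal-n standard
#' error `sqrt((MSW/2) * (1/n_i + 1/n_j))`. The mean difference follows the
#' column-vs-row sign convention: `diff = mean(col_group) - mean(row_group)`
#' with pairs enumerated in the group order of `groups`.
#'
#' @inheritParams one_way_anova
#' @param level Significance threshold for the `significant` flag.
#' @return Data frame with one row per pair: `row_group`, `col_group`,
#'   `diff`, `p_adj`, `significant`.
#' @export
tukey_kramer <- function(groups, level = 0.01) {
  stopifnot(inherits(groups, "grouped_values"))
  an <- one_way_anova(groups)
  k <- length(groups$values)
  labs <- names(groups$values)
  rows <- list()
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    d <- groups$mean[j] - groups$mean[i]  # column (later) minus row (earlier)
    se <- sqrt((an$ms_within / 2) * (1 / groups$n[i] + 1 / groups$n[j]))
    q <- abs(d) / se
    p <- stats::ptukey(q, nmeans = k, df = an$df_within, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <-
      data.frame(row_group = labs[i], col_group = labs[j], diff = unname(d),
                 p_adj = p, significant = p < level,
                 stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Benjamini--Hochberg FDR adjustment
#'
#' Step-up adjustment: sorted p-values are scaled by `m/rank` and a running
#' minimum from the largest rank downwards enforces monotonicity; the
#' result is returned in the input order and capped at 1.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, order-preserving with the input.
#' @export
bh_fdr <- function(pvals) {
  p <- as.numeric(pvals)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  adj <- pmin(1, p[o] * m / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}
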