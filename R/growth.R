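#' Ellipsoid tumor volume from caliper measurements
#'
#' `V = pi * length * width^2 / 6` (mm^3), the standard modified-ellipsoid
#' caliper formula; for `length = width = d` it reduces to the sphere
#' volume `pi d^3 / 6`.
#'
#' @param length_mm,width_mm Caliper dimensions in mm (> 0); vectorized.
#' @return Volumes in mm^3.
#' @export
ellipsoid_volume <- function(length_mm, width_mm) {
  if (any(!is.finite(length_mm)) || any(!is.finite(width_mm)) ||
      any(length_mm <= 0) || any(width_mm <= 0))
    stop("caliper dimensions must be positive", call. = FALSE)
  pi * length_mm * width_mm^2 / 6
}

#' Tumor doubling time by log-linear regression
#'
#' Fits ordinary least squares of `ln(V)` on day and reports
#' `ln(2) / slope` in days. A non-positive slope means the tumor is not
#' growing; the doubling time is then `NA` with `growing = FALSE`, not an
#' error.
#'
#' @param series A [growth_series()], or any data frame with columns `day`,
#'   `length_mm`, `width_mm` (or a precomputed `volume` column).
#' @return List with `doubling_days`, `slope` (per day), `growing`.
#' @export
doubling_time <- function(series) {
  v <- if ("volume" %in% names(series)) series$volume
       else ellipsoid_volume(series$length_mm, series$width_mm)
  day <- series$day
  if (length(unique(day)) < 2L)
    stop("need >= 2 distinct days for a doubling-time estimate",
         call. = FALSE)
  if (any(v <= 0)) stop("volumes must be > 0", call. = FALSE)
  slope <- unname(stats::coef(stats::lm(log(v) ~ day))[2L])
  # slopes at floating-point noise level count as flat
  if (slope <= 1e-12) list(doubling_days = NA_real_, slope = slope,
                           growing = FALSE)
  else list(doubling_days = log(2) / slope, slope = slope, growing = TRUE)
}

#' Compare doubling times between two groups
#'
#' Two-sample two-tailed t-test on per-animal doubling times; delegates to
#' [two_sample_t()] (pooled variance by default, Welch optional).
#'
#' @param a,b Numeric vectors of doubling times (days), each n >= 2.
#' @param variant `"pooled"` or `"welch"`.
#' @return List with `t`, `df`, `p` (two-tailed).
#' @export
compare_doubling <- function(a, b, variant = c("pooled", "welch")) {
  two_sample_t(a, b, variant = match.arg(variant), tail = "two")
}

#' Read a caliper measurement file and compute per-animal kinetics
#'
#' The file is tab-delimited with columns `animal`, `group`, `day`,
#' `length_mm`, `width_mm`. Returns per-animal doubling times and, when
#' exactly two groups are present, their comparison.
#'
#' @param path Path to the caliper file.
#' @param variant t-test variant for the group comparison.
#' @return List with `per_animal` (data frame `animal`, `group`,
#'   `doubling_days`, `growing`) and `comparison` (or `NULL`).
#' @export
growth_report <- function(path, variant = "pooled") {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("animal", "group", "day", "length_mm", "width_mm")
  if (!all(need %in% names(d)))
    stop("caliper file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  per <- lapply(split(d, d$animal), function(s) {
    dt <- doubling_time(s)
    data.frame(animal = s$animal[1L], group = s$group[1L],
               doubling_days = dt$doubling_days, growing = dt$growing,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, c(per, make.row.names = FALSE))
  groups <- unique(per$group)
  cmp <- NULL
  if (length(groups) == 2L) {
    g1 <- per$doubling_days[per$group == groups[1L] & per$growing]
    g2 <- per$doubling_days[per$group == groups[2L] & per$growing]
    if (length(g1) >= 2L && length(g2) >= 2L)
      cmp <- c(list(groups = groups), compare_doubling(g1, g2, variant))
  }
  list(per_animal = per, comparison = cmp)
}
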