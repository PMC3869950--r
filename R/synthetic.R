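#' Specification for a synthetic multi-study expression collection
#'
#' Describes the stated world the generator emulates: a collection of
#' GCRMA-style log2 matrices from several studies, each contributing the
#' same per-group sample counts, with one additive Gaussian baseline shift
#' per study, independent Gaussian probe-level noise, and a planted subset
#' of probes whose group means follow declared ordering patterns.
#'
#' The defaults mimic the imbalance of the real grouped collection
#' (normal 53, low-grade 32, high-grade 376 across ten studies) scaled to
#' desk size: three studies of 5 normal, 3 low-grade and 12 high-grade
#' samples each.
#'
#' @param n_probes Number of probes.
#' @param group_sizes Named integer vector: samples per group per study;
#'   names drawn from `N`, `L`, `H`.
#' @param n_studies Number of studies.
#' @param study_shift_sd SD (log2 units) of the per-study additive shift.
#' @param noise_sd SD (log2 units) of per-probe, per-sample Gaussian noise.
#' @param baseline_mean Baseline log2 expression level.
#' @param planted List of entries `list(pattern =, n =, effect =)`: a chain
#'   pattern over the groups (e.g. `"N<L<H"`), how many probes follow it,
#'   and the log2 effect size between adjacent chain levels (must be > 0).
#' @param seed Integer seed making the generated collection reproducible.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_probes = 2000L,
                           group_sizes = c(N = 5L, L = 3L, H = 12L),
                           n_studies = 3L,
                           study_shift_sd = 0.5,
                           noise_sd = 1.0,
                           baseline_mean = 6,
                           planted = list(),
                           seed = 1L) {
  chk_count <- function(v, what) {
    if (length(v) < 1L || any(!is.finite(v)) || any(v < 0) ||
        any(v != floor(v)))
      stop("invalid synthetic spec: ", what, " must be a nonnegative integer",
           call. = FALSE)
  }
  chk_count(n_probes, "n_probes"); chk_count(n_studies, "n_studies")
  chk_count(group_sizes, "group_sizes")
  if (is.null(names(group_sizes)) ||
      !all(names(group_sizes) %in% c("N", "L", "H")))
    stop("invalid synthetic spec: group_sizes names must be among N, L, H",
         call. = FALSE)
  if (any(c(study_shift_sd, noise_sd) < 0))
    stop("invalid synthetic spec: study_shift_sd and noise_sd must be >= 0",
         call. = FALSE)
  for (pl in planted) {
    if (!all(c("pattern", "n", "effect") %in% names(pl)))
      stop("invalid synthetic spec: planted entries need pattern, n, effect",
           call. = FALSE)
    chk_count(pl$n, "planted n")
    if (!is.finite(pl$effect) || pl$effect <= 0)
      stop("invalid synthetic spec: planted effect must be > 0", call. = FALSE)
    parse_pattern_chain(pl$pattern)  # errors on malformed labels
  }
  n_planted <- sum(vapply(planted, function(p) p$n, numeric(1)))
  if (n_probes < n_planted)
    stop("invalid synthetic spec: n_probes smaller than total planted probes",
         call. = FALSE)
  structure(list(n_probes = as.integer(n_probes),
                 group_sizes = group_sizes, n_studies = as.integer(n_studies),
                 study_shift_sd = study_shift_sd, noise_sd = noise_sd,
                 baseline_mean = baseline_mean, planted = planted,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Parse an ordering-chain pattern such as "N<L<H" or "L>N<H" into per-group
# mean offsets in effect-size units (minimum level shifted to zero). Groups
# absent from the chain get offset 0.
parse_pattern_chain <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L ||
      !grepl("^[NLH]([<>][NLH])+$", pattern))
    stop("malformed pattern chain: ", pattern, call. = FALSE)
  groups <- strsplit(gsub("[<>]", " ", pattern), " ")[[1L]]
  ops <- strsplit(gsub("[NLH]", "", pattern), "")[[1L]]
  if (anyDuplicated(groups))
    stop("malformed pattern chain (repeated group): ", pattern, call. = FALSE)
  lev <- numeric(length(groups))
  for (i in seq_along(ops))
    lev[i + 1L] <- lev[i] + if (ops[i] == "<") 1 else -1
  lev <- lev - min(lev)
  off <- c(N = 0, L = 0, H = 0)
  off[groups] <- lev
  off
}

#' Generate a multi-study expression collection with planted patterns
#'
#' Draws `X[i, j] = baseline + pattern_offset(i, group(j)) + study_shift +
#' noise` per the spec's additive Gaussian model. Planted probes have group
#' means separated by the stated effect size between adjacent groups of
#' their chain; all other probes are null. One shift is drawn per study and
#' applied to all its samples, so within-study group exchangeability holds
#' exactly under the null.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `expr` (probe x sample matrix), `design` (a
#'   [group_design()] with study ids), and `truth` (data frame `probe_id`,
#'   `pattern`, `"null"` for unplanted probes).
#' @export
generate_meta_dataset <- function(spec) {
  if (!inherits(spec, "synthetic_spec"))
    spec <- do.call(synthetic_spec, spec)
  gs <- spec$group_sizes[spec$group_sizes > 0]
  groups <- rep(rep(names(gs), times = gs), times = spec$n_studies)
  study <- rep(paste0("study", seq_len(spec$n_studies)),
               each = sum(gs))
  sample_id <- paste0(study, "_", groups,
                      stats::ave(seq_along(groups), paste(study, groups),
                                 FUN = seq_along))
  design <- group_design(sample_id, groups, study)

  probe_id <- sprintf("probe_%05d", seq_len(spec$n_probes))
  pattern <- rep("null", spec$n_probes)
  offsets <- matrix(0, spec$n_probes, 3,
                    dimnames = list(probe_id, c("N", "L", "H")))
  at <- 1L
  for (pl in spec$planted) {
    if (pl$n == 0L) next
    idx <- at:(at + pl$n - 1L)
    pattern[idx] <- pl$pattern
    offsets[idx, ] <- rep(parse_pattern_chain(pl$pattern) * pl$effect,
                          each = pl$n)
    at <- at + pl$n
  }

  expr <- withr::with_seed(spec$seed, {
    shifts <- stats::rnorm(spec$n_studies, 0, spec$study_shift_sd)
    names(shifts) <- paste0("study", seq_len(spec$n_studies))
    m <- spec$baseline_mean + offsets[, groups, drop = FALSE] +
      rep(shifts[study], each = spec$n_probes)
    m + stats::rnorm(length(m), 0, spec$noise_sd)
  })
  dimnames(expr) <- list(probe_id, sample_id)
  list(expr = expr, design = design,
       truth = data.frame(probe_id = probe_id, pattern = pattern,
                          stringsAsFactors = FALSE))
}

#' Load the packaged 42-sample brain-tumor biopsy cohort
#'
#' Returns the tab-delimited biopsy table shipped with the package: 42
#' surgical samples with sex, age, log-scale microarray KAL1 expression,
#' qRT-PCR concentration ratio normalized to beta-actin (absent where the
#' assay was not run; one meningioma has a literal zero for "non-detected"),
#' tumor type, and WHO grade (`I`--`IV` or `metastatic`).
#'
#' @return Data frame of class `biopsy_cohort` with columns `sample_id`,
#'   `sex`, `age`, `microarray`, `qrt_pcr`, `tumor_type`, `who_grade`.
#' @export
load_biopsy_fixture <- function() {
  path <- system.file("extdata", "biopsy_cohort.tsv", package = "rpmeta")
  if (!nzchar(path) || !file.exists(path))
    stop("biopsy fixture not found in installed package", call. = FALSE)
  d <- utils::read.delim(path, colClasses = c(sample_id = "character"),
                         stringsAsFactors = FALSE)
  need <- c("sample_id", "sex", "age", "microarray", "qrt_pcr",
            "tumor_type", "who_grade")
  if (!identical(names(d), need) || nrow(d) != 42L ||
      anyNA(d$microarray))
    stop("biopsy fixture is corrupt", call. = FALSE)
  class(d) <- c("biopsy_cohort", "data.frame")
  d
}

#' Simulate xenograft caliper growth series
#'
#' Each mouse gets caliper measurements (day, length, width in mm) of a
#' tumor growing exponentially with the given doubling time, observed with
#' multiplicative lognormal volume noise. Volumes are rendered as spherical
#' caliper dimensions (length = width), so the ellipsoid volume formula
#' recovers them exactly.
#'
#' @param n_mice Number of animals.
#' @param true_doubling_days True doubling time(s) in days (> 0); recycled
#'   across mice, so per-animal truths may be supplied.
#' @param noise_sd Relative (lognormal sigma) measurement noise on volume.
#' @param seed Integer seed.
#' @param days Measurement days (>= 4 timepoints).
#' @param v0 Volume (mm^3) at the first measurement day.
#' @param group Group label attached to every series.
#' @return List of `growth_series` data frames (columns `day`, `length_mm`,
#'   `width_mm`; attributes `animal_id`, `group`).
#' @export
generate_growth_series <- function(n_mice, true_doubling_days, noise_sd = 0.1,
                                   seed = 1L, days = seq(0, 28, by = 7),
                                   v0 = 50, group = "group1") {
  if (any(!is.finite(true_doubling_days)) || any(true_doubling_days <= 0))
    stop("true_doubling_days must be > 0", call. = FALSE)
  if (length(days) < 4L) stop("need >= 4 timepoints", call. = FALSE)
  td <- rep_len(true_doubling_days, n_mice)
  withr::with_seed(seed, {
    lapply(seq_len(n_mice), function(i) {
      v <- v0 * 2^(days / td[i]) *
        exp(stats::rnorm(length(days), 0, noise_sd))
      d <- (6 * v / pi)^(1 / 3)  # sphere: length = width = diameter
      growth_series(animal_id = sprintf("mouse_%02d", i), group = group,
                    day = days, length_mm = d, width_mm = d)
    })
  })
}

#' Construct a caliper growth series
#'
#' @param animal_id Animal identifier.
#' @param group Group label.
#' @param day Days post-transplantation.
#' @param length_mm,width_mm Caliper dimensions in mm; requires
#'   `length >= width > 0`.
#' @return Data frame of class `growth_series`.
#' @export
growth_series <- function(animal_id, group, day, length_mm, width_mm) {
  if (any(width_mm <= 0) || any(length_mm < width_mm))
    stop("growth series requires length >= width > 0", call. = FALSE)
  structure(data.frame(day = day, length_mm = length_mm, width_mm = width_mm),
            animal_id = animal_id, group = group,
            class = c("growth_series", "data.frame"))
}
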