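#' Sample-to-group design
#'
#' Constructs and validates the annotation that assigns each expression
#' column to a group (and optionally a study). Group labels are restricted
#' to a declared vocabulary to prevent silent misassignment.
#'
#' @param sample_id Character vector of sample ids (unique).
#' @param group Character vector of group labels, same length.
#' @param study Optional study identifier per sample.
#' @param levels Allowed group labels; defaults to the normal / low-grade /
#'   high-grade vocabulary `c("N", "L", "H")`.
#' @return A data frame of class `group_design` with columns `sample_id`,
#'   `group`, `study`.
#' @export
group_design <- function(sample_id, group, study = NULL,
                         levels = c("N", "L", "H")) {
  sample_id <- as.character(sample_id)
  group <- as.character(group)
  if (length(sample_id) != length(group))
    stop("sample_id and group must have equal length", call. = FALSE)
  if (anyDuplicated(sample_id))
    stop("duplicate sample ids in design: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(group), levels)
  if (length(bad) > 0L)
    stop("group labels outside declared vocabulary: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(study)) study <- rep("study1", length(sample_id))
  d <- data.frame(sample_id = sample_id, group = group,
                  study = as.character(study), stringsAsFactors = FALSE)
  class(d) <- c("group_design", "data.frame")
  d
}

# Check a design against a matrix: every matrix column must be annotated.
validate_design <- function(design, x = NULL) {
  if (!is.data.frame(design) ||
      !all(c("sample_id", "group") %in% names(design)))
    stop("design must be a data frame with sample_id and group columns",
         call. = FALSE)
  if (anyDuplicated(design$sample_id))
    stop("duplicate sample ids in design", call. = FALSE)
  if (!is.null(x)) {
    if (is.null(colnames(x)) || is.null(rownames(x)))
      stop("expression matrix must carry probe rownames and sample colnames",
           call. = FALSE)
    missing <- setdiff(colnames(x), design$sample_id)
    if (length(missing) > 0L)
      stop("samples missing from design: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  design
}

#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample ids and a first column of probe ids, as
#' written by [write_expression_matrix()] (the GEO series-matrix style).
#' Malformed input is rejected, not coerced: duplicate ids and non-numeric
#' cells are errors naming the offender.
#'
#' @param path Path to the file.
#' @return Numeric matrix with probe rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L)
    stop("malformed header in ", path, ": need probe id column plus samples",
         call. = FALSE)
  probes <- raw[[1L]]
  if (anyDuplicated(probes))
    stop("duplicate probe id in ", path, ": ",
         paste(unique(probes[duplicated(probes)]), collapse = ", "),
         call. = FALSE)
  samples <- colnames(raw)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample id in ", path, ": ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "),
         call. = FALSE)
  vals <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  vals <- matrix(vals, nrow = nrow(raw),
                 dimnames = list(probes, samples))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-numeric or non-finite value at line ", bad[1L, 1L] + 1L,
         ", sample '", samples[bad[1L, 2L]], "' in ", path, call. = FALSE)
  vals
}

#' @rdname read_expression_matrix
#' @param x Numeric matrix (probes x samples) to write.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(probe_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write a sample annotation table
#'
#' Tab-delimited with columns `sample_id`, `group`, `study`.
#'
#' @param path Path to the annotation file.
#' @param levels Allowed group labels (see [group_design()]).
#' @return A `group_design`.
#' @export
read_group_design <- function(path, levels = c("N", "L", "H")) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.delim(path, header = TRUE, colClasses = "character")
  need <- c("sample_id", "group")
  if (!all(need %in% names(d)))
    stop("annotation file must have columns sample_id and group", call. = FALSE)
  group_design(d$sample_id, d$group, d$study, levels = levels)
}

#' @rdname read_group_design
#' @param design A `group_design` to write.
#' @export
write_group_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a flat key-value pipeline configuration
#'
#' Parses a minimal `key: value` file (one pair per line, `#` comments
#' allowed) and merges it over the pipeline defaults: `alpha: 0.001`,
#' `n_permutations: 5000`, `seed: 1`.
#'
#' @param path Path to the config file, or `NULL` for pure defaults.
#' @return Named list with `alpha`, `n_permutations`, `seed` and any extra
#'   keys present in the file.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- list(alpha = 0.001, n_permutations = 5000L, seed = 1L)
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    if (!grepl(":", ln, fixed = TRUE))
      stop("malformed config line (expected 'key: value'): ", ln,
           call. = FALSE)
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num else val
  }
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("config alpha must lie in (0, 1)", call. = FALSE)
  if (cfg$n_permutations < 1)
    stop("config n_permutations must be >= 1", call. = FALSE)
  cfg$n_permutations <- as.integer(cfg$n_permutations)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full three-test meta-analysis pipeline
#'
#' Executes the pairwise rank-product tests N vs L, L vs H and N vs H on an
#' expression matrix, classifies probes significant in at least two tests
#' into the twelve expression-ordering patterns, and writes per-test TSVs, a
#' DE-count summary, per-probe pattern calls, a pattern summary, and a JSON
#' run manifest into `out_dir`. Re-running with the same inputs and seed
#' reproduces the outputs byte for byte.
#'
#' @param x Expression matrix, or a path to one (see
#'   [read_expression_matrix()]).
#' @param design A `group_design`, or a path to an annotation file.
#' @param out_dir Output directory (created if absent).
#' @param alpha Significance level for DE calls.
#' @param n_perm Permutation rounds per test.
#' @param seed Master seed; per-test seeds are derived deterministically.
#' @param pairs List of ordered group pairs to test.
#' @return Invisibly, a list with the `meta_test` objects, the pattern calls,
#'   and the paths of all written files.
#' @export
run_pipeline <- function(x, design, out_dir, alpha = 0.001, n_perm = 5000L,
                         seed = 1L,
                         pairs = list(c("N", "L"), c("L", "H"), c("N", "H"))) {
  if (is.character(x)) x <- read_expression_matrix(x)
  if (is.character(design)) design <- read_group_design(design)
  design <- validate_design(design, x)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  tests <- list(); paths <- character(0)
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    mt <- run_meta_test(x, design, pr, alpha = alpha, n_perm = n_perm,
                        seed = seed + i - 1L)
    key <- paste0(pr[1L], pr[2L])
    tests[[key]] <- mt
    f <- file.path(out_dir, sprintf("meta_test_%s.tsv", key))
    utils::write.table(mt$table, f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, f)
  }

  summ <- summarize_meta_tests(tests)
  f_sum <- file.path(out_dir, "summary_tests.tsv")
  utils::write.table(summ, f_sum, sep = "\t", quote = FALSE, row.names = FALSE)

  vm <- venn_membership(tests[["NL"]], tests[["LH"]], tests[["NH"]])
  calls <- vm$calls
  calls$pattern <- assign_pattern(calls$nl, calls$lh, calls$nh)
  f_pat <- file.path(out_dir, "patterns.tsv")
  utils::write.table(calls, f_pat, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  pat_sum <- summarize_patterns(calls$pattern)
  f_psum <- file.path(out_dir, "pattern_summary.tsv")
  utils::write.table(pat_sum, f_psum, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  manifest <- list(
    tool = "rpmeta",
    version = as.character(utils::packageVersion("rpmeta")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = list(alpha = alpha, n_permutations = n_perm, seed = seed,
                  pairs = vapply(pairs, paste, "", collapse = ",")),
    n_probes = nrow(x), n_samples = ncol(x),
    outputs = basename(c(paths, f_sum, f_pat, f_psum)))
  f_man <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f_man, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(tests = tests, calls = calls, summary = summ,
                 pattern_summary = pat_sum,
                 files = c(paths, f_sum, f_pat, f_psum, f_man)))
}
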