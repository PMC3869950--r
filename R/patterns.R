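#' The twelve cross-test expression-ordering patterns
#'
#' For each of the three pairwise tests (NL, LH, NH) a probe can be
#' up-regulated, down-regulated, or not differentially expressed. Probes
#' significant in at least two tests are assigned an ordering chain over
#' the groups N, L, H implied by the significant directions: four direction
#' combinations per significant test pair times three test pairs gives
#' twelve reachable labels.
#'
#' @return Character vector of the 12 pattern labels in canonical order.
#' @export
pattern_labels <- function() {
  c("N<L<H", "N<L>H", "N>L<H", "N>L>H",     # NL & LH significant
    "L>N<H", "L>N>H", "L<N<H", "L<N>H",     # NL & NH significant
    "L<H>N", "L<H<N", "L>H>N", "L>H<N")     # LH & NH significant
}

# status vectors: values in {"up", "down", "not-DE"}
check_status <- function(s, what) {
  s <- as.character(s)
  bad <- setdiff(unique(s), c("up", "down", "not-DE"))
  if (length(bad) > 0L)
    stop(what, " status must be up/down/not-DE, got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  s
}

# DE status of one meta_test at its stored (or overriding) alpha
test_status <- function(test, alpha = NULL) {
  stopifnot(inherits(test, "meta_test"))
  tab <- test$table
  up <- if (is.null(alpha)) tab$de_up else tab$p_up < alpha
  dn <- if (is.null(alpha)) tab$de_down else tab$p_down < alpha
  both <- up & dn
  if (any(both))
    stop("probe DE in both directions of one test: ",
         paste(utils::head(tab$probe_id[both], 5L), collapse = ", "),
         call. = FALSE)
  stats::setNames(ifelse(up, "up", ifelse(dn, "down", "not-DE")),
                  tab$probe_id)
}

#' Cross-test DE membership and Venn regions
#'
#' Combines the three pairwise meta-tests into a per-probe status triple and
#' counts the four at-least-two-tests Venn regions (`NL&LH only`,
#' `NL&NH only`, `LH&NH only`, `all three`), whose sum is the size of the
#' ">= 2 tests" probe set.
#'
#' @param nl,lh,nh `meta_test` objects for the N-L, L-H and N-H pairs,
#'   computed on the same probe universe.
#' @param alpha Optional significance level overriding the stored DE flags.
#' @return List with `calls` (data frame `probe_id`, `nl`, `lh`, `nh`,
#'   `n_sig`, `region`) and `region_counts` (named vector over the four
#'   regions plus `total`).
#' @export
venn_membership <- function(nl, lh, nh, alpha = NULL) {
  s_nl <- test_status(nl, alpha)
  s_lh <- test_status(lh, alpha)
  s_nh <- test_status(nh, alpha)
  if (!identical(names(s_nl), names(s_lh)) ||
      !identical(names(s_nl), names(s_nh)))
    stop("meta-tests were not computed on the same probe universe",
         call. = FALSE)
  sig <- cbind(s_nl != "not-DE", s_lh != "not-DE", s_nh != "not-DE")
  n_sig <- rowSums(sig)
  region <- rep(NA_character_, length(n_sig))
  region[sig[, 1] & sig[, 2] & !sig[, 3]] <- "NL&LH only"
  region[sig[, 1] & !sig[, 2] & sig[, 3]] <- "NL&NH only"
  region[!sig[, 1] & sig[, 2] & sig[, 3]] <- "LH&NH only"
  region[n_sig == 3L] <- "all three"
  calls <- data.frame(probe_id = names(s_nl), nl = unname(s_nl),
                      lh = unname(s_lh), nh = unname(s_nh),
                      n_sig = n_sig, region = region,
                      stringsAsFactors = FALSE)
  rc <- c("NL&LH only" = sum(region == "NL&LH only", na.rm = TRUE),
          "NL&NH only" = sum(region == "NL&NH only", na.rm = TRUE),
          "LH&NH only" = sum(region == "LH&NH only", na.rm = TRUE),
          "all three" = sum(region == "all three", na.rm = TRUE))
  rc <- c(rc, total = sum(rc))
  list(calls = calls, region_counts = rc)
}

#' Assign ordering patterns from per-test DE status triples
#'
#' A pure, vectorized function of the status triple. Probes significant in
#' fewer than two tests get `NA`; probes significant in exactly two get the
#' chain implied by those two directions; probes significant in all three
#' are labeled by the NL and LH directions, with the NH direction required
#' to be consistent when NL and LH agree in sign -- otherwise the probe is
#' `"unclassified"`. (When NL and LH disagree, e.g. `N<L>H`, the N-H
#' relation is unconstrained by the label, so any NH direction is
#' consistent.)
#'
#' @param nl,lh,nh Character vectors of per-test status, each `"up"`,
#'   `"down"` or `"not-DE"` (`"up"` means significant under the `<`
#'   alternative of that pair).
#' @return Character vector of pattern labels, `"unclassified"`, or `NA`.
#' @export
assign_pattern <- function(nl, lh, nh) {
  nl <- check_status(nl, "NL"); lh <- check_status(lh, "LH")
  nh <- check_status(nh, "NH")
  stopifnot(length(nl) == length(lh), length(nl) == length(nh))
  vapply(seq_along(nl), function(i) {
    assign_pattern_one(nl[i], lh[i], nh[i])
  }, character(1))
}

assign_pattern_one <- function(nl, lh, nh) {
  sig <- c(nl, lh, nh) != "not-DE"
  if (sum(sig) < 2L) return(NA_character_)
  chain_nl_lh <- function(nl, lh)
    paste0("N", if (nl == "up") "<" else ">", "L",
           if (lh == "up") "<" else ">", "H")
  if (all(sig)) {
    if (nl == lh && nh != nl) return("unclassified")
    return(chain_nl_lh(nl, lh))
  }
  if (sig[1L] && sig[2L]) return(chain_nl_lh(nl, lh))
  if (sig[1L] && sig[3L])  # relations N-L and N-H, chain L ? N ? H
    return(paste0("L", if (nl == "up") ">" else "<", "N",
                  if (nh == "up") "<" else ">", "H"))
  # relations L-H and N-H, chain L ? H ? N
  paste0("L", if (lh == "up") "<" else ">", "H",
         if (nh == "up") ">" else "<", "N")
}

#' Count probes per ordering pattern
#'
#' Tabulates classified probes over all twelve pattern labels (zero rows
#' included) plus an `"unclassified"` row when any inconsistent triples were
#' seen.
#'
#' @param patterns Character vector of labels as returned by
#'   [assign_pattern()]; `NA` entries (fewer than two significant tests) are
#'   ignored.
#' @return Data frame with columns `pattern` and `n`; the 12 labels always
#'   present in canonical order.
#' @export
summarize_patterns <- function(patterns) {
  patterns <- patterns[!is.na(patterns)]
  labs <- pattern_labels()
  n <- vapply(labs, function(l) sum(patterns == l), numeric(1))
  out <- data.frame(pattern = labs, n = unname(n), stringsAsFactors = FALSE)
  n_unc <- sum(patterns == "unclassified")
  if (n_unc > 0L)
    out <- rbind(out, data.frame(pattern = "unclassified", n = n_unc))
  out
}
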