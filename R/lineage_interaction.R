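# Mutation x lineage interaction tests and the lineage-subtraction internal
# cross-validation: lineages that individually interact with a biomarker are
# removed, and the biomarker is re-tested on the remaining cell lines.

#' Enumerate event-lineage pairs
#'
#' One entry per (locus, lineage) combination carried by at least one cell
#' line, with its panel-wide carrier count.
#'
#' @param matrix An `event_matrix` with lineage annotations.
#' @return Data frame with columns `locus`, `lineage`, `count`, sorted by
#'   locus then lineage.
#' @export
enumerate_event_lineage_pairs <- function(matrix) {
  lin <- matrix_lineages(matrix)
  ev <- matrix$events
  counts <- rowsum(ev * 1L, group = lin)  # lineage x locus counts
  idx <- which(counts > 0, arr.ind = TRUE)
  out <- data.frame(
    locus = colnames(counts)[idx[, 2]],
    lineage = rownames(counts)[idx[, 1]],
    count = counts[idx],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$locus, out$lineage), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Test an event-lineage pair against the sensitive/resistant split
#'
#' Carriers are tested cell lines of the given lineage bearing all the given
#' loci. The default `proportional_gof` null splits the `m` carriers between
#' S and R in proportion to the group sizes and applies the 1-df
#' observed-vs-predicted chi-square; `fisher_2x2` instead tests carriers
#' versus non-carriers against S/R membership with Fisher's exact test.
#'
#' @param loci Character vector of 1-3 locus identifiers.
#' @param lineage_label A single lineage label.
#' @param matrix An `event_matrix` with lineage annotations.
#' @param call A non-degenerate `response_call`.
#' @param null `"proportional_gof"` (default) or `"fisher_2x2"`.
#' @param alpha Significance level.
#' @param min_carriers Minimum carriers required to test (default 3);
#'   smaller pairs are returned untested (`p_value = NA`).
#' @return One-row data frame with columns `loci`, `lineage`, `drug`,
#'   `count_S`, `count_R`, `expected_S`, `expected_R`, `chi2`, `p_value`,
#'   `significant`.
#' @export
test_event_lineage_association <- function(loci, lineage_label, matrix, call,
                                           null = c("proportional_gof", "fisher_2x2"),
                                           alpha = 0.05, min_carriers = 3L) {
  null <- match.arg(null)
  grp <- association_groups(matrix, call)
  lin <- matrix_lineages(matrix)
  carriers <- carrier_lines(matrix, loci)
  carriers <- carriers[lin[carriers] == lineage_label]
  cS <- sum(carriers %in% grp$S)
  cR <- sum(carriers %in% grp$R)
  m <- cS + cR
  n_S <- length(grp$S); n_R <- length(grp$R); n <- n_S + n_R
  eS <- m * n_S / n
  eR <- m * n_R / n
  chi2 <- p <- NA_real_
  if (m >= min_carriers) {
    if (null == "proportional_gof") {
      r <- chisq_obs_vs_pred(cS, eS, m)
      chi2 <- r$chi2; p <- r$p_value
    } else {
      p <- stats::fisher.test(matrix(c(cS, n_S - cS, cR, n_R - cR),
                                     nrow = 2, byrow = TRUE))$p.value
    }
  }
  data.frame(
    loci = paste(sort(loci), collapse = "::"), lineage = lineage_label,
    drug = call$drug, count_S = cS, count_R = cR,
    expected_S = eS, expected_R = eR, chi2 = chi2, p_value = p,
    significant = !is.na(p) & p <= alpha,
    stringsAsFactors = FALSE
  )
}

#' Scan all lineages for interaction with one event tuple
#'
#' @inheritParams test_event_lineage_association
#' @return Data frame, one row per lineage in which the tuple occurs among
#'   tested lines.
#' @export
scan_lineage_interactions <- function(loci, matrix, call,
                                      null = c("proportional_gof", "fisher_2x2"),
                                      alpha = 0.05, min_carriers = 3L) {
  null <- match.arg(null)
  lin <- matrix_lineages(matrix)
  grp <- association_groups(matrix, call)
  carriers <- carrier_lines(matrix, loci)
  carriers <- carriers[carriers %in% c(grp$S, grp$R)]
  lineages <- sort(unique(lin[carriers]))
  out <- do.call(rbind, lapply(lineages, function(L) {
    test_event_lineage_association(loci, L, matrix, call, null = null,
                                   alpha = alpha, min_carriers = min_carriers)
  }))
  if (is.null(out)) {
    out <- data.frame(loci = character(0), lineage = character(0),
                      drug = character(0), count_S = integer(0),
                      count_R = integer(0), expected_S = numeric(0),
                      expected_R = numeric(0), chi2 = numeric(0),
                      p_value = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Re-test an event tuple after subtracting interacting lineages
#'
#' Cell lines whose lineage individually interacted with the tuple are
#' removed, and the association of the tuple with sensitivity/resistance is
#' recomputed on the remainder: Fisher's exact test for single loci, the
#' 2x2 Pearson chi-square for co-events. The result is flagged `powered`
#' only when the event still occurs in more than `min_prevalence` of the
#' remaining sensitive or resistant lines; "no power" is a first-class
#' state, never an exception.
#'
#' @param loci Character vector of 1-3 loci.
#' @param matrix An `event_matrix` with lineage annotations.
#' @param call A non-degenerate `response_call`.
#' @param significant_lineages Lineage labels to subtract (usually the
#'   significant rows of [scan_lineage_interactions()]).
#' @param min_prevalence Prevalence filter for the `powered` flag (default
#'   0.12).
#' @param fold Fold threshold for the reported direction (default 1.5).
#' @param alpha Significance level for the `significant` flag.
#' @return One-row data frame with `loci`, `drug`, `removed_lineages`,
#'   `n_remaining`, `n_S`, `n_R`, `count_S`, `count_R`, `sr_ratio`,
#'   `p_value`, `direction`, `powered`, `significant`.
#' @export
subtract_and_retest <- function(loci, matrix, call, significant_lineages,
                                min_prevalence = 0.12, fold = 1.5,
                                alpha = 0.05) {
  grp <- association_groups(matrix, call)
  lin <- matrix_lineages(matrix)
  keep_line <- function(cl) !(lin[cl] %in% significant_lineages)
  S <- grp$S[keep_line(grp$S)]
  R <- grp$R[keep_line(grp$R)]
  carriers <- carrier_lines(matrix, loci)
  cS <- sum(S %in% carriers)
  cR <- sum(R %in% carriers)
  n_S <- length(S); n_R <- length(R)
  freq_S <- if (n_S > 0) cS / n_S else 0
  freq_R <- if (n_R > 0) cR / n_R else 0
  powered <- (cS + cR) > 0 &&
    (freq_S > min_prevalence || freq_R > min_prevalence)
  p <- NA_real_
  if (n_S > 0 && n_R > 0 && (cS + cR) > 0) {
    tab <- matrix(c(cS, n_S - cS, cR, n_R - cR), nrow = 2, byrow = TRUE)
    p <- if (length(loci) == 1L) {
      stats::fisher.test(tab)$p.value
    } else {
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    }
  }
  sr <- if (cR > 0) freq_S / freq_R else if (cS > 0) Inf else NaN
  direction <- "none"
  if (!is.nan(sr) && sr > fold) direction <- "sensitive"
  if (!is.nan(sr) && sr < 1 / fold) direction <- "resistant"
  data.frame(
    loci = paste(sort(loci), collapse = "::"), drug = call$drug,
    removed_lineages = paste(sort(unique(significant_lineages)), collapse = ","),
    n_remaining = n_S + n_R, n_S = n_S, n_R = n_R,
    count_S = cS, count_R = cR, sr_ratio = sr, p_value = p,
    direction = direction, powered = powered,
    significant = !is.na(p) & p <= alpha,
    stringsAsFactors = FALSE
  )
}

#' Lineage interaction and subtraction for a list of event tuples
#'
#' For each tuple: scan lineage interactions, subtract the lineages that
#' reached significance, and re-test the tuple on the remaining lines.
#'
#' @param loci_list List of character vectors (tuples of 1-3 loci).
#' @param matrix An `event_matrix` with lineage annotations.
#' @param call A non-degenerate `response_call`.
#' @param null Lineage-test null, see [test_event_lineage_association()].
#' @param alpha Significance level.
#' @param min_prevalence,fold Passed to [subtract_and_retest()].
#' @return List with `lineage_tests` (row-bound scan results) and
#'   `residual` (row-bound re-test results).
#' @export
lineage_subtraction_analysis <- function(loci_list, matrix, call,
                                         null = "proportional_gof",
                                         alpha = 0.05,
                                         min_prevalence = 0.12, fold = 1.5) {
  scans <- lapply(loci_list, scan_lineage_interactions, matrix = matrix,
                  call = call, null = null, alpha = alpha)
  residual <- mapply(function(loci, sc) {
    sig <- sc$lineage[sc$significant]
    subtract_and_retest(loci, matrix, call, sig,
                        min_prevalence = min_prevalence, fold = fold,
                        alpha = alpha)
  }, loci_list, scans, SIMPLIFY = FALSE)
  list(lineage_tests = do.call(rbind, scans),
       residual = do.call(rbind, residual))
}

#' Summarise lineage-independent associations
#'
#' Counts the fraction of co-events whose residual (post-subtraction)
#' association stays significant at each level, over the powered results.
#' An optional exclusion list removes tuples containing any of the given
#' loci before counting (e.g. to look past near-universal tumour-suppressor
#' events).
#'
#' @param results Data frame of [subtract_and_retest()] rows.
#' @param alphas Significance levels to summarise (default `c(0.05, 0.10)`).
#' @param exclude_loci Optional locus identifiers; tuples containing any of
#'   them are excluded from the summary.
#' @return Data frame with columns `alpha`, `n_tested`, `n_significant`,
#'   `fraction`.
#' @export
lineage_independence_summary <- function(results, alphas = c(0.05, 0.10),
                                         exclude_loci = NULL) {
  if (nrow(results) == 0) stop("no results to summarise", call. = FALSE)
  res <- results
  if (!is.null(exclude_loci) && length(exclude_loci)) {
    parts <- strsplit(res$loci, "::", fixed = TRUE)
    drop <- vapply(parts, function(p) any(p %in% exclude_loci), logical(1))
    res <- res[!drop, , drop = FALSE]
  }
  res <- res[res$powered & !is.na(res$p_value), , drop = FALSE]
  do.call(rbind, lapply(alphas, function(a) {
    n_sig <- sum(res$p_value <= a)
    data.frame(alpha = a, n_tested = nrow(res), n_significant = n_sig,
               fraction = if (nrow(res) > 0) n_sig / nrow(res) else NA_real_)
  }))
}

# --- internal ----------------------------------------------------------------

matrix_lineages <- function(matrix) {
  if (is.null(matrix$lineage)) {
    stop("event matrix has no lineage annotations", call. = FALSE)
  }
  stats::setNames(lineage_of(matrix$lineage, rownames(matrix$events)),
                  rownames(matrix$events))
}

carrier_lines <- function(matrix, loci) {
  missing <- setdiff(loci, colnames(matrix$events))
  if (length(missing)) {
    stop(sprintf("loci not in matrix: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  sub <- matrix$events[, loci, drop = FALSE]
  rownames(sub)[rowSums(sub) == length(loci)]
}
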