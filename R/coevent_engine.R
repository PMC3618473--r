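# Co-event statistics: enumeration of event tuples, the independence model
# for predicted co-occurrence, the observed-vs-predicted chi-square,
# disequilibrium classification, and per-drug association scoring.

#' Enumerate event tuples of size k
#'
#' The potential space is all `choose(G, k)` tuples over the loci that carry
#' at least one event in the matrix; the observed tuples are those carried
#' jointly by at least one cell line, with the count of cell lines carrying
#' all `k` events.
#'
#' @param matrix An `event_matrix` (loci with zero events are dropped before
#'   enumeration, and recorded in the `dropped_loci` attribute of the
#'   result).
#' @param k Tuple size, 2 or 3.
#' @return A list with `potential_space` (a count), `loci_used`, and
#'   `tuples`: a data frame with the locus identifiers (`locus1`, ...,
#'   canonically sorted within each tuple) and `count`.
#' @export
enumerate_event_tuples <- function(matrix, k = 2L) {
  if (!k %in% c(2L, 3L)) stop("k must be 2 or 3", call. = FALSE)
  m <- subset_event_matrix(matrix, drop_empty_loci = TRUE)
  ev <- m$events
  G <- ncol(ev)
  potential <- choose(G, k)
  if (k == 2L) {
    cnt <- crossprod(ev * 1L)
    idx <- which(upper.tri(cnt) & cnt > 0, arr.ind = TRUE)
    tuples <- data.frame(
      locus1 = colnames(ev)[idx[, 1]],
      locus2 = colnames(ev)[idx[, 2]],
      count = cnt[idx],
      stringsAsFactors = FALSE
    )
    tuples <- tuples[order(tuples$locus1, tuples$locus2), , drop = FALSE]
  } else {
    per_line <- lapply(seq_len(nrow(ev)), function(i) {
      hits <- which(ev[i, ])
      if (length(hits) < 3) return(NULL)
      t(utils::combn(colnames(ev)[hits], 3))
    })
    all_triples <- do.call(rbind, per_line)
    if (is.null(all_triples)) {
      tuples <- data.frame(locus1 = character(0), locus2 = character(0),
                           locus3 = character(0), count = integer(0),
                           stringsAsFactors = FALSE)
    } else {
      key <- paste(all_triples[, 1], all_triples[, 2], all_triples[, 3],
                   sep = "::")
      tab <- table(key)
      parts <- do.call(rbind, strsplit(names(tab), "::", fixed = TRUE))
      tuples <- data.frame(locus1 = parts[, 1], locus2 = parts[, 2],
                           locus3 = parts[, 3],
                           count = as.integer(tab),
                           stringsAsFactors = FALSE)
      tuples <- tuples[order(tuples$locus1, tuples$locus2, tuples$locus3), ,
                       drop = FALSE]
    }
  }
  rownames(tuples) <- NULL
  list(potential_space = potential, loci_used = colnames(ev),
       dropped_loci = attr(m, "dropped_loci"), tuples = tuples)
}

#' Predicted co-occurrence under the independence model
#'
#' If events arise independently, the predicted co-event frequency is the
#' product of the marginal locus frequencies, and the predicted count is
#' `N` times that product. In `rounded` mode the predicted count is
#' rounded to the nearest integer (half away from zero) before any test, so
#' that printed integer "predicted" columns can be reproduced exactly;
#' `exact` mode keeps the raw expectation.
#'
#' @param marginal_freqs Numeric vector of 2 or 3 marginal frequencies in
#'   `[0, 1]`.
#' @param N Number of cell lines.
#' @param rounding `"rounded"` (default) or `"exact"`.
#' @return List with `E_raw` and `E`.
#' @export
predicted_cooccurrence <- function(marginal_freqs, N,
                                   rounding = c("rounded", "exact")) {
  rounding <- match.arg(rounding)
  stopifnot(all(marginal_freqs >= 0), all(marginal_freqs <= 1), N >= 1)
  E_raw <- N * prod(marginal_freqs)
  E <- if (rounding == "rounded") round_half_away(E_raw) else E_raw
  list(E_raw = E_raw, E = E)
}

#' Observed-vs-predicted chi-square for a co-event count
#'
#' Two-cell goodness-of-fit over \{co-event, no co-event\}:
#' `chi2 = (O - E)^2 * (1/E + 1/(N - E))`, compared to a chi-square
#' distribution with 1 degree of freedom (upper tail). The predicted count
#' `E` is treated as fixed. Tables with `E <= 0` or `E >= N` are untestable
#' and flagged rather than producing a silent `NaN`.
#'
#' @param O Observed co-event count (0..N).
#' @param E Predicted co-event count (0 < E < N for a testable result).
#' @param N Number of cell lines.
#' @return List with `chi2`, `p_value` and `untestable`.
#' @export
chisq_obs_vs_pred <- function(O, E, N) {
  stopifnot(O >= 0, O <= N)
  if (E <= 0 || E >= N) {
    return(list(chi2 = NA_real_, p_value = NA_real_, untestable = TRUE))
  }
  chi2 <- (O - E)^2 * (1 / E + 1 / (N - E))
  list(chi2 = chi2,
       p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       untestable = FALSE)
}

#' Classify pairwise disequilibrium
#'
#' Mutually exclusive: never observed together (`O = 0`) with significantly
#' nonzero prediction. Partially exclusive: observed together, but
#' significantly below prediction. Co-selected: observed significantly above
#' prediction. Anything non-significant (or untestable) is `"none"`.
#'
#' @param observed_freq,predicted_freq Observed and predicted co-event
#'   frequencies.
#' @param O Observed count.
#' @param p_value Chi-square p-value from [chisq_obs_vs_pred()] (may be
#'   `NA` for untestable tuples).
#' @param alpha Significance level (default 0.05).
#' @return One of `"co_selected"`, `"partially_exclusive"`,
#'   `"mutually_exclusive"`, `"none"`.
#' @export
classify_disequilibrium <- function(observed_freq, predicted_freq, O,
                                    p_value, alpha = 0.05) {
  if (is.na(p_value) || p_value > alpha) return("none")
  if (O == 0 && predicted_freq > 0) return("mutually_exclusive")
  if (observed_freq > predicted_freq) return("co_selected")
  if (observed_freq > 0 && observed_freq < predicted_freq) {
    return("partially_exclusive")
  }
  "none"
}

#' Population-wide disequilibrium scan
#'
#' Scores every tuple in the potential space (pairs) or every observed tuple
#' (triples) against the independence model and classifies each as
#' co-selected, partially exclusive, mutually exclusive, or none. Pairs with
#' zero observed count are retained: strict exclusivity is only visible
#' there. Results are ordered by the observed-minus-predicted frequency
#' difference, most negative first.
#'
#' @param matrix An `event_matrix`.
#' @param k Tuple size (2 or 3). Triples are scored only over tuples
#'   observed at least once, the potential triple space being too large to
#'   materialise.
#' @param alpha Significance level for classification.
#' @param rounding Predicted-count mode, see [predicted_cooccurrence()].
#' @param correction Optional multiple-testing mask to attach: `"none"`,
#'   `"bh"` or `"bonferroni"` (computed over testable tuples at level
#'   `alpha`).
#' @param subset Optional cell-line subset over which counts and marginals
#'   are computed.
#' @return A data frame of class `coevent_result` with columns `loci`,
#'   `n_total`, `observed_count`, `predicted_count_raw`, `predicted_count`,
#'   `observed_freq`, `predicted_freq`, `difference`, `chi2`, `p_value`,
#'   `untestable`, `class`, and (unless `correction = "none"`)
#'   `significant_corrected`.
#' @export
population_disequilibrium_scan <- function(matrix, k = 2L, alpha = 0.05,
                                           rounding = c("rounded", "exact"),
                                           correction = c("none", "bh", "bonferroni"),
                                           subset = NULL) {
  rounding <- match.arg(rounding)
  correction <- match.arg(correction)
  if (!k %in% c(2L, 3L)) stop("k must be 2 or 3", call. = FALSE)
  m <- subset_event_matrix(matrix, cell_lines = subset, drop_empty_loci = TRUE)
  ev <- m$events
  N <- nrow(ev)
  f <- colMeans(ev)
  if (k == 2L) {
    cnt <- crossprod(ev * 1L)
    idx <- which(upper.tri(cnt), arr.ind = TRUE)
    O <- cnt[idx]
    E_raw <- N * f[idx[, 1]] * f[idx[, 2]]
    lab <- paste(colnames(ev)[idx[, 1]], colnames(ev)[idx[, 2]], sep = "::")
  } else {
    en <- enumerate_event_tuples(m, 3L)
    tp <- en$tuples
    O <- tp$count
    E_raw <- N * f[tp$locus1] * f[tp$locus2] * f[tp$locus3]
    lab <- paste(tp$locus1, tp$locus2, tp$locus3, sep = "::")
  }
  E <- if (rounding == "rounded") round_half_away(E_raw) else E_raw
  untestable <- E <= 0 | E >= N
  chi2 <- ifelse(untestable, NA_real_, (O - E)^2 * (1 / E + 1 / (N - E)))
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  obs_f <- O / N
  pred_f <- E_raw / N
  klass <- rep("none", length(O))
  sig <- !is.na(p) & p <= alpha
  klass[sig & O == 0 & pred_f > 0] <- "mutually_exclusive"
  klass[sig & obs_f > pred_f] <- "co_selected"
  klass[sig & O > 0 & obs_f < pred_f] <- "partially_exclusive"
  out <- data.frame(
    loci = unname(lab), n_total = N, observed_count = unname(O),
    predicted_count_raw = unname(E_raw), predicted_count = unname(E),
    observed_freq = unname(obs_f), predicted_freq = unname(pred_f),
    difference = unname(obs_f - pred_f), chi2 = unname(chi2),
    p_value = unname(p), untestable = unname(untestable),
    class = klass, stringsAsFactors = FALSE
  )
  if (correction != "none") {
    out$significant_corrected <- FALSE
    testable <- !out$untestable
    mt <- multiple_testing(out$p_value[testable], method = correction, q = alpha)
    out$significant_corrected[testable] <- mt$significant
  }
  out <- out[order(out$difference, out$loci), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("coevent_result", "data.frame")
  out
}

#' Single-event association with drug sensitivity
#'
#' For every locus, compares event frequency among sensitive versus
#' resistant lines (restricted to lines with genomic characterisation).
#' Two-sided Fisher's exact test; the S/R frequency ratio carries an `Inf`
#' sentinel when the event is absent from the resistant group. An event is
#' `powered` when it occurs in more than `min_prevalence` of the sensitive
#' or of the resistant lines.
#'
#' @param matrix An `event_matrix`.
#' @param call A non-degenerate `response_call`.
#' @param min_prevalence Prevalence filter (default 0.12).
#' @param fold Fold-change threshold: direction `sensitive` when the S/R
#'   ratio exceeds `fold`, `resistant` when below `1/fold` (default 1.5).
#' @return Data frame with columns `drug`, `loci`, `tuple_size`, `n_S`,
#'   `n_R`, `count_S`, `count_R`, `freq_S`, `freq_R`, `sr_ratio`,
#'   `p_value`, `direction`, `powered`.
#' @export
single_event_drug_association <- function(matrix, call,
                                          min_prevalence = 0.12,
                                          fold = 1.5) {
  grp <- association_groups(matrix, call)
  evS <- matrix$events[grp$S, , drop = FALSE]
  evR <- matrix$events[grp$R, , drop = FALSE]
  count_S <- colSums(evS)
  count_R <- colSums(evR)
  keep <- count_S + count_R > 0
  count_S <- count_S[keep]; count_R <- count_R[keep]
  n_S <- length(grp$S); n_R <- length(grp$R)
  p <- mapply(function(cs, cr) {
    stats::fisher.test(matrix(c(cs, n_S - cs, cr, n_R - cr), nrow = 2,
                              byrow = TRUE))$p.value
  }, count_S, count_R)
  build_assoc_frame(call$drug, names(count_S), 1L, n_S, n_R, count_S, count_R,
                    p, min_prevalence, fold)
}

#' Co-event association with drug sensitivity
#'
#' For every observed event tuple of size `k` among the genomically
#' characterised, drug-tested lines, tests whether the tuple's frequency
#' differs between sensitive and resistant lines. The primary p-value is
#' the Pearson chi-square on the 2x2 table (co-event presence x S/R
#' membership, no continuity correction); the Yates-corrected variant is
#' reported alongside as `p_value_yates`. As a secondary diagnostic, the
#' observed-vs-predicted goodness of fit is computed within the sensitive
#' and within the resistant subpopulation, using marginals from that
#' subpopulation (or panel-wide marginals with
#' `subpop_marginals = "whole"`).
#'
#' @inheritParams single_event_drug_association
#' @param k Tuple size, 2 or 3.
#' @param min_count Minimum number of cell lines carrying the co-event
#'   (default 4); smaller tuples are excluded.
#' @param alpha Significance level for the `selected` flag.
#' @param subpop_marginals Marginals used for the within-subpopulation
#'   diagnostics: `"subpopulation"` (default) or `"whole"`.
#' @param rounding Predicted-count mode for the diagnostics.
#' @return Data frame as in [single_event_drug_association()], plus
#'   `p_value_yates`, `chi2_S`, `p_S`, `chi2_R`, `p_R`, `selected`.
#' @export
coevent_drug_association <- function(matrix, call, k = 2L, min_count = 4L,
                                     fold = 1.5, alpha = 0.05,
                                     min_prevalence = 0.12,
                                     subpop_marginals = c("subpopulation", "whole"),
                                     rounding = c("rounded", "exact")) {
  subpop_marginals <- match.arg(subpop_marginals)
  rounding <- match.arg(rounding)
  grp <- association_groups(matrix, call)
  tested <- c(grp$S, grp$R)
  sub <- subset_event_matrix(matrix, cell_lines = tested, drop_empty_loci = TRUE)
  en <- enumerate_event_tuples(sub, k)
  tp <- en$tuples
  if (nrow(tp) == 0) return(empty_assoc_frame(coevent = TRUE))
  loci_cols <- grep("^locus", names(tp), value = TRUE)
  ev <- sub$events
  carrier <- Reduce(`&`, lapply(loci_cols, function(cc) ev[, tp[[cc]], drop = FALSE]))
  # carrier: lines x tuples logical
  inS <- rownames(ev) %in% grp$S
  count_S <- colSums(carrier[inS, , drop = FALSE])
  count_R <- colSums(carrier[!inS, , drop = FALSE])
  tot <- count_S + count_R
  keep <- tot >= min_count
  if (!any(keep)) return(empty_assoc_frame(coevent = TRUE))
  tp <- tp[keep, , drop = FALSE]
  count_S <- count_S[keep]; count_R <- count_R[keep]
  n_S <- sum(inS); n_R <- sum(!inS)
  p_plain <- p_yates <- numeric(nrow(tp))
  for (i in seq_len(nrow(tp))) {
    tab <- matrix(c(count_S[i], n_S - count_S[i],
                    count_R[i], n_R - count_R[i]), nrow = 2, byrow = TRUE)
    p_plain[i] <- suppressWarnings(
      stats::chisq.test(tab, correct = FALSE)$p.value)
    p_yates[i] <- suppressWarnings(
      stats::chisq.test(tab, correct = TRUE)$p.value)
  }
  lab <- do.call(paste, c(tp[loci_cols], sep = "::"))
  out <- build_assoc_frame(call$drug, lab, as.integer(k), n_S, n_R,
                           count_S, count_R, p_plain, min_prevalence, fold)
  out$p_value_yates <- p_yates
  # secondary diagnostics: obs vs predicted within each subpopulation
  fS <- locus_frequencies(sub, subset = grp$S)
  fR <- locus_frequencies(sub, subset = grp$R)
  if (subpop_marginals == "whole") {
    fS <- fR <- locus_frequencies(sub)
  }
  diag_one <- function(freqs, counts, n) {
    E <- vapply(seq_len(nrow(tp)), function(i) {
      predicted_cooccurrence(freqs[unlist(tp[i, loci_cols])], n, rounding)$E
    }, numeric(1))
    t(vapply(seq_len(nrow(tp)), function(i) {
      r <- chisq_obs_vs_pred(counts[i], E[i], n)
      c(r$chi2, r$p_value)
    }, numeric(2)))
  }
  dS <- diag_one(fS, count_S, n_S)
  dR <- diag_one(fR, count_R, n_R)
  out$chi2_S <- dS[, 1]; out$p_S <- dS[, 2]
  out$chi2_R <- dR[, 1]; out$p_R <- dR[, 2]
  out$selected <- !is.na(out$p_value) & out$p_value <= alpha &
    (out$sr_ratio > fold | out$sr_ratio < 1 / fold)
  out
}

#' Multiple-testing correction
#'
#' Benjamini-Hochberg step-up control of the false discovery rate, or the
#' Bonferroni bound, at level `q`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (NAs are never
#'   significant).
#' @param method `"bh"`, `"bonferroni"` or `"none"`.
#' @param q FDR level / family-wise level (default 0.05).
#' @return List of class `multiple_testing_result` with `p_values`,
#'   `method`, `q`, `significant` (logical mask) and `threshold` (largest
#'   p-value rejected; 0 when none).
#' @export
multiple_testing <- function(p_values, method = c("bh", "bonferroni", "none"),
                             q = 0.05) {
  method <- match.arg(method)
  p <- p_values
  if (length(p) == 0) {
    return(structure(list(p_values = p, method = method, q = q,
                          significant = logical(0), threshold = 0),
                     class = "multiple_testing_result"))
  }
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  sig <- switch(method,
    none = !is.na(p) & p <= q,
    bonferroni = !is.na(p) & stats::p.adjust(p, "bonferroni") <= q,
    bh = !is.na(p) & stats::p.adjust(p, "BH") <= q
  )
  thr <- if (any(sig)) max(p[sig]) else 0
  structure(list(p_values = p, method = method, q = q, significant = sig,
                 threshold = thr),
            class = "multiple_testing_result")
}

#' Rank drug-association results by the reporting key
#'
#' Filters to `p <= alpha` and orders by ascending p-value, then descending
#' co-event cell-line count, then descending distance of the S/R ratio from
#' unity on the log scale (the `Inf` sentinel outranks every finite ratio),
#' with deterministic ties by locus tuple.
#'
#' @param results Data frame from [single_event_drug_association()] or
#'   [coevent_drug_association()].
#' @param alpha Significance filter (default 0.05).
#' @return The filtered, reordered data frame.
#' @export
rank_top_events <- function(results, alpha = 0.05) {
  keep <- !is.na(results$p_value) & results$p_value <= alpha
  res <- results[keep, , drop = FALSE]
  if (nrow(res) == 0) return(res)
  count <- res$count_S + res$count_R
  dist_unity <- abs(log(res$sr_ratio))
  dist_unity[res$sr_ratio == 0] <- Inf   # 0 is as far from unity as Inf
  res <- res[order(res$p_value, -count, -dist_unity, res$loci), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# --- internal ----------------------------------------------------------------

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Intersect a response call with the genomically characterised lines.
association_groups <- function(matrix, call) {
  if (isTRUE(call$degenerate)) {
    stop("response call is degenerate; no S/R partition", call. = FALSE)
  }
  S <- intersect(call$sensitive, rownames(matrix$events))
  R <- intersect(call$resistant, rownames(matrix$events))
  if (length(S) == 0 || length(R) == 0) {
    stop("empty sensitive or resistant group after intersecting with genomic data",
         call. = FALSE)
  }
  list(S = S, R = R)
}

build_assoc_frame <- function(drug, lab, tuple_size, n_S, n_R,
                              count_S, count_R, p, min_prevalence, fold) {
  freq_S <- count_S / n_S
  freq_R <- count_R / n_R
  sr <- ifelse(count_R > 0, freq_S / freq_R,
               ifelse(count_S > 0, Inf, NaN))
  direction <- rep("none", length(sr))
  direction[!is.nan(sr) & sr > fold] <- "sensitive"
  direction[!is.nan(sr) & sr < 1 / fold] <- "resistant"
  out <- data.frame(
    drug = drug, loci = unname(lab), tuple_size = tuple_size,
    n_S = n_S, n_R = n_R,
    count_S = unname(count_S), count_R = unname(count_R),
    freq_S = unname(freq_S), freq_R = unname(freq_R),
    sr_ratio = unname(sr), p_value = unname(p),
    direction = direction,
    powered = unname(freq_S > min_prevalence | freq_R > min_prevalence),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$loci), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_assoc_frame <- function(coevent = FALSE) {
  out <- data.frame(
    drug = character(0), loci = character(0), tuple_size = integer(0),
    n_S = integer(0), n_R = integer(0), count_S = integer(0),
    count_R = integer(0), freq_S = numeric(0), freq_R = numeric(0),
    sr_ratio = numeric(0), p_value = numeric(0), direction = character(0),
    powered = logical(0), stringsAsFactors = FALSE
  )
  if (coevent) {
    out$p_value_yates <- numeric(0)
    out$chi2_S <- numeric(0); out$p_S <- numeric(0)
    out$chi2_R <- numeric(0); out$p_R <- numeric(0)
    out$selected <- logical(0)
  }
  out
}
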