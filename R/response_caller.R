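# Sensitive/resistant calling from the rank-ordered growth-inhibition curve.
#
# The per-drug GI profile (gIC50 in nM, or a 72-h viability ratio) is rank
# ordered, modelled as a high-order polynomial on a rescaled [0,1] rank axis,
# and the partition boundary is placed at the first rank where the absolute
# second derivative of the fitted curve attains its interior maximum.

#' Construct a drug screen
#'
#' @param drug Drug identifier.
#' @param gi Named numeric vector of growth-inhibition values (names are
#'   cell lines). Lower GI means more sensitive. Untested cell lines are
#'   simply absent.
#' @param assay_mode `"gic50_nm"` (GI in nM) or `"viability_ratio"`
#'   (dimensionless fraction of viable cells after 72 h).
#' @return An object of class `drug_screen`.
#' @export
drug_screen <- function(drug, gi, assay_mode = c("gic50_nm", "viability_ratio")) {
  assay_mode <- match.arg(assay_mode)
  stopifnot(is.numeric(gi), !is.null(names(gi)), all(nzchar(names(gi))))
  if (anyDuplicated(names(gi))) stop("duplicate cell lines in screen", call. = FALSE)
  if (any(!is.finite(gi))) stop("GI values must be finite", call. = FALSE)
  if (assay_mode == "viability_ratio" && any(gi < 0)) {
    stop("viability ratios must be non-negative", call. = FALSE)
  }
  structure(list(drug = drug, assay_mode = assay_mode, gi = gi),
            class = "drug_screen")
}

#' @export
print.drug_screen <- function(x, ...) {
  cat(sprintf("drug_screen '%s' (%s): %d cell lines, GI range [%g, %g]\n",
              x$drug, x$assay_mode, length(x$gi), min(x$gi), max(x$gi)))
  invisible(x)
}

#' Rank-order a GI profile
#'
#' Orders tested cell lines by ascending GI, ties broken lexicographically
#' by cell-line identifier. Ranks are 0-based.
#'
#' @param screen A `drug_screen`.
#' @param min_lines Minimum number of tested lines required for a
#'   non-degenerate call (default 10).
#' @return Data frame with columns `rank` (0..n-1), `cell_line`, `gi`.
#' @export
rank_order_profile <- function(screen, min_lines = 10L) {
  n <- length(screen$gi)
  if (n < min_lines) {
    stop(sprintf("screen '%s' has %d lines; %d required", screen$drug, n,
                 min_lines), call. = FALSE)
  }
  ord <- order(screen$gi, names(screen$gi))
  data.frame(rank = seq_len(n) - 1L,
             cell_line = names(screen$gi)[ord],
             gi = unname(screen$gi[ord]),
             stringsAsFactors = FALSE)
}

#' Fit a polynomial response curve
#'
#' Least-squares polynomial fit of GI against rank rescaled to `[0, 1]`.
#' If the Vandermonde system is ill-conditioned the degree is reduced until
#' the fit is stable; the degree actually used is reported.
#'
#' @param ordered Data frame from [rank_order_profile()].
#' @param degree Requested polynomial degree (default 9; must be at least 3
#'   and below the number of points).
#' @param cond_max Maximum acceptable condition number of the rescaled
#'   Vandermonde matrix before the degree is reduced. Default `1e10`.
#' @return A list of class `response_fit` with `coefficients` (highest
#'   degree first, on the rescaled axis), `degree` (degree used),
#'   `requested_degree`, `residual_norm` and `n`.
#' @export
fit_response_curve <- function(ordered, degree = 9L, cond_max = 1e10) {
  n <- nrow(ordered)
  if (degree < 3L) stop("degree must be at least 3", call. = FALSE)
  if (degree >= n) stop("degree must be below the number of points", call. = FALSE)
  x <- rescaled_ranks(n)
  y <- ordered$gi
  d <- as.integer(degree)
  repeat {
    V <- outer(x, d:0, `^`)
    if (d == 3L || kappa(V, exact = FALSE) <= cond_max) break
    d <- d - 1L
  }
  coef <- pracma::polyfit(x, y, d)
  res <- sqrt(sum((pracma::polyval(coef, x) - y)^2))
  structure(list(coefficients = coef, degree = d,
                 requested_degree = as.integer(degree),
                 residual_norm = res, n = n),
            class = "response_fit")
}

#' Locate the inflection point of a fitted response curve
#'
#' Evaluates the analytic second derivative of the fitted polynomial at the
#' rescaled rank positions and returns the smallest interior rank at which
#' the absolute second derivative attains its maximum (the first instance of
#' the largest absolute curvature). Endpoint ranks are excluded because
#' polynomial fits ring at the boundary. The call is degenerate when the
#' interior maximum falls below an absolute floor (flat or linear profiles).
#'
#' @param fit A `response_fit`, or a numeric coefficient vector (highest
#'   degree first) on the rescaled axis.
#' @param n Number of rank positions (taken from the fit if omitted).
#' @param tol Relative tolerance within which curvature values count as
#'   attaining the maximum; the first such rank is returned. Default 1e-9.
#' @param floor Absolute curvature below which the profile is declared
#'   degenerate. Default 1e-8.
#' @param edge_exclude Fraction of ranks excluded from the extremum search
#'   at each end of the curve (at least one rank). Least-squares polynomial
#'   fits ring over a boundary layer a few ranks wide, so the default
#'   excludes 5% of ranks per side.
#' @param first_local If `TRUE`, return the first interior local maximum of
#'   the absolute second derivative instead of the first attainment of the
#'   global maximum. Default `FALSE`.
#' @return A list with `inflection_index` (0-based rank, `NA` if degenerate)
#'   and `degenerate`.
#' @export
find_inflection_point <- function(fit, n = NULL, tol = 1e-9, floor = 1e-8,
                                  edge_exclude = 0.05, first_local = FALSE) {
  if (inherits(fit, "response_fit")) {
    coef <- fit$coefficients
    if (is.null(n)) n <- fit$n
  } else {
    coef <- fit
    if (is.null(n)) stop("n is required with a raw coefficient vector", call. = FALSE)
  }
  if (length(coef) - 1L < 3L) {
    return(list(inflection_index = NA_integer_, degenerate = TRUE))
  }
  d2 <- pracma::polyder(pracma::polyder(coef))
  x <- rescaled_ranks(n)
  margin <- max(1L, ceiling(edge_exclude * n))
  interior <- (margin + 1L):(n - margin)
  curv <- abs(pracma::polyval(d2, x[interior]))
  mx <- max(curv)
  if (!is.finite(mx) || mx < floor) {
    return(list(inflection_index = NA_integer_, degenerate = TRUE))
  }
  if (first_local) {
    rising <- c(TRUE, diff(curv) > 0)
    falling <- c(diff(curv) < 0, TRUE)
    loc <- which(rising & falling & curv >= floor)
    i <- if (length(loc)) loc[1] else which(curv >= mx * (1 - tol))[1]
  } else {
    i <- which(curv >= mx * (1 - tol))[1]
  }
  list(inflection_index = interior[i] - 1L, degenerate = FALSE)
}

#' Partition a screen into sensitive and resistant cell lines
#'
#' In gIC50 mode the cutoff is the GI value at the inflection rank, so lines
#' ranked strictly before the inflection are sensitive. In viability mode
#' with a cap, the cutoff is the smaller of the inflection GI and the cap
#' (whichever gives the greater sensitivity). Lines whose GI equals the
#' cutoff are assigned resistant, so tied GI values never straddle the
#' boundary.
#'
#' @param screen A `drug_screen`.
#' @param inflection Result of [find_inflection_point()] for this screen.
#' @param cap Optional GI cap (conventionally 0.78 for viability-ratio
#'   screens; unused for gIC50 screens).
#' @param min_lines Passed to [rank_order_profile()].
#' @return An object of class `response_call` with elements `drug`,
#'   `ordered_cell_lines`, `gi` (ordered), `inflection_index`, `cutoff_gi`,
#'   `sensitive`, `resistant` and `degenerate`.
#' @export
classify_sensitivity <- function(screen, inflection, cap = NULL,
                                 min_lines = 10L) {
  ord <- rank_order_profile(screen, min_lines = min_lines)
  n <- nrow(ord)
  degenerate <- isTRUE(inflection$degenerate)
  cutoff <- NA_real_
  if (!degenerate) {
    # inflection_index is 0-based: it is the rank of the first resistant line
    cutoff <- ord$gi[inflection$inflection_index + 1L]
  }
  if (!is.null(cap) && screen$assay_mode == "viability_ratio") {
    cutoff <- if (degenerate) cap else min(cutoff, cap)
    degenerate <- FALSE
  }
  if (is.na(cutoff)) {
    return(structure(list(
      drug = screen$drug, ordered_cell_lines = ord$cell_line, gi = ord$gi,
      inflection_index = NA_integer_, cutoff_gi = NA_real_,
      sensitive = character(0), resistant = ord$cell_line,
      degenerate = TRUE
    ), class = "response_call"))
  }
  sens <- ord$gi < cutoff
  structure(list(
    drug = screen$drug,
    ordered_cell_lines = ord$cell_line,
    gi = ord$gi,
    inflection_index = if (isTRUE(inflection$degenerate)) NA_integer_ else
      inflection$inflection_index,
    cutoff_gi = cutoff,
    sensitive = ord$cell_line[sens],
    resistant = ord$cell_line[!sens],
    degenerate = FALSE
  ), class = "response_call")
}

#' @export
print.response_call <- function(x, ...) {
  cat(sprintf("response_call '%s': %d sensitive / %d resistant (cutoff %s%s)\n",
              x$drug, length(x$sensitive), length(x$resistant),
              format(x$cutoff_gi),
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Call sensitivity for one screen (fit + inflection + partition)
#'
#' Convenience wrapper running [rank_order_profile()],
#' [fit_response_curve()], [find_inflection_point()] and
#' [classify_sensitivity()]. The inflection point is always determined
#' independently per screen, so training and test cohorts of the same drug
#' get their own cutoffs.
#'
#' @inheritParams classify_sensitivity
#' @inheritParams fit_response_curve
#' @param cap GI cap for viability screens; default 0.78 in viability mode,
#'   none in gIC50 mode.
#' @return A `response_call`.
#' @export
call_response <- function(screen, degree = 9L,
                          cap = if (screen$assay_mode == "viability_ratio") 0.78 else NULL,
                          min_lines = 10L) {
  if (length(screen$gi) < min_lines) {
    return(structure(list(
      drug = screen$drug, ordered_cell_lines = names(screen$gi),
      gi = unname(screen$gi), inflection_index = NA_integer_,
      cutoff_gi = NA_real_, sensitive = character(0),
      resistant = names(screen$gi), degenerate = TRUE
    ), class = "response_call"))
  }
  ord <- rank_order_profile(screen, min_lines = min_lines)
  fit <- fit_response_curve(ord, degree = degree)
  infl <- find_inflection_point(fit)
  classify_sensitivity(screen, infl, cap = cap, min_lines = min_lines)
}

#' Read per-drug screens from a long-format TSV
#'
#' Expects columns `cell_line`, `drug`, `gi_value`, `assay_mode`.
#'
#' @param path Path to the TSV.
#' @return Named list of `drug_screen` objects (one per drug).
#' @export
read_screens_tsv <- function(path) {
  tab <- read_tsv_checked(path, c("cell_line", "drug", "gi_value", "assay_mode"))
  tab$gi_value <- as.numeric(tab$gi_value)
  out <- lapply(split(tab, tab$drug), function(d) {
    mode <- unique(d$assay_mode)
    if (length(mode) != 1) {
      stop(sprintf("drug '%s' has mixed assay modes", d$drug[1]), call. = FALSE)
    }
    drug_screen(d$drug[1], stats::setNames(d$gi_value, d$cell_line), mode)
  })
  out[order(names(out))]
}

#' Write screens to the long-format TSV dialect
#' @param screens List of `drug_screen` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screens_tsv <- function(screens, path) {
  tab <- do.call(rbind, lapply(screens, function(s) {
    data.frame(cell_line = names(s$gi), drug = s$drug,
               gi_value = unname(s$gi), assay_mode = s$assay_mode,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tabulate response calls in the calls.tsv dialect
#'
#' @param calls List of `response_call` objects.
#' @return Data frame with columns `drug`, `cell_line`, `group` (S/R),
#'   `cutoff_gi`, `inflection_index`, `degenerate`.
#' @export
calls_table <- function(calls) {
  do.call(rbind, lapply(calls, function(cl) {
    data.frame(
      drug = cl$drug,
      cell_line = cl$ordered_cell_lines,
      group = ifelse(cl$ordered_cell_lines %in% cl$sensitive, "S", "R"),
      cutoff_gi = cl$cutoff_gi,
      inflection_index = cl$inflection_index,
      degenerate = cl$degenerate,
      stringsAsFactors = FALSE
    )
  }))
}

rescaled_ranks <- function(n) seq(0, 1, length.out = n)
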