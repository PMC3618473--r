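# Synthetic cell-line panels with known ground truth: event matrices with
# planted marginals, pairwise couplings and lineage enrichment, plus drug
# screens with planted single-event, epistatic and lineage effects.

#' Panel configuration
#'
#' Describes a synthetic cell-line panel. The defaults emulate a large
#' compound-screening panel: 300 cell lines, 260 event loci, 20 lineages
#' of unequal size, and per-locus marginal event frequencies that are
#' mostly rare with a few common tumour-suppressor-like loci.
#'
#' A pairwise coupling `(A, B, lambda)` plants
#' `P(A and B) = lambda * f_A * f_B`: `lambda = 1` is independence,
#' `lambda > 1` co-selection, `lambda < 1` exclusivity and `lambda = 0`
#' strict mutual exclusivity. Couplings must be feasible
#' (`lambda * f_A * f_B <= min(f_A, f_B)`) and disjoint (no locus in two
#' couplings), which keeps the pairwise law exact without graphical-model
#' machinery.
#'
#' @param n_cell_lines Number of cell lines (default 300).
#' @param n_loci Number of event loci (default 260).
#' @param lineages Character vector of lineage labels (default
#'   `lineage01..lineage20`).
#' @param lineage_weights Mixture weights (default linearly decreasing, so
#'   lineage sizes are unequal as in real panels).
#' @param marginal_freqs Per-locus marginal event frequencies. Default: the
#'   Beta(1.1, 12) quantile ladder clipped to `[0.01, 0.6]` - most loci in
#'   the 1-15% range, the most frequent around 35%.
#' @param couplings List of `list(locusA=, locusB=, lambda=)`.
#' @param lineage_enrichment Optional data frame with columns `locus`,
#'   `lineage`, `multiplier`: the locus' event odds are multiplied in that
#'   lineage (probabilities clipped to (0, 1), applied before coupling).
#' @param drugs List of [drug_effect_spec()] objects.
#' @param seed Integer seed.
#' @return A list of class `panel_config`.
#' @export
panel_config <- function(n_cell_lines = 300L, n_loci = 260L,
                         lineages = sprintf("lineage%02d", 1:20),
                         lineage_weights = NULL,
                         marginal_freqs = NULL,
                         couplings = list(),
                         lineage_enrichment = NULL,
                         drugs = list(),
                         seed = 1L) {
  if (is.null(lineage_weights)) {
    w <- rev(seq_along(lineages))
    lineage_weights <- w / sum(w)
  }
  stopifnot(length(lineage_weights) == length(lineages),
            all(lineage_weights > 0))
  if (is.null(marginal_freqs)) {
    marginal_freqs <- pmin(pmax(
      stats::qbeta(stats::ppoints(n_loci), 1.1, 12), 0.01), 0.6)
  }
  stopifnot(length(marginal_freqs) == n_loci,
            all(marginal_freqs > 0), all(marginal_freqs < 1))
  loci <- sprintf("locus%03d", seq_len(n_loci))
  names(marginal_freqs) <- loci
  cfg <- structure(list(
    n_cell_lines = as.integer(n_cell_lines), n_loci = as.integer(n_loci),
    loci = loci, lineages = lineages,
    lineage_weights = lineage_weights / sum(lineage_weights),
    marginal_freqs = marginal_freqs, couplings = couplings,
    lineage_enrichment = lineage_enrichment, drugs = drugs,
    seed = as.integer(seed)
  ), class = "panel_config")
  validate_couplings(cfg)
  cfg
}

#' Drug effect specification for the synthetic screen generator
#'
#' GI values are generated as
#' `GI_i = baseline_i * prod(applicable shifts) * exp(eps_i)` with
#' `eps_i ~ Normal(0, sigma^2)`. Shifts are multiplicative on the GI scale:
#' sensitizing shifts are below 1 (lower GI = more sensitive). gIC50
#' baselines are log-normal with a median near 650 nM (the scale of typical
#' inflection-point cutoffs); viability baselines are concentrated near
#' 0.9 so the 0.78 cap rule is exercised.
#'
#' @param drug Drug identifier.
#' @param assay_mode `"gic50_nm"` or `"viability_ratio"`.
#' @param baseline List: for gIC50 mode `meanlog` (default `log(650)`) and
#'   `sdlog` (default 0.4); for viability mode `center` (default 0.9) and
#'   `sdlog` (default 0.15).
#' @param single_effects List of `list(locus=, shift=)`.
#' @param epistatic_effects List of `list(loci = c(...), shift=)`: the
#'   shift applies only to lines carrying every listed event.
#' @param lineage_effects List of `list(lineage=, shift=)`.
#' @param sigma Log-scale noise standard deviation (default 0.2).
#' @param fraction_tested Fraction of cell lines screened (default 1).
#' @return A list of class `drug_effect_spec`.
#' @export
drug_effect_spec <- function(drug,
                             assay_mode = c("gic50_nm", "viability_ratio"),
                             baseline = NULL,
                             single_effects = list(),
                             epistatic_effects = list(),
                             lineage_effects = list(),
                             sigma = 0.2,
                             fraction_tested = 1) {
  assay_mode <- match.arg(assay_mode)
  if (is.null(baseline)) {
    baseline <- if (assay_mode == "gic50_nm") {
      list(meanlog = log(650), sdlog = 0.4)
    } else {
      list(center = 0.9, sdlog = 0.15)
    }
  }
  all_shifts <- c(
    vapply(single_effects, function(e) e$shift, numeric(1)),
    vapply(epistatic_effects, function(e) e$shift, numeric(1)),
    vapply(lineage_effects, function(e) e$shift, numeric(1))
  )
  stopifnot(all(all_shifts > 0), sigma >= 0,
            fraction_tested > 0, fraction_tested <= 1)
  structure(list(drug = drug, assay_mode = assay_mode, baseline = baseline,
                 single_effects = single_effects,
                 epistatic_effects = epistatic_effects,
                 lineage_effects = lineage_effects,
                 sigma = sigma, fraction_tested = fraction_tested),
            class = "drug_effect_spec")
}

#' Generate a synthetic event matrix
#'
#' Uncoupled loci are sampled independently at their (lineage-adjusted)
#' marginal frequencies; coupled pairs are sampled jointly from the 2x2 law
#' with the specified marginals and `P11 = lambda * f_A * f_B`. A fixed
#' seed yields an identical matrix.
#'
#' @param config A [panel_config()].
#' @param seed Seed to set before sampling (default the config seed; `NULL`
#'   to continue the current RNG stream).
#' @return List with `matrix` (an `event_matrix` with lineage annotations)
#'   and `truth` (lineage assignment, per-line event probabilities and the
#'   planted couplings).
#' @export
generate_event_matrix <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_cell_lines
  cl <- sprintf("line%04d", seq_len(n))
  lineage <- sample(config$lineages, n, replace = TRUE,
                    prob = config$lineage_weights)
  names(lineage) <- cl
  # per-line, per-locus event probability (lineage enrichment as odds mult.)
  p <- matrix(rep(config$marginal_freqs, each = n), nrow = n,
              dimnames = list(cl, config$loci))
  enr <- config$lineage_enrichment
  if (!is.null(enr) && nrow(enr) > 0) {
    for (i in seq_len(nrow(enr))) {
      rows <- lineage == enr$lineage[i]
      f0 <- p[rows, enr$locus[i]]
      odds <- f0 / (1 - f0) * enr$multiplier[i]
      p[rows, enr$locus[i]] <- pmin(pmax(odds / (1 + odds), 1e-6), 1 - 1e-6)
    }
  }
  ev <- matrix(stats::runif(n * config$n_loci) < p, nrow = n,
               dimnames = dimnames(p))
  for (cp in config$couplings) {
    fa <- p[, cp$locusA]
    fb <- p[, cp$locusB]
    p11 <- cp$lambda * fa * fb
    if (any(p11 > pmin(fa, fb) + 1e-12)) {
      stop(sprintf("infeasible coupling %s::%s (lambda = %g)",
                   cp$locusA, cp$locusB, cp$lambda), call. = FALSE)
    }
    u <- stats::runif(n)
    both <- u < p11
    a_only <- !both & u < p11 + (fa - p11)
    b_only <- !both & !a_only & u < fa + fb - p11
    ev[, cp$locusA] <- both | a_only
    ev[, cp$locusB] <- both | b_only
  }
  m <- new_event_matrix(ev, lineage)
  list(matrix = m,
       truth = list(lineage = lineage, probabilities = p,
                    couplings = config$couplings))
}

#' Generate synthetic drug screens over a panel
#'
#' @param matrix An `event_matrix` (rows define the candidate cell lines).
#' @param specs List of [drug_effect_spec()] objects.
#' @param seed Seed (`NULL` to continue the current RNG stream).
#' @return Named list of `drug_screen` objects.
#' @export
generate_drug_screens <- function(matrix, specs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cl <- rownames(matrix$events)
  n <- length(cl)
  lineage <- if (is.null(matrix$lineage)) NULL else
    lineage_of(matrix$lineage, cl)
  out <- lapply(specs, function(sp) {
    base <- if (sp$assay_mode == "gic50_nm") {
      stats::rlnorm(n, sp$baseline$meanlog, sp$baseline$sdlog)
    } else {
      sp$baseline$center * exp(stats::rnorm(n, 0, sp$baseline$sdlog))
    }
    shift <- rep(1, n)
    for (e in sp$single_effects) {
      hit <- matrix$events[, e$locus]
      shift[hit] <- shift[hit] * e$shift
    }
    for (e in sp$epistatic_effects) {
      hit <- rowSums(matrix$events[, e$loci, drop = FALSE]) == length(e$loci)
      shift[hit] <- shift[hit] * e$shift
    }
    for (e in sp$lineage_effects) {
      if (is.null(lineage)) stop("lineage effects need lineage annotations",
                                 call. = FALSE)
      hit <- lineage == e$lineage
      shift[hit] <- shift[hit] * e$shift
    }
    gi <- base * shift * exp(stats::rnorm(n, 0, sp$sigma))
    names(gi) <- cl
    if (sp$fraction_tested < 1) {
      keep <- sort(sample.int(n, max(2L, round(sp$fraction_tested * n))))
      gi <- gi[keep]
    }
    drug_screen(sp$drug, gi, sp$assay_mode)
  })
  names(out) <- vapply(specs, function(sp) sp$drug, character(1))
  out
}

#' Generate a full synthetic panel (matrix, screens, lineage, truth)
#'
#' Composition of [generate_event_matrix()] and [generate_drug_screens()]
#' under a single seed. With `out_dir`, the panel is written in the TSV
#' dialects consumed by the loaders: `mutations.tsv` (every cell line x
#' locus combination with its 0/1 event state, so the written panel
#' round-trips losslessly), `lineage.tsv`, `screens.tsv`, and the planted
#' truth in `truth_couplings.tsv` / `truth_effects.tsv`.
#'
#' @param config A [panel_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return List with `matrix`, `screens`, `lineage`, `truth`, and `files`
#'   (paths written, or `NULL`).
#' @export
generate_panel <- function(config, out_dir = NULL) {
  set.seed(config$seed)
  gm <- generate_event_matrix(config, seed = NULL)
  screens <- generate_drug_screens(gm$matrix, config$drugs, seed = NULL)
  files <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ev <- gm$matrix$events
    long <- data.frame(
      cell_line = rep(rownames(ev), times = ncol(ev)),
      locus = rep(colnames(ev), each = nrow(ev)),
      mutated = as.integer(as.vector(ev)),
      stringsAsFactors = FALSE
    )
    long <- long[order(long$cell_line, long$locus), , drop = FALSE]
    files <- list(
      mutations = file.path(out_dir, "mutations.tsv"),
      lineage = file.path(out_dir, "lineage.tsv"),
      screens = file.path(out_dir, "screens.tsv"),
      truth_couplings = file.path(out_dir, "truth_couplings.tsv"),
      truth_effects = file.path(out_dir, "truth_effects.tsv")
    )
    utils::write.table(long, files$mutations, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(
      data.frame(cell_line = names(gm$truth$lineage),
                 lineage = unname(gm$truth$lineage)),
      files$lineage, sep = "\t", quote = FALSE, row.names = FALSE)
    write_screens_tsv(screens, files$screens)
    cp <- config$couplings
    utils::write.table(
      data.frame(
        locusA = vapply(cp, `[[`, character(1), "locusA"),
        locusB = vapply(cp, `[[`, character(1), "locusB"),
        lambda = vapply(cp, `[[`, numeric(1), "lambda")
      ),
      files$truth_couplings, sep = "\t", quote = FALSE, row.names = FALSE)
    eff <- do.call(rbind, lapply(config$drugs, function(sp) {
      rbind(
        if (length(sp$single_effects)) data.frame(
          drug = sp$drug, type = "single",
          target = vapply(sp$single_effects, `[[`, character(1), "locus"),
          shift = vapply(sp$single_effects, `[[`, numeric(1), "shift")),
        if (length(sp$epistatic_effects)) data.frame(
          drug = sp$drug, type = "epistatic",
          target = vapply(sp$epistatic_effects,
                          function(e) paste(sort(e$loci), collapse = "::"),
                          character(1)),
          shift = vapply(sp$epistatic_effects, `[[`, numeric(1), "shift")),
        if (length(sp$lineage_effects)) data.frame(
          drug = sp$drug, type = "lineage",
          target = vapply(sp$lineage_effects, `[[`, character(1), "lineage"),
          shift = vapply(sp$lineage_effects, `[[`, numeric(1), "shift"))
      )
    }))
    if (is.null(eff)) {
      eff <- data.frame(drug = character(0), type = character(0),
                        target = character(0), shift = numeric(0))
    }
    utils::write.table(eff, files$truth_effects, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  list(matrix = gm$matrix, screens = screens, lineage = gm$truth$lineage,
       truth = gm$truth, files = files)
}

# --- internal ----------------------------------------------------------------

validate_couplings <- function(cfg) {
  if (!length(cfg$couplings)) return(invisible(cfg))
  used <- unlist(lapply(cfg$couplings, function(cp) c(cp$locusA, cp$locusB)))
  if (anyDuplicated(used)) {
    stop("couplings must be disjoint: locus appears twice", call. = FALSE)
  }
  missing <- setdiff(used, cfg$loci)
  if (length(missing)) {
    stop(sprintf("coupling references unknown loci: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (cp in cfg$couplings) {
    fa <- cfg$marginal_freqs[cp$locusA]
    fb <- cfg$marginal_freqs[cp$locusB]
    stopifnot(cp$lambda >= 0)
    if (cp$lambda * fa * fb > min(fa, fb) + 1e-12 ||
        1 - fa - fb + cp$lambda * fa * fb < -1e-12) {
      stop(sprintf("infeasible coupling %s::%s (lambda = %g)",
                   cp$locusA, cp$locusB, cp$lambda), call. = FALSE)
    }
  }
  invisible(cfg)
}
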