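# Benchmark scenarios with planted ground truth. These are the package's
# standard validation settings: each returns a ready-to-run synthetic panel
# (or profile) whose construction pins down what the pipeline should find.

#' Two-regime response profile for knee-recovery benchmarks
#'
#' A rank-space profile with a flat sensitive plateau followed by a steeply
#' rising resistant ramp - the shape of a rank-ordered gIC50 curve with a
#' distinct sensitive minority. The knee (last plateau rank) is the ground
#' truth. Noise is kept small relative to the per-rank ramp increment so the
#' discrete second difference of the profile is a well-defined independent
#' locator of the knee.
#'
#' @param n Number of cell lines (default 60).
#' @param knee_fraction Fraction of lines on the sensitive plateau
#'   (default 0.3).
#' @param mu1 Plateau GI (default 100 nM).
#' @param mu2 GI at the top of the ramp (default 4000 nM).
#' @param sigma Additive noise SD (default 1 nM).
#' @return A list with `screen` (a `drug_screen`), `knee_rank` (0-based rank
#'   of the first post-plateau line) and `knee_fraction`.
#' @export
two_regime_profile <- function(n = 60L, knee_fraction = 0.3, mu1 = 100,
                               mu2 = 4000, sigma = 1) {
  k <- round(knee_fraction * n)
  stopifnot(k >= 2, n - k >= 2)
  ramp <- seq(1 / (n - k), 1, length.out = n - k)
  gi <- c(rep(mu1, k), mu1 + (mu2 - mu1) * ramp) +
    stats::rnorm(n, 0, sigma)
  names(gi) <- sprintf("line%04d", seq_len(n))
  list(screen = drug_screen("two_regime", gi, "gic50_nm"),
       knee_rank = k, knee_fraction = knee_fraction)
}

#' Independence panel for type-I calibration
#'
#' A panel with the default marginal-frequency ladder and no couplings:
#' every locus is sampled independently, so any disequilibrium call is a
#' false positive.
#'
#' @param seed Integer seed.
#' @param n_cell_lines,n_loci Panel size (defaults 300 x 40).
#' @return An `event_matrix`.
#' @export
independence_panel <- function(seed, n_cell_lines = 300L, n_loci = 40L) {
  cfg <- panel_config(n_cell_lines = n_cell_lines, n_loci = n_loci,
                      seed = seed)
  generate_event_matrix(cfg)$matrix
}

#' Panel with one planted coupling
#'
#' Two loci at marginal frequencies 0.25 and 0.30 coupled at the given
#' lambda (`P(A and B) = lambda * f_A * f_B`); the remaining loci follow the
#' default ladder, independent.
#'
#' @param seed Integer seed.
#' @param lambda Planted coupling (0 = strict mutual exclusivity, 1 =
#'   independence, >1 co-selection).
#' @param n_cell_lines,n_loci Panel size (defaults 300 x 40).
#' @return A list with `matrix` and `pair` (the coupled locus pair label).
#' @export
coupled_pair_panel <- function(seed, lambda, n_cell_lines = 300L,
                               n_loci = 40L) {
  mf <- pmin(pmax(stats::qbeta(stats::ppoints(n_loci), 1.1, 12), 0.01), 0.6)
  mf[n_loci - 1L] <- 0.25
  mf[n_loci] <- 0.30
  loci <- sprintf("locus%03d", c(n_loci - 1L, n_loci))
  cfg <- panel_config(n_cell_lines, n_loci, marginal_freqs = mf,
                      couplings = list(list(locusA = loci[1],
                                            locusB = loci[2],
                                            lambda = lambda)),
                      seed = seed)
  list(matrix = generate_event_matrix(cfg)$matrix,
       pair = paste(loci, collapse = "::"))
}

#' Epistatic-effect panel: sensitivity requires two co-occurring events
#'
#' A 500-line viability-mode screen (the scale of large published viability
#' screens) where the drug effect is purely epistatic: lines carrying
#' events in both planted loci (each at
#' marginal frequency 0.7, independent) get a multiplicative viability shift
#' of 0.844 around a 0.9 baseline, with log-scale noise chosen so that
#' roughly 55% of co-carriers and 25% of other lines fall below the 0.78
#' viability cap. Under this partial-penetrance regime the co-event is
#' strongly enriched among sensitive lines while each single locus stays
#' inside the 1.5-fold S/R band - the defining signature of an epistatic
#' biomarker. (With complete penetrance the single-locus S/R ratio is
#' bounded below by 2, so partial penetrance is what makes the co-event,
#' and only the co-event, detectable.)
#'
#' @param seed Integer seed.
#' @param n_cell_lines Panel size (default 500).
#' @param n_loci Number of loci (default 40).
#' @return List with `matrix`, `screen` (a `drug_screen`), and `pair`
#'   (the planted locus pair label).
#' @export
epistasis_panel <- function(seed, n_cell_lines = 500L, n_loci = 40L) {
  mf <- pmin(pmax(stats::qbeta(stats::ppoints(n_loci), 1.1, 12), 0.01), 0.6)
  mf[n_loci - 1L] <- 0.7
  mf[n_loci] <- 0.7
  loci <- sprintf("locus%03d", c(n_loci - 1L, n_loci))
  cfg <- panel_config(
    n_cell_lines, n_loci, marginal_freqs = mf, seed = seed,
    drugs = list(drug_effect_spec(
      "epistatic_drug", assay_mode = "viability_ratio",
      baseline = list(center = 0.9, sdlog = 0.15),
      epistatic_effects = list(list(loci = loci, shift = 0.844)),
      sigma = 0.15))
  )
  panel <- generate_panel(cfg)
  list(matrix = panel$matrix, screen = panel$screens[[1]],
       pair = paste(loci, collapse = "::"))
}

#' Lineage-effect panels for the subtraction cross-validation benchmark
#'
#' Both variants are 300-line, 20-lineage viability-mode screens with a
#' marker locus (`locus040` by default).
#'
#' `confined = TRUE`: the marker's event odds are enriched 30-fold in one
#' lineage and the drug sensitizes that lineage only (shift 0.6), so the
#' marker's apparent association with sensitivity is entirely mediated by
#' lineage and must vanish once that lineage is subtracted.
#'
#' `confined = FALSE`: the marker (marginal 0.15, uniform across lineages)
#' itself sensitizes carriers with partial penetrance (shift 0.79), so the
#' association must survive subtraction of whichever lineages individually
#' reach significance.
#'
#' @param seed Integer seed.
#' @param confined Logical; see above.
#' @param n_cell_lines,n_loci Panel size (defaults 300 x 40).
#' @return List with `matrix`, `screen`, `locus` (the marker) and
#'   `effect_lineage` (the sensitized lineage, `NA` when `confined = FALSE`).
#' @export
lineage_effect_panel <- function(seed, confined, n_cell_lines = 300L,
                                 n_loci = 40L) {
  mf <- pmin(pmax(stats::qbeta(stats::ppoints(n_loci), 1.1, 12), 0.01), 0.6)
  locus <- sprintf("locus%03d", n_loci)
  mf[n_loci] <- if (confined) 0.10 else 0.15
  enr <- if (confined) {
    data.frame(locus = locus, lineage = "lineage01", multiplier = 30)
  }
  drug <- if (confined) {
    drug_effect_spec("lineage_drug", assay_mode = "viability_ratio",
                     baseline = list(center = 0.9, sdlog = 0.1),
                     lineage_effects = list(list(lineage = "lineage01",
                                                 shift = 0.6)),
                     sigma = 0.15)
  } else {
    drug_effect_spec("lineage_drug", assay_mode = "viability_ratio",
                     baseline = list(center = 0.9, sdlog = 0.1),
                     single_effects = list(list(locus = locus, shift = 0.79)),
                     sigma = 0.15)
  }
  cfg <- panel_config(n_cell_lines, n_loci, marginal_freqs = mf,
                      lineage_enrichment = enr, drugs = list(drug),
                      seed = seed)
  panel <- generate_panel(cfg)
  list(matrix = panel$matrix, screen = panel$screens[[1]], locus = locus,
       effect_lineage = if (confined) "lineage01" else NA_character_)
}

#' Event matrix reproducing a printed exclusivity table row
#'
#' A 294-line panel in which locus `eventA` occurs in 59 lines, locus
#' `eventB` in 102 lines and the two co-occur in exactly `overlap` lines,
#' so that the pair's marginal product matches a predicted co-event
#' frequency of 59*102/294^2 = 0.0696... This is the configuration behind
#' the partially-exclusive pair used in the package's worked examples.
#'
#' @param overlap Co-occurrence count (default 8).
#' @return An `event_matrix` with 294 cell lines and the two loci.
#' @export
printed_pair_matrix <- function(overlap = 8L) {
  n <- 294L; a <- 59L; b <- 102L
  stopifnot(overlap <= min(a, b), a + b - overlap <= n)
  cl <- sprintf("line%04d", seq_len(n))
  ev <- matrix(FALSE, n, 2, dimnames = list(cl, c("eventA", "eventB")))
  ev[seq_len(a), "eventA"] <- TRUE
  ev[seq_len(overlap), "eventB"] <- TRUE
  ev[(a + 1L):(a + b - overlap), "eventB"] <- TRUE
  new_event_matrix(ev)
}
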