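lineage6 <- c(L1 = "Mel", L2 = "Mel", L3 = "Colon",
              L4 = "Colon", L5 = "Lung", L6 = "Lung")

test_that("event-lineage pair enumeration matches cross-tabulation", {
  m <- tiny_matrix(lineage = lineage6)
  pairs <- enumerate_event_lineage_pairs(m)
  # brute force
  for (i in seq_len(nrow(pairs))) {
    lines_in <- names(lineage6)[lineage6 == pairs$lineage[i]]
    expect_equal(pairs$count[i], sum(m$events[lines_in, pairs$locus[i]]))
  }
  expect_true(all(pairs$count >= 1))
  # locus D occurs only in L1 (Mel): exactly one pair for D
  expect_equal(sum(pairs$locus == "D"), 1)
  expect_identical(pairs$lineage[pairs$locus == "D"], "Mel")
  expect_error(enumerate_event_lineage_pairs(tiny_matrix()), "lineage")
})

test_that("proportional goodness-of-fit reproduces the hand-computed carrier split", {
  # 14 sensitive / 0 resistant carriers with group sizes 154 / 107:
  # E_S = 14*154/261, chi2 = (14-E_S)^2*(1/E_S + 1/E_R) ~ 9.73
  n <- 261
  cl_names <- sprintf("L%03d", 1:n)
  S <- cl_names[1:154]; R <- cl_names[155:261]
  lin <- stats::setNames(rep("Other", n), cl_names)
  lin[c(1:14, 255:261)] <- "Melanoma"   # carriers will be the 14 in S
  ev <- matrix(FALSE, n, 1, dimnames = list(cl_names, "BRAF"))
  ev[1:14, "BRAF"] <- TRUE
  m <- new_event_matrix(ev, lin)
  cl <- manual_call(S = S, R = R)
  res <- test_event_lineage_association("BRAF", "Melanoma", m, cl)
  expect_equal(res$count_S, 14)
  expect_equal(res$count_R, 0)
  expect_equal(res$expected_S, 14 * 154 / 261)
  expect_equal(res$chi2, 9.727, tolerance = 1e-3)
  expect_lt(res$p_value, 0.01)
  expect_true(res$significant)
  expect_equal(res$expected_S + res$expected_R, res$count_S + res$count_R)
})

test_that("an exactly proportional carrier split gives p = 1", {
  n <- 30
  cl_names <- sprintf("L%02d", 1:n)
  S <- cl_names[1:10]; R <- cl_names[11:30]
  lin <- stats::setNames(rep("X", n), cl_names)
  ev <- matrix(FALSE, n, 1, dimnames = list(cl_names, "g"))
  ev[c(1, 2, 11, 12, 13, 14), "g"] <- TRUE  # 2 of 10 S, 4 of 20 R
  m <- new_event_matrix(ev, lin)
  res <- test_event_lineage_association("g", "X", m, manual_call(S, R))
  expect_equal(res$p_value, 1)
})

test_that("both null options agree in direction for small carrier counts", {
  set.seed(17)
  n <- 80
  cl_names <- sprintf("L%02d", 1:n)
  S <- cl_names[1:30]; R <- cl_names[31:80]
  lin <- stats::setNames(rep("X", n), cl_names)
  for (mcar in 3:20) {
    cS <- sample(0:mcar, 1)
    carriers <- c(sample(S, min(cS, 30)), sample(R, min(mcar - cS, 50)))
    ev <- matrix(FALSE, n, 1, dimnames = list(cl_names, "g"))
    ev[carriers, "g"] <- TRUE
    m <- new_event_matrix(ev, lin)
    gof <- test_event_lineage_association("g", "X", m, manual_call(S, R),
                                          null = "proportional_gof")
    fi <- test_event_lineage_association("g", "X", m, manual_call(S, R),
                                         null = "fisher_2x2")
    # same observed counts, same direction of deviation from expectation
    expect_equal(gof$count_S, fi$count_S)
    expect_identical(sign(gof$count_S - gof$expected_S),
                     sign(fi$count_S - fi$expected_S))
  }
})

test_that("subtraction removes whole lineages and never leaks them back", {
  set.seed(23)
  panel <- lineage_effect_panel(101, confined = TRUE)
  cl <- call_response(panel$screen)
  sc <- scan_lineage_interactions(panel$locus, panel$matrix, cl)
  sig <- sc$lineage[sc$significant]
  rt <- subtract_and_retest(panel$locus, panel$matrix, cl, sig)
  lin <- stats::setNames(lineage_of(panel$matrix$lineage,
                                    rownames(panel$matrix$events)),
                         rownames(panel$matrix$events))
  tested <- c(cl$sensitive, cl$resistant)
  tested <- tested[tested %in% names(lin)]
  removed <- sum(lin[tested] %in% sig)
  expect_equal(rt$n_remaining + removed, length(tested))

  # all carriers confined to one subtracted lineage: residual count 0
  n <- 40
  cl_names <- sprintf("L%02d", 1:n)
  lin2 <- stats::setNames(rep(c("Mel", "Other"), c(10, 30)), cl_names)
  ev <- matrix(FALSE, n, 1, dimnames = list(cl_names, "g"))
  ev[1:8, "g"] <- TRUE
  m <- new_event_matrix(ev, lin2)
  call2 <- manual_call(S = cl_names[1:12], R = cl_names[13:40])
  rt2 <- subtract_and_retest("g", m, call2, "Mel")
  expect_equal(rt2$count_S + rt2$count_R, 0)
  expect_false(rt2$powered)
  expect_false(rt2$significant)
})

test_that("lineage-confined and lineage-wide effects separate after subtraction", {
  confined_sig <- independent_sig <- logical(8)
  for (i in 1:8) {
    pc <- lineage_effect_panel(300 + i, confined = TRUE)
    clc <- call_response(pc$screen)
    scc <- scan_lineage_interactions(pc$locus, pc$matrix, clc)
    rtc <- subtract_and_retest(pc$locus, pc$matrix, clc,
                               scc$lineage[scc$significant])
    confined_sig[i] <- isTRUE(rtc$significant)

    pi_ <- lineage_effect_panel(400 + i, confined = FALSE)
    cli <- call_response(pi_$screen)
    sci <- scan_lineage_interactions(pi_$locus, pi_$matrix, cli)
    rti <- subtract_and_retest(pi_$locus, pi_$matrix, cli,
                               sci$lineage[sci$significant])
    independent_sig[i] <- isTRUE(rti$significant)
  }
  expect_lte(sum(confined_sig), 2)
  expect_gte(sum(independent_sig), 6)
})

test_that("uniform-lineage panels give roughly uniform lineage-test p-values", {
  set.seed(77)
  ps <- c()
  for (i in 1:30) {
    cfg <- panel_config(n_cell_lines = 120, n_loci = 12,
                        lineages = c("A", "B", "C"),
                        lineage_weights = c(1, 1, 1) / 3, seed = 500 + i)
    m <- generate_event_matrix(cfg)$matrix
    cl_names <- rownames(m$events)
    call_i <- manual_call(S = cl_names[1:40], R = cl_names[41:120])
    for (loc in sample(colnames(m$events), 3)) {
      sc <- scan_lineage_interactions(loc, m, call_i, null = "fisher_2x2")
      ps <- c(ps, sc$p_value[!is.na(sc$p_value)])
    }
  }
  # Fisher p-values are discrete and conservative; demand approximate
  # uniformity only coarsely
  expect_lt(mean(ps <= 0.05), 0.08)
  expect_gt(mean(ps), 0.35)
})

test_that("lineage-independence summary counts fractions with and without exclusions", {
  res <- data.frame(
    loci = c(paste0("g", 1:18, "::h", 1:18), paste0("TP53::g", 19:27)),
    drug = "d", removed_lineages = "", n_remaining = 200, n_S = 60, n_R = 140,
    count_S = 10, count_R = 10, sr_ratio = 2,
    p_value = c(rep(0.01, 9), rep(0.08, 8), rep(0.5, 10)),
    direction = "sensitive", powered = TRUE,
    significant = NA, stringsAsFactors = FALSE
  )
  s <- lineage_independence_summary(res)
  expect_equal(s$n_tested, c(27, 27))
  expect_equal(s$n_significant[s$alpha == 0.05], 9)
  expect_equal(s$fraction[s$alpha == 0.05], 1 / 3)
  expect_equal(s$n_significant[s$alpha == 0.10], 17)

  s2 <- lineage_independence_summary(res, exclude_loci = "TP53")
  expect_equal(s2$n_tested, c(18, 18))
  s3 <- lineage_independence_summary(res, exclude_loci = character(0))
  expect_equal(s3$n_tested, s$n_tested)
})
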