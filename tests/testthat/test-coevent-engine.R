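test_that("tuple enumeration: potential space sizes and observed counts", {
  # G = 262 loci with at least one event each: identity-like matrix
  ev <- diag(262) == 1
  dimnames(ev) <- list(sprintf("L%03d", 1:262), sprintf("g%03d", 1:262))
  en <- enumerate_event_tuples(new_event_matrix(ev), k = 2)
  expect_identical(en$potential_space, 34191)
  expect_equal(nrow(en$tuples), 0)

  m <- tiny_matrix()  # loci A, B, C, D all non-empty
  en2 <- enumerate_event_tuples(m, k = 2)
  expect_identical(en2$potential_space, 6)   # C(4,2)
  # brute-force pair counts
  expect_equal(
    en2$tuples[en2$tuples$locus1 == "A" & en2$tuples$locus2 == "B", "count"],
    sum(m$events[, "A"] & m$events[, "B"]))

  ev5 <- matrix(TRUE, 2, 5, dimnames = list(c("L1", "L2"), paste0("g", 1:5)))
  en3 <- enumerate_event_tuples(new_event_matrix(ev5), k = 3)
  expect_identical(en3$potential_space, 10)  # C(5,3)
  expect_true(all(en3$tuples$count == 2))
  expect_error(enumerate_event_tuples(m, k = 4), "k must be")
})

test_that("independence model prediction and printed-table rounding", {
  p <- predicted_cooccurrence(c(0.5, 0.5), 100)
  expect_equal(p$E_raw, 25)
  expect_equal(p$E, 25)

  # predicted frequency 0.069623768 over 294 lines rounds to 20 co-events
  p2 <- predicted_cooccurrence(c(59 / 294, 102 / 294), 294)
  expect_equal(p2$E_raw, 0.069623768 * 294, tolerance = 1e-7)
  expect_equal(p2$E, 20)
  expect_equal(predicted_cooccurrence(c(59 / 294, 102 / 294), 294,
                                      rounding = "exact")$E, p2$E_raw)
  expect_equal(predicted_cooccurrence(c(0, 0.9), 100)$E, 0)
})

test_that("observed-vs-predicted chi-square reproduces printed p-values", {
  expect_equal(chisq_obs_vs_pred(8, 20, 294)$p_value, 0.005444485,
               tolerance = 1e-6)
  expect_equal(chisq_obs_vs_pred(0, 4, 294)$p_value, 0.044036228,
               tolerance = 1e-6)
  eq <- chisq_obs_vs_pred(15, 15, 294)
  expect_equal(eq$chi2, 0)
  expect_equal(eq$p_value, 1)
  expect_true(chisq_obs_vs_pred(0, 0, 294)$untestable)
  expect_true(chisq_obs_vs_pred(10, 294, 294)$untestable)
})

test_that("chi-square is cell-symmetric and monotone in |O - E|", {
  for (O in c(0, 3, 17)) {
    a <- chisq_obs_vs_pred(O, 12, 100)
    b <- chisq_obs_vs_pred(100 - O, 88, 100)
    expect_equal(a$chi2, b$chi2)
  }
  ps <- vapply(0:24, function(O) chisq_obs_vs_pred(O, 25, 200)$p_value,
               numeric(1))
  expect_true(all(diff(ps) > 0))  # p rises as O approaches E from below
})

test_that("disequilibrium classes follow the observed/predicted geometry", {
  expect_identical(classify_disequilibrium(0, 4 / 294, 0, 0.044),
                   "mutually_exclusive")
  expect_identical(classify_disequilibrium(0.2, 0.1, 20, 0.01),
                   "co_selected")
  expect_identical(classify_disequilibrium(0.02, 0.07, 6, 0.01),
                   "partially_exclusive")
  expect_identical(classify_disequilibrium(0.05, 0.05, 5, 1), "none")
  expect_identical(classify_disequilibrium(0.2, 0.1, 20, 0.2), "none")
  expect_identical(classify_disequilibrium(0.1, 0.2, 10, NA_real_), "none")
})

test_that("population scan reproduces the printed pair end to end", {
  m <- printed_pair_matrix(overlap = 8)
  sc <- population_disequilibrium_scan(m)
  row <- sc[sc$loci == "eventA::eventB", ]
  expect_equal(row$observed_count, 8)
  expect_equal(row$predicted_count, 20)
  expect_lt(abs(row$difference - (-0.042412884)), 1e-9)
  expect_equal(row$p_value, 0.005444485, tolerance = 1e-6)
  expect_identical(row$class, "partially_exclusive")
  expect_equal(row$difference, row$observed_freq - row$predicted_freq,
               tolerance = 1e-12)

  strict <- population_disequilibrium_scan(printed_pair_matrix(overlap = 0))
  expect_identical(strict$class[strict$loci == "eventA::eventB"],
                   "mutually_exclusive")
})

test_that("single-event association computes ratios, sentinel and Fisher p", {
  m <- tiny_matrix()
  cl <- manual_call(S = c("L1", "L2"), R = c("L3", "L4", "L5", "L6"))
  res <- single_event_drug_association(m, cl)
  a <- res[res$loci == "A", ]   # A in L1,L2,L3: count_S=2, count_R=1
  expect_equal(a$freq_S, 1)
  expect_equal(a$freq_R, 0.25)
  expect_equal(a$sr_ratio, 4)
  expect_identical(a$direction, "sensitive")
  d <- res[res$loci == "D", ]   # D only in L1 (sensitive)
  expect_identical(d$sr_ratio, Inf)
  expect_identical(d$direction, "sensitive")
  # Fisher p matches exhaustive hypergeometric enumeration
  expect_equal(a$p_value, fisher_enum_p(2, 0, 1, 3), tolerance = 1e-12)

  expect_error(single_event_drug_association(m,
    manual_call(S = character(0), R = paste0("L", 1:6))), "empty")
})

test_that("module Fisher p equals hypergeometric enumeration (all tables, n <= 12)", {
  for (n in 2:12) {
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      d <- n - a - b - cc
      if (a + b == 0 || cc + d == 0 || a + cc == 0 || b + d == 0) next
      p_pkg <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value
      expect_equal(p_pkg, fisher_enum_p(a, b, cc, d), tolerance = 1e-9)
    }
  }
})

test_that("co-event association: filters, boundary rule and diagnostics", {
  set.seed(21)
  ev <- matrix(runif(600) < 0.4, 60, 10,
               dimnames = list(sprintf("L%02d", 1:60), paste0("g", 1:10)))
  m <- new_event_matrix(ev)
  cl <- manual_call(S = sprintf("L%02d", 1:20), R = sprintf("L%02d", 21:60))
  res <- coevent_drug_association(m, cl, k = 2, min_count = 4)
  expect_true(all(res$count_S + res$count_R >= 4))
  # counts agree with brute force
  for (i in sample(nrow(res), 5)) {
    loci_i <- strsplit(res$loci[i], "::")[[1]]
    carriers <- rownames(ev)[rowSums(ev[, loci_i]) == 2]
    expect_equal(res$count_S[i], sum(carriers %in% cl$sensitive))
    expect_equal(res$count_R[i], sum(carriers %in% cl$resistant))
  }
  # primary p agrees with stats::chisq.test on the same table
  i <- which.min(res$p_value)
  tab <- matrix(c(res$count_S[i], res$n_S[i] - res$count_S[i],
                  res$count_R[i], res$n_R[i] - res$count_R[i]), 2,
                byrow = TRUE)
  expect_equal(res$p_value[i],
               suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value))
  # sr exactly at the fold boundary is not selected (strict inequality)
  fake <- res[1, ]
  fake$sr_ratio <- 1.5; fake$p_value <- 0.01
  expect_false(fake$sr_ratio > 1.5 | fake$sr_ratio < 1 / 1.5)
  # subpopulation diagnostics carry both chi2 and p
  expect_true(all(c("chi2_S", "p_S", "chi2_R", "p_R", "p_value_yates")
                  %in% names(res)))
})

test_that("co-selection in sensitive lines is reciprocally depleted in resistant lines", {
  # a pair enriched among S relative to R: observed exceeds predicted in S,
  # and falls below predicted in R, when marginals are shared
  set.seed(33)
  n <- 200
  S <- sprintf("L%03d", 1:80); R <- sprintf("L%03d", 81:200)
  ev <- matrix(FALSE, n, 2, dimnames = list(c(S, R), c("a", "b")))
  ev[1:40, "a"] <- TRUE;  ev[1:40, "b"] <- TRUE        # co-carriers in S
  ev[81:110, "a"] <- TRUE; ev[111:140, "b"] <- TRUE    # disjoint in R
  m <- new_event_matrix(ev)
  cl <- manual_call(S = S, R = R)
  res <- coevent_drug_association(m, cl, k = 2, rounding = "exact")
  expect_gt(res$sr_ratio, 1)
  fS <- locus_frequencies(m, subset = S); fR <- locus_frequencies(m, subset = R)
  expect_gt(res$count_S, 80 * fS["a"] * fS["b"])   # above prediction in S
  expect_lt(res$count_R, 120 * fR["a"] * fR["b"])  # below prediction in R
})

test_that("BH and Bonferroni match the brute-force step-up rule", {
  mt <- multiple_testing(c(0.01, 0.02, 0.03, 0.04), "bh", q = 0.05)
  expect_true(all(mt$significant))
  expect_false(any(multiple_testing(rep(1, 5), "bh")$significant))
  expect_length(multiple_testing(numeric(0), "bh")$significant, 0)

  set.seed(13)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    bh <- multiple_testing(p, "bh", q = 0.05)
    bon <- multiple_testing(p, "bonferroni", q = 0.05)
    expect_identical(bh$significant, bh_stepup(p, 0.05))
    expect_identical(bon$significant, p <= 0.05 / length(p))
    expect_true(all(bh$significant[bon$significant]))  # BH contains Bonferroni
  }
})

test_that("top-event ranking follows p, then count, then distance from unity", {
  res <- data.frame(
    drug = "d", loci = c("a::b", "c::d", "e::f", "g::h", "i::j"),
    tuple_size = 2L, n_S = 50, n_R = 50,
    count_S = c(25, 8, 10, 10, 3), count_R = c(5, 2, 0, 4, 1),
    freq_S = NA, freq_R = NA,
    sr_ratio = c(5, 4, Inf, 6.9, 3), p_value = c(0.01, 0.01, 0.03, 0.03, 0.2),
    direction = "sensitive", powered = TRUE, stringsAsFactors = FALSE
  )
  top <- rank_top_events(res, alpha = 0.05)
  # equal p: larger carrier count first (g::h count 14 beats e::f count 10)
  expect_identical(top$loci, c("a::b", "c::d", "g::h", "e::f"))
  # equal p and count: the Inf sentinel beats any finite ratio
  res2 <- res[3:4, ]
  res2$count_S <- c(10, 10); res2$count_R <- c(4, 4)
  top2 <- rank_top_events(res2, alpha = 0.05)
  expect_identical(top2$sr_ratio[1], Inf)
  # brute-force sort oracle on a shuffled copy
  set.seed(9)
  sh <- res[sample(nrow(res)), ]
  top3 <- rank_top_events(sh, alpha = 0.05)
  key <- order(sh$p_value, -(sh$count_S + sh$count_R),
               -ifelse(sh$sr_ratio == 0, Inf, abs(log(sh$sr_ratio))), sh$loci)
  keep <- sh$p_value <= 0.05
  expect_identical(top3$loci, sh$loci[key][sh$p_value[key] <= 0.05])
})
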