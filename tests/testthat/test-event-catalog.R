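test_that("mutation table parsing handles valid rows, schema errors and duplicates", {
  rec <- load_mutation_table(tiny_mutation_file())
  expect_equal(nrow(rec), 3)
  expect_equal(rec$mutated, c(TRUE, TRUE, FALSE))

  bad <- write_fixture(c("cell_line\tgene\tmutated", "L1\tKRAS\t1"))
  expect_error(load_mutation_table(bad), "locus")

  dup <- write_fixture(c("cell_line\tlocus\tmutated",
                         "L1\tKRAS\t1", "L1\tKRAS\ttrue", "L2\tKRAS\t0"))
  expect_equal(nrow(load_mutation_table(dup)), 2)

  conflict <- write_fixture(c("cell_line\tlocus\tmutated",
                              "L1\tKRAS\t1", "L1\tKRAS\t0"))
  expect_error(load_mutation_table(conflict), "conflicting")

  notbool <- write_fixture(c("cell_line\tlocus\tmutated", "L1\tKRAS\tmaybe"))
  expect_error(load_mutation_table(notbool), "row 1")
})

test_that("copy-number table enforces non-negative integers and round-trips", {
  ok <- write_fixture(c("cell_line\tlocus\ttotal_copy_number", "L1\tKRAS\t2"))
  rec <- load_copy_number_table(ok)
  expect_identical(rec$total_copy_number, 2L)

  neg <- write_fixture(c("cell_line\tlocus\ttotal_copy_number", "L1\tMYC\t-1"))
  expect_error(load_copy_number_table(neg), "non-negative")

  frac <- write_fixture(c("cell_line\tlocus\ttotal_copy_number", "L1\tMYC\t2.5"))
  expect_error(load_copy_number_table(frac), "integer")

  set.seed(1)
  big <- data.frame(
    cell_line = sprintf("L%04d", sample(1000)),
    locus = sample(LETTERS, 1000, replace = TRUE),
    total_copy_number = sample(0:12, 1000, replace = TRUE),
    stringsAsFactors = FALSE
  )
  p1 <- tempfile(); p2 <- tempfile()
  write_copy_number_table(big, p1)
  write_copy_number_table(load_copy_number_table(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("lineage table maps cell lines, rejects conflicts, unknown is a sentinel", {
  ok <- write_fixture(c("cell_line\tlineage", "L1\tMelanoma", "L2\tColon"))
  lin <- load_lineage_table(ok)
  expect_identical(lin[["L1"]], "Melanoma")
  expect_identical(lineage_of(lin, c("L2", "L9")), c("Colon", "unknown"))

  conflict <- write_fixture(c("cell_line\tlineage",
                              "L1\tMelanoma", "L1\tColon"))
  expect_error(load_lineage_table(conflict), "conflicting")
})

test_that("event calling applies the mutation / deletion / amplification rules", {
  mut <- data.frame(cell_line = "L1", locus = "KRAS", mutated = TRUE,
                    stringsAsFactors = FALSE)
  cn <- data.frame(cell_line = rep("L2", 4),
                   locus = c("KRAS", "MYC", "PTEN", "RB1"),
                   total_copy_number = c(2L, 8L, 0L, 7L),
                   stringsAsFactors = FALSE)
  m <- build_event_matrix(mut, cn)
  expect_true(m$events["L1", "KRAS"])    # mutation alone suffices
  expect_false(m$events["L2", "KRAS"])   # CN = 2 is no event
  expect_true(m$events["L2", "MYC"])     # amplification at CN >= 8
  expect_true(m$events["L2", "PTEN"])    # homozygous deletion at CN = 0
  expect_false(m$events["L2", "RB1"])    # CN = 7 is below the threshold

  empty <- build_event_matrix(mut[0, ], cn[0, ])
  expect_equal(dim(empty$events), c(0, 0))
  expect_error(build_event_matrix(mut, cn, amplification_threshold = 0),
               "smaller")
})

test_that("event count is monotone as the amplification threshold decreases", {
  set.seed(7)
  cn <- data.frame(
    cell_line = rep(sprintf("L%02d", 1:20), each = 5),
    locus = rep(paste0("g", 1:5), 20),
    total_copy_number = sample(0:12, 100, replace = TRUE),
    stringsAsFactors = FALSE
  )
  counts <- vapply(c(12, 10, 8, 6, 4, 2),
                   function(th) sum(build_event_matrix(NULL, cn,
                     amplification_threshold = th)$events),
                   numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("matrix construction is invariant to input row order", {
  set.seed(11)
  mut <- data.frame(
    cell_line = sample(sprintf("L%02d", 1:15), 40, replace = TRUE),
    locus = sample(paste0("g", 1:8), 40, replace = TRUE),
    mutated = TRUE, stringsAsFactors = FALSE
  )
  mut <- mut[!duplicated(mut[c("cell_line", "locus")]), ]
  m1 <- build_event_matrix(mut, NULL)
  m2 <- build_event_matrix(mut[sample(nrow(mut)), ], NULL)
  expect_identical(m1$events, m2$events)
})

test_that("locus frequencies match direct counts and sum to total events", {
  set.seed(3)
  ev <- matrix(runif(300) < 0.3, 30, 10,
               dimnames = list(sprintf("L%02d", 1:30), sprintf("g%02d", 1:10)))
  m <- new_event_matrix(ev)
  f <- locus_frequencies(m)
  expect_equal(unname(f), unname(colSums(ev) / 30))
  expect_equal(sum(f * 30), sum(ev))

  sub <- sample(rownames(ev), 12)
  fs <- locus_frequencies(m, subset = sub)
  expect_equal(unname(fs), unname(colSums(ev[sub, ]) / 12))
  expect_equal(unname(locus_frequencies(m, subset = "L01")),
               unname(ev["L01", ] * 1))
  expect_error(locus_frequencies(m, subset = character(0)), "empty")
})

test_that("events table round-trips through writer and reader", {
  m <- tiny_matrix()
  path <- tempfile()
  write_events_tsv(m, path)
  m2 <- read_events_tsv(path)
  # writer emits only true entries, so loci/lines with no events drop out
  expect_identical(m2$events, m$events[rowSums(m$events) > 0,
                                       colSums(m$events) > 0])
})
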