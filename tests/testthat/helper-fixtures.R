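# Shared fixtures: tiny tables written to tempfiles, small matrices with
# hand-countable structure, and independent oracles used across test files.

write_fixture <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

tiny_mutation_file <- function() {
  write_fixture(c(
    "cell_line\tlocus\tmutated",
    "L1\tKRAS\t1",
    "L1\tTP53\tTRUE",
    "L2\tKRAS\t0"
  ))
}

# small deterministic event matrix: 6 lines x 4 loci
tiny_matrix <- function(lineage = NULL) {
  ev <- matrix(FALSE, 6, 4,
               dimnames = list(paste0("L", 1:6), c("A", "B", "C", "D")))
  ev[c(1, 2, 3), "A"] <- TRUE
  ev[c(1, 2, 5), "B"] <- TRUE
  ev[c(4, 5), "C"] <- TRUE
  ev[1, "D"] <- TRUE
  new_event_matrix(ev, lineage)
}

# a response call with a prescribed S/R split (bypasses curve fitting)
manual_call <- function(S, R, drug = "drug1") {
  n <- length(S) + length(R)
  structure(list(
    drug = drug, ordered_cell_lines = c(S, R),
    gi = seq_len(n), inflection_index = length(S),
    cutoff_gi = length(S) + 0.5, sensitive = S, resistant = R,
    degenerate = FALSE
  ), class = "response_call")
}

# independent oracle: two-sided Fisher p by exhaustive hypergeometric
# enumeration over all tables with the observed margins
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  probs <- stats::dhyper(x, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# independent oracle: BH step-up rejection set by direct rule
bh_stepup <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  below <- which(ps <= (seq_len(m) / m) * q)
  out <- logical(m)
  if (length(below)) out[ord[seq_len(max(below))]] <- TRUE
  out
}

# independent oracle: naive O(n^3) average-linkage merge heights
naive_average_linkage_heights <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, n + (n - 1))
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); best_h <- Inf
    ids <- which(active[seq_along(clusters)])
    for (i in ids) for (j in ids) if (i < j) {
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best_h - 1e-12) { best_h <- h; best <- c(i, j) }
    }
    heights[step] <- best_h
    clusters[[length(clusters) + 1]] <- c(clusters[[best[1]]],
                                          clusters[[best[2]]])
    active[best] <- FALSE
    active[length(clusters)] <- TRUE
  }
  heights
}
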