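# Scaled growth-inhibition profiles and hierarchical clustering of drugs and
# cell lines with a Pearson-correlation metric and average linkage.

#' Median-center and normalize GI profiles
#'
#' For each drug (column), non-missing GI values are median-centered and
#' then scaled so the column sum of squares is 1 (the Cluster-3.0
#' "normalize" convention), producing a potency-independent scaled growth
#' inhibition score. Missing entries (untested combinations) stay missing.
#' Columns that are constant after centering cannot be normalized and are
#' flagged; columns with everything missing are dropped.
#'
#' @param gi_matrix Numeric matrix, rows cell lines, columns drugs, `NA`
#'   for untested combinations.
#' @param min_values Minimum non-missing values per column (default 3).
#' @param unit_variance Use the unit-variance reading of "normalized"
#'   (divide by the standard deviation) instead of unit sum of squares.
#'   Default `FALSE`.
#' @return Matrix of the same shape (minus dropped columns) with attributes
#'   `flagged_constant` and `dropped_columns`.
#' @export
scale_profiles <- function(gi_matrix, min_values = 3L, unit_variance = FALSE) {
  stopifnot(is.matrix(gi_matrix), is.numeric(gi_matrix))
  n_ok <- colSums(!is.na(gi_matrix))
  dropped <- colnames(gi_matrix)[n_ok == 0]
  gi_matrix <- gi_matrix[, n_ok > 0, drop = FALSE]
  n_ok <- n_ok[n_ok > 0]
  if (any(n_ok < min_values)) {
    stop(sprintf("column '%s' has fewer than %d non-missing values",
                 colnames(gi_matrix)[which(n_ok < min_values)[1]], min_values),
         call. = FALSE)
  }
  flagged <- character(0)
  out <- gi_matrix
  for (j in seq_len(ncol(out))) {
    v <- out[, j]
    ok <- !is.na(v)
    v[ok] <- v[ok] - stats::median(v[ok])
    norm <- if (unit_variance) stats::sd(v[ok]) else sqrt(sum(v[ok]^2))
    if (is.na(norm) || norm < .Machine$double.eps^0.5) {
      flagged <- c(flagged, colnames(out)[j])
    } else {
      v[ok] <- v[ok] / norm
    }
    out[, j] <- v
  }
  attr(out, "flagged_constant") <- flagged
  attr(out, "dropped_columns") <- dropped
  out
}

#' Pearson distance between two profiles
#'
#' `d = 1 - r` over pairwise-complete positions; in `[0, 2]`.
#'
#' @param u,v Numeric vectors of equal length, `NA` allowed.
#' @param min_complete Minimum pairwise-complete positions (default 3);
#'   below this the distance is undefined (`NA` with a warning).
#' @return The distance, or `NA`.
#' @export
pearson_distance <- function(u, v, min_complete = 3L) {
  ok <- !is.na(u) & !is.na(v)
  if (sum(ok) < min_complete) {
    warning("fewer than ", min_complete,
            " pairwise-complete positions; distance undefined")
    return(NA_real_)
  }
  1 - stats::cor(u[ok], v[ok])
}

#' Pairwise Pearson distance matrix over one axis
#'
#' @param mat Numeric matrix (rows cell lines, columns drugs), `NA` allowed.
#' @param axis `"drugs"` (columns, default) or `"cell_lines"` (rows).
#' @param min_complete Passed to the pairwise correlations.
#' @return Symmetric distance matrix (`NA` for undefined pairs).
#' @export
pearson_distance_matrix <- function(mat, axis = c("drugs", "cell_lines"),
                                    min_complete = 3L) {
  axis <- match.arg(axis)
  x <- if (axis == "drugs") mat else t(mat)
  n <- ncol(x)
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  # cor() happily returns values from < min_complete pairs; mask those
  complete <- crossprod(!is.na(x) * 1L)
  r[complete < min_complete] <- NA
  d <- 1 - r
  diag(d) <- 0
  d
}

#' Average-linkage hierarchical clustering with the Pearson metric
#'
#' UPGMA over the `1 - r` distance matrix. Entities with undefined
#' distances to any other entity are left out of the tree and appended as
#' singletons in the reported leaf order (with a warning).
#'
#' @inheritParams pearson_distance_matrix
#' @return A list of class `cluster_tree` with `merge`, `height`, `order`,
#'   `labels` (the clustered entities), `singletons` (entities excluded for
#'   undefined distances) and `leaf_order` (clustered leaves then
#'   singletons).
#' @export
hierarchical_cluster <- function(mat, axis = c("drugs", "cell_lines"),
                                 min_complete = 3L) {
  axis <- match.arg(axis)
  d <- pearson_distance_matrix(mat, axis, min_complete)
  singles <- character(0)
  # iteratively shed the entity with the most undefined distances until the
  # remaining distance matrix is complete
  while (nrow(d) > 2 && anyNA(d)) {
    n_na <- rowSums(is.na(d))
    worst <- which.max(n_na)
    singles <- c(singles, rownames(d)[worst])
    d <- d[-worst, -worst, drop = FALSE]
  }
  labels <- colnames(d)
  if (length(singles)) {
    warning("entities with undefined distances appended as singletons: ",
            paste(singles, collapse = ", "))
  }
  if (length(labels) < 2) {
    stop("need at least 2 entities with defined pairwise distances",
         call. = FALSE)
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = labels, singletons = singles,
                 leaf_order = c(labels[hc$order], singles)),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("cluster_tree: %d leaves (+%d singletons), height range [%g, %g]\n",
              length(x$labels), length(x$singletons),
              min(x$height), max(x$height)))
  invisible(x)
}

#' Mean pairwise correlation of a drug subcluster
#'
#' @param mat Scaled response matrix (rows cell lines, columns drugs).
#' @param members Drug identifiers (at least 2).
#' @param min_complete Minimum pairwise-complete positions per pair.
#' @return List with `mean_r`, `n_pairs` (defined pairs used) and
#'   `n_undefined`.
#' @export
subcluster_correlation <- function(mat, members, min_complete = 3L) {
  stopifnot(length(members) >= 2, all(members %in% colnames(mat)))
  x <- mat[, members, drop = FALSE]
  r <- suppressWarnings(stats::cor(x, use = "pairwise.complete.obs"))
  complete <- crossprod(!is.na(x) * 1L)
  r[complete < min_complete] <- NA
  vals <- r[upper.tri(r)]
  list(mean_r = mean(vals, na.rm = TRUE),
       n_pairs = sum(!is.na(vals)),
       n_undefined = sum(is.na(vals)))
}

#' Assemble a GI matrix from a list of screens
#'
#' @param screens List of `drug_screen` objects.
#' @return Numeric matrix, rows = union of cell lines (sorted), columns =
#'   drugs (sorted), `NA` where untested.
#' @export
gi_matrix_from_screens <- function(screens) {
  cl <- sort(unique(unlist(lapply(screens, function(s) names(s$gi)))))
  drugs <- sort(vapply(screens, function(s) s$drug, character(1)))
  out <- matrix(NA_real_, length(cl), length(drugs),
                dimnames = list(cl, drugs))
  for (s in screens) out[names(s$gi), s$drug] <- s$gi
  out
}
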