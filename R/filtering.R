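#' Descriptor pre-filtering
#'
#' The three elimination tests applied before variable selection, in order:
#' drop descriptors with any missing value, drop descriptors whose fraction
#' of non-zero values is below a threshold, and greedily drop the later
#' member of every descriptor pair whose squared Pearson correlation
#' exceeds a threshold. Each removal is recorded with its reason.
#'
#' @name feature_filtering
NULL

#' @describeIn feature_filtering drop every column containing a missing value.
#' @param m numeric matrix with named columns (a [descriptor_matrix()] works).
#' @return for the individual tests, a list with `keep` (surviving column
#'   names) and `removed` (named removals); [filter_descriptors()] returns
#'   a list with the filtered `matrix` and a `report` of class
#'   `filter_report`.
#' @export
missing_values_test <- function(m) {
  bad <- colnames(m)[apply(m, 2, function(x) any(is.na(x)))]
  list(keep = setdiff(colnames(m), bad), removed = bad)
}

#' @describeIn feature_filtering drop columns with too few non-zero entries.
#' @param min_nonzero_fraction minimum admissible fraction of non-zero
#'   values, in (0, 1]. Kept when the fraction is greater than or equal to
#'   the threshold.
#' @export
zero_test <- function(m, min_nonzero_fraction = 0.1) {
  stopifnot(min_nonzero_fraction > 0, min_nonzero_fraction <= 1)
  frac <- apply(m, 2, function(x) mean(x != 0, na.rm = TRUE))
  bad <- colnames(m)[frac < min_nonzero_fraction]
  list(keep = setdiff(colnames(m), bad),
       removed = stats::setNames(frac[bad], bad))
}

#' @describeIn feature_filtering greedy pairwise-correlation pruning. Columns
#'   are scanned in fixed order; whenever a pair with squared correlation
#'   above `r2_threshold` is met, the later column is dropped, so the
#'   surviving set has all pairwise R^2 at or below the threshold.
#'   Zero-variance columns are removed first (recorded separately).
#' @param r2_threshold maximum admissible pairwise R^2 (the published
#'   workflow used 0.7).
#' @export
correlation_prune <- function(m, r2_threshold = 0.7) {
  if (ncol(m) < 2) stop("need at least two columns")
  sds <- apply(m, 2, stats::sd)
  constant <- colnames(m)[sds == 0 | is.na(sds)]
  cols <- setdiff(colnames(m), constant)
  r <- stats::cor(m[, cols, drop = FALSE])
  keep <- logical(length(cols))
  dropped <- list()
  for (j in seq_along(cols)) {
    prior <- which(keep)
    conflict <- prior[r[prior, j]^2 > r2_threshold]
    if (length(conflict)) {
      dropped[[cols[j]]] <- list(kept = cols[conflict[1]],
                                 r2 = unname(r[conflict[1], j]^2))
    } else keep[j] <- TRUE
  }
  list(keep = cols[keep], removed = dropped, removed_constant = constant)
}

#' @describeIn feature_filtering run all three tests in sequence.
#' @export
filter_descriptors <- function(m, min_nonzero_fraction = 0.1, r2_threshold = 0.7) {
  mv <- missing_values_test(m)
  m1 <- m[, mv$keep, drop = FALSE]
  zt <- zero_test(m1, min_nonzero_fraction)
  m2 <- m1[, zt$keep, drop = FALSE]
  cp <- correlation_prune(m2, r2_threshold)
  m3 <- m2[, cp$keep, drop = FALSE]
  report <- structure(list(
    removed_by_missing = mv$removed,
    removed_by_zero = zt$removed,
    removed_by_constant = cp$removed_constant,
    removed_by_correlation = cp$removed,
    surviving = cp$keep,
    thresholds = list(min_nonzero_fraction = min_nonzero_fraction,
                      r2_threshold = r2_threshold)
  ), class = "filter_report")
  list(matrix = m3, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:",
      length(x$removed_by_missing), "removed (missing),",
      length(x$removed_by_zero), "removed (zero test),",
      length(x$removed_by_constant), "removed (constant),",
      length(x$removed_by_correlation), "removed (correlation),",
      length(x$surviving), "surviving\n")
  invisible(x)
}

#' Cluster-based external test-set selection
#'
#' Reproduces the tree-clustering route to an external test set: the
#' descriptor block and the activity are z-scored column-wise, a
#' single-linkage hierarchical clustering is built on Euclidean distances,
#' the tree is cut into `n_test` clusters, and the medoid of each cluster
#' (the member with the smallest summed within-cluster distance; ties go to
#' the lowest row index) becomes a test compound.
#'
#' @param m numeric descriptor matrix, one row per compound.
#' @param activity numeric response vector aligned with the rows of `m`.
#' @param n_test number of test compounds (= number of clusters).
#' @param linkage `"single"` (the published choice) or `"complete"`.
#' @return character vector: `"test"`/`"train"` per row of `m`.
#' @export
select_test_set <- function(m, activity, n_test = 8, linkage = c("single", "complete")) {
  linkage <- match.arg(linkage)
  stopifnot(length(activity) == nrow(m))
  if (n_test < 1 || n_test >= nrow(m)) stop("need 1 <= n_test < number of rows")
  z <- cbind(m, activity = activity)
  z <- apply(z, 2, function(col) {
    s <- stats::sd(col)
    if (s > 0) (col - mean(col)) / s else rep(0, length(col))
  })
  d <- stats::dist(z)
  cl <- stats::cutree(stats::hclust(d, method = linkage), k = n_test)
  dm <- as.matrix(d)
  test_idx <- vapply(seq_len(n_test), function(k) {
    members <- which(cl == k)
    if (length(members) == 1) return(members)
    tot <- rowSums(dm[members, members, drop = FALSE])
    members[which.min(tot)]          # which.min takes the first = lowest index
  }, integer(1))
  out <- rep("train", nrow(m))
  out[test_idx] <- "test"
  out
}

#' Serialize a filter report to JSON
#'
#' @param report a `filter_report` from [filter_descriptors()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
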