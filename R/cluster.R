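#' Uncentered correlation distance between two profiles
#'
#' `d = 1 - sum(x*y) / sqrt(sum(x^2) * sum(y^2))` over pairwise-complete
#' positions (entries missing in either vector are dropped). Unlike Pearson
#' distance the profiles are not centred, so two profiles must agree in both
#' shape and sign to be close — appropriate for GI profiles where the zero
#' point (no growth inhibition) is meaningful. The value lies in [0, 2]; it
#' is symmetric with d(x, x) = 0, but it is not a metric (no triangle
#' inequality).
#'
#' @param x,y Numeric vectors of equal length; `NA`s dropped pairwise, with at
#'   least `min_complete` complete positions required.
#' @param min_complete Minimum pairwise-complete positions (default 2).
#' @return The distance, a scalar in [0, 2].
#' @export
uncentered_corr_distance <- function(x, y, min_complete = 2) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_complete) {
    abort(sprintf("fewer than %d pairwise-complete positions.", min_complete))
  }
  x <- x[ok]; y <- y[ok]
  nx <- sum(x^2); ny <- sum(y^2)
  if (nx == 0 || ny == 0) {
    abort("zero vector after missing-data removal; distance undefined.")
  }
  1 - sum(x * y) / sqrt(nx * ny)
}

#' Pairwise uncentered-correlation distance matrix for GI profiles
#'
#' @param gi_matrix Tibble with `mutant_id` and one numeric column per screen
#'   (missing GI values allowed).
#' @param min_complete Minimum pairwise-complete screens per pair.
#' @return A `dist` object over the mutants.
#' @export
gi_distance <- function(gi_matrix, min_complete = 2) {
  assert_count_table(gi_matrix)
  m <- as.matrix(gi_matrix[setdiff(names(gi_matrix), "mutant_id")])
  rownames(m) <- gi_matrix$mutant_id
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d[i, j] <- d[j, i] <- uncentered_corr_distance(m[i, ], m[j, ], min_complete)
    }
  }
  as.dist(d)
}

#' Average-linkage (UPGMA) hierarchical clustering of a distance matrix
#'
#' Unweighted average linkage over the supplied dissimilarities. Average
#' linkage is monotone, so merge heights never decrease. Missing values must
#' be resolved at the distance step (pairwise-complete deletion in
#' [gi_distance()]); a `NaN`/`NA` in the matrix is an error here.
#'
#' @param d A `dist` object or symmetric matrix with zero diagonal.
#' @return A `barseq_dendrogram`: list with `hclust` (the fitted tree),
#'   `merges` (tibble of merge heights) and `labels`.
#' @export
average_linkage <- function(d) {
  if (is.matrix(d)) {
    if (!isSymmetric(unname(d)) || any(diag(d) != 0)) {
      abort("`d` must be symmetric with a zero diagonal.")
    }
    d <- as.dist(d)
  }
  if (anyNA(d) || any(!is.finite(d))) {
    abort("distance matrix contains missing or non-finite entries; resolve missing data at the distance step.")
  }
  hc <- hclust(d, method = "average")
  structure(
    list(hclust = hc,
         merges = tibble(step = seq_along(hc$height), height = hc$height),
         labels = hc$labels),
    class = "barseq_dendrogram"
  )
}

#' @export
print.barseq_dendrogram <- function(x, ...) {
  cat(sprintf("<barseq_dendrogram> %d leaves, %d merges, heights %.3g..%.3g\n",
              length(x$labels), nrow(x$merges),
              min(x$merges$height), max(x$merges$height)))
  invisible(x)
}

#' Export a dendrogram to Newick
#'
#' @param dendro A `barseq_dendrogram` from [average_linkage()].
#' @param path Optional output path; if `NULL` the Newick string is returned.
#' @return The Newick string (invisibly when written to a file).
#' @export
as_newick <- function(dendro, path = NULL) {
  phy <- ape::as.phylo(dendro$hclust)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}

#' Cluster-ordered GI matrix for heat-map rendering
#'
#' Reorders the rows of a GI matrix by the dendrogram's left-to-right leaf
#' order, the layout used for clustergram displays.
#'
#' @param gi_matrix Tibble with `mutant_id` + screen columns.
#' @param dendro A `barseq_dendrogram` over the same mutants.
#' @return The reordered tibble.
#' @export
ordered_gi_matrix <- function(gi_matrix, dendro) {
  ord <- dendro$hclust$labels[dendro$hclust$order]
  gi_matrix[match(ord, gi_matrix$mutant_id), ]
}
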